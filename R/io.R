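#' @include AllClasses.R
NULL

#' Default residue-name to species mapping
#'
#' PDB/GRO files carry no solvent/protein species field, so species tags are
#' assigned from residue names. Unlisted residue names are tagged
#' \code{"protein"}.
#'
#' @return named character vector mapping residue name to species.
#' @export
defaultSpeciesMap <- function() {
  c(SOL = "water", HOH = "water", WAT = "water", TIP = "water",
    DCM = "organic", MCL = "organic", ORG = "organic")
}

.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974)

# Guess an element from an atom name (strip digits, first letter wins).
.guessMass <- function(name, resname, massMap = NULL) {
  if (!is.null(massMap) && resname %in% names(massMap))
    return(unname(massMap[resname]))
  el <- toupper(substr(gsub("[0-9 ]", "", name), 1, 1))
  m <- .ELEMENT_MASS[el]
  if (is.na(m)) m <- 12.011
  unname(m)
}

.speciesFromResname <- function(resname, speciesMap) {
  sp <- unname(speciesMap[resname])
  sp[is.na(sp)] <- "protein"
  sp
}

#' Read a structure file into a Topology and a one-frame Trajectory
#'
#' Supports PDB (via bio3d; coordinates converted from Angstrom to nm) and
#' GRO (native nm). Species tags are assigned from residue names via
#' \code{speciesMap}; particle masses from \code{massMap} (residue name to
#' mass in u) where given, otherwise from the element implied by the atom
#' name.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or \code{"gro"}.
#' @param speciesMap residue-name to species mapping, see
#'   [defaultSpeciesMap()].
#' @param massMap optional named vector, residue name to particle mass (u).
#' @return list with elements \code{topology} ([Topology-class]) and
#'   \code{trajectory} (one-frame [Trajectory-class]).
#' @examples
#' gro <- tempfile(fileext = ".gro")
#' top <- Topology(name = "OW", species = "water", mass = 18, resname = "SOL")
#' writeStructure(top, matrix(c(1, 2, 3), 1), c(5, 5, 5), gro)
#' st <- readStructure(gro)
#' frameCoords(st$trajectory, 1)
#' @export
readStructure <- function(path, format = c("auto", "pdb", "gro"),
                          speciesMap = defaultSpeciesMap(), massMap = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", gro = "gro",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  if (format == "pdb") .readStructurePDB(path, speciesMap, massMap)
  else .readStructureGRO(path, speciesMap, massMap)
}

.readStructurePDB <- function(path, speciesMap, massMap) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  coords <- cbind(a$x, a$y, a$z) / 10  # Angstrom -> nm
  resname <- trimws(a$resid)
  top <- Topology(name = trimws(a$elety),
                  species = .speciesFromResname(resname, speciesMap),
                  mass = vapply(seq_len(nrow(a)), function(i)
                    .guessMass(a$elety[i], resname[i], massMap), 1.0),
                  chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
                  resid = as.integer(a$resno),
                  resname = resname,
                  atomId = as.integer(a$eleno))
  box <- c(10, 10, 10)
  if (!is.null(pdb$cryst1) && length(pdb$cryst1$abc) == 3 &&
      all(is.finite(pdb$cryst1$abc)) && all(pdb$cryst1$abc > 0))
    box <- pdb$cryst1$abc / 10
  list(topology = top, trajectory = Trajectory(coords, box, 0))
}

.parseGROBlock <- function(lines, start, path) {
  title <- lines[start]
  natoms <- suppressWarnings(as.integer(trimws(lines[start + 1L])))
  if (is.na(natoms))
    stop("malformed GRO atom-count line ", start + 1L, " in ", path)
  end <- start + 1L + natoms + 1L
  if (end > length(lines))
    stop("truncated GRO frame starting at line ", start, " in ", path)
  al <- lines[(start + 2L):(start + 1L + natoms)]
  resid <- as.integer(substr(al, 1, 5))
  resname <- trimws(substr(al, 6, 10))
  name <- trimws(substr(al, 11, 15))
  x <- as.numeric(substr(al, 21, 28))
  y <- as.numeric(substr(al, 29, 36))
  z <- as.numeric(substr(al, 37, 44))
  if (any(is.na(c(x, y, z))))
    stop("malformed GRO coordinate in frame starting at line ", start,
         " of ", path)
  box <- as.numeric(strsplit(trimws(lines[end]), "\\s+")[[1]])[1:3]
  tm <- 0
  m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  if (length(m)) tm <- as.numeric(sub("t=\\s*", "", m))
  list(natoms = natoms, resid = resid, resname = resname, name = name,
       coords = cbind(x, y, z), box = box, time = tm, nextStart = end + 1L)
}

.readStructureGRO <- function(path, speciesMap, massMap) {
  lines <- readLines(path)
  blk <- .parseGROBlock(lines, 1L, path)
  top <- Topology(name = blk$name,
                  species = .speciesFromResname(blk$resname, speciesMap),
                  mass = vapply(seq_len(blk$natoms), function(i)
                    .guessMass(blk$name[i], blk$resname[i], massMap), 1.0),
                  chain = "A", resid = blk$resid, resname = blk$resname)
  list(topology = top,
       trajectory = Trajectory(blk$coords, blk$box, blk$time))
}

#' Write a single frame as a GRO file
#'
#' @param topology a [Topology-class].
#' @param coords \code{[nAtoms, 3]} matrix (nm).
#' @param box length-3 box edge vector (nm).
#' @param path output path.
#' @param time frame time (ps), written into the title line.
#' @export
writeStructure <- function(topology, coords, box, path, time = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  .writeGROFrame(con, topology, coords, box, time)
  invisible(path)
}

.writeGROFrame <- function(con, topology, coords, box, time) {
  a <- atomData(topology)
  writeLines(sprintf("slabtraj frame t= %.4f", time), con)
  writeLines(sprintf("%5d", nrow(a)), con)
  writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     a$resid %% 100000L, substr(a$resname, 1, 5),
                     substr(a$name, 1, 5), a$atomId %% 100000L,
                     coords[, 1], coords[, 2], coords[, 3]), con)
  writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
}

#' Read a multi-frame trajectory
#'
#' Multi-frame GRO carries the box per frame; the XYZ dialect stores
#' coordinates in nm with \code{time= <ps> box= <Lx> <Ly> <Lz>} on the
#' comment line. The frame atom count must match the topology.
#'
#' @param path file path.
#' @param topology the [Topology-class] the frames belong to.
#' @param format \code{"auto"}, \code{"gro"} or \code{"xyz"}.
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(path, topology, format = c("auto", "gro", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), gro = "gro",
                     xyz = "xyz", stop("cannot infer trajectory format"))
  lines <- readLines(path)
  frames <- list()
  if (format == "gro") {
    start <- 1L
    while (start <= length(lines) && nzchar(trimws(lines[start]))) {
      blk <- tryCatch(.parseGROBlock(lines, start, path), error = function(e)
        stop("frame ", length(frames) + 1L, ": ", conditionMessage(e)))
      frames[[length(frames) + 1L]] <- blk
      start <- blk$nextStart
    }
  } else {
    start <- 1L
    while (start <= length(lines) && nzchar(trimws(lines[start]))) {
      natoms <- suppressWarnings(as.integer(trimws(lines[start])))
      if (is.na(natoms))
        stop("frame ", length(frames) + 1L, ": malformed XYZ count line")
      if (start + 1L + natoms > length(lines))
        stop("frame ", length(frames) + 1L, ": truncated XYZ frame")
      comment <- lines[start + 1L]
      toks <- strsplit(trimws(lines[(start + 2L):(start + 1L + natoms)]),
                       "\\s+")
      if (any(lengths(toks) < 4))
        stop("frame ", length(frames) + 1L, ": malformed XYZ atom line")
      xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
      if (any(is.na(xyz)))
        stop("frame ", length(frames) + 1L, ": non-numeric XYZ coordinate")
      tm <- 0; box <- c(NA_real_, NA_real_, NA_real_)
      m <- regmatches(comment, regexpr("time=\\s*[-0-9.eE+]+", comment))
      if (length(m)) tm <- as.numeric(sub("time=\\s*", "", m))
      m <- regmatches(comment,
                      regexpr("box=\\s*([-0-9.eE+]+\\s+){2}[-0-9.eE+]+", comment))
      if (length(m))
        box <- as.numeric(strsplit(sub("box=\\s*", "", m), "\\s+")[[1]])
      if (any(is.na(box)))
        stop("frame ", length(frames) + 1L,
             ": XYZ comment line must carry box= Lx Ly Lz")
      frames[[length(frames) + 1L]] <-
        list(natoms = natoms, coords = xyz, box = box, time = tm)
      start <- start + 2L + natoms
    }
  }
  if (!length(frames)) stop("no frames found in ", path)
  nat <- vapply(frames, `[[`, 1L, "natoms")
  if (any(nat != nAtoms(topology)))
    stop("frame ", which(nat != nAtoms(topology))[1], ": atom count ",
         nat[nat != nAtoms(topology)][1], " does not match topology (",
         nAtoms(topology), ")")
  coords <- array(0, c(nat[1], 3, length(frames)))
  for (i in seq_along(frames)) coords[, , i] <- frames[[i]]$coords
  Trajectory(coords,
             do.call(rbind, lapply(frames, `[[`, "box")),
             vapply(frames, `[[`, 0, "time"))
}

#' Write a trajectory as multi-frame GRO or XYZ
#'
#' @param trajectory a [Trajectory-class].
#' @param topology matching [Topology-class].
#' @param path output path; extension selects the format unless given.
#' @param format \code{"auto"}, \code{"gro"} or \code{"xyz"}.
#' @export
writeTrajectory <- function(trajectory, topology, path,
                            format = c("auto", "gro", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), gro = "gro",
                     xyz = "xyz", stop("cannot infer trajectory format"))
  con <- file(path, "w")
  on.exit(close(con))
  nm <- atomData(topology)$name
  for (i in seq_len(nFrames(trajectory))) {
    cf <- trajectory@coords[, , i]
    if (format == "gro") {
      .writeGROFrame(con, topology, cf, trajectory@box[i, ],
                     trajectory@time[i])
    } else {
      writeLines(sprintf("%d", nrow(cf)), con)
      writeLines(sprintf("# time= %.4f box= %.5f %.5f %.5f (nm)",
                         trajectory@time[i], trajectory@box[i, 1],
                         trajectory@box[i, 2], trajectory@box[i, 3]), con)
      writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", substr(nm, 1, 4),
                         cf[, 1], cf[, 2], cf[, 3]), con)
    }
  }
  invisible(path)
}

.PRESSURE_ALIASES <- list(
  time = c("time", "t", "time_ps"),
  Pxx = c("pxx", "p_xx"), Pyy = c("pyy", "p_yy"), Pzz = c("pzz", "p_zz"),
  Lx = c("lx", "l_x", "box_x"), Ly = c("ly", "l_y", "box_y"),
  Lz = c("lz", "l_z", "box_z"))

#' Read a pressure-tensor table
#'
#' Delimited text (tab, comma or whitespace, auto-detected) with named
#' columns. Columns are matched by header name, case-insensitively, with
#' common aliases (\code{P_XX}/\code{Pxx}, \code{L_X}/\code{Lx});
#' unrecognised columns are ignored. Units are assumed bar and nm.
#'
#' @param path file path.
#' @return a [PressureSeries-class].
#' @export
readPressureTable <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  df <- read.table(path, header = TRUE, sep = sep,
                   stringsAsFactors = FALSE, check.names = FALSE)
  lower <- tolower(gsub("[^a-z0-9_]", "", tolower(names(df))))
  out <- list()
  for (canon in names(.PRESSURE_ALIASES)) {
    hit <- which(lower %in% c(tolower(canon), .PRESSURE_ALIASES[[canon]]))
    if (length(hit)) out[[canon]] <- as.numeric(df[[hit[1]]])
  }
  need <- c("Pxx", "Pyy", "Pzz", "Lx", "Ly", "Lz")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("pressure table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(out$time)) out$time <- as.numeric(seq_len(nrow(df)) - 1L)
  PressureSeries(as.data.frame(out)[, c("time", need)])
}

#' Write a pressure-tensor table as TSV
#'
#' @param series a [PressureSeries-class].
#' @param path output path.
#' @export
writePressureTable <- function(series, path) {
  d <- pressureData(series)
  d <- cbind(frame = seq_len(nrow(d)) - 1L, d)
  names(d) <- c("frame", "time", "P_xx", "P_yy", "P_zz", "L_x", "L_y", "L_z")
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
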