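#' @include AllClasses.R io.R
NULL

#' Per-residue contact frequencies over a docked-complex ensemble
#'
#' A receptor residue counts as contacting in a model iff at least one of
#' its atoms lies within the cutoff of any ligand-chain atom
#' (\code{mode = "atom"}, default; \code{mode = "residue"} compares
#' residue centres of mass instead). The frequency is the fraction of
#' models in which the residue contacts. Residue numbering must be
#' consistent across models.
#'
#' @param models list of models, each a list with \code{topology}
#'   ([Topology-class]) and \code{coords} (\code{[nAtoms, 3]} nm), e.g.
#'   from [makeComplexEnsemble()] or [readEnsemble()].
#' @param receptorChains chain ids of the receptor.
#' @param ligandChains chain ids of the partner protein.
#' @param cutoff contact cutoff (nm); default 0.5.
#' @param mode \code{"atom"} or \code{"residue"}.
#' @return a [ContactFrequencyMap-class].
#' @export
contactFrequency <- function(models, receptorChains = "R",
                             ligandChains = "L", cutoff = 0.5,
                             mode = c("atom", "residue")) {
  mode <- match.arg(mode)
  if (!length(models)) stop("empty ensemble")
  keyOf <- function(top) {
    a <- atomData(top)
    sel <- a$chain %in% receptorChains
    unique(paste(a$chain[sel], a$resid[sel], sep = ":"))
  }
  key <- keyOf(models[[1]]$topology)
  if (!length(key)) stop("no receptor residues found")
  hits <- integer(length(key))
  for (m in seq_along(models)) {
    top <- models[[m]]$topology
    if (!identical(keyOf(top), key))
      stop("model ", m, ": receptor residue numbering is inconsistent ",
           "with model 1")
    a <- atomData(top)
    cf <- models[[m]]$coords
    recSel <- which(a$chain %in% receptorChains)
    ligSel <- which(a$chain %in% ligandChains)
    if (!length(ligSel)) stop("model ", m, ": no ligand atoms")
    contact <- .residueContacts(cf, a, recSel, ligSel, key, cutoff, mode)
    hits <- hits + as.integer(contact)
  }
  parts <- strsplit(key, ":", fixed = TRUE)
  tab <- data.frame(chain = vapply(parts, `[`, "", 1),
                    resid = as.integer(vapply(parts, `[`, "", 2)),
                    frequency = hits / length(models))
  new("ContactFrequencyMap", table = tab,
      nModels = length(models), cutoff = as.numeric(cutoff))
}

# Logical contact vector over receptor residue keys.
.residueContacts <- function(cf, a, recSel, ligSel, key, cutoff, mode) {
  if (cutoff <= 0) return(setNames(rep(FALSE, length(key)), key))
  if (mode == "atom") {
    near <- .hasNeighborWithin(cf[recSel, , drop = FALSE],
                               cf[ligSel, , drop = FALSE], cutoff)
    rk <- paste(a$chain[recSel], a$resid[recSel], sep = ":")
    hit <- vapply(split(near, rk), any, TRUE)
  } else {
    recCom <- .chainResidueCom(cf, a, recSel)
    ligCom <- .chainResidueCom(cf, a, ligSel)
    near <- .hasNeighborWithin(recCom, ligCom, cutoff)
    hit <- setNames(near, rownames(recCom))
  }
  hit[key]
}

.chainResidueCom <- function(cf, a, sel) {
  k <- paste(a$chain[sel], a$resid[sel], sep = ":")
  m <- a$mass[sel]
  num <- rowsum(cf[sel, , drop = FALSE] * m, k)
  den <- as.numeric(rowsum(m, k))
  num / den
}

#' Total model count of a sequential docking campaign
#'
#' A campaign docks a partner to each of several seed structures, carries
#' the top-cluster centre forward for several sequential rounds, and
#' retains the centre structures of a fixed number of clusters at every
#' round, so the ensemble size is the plain product of the three design
#' factors.
#'
#' @param seeds number of seed structures.
#' @param rounds sequential docking rounds.
#' @param clusters cluster centres retained per round.
#' @return total retained models (integer).
#' @examples
#' campaignModelCount(11, 4, 10)  # 440
#' @export
campaignModelCount <- function(seeds, rounds, clusters) {
  v <- c(seeds = seeds, rounds = rounds, clusters = clusters)
  if (any(v != as.integer(v)) || any(v < 1))
    stop("design factors must be positive integers")
  as.integer(seeds) * as.integer(rounds) * as.integer(clusters)
}

#' Geometric hydrogen-bond count
#'
#' Counts donor--acceptor pairs whose heavy-atom distance is at most
#' \code{dCut}; when donor hydrogens are supplied, the D-H...A angle at the
#' hydrogen must additionally be at least \code{180 - angleCut} degrees for
#' some hydrogen attached to the donor. Without hydrogens the heavy-atom
#' distance criterion alone applies.
#'
#' @param coords \code{[nAtoms, 3]} matrix (nm).
#' @param donors donor heavy-atom indices.
#' @param acceptors acceptor heavy-atom indices.
#' @param hydrogens optional list, parallel to \code{donors}, of hydrogen
#'   atom indices attached to each donor.
#' @param dCut heavy-atom distance cutoff (nm); default 0.35.
#' @param angleCut deviation from linearity allowed (degrees); default 30.
#' @return number of hydrogen-bonded donor-acceptor pairs.
#' @export
hydrogenBondCount <- function(coords, donors, acceptors, hydrogens = NULL,
                              dCut = 0.35, angleCut = 30) {
  if (!length(donors) || !length(acceptors)) return(0L)
  coords <- as.matrix(coords)
  minAngle <- (180 - angleCut) * pi / 180
  count <- 0L
  for (di in seq_along(donors)) {
    d <- donors[di]
    for (a in acceptors) {
      if (a == d) next
      dv <- coords[a, ] - coords[d, ]
      if (sqrt(sum(dv * dv)) > dCut) next
      if (is.null(hydrogens)) {
        count <- count + 1L
        next
      }
      hs <- hydrogens[[di]]
      ok <- FALSE
      for (h in hs) {
        v1 <- coords[d, ] - coords[h, ]
        v2 <- coords[a, ] - coords[h, ]
        cosang <- sum(v1 * v2) /
          sqrt(sum(v1 * v1) * sum(v2 * v2))
        if (acos(pmin(1, pmax(-1, cosang))) >= minAngle) { ok <- TRUE; break }
      }
      if (ok) count <- count + 1L
    }
  }
  count
}

#' Read an ensemble of complex structures from PDB files
#'
#' @param paths PDB file paths, or a directory containing \code{*.pdb}.
#' @param speciesMap,massMap see [readStructure()].
#' @return list of models (\code{topology}, \code{coords}, \code{box}).
#' @export
readEnsemble <- function(paths, speciesMap = defaultSpeciesMap(),
                         massMap = NULL) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.pdb$", full.names = TRUE)
  if (!length(paths)) stop("no PDB files found for the ensemble")
  lapply(paths, function(p) {
    st <- readStructure(p, format = "pdb", speciesMap = speciesMap,
                        massMap = massMap)
    list(topology = st$topology, coords = frameCoords(st$trajectory, 1),
         box = boxLengths(st$trajectory, 1))
  })
}

#' Write an ensemble as numbered PDB files
#'
#' @param models list of models (\code{topology}, \code{coords} in nm).
#' @param dir output directory (created if needed).
#' @return the written paths.
#' @export
writeEnsemblePDB <- function(models, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(models))
  for (m in seq_along(models)) {
    paths[m] <- file.path(dir, sprintf("model_%03d.pdb", m))
    .writeModelPDB(models[[m]], paths[m])
  }
  invisible(paths)
}

.writeModelPDB <- function(model, path, b = NULL) {
  a <- atomData(model$topology)
  if (is.null(b)) b <- rep(0, nrow(a))
  bio3d::write.pdb(file = path, xyz = as.numeric(t(model$coords * 10)),
                   resno = a$resid, resid = substr(a$resname, 1, 3),
                   chain = a$chain, eleno = a$atomId,
                   elety = a$name, b = round(b, 2))
  invisible(path)
}

#' Paint contact frequencies into the B-factor column of a PDB
#'
#' Writes a copy of the model with every receptor atom's B-factor set to
#' its residue's contact frequency (scaled to 0-100), for structure
#' colouring in molecular viewers.
#'
#' @param model a model (\code{topology}, \code{coords}).
#' @param map a [ContactFrequencyMap-class].
#' @param path output PDB path.
#' @export
paintContactMap <- function(model, map, path) {
  a <- atomData(model$topology)
  tab <- frequencyTable(map)
  key <- paste(a$chain, a$resid, sep = ":")
  freq <- setNames(tab$frequency, paste(tab$chain, tab$resid, sep = ":"))
  b <- unname(freq[key]) * 100
  b[is.na(b)] <- 0
  .writeModelPDB(model, path, b = b)
  invisible(path)
}
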