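#' @include AllClasses.R protein-geometry.R
NULL

.ORIENTATION_LABELS <- c("red", "orange", "yellow", "green", "blue", "purple")

#' Build a six-pose orientation reference library
#'
#' Generates the six reference coordinate sets used for orientation
#' classification: the base pose and its 90/180/270 degree rotations about
#' the first axis plus the +/-90 degree rotations about the second axis --
#' the six distinct faces a rigid body can present to a planar interface.
#'
#' @param refCoords \code{[nAtoms, 3]} base-pose coordinates (nm).
#' @param labels six unique labels; default
#'   \code{red, orange, yellow, green, blue, purple}.
#' @return an [OrientationLibrary-class].
#' @examples
#' lib <- makeOrientationLibrary(makeTestProtein(30))
#' orientationLabels(lib)
#' @export
makeOrientationLibrary <- function(refCoords, labels = .ORIENTATION_LABELS) {
  refCoords <- as.matrix(refCoords)
  refCoords <- sweep(refCoords, 2, colMeans(refCoords))
  rots <- list(diag(3),
               .rotationAbout("x", 90), .rotationAbout("x", 180),
               .rotationAbout("x", 270), .rotationAbout("y", 90),
               .rotationAbout("y", 270))
  new("OrientationLibrary",
      coords = lapply(rots, function(R) refCoords %*% t(R)),
      labels = as.character(labels))
}

#' Root-mean-square deviation between two coordinate sets
#'
#' With \code{superpose = TRUE} the optimal least-squares rigid
#' superposition (Kabsch) is applied to the mobile coordinates first, so
#' rigid motions give zero; with \code{superpose = FALSE} (default) the
#' raw per-atom displacement RMS is returned, so deformation and
#' reorientation both contribute -- the appropriate reading when RMSD is
#' used as an interfacial-instability signal.
#'
#' @param coords,reference \code{[nAtoms, 3]} matrices (nm).
#' @param selection optional atom indices (e.g. C-alpha set) used both for
#'   fitting and for the reported RMS.
#' @param superpose apply optimal rotation + translation first.
#' @return RMSD in nm.
#' @examples
#' a <- makeTestProtein(20)
#' rmsdTo(a, a)                         # 0
#' @export
rmsdTo <- function(coords, reference, selection = NULL, superpose = FALSE) {
  coords <- as.matrix(coords); reference <- as.matrix(reference)
  if (is.null(selection)) selection <- seq_len(nrow(coords))
  if (nrow(coords) != nrow(reference))
    stop("coordinate sets must map one-to-one (",
         nrow(coords), " vs ", nrow(reference), " atoms)")
  if (superpose)
    coords <- .superpose(coords, reference, fitIdx = selection)
  d <- coords[selection, , drop = FALSE] -
    reference[selection, , drop = FALSE]
  sqrt(mean(rowSums(d * d)))
}

#' Per-residue root-mean-square fluctuation
#'
#' Each window frame is superposed (Kabsch, on the selection) onto the
#' reference; the RMSF of each selected atom is the root-mean-square
#' deviation of its position about its window-mean position, reported per
#' residue. The default window is the final half of the trajectory, the
#' equilibrated tail of an adsorption run.
#'
#' @param trajectory a [Trajectory-class].
#' @param topology matching [Topology-class].
#' @param reference \code{[nAtoms, 3]} reference coordinates (nm; same atom
#'   indexing as the trajectory). Default: first window frame.
#' @param selection atom indices to analyse; default all C-alpha
#'   (\code{name == "CA"}) protein atoms.
#' @param window fraction range of frames to use, default \code{c(0.5, 1)}
#'   (the last half).
#' @return data.frame with columns \code{chain}, \code{resid},
#'   \code{rmsf} (nm).
#' @export
rmsfProfile <- function(trajectory, topology, reference = NULL,
                        selection = NULL, window = c(0.5, 1)) {
  a <- atomData(topology)
  if (is.null(selection))
    selection <- which(a$species == "protein" & a$name == "CA")
  if (!length(selection)) stop("empty selection")
  nf <- nFrames(trajectory)
  lo <- max(1L, as.integer(ceiling(window[1] * nf)))
  if (window[1] == 0) lo <- 1L
  hi <- as.integer(floor(window[2] * nf))
  if (lo > hi || hi > nf) stop("window outside trajectory range")
  frames <- lo:hi
  if (is.null(reference)) reference <- trajectory@coords[, , frames[1]]
  fitted <- vapply(frames, function(f)
    .superpose(trajectory@coords[, , f], reference,
               fitIdx = selection)[selection, , drop = FALSE],
    matrix(0, length(selection), 3))
  meanPos <- apply(fitted, c(1, 2), mean)
  dev2 <- vapply(seq_along(frames), function(i)
    rowSums((fitted[, , i] - meanPos)^2), numeric(length(selection)))
  dev2 <- matrix(dev2, nrow = length(selection))
  rmsf <- sqrt(rowMeans(dev2))
  data.frame(chain = a$chain[selection], resid = a$resid[selection],
             rmsf = rmsf, row.names = NULL)
}

#' Classify a pose against the six-reference orientation library
#'
#' The frame is aligned to each reference by centre-of-mass translation
#' only -- no rotational fit, since the orientation itself is the
#' classified quantity -- and the per-atom RMS deviation is computed
#' against each reference; the label with the smallest deviation wins,
#' with ties broken by library order.
#'
#' @param coords \code{[nAtoms, 3]} protein coordinates (nm).
#' @param library an [OrientationLibrary-class] with matching atom count.
#' @return the winning label (character), with attribute
#'   \code{"deviations"} holding all six RMS deviations.
#' @export
classifyOrientation <- function(coords, library) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(referenceCoords(library, 1)))
    stop("atom count does not match the library (",
         nrow(coords), " vs ", nrow(referenceCoords(library, 1)), ")")
  centred <- sweep(coords, 2, colMeans(coords))
  dev <- vapply(referenceCoords(library), function(ref) {
    d <- centred - ref
    sqrt(mean(rowSums(d * d)))
  }, 0)
  names(dev) <- orientationLabels(library)
  structure(orientationLabels(library)[which.min(dev)], deviations = dev)
}

#' Orientation labels for every trajectory frame
#'
#' @param trajectory a [Trajectory-class].
#' @param topology matching [Topology-class].
#' @param library an [OrientationLibrary-class].
#' @param chains optional protein chain subset.
#' @return character vector of labels, one per frame.
#' @export
classifyOrientations <- function(trajectory, topology, library,
                                 chains = NULL) {
  a <- atomData(topology)
  sel <- a$species == "protein"
  if (!is.null(chains)) sel <- sel & a$chain %in% chains
  if (!any(sel)) stop("no protein atoms selected")
  vapply(seq_len(nFrames(trajectory)), function(f)
    as.character(classifyOrientation(
      trajectory@coords[sel, , f, drop = TRUE], library)), "")
}

#' Per-frame conformation series: RMSD, orientation, interfacial distance
#'
#' @param trajectory a [Trajectory-class].
#' @param topology matching [Topology-class].
#' @param interface an [InterfaceModel-class].
#' @param library an [OrientationLibrary-class].
#' @param reference reference coordinates for the RMSD (protein atoms, nm);
#'   default the first-frame protein coordinates.
#' @param chains optional protein chain subset.
#' @param selection optional atom indices within the protein selection for
#'   the RMSD (e.g. C-alpha); default all protein atoms.
#' @param superpose RMSD superposition flag (default \code{FALSE}; see
#'   [rmsdTo()]).
#' @return data.frame \code{frame}, \code{time}, \code{rmsd},
#'   \code{orientation}, \code{distance}.
#' @export
conformationSeries <- function(trajectory, topology, interface, library,
                               reference = NULL, chains = NULL,
                               selection = NULL, superpose = FALSE) {
  a <- atomData(topology)
  sel <- which(a$species == "protein" &
                 (if (is.null(chains)) TRUE else a$chain %in% chains))
  if (!length(sel)) stop("no protein atoms selected")
  if (is.null(reference))
    reference <- trajectory@coords[sel, , 1, drop = TRUE]
  dist <- proteinInterfaceDistance(trajectory, topology, interface, chains)
  labels <- classifyOrientations(trajectory, topology, library, chains)
  rmsd <- vapply(seq_len(nFrames(trajectory)), function(f)
    rmsdTo(trajectory@coords[sel, , f, drop = TRUE], reference,
           selection = selection, superpose = superpose), 0)
  data.frame(frame = seq_len(nFrames(trajectory)) - 1L,
             time = frameTimes(trajectory), rmsd = rmsd,
             orientation = labels, distance = dist)
}

#' RMSD distribution summaries per orientation and distance regime
#'
#' @param series data.frame from [conformationSeries()].
#' @param thresholds a [regimeThresholds()].
#' @return data.frame with one row per (orientation, regime) cell:
#'   \code{n}, \code{median}, \code{q25}, \code{q75}; cell counts sum to
#'   the number of frames.
#' @export
orientationResolvedStats <- function(series,
                                     thresholds = regimeThresholds()) {
  if (!nrow(series)) stop("empty series")
  regime <- classifyRegime(series$distance, thresholds)
  cells <- split(series$rmsd,
                 list(orientation = series$orientation, regime = regime),
                 drop = TRUE)
  out <- do.call(rbind, lapply(names(cells), function(nm) {
    v <- cells[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(orientation = parts[1], regime = parts[2],
               n = length(v), median = median(v),
               q25 = unname(quantile(v, 0.25)),
               q75 = unname(quantile(v, 0.75)))
  }))
  rownames(out) <- NULL
  out
}
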