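#' @include AllClasses.R interface.R
NULL

#' Distance-regime thresholds
#'
#' Protein--interface separations are conditioned into three regimes:
#' close (\code{|d| <= close}), near (\code{close < |d| <= near}) and far.
#' The default close bound, 1.2 nm, is the separation at which non-bonded
#' protein--interface interactions set in; the default near bound, 3.0 nm,
#' lies just beyond the largest preferred adsorption COM distance. Both are
#' analysis parameters and should be set deliberately.
#'
#' @param close upper bound of the close regime (nm).
#' @param near upper bound of the near regime (nm); must exceed
#'   \code{close}.
#' @return list of class \code{"RegimeThresholds"}.
#' @export
regimeThresholds <- function(close = 1.2, near = 3.0) {
  if (!(close > 0 && near > close))
    stop("need 0 < close < near")
  structure(list(close = close, near = near), class = "RegimeThresholds")
}

#' Classify protein--interface distances into regimes
#'
#' Side-agnostic: the absolute distance is compared against the thresholds,
#' with inclusive upper bounds.
#'
#' @param distance numeric signed or absolute distances (nm).
#' @param thresholds a [regimeThresholds()].
#' @return factor with levels \code{close}, \code{near}, \code{far}.
#' @examples
#' classifyRegime(c(0, 1.2, 2, 10), regimeThresholds())
#' @export
classifyRegime <- function(distance, thresholds = regimeThresholds()) {
  stopifnot(inherits(thresholds, "RegimeThresholds"))
  if (any(!is.finite(distance))) stop("distances must be finite")
  d <- abs(distance)
  factor(ifelse(d <= thresholds$close, "close",
                ifelse(d <= thresholds$near, "near", "far")),
         levels = c("close", "near", "far"))
}

# Per-residue COM coordinate along one axis, mass-weighted.
.residueComAxis <- function(cf, a, sel, ax) {
  key <- paste(a$chain[sel], a$resid[sel], sep = ":")
  m <- a$mass[sel]
  num <- rowsum(cf[sel, ax] * m, key)
  den <- rowsum(m, key)
  setNames(as.numeric(num / den), rownames(num))
}

#' Per-residue interfacial distance profile by regime
#'
#' For each frame whose whole-protein COM distance falls in the requested
#' regime, computes every residue's signed COM distance to the nearest
#' interface (positive on the water side), then averages per residue over
#' those frames.
#'
#' @param trajectory a [Trajectory-class].
#' @param topology matching [Topology-class].
#' @param interface an [InterfaceModel-class].
#' @param regime \code{"close"}, \code{"near"}, \code{"far"} or \code{NULL}
#'   for all frames.
#' @param thresholds a [regimeThresholds()].
#' @param chains optional protein chain subset.
#' @return data.frame with columns \code{chain}, \code{resid},
#'   \code{mean}, \code{sd}, \code{n}, \code{regime}; zero rows (with a
#'   \code{regime} marker attribute) when no frame falls in the regime.
#' @export
residueDistanceProfile <- function(trajectory, topology, interface,
                                   regime = NULL,
                                   thresholds = regimeThresholds(),
                                   chains = NULL) {
  a <- atomData(topology)
  sel <- a$species == "protein"
  if (!is.null(chains)) sel <- sel & a$chain %in% chains
  if (!any(sel)) stop("no protein atoms selected")
  ax <- normalAxis(interface)
  pos <- interfacePositions(interface)
  pbc <- ncol(pos) == 2L
  frames <- seq_len(nFrames(trajectory))
  if (!is.null(regime)) {
    d <- proteinInterfaceDistance(trajectory, topology, interface, chains)
    frames <- frames[classifyRegime(d, thresholds) == regime]
  }
  key <- unique(paste(a$chain[sel], a$resid[sel], sep = ":"))
  if (!length(frames)) {
    out <- data.frame(chain = character(0), resid = integer(0),
                      mean = numeric(0), sd = numeric(0), n = integer(0),
                      regime = character(0))
    attr(out, "emptyRegime") <- regime
    return(out)
  }
  dmat <- vapply(frames, function(f) {
    cf <- trajectory@coords[, , f]
    L <- boxLengths(trajectory, f)[ax]
    rc <- .residueComAxis(cf, a, sel, ax)[key]
    dd <- vapply(rc, function(cx) {
      disp <- if (pbc) .minImageDiff(cx - pos[f, ], L) else cx - pos[f, ]
      k <- which.min(abs(disp))
      side <- .waterSideSign(cf, topology, pos[f, k], ax, L, pbc = pbc)
      disp[k] * side
    }, 0)
    dd
  }, numeric(length(key)))
  dmat <- matrix(dmat, nrow = length(key))
  parts <- strsplit(key, ":", fixed = TRUE)
  data.frame(chain = vapply(parts, `[`, "", 1),
             resid = as.integer(vapply(parts, `[`, "", 2)),
             mean = rowMeans(dmat),
             sd = apply(dmat, 1, function(r) if (length(r) > 1) sd(r) else 0),
             n = ncol(dmat),
             regime = if (is.null(regime)) "all" else regime,
             row.names = NULL)
}

#' Frame counts by distance bin and orientation
#'
#' Histogram of simulation frames over (interfacial-distance bin x
#' orientation label); counts sum to the number of frames.
#'
#' @param distances per-frame signed distances (nm).
#' @param labels per-frame orientation labels, aligned with
#'   \code{distances}.
#' @param binWidth distance bin width (nm).
#' @return integer matrix \code{[nBins, nLabels]} with bin-centre rownames.
#' @export
frameCountByDistance <- function(distances, labels, binWidth = 0.25) {
  if (length(distances) != length(labels))
    stop("labels must align with distances")
  lo <- floor(min(distances) / binWidth) * binWidth
  hi <- ceiling(max(distances) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  breaks <- seq(lo, hi, by = binWidth)
  bin <- cut(distances, breaks, include.lowest = TRUE, right = FALSE)
  tab <- table(bin, factor(labels))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = list(sprintf("%.6g", head(breaks, -1) + binWidth / 2),
                              colnames(tab)))
  m
}

#' Spreading width of a protein along an axis
#'
#' Default metric: mass-weighted standard deviation of atom coordinates
#' along the axis. A protein spreading parallel to the interface narrows
#' this width along the normal. \code{"fwhm"} instead reports the full
#' width at half maximum of a Gaussian-kernel density profile of the
#' mass-weighted coordinates.
#'
#' @param trajectory a [Trajectory-class].
#' @param topology matching [Topology-class].
#' @param axis axis along which to measure.
#' @param chains optional protein chain subset.
#' @param metric \code{"sd"} (default) or \code{"fwhm"}.
#' @return numeric vector, one width (nm) per frame.
#' @export
densityWidth <- function(trajectory, topology, axis = "x", chains = NULL,
                         metric = c("sd", "fwhm")) {
  metric <- match.arg(metric)
  ax <- .axisIndex(axis)
  a <- atomData(topology)
  sel <- a$species == "protein"
  if (!is.null(chains)) sel <- sel & a$chain %in% chains
  if (sum(sel) < 2) stop("need >= 2 protein atoms")
  m <- a$mass[sel]
  w <- m / sum(m)
  vapply(seq_len(nFrames(trajectory)), function(f) {
    x <- trajectory@coords[sel, ax, f]
    if (metric == "sd") {
      mu <- sum(w * x)
      sqrt(sum(w * (x - mu)^2))
    } else {
      den <- stats::density(x, weights = w)
      half <- max(den$y) / 2
      above <- which(den$y >= half)
      den$x[above[length(above)]] - den$x[above[1]]
    }
  }, 0)
}

.ATOM_RADII_NM <- c(C = 0.170, N = 0.155, O = 0.152, S = 0.180,
                    H = 0.110, P = 0.180)

#' Van der Waals radii from atom names
#'
#' Element inferred from the atom name (digits stripped, first letter);
#' united-atom convention with unknown elements treated as carbon.
#'
#' @param topology a [Topology-class].
#' @return numeric vector of radii (nm).
#' @export
atomRadii <- function(topology) {
  nm <- atomData(topology)$name
  el <- toupper(substr(gsub("[0-9 ]", "", nm), 1, 1))
  r <- .ATOM_RADII_NM[el]
  r[is.na(r)] <- .ATOM_RADII_NM["C"]
  unname(r)
}

#' Shrake--Rupley solvent-accessible surface area
#'
#' Per-atom SASA by test points on each atom's solvent-expanded sphere
#' (radius + probe), placed on a Fibonacci lattice; a point is buried if it
#' falls inside any other atom's expanded sphere.
#'
#' @param coords \code{[nAtoms, 3]} matrix (nm).
#' @param radii per-atom radii (nm).
#' @param probe probe radius (nm); default 0.14 (water).
#' @param nPoints test points per atom; default 960.
#' @return numeric vector of per-atom areas (nm^2).
#' @export
shrakeRupleySASA <- function(coords, radii, probe = 0.14, nPoints = 960) {
  n <- nrow(coords)
  radii <- rep_len(radii, n)
  sphere <- .spherePoints(nPoints)
  rExp <- radii + probe
  out <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sphere * rExp[i], 2, coords[i, ], `+`)
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nbr <- which(d2 > 0 & d2 < (rExp + rExp[i])^2)
    exposed <- rep(TRUE, nPoints)
    for (j in nbr) {
      dj <- sweep(pts, 2, coords[j, ])
      exposed <- exposed & rowSums(dj * dj) > rExp[j]^2
      if (!any(exposed)) break
    }
    out[i] <- 4 * pi * rExp[i]^2 * sum(exposed) / nPoints
  }
  out
}

#' Interface-accessible surface area
#'
#' Shrake--Rupley SASA summed over protein atoms whose normal coordinate
#' lies within a slab of half-width \code{slab} around the interface plane;
#' occlusion still counts all protein atoms. Measures how much protein
#' surface is presented to the interfacial region.
#'
#' @param trajectory a [Trajectory-class] (or \code{[nAtoms, 3]} matrix).
#' @param topology matching [Topology-class].
#' @param interfacePosition interface plane position along the normal (nm).
#' @param frame frame index (default 1).
#' @param axis interface normal axis.
#' @param chains optional protein chain subset.
#' @param slab slab half-width on each side of the plane (nm); default 1.0.
#' @param probe probe radius (nm).
#' @param nPoints Shrake--Rupley sample points per atom.
#' @return total interface-accessible area (nm^2); 0 when no atom lies in
#'   the slab.
#' @export
interfaceAccessibleArea <- function(trajectory, topology, interfacePosition,
                                    frame = 1, axis = "x", chains = NULL,
                                    slab = 1.0, probe = 0.14,
                                    nPoints = 960) {
  ax <- .axisIndex(axis)
  cf <- if (is.matrix(trajectory)) trajectory
        else trajectory@coords[, , frame]
  a <- atomData(topology)
  sel <- a$species == "protein"
  if (!is.null(chains)) sel <- sel & a$chain %in% chains
  if (!any(sel)) stop("no protein atoms selected")
  coords <- cf[sel, , drop = FALSE]
  radii <- atomRadii(topology)[sel]
  inSlab <- abs(coords[, ax] - interfacePosition) <= slab
  if (!any(inSlab)) return(0)
  areas <- shrakeRupleySASA(coords, radii, probe, nPoints)
  sum(areas[inSlab])
}
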