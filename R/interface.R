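#' @include AllClasses.R
NULL

#' Mass-density profile along the interface normal
#'
#' Mass-weighted histogram of the wrapped normal coordinate, normalized by
#' bin volume (box cross-section times bin width) and converted to kg/m^3,
#' optionally time-averaged over a frame window.
#'
#' @param trajectory a [Trajectory-class].
#' @param topology matching [Topology-class].
#' @param species species tags to profile (columns of the result).
#' @param axis normal axis.
#' @param nBins number of uniform bins (>= 4).
#' @param frames frame indices to use (default all).
#' @param average if \code{TRUE} (default) return the time-averaged
#'   [DensityProfile-class]; otherwise a list of per-frame profiles.
#' @return a [DensityProfile-class] (or list of them).
#' @export
densityProfile <- function(trajectory, topology,
                           species = c("water", "organic"), axis = "x",
                           nBins = 80, frames = NULL, average = TRUE) {
  ax <- .axisIndex(axis)
  if (nBins < 4) stop("nBins must be >= 4")
  if (is.null(frames)) frames <- seq_len(nFrames(trajectory))
  sp <- atomSpecies(topology)
  mass <- atomMasses(topology)
  for (s in species) if (!any(sp == s))
    stop("no atoms of species '", s, "' in the topology")
  L <- boxLengths(trajectory, frames[1])[ax]
  area <- prod(boxLengths(trajectory, frames[1])[-ax])
  binw <- L / nBins
  centers <- (seq_len(nBins) - 0.5) * binw
  oneFrame <- function(f) {
    x <- .wrapCoord(trajectory@coords[, ax, f], L)
    bin <- pmin(nBins, 1L + as.integer(floor(x / binw)))
    dens <- sapply(species, function(s) {
      sel <- sp == s
      m <- vapply(split(mass[sel], factor(bin[sel], levels = seq_len(nBins))),
                  sum, 0)
      m / (area * binw) * .MASS_U_TO_KG_M3
    })
    matrix(dens, nBins, length(species), dimnames = list(NULL, species))
  }
  mats <- lapply(frames, oneFrame)
  mk <- function(d) new("DensityProfile", centers = centers, density = d,
                        binWidth = binw, axis = ax, area = area)
  if (average) mk(Reduce(`+`, mats) / length(mats)) else lapply(mats, mk)
}

# Contiguous occupied-bin zones, allowing gaps of up to `maxGap` empty bins;
# circular when pbc. Returns a list of integer bin-index vectors (indices
# may exceed nb when a zone wraps; callers unwrap modulo nb).
.contactZones <- function(occupied, maxGap = 3L, pbc = TRUE) {
  nb <- length(occupied)
  idx <- which(occupied)
  if (!length(idx)) return(list())
  gaps <- diff(idx)
  breaks <- which(gaps > maxGap + 1L)
  zones <- split(idx, cumsum(c(0L, as.integer(gaps > maxGap + 1L))))
  zones <- unname(zones)
  if (pbc && length(zones) > 1L) {
    wrapGap <- (idx[1] + nb) - idx[length(idx)]
    if (wrapGap <= maxGap + 1L) {
      zones[[1]] <- c(zones[[length(zones)]], zones[[1]] + nb)
      zones[[length(zones)]] <- NULL
    }
  }
  zones
}

# Histogram mode with ties broken toward the bin nearest the box centre.
.modeBin <- function(counts, centers, L) {
  mx <- max(counts)
  cand <- which(counts == mx)
  cand[which.min(abs(.wrapCoord(centers[cand], L) - L / 2))]
}

#' Locate interfaces by cross-solvent proximity histograms
#'
#' For each frame, organic particles within \code{cutoff} of any water
#' particle and water particles within \code{cutoff} of any organic
#' particle are histogrammed along the normal; each interface is the
#' midpoint between the two histogram mode positions within a contiguous
#' contact zone (1 or 2 zones under periodic boundaries). This construction
#' is insensitive to a protein sitting at the interface, unlike the Gibbs
#' dividing surface, because only solvent particles enter the histograms.
#'
#' @param trajectory a [Trajectory-class].
#' @param topology matching [Topology-class].
#' @param axis interface normal axis.
#' @param cutoff cross-species proximity cutoff (nm); default 0.5.
#' @param binWidth histogram bin width (nm); default 0.1.
#' @param pbc treat the normal axis as periodic (default \code{TRUE}; set
#'   \code{FALSE} for slabs built with a single interface and open normal).
#' @param frames frame indices (default all).
#' @param maxGap contact zones separated by more than this many empty bins
#'   are distinct interfaces.
#' @return an [InterfaceModel-class] with method \code{"histogram"}.
#' @export
locateInterfaceHistogram <- function(trajectory, topology, axis = "x",
                                     cutoff = 0.5, binWidth = 0.1,
                                     pbc = TRUE, frames = NULL, maxGap = 3L) {
  ax <- .axisIndex(axis)
  if (is.null(frames)) frames <- seq_len(nFrames(trajectory))
  sp <- atomSpecies(topology)
  iW <- which(sp == "water")
  iO <- which(sp == "organic")
  if (!length(iW) || !length(iO))
    stop("both solvent species must be present")
  posList <- lapply(frames, function(f) {
    box <- boxLengths(trajectory, f)
    L <- box[ax]
    nb <- max(4L, as.integer(round(L / binWidth)))
    bw <- L / nb
    centers <- (seq_len(nb) - 0.5) * bw
    cf <- trajectory@coords[, , f]
    W <- cf[iW, , drop = FALSE]
    O <- cf[iO, , drop = FALSE]
    pbox <- if (pbc) box else NULL
    wContact <- .hasNeighborWithin(W, O, cutoff, pbox)
    oContact <- .hasNeighborWithin(O, W, cutoff, pbox)
    if (!any(wContact) || !any(oContact))
      stop("no cross-species contacts within ", cutoff,
           " nm in frame ", f, "; phases fully separated")
    binOf <- function(x) pmin(nb, 1L + as.integer(floor(.wrapCoord(x, L) / bw)))
    hW <- tabulate(binOf(W[wContact, ax]), nb)
    hO <- tabulate(binOf(O[oContact, ax]), nb)
    zones <- .contactZones(hW + hO > 0L, maxGap, pbc)
    if (length(zones) > 1L) {
      # stray dissolved particles seed tiny spurious zones; keep only
      # zones holding a substantial share of the contact population
      tot <- hW + hO
      counts <- vapply(zones, function(z) sum(tot[((z - 1L) %% nb) + 1L]), 0)
      zones <- zones[counts >= 0.1 * max(counts)]
    }
    if (length(zones) > 2L)
      stop("frame ", f, ": more than two contact zones found")
    vapply(zones, function(z) {
      zc <- (z - 0.5) * bw  # zone bin centres, unwrapped past L if needed
      zi <- ((z - 1L) %% nb) + 1L
      mW <- .modeBin(hW[zi], zc, L)
      mO <- .modeBin(hO[zi], zc, L)
      .wrapCoord((zc[mW] + zc[mO]) / 2, L)
    }, 0)
  })
  nz <- lengths(posList)
  if (length(unique(nz)) != 1L)
    stop("inconsistent interface count across frames (",
         paste(unique(nz), collapse = ", "), ")")
  pos <- do.call(rbind, posList)
  pos <- t(apply(pos, 1, sort))
  if (nz[1] == 1L) pos <- matrix(pos, ncol = 1)
  InterfaceModel(pos, ax, "histogram", cutoff = cutoff,
                 binWidth = binWidth)
}

# Plateau bins: both species within tol of their bulk values (absolute
# slack tol * bulk of the species that is nonzero there).
.plateauMask <- function(dw, do, bulkW, bulkO, tol) {
  waterSide <- abs(dw - bulkW) <= tol * bulkW & do <= tol * bulkO
  organicSide <- abs(do - bulkO) <= tol * bulkO & dw <= tol * bulkW
  list(water = waterSide, organic = organicSide)
}

#' Locate the Gibbs dividing surface from a density profile
#'
#' Reference construction: from a two-species density profile with bulk
#' plateaus, the dividing surface x_b between a water-side plateau end x_a
#' and an organic-side plateau start x_c balances the integrated
#' concentration deviations: the excess of each species' deviation from its
#' x_a-side value over \[x_a, x_b\] equals the deficit relative to its
#' x_c-side value over \[x_b, x_c\]. Solved by trapezoidal quadrature on the
#' linearly interpolated profile with root bracketing on x_b (the balance
#' function is strictly monotone). Profiles with two transitions (periodic
#' slabs) yield one position per transition.
#'
#' A protein at the interface distorts the solvent plateaus and makes the
#' bulk ill-defined; this construction is therefore the protein-free oracle
#' against which the histogram locator is validated.
#'
#' @param profile a [DensityProfile-class] containing columns
#'   \code{"water"} and \code{"organic"}.
#' @param plateauTol plateau tolerance as a fraction of the bulk value
#'   (default 0.02) over at least \code{minPlateauBins} consecutive bins.
#' @param minPlateauBins minimum plateau run length (default 3).
#' @return numeric vector of dividing-surface positions (nm), one per
#'   water/organic transition.
#' @export
locateInterfaceGibbs <- function(profile, plateauTol = 0.02,
                                 minPlateauBins = 3L) {
  d <- profileDensity(profile)
  if (!all(c("water", "organic") %in% colnames(d)))
    stop("profile must contain 'water' and 'organic' densities")
  x <- profileCenters(profile)
  dw <- d[, "water"]; do <- d[, "organic"]
  bulkW <- median(dw[dw > 0.9 * max(dw)])
  bulkO <- median(do[do > 0.9 * max(do)])
  pm <- .plateauMask(dw, do, bulkW, bulkO, plateauTol)
  runs <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= minPlateauBins
    cbind(starts[keep], ends[keep])
  }
  rw <- runs(pm$water); ro <- runs(pm$organic)
  if (!nrow(rw) || !nrow(ro))
    stop("no bulk plateau detected for ",
         if (!nrow(rw)) "water" else "organic",
         "; bulk is ill-defined (e.g. protein-perturbed profile)")
  # transitions: sign changes of the normalized species difference
  g <- dw / bulkW - do / bulkO
  sgn <- sign(g)
  nz <- which(sgn != 0)
  flips <- nz[which(diff(sgn[nz]) != 0)]
  if (!length(flips)) stop("no water/organic transition in profile")
  vapply(flips, function(i) {
    # nearest enclosing plateau run on each side of the transition
    leftRuns <- rbind(rw[rw[, 2] <= i, , drop = FALSE],
                      ro[ro[, 2] <= i, , drop = FALSE])
    rightRuns <- rbind(rw[rw[, 1] > i, , drop = FALSE],
                       ro[ro[, 1] > i, , drop = FALSE])
    if (!nrow(leftRuns) || !nrow(rightRuns))
      stop("transition near ", signif(x[i], 4),
           " nm lacks a bulk plateau on one side")
    ia <- max(leftRuns[, 2])   # last plateau bin before the transition
    ic <- min(rightRuns[, 1])  # first plateau bin after it
    .gibbsBalance(x, dw, do, ia, ic)
  }, 0)
}

# Solve the equal-excess balance for x_b on [x[ia], x[ic]] using fine
# trapezoidal quadrature of the linearly interpolated profile.
.gibbsBalance <- function(x, dw, do, ia, ic, nGrid = 4000L) {
  xa <- x[ia]; xc <- x[ic]
  g <- seq(xa, xc, length.out = nGrid)
  cw <- approx(x, dw, g, rule = 2)$y
  co <- approx(x, do, g, rule = 2)$y
  cwA <- cw[1]; coA <- co[1]; cwC <- cw[nGrid]; coC <- co[nGrid]
  h <- g[2] - g[1]
  cum <- function(v) c(0, cumsum((v[-1] + v[-nGrid]) / 2 * h))
  # F(xb) = int_a^b [(Cw-Cw(a)) - (Co-Co(a))] - int_b^c [(Co-Co(c)) - (Cw-Cw(c))]
  lhs <- cum((cw - cwA) - (co - coA))
  rhsTot <- cum((co - coC) - (cw - cwC))
  FF <- lhs - (rhsTot[nGrid] - rhsTot)
  s <- sign(FF)
  cross <- which(s[-1] * s[-nGrid] < 0)
  if (!length(cross)) {
    zero <- which(s == 0)
    if (length(zero)) return(g[zero[1]])
    stop("Gibbs balance has no root in [", signif(xa, 4), ", ",
         signif(xc, 4), "]")
  }
  i <- cross[1]
  g[i] + (g[i + 1] - g[i]) * FF[i] / (FF[i] - FF[i + 1])
}

# Is the water-rich side above (+1) or below (-1) position xb along ax?
.waterSideSign <- function(cf, topology, xb, ax, L, window = 1.5,
                           pbc = TRUE) {
  xw <- cf[atomSpecies(topology) == "water", ax]
  if (pbc) {
    d <- .minImageDiff(xw - xb, L)
  } else {
    d <- xw - xb
  }
  above <- sum(d > 0 & d <= window)
  below <- sum(d < 0 & d >= -window)
  if (above >= below) 1 else -1
}

#' Signed protein centre-of-mass distance to the interface
#'
#' Mass-weighted protein COM along the normal minus the nearest interface
#' position, with positive sign on the water side. With two interfaces the
#' nearer one under the minimum-image convention is used.
#'
#' @param trajectory a [Trajectory-class].
#' @param topology matching [Topology-class].
#' @param interface an [InterfaceModel-class] covering the same frames.
#' @param chains optional protein chain subset.
#' @param pbc minimum-image treatment along the normal; defaults to
#'   \code{TRUE} when the model carries two interfaces.
#' @return numeric vector, one signed distance (nm) per frame.
#' @export
proteinInterfaceDistance <- function(trajectory, topology, interface,
                                     chains = NULL, pbc = NULL) {
  ax <- normalAxis(interface)
  a <- atomData(topology)
  sel <- a$species == "protein"
  if (!is.null(chains)) sel <- sel & a$chain %in% chains
  if (!any(sel)) stop("no protein atoms selected")
  mass <- a$mass[sel]
  pos <- interfacePositions(interface)
  if (nrow(pos) != nFrames(trajectory))
    stop("interface model frame count does not match the trajectory")
  if (is.null(pbc)) pbc <- ncol(pos) == 2L
  vapply(seq_len(nFrames(trajectory)), function(f) {
    cf <- trajectory@coords[, , f]
    L <- boxLengths(trajectory, f)[ax]
    comX <- sum(cf[sel, ax] * mass) / sum(mass)
    disp <- if (pbc) .minImageDiff(comX - pos[f, ], L) else comX - pos[f, ]
    k <- which.min(abs(disp))
    side <- .waterSideSign(cf, topology, pos[f, k], ax, L, pbc = pbc)
    sign(disp[k]) * side * abs(disp[k])
  }, 0)
}

#' Export per-frame interface positions as TSV
#'
#' @param interface an [InterfaceModel-class].
#' @param trajectory the [Trajectory-class] providing frame times.
#' @param path output path.
#' @export
writeInterfaceTable <- function(interface, trajectory, path) {
  pos <- interfacePositions(interface)
  df <- data.frame(frame = seq_len(nrow(pos)) - 1L,
                   time = frameTimes(trajectory)[seq_len(nrow(pos))],
                   x_b = pos[, 1])
  if (ncol(pos) == 2L) df$x_b2 <- pos[, 2]
  df$method <- interface@method
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
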