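# Low-level geometry helpers shared across modules. Coordinates are plain
# numeric matrices (n x 3) in nm; boxes are length-3 vectors of box edges.

.AXES <- c(x = 1L, y = 2L, z = 3L)

.axisIndex <- function(axis) {
  if (is.numeric(axis)) {
    axis <- as.integer(axis)
    if (!axis %in% 1:3) stop("axis must be 1, 2 or 3 (or 'x','y','z')")
    return(axis)
  }
  ax <- .AXES[tolower(as.character(axis))]
  if (is.na(ax)) stop("unknown axis '", axis, "'; use 'x', 'y' or 'z'")
  unname(ax)
}

# Wrap scalar coordinates into the half-open interval [0, L).
.wrapCoord <- function(x, L) {
  x - floor(x / L) * L
}

# Minimum-image separation along one periodic axis.
.minImageDiff <- function(dx, L) {
  dx - round(dx / L) * L
}

# Mass-weighted centre of mass (vector of length 3).
.com <- function(coords, mass) {
  if (is.null(mass)) mass <- rep(1, nrow(coords))
  colSums(coords * mass) / sum(mass)
}

# Optimal least-squares rotation (Kabsch, via SVD) mapping P onto Q after
# both are centred. Returns the 3x3 rotation matrix R such that P %*% R
# best matches Q. Reflections are removed by sign correction.
.kabschRotation <- function(P, Q, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(P))
  H <- crossprod(P * weights, Q)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  sv$u %*% D %*% t(sv$v)
}

# Superpose mobile onto ref (least-squares rotation + translation).
.superpose <- function(mobile, ref, weights = NULL, fitIdx = NULL) {
  if (is.null(fitIdx)) fitIdx <- seq_len(nrow(mobile))
  w <- if (is.null(weights)) rep(1, length(fitIdx)) else weights[fitIdx]
  cm <- colSums(mobile[fitIdx, , drop = FALSE] * w) / sum(w)
  cr <- colSums(ref[fitIdx, , drop = FALSE] * w) / sum(w)
  Pc <- sweep(mobile[fitIdx, , drop = FALSE], 2, cm)
  Qc <- sweep(ref[fitIdx, , drop = FALSE], 2, cr)
  R <- .kabschRotation(Pc, Qc, w)
  sweep(sweep(mobile, 2, cm) %*% R, 2, cr, `+`)
}

# For each row of `a`, is any row of `b` within `cutoff`? Cell-list search
# over a 3D grid with edge >= cutoff; `box` (length-3) enables periodic
# minimum-image distances; NULL means open boundaries.
.hasNeighborWithin <- function(a, b, cutoff, box = NULL) {
  na <- nrow(a)
  if (na == 0L) return(logical(0))
  if (nrow(b) == 0L) return(rep(FALSE, na))
  periodic <- !is.null(box)
  if (periodic) {
    for (k in 1:3) {
      a[, k] <- .wrapCoord(a[, k], box[k])
      b[, k] <- .wrapCoord(b[, k], box[k])
    }
    span <- box
    origin <- c(0, 0, 0)
  } else {
    lo <- pmin(apply(a, 2, min), apply(b, 2, min))
    hi <- pmax(apply(a, 2, max), apply(b, 2, max))
    origin <- lo
    span <- pmax(hi - lo, cutoff)
  }
  ncell <- pmax(1L, as.integer(floor(span / cutoff)))
  width <- span / ncell
  cellOf <- function(m) {
    idx <- matrix(0L, nrow(m), 3)
    for (k in 1:3) {
      idx[, k] <- pmin(as.integer(floor((m[, k] - origin[k]) / width[k])),
                       ncell[k] - 1L)
      idx[, k] <- pmax(idx[, k], 0L)
    }
    idx
  }
  key <- function(idx) idx[, 1] + ncell[1] * (idx[, 2] + ncell[2] * idx[, 3])
  ia <- cellOf(a); ib <- cellOf(b)
  bByCell <- split(seq_len(nrow(b)), key(ib))
  out <- rep(FALSE, na)
  cut2 <- cutoff^2
  aCells <- split(seq_len(na), key(ia))
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (ck in names(aCells)) {
    aIdx <- aCells[[ck]]
    c0 <- ia[aIdx[1], ]
    cand <- integer(0)
    for (r in seq_len(nrow(offsets))) {
      nb <- c0 + offsets[r, ]
      if (periodic) {
        nb <- nb %% ncell
      } else if (any(nb < 0L) || any(nb >= ncell)) next
      hit <- bByCell[[as.character(nb[1] + ncell[1] * (nb[2] + ncell[2] * nb[3]))]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    if (length(cand) == 0L) next
    cand <- unique(cand)
    bsub <- b[cand, , drop = FALSE]
    for (i in aIdx) {
      d <- sweep(bsub, 2, a[i, ])
      if (periodic) for (k in 1:3) d[, k] <- .minImageDiff(d[, k], box[k])
      if (any(rowSums(d * d) <= cut2)) out[i] <- TRUE
    }
  }
  out
}

# Brute-force reference for .hasNeighborWithin (used by tests as an oracle
# and internally for tiny inputs where the grid is overkill).
.hasNeighborBrute <- function(a, b, cutoff, box = NULL) {
  na <- nrow(a)
  if (na == 0L) return(logical(0))
  if (nrow(b) == 0L) return(rep(FALSE, na))
  out <- logical(na)
  cut2 <- cutoff^2
  for (i in seq_len(na)) {
    d <- sweep(b, 2, a[i, ])
    if (!is.null(box)) for (k in 1:3) d[, k] <- .minImageDiff(d[, k], box[k])
    out[i] <- any(rowSums(d * d) <= cut2)
  }
  out
}

# Near-uniform points on the unit sphere (Fibonacci / golden-spiral lattice).
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Rotation matrices about the principal axes (degrees).
.rotationAbout <- function(axis, degrees) {
  th <- degrees * pi / 180
  c0 <- cos(th); s0 <- sin(th)
  switch(.axisIndex(axis),
         matrix(c(1, 0, 0, 0, c0, s0, 0, -s0, c0), 3, 3),
         matrix(c(c0, 0, -s0, 0, 1, 0, s0, 0, c0), 3, 3),
         matrix(c(c0, s0, 0, -s0, c0, 0, 0, 0, 1), 3, 3))
}

.MASS_U_TO_KG_M3 <- 1.66053906660  # (u / nm^3) -> kg/m^3
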