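# Shared fixture builders; everything is generated in code.

# Minimal two-species topology/trajectory with hand-placed particles.
handSlab <- function(waterX, organicX, box = c(10, 4, 4), y = 2, z = 2) {
  nW <- length(waterX); nO <- length(organicX)
  top <- Topology(name = c(rep("OW", nW), rep("C1", nO)),
                  species = c(rep("water", nW), rep("organic", nO)),
                  mass = c(rep(18, nW), rep(85, nO)),
                  chain = c(rep("W", nW), rep("O", nO)),
                  resid = c(seq_len(nW), seq_len(nO)),
                  resname = c(rep("SOL", nW), rep("DCM", nO)))
  coords <- cbind(c(waterX, organicX), y, z)
  list(topology = top, trajectory = Trajectory(coords, box))
}

# A DensityProfile built directly from density vectors.
handProfile <- function(centers, water, organic, area = 16) {
  bw <- centers[2] - centers[1]
  new("DensityProfile", centers = centers,
      density = cbind(water = water, organic = organic),
      binWidth = bw, axis = 1L, area = area)
}

# Step profile: water bulk below x0, organic bulk above, on uniform bins.
stepProfile <- function(x0 = 5, L = 10, nBins = 100, bulkW = 997,
                        bulkO = 1322) {
  bw <- L / nBins
  centers <- (seq_len(nBins) - 0.5) * bw
  handProfile(centers, ifelse(centers < x0, bulkW, 0),
              ifelse(centers < x0, 0, bulkO))
}

# Antisymmetric tanh profile about x0 with 10-90 style width w.
tanhProfile <- function(x0 = 5, w = 0.6, L = 10, nBins = 100,
                        bulkW = 997, bulkO = 1322) {
  bw <- L / nBins
  centers <- (seq_len(nBins) - 0.5) * bw
  s <- tanh(2 * (centers - x0) / w)
  handProfile(centers, bulkW * (1 - s) / 2, bulkO * (1 + s) / 2)
}

# Protein-only system: rigid body at a COM with given per-frame coords fn.
proteinOnlyTraj <- function(frames, masses = NULL, box = c(10, 10, 10),
                            chain = "P") {
  n <- nrow(frames[[1]])
  if (is.null(masses)) masses <- rep(110, n)
  top <- Topology(name = rep("CA", n), species = "protein", mass = masses,
                  chain = chain, resid = seq_len(n), resname = "PRT")
  coords <- array(0, c(n, 3, length(frames)))
  for (i in seq_along(frames)) coords[, , i] <- frames[[i]]
  list(topology = top, trajectory = Trajectory(coords, box))
}

# Haar-uniform random rotation: QR of a Gaussian matrix with the R-diagonal
# sign fix; an improper result is negated (dimension is odd) to stay Haar.
randomRotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q <- -q
  q
}
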