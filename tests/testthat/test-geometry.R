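test_that("regime classification is a total inclusive-boundary partition", {
  th <- regimeThresholds(close = 1.2, near = 3.0)
  expect_equal(as.character(classifyRegime(0, th)), "close")
  expect_equal(as.character(classifyRegime(1.2, th)), "close")
  expect_equal(as.character(classifyRegime(-1.2, th)), "close")
  expect_equal(as.character(classifyRegime(3.0, th)), "near")
  expect_equal(as.character(classifyRegime(10, th)), "far")
  # total partition over random signed distances
  set.seed(1)
  d <- runif(500, -8, 8)
  r <- classifyRegime(d, th)
  expect_false(anyNA(r))
  expect_equal(as.vector(table(r)),
               c(sum(abs(d) <= 1.2), sum(abs(d) > 1.2 & abs(d) <= 3),
                 sum(abs(d) > 3)))
  expect_error(regimeThresholds(3, 1.2), "close < near")
  expect_error(classifyRegime(NaN, th), "finite")
})

test_that("residues keep constant interfacial distance under parallel translation", {
  base <- cbind(c(1, 1.4, 1.8), 2, 2)  # three residues at fixed x
  frames <- lapply(0:4, function(k) base + matrix(c(0, 0.3 * k, 0), 3, 3,
                                                  byrow = TRUE))
  po <- proteinOnlyTraj(frames)
  # add solvent so the water side is defined
  hs <- handSlab(waterX = seq(0.2, 4.8, 0.2), organicX = seq(5.2, 9.8, 0.2))
  aS <- atomData(hs$topology); aP <- atomData(po$topology)
  top <- Topology(name = c(aS$name, aP$name),
                  species = c(aS$species, aP$species),
                  mass = c(aS$mass, aP$mass),
                  chain = c(aS$chain, aP$chain),
                  resid = c(aS$resid, aP$resid),
                  resname = c(aS$resname, aP$resname))
  coords <- array(0, c(nrow(aS) + 3, 3, 5))
  for (f in 1:5) {
    coords[seq_len(nrow(aS)), , f] <- frameCoords(hs$trajectory, 1)
    coords[nrow(aS) + 1:3, , f] <- frames[[f]]
  }
  traj <- Trajectory(coords, c(10, 4, 4))
  im <- InterfaceModel(matrix(5, 5), "x", "planted")
  prof <- residueDistanceProfile(traj, top, im)
  expect_equal(prof$sd, rep(0, 3), tolerance = 1e-12)
  expect_equal(prof$mean[order(prof$resid)], c(4, 3.6, 3.2),
               tolerance = 1e-9)
})

test_that("a planted 1 nm tilt offset is recovered in the residue profile", {
  # residues 1-5 sit 1 nm farther from the interface than residues 6-10
  xs <- c(rep(2, 5), rep(3, 5))
  frames <- lapply(1:3, function(k) cbind(xs, 1.5 + 0.1 * k, 2))
  po <- proteinOnlyTraj(frames, box = c(10, 4, 4))
  im <- InterfaceModel(matrix(5, 3), "x", "planted")
  # no solvent: side sign falls back to +1 (no water found on either side)
  prof <- residueDistanceProfile(po$trajectory, po$topology, im)
  gap <- mean(prof$mean[prof$resid <= 5]) - mean(prof$mean[prof$resid > 5])
  expect_equal(abs(gap), 1, tolerance = 1e-9)
})

test_that("an isotropically tumbling far body has uniform residue distances", {
  set.seed(7)
  nf <- 500
  base <- makeTestProtein(30, size = 0.8)
  frames <- lapply(seq_len(nf), function(k)
    sweep(base %*% randomRotation(), 2, c(2, 5, 5), `+`))
  po <- proteinOnlyTraj(frames, box = c(12, 10, 10))
  im <- InterfaceModel(matrix(10, nf), "x", "planted")
  prof <- residueDistanceProfile(po$trajectory, po$topology, im,
                                 regime = "far",
                                 thresholds = regimeThresholds(1.2, 3))
  expect_equal(nrow(prof), 30)
  # per-residue means agree within sampling error: the residue farthest
  # from the COM has per-frame x-projection sd r/sqrt(3), so its mean over
  # nf frames wanders by about r/sqrt(3 nf)
  rmax <- max(sqrt(rowSums(base^2)))
  bound <- 8 * rmax / sqrt(3 * nf)
  expect_lt(diff(range(abs(prof$mean))), bound)
  expect_lt(sd(prof$mean), bound / 3)
})

test_that("empty regimes yield an empty profile marker, not an error", {
  frames <- list(cbind(c(2, 2.4), 2, 2))
  po <- proteinOnlyTraj(frames, box = c(10, 4, 4))
  im <- InterfaceModel(matrix(5, 1), "x", "planted")
  prof <- residueDistanceProfile(po$trajectory, po$topology, im,
                                 regime = "close")
  expect_equal(nrow(prof), 0)
  expect_equal(attr(prof, "emptyRegime"), "close")
})

test_that("frame counts by distance and orientation are conserved", {
  d <- rep(1.4, 10)
  lab <- rep("yellow", 10)
  h <- frameCountByDistance(d, lab, binWidth = 0.25)
  expect_equal(sum(h), 10)
  expect_equal(sum(h > 0), 1)

  set.seed(3)
  d2 <- runif(400, 0, 4)
  lab2 <- sample(c("red", "yellow"), 400, replace = TRUE)
  h2 <- frameCountByDistance(d2, lab2, binWidth = 1)
  expect_equal(sum(h2), 400)
  expect_equal(nrow(h2), 4)
  expect_true(all(abs(rowSums(h2) - 100) < 40))  # uniform within noise
  expect_error(frameCountByDistance(d2, lab2[-1]), "align")
})

test_that("density width has the closed forms of degenerate and uniform bodies", {
  # all atoms coplanar perpendicular to the axis -> width 0
  plane <- cbind(5, runif(20, 0, 3), runif(20, 0, 3))
  po <- proteinOnlyTraj(list(plane), box = c(10, 4, 4))
  expect_equal(densityWidth(po$trajectory, po$topology, axis = "x"), 0,
               tolerance = 1e-12)
  # uniform rod of length L along the axis -> L / sqrt(12)
  Lrod <- 3
  rod <- cbind(seq(2, 2 + Lrod, length.out = 2000), 2, 2)
  po2 <- proteinOnlyTraj(list(rod), box = c(10, 4, 4))
  expect_equal(densityWidth(po2$trajectory, po2$topology, axis = "x"),
               Lrod / sqrt(12), tolerance = 1e-3)
  # rotating an elongated body away from the axis narrows the width
  rot <- rod %*% t(slabtraj:::.rotationAbout("z", 60))
  po3 <- proteinOnlyTraj(list(sweep(rot, 2, c(4, 4, 0), `+`)),
                         box = c(12, 12, 4))
  expect_lt(densityWidth(po3$trajectory, po3$topology, axis = "x"),
            densityWidth(po2$trajectory, po2$topology, axis = "x"))
  # translation and atom-permutation invariance
  set.seed(2)
  perm <- sample(2000)
  po4 <- proteinOnlyTraj(list(sweep(rod[perm, ], 2, c(1, 0.5, 0), `+`)),
                         box = c(10, 4, 4))
  expect_equal(densityWidth(po4$trajectory, po4$topology, axis = "x"),
               densityWidth(po2$trajectory, po2$topology, axis = "x"),
               tolerance = 1e-12)
})

test_that("SASA of an isolated sphere matches the analytic value", {
  a <- shrakeRupleySASA(matrix(0, 1, 3), 0.17, probe = 0.14, nPoints = 960)
  expect_equal(a, 4 * pi * 0.31^2, tolerance = 0.02)
})

test_that("SASA of disjoint spheres is additive within 1%", {
  single <- shrakeRupleySASA(matrix(0, 1, 3), 0.17, nPoints = 960)
  pair <- shrakeRupleySASA(rbind(c(0, 0, 0), c(5, 0, 0)), c(0.17, 0.17),
                           nPoints = 960)
  expect_equal(sum(pair), 2 * single, tolerance = 0.01)
})

test_that("SASA error decays with sampling density on an occluded pair", {
  R <- 0.17 + 0.14; d <- 0.25
  exact <- 2 * 2 * pi * R * (R + d / 2)
  err <- vapply(c(60, 960, 7680), function(np)
    abs(sum(shrakeRupleySASA(rbind(c(0, 0, 0), c(d, 0, 0)), c(0.17, 0.17),
                             nPoints = np)) - exact) / exact, 0)
  expect_lt(err[2], err[1])
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.005)
})

test_that("interface-accessible area selects the slab and excludes distant atoms", {
  top1 <- Topology(name = "C1", species = "protein", mass = 12)
  # sphere centred on the interface plane, fully inside the slab
  a <- interfaceAccessibleArea(matrix(c(0, 0, 0), 1), top1,
                               interfacePosition = 0, slab = 1)
  expect_equal(a, 4 * pi * 0.31^2, tolerance = 0.02)
  # sphere entirely outside the slab
  expect_equal(interfaceAccessibleArea(matrix(c(3, 0, 0), 1), top1,
                                       interfacePosition = 0, slab = 1), 0)
})
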