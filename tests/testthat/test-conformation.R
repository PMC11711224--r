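test_that("RMSD obeys identity, rigid-motion and hand-computed cases", {
  a <- makeTestProtein(25)
  expect_equal(rmsdTo(a, a), 0)
  # rigid rotation + translation vanishes under superposition
  set.seed(4)
  moved <- sweep(a %*% randomRotation(), 2, c(1, -2, 0.5), `+`)
  expect_lt(rmsdTo(moved, a, superpose = TRUE), 1e-6)
  expect_gt(rmsdTo(moved, a, superpose = FALSE), 0.1)
  # 3-atom toy: one atom displaced by 0.3 nm, no superposition
  ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  frm <- ref; frm[1, 3] <- 0.3
  expect_equal(rmsdTo(frm, ref), sqrt(0.09 / 3), tolerance = 1e-12)
  expect_error(rmsdTo(ref[1:2, ], ref), "one-to-one")
})

test_that("superposed RMSD never exceeds raw RMSD", {
  set.seed(11)
  base <- makeTestProtein(30)
  for (k in 1:25) {
    frm <- sweep(base %*% randomRotation(), 2, rnorm(3, sd = 0.5), `+`) +
      matrix(rnorm(90, sd = 0.05), 30, 3)
    expect_lte(rmsdTo(frm, base, superpose = TRUE),
               rmsdTo(frm, base, superpose = FALSE) + 1e-12)
  }
})

test_that("superposed RMSD matches the independent bio3d implementation", {
  set.seed(12)
  base <- makeTestProtein(20)
  for (k in 1:5) {
    frm <- sweep(base %*% randomRotation(), 2, rnorm(3), `+`) +
      matrix(rnorm(60, sd = 0.08), 20, 3)
    mine <- rmsdTo(frm, base, superpose = TRUE)
    theirs <- bio3d::rmsd(as.numeric(t(base)), as.numeric(t(frm)),
                          fit = TRUE)  # bio3d reports 3 decimals
    expect_equal(round(mine, 3), theirs, tolerance = 1e-9)
  }
})

test_that("RMSF vanishes for a static trajectory and matches the square-wave closed form", {
  base <- makeTestProtein(10)
  po <- proteinOnlyTraj(rep(list(sweep(base, 2, c(5, 5, 5), `+`)), 8))
  r <- rmsfProfile(po$trajectory, po$topology,
                   selection = 1:10, window = c(0, 1))
  expect_equal(r$rmsf, rep(0, 10), tolerance = 1e-10)
  # one residue oscillating +/- 0.2 nm as a square wave -> RMSF 0.2 for it.
  # The mobile atom sits at the centre of a 99-atom shell so the rigid fit
  # has no lever arm to absorb its motion.
  shell <- slabtraj:::.spherePoints(99) * 1.5
  big <- sweep(rbind(shell, c(0, 0, 0)), 2, c(5, 5, 5), `+`)
  frames <- lapply(1:20, function(f) {
    m <- big
    m[100, 1] <- m[100, 1] + ifelse(f %% 2 == 0, 0.2, -0.2)
    m
  })
  po2 <- proteinOnlyTraj(frames)
  full <- rmsfProfile(po2$trajectory, po2$topology,
                      reference = frames[[1]],
                      selection = 1:100, window = c(0, 1))
  expect_equal(full$rmsf[100], 0.2, tolerance = 0.02)
  expect_lt(max(full$rmsf[-100]), 0.02)
})

test_that("isotropic Gaussian jitter gives RMSF near sigma * sqrt(3)", {
  set.seed(21)
  n <- 60; nf <- 4000; sig <- 0.04
  base <- sweep(makeTestProtein(n), 2, c(5, 5, 5), `+`)
  coords <- array(rep(base, nf), c(n, 3, nf)) +
    array(rnorm(n * 3 * nf, sd = sig), c(n, 3, nf))
  po <- proteinOnlyTraj(lapply(seq_len(nf), function(f) coords[, , f]))
  r <- rmsfProfile(po$trajectory, po$topology, reference = base,
                   selection = seq_len(n), window = c(0, 1))
  expect_equal(mean(r$rmsf), sig * sqrt(3), tolerance = 0.04)
})

test_that("RMSF window bounds are validated", {
  po <- proteinOnlyTraj(rep(list(makeTestProtein(5) + 5), 4))
  expect_error(rmsfProfile(po$trajectory, po$topology, selection = 1:5,
                           window = c(0.9, 2)), "window")
})

test_that("orientation classification recovers exact and perturbed library poses", {
  lib <- makeOrientationLibrary(makeTestProtein(40))
  labs <- orientationLabels(lib)
  # exact match, zero deviation
  got <- classifyOrientation(referenceCoords(lib, 3), lib)
  expect_equal(as.character(got), labs[3])
  expect_equal(unname(attr(got, "deviations")[labs[3]]), 0)
  # 10-degree rotation about the normal stays classified as the same pose,
  # verified against all six references
  for (i in seq_along(labs)) {
    tilted <- referenceCoords(lib, i) %*% t(slabtraj:::.rotationAbout("z", 10))
    expect_equal(as.character(classifyOrientation(tilted, lib)), labs[i])
  }
})

test_that("orientation ties break toward the earlier library label", {
  lib <- makeOrientationLibrary(makeTestProtein(40))
  # halfway (45 degrees) between the base pose and its 90-degree x-rotation
  halfway <- referenceCoords(lib, 1) %*% t(slabtraj:::.rotationAbout("x", 45))
  dev <- attr(classifyOrientation(halfway, lib), "deviations")
  expect_equal(unname(dev[1]), unname(dev[2]), tolerance = 1e-9)
  expect_equal(as.character(classifyOrientation(halfway, lib)),
               orientationLabels(lib)[1])
})

test_that("orientation classification is idempotent and reorder-invariant", {
  set.seed(31)
  lib <- makeOrientationLibrary(makeTestProtein(30))
  pose <- referenceCoords(lib, 5) + matrix(rnorm(90, sd = 0.02), 30, 3)
  first <- as.character(classifyOrientation(pose, lib))
  expect_equal(as.character(classifyOrientation(pose, lib)), first)
  # consistent reordering of atoms in both frame and library
  perm <- sample(30)
  libP <- new("OrientationLibrary",
              coords = lapply(referenceCoords(lib),
                              function(m) m[perm, , drop = FALSE]),
              labels = orientationLabels(lib))
  expect_equal(as.character(classifyOrientation(pose[perm, ], libP)), first)
})

test_that("planted orientation schedules are recovered on noise-free frames", {
  ref <- makeTestProtein(50, size = 0.8)
  lib <- makeOrientationLibrary(ref)
  sched <- rep(orientationLabels(lib), length.out = 12)
  prot <- pseudoProteinSpec(ref, library = lib, comStart = c(3, 2, 2),
                            orientations = sched)
  sim <- makeSlabTrajectory(slabSpec(box = c(8, 4, 4), interfaces = 5,
                                     nFrames = 12, seed = 17), prot)
  got <- classifyOrientations(sim$trajectory, sim$topology, lib)
  expect_equal(got, sched)
})

test_that("orientation x regime statistics conserve counts and recover planted medians", {
  series <- data.frame(
    frame = 0:19, time = 0:19,
    rmsd = c(rep(0.2, 10), rep(0.6, 10)),
    orientation = rep("purple", 20),
    distance = c(rep(5, 10), rep(0.8, 10)))
  st <- orientationResolvedStats(series, regimeThresholds(1.2, 3))
  expect_equal(sum(st$n), 20)
  expect_equal(st$median[st$regime == "far"], 0.2)
  expect_equal(st$median[st$regime == "close"], 0.6)
  # single-cell series: cell median equals the global median
  one <- series[series$distance < 1, ]
  st1 <- orientationResolvedStats(one, regimeThresholds(1.2, 3))
  expect_equal(nrow(st1), 1)
  expect_equal(st1$median, median(one$rmsd))
})
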