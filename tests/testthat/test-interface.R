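test_that("density profile of a single particle equals mass over bin volume", {
  hs <- handSlab(waterX = 2.05, organicX = 8.05, box = c(10, 4, 4))
  prof <- densityProfile(hs$trajectory, hs$topology, nBins = 100)
  d <- profileDensity(prof)
  binVol <- 16 * 0.1
  expect_equal(max(d[, "water"]), 18 / binVol * 1.66053906660,
               tolerance = 1e-9)
  expect_equal(sum(d[, "water"] > 0), 1)
})

test_that("sharp slab profiles plateau at bulk density on one side and zero on the other", {
  sim <- makeSlabTrajectory(slabSpec(box = c(10, 4, 4), interfaces = 5,
                                     mixingWidth = 0, nFrames = 4, seed = 2))
  prof <- densityProfile(sim$trajectory, sim$topology, nBins = 50)
  d <- profileDensity(prof)
  ctr <- profileCenters(prof)
  expect_lt(abs(mean(d[ctr < 4, "water"]) - 997) / 997, 0.01)
  expect_equal(sum(d[ctr > 5.2, "water"]), 0)
  expect_equal(sum(d[ctr < 4.8, "organic"]), 0)
})

test_that("integrated profile recovers total species mass within 0.5%", {
  sim <- makeSlabTrajectory(slabSpec(box = c(8, 3, 3), interfaces = 4,
                                     mixingWidth = 0.4, nFrames = 3,
                                     seed = 8))
  prof <- densityProfile(sim$trajectory, sim$topology, nBins = 40)
  a <- atomData(sim$topology)
  for (s in c("water", "organic")) {
    integrated <- sum(profileDensity(prof)[, s]) * prof@area *
      prof@binWidth / 1.66053906660
    expect_lt(abs(integrated - sum(a$mass[a$species == s])) /
                sum(a$mass[a$species == s]), 0.005)
  }
})

test_that("profile bulk plateau is stable under bin refinement", {
  sim <- makeSlabTrajectory(slabSpec(box = c(8, 3, 3), interfaces = 4,
                                     nFrames = 4, seed = 12))
  bulk <- function(nb) {
    p <- densityProfile(sim$trajectory, sim$topology, nBins = nb)
    mean(profileDensity(p)[profileCenters(p) < 3, "water"])
  }
  expect_lt(abs(bulk(20) - bulk(40)) / bulk(20), 0.02)
})

test_that("histogram locator recovers a sharp planted interface within a bin", {
  sim <- makeSlabTrajectory(slabSpec(box = c(10, 4, 4), interfaces = 5,
                                     mixingWidth = 0, nFrames = 4, seed = 2))
  im <- locateInterfaceHistogram(sim$trajectory, sim$topology, pbc = FALSE)
  expect_true(all(abs(interfacePositions(im) - 5) <= 0.1))
})

test_that("histogram locator recovers both periodic interfaces", {
  sim <- makeSlabTrajectory(slabSpec(box = c(10, 4, 4),
                                     interfaces = c(2.5, 7.5),
                                     mixingWidth = 0.4, nFrames = 4,
                                     seed = 4))
  im <- locateInterfaceHistogram(sim$trajectory, sim$topology)
  pos <- interfacePositions(im)
  expect_equal(ncol(pos), 2)
  expect_true(all(abs(pos[, 1] - 2.5) <= 0.1 + 1e-9))
  expect_true(all(abs(pos[, 2] - 7.5) <= 0.1 + 1e-9))
})

test_that("fully separated phases raise a no-interface error", {
  hs <- handSlab(waterX = c(1, 1.2, 1.4), organicX = c(8, 8.2, 8.4))
  expect_error(locateInterfaceHistogram(hs$trajectory, hs$topology,
                                        pbc = FALSE),
               "fully separated")
})

test_that("histogram locator is invariant to atom relabeling and equivariant to translation", {
  sim <- makeSlabTrajectory(slabSpec(box = c(8, 3, 3), interfaces = 4,
                                     mixingWidth = 0.3, nFrames = 2,
                                     seed = 6))
  im <- locateInterfaceHistogram(sim$trajectory, sim$topology, pbc = FALSE)
  # shuffle atom order consistently in topology and coordinates
  set.seed(1)
  perm <- sample(nAtoms(sim$topology))
  a <- atomData(sim$topology)[perm, ]
  topP <- Topology(name = a$name, species = a$species, mass = a$mass,
                   chain = a$chain, resid = a$resid, resname = a$resname)
  trajP <- Trajectory(sim$trajectory@coords[perm, , , drop = FALSE],
                      sim$trajectory@box, frameTimes(sim$trajectory))
  imP <- locateInterfaceHistogram(trajP, topP, pbc = FALSE)
  expect_equal(interfacePositions(imP), interfacePositions(im))
  # translate everything by +1 nm along the normal (box widened to keep
  # all particles inside)
  shifted <- sim$trajectory@coords
  shifted[, 1, ] <- shifted[, 1, ] + 1
  boxT <- sim$trajectory@box
  boxT[, 1] <- boxT[, 1] + 2
  trajT <- Trajectory(shifted, boxT, frameTimes(sim$trajectory))
  imT <- locateInterfaceHistogram(trajT, sim$topology, pbc = FALSE)
  expect_equal(interfacePositions(imT), interfacePositions(im) + 1,
               tolerance = 0.051)
})

test_that("Gibbs construction solves the step profile exactly and respects translation", {
  expect_equal(locateInterfaceGibbs(stepProfile(5)), 5, tolerance = 1e-6)
  # translated by +1 nm -> x_b shifts by exactly +1 nm
  expect_equal(locateInterfaceGibbs(stepProfile(6)),
               locateInterfaceGibbs(stepProfile(5)) + 1, tolerance = 1e-6)
})

test_that("Gibbs construction finds the centre of an antisymmetric tanh profile", {
  expect_equal(locateInterfaceGibbs(tanhProfile(5, w = 0.6)), 5,
               tolerance = 1e-3)
  expect_equal(locateInterfaceGibbs(tanhProfile(4.3, w = 1.0)), 4.3,
               tolerance = 1e-3)
})

test_that("Gibbs construction refuses profiles without bulk plateaus", {
  centers <- (1:100 - 0.5) / 10
  ramp <- handProfile(centers, 997 * (1 - centers / 10),
                      1322 * centers / 10)
  expect_error(locateInterfaceGibbs(ramp), "plateau")
})

test_that("histogram and Gibbs locators agree within one bin on diffuse protein-free slabs", {
  sim <- makeSlabTrajectory(slabSpec(box = c(10, 4, 4), interfaces = 5,
                                     mixingWidth = 0.8, nFrames = 6,
                                     seed = 5))
  im <- locateInterfaceHistogram(sim$trajectory, sim$topology, pbc = FALSE)
  gb <- locateInterfaceGibbs(densityProfile(sim$trajectory, sim$topology,
                                            nBins = 50))
  expect_lt(abs(mean(interfacePositions(im)) - gb), 0.1)
})

test_that("histogram locator tolerates a protein sitting at the interface", {
  spec <- slabSpec(box = c(10, 4, 4), interfaces = 5, mixingWidth = 0.3,
                   nFrames = 4, seed = 13)
  bare <- locateInterfaceHistogram(makeSlabTrajectory(spec)$trajectory,
                                   makeSlabTrajectory(spec)$topology,
                                   pbc = FALSE)
  ref <- makeTestProtein(50, size = 0.8)
  prot <- pseudoProteinSpec(ref, comStart = c(5, 2, 2))
  sim <- makeSlabTrajectory(spec, prot)
  withProt <- locateInterfaceHistogram(sim$trajectory, sim$topology,
                                       pbc = FALSE)
  expect_lt(max(abs(interfacePositions(withProt) -
                      interfacePositions(bare))), 0.1 + 1e-9)
})

test_that("signed COM distance is positive on the water side and zero on the plane", {
  # water on [0, 5): protein at x = 3.6 is 1.4 nm on the water side
  prot <- cbind(c(3.55, 3.65), 2, 2)
  hs <- handSlab(waterX = seq(0.1, 4.9, by = 0.1),
                 organicX = seq(5.1, 9.9, by = 0.1))
  a <- atomData(hs$topology)
  top <- Topology(name = c(a$name, "CA", "CA"),
                  species = c(a$species, "protein", "protein"),
                  mass = c(a$mass, 110, 110),
                  chain = c(a$chain, "P", "P"),
                  resid = c(a$resid, 1L, 2L),
                  resname = c(a$resname, "PRT", "PRT"))
  coords <- rbind(cbind(c(seq(0.1, 4.9, by = 0.1),
                          seq(5.1, 9.9, by = 0.1)), 2, 2), prot)
  traj <- Trajectory(coords, c(10, 4, 4))
  im <- InterfaceModel(matrix(5), "x", "planted")
  expect_equal(proteinInterfaceDistance(traj, top, im), 1.4,
               tolerance = 1e-9)
  # COM exactly on the interface
  coords0 <- coords
  coords0[99:100, 1] <- c(4.95, 5.05)
  expect_equal(proteinInterfaceDistance(Trajectory(coords0, c(10, 4, 4)),
                                        top, im), 0, tolerance = 1e-9)
})

test_that("with two interfaces the nearer one is used under minimum image", {
  # water interior [2, 7); protein COM at x = 1, i.e. 1 nm outside via the
  # lower interface and 4 nm via the upper one
  sim <- makeSlabTrajectory(slabSpec(box = c(10, 4, 4),
                                     interfaces = c(2, 7), mixingWidth = 0,
                                     nFrames = 1, seed = 3))
  a <- atomData(sim$topology)
  top <- Topology(name = c(a$name, "CA", "CA"),
                  species = c(a$species, "protein", "protein"),
                  mass = c(a$mass, 110, 110),
                  chain = c(a$chain, "P", "P"),
                  resid = c(a$resid, 1L, 2L),
                  resname = c(a$resname, "PRT", "PRT"))
  coords <- rbind(frameCoords(sim$trajectory, 1), cbind(c(0.9, 1.1), 2, 2))
  traj <- Trajectory(coords, c(10, 4, 4))
  im <- InterfaceModel(matrix(c(2, 7), 1), "x", "planted")
  expect_equal(proteinInterfaceDistance(traj, top, im), -1,
               tolerance = 1e-9)
  # and a COM inside the water slab is positive
  coords2 <- coords
  coords2[nrow(coords) - 1:0, 1] <- c(2.9, 3.1)
  expect_equal(proteinInterfaceDistance(Trajectory(coords2, c(10, 4, 4)),
                                        top, im), 1, tolerance = 1e-9)
})
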