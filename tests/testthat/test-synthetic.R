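small_params <- function(nFrames = 10L, nSites = 6L,
                         nLipidsPerLeaflet = 8L, ...) {
  syntheticParams(nFrames = nFrames, nSites = nSites,
                  nLipidsPerLeaflet = nLipidsPerLeaflet,
                  residuesPerChain = 12L, ...)
}

test_that("generation is bit-identical under a seed and differs across seeds", {
  a <- generateMembraneTrajectory(small_params(seed = 101L))
  b <- generateMembraneTrajectory(small_params(seed = 101L))
  c <- generateMembraneTrajectory(small_params(seed = 102L))
  expect_identical(coords(a$trajectory), coords(b$trajectory))
  expect_identical(a$groundTruth$occupancy, b$groundTruth$occupancy)
  expect_false(identical(coords(a$trajectory), coords(c$trajectory)))
  # the generator leaves the caller's RNG stream untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generateMembraneTrajectory(small_params()))
  expect_identical(runif(1), before)
})

test_that("permanently bound sites give unit contact fractions", {
  p <- small_params(occupancyModel = "markov", pOn = 1, pOff = 0,
                    jitter = 0, seed = 7L)
  g <- generateMembraneTrajectory(p)
  expect_true(all(g$groundTruth$occupancy))
  traj <- classifyParticles(g$trajectory, bundledScheme("martini"))
  rt <- lipidContactFractions(traj, params = contactParams(window = c(0, 1)))
  sites <- match(g$groundTruth$siteMoleculeIds,
                 lipidTable(rt)$molecule_id)
  expect_equal(lipidTable(rt)$contact_fraction[sites], rep(1, 6))
  # the residence histogram is a point mass at 1 for the sites
  h <- rt@histogram
  expect_equal(h$count[h$bin_lo == max(h$bin_lo[h$count > 0])], 6L)
})

test_that("independent-frame occupancy recovers p within binomial error", {
  p <- small_params(nFrames = 200L, nSites = 30L, pOcc = 0.25, seed = 61L)
  g <- generateMembraneTrajectory(p)
  occ <- colMeans(g$groundTruth$occupancy)
  tol <- 3 * sqrt(0.25 * 0.75 / 200)
  expect_gt(mean(abs(occ - 0.25) <= tol), 0.9)
})

test_that("closed-form expectations follow the stated formulas", {
  p <- small_params(occupancyModel = "markov", pOn = 0.2, pOff = 0.6)
  gt <- groundTruthExpectations(p)
  expect_equal(gt$stationaryOccupancy, 0.2 / 0.8)
  expect_equal(gt$contactFractionVar(100), 0.25 * 0.75 / 100)
  # thickness profile: pinned at the annular value near the protein,
  # relaxing exponentially to bulk
  f <- gt$thicknessAt
  expect_equal(f(0), 35)
  expect_equal(f(p@proteinRadius + 3), 35)
  edge <- p@proteinRadius + 6
  expect_equal(f(edge + 5), 50 - 15 * exp(-1))
  expect_lt(abs(f(edge + 50) - 50), 1e-3)
  # degenerate kinetics: permanently bound, zero variance
  p0 <- small_params(occupancyModel = "markov", pOn = 1, pOff = 0,
                     jitter = 0)
  gt0 <- groundTruthExpectations(p0)
  expect_equal(gt0$stationaryOccupancy, 1)
  expect_equal(gt0$contactFractionVar(100), 0)
})

test_that("generated systems round-trip through the I/O layer", {
  g <- generateMembraneTrajectory(small_params(nFrames = 3L, seed = 3L))
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeTrajectory(g$trajectory, tf)
  back <- readTrajectory(tf, resolution = "coarse_grained")
  expect_equal(topology(back)$resname, topology(g$trajectory)$resname)
  expect_lt(max(abs(coords(back) - coords(g$trajectory))), 0.0011)
  fg <- withr::local_tempfile(fileext = ".gro")
  writeStructure(getFrame(g$trajectory, 1), fg)
  sys <- readStructure(fg, resolution = "coarse_grained")
  expect_lt(max(abs(coords(sys) - coords(getFrame(g$trajectory, 1)))),
            0.006)
})

test_that("infeasible packing and invalid parameters are rejected", {
  expect_error(generateMembraneTrajectory(
    small_params(nLipidsPerLeaflet = 10000L)), "packing|capacity")
  expect_error(syntheticParams(annularThickness = 60, bulkThickness = 50),
               "annular")
  expect_error(syntheticParams(pOcc = 1.5), "probabilities")
  expect_error(syntheticParams(occupancyModel = "teleport"),
               "occupancyModel")
})

test_that("synthetic crystals carry the designed census and P-P distance", {
  cr <- makeSyntheticCrystal(nLipids = 12, ppDistance = 35, seed = 5L)
  sch <- bundledScheme("martini")
  expect_equal(annularLipidCensus(cr, sch), 12L)
  ann <- classifyParticles(cr, sch)
  expect_lt(abs(bilayerPPDistance(ann) - 35), 0.5)
  # the double-layer (octameric) assembly doubles the complement
  asm <- buildDoubleLayerAssembly(cr)
  expect_equal(annularLipidCensus(asm, sch), 24L)
  p <- particles(asm)
  expect_equal(length(unique(p$chain[p$resname != "DSP"])), 8L)
})
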