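test_that("contact fractions hit the always/never extremes", {
  near <- rbind(p_row(0, 0, 0), lip_rows(4, 0, 1, 2), lip_rows(50, 0, 1, 3))
  traj <- traj_from_systems(replicate(6, annot_from_rows(near),
                                      simplify = FALSE))
  rt <- lipidContactFractions(traj, params = contactParams(
    cutoff = 6, window = c(0, 1)))
  l <- lipidTable(rt)
  expect_equal(l$contact_fraction, c(1, 0))
  expect_equal(l$n_binding_events, c(1L, 0L))
  expect_equal(l$longest_run, c(6L, 0L))
  expect_equal(sum(rt@histogram$count), 2L)
})

test_that("binding events tolerate single-frame losses; longest_run does not", {
  near <- rbind(p_row(0, 0, 0), lip_rows(4, 0, 1, 2))
  far <- rbind(p_row(0, 0, 0), lip_rows(50, 0, 1, 2))
  # pattern over 7 frames: on on off on on off off
  frames <- lapply(c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
                   function(on) annot_from_rows(if (on) near else far))
  traj <- traj_from_systems(frames)
  w <- contactParams(cutoff = 6, window = c(0, 1))
  rt <- lipidContactFractions(traj, params = w, eventTolerance = 1L)
  l <- lipidTable(rt)
  expect_equal(l$contact_fraction, 4 / 7)
  expect_equal(l$n_binding_events, 1L)  # the single off-frame is absorbed
  expect_equal(l$longest_run, 2L)       # raw runs are not merged
  rt0 <- lipidContactFractions(traj, params = w, eventTolerance = 0L)
  expect_equal(lipidTable(rt0)$n_binding_events, 2L)
})

test_that("contact fraction is monotone in the cutoff", {
  g <- generateMembraneTrajectory(
    syntheticParams(nFrames = 20L, nSites = 8L, nLipidsPerLeaflet = 10L,
                    pOcc = 0.5, seed = 31L))
  traj <- classifyParticles(g$trajectory, bundledScheme("martini"))
  w <- function(cut) contactParams(cutoff = cut, window = c(0, 1))
  f4 <- lipidTable(lipidContactFractions(traj, params = w(4)))
  f6 <- lipidTable(lipidContactFractions(traj, params = w(6)))
  f9 <- lipidTable(lipidContactFractions(traj, params = w(9)))
  expect_true(all(f6$contact_fraction >= f4$contact_fraction))
  expect_true(all(f9$contact_fraction >= f6$contact_fraction))
})

test_that("fractions recover the Markov stationary occupancy", {
  p <- syntheticParams(nFrames = 400L, nSites = 60L,
                       nLipidsPerLeaflet = 10L,
                       occupancyModel = "markov", pOn = 0.15, pOff = 0.15,
                       seed = 37L)
  g <- generateMembraneTrajectory(p)
  traj <- classifyParticles(g$trajectory, bundledScheme("martini"))
  rt <- lipidContactFractions(traj, params = contactParams(window = c(0, 1)))
  gt <- groundTruthExpectations(p)
  expect_equal(gt$stationaryOccupancy, 0.5)
  sites <- match(g$groundTruth$siteMoleculeIds,
                 lipidTable(rt)$molecule_id)
  fr <- lipidTable(rt)$contact_fraction[sites]
  # mean over 60 lipids within 3 standard errors of the stationary value
  se <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.5), 3 * se + 1e-9)
  # measured series equals the generated occupancy exactly
  expect_equal(fr, unname(colMeans(g$groundTruth$occupancy)))
})

test_that("fraction spread matches the binomial variance for independent frames", {
  p <- syntheticParams(nFrames = 250L, nSites = 80L,
                       nLipidsPerLeaflet = 10L, pOcc = 0.3, seed = 41L)
  g <- generateMembraneTrajectory(p)
  traj <- classifyParticles(g$trajectory, bundledScheme("martini"))
  rt <- lipidContactFractions(traj, params = contactParams(window = c(0, 1)))
  sites <- match(g$groundTruth$siteMoleculeIds,
                 lipidTable(rt)$molecule_id)
  fr <- lipidTable(rt)$contact_fraction[sites]
  v_expect <- 0.3 * 0.7 / 250
  # chi-square bounds on the sample variance of 80 binomial fractions
  ratio <- stats::var(fr) / v_expect
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 1.8)
})

test_that("max-contact trace picks ties by lowest molecule id", {
  near <- rbind(p_row(0, 0, 0), lip_rows(4, 0, 1, 2), lip_rows(0, 4, 1, 3))
  far <- rbind(p_row(0, 0, 0), lip_rows(50, 0, 1, 2), lip_rows(0, 50, 1, 3))
  frames <- lapply(c(TRUE, FALSE), function(on)
    annot_from_rows(if (on) near else far))
  traj <- traj_from_systems(frames)
  rt <- lipidContactFractions(traj, params = contactParams(
    cutoff = 6, window = c(0, 1)))
  l <- lipidTable(rt)
  expect_equal(l$contact_fraction, c(0.5, 0.5))
  tr <- maxContactLipidTrace(traj, rt)
  expect_equal(attr(tr, "molecule_id"), min(l$molecule_id))
  expect_equal(nrow(tr), 2L)
  # all-zero fractions still trace, with a warning
  traj0 <- traj_from_systems(list(annot_from_rows(far)))
  rt0 <- lipidContactFractions(traj0, params = contactParams(
    cutoff = 6, window = c(0, 1)))
  expect_warning(tr0 <- maxContactLipidTrace(traj0, rt0), "zero")
  expect_equal(attr(tr0, "molecule_id"), min(lipidTable(rt0)$molecule_id))
})

test_that("a sticky-site lipid's trace alternates site residence and bulk", {
  p <- syntheticParams(nFrames = 80L, nSites = 2L, nLipidsPerLeaflet = 10L,
                       occupancyModel = "markov", pOn = 0.3, pOff = 0.3,
                       jitter = 0.2, seed = 43L)
  g <- generateMembraneTrajectory(p)
  traj <- classifyParticles(g$trajectory, bundledScheme("martini"))
  rt <- lipidContactFractions(traj, params = contactParams(window = c(0, 1)))
  tr <- maxContactLipidTrace(traj, rt)
  mol <- attr(tr, "molecule_id")
  s <- which(g$groundTruth$siteMoleculeIds == mol)
  occ <- g$groundTruth$occupancy[, s]
  # protein xy drift is ~zero by construction; the aligned trace is the
  # absolute position minus the box-centre protein origin
  sxy <- g$groundTruth$siteXY[s, ]
  ctr <- p@boxLengths[1:2] / 2
  d <- sqrt((tr$x - (sxy[1] - ctr[1]))^2 + (tr$y - (sxy[2] - ctr[2]))^2)
  expect_true(all(d[occ] < 2))      # resident frames cluster at the site
  expect_true(all(d[!occ] > 5))     # off frames are out in the bulk
})

test_that("residence histogram partitions all lipids", {
  g <- generateMembraneTrajectory(
    syntheticParams(nFrames = 30L, nSites = 10L, nLipidsPerLeaflet = 15L,
                    pOcc = 0.4, seed = 47L))
  traj <- classifyParticles(g$trajectory, bundledScheme("martini"))
  rt <- lipidContactFractions(traj, params = contactParams(window = c(0, 1)))
  expect_equal(sum(rt@histogram$count), nrow(lipidTable(rt)))
  expect_equal(nrow(lipidTable(rt)), 10 + 30)
  l <- lipidTable(rt)
  expect_true(all((l$n_binding_events >= 1) == (l$contact_fraction > 0)))
  expect_true(all(l$longest_run <= round(l$contact_fraction * rt@nFrames)))
})
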