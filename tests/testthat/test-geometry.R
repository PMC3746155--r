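test_that("leaflet assignment splits phosphates about the midplane", {
  rows <- do.call(rbind, c(
    lapply(1:4, function(i) lip_rows(i * 10, 0, 17.5, i, sgn = 1)),
    lapply(5:8, function(i) lip_rows(i * 10, 0, -17.5, i, sgn = -1))))
  lf <- assignLeaflets(annot_from_rows(rows))
  expect_equal(sum(lf$leaflet == "upper"), 4L)
  expect_equal(sum(lf$leaflet == "lower"), 4L)
  # one lipid flipped to the other side is assigned there
  rows2 <- rbind(rows[1:(7 * 4), ], lip_rows(80, 0, -17.5, 8, sgn = -1))
  lf2 <- assignLeaflets(annot_from_rows(rows2))
  expect_equal(lf2$leaflet[lf2$molecule_id ==
                           lf2$molecule_id[length(lf2$molecule_id)]],
               "lower")
  # coplanar phosphates cannot be split
  flat <- do.call(rbind, lapply(1:4, function(i) lip_rows(i * 10, 0, 0, i)))
  expect_error(assignLeaflets(annot_from_rows(flat)), "coplanar")
})

test_that("leaflet assignment matches the generator's ground truth", {
  g <- generateMembraneTrajectory(
    syntheticParams(nFrames = 3L, nSites = 10L, nLipidsPerLeaflet = 30L,
                    seed = 13L))
  traj <- classifyParticles(g$trajectory, bundledScheme("martini"))
  lf <- assignLeaflets(getFrame(traj, 2))
  truth <- g$groundTruth$lipidLeaflet
  expect_equal(lf$leaflet,
               unname(truth[as.character(lf$molecule_id)]))
})

test_that("a single static lipid gives a one-bin density of integral 1", {
  rows <- rbind(p_row(0, 0, 0), p_row(0, 0, 1, "BB", "GLY", 2),
                lip_rows(10, 10, 17.5, 3), lip_rows(12, 8, -17.5, 4))
  frames <- replicate(10, annot_from_rows(rows), simplify = FALSE)
  traj <- traj_from_systems(frames)
  d <- phosphateDensity(traj, "upper", spacing = 1,
                        params = contactParams(window = c(0, 1)))
  v <- gridValues(d)
  expect_equal(sum(v > 0), 1L)
  expect_equal(sum(v) * 1^2, 1.0)
  expect_error(phosphateDensity(traj, "upper", spacing = 1,
                                params = contactParams(window = c(0, 0.05))),
               "window")
})

test_that("density integral equals the mean per-frame phosphate count", {
  g <- generateMembraneTrajectory(
    syntheticParams(nFrames = 40L, nSites = 12L, nLipidsPerLeaflet = 25L,
                    seed = 17L))
  traj <- classifyParticles(g$trajectory, bundledScheme("martini"))
  for (sp in c(1, 2)) {
    d <- phosphateDensity(traj, "upper", spacing = sp)
    # upper leaflet holds half the sites and half the bulk lipids
    expect_equal(sum(gridValues(d)) * sp^2, 6 + 25, tolerance = 1e-12)
  }
})

test_that("coarse density bins equal block-sums of nested finer bins", {
  set.seed(5)
  # points confined to [0, 8)^2 so both grids share the origin
  rows <- do.call(rbind, c(
    list(p_row(4, 4, 0), lip_rows(0.15, 0.15, 17.5, 99),
         lip_rows(0.2, 0.3, -17.5, 100, sgn = -1)),
    lapply(1:30, function(i)
      lip_rows(runif(1, 0.1, 7.9), runif(1, 0.1, 7.9),
               sample(c(-17.5, 17.5), 1), i + 1))))
  traj <- traj_from_systems(list(annot_from_rows(rows)))
  w <- contactParams(window = c(0, 1))
  fine <- gridValues(phosphateDensity(traj, "upper", spacing = 1,
                                      params = w))
  coarse <- gridValues(phosphateDensity(traj, "upper", spacing = 2,
                                        params = w))
  # pad fine grid to even dimensions before 2x2 block aggregation
  fm <- matrix(0, 2 * nrow(coarse), 2 * ncol(coarse))
  fm[seq_len(nrow(fine)), seq_len(ncol(fine))] <- fine
  block <- 0.25 * (fm[c(TRUE, FALSE), c(TRUE, FALSE)] +
                   fm[c(FALSE, TRUE), c(TRUE, FALSE)] +
                   fm[c(TRUE, FALSE), c(FALSE, TRUE)] +
                   fm[c(FALSE, TRUE), c(FALSE, TRUE)])
  expect_equal(block, coarse, tolerance = 1e-12)
})

test_that("a flat bilayer has uniform thickness equal everywhere", {
  set.seed(3)
  rows <- do.call(rbind, c(list(p_row(30, 30, 0)), lapply(1:40, function(i)
    lip_rows(runif(1, 0, 60), runif(1, 0, 60),
             ifelse(i %% 2 == 0, 17.5, -17.5), i + 1,
             sgn = ifelse(i %% 2 == 0, 1, -1)))))
  traj <- traj_from_systems(replicate(5, annot_from_rows(rows),
                                      simplify = FALSE))
  tm <- thicknessMap(traj, spacing = 10,
                     params = contactParams(window = c(0, 1)))
  v <- gridValues(tm)
  expect_true(all(abs(v[!is.na(v)] - 35) < 1e-9))
  if (!is.na(annularThickness(tm)))
    expect_equal(annularThickness(tm), 35)
  expect_equal(bulkThickness(tm), 35)
})

test_that("thickness recovers the generator's bulk and annular values", {
  g <- generateMembraneTrajectory(syntheticParams(nFrames = 150L,
                                                  seed = 23L))
  traj <- classifyParticles(g$trajectory, bundledScheme("martini"))
  tm <- thicknessMap(traj)
  expect_lt(abs(bulkThickness(tm) - 50), 1)
  expect_lt(abs(annularThickness(tm) - 35), 1)
  # thickness is unchanged by a rigid translation of the whole system
  moved <- traj
  moved@coords <- traj@coords + 7.3
  tm2 <- thicknessMap(moved)
  expect_equal(bulkThickness(tm2), bulkThickness(tm), tolerance = 1e-9)
  expect_equal(annularThickness(tm2), annularThickness(tm),
               tolerance = 1e-9)
})

test_that("axial distributions land residue types in the right z bins", {
  rows <- rbind(p_row(5, 0, 15, "BB", "TRP", 1),
                p_row(5, 5, 0, "BB", "LEU", 2),
                lip_rows(20, 0, 17.5, 3), lip_rows(20, 5, -17.5, 4,
                                                   sgn = -1))
  traj <- traj_from_systems(replicate(4, annot_from_rows(rows),
                                      simplify = FALSE))
  expect_warning(
    h <- axialDistribution(traj, c("TRP", "LYS"), binWidth = 1,
                           params = contactParams(window = c(0, 1))),
    "LYS")
  expect_equal(colnames(h@counts), c("TRP", "LYS"))
  expect_equal(sum(h@counts[, "LYS"]), 0)
  trp <- h@counts[, "TRP"]
  hit <- which(trp > 0)
  expect_length(hit, 1L)
  # all mass in the bin containing z = +15 (midplane at 0)
  expect_true(h@breaks[hit] <= 15 && 15 <= h@breaks[hit + 1])
  # head-group band straddles the phosphate levels
  expect_true(h@headgroupBand["upper", "lo"] <= 17.5 &&
              17.5 <= h@headgroupBand["upper", "hi"] + 1e-9)
})

test_that("grids round-trip through the plain-text format", {
  g <- new("PlanarGrid", origin = c(-4, 6), spacing = 1.5,
           values = matrix(c(0, 1.25, NA, 3), 2, 2), kind = "thickness")
  tf <- withr::local_tempfile(fileext = ".txt")
  writeGrid(g, tf)
  back <- readGrid(tf)
  expect_equal(back@origin, g@origin)
  expect_equal(back@spacing, g@spacing)
  expect_equal(back@kind, g@kind)
  expect_equal(back@values, g@values)
})
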