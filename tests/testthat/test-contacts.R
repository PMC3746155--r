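test_that("contacts respect the cutoff boundary", {
  mk <- function(x) annot_from_rows(
    rbind(p_row(0, 0, 0), p_row(x, 0, 0, "C1A", "LIP", 2, "L")))
  inside <- frameContacts(mk(5.9), contactParams(cutoff = 6))
  expect_equal(nrow(inside), 1L)
  expect_equal(inside$segment, "tail")
  expect_equal(inside$distance, 5.9)
  outside <- frameContacts(mk(6.1), contactParams(cutoff = 6))
  expect_equal(nrow(outside), 0L)
})

test_that("minimum-image contacts see across the periodic boundary", {
  ann <- annot_from_rows(
    rbind(p_row(0.5, 50, 50), p_row(99.5, 50, 50, "PO4", "LIP", 2, "L")),
    box = c(100, 100, 100))
  ct <- frameContacts(ann, contactParams(cutoff = 6, usePbc = TRUE))
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$distance, 1.0)
  # without PBC the pair is far apart
  ct2 <- frameContacts(ann, contactParams(cutoff = 6, usePbc = FALSE))
  expect_equal(nrow(ct2), 0L)
  # requesting PBC without a box errors
  ann2 <- annot_from_rows(
    rbind(p_row(0.5, 50, 50), p_row(99.5, 50, 50, "PO4", "LIP", 2, "L")))
  expect_error(frameContacts(ann2, contactParams(usePbc = TRUE)), "box")
})

test_that("cell-list search equals brute force on random systems", {
  set.seed(42)
  for (rep in 1:25) {
    nA <- sample(20:150, 1)
    nB <- sample(20:350, 1)
    box <- runif(3, 25, 60)
    A <- cbind(runif(nA, -10, box[1] + 10), runif(nA, 0, box[2]),
               runif(nA, 0, box[3]))
    B <- cbind(runif(nB, 0, box[1]), runif(nB, 0, box[2]),
               runif(nB, -5, box[3] + 5))
    cutoff <- runif(1, 3, 9)
    for (bx in list(NULL, box)) {
      a <- neighborPairs(A, B, cutoff, bx, method = "cell")
      b <- neighborPairs(A, B, cutoff, bx, method = "brute")
      oa <- order(a$i, a$j); ob <- order(b$i, b$j)
      expect_identical(a$i[oa], b$i[ob])
      expect_identical(a$j[oa], b$j[ob])
      expect_identical(a$dist[oa], b$dist[ob])
    }
  }
})

test_that("increasing the cutoff never removes a contact pair", {
  set.seed(7)
  A <- matrix(runif(60, 0, 30), ncol = 3)
  B <- matrix(runif(120, 0, 30), ncol = 3)
  small <- neighborPairs(A, B, 4)
  big <- neighborPairs(A, B, 7)
  expect_true(all(paste(small$i, small$j) %in% paste(big$i, big$j)))
})

test_that("analysis window excludes early frames", {
  # residue in contact only in the first 2 of 10 frames
  near <- rbind(p_row(0, 0, 0), lip_rows(3, 0, 2, 2))
  far <- rbind(p_row(0, 0, 0), lip_rows(40, 0, 2, 2))
  frames <- c(replicate(2, annot_from_rows(near), simplify = FALSE),
              replicate(8, annot_from_rows(far), simplify = FALSE))
  traj <- traj_from_systems(frames)
  prof <- contactProfile(traj, params = contactParams(cutoff = 6))
  expect_equal(profileTable(prof)$headgroup_fraction, 0)
  # with the full window the fraction is 2/10
  prof2 <- contactProfile(traj,
                          params = contactParams(cutoff = 6,
                                                 window = c(0, 1)))
  expect_equal(profileTable(prof2)$headgroup_fraction, 0.2)
  expect_error(contactProfile(traj,
                              params = contactParams(window = c(0, 0.05))),
               "window")
})

test_that("contact fractions equal the constructed occupancy", {
  # one residue, lipid present in 6 of 10 frames (head groups only:
  # the tail bead is 7 A below the phosphate, outside the cutoff)
  near <- rbind(p_row(0, 0, 0), lip_rows(3.9, 0, 1, 2))
  far <- rbind(p_row(0, 0, 0), lip_rows(40, 0, 1, 2))
  frames <- c(replicate(6, annot_from_rows(near), simplify = FALSE),
              replicate(4, annot_from_rows(far), simplify = FALSE))
  traj <- traj_from_systems(frames)
  prof <- contactProfile(traj, params = contactParams(cutoff = 5,
                                                      window = c(0, 1)))
  r <- profileTable(prof)
  expect_equal(r$headgroup_fraction, 0.6)
  expect_equal(r$phosphate, 0.6)
  expect_equal(r$tail, 0)  # tail bead sits 7 A below the phosphate
  expect_true(all(r$headgroup_fraction >=
                  pmax(r$head_terminal, r$phosphate, r$glycerol)))
})

test_that("profiles are invariant under joint rigid motion (no PBC)", {
  g <- generateMembraneTrajectory(
    syntheticParams(nFrames = 8L, nSites = 6L, nLipidsPerLeaflet = 6L,
                    residuesPerChain = 12L, pOcc = 0.7, seed = 9L))
  traj <- classifyParticles(g$trajectory, bundledScheme("martini"))
  w <- contactParams(window = c(0, 1))
  p1 <- contactProfile(traj, params = w)
  th <- 0.3
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- traj
  for (f in seq_len(nFrames(traj))) {
    m <- coords(traj, frame = f) %*% t(Rz)
    moved@coords[, , f] <- sweep(m, 2, c(5, -3, 11), "+")
  }
  p2 <- contactProfile(moved, params = w)
  expect_equal(profileTable(p1)$headgroup_fraction,
               profileTable(p2)$headgroup_fraction)
  expect_equal(profileTable(p1)$tail_fraction,
               profileTable(p2)$tail_fraction)
})

test_that("crystal profiles are 0/1 indicators and react to translation", {
  rows <- rbind(p_row(0, 0, 0, resseq = 11),
                p_row(0, 0, 5, resseq = 12),
                lip_rows(3.5, 0, 0, 20))
  ann <- annot_from_rows(rows)
  prof <- crystalContactProfile(ann, contactParams(cutoff = 4))
  r <- profileTable(prof)
  expect_equal(prof@scale, "binary")
  expect_equal(r$headgroup_fraction[r$resseq == 11], 1)
  expect_equal(r$headgroup_fraction[r$resseq == 12], 0)
  # shift the lipid far beyond the cutoff: all-zero profile
  rows2 <- rbind(p_row(0, 0, 0, resseq = 11),
                 p_row(0, 0, 5, resseq = 12),
                 lip_rows(3.5, 0, 100, 20))
  prof2 <- crystalContactProfile(annot_from_rows(rows2),
                                 contactParams(cutoff = 4))
  expect_true(all(profileTable(prof2)$headgroup_fraction == 0))
  # no lipids at all is an error
  expect_error(
    crystalContactProfile(annot_from_rows(p_row(0, 0, 0))), "lipid")
})

test_that("interacting-lipid count uses the phosphate-within-cutoff rule", {
  rows <- rbind(p_row(0, 0, 0),
                lip_rows(5, 0, 0, 2), lip_rows(7, 0, 0, 3),
                lip_rows(0, 5.5, 0, 4))
  # phosphates at 5, 7 and 5.5 A; tail beads are below the protein plane
  ann <- annot_from_rows(rows)
  traj <- traj_from_systems(list(ann, ann))
  out <- interactingLipidCount(traj,
                               params = contactParams(cutoff = 6,
                                                      window = c(0, 1)))
  expect_equal(out$counts, c(2L, 2L))
  expect_equal(out$mean, 2)
})

test_that("Pearson correlation matches the hand-computed formula", {
  p1 <- mk_profile(c("ALA", "GLY", "TRP", "LYS"),
                   head = c(0.2, 0.8, 0.4, 0.6), tail = c(1, 2, 3, 4) / 4)
  p2 <- mk_profile(c("ALA", "GLY", "TRP", "LYS"),
                   head = c(0.1, 0.9, 0.2, 0.5), tail = c(3, 2, 1, 0) / 4)
  # independent evaluation: covariance over product of standard deviations
  x <- c(0.2, 0.8, 0.4, 0.6); y <- c(0.1, 0.9, 0.2, 0.5)
  n <- 4
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  r_hand <- sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
                   sqrt(sum((y - mean(y))^2) / (n - 1)))
  expect_equal(as.numeric(correlateProfiles(p1, p2, "headgroup")), r_hand,
               tolerance = 1e-12)
  expect_equal(as.numeric(correlateProfiles(p1, p1, "headgroup")), 1.0)
  expect_equal(as.numeric(correlateProfiles(p1, p2, "tail")), -1.0)
})

test_that("correlation handles zero variance, scale mixing and key alignment", {
  pflat <- mk_profile(c("ALA", "GLY", "TRP"), head = c(0.5, 0.5, 0.5),
                      tail = c(0, 0, 0))
  pvar <- mk_profile(c("ALA", "GLY", "TRP"), head = c(0.1, 0.5, 0.9),
                     tail = c(0, 1, 0))
  r <- correlateProfiles(pflat, pvar, "headgroup")
  expect_true(is.na(r))
  expect_true(attr(r, "undefined"))
  # non-shared residues are dropped, and < 3 shared is an error
  plong <- mk_profile(c("ALA", "GLY", "TRP", "LYS"),
                      head = c(0.1, 0.5, 0.9, 0.3), tail = rep(0, 4))
  r2 <- correlateProfiles(plong, pvar, "headgroup")
  expect_equal(attr(r2, "n_shared"), 3L)
  expect_equal(attr(r2, "n_dropped"), 1L)
  pshort <- mk_profile(c("ALA", "GLY"), head = c(0.1, 0.5), tail = c(0, 0))
  expect_error(correlateProfiles(pshort, pvar, "headgroup"), "shared")
  pbin <- mk_profile(c("ALA", "GLY", "TRP"), head = c(0, 1, 1),
                     tail = c(0, 0, 1), scale = "binary")
  expect_true(attr(correlateProfiles(pvar, pbin, "headgroup"),
                   "mixed_scale"))
})

test_that("correlation is invariant to affine rescaling up to sign", {
  x <- c(0.1, 0.7, 0.3, 0.9, 0.5)
  p1 <- mk_profile(rep("ALA", 5), head = x, tail = x)
  p2 <- mk_profile(rep("ALA", 5), head = 0.5 * x + 0.1, tail = x)
  expect_equal(as.numeric(correlateProfiles(p1, p2, "headgroup")), 1,
               tolerance = 1e-12)
})

test_that("correlation matrix splits channels across the triangles", {
  ps <- list(
    a = mk_profile(c("ALA", "GLY", "TRP"), head = c(0.1, 0.5, 0.9),
                   tail = c(0.2, 0.1, 0.6)),
    b = mk_profile(c("ALA", "GLY", "TRP"), head = c(0.2, 0.4, 0.8),
                   tail = c(0.6, 0.1, 0.2)),
    c = mk_profile(c("ALA", "GLY", "TRP"), head = c(0.9, 0.1, 0.1),
                   tail = c(0.3, 0.3, 0.1)))
  m <- correlationMatrix(ps)
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(m[i, j],
                 as.numeric(correlateProfiles(ps[[i]], ps[[j]],
                                              "headgroup")))
    expect_equal(m[j, i],
                 as.numeric(correlateProfiles(ps[[j]], ps[[i]], "tail")))
  }
  # identical profiles correlate at 1 in both triangles
  m2 <- correlationMatrix(list(x = ps$a, y = ps$a))
  expect_equal(unname(m2), matrix(1, 2, 2))
})

test_that("profile TSV round-trips through write/read", {
  p <- mk_profile(c("ALA", "GLY", "TRP"), head = c(0.1, 0.5, 0.9),
                  tail = c(0.2, 0.1, 0.6), tag = "demo")
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeProfile(p, tf)
  back <- readProfile(tf)
  expect_equal(profileTable(back), profileTable(p))
  expect_equal(back@sourceTag, "demo")
  expect_equal(back@nFrames, p@nFrames)
})

test_that("subunit averaging pools chains at aligned residue numbers", {
  r1 <- mk_profile(c("ALA", "GLY"), head = c(0.2, 0.4), tail = c(0, 0),
                   chain = "A")
  r2 <- mk_profile(c("ALA", "GLY"), head = c(0.6, 0.0), tail = c(0, 0),
                   chain = "B")
  both <- new("ContactProfile",
              residues = rbind(profileTable(r1), profileTable(r2)),
              nFrames = 10L, sourceTag = "t", scale = "fraction")
  avg <- averageSubunits(both)
  expect_equal(profileTable(avg)$headgroup_fraction, c(0.4, 0.2))
  expect_equal(unique(profileTable(avg)$chain), "*")
})
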