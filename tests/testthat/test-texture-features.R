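# Discretization, co-occurrence and run-length matrices, their features,
# and the gradient energies.

make_voi <- function(u, maskarr, n_levels = 16)
  discretize_voi(vol_of(u), mask_of(maskarr), n_levels = n_levels)

test_that("discretization bins masked SUVs between VOI min and max", {
  # constant VOI: everything maps to level 1
  u <- array(4, dim = c(3, 3, 3))
  d <- make_voi(u, array(TRUE, dim = c(3, 3, 3)))
  expect_true(all(d$levels[d$levels > 0] == 1L))
  expect_equal(d$histogram[1], 27)

  # values 0..15 with 16 levels: one voxel per level
  u2 <- array(0, dim = c(4, 4, 2))
  u2[1:16] <- 0:15
  msk <- array(FALSE, dim = c(4, 4, 2)); msk[1:16] <- TRUE
  d2 <- make_voi(u2, msk)
  expect_identical(sort(d2$levels[d2$levels > 0L]), 1:16)

  # random VOI against loop-based binning
  set.seed(51)
  v <- random_voi(c(5, 5, 5))
  d3 <- make_voi(v$u, v$mask, n_levels = 8)
  s <- v$u[v$mask]
  ref <- pmin(8, floor(8 * (s - min(s)) / (max(s) - min(s))) + 1)
  expect_equal(d3$histogram, tabulate(ref, nbins = 8))
  expect_equal(sum(d3$histogram), sum(v$mask))
})

test_that("co-occurrence matrix matches hand and brute-force enumeration", {
  # two adjacent voxels with levels 3 and 5: symmetric halves
  lev_u <- array(0, dim = c(2, 2, 2))
  lev_u[1, 1, 1] <- 3; lev_u[2, 1, 1] <- 5
  msk <- lev_u > 0
  # craft SUVs whose 16-level discretization yields exactly levels 3, 5
  u <- array(0, dim = c(2, 2, 2))
  u[1, 1, 1] <- 2.1; u[2, 1, 1] <- 4.3   # levels from relative binning
  d <- make_voi(u, msk, n_levels = 16)
  # the exact levels depend on binning; instead drive build_cm via a
  # controlled discretized object for the fixture:
  d$levels[] <- 0L; d$levels[1, 1, 1] <- 3L; d$levels[2, 1, 1] <- 5L
  cm <- build_cm(d)
  expect_equal(cm$p[3, 5], 0.5)
  expect_equal(cm$p[5, 3], 0.5)
  expect_equal(sum(cm$p), 1)
  expect_identical(cm$pairs, 2L)

  # constant 2x2x2 VOI: all mass at (1,1)
  dc <- make_voi(array(2, dim = c(2, 2, 2)), array(TRUE, dim = c(2, 2, 2)))
  cmc <- build_cm(dc)
  expect_equal(cmc$p[1, 1], 1)

  # random masked regions: exact match to the triple-loop oracle
  set.seed(52)
  for (rep in 1:10) {
    v <- random_voi(c(5, 5, 5), p_mask = 0.6)
    d <- make_voi(v$u, v$mask, n_levels = 4)
    cm <- build_cm(d)
    expect_equal(cm$counts, oracle_cm_counts(d$levels, 4))
    expect_true(isSymmetric(cm$counts))
  }
})

test_that("CM features reproduce hand-evaluated fixtures", {
  # homogeneous limit
  p1 <- matrix(0, 16, 16); p1[1, 1] <- 1
  f1 <- cm_features(p1)
  expect_equal(unname(f1), c(0, 1, 0, 0, 1))

  # 0.5 at (1,2) and (2,1)
  p2 <- matrix(0, 16, 16); p2[1, 2] <- 0.5; p2[2, 1] <- 0.5
  f2 <- cm_features(p2)
  expect_equal(f2[["ENT"]], log(2), tolerance = 1e-12)
  expect_equal(f2[["HOM"]], 0.5, tolerance = 1e-12)
  expect_equal(f2[["CON"]], 1, tolerance = 1e-12)
  expect_equal(f2[["DIS"]], 1, tolerance = 1e-12)
  expect_equal(f2[["UNI"]], 0.5, tolerance = 1e-12)

  # random normalized CMs vs independent double loop
  set.seed(53)
  for (rep in 1:5) {
    p <- matrix(runif(36), 6, 6); p <- (p + t(p)); p <- p / sum(p)
    f <- cm_features(p)
    ent <- hom <- con <- dis <- uni <- 0
    for (i in 1:6) for (j in 1:6) {
      if (p[i, j] > 0) ent <- ent - p[i, j] * log(p[i, j])
      hom <- hom + p[i, j] / (1 + (i - j)^2)
      con <- con + p[i, j] * (i - j)^2
      dis <- dis + p[i, j] * abs(i - j)
      uni <- uni + p[i, j]^2
    }
    expect_equal(unname(f), c(ent, hom, con, dis, uni))
    expect_lte(f[["DIS"]], sqrt(f[["CON"]]) + 1e-12)   # Jensen
  }
  expect_error(cm_features(matrix(0.3, 2, 2)), "normalized")
})

test_that("run-length matrix matches hand enumeration and the oracle", {
  # a single masked voxel: 13 runs of length 1
  msk <- array(FALSE, dim = c(3, 3, 3)); msk[2, 2, 2] <- TRUE
  u <- array(0, dim = c(3, 3, 3)); u[2, 2, 2] <- 5
  r1 <- build_rlm(make_voi(u, msk))
  expect_identical(r1$n_runs, 13L)
  expect_equal(r1$counts[1, 1], 13)

  # 1x1x4 constant line: 1 run of 4 along the line, 48 singletons
  msk2 <- array(FALSE, dim = c(3, 3, 6)); msk2[2, 2, 2:5] <- TRUE
  u2 <- array(0, dim = c(3, 3, 6)); u2[2, 2, 2:5] <- 7
  r2 <- build_rlm(make_voi(u2, msk2))
  expect_identical(r2$n_runs, 49L)
  expect_equal(r2$counts[1, 4], 1)
  expect_equal(r2$counts[1, 1], 48)
  expect_equal(sum(r2$counts), 49)

  # random regions: exact equality with the walking oracle, plus the
  # conservation law sum_ij RLM(i,j) * j = 13 * |mask|
  set.seed(54)
  for (rep in 1:10) {
    v <- random_voi(c(5, 5, 5), p_mask = 0.6)
    d <- make_voi(v$u, v$mask, n_levels = 4)
    r <- build_rlm(d)
    ref <- oracle_rlm_counts(d$levels, 4)
    expect_equal(unname(r$counts), unname(ref), ignore_attr = TRUE)
    expect_equal(sum(r$counts * col(r$counts)), 13 * sum(v$mask))
    expect_identical(r$n_runs, as.integer(sum(ref)))
  }
})

test_that("RLM features reproduce hand-evaluated fixtures", {
  # degenerate: k singleton runs at level 1
  k <- 7L
  r <- structure(list(counts = matrix(c(k, rep(0, 15)), 16, 1),
                      n_runs = k, n_directions = 13L, n_voxels = k),
                 class = "run_length_matrix")
  f <- rlm_features(r)
  expect_equal(f[["SRE"]], 1); expect_equal(f[["LRE"]], 1)
  expect_equal(f[["RPC"]], 1); expect_equal(f[["LGRE"]], 1)
  expect_equal(f[["HGRE"]], 1)
  expect_equal(f[["GLNU"]], k); expect_equal(f[["RLNU"]], k)

  # the 1x1x4 line fixture
  cnt <- matrix(0, 16, 4); cnt[1, 1] <- 48; cnt[1, 4] <- 1
  rl <- structure(list(counts = cnt, n_runs = 49L, n_directions = 13L,
                       n_voxels = 4L), class = "run_length_matrix")
  fl <- rlm_features(rl)
  expect_equal(fl[["SRE"]], (48 + 1 / 16) / 49, tolerance = 1e-12)
  expect_equal(fl[["LRE"]], 64 / 49, tolerance = 1e-12)
  expect_equal(fl[["RPC"]], 49 / 52, tolerance = 1e-12)

  # random RLMs vs independent double loop
  set.seed(55)
  for (rep in 1:5) {
    cnt <- matrix(rpois(5 * 4, 2), 5, 4)
    cnt[1, 1] <- cnt[1, 1] + 1   # nonempty
    rr <- structure(list(counts = cnt, n_runs = sum(cnt),
                         n_directions = 13L, n_voxels = NA),
                    class = "run_length_matrix")
    f <- rlm_features(rr)
    nr <- sum(cnt)
    acc <- c(SRE = 0, LRE = 0, LGRE = 0, HGRE = 0, SRLGE = 0, SRHGE = 0,
             LRLGE = 0, LRHGE = 0)
    for (i in 1:5) for (j in 1:4) {
      acc["SRE"] <- acc["SRE"] + cnt[i, j] / j^2
      acc["LRE"] <- acc["LRE"] + cnt[i, j] * j^2
      acc["LGRE"] <- acc["LGRE"] + cnt[i, j] / i^2
      acc["HGRE"] <- acc["HGRE"] + cnt[i, j] * i^2
      acc["SRLGE"] <- acc["SRLGE"] + cnt[i, j] / (i^2 * j^2)
      acc["SRHGE"] <- acc["SRHGE"] + cnt[i, j] * i^2 / j^2
      acc["LRLGE"] <- acc["LRLGE"] + cnt[i, j] * j^2 / i^2
      acc["LRHGE"] <- acc["LRHGE"] + cnt[i, j] * i^2 * j^2
    }
    expect_equal(f[names(acc)], acc / nr)
    expect_equal(f[["GLNU"]], sum(rowSums(cnt)^2) / nr)
    expect_equal(f[["RLNU"]], sum(colSums(cnt)^2) / nr)
    expect_equal(f[["RPC"]], nr / sum(cnt * col(cnt)))
  }
})

test_that("gradient energies: homogeneous limit, scaling, ramp oracle", {
  # constant VOI: zero gradient
  u <- array(6, dim = c(4, 4, 4))
  m <- mask_of(array(TRUE, dim = c(4, 4, 4)))
  e <- energy_features(vol_of(u), m)
  expect_equal(unname(e), c(0, 0))

  # homogeneity of degree 0: invariant under u -> c u
  set.seed(56)
  v <- random_voi(c(5, 5, 5))
  e1 <- energy_features(vol_of(v$u, c(2, 2, 3)), mask_of(v$mask))
  e2 <- energy_features(vol_of(4 * v$u, c(2, 2, 3)), mask_of(v$mask))
  expect_equal(e1, e2)

  # linear ramp u = a * x on a full 4x4x4 mask, unit spacing:
  # gradient magnitude a everywhere (central interior, one-sided edges)
  a <- 0.7
  x <- array(rep(1:4, 16), dim = c(4, 4, 4))
  ur <- a * x
  er <- energy_features(vol_of(ur), m)
  num <- sqrt(64 * a^2)                     # sum |grad u|^2 dV, dV = 1
  expect_equal(er[["SE"]], num / sqrt(sum(ur^2)), tolerance = 1e-12)
  expect_equal(er[["TE"]], num / (4 * a), tolerance = 1e-12)
})

test_that("feature extraction is deterministic and orders heterogeneity", {
  set.seed(57)
  ph <- make_phantom(phantom_spec(grid_shape = c(32, 32, 18),
                                  lesion_axes = c(26, 26, 26),
                                  texture_amplitude = 0.3, seed = 5))
  mask <- segment_lesion(ph$pet1, ph$truth$box)
  f1 <- extract_features(ph$pet1, mask)
  f2 <- extract_features(ph$pet1, mask)
  expect_identical(f1, f2)

  # smooth field vs the same voxel values spatially shuffled: identical
  # level histogram, but rougher local texture
  dmv <- c(12, 12, 12)
  ramp <- array(rep(seq(0, 10, length.out = 12), each = 1), dim = dmv)
  smooth <- vol_of(ramp + 0.2 * array(rnorm(prod(dmv)), dim = dmv) + 5)
  full <- mask_of(array(TRUE, dim = dmv))
  shuffled <- smooth
  shuffled$suv[] <- sample(smooth$suv)
  ds <- discretize_voi(shuffled, full)
  do <- discretize_voi(smooth, full)
  expect_identical(ds$histogram, do$histogram)
  fs <- extract_features(shuffled, full)
  fo <- extract_features(smooth, full)
  expect_gt(fs[["CON"]], fo[["CON"]])
  expect_gt(fs[["DIS"]], fo[["DIS"]])
  expect_gt(fs[["SE"]], fo[["SE"]])
  expect_lt(fs[["HOM"]], fo[["HOM"]])
})

test_that("features approach the homogeneous limit as noise vanishes", {
  # constant lesion with shrinking additive noise, discretized against
  # fixed bounds (relative per-lesion binning is amplitude-invariant by
  # construction, so the limit is only visible with fixed bounds):
  # ENT, CON, DIS, SE trend down to 0; HOM, UNI trend up to 1
  base <- array(5, dim = c(6, 6, 6))
  m <- mask_of(array(TRUE, dim = c(6, 6, 6)))
  set.seed(58)
  eps <- array(rnorm(216), dim = c(6, 6, 6))
  amp <- c(0.8, 0.4, 0.2, 0.1, 0)
  feats <- sapply(amp, function(a) {
    vol <- vol_of(pmax(base + a * eps, 0))
    d <- discretize_voi(vol, m, n_levels = 16, bounds = c(0, 10))
    c(cm_features(build_cm(d)), energy_features(vol, m))
  })
  # exact homogeneous limit at zero noise
  expect_equal(unname(feats[c("ENT", "CON", "DIS", "SE"), 5]), c(0, 0, 0, 0))
  expect_equal(unname(feats[c("HOM", "UNI"), 5]), c(1, 1))
  for (k in c("ENT", "CON", "DIS", "SE")) {
    expect_true(all(diff(feats[k, ]) <= 1e-12), info = k)
    expect_gt(feats[k, 1], feats[k, 5])
  }
  for (k in c("HOM", "UNI")) {
    expect_true(all(diff(feats[k, ]) >= -1e-12), info = k)
    expect_lt(feats[k, 1], feats[k, 5])
  }
})
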