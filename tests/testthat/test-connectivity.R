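make_tiny_connectome <- function(ts_list, shape = c(2, 2, 2)) {
  g <- mm_grid(shape)
  mask <- array(TRUE, shape)
  connectome_dataset(g, mask, ts_list)
}

test_that("seed time-courses are site-weighted voxel means", {
  g <- mm_grid(c(2, 2, 2))
  mask <- array(TRUE, c(2, 2, 2))
  set.seed(9)
  ts <- matrix(rnorm(10 * 8), 10, 8)
  # single voxel
  s1 <- single_voxel_site(g, mask, 3L)
  expect_equal(seed_timecourse(s1, ts, mask), ts[, 3])
  # equal weights on voxels 1 and 2
  m <- array(0, c(2, 2, 2)); m[1:2, 1, 1] <- 1
  s2 <- lesion_site(brain_volume(g, m, mask))
  expect_equal(seed_timecourse(s2, ts, mask), (ts[, 1] + ts[, 2]) / 2)
  # weights 0.75 / 0.25 via a weighted tms-like site built directly
  w <- array(0, c(2, 2, 2)); w[1, 1, 1] <- 0.75; w[2, 1, 1] <- 0.25
  s3 <- circuitmap:::new_stimulation_site("tms", brain_volume(g, w, mask))
  expect_equal(seed_timecourse(s3, ts, mask), 0.75 * ts[, 1] + 0.25 * ts[, 2])
})

test_that("seed connectivity: perfect correlation clips, orthogonality gives 0", {
  g <- mm_grid(c(2, 2, 2)); mask <- array(TRUE, c(2, 2, 2))
  seed_series <- as.numeric(scale(sin(1:32)))
  # every voxel identical to the seed
  ts <- matrix(rep(seed_series, 8), 32, 8)
  con <- make_tiny_connectome(list(ts))
  cm <- seed_connectivity(single_voxel_site(g, mask, 1L), con)
  expect_equal(unname(cm$zmap$data[2, 1, 1]), atanh(1 - 1e-7))
  expect_equal(cm$n_subjects_used, 1L)
  # a voxel exactly orthogonal to the seed
  orth <- as.numeric(scale(cos(1:32)))
  orth <- orth - seed_series * sum(orth * seed_series) / sum(seed_series^2)
  ts2 <- ts; ts2[, 5] <- orth
  cm2 <- seed_connectivity(single_voxel_site(g, mask, 1L),
                           make_tiny_connectome(list(ts2)))
  expect_lt(abs(cm2$zmap$data[1, 1, 2]), 1e-12)  # voxel 5 -> index (1,1,2)
})

test_that("opposite correlations across two subjects average to zero z", {
  g <- mm_grid(c(2, 2, 2)); mask <- array(TRUE, c(2, 2, 2))
  set.seed(11)
  a <- as.numeric(scale(rnorm(40)))
  b <- as.numeric(scale(rnorm(40)))
  b <- as.numeric(scale(b - a * sum(a * b) / sum(a^2)))
  mix <- function(r) as.numeric(scale(r * a + sqrt(1 - r^2) * b))
  ts_pos <- matrix(rep(a, 8), 40, 8); ts_pos[, 2] <- mix(0.5)
  ts_neg <- matrix(rep(a, 8), 40, 8); ts_neg[, 2] <- mix(-0.5)
  cm <- seed_connectivity(single_voxel_site(g, mask, 1L),
                          make_tiny_connectome(list(ts_pos, ts_neg)))
  expect_equal(unname(cm$zmap$data[2, 1, 1]), 0, tolerance = 1e-10)
})

test_that("seed connectivity is invariant to positive rescaling of time-series", {
  g <- mm_grid(c(2, 2, 2)); mask <- array(TRUE, c(2, 2, 2))
  set.seed(4)
  ts <- matrix(rnorm(30 * 8), 30, 8)
  site <- single_voxel_site(g, mask, 2L)
  cm1 <- seed_connectivity(site, make_tiny_connectome(list(ts)))
  cm2 <- seed_connectivity(site, make_tiny_connectome(list(ts * 37.5)))
  expect_equal(cm1$zmap$data, cm2$zmap$data, tolerance = 1e-12)
})

test_that("S identical subjects give the single-subject map; zero-variance seeds are skipped", {
  g <- mm_grid(c(2, 2, 2)); mask <- array(TRUE, c(2, 2, 2))
  set.seed(5)
  ts <- matrix(rnorm(30 * 8), 30, 8)
  site <- single_voxel_site(g, mask, 4L)
  cm1 <- seed_connectivity(site, make_tiny_connectome(list(ts)))
  cm3 <- seed_connectivity(site, make_tiny_connectome(list(ts, ts, ts)))
  expect_equal(cm1$zmap$data, cm3$zmap$data, tolerance = 1e-12)
  expect_equal(cm3$n_subjects_used, 3L)
  # a subject with a flat seed voxel is skipped with a warning
  flat <- ts; flat[, 4] <- 1
  expect_warning(cmx <- seed_connectivity(site,
                                          make_tiny_connectome(list(ts, flat))),
                 "skipped")
  expect_equal(cmx$n_subjects_used, 1L)
  expect_error(suppressWarnings(
    seed_connectivity(site, make_tiny_connectome(list(flat)))), "skipped|usable")
})

test_that("dbs pairs are rejected as seeds", {
  g <- mm_grid(c(2, 2, 2)); mask <- array(TRUE, c(2, 2, 2))
  l <- array(0, c(2, 2, 2)); l[1, 1, 1] <- 1
  r <- array(0, c(2, 2, 2)); r[2, 1, 1] <- 1
  pair <- dbs_pair_site(brain_volume(g, l), brain_volume(g, r))
  ts <- matrix(rnorm(30 * 8), 30, 8)
  expect_error(seed_connectivity(pair, make_tiny_connectome(list(ts))),
               "overlap")
})

test_that("mean zmap converges to atanh of the model correlation (factor oracle)", {
  # factor model: cor(x_u, x_v) = a_u * a_v, seed = voxel 1
  g <- mm_grid(c(3, 3, 3))
  mask <- array(TRUE, c(3, 3, 3))
  V <- 27; Tn <- 200; S <- 50
  loadings <- seq(0.9, 0.1, length.out = V)
  con <- factor_connectome(g, mask, loadings, S, Tn, seed = 202)
  cm <- seed_connectivity(single_voxel_site(g, mask, 1L), con)
  z <- cm$zmap$data[c(14, 27)]           # two probe voxels
  rho <- loadings[1] * loadings[c(14, 27)]
  se <- 1 / sqrt((Tn - 3) * S)
  expect_true(all(abs(z - atanh(rho)) < 3 * se + abs(rho) / (2 * (Tn - 1)) * 3))
})

test_that("within-circuit connectivity: constructed extremes, symmetry, white-noise null", {
  g <- mm_grid(c(3, 3, 3)); mask <- array(TRUE, c(3, 3, 3))
  vals <- c(rep(1, 5), rep(-1, 5), rep(0, 17))
  circuit <- volume_from_mask(g, mask, vals)
  set.seed(21)
  a <- as.numeric(scale(rnorm(60)))
  ts <- matrix(rnorm(60 * 27) * 1e-6, 60, 27)
  ts[, 1:5] <- a; ts[, 6:10] <- -a
  zmax <- atanh(1 - 1e-7)
  s <- within_circuit_connectivity(circuit, ts, mask, top_fraction = 1)
  expect_gt(s, 3 * zmax - 0.5)
  # P/N swap symmetry under negation (pole sizes equal, no subsampling)
  neg <- volume_from_mask(g, mask, -vals)
  expect_equal(within_circuit_connectivity(neg, ts, mask, top_fraction = 1), s)
  # independent white noise: mean score over subjects near 0
  scores <- vapply(1:30, function(i) {
    set.seed(100 + i)
    within_circuit_connectivity(circuit, matrix(rnorm(60 * 27), 60, 27), mask,
                                top_fraction = 1)
  }, numeric(1))
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores)), 3 * se + 0.01)
  # degenerate inputs
  allpos <- volume_from_mask(g, mask, abs(vals) + 0.1)
  expect_error(within_circuit_connectivity(allpos, ts, mask), "positive and negative")
})

test_that("control network scores: constructed blocks and 7-network counting", {
  g <- mm_grid(c(3, 3, 3)); mask <- array(TRUE, c(3, 3, 3))
  set.seed(31)
  a <- as.numeric(scale(rnorm(50)))
  b <- as.numeric(scale(rnorm(50)))
  b <- as.numeric(scale(b - a * sum(a * b) / sum(a^2)))
  ts <- matrix(0, 50, 27)
  ts[, 1:4] <- a + matrix(rnorm(50 * 4), 50, 4) * 1e-4
  ts[, 5:8] <- b + matrix(rnorm(50 * 4), 50, 4) * 1e-4
  labels <- c(rep(1L, 4), rep(2L, 4), rep(0L, 19))
  sc <- control_network_scores(ts, labels)
  within1 <- sc$score[sc$net_a == 1 & sc$net_b == 1]
  between <- sc$score[sc$net_a == 1 & sc$net_b == 2]
  expect_gt(within1, 4)
  expect_lt(abs(between), 0.2)
  # 7 networks -> 28 rows (7 within + 21 between)
  labels7 <- rep(1:7, length.out = 27)
  sc7 <- control_network_scores(matrix(rnorm(50 * 27), 50, 27), labels7)
  expect_equal(nrow(sc7), 28L)
  expect_equal(sum(sc7$type == "within"), 7L)
  expect_equal(sum(sc7$type == "between"), 21L)
  expect_error(control_network_scores(ts, c(1L, rep(0L, 26))), "2 networks")
})
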