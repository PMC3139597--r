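test_that("L-function matches closed-form values on hand-checked patterns", {
  # two points 10 m apart in a 10,000 m^2 region
  b <- distance_bins(100, 10)
  l2 <- l_function(c(0, 10), c(0, 0), bins = b, area = 1e4)
  # the pair sits exactly at the first bin edge (closed upper bound), so
  # every edge >= 10 m sees it
  expect_equal(l2, rep(sqrt(1e4 * 2 / (pi * 2)), length(b$edges)),
               tolerance = 1e-12)
  expect_equal(round(l2[1], 2), 56.42)
  lfine <- l_function(c(0, 10), c(0, 0), bins = distance_bins(100, 4),
                      area = 1e4)
  expect_equal(lfine[1:2], c(0, 0))  # below the pair separation L is zero

  # three collinear points at 0, 30, 100 in a 200 x 200 region
  b2 <- distance_bins(200, 50)
  l3 <- l_function(c(0, 30, 100), c(0, 0, 0), bins = b2, area = 4e4)
  expect_equal(l3[1], sqrt(4e4 * 2 / (pi * 6)), tolerance = 1e-12)
  expect_equal(round(l3[1], 2), 65.15)

  # same points, weights (2, 1, 1)
  lw <- l_function(c(0, 30, 100), c(0, 0, 0), c(2, 1, 1), b2, 4e4)
  expect_equal(lw[1], sqrt(4e4 * 4 / (pi * 10)), tolerance = 1e-12)
  expect_equal(round(lw[1], 2), 71.36)
})

test_that("L-function equals the naive double-loop oracle to 1e-9 relative error", {
  set.seed(21)
  for (n in c(5, 37, 200)) {
    x <- runif(n, 0, 1000); y <- runif(n, 0, 500)
    b <- distance_bins(600, 60)
    expect_rel_equal(l_function(x, y, bins = b, area = 5e5),
                     naive_l(x, y, NULL, b$edges, 5e5), 1e-9)
    w <- rpois(n, 5); w[1:2] <- pmax(w[1:2], 1)  # zeros allowed elsewhere
    expect_rel_equal(l_function(x, y, w, b, 5e5),
                     naive_l(x, y, w, b$edges, 5e5), 1e-9)
  }
})

test_that("L respects monotonicity, scale equivariance and edge-tie handling", {
  set.seed(22)
  for (rep in 1:5) {
    n <- sample(10:80, 1)
    x <- runif(n, 0, 800); y <- runif(n, 0, 800)
    w <- sample(1:6, n, replace = TRUE)
    b <- distance_bins(1000, 100)
    l <- l_function(x, y, w, b, 6.4e5)
    expect_true(all(diff(l) >= -1e-12))
    # scaling space by c scales L by c
    cf <- 3.7
    bs <- distance_bins(1000 * cf, 100 * cf)
    ls <- l_function(x * cf, y * cf, w, bs, 6.4e5 * cf^2)
    expect_rel_equal(ls, l * cf, 1e-9)
  }
  # a pair at exactly a bin edge counts toward that bin (closed upper bound)
  b <- distance_bins(100, 50)
  l <- l_function(c(0, 50), c(0, 0), bins = b, area = 1e4)
  expect_gt(l[1], 0)
})

test_that("toroidal edge correction wraps distances and preserves translation invariance", {
  b <- distance_bins(100, 20)
  # points hugging opposite edges of a 1000-wide strip: 20 m apart on the torus
  l_plain <- l_function(c(10, 990), c(0, 0), bins = b, area = 1e5)
  l_torus <- l_function(c(10, 990), c(0, 0), bins = b, area = 1e5,
                        torus = c(1000, 100))
  expect_equal(l_plain[1], 0)
  expect_gt(l_torus[1], 0)
  # translating a pattern on the torus leaves L unchanged
  set.seed(55)
  x <- runif(40, 0, 1000); y <- runif(40, 0, 500)
  l1 <- l_function(x, y, bins = b, area = 5e5, torus = c(1000, 500))
  l2 <- l_function((x + 333) %% 1000, (y + 111) %% 500, bins = b,
                   area = 5e5, torus = c(1000, 500))
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("degenerate L-function inputs are rejected", {
  b <- distance_bins(100, 10)
  expect_error(l_function(1, 1, bins = b, area = 100), "2 points")
  expect_error(l_function(c(0, 1), c(0, 1), c(0, 0), b, 100), "positive weight")
  expect_error(l_function(c(0, 1), c(0, 1), c(-1, 1), b, 100), "nonnegative")
  expect_error(distance_bins(100, 30), "multiple")
})

test_that("CSR envelopes behave at their boundaries and calibrate on uniform data", {
  reg <- region_rectangle(0, 1000, 0, 1000)
  b <- distance_bins(500, 100)
  e1 <- csr_envelope(30, region = reg, bins = b, n_sims = 1, seed = 1)
  expect_identical(e1$low, e1$high)

  # uniform data: observed curve inside the 99-draw envelope at >= 90% of
  # bins (median over 20 seeds)
  frac_inside <- vapply(1:20, function(s) {
    set.seed(s)
    pts <- runif_pts <- cbind(runif(100, 0, 1000), runif(100, 0, 1000))
    l <- l_function(pts[, 1], pts[, 2], bins = b, area = 1e6)
    e <- csr_envelope(100, region = reg, bins = b, n_sims = 99, seed = s + 100)
    mean(l >= e$low & l <= e$high)
  }, 0)
  expect_gte(median(frac_inside), 0.9)
})

test_that("strong clustering is detected as significant at short range", {
  reg <- region_rectangle(0, 1000, 0, 1000)
  b <- distance_bins(500, 100)
  hits <- vapply(1:20, function(s) {
    cfg <- scenario_config(n_transects = 100, region = reg,
                           location_process = "clustered",
                           offspring_sd = 30, offspring_per_parent = 10)
    pts <- generate_transect_locations(cfg, seed = s)
    lf_obs <- l_function(pts[, 1], pts[, 2], bins = b, area = 1e6)
    e <- csr_envelope(100, region = reg, bins = b, n_sims = 99, seed = s + 40)
    any(lf_obs[1:2] > e$high[1:2])
  }, TRUE)
  expect_gte(sum(hits), 18)
})

test_that("difference function vanishes when disease equals the population", {
  s <- tiny_survey()
  rec <- s$records
  rec$n_diseased <- rec$n_colonies  # every colony diseased
  all_dis <- survey_dataset(rec, region = s$region)
  for (m in c("transect", "colony")) {
    d <- difference_function(all_dis, mode = m, bins = distance_bins(1000, 200),
                             n_sims = 19, seed = 1)
    expect_equal(d$d_values, rep(0, 5))
    expect_true(all(d$significance_class == "random"))
  }
})

test_that("constructed extreme labelings drive D(d) out of the envelope", {
  set.seed(31)
  n <- 60
  x <- runif(n, 0, 2000); y <- runif(n, 0, 2000)
  b <- distance_bins(800, 200)
  reg <- region_rectangle(0, 2000, 0, 2000)
  m <- 12

  # the m mutually closest points: take the point with the smallest mean
  # distance and its m-1 nearest neighbours
  D <- as.matrix(dist(cbind(x, y)))
  ctr <- which.min(rowMeans(D))
  close_set <- order(D[ctr, ])[1:m]
  dis <- integer(n); dis[close_set] <- 1L
  s_close <- survey_dataset(data.frame(id = as.character(1:n), x = x, y = y,
                                       n_colonies = 1L, n_diseased = dis),
                            region = reg)
  d_close <- difference_function(s_close, "transect", b, n_sims = 99, seed = 2)
  expect_true(any(d_close$d_values[1:2] > d_close$envelope_high[1:2]))

  # greedy farthest-point labeling
  far_set <- which.max(rowMeans(D))
  while (length(far_set) < m) {
    cand <- setdiff(seq_len(n), far_set)
    far_set <- c(far_set,
                 cand[which.max(vapply(cand, function(i)
                   min(D[i, far_set]), 0))])
  }
  dis2 <- integer(n); dis2[far_set] <- 1L
  s_far <- survey_dataset(data.frame(id = as.character(1:n), x = x, y = y,
                                     n_colonies = 1L, n_diseased = dis2),
                          region = reg)
  d_far <- difference_function(s_far, "transect", b, n_sims = 99, seed = 3)
  expect_lt(d_far$d_values[1], 0)
})

test_that("difference function demands disease be a subset of the population", {
  s <- tiny_survey()
  rec <- s$records
  rec$n_colonies[1] <- 0   # diseased colony with no population support
  rec$n_diseased[1] <- 1
  expect_error(survey_dataset(rec, region = s$region))  # container already blocks it
  # a single positive transect is not enough
  rec2 <- tiny_survey()$records
  rec2$n_diseased <- c(1, 0, 0, 0, 0, 0)
  one <- survey_dataset(rec2, region = s$region)
  expect_error(difference_function(one, "transect"), "fewer than 2")
})

test_that("cross-resolution tests: unit weights are degenerate, clumped weights reject", {
  set.seed(41)
  n <- 80
  reg <- region_rectangle(0, 1500, 0, 1500)
  rec <- data.frame(id = as.character(1:n),
                    x = runif(n, 0, 1500), y = runif(n, 0, 1500),
                    n_colonies = 1L, n_diseased = 0L)
  s1 <- survey_dataset(rec, region = reg)
  b <- distance_bins(600, 150)
  lw <- lfun(s1, "population", "colony", b, n_sims = 49, seed = 5)
  lu <- lfun(s1, "population", "transect", b, n_sims = 49, seed = 6)
  tab <- cross_resolution_test(lw, lu)
  # all-unit weights: the two observed curves coincide
  expect_equal(tab$l_weighted, tab$l_unweighted, tolerance = 1e-12)

  # weights piled on one tight spatial clump: weighted pattern far more
  # clustered than the transect envelope allows at small d
  clump <- which((rec$x - 200)^2 + (rec$y - 200)^2 < 300^2)
  if (length(clump) < 3) clump <- order((rec$x - 200)^2 + (rec$y - 200)^2)[1:5]
  rec2 <- rec; rec2$n_colonies <- 1L
  rec2$n_colonies[clump] <- 40L
  s2 <- survey_dataset(rec2, region = reg)
  lw2 <- lfun(s2, "population", "colony", b, n_sims = 99, seed = 7)
  lu2 <- lfun(s2, "population", "transect", b, n_sims = 99, seed = 8)
  tab2 <- cross_resolution_test(lw2, lu2)
  expect_true(any(tab2$reject_weighted_in_unweighted[1:2]))

  # mismatched bins refuse to compare
  lu3 <- lfun(s1, "population", "transect", distance_bins(600, 200),
              n_sims = 9, seed = 1)
  expect_error(cross_resolution_test(lw, lu3), "bins")
})

test_that("location-independent weights stay calibrated against the weighted envelope", {
  # when weights carry no spatial information, the weighted observed curve is
  # one more draw from the weighted CSR ensemble, so it should exit its own
  # weight-permuting envelope at roughly the pointwise exceedance rate (~2%
  # per bin for 99 sims), far below what a spatially clumped weighting shows
  reg <- region_rectangle(0, 1500, 0, 1500)
  b <- distance_bins(600, 150)
  sig <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 100
    rec <- data.frame(id = as.character(1:n),
                      x = runif(n, 0, 1500), y = runif(n, 0, 1500),
                      n_colonies = sample(c(rep(1L, 85), rep(6L, 15))),
                      n_diseased = 0L)
    sv <- survey_dataset(rec, region = reg)
    lw <- lfun(sv, "population", "colony", b, n_sims = 99, seed = 300 + s)
    mean(lw$significance_class %in%
           c("clustered_significant", "dispersed_significant"))
  }, 0)
  expect_lt(mean(sig), 0.10)
})
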