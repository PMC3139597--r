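test_that("standard distance and bandwidth follow their closed forms", {
  expect_equal(standard_distance(c(0, 2), c(0, 0)), 1)
  expect_equal(standard_distance(c(0, 1, 1, 0), c(0, 0, 1, 1)), sqrt(0.5))
  expect_equal(standard_distance(rep(3, 4), rep(7, 4)), 0)
  expect_error(standard_distance(1, 1), "2 points")

  expect_equal(h_opt(375, 2 * 1688.2), 2 * h_opt(375, 1688.2))  # linear in sigma
  expect_equal(h_opt(16 * 375, 1688.2), h_opt(375, 1688.2) / 2) # fourth-root in n
  expect_error(h_opt(1, 100), "count")
  expect_error(h_opt(10, 0), "positive")
})

test_that("filtered prevalence reproduces a hand-aggregated example", {
  rec <- data.frame(id = c("a", "b"), x = c(0, 100), y = 0,
                    n_colonies = c(4, 6), n_diseased = c(1, 0))
  s <- survey_dataset(rec, region = region_rectangle(-200, 300, -200, 200))
  g <- grid_spec(0, -50, 100, 50, cell = 50)  # includes node (50, 0)
  node <- function(surf) {
    i <- which(surf$grid$node_y == 0); j <- which(surf$grid$node_x == 50)
    surf$prevalence[i, j]
  }
  sc <- filtered_prevalence(s, g, radius = 150, mode = "colony")
  st <- filtered_prevalence(s, g, radius = 150, mode = "transect")
  expect_equal(node(sc), 1 / 10)
  expect_equal(node(st), 1 / 2)

  # nodes beyond the radius of every transect are undefined, never zero
  g2 <- grid_spec(0, -50, 1000, 50, cell = 50)
  far <- filtered_prevalence(s, g2, radius = 150, mode = "colony")
  j_far <- which(far$grid$node_x > 250 + 1e-9)
  expect_true(all(is.na(far$prevalence[, j_far])))
  # along y = 0 every node out to x = 250 (exactly 150 m from the transect
  # at x = 100; closed disc) is defined
  i0 <- which(far$grid$node_y == 0)
  expect_true(all(!is.na(far$prevalence[i0, far$grid$node_x <= 250])))

  # fully diseased survey: prevalence 1 wherever defined
  rec3 <- rec; rec3$n_diseased <- rec3$n_colonies
  s3 <- survey_dataset(rec3, region = s$region)
  all1 <- filtered_prevalence(s3, g, radius = 150, mode = "colony")
  expect_true(all(all1$prevalence[!is.na(all1$prevalence)] == 1))

  expect_warning(filtered_prevalence(s, g, radius = 20), "radius")
})

test_that("filtered prevalence matches the naive per-node oracle exactly", {
  for (seed in 1:3) {
    s <- simulate_survey(scenario_config(n_transects = 120,
        region = region_rectangle(0, 2000, 0, 1500)), seed = seed)
    g <- grid_for_survey(s, cell = 250)
    for (mode in c("transect", "colony")) {
      surf <- filtered_prevalence(s, g, radius = 400, mode = mode)
      nodes_x <- rep(g$node_x, each = g$n_rows)
      nodes_y <- rep(g$node_y, times = g$n_cols)
      o <- naive_surface(s$records, nodes_x, nodes_y, 400, mode)
      expect_identical(as.numeric(surf$numerator), o$numerator)
      expect_identical(as.numeric(surf$denominator), o$denominator)
      expect_identical(as.numeric(surf$prevalence), o$prevalence)
    }
  }
})

test_that("larger filter radii never roughen the surface", {
  for (seed in 1:10) {
    s <- simulate_survey(scenario_config(n_transects = 150,
        region = region_rectangle(0, 3000, 0, 1500)), seed = seed)
    g <- grid_for_survey(s, cell = 150)
    v <- vapply(c(300, 500, 800), function(r) {
      p <- filtered_prevalence(s, g, radius = r, mode = "colony")$prevalence
      var(p[!is.na(p)])
    }, 0)
    expect_true(all(diff(v) <= 1e-12))
  }
})

test_that("Monte Carlo p-values follow the add-one convention and its bounds", {
  s <- tiny_survey()
  g <- grid_for_survey(s, cell = 250)
  surf <- filtered_prevalence(s, g, radius = 500, mode = "colony")
  surf <- monte_carlo_significance(surf, s, n_sims = 200, seed = 9)
  p <- surf$p_value[!is.na(surf$p_value)]
  expect_true(all(p > 0 & p <= 1))
  expect_gte(min(p), 1 / 201)
  # zero observed prevalence forces p = 1
  zero_nodes <- !is.na(surf$prevalence) & surf$prevalence == 0
  expect_true(all(surf$p_value[zero_nodes] == 1))
  expect_equal(surf$global_p, summary(s)$prevalence_colony / 100)
})

test_that("a node that beats every simulation gets p = 1/(n_sims+1)", {
  # one heavily diseased transect far from the rest makes its node unbeatable
  rec <- data.frame(id = as.character(1:12),
                    x = c(rep(seq(0, 1000, length.out = 11), 1), 5000),
                    y = 0,
                    n_colonies = c(rep(10L, 11), 30L),
                    n_diseased = c(rep(0L, 11), 30L))
  s <- survey_dataset(rec, region = region_rectangle(-100, 5100, -100, 100))
  g <- grid_spec(0, 0, 5000, 50, cell = 50)
  surf <- filtered_prevalence(s, g, radius = 200, mode = "colony")
  surf <- monte_carlo_significance(surf, s, n_sims = 1000, seed = 10)
  hot <- which(surf$grid$node_x == 5000)
  expect_equal(min(surf$p_value[, hot]), 1 / 1001)
})

test_that("cluster extraction obeys area accounting and 8-connectivity", {
  # fabricate a tested surface via the public pipeline on a sparse pattern,
  # then check the geometry rules on its significant nodes
  mk_surface <- function(sig_nodes, n_rows = 5, n_cols = 5, cell = 50) {
    g <- grid_spec(0, 0, (n_cols - 1) * cell, (n_rows - 1) * cell, cell = cell)
    prev <- matrix(0.5, n_rows, n_cols)
    p <- matrix(1, n_rows, n_cols)
    for (rc in sig_nodes) p[rc[1], rc[2]] <- 0.01
    structure(list(grid = g, radius = cell * 2, mode = "transect",
                   numerator = prev, denominator = prev * 2, prevalence = prev,
                   p_value = p, n_sims = 99, global_p = 0.1,
                   incidence = NULL),
              class = "prevalence_surface")
  }
  one <- extract_clusters(mk_surface(list(c(2, 2))), alpha = 0.05)
  expect_equal(one$n_clusters, 1)
  expect_equal(one$total_area_km2, 0.0025)   # a single 50 m cell

  diag2 <- extract_clusters(mk_surface(list(c(2, 2), c(3, 3))), alpha = 0.05)
  expect_equal(diag2$n_clusters, 1)          # diagonal neighbours connect
  expect_equal(diag2$clusters[[1]]$n_nodes, 2)

  apart <- extract_clusters(mk_surface(list(c(1, 1), c(5, 5))), alpha = 0.05)
  expect_equal(apart$n_clusters, 2)

  none <- extract_clusters(mk_surface(list()), alpha = 0.05)
  expect_equal(none$n_clusters, 0)
  expect_equal(none$total_area_km2, 0)
})

test_that("cluster summaries report containment and buffer percentages consistently", {
  s <- tiny_survey()
  g <- grid_for_survey(s, cell = 250)
  surf <- filtered_prevalence(s, g, radius = 600, mode = "transect")
  surf <- monte_carlo_significance(surf, s, n_sims = 99, seed = 3)

  # force every node significant: all positive transects must fall inside
  surf_all <- surf
  surf_all$p_value[!is.na(surf_all$p_value)] <- 0.01
  surf_all$prevalence[!is.na(surf_all$prevalence)] <-
    pmax(surf_all$prevalence[!is.na(surf_all$prevalence)], 0.01)
  cl_all <- extract_clusters(surf_all, alpha = 0.05)
  cs_all <- cluster_summary(cl_all, s)
  expect_equal(cs_all$pct_positive_transects_inside, 100)
  expect_equal(cs_all$pct_positive_transects_within_buffer, 100)
  expect_equal(cs_all$pct_diseased_colonies_inside, 100)

  # empty cluster set: all percentages zero
  surf_none <- surf
  surf_none$p_value[!is.na(surf_none$p_value)] <- 1
  cs_none <- cluster_summary(extract_clusters(surf_none), s)
  expect_equal(cs_none$n_clusters, 0)
  expect_equal(cs_none$pct_positive_transects_inside, 0)
  expect_equal(cs_none$total_area_km2, 0)

  # buffer percentages dominate inside percentages (superset)
  cs <- cluster_summary(extract_clusters(surf), s)
  expect_gte(cs$pct_positive_transects_within_buffer,
             cs$pct_positive_transects_inside)
  expect_gte(cs$pct_diseased_colonies_within_buffer,
             cs$pct_diseased_colonies_inside)
})

test_that("ASCII grid export round-trips the prevalence layer", {
  s <- tiny_survey()
  g <- grid_for_survey(s, cell = 500)
  surf <- filtered_prevalence(s, g, radius = 600, mode = "colony")
  f <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(surf, f, "prevalence")
  hdr <- readLines(f, n = 6)
  expect_match(hdr[1], sprintf("ncols %d", g$n_cols))
  vals <- do.call(rbind, lapply(readLines(f)[-(1:6)],
                                function(l)
                                  as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  got <- vals[rev(seq_len(g$n_rows)), , drop = FALSE]
  got[got == -9999] <- NA
  expect_equal(got, unname(surf$prevalence), tolerance = 1e-9)
})
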