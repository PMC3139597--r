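# Independent oracles and fixtures shared across the suite. The oracles are
# deliberately naive (double loops) and must stay independent of the package's
# vectorised implementations.

# naive weighted L: ordered-pair double loop
naive_l <- function(x, y, w = NULL, edges, area) {
  n <- length(x)
  if (is.null(w)) w <- rep(1, n)
  S <- numeric(length(edges))
  W <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dij <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    W <- W + w[i] * w[j]
    S <- S + w[i] * w[j] * (dij <= edges)
  }
  sqrt(area * S / (pi * W))
}

# naive filtered prevalence: per-node double loop over transects
naive_surface <- function(rec, node_x, node_y, radius, mode) {
  nn <- length(node_x)
  num <- den <- numeric(nn)
  for (g in seq_len(nn)) {
    for (t in seq_len(nrow(rec))) {
      d <- sqrt((rec$x[t] - node_x[g])^2 + (rec$y[t] - node_y[g])^2)
      if (d <= radius) {
        if (mode == "transect") {
          num[g] <- num[g] + (rec$n_diseased[t] > 0)
          den[g] <- den[g] + 1
        } else {
          num[g] <- num[g] + rec$n_diseased[t]
          den[g] <- den[g] + rec$n_colonies[t]
        }
      }
    }
  }
  list(numerator = num, denominator = den,
       prevalence = ifelse(den > 0, num / den, NA_real_))
}

# great-circle distance on a sphere (independent check on the projection)
great_circle_m <- function(lon1, lat1, lon2, lat2, R = 6371000) {
  to_rad <- pi / 180
  p1 <- lat1 * to_rad; p2 <- lat2 * to_rad
  dl <- (lon2 - lon1) * to_rad
  a <- sin((p2 - p1) / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * R * asin(sqrt(a))
}

# a small deterministic survey used by several tests
tiny_survey <- function() {
  survey_dataset(data.frame(
    id = paste0("t", 1:6),
    x = c(100, 300, 900, 1500, 2000, 2400),
    y = c(200, 600, 400, 900, 300, 700),
    n_colonies = c(4, 6, 2, 10, 1, 7),
    n_diseased = c(1, 0, 0, 3, 0, 2),
    depth = c(5, 6, NA, 8, 4, 7)
  ), region = region_rectangle(0, 2500, 0, 1000))
}

# deterministic survey reproducing the reference totals: 375 transects,
# 44 positive, 2492 colonies, 69 diseased (counts in 1..40, diseased 1..2)
reference_survey <- function(seed = 42) {
  set.seed(seed)
  n <- 375
  counts <- rep(1L, n)
  extra <- 2492L - n            # 2117 colonies above the floor of 1
  big <- extra %/% 39L          # transects raised to the cap of 40
  counts[seq_len(big)] <- 40L
  rem <- extra - big * 39L
  if (rem > 0) counts[big + 1L] <- counts[big + 1L] + rem
  diseased <- integer(n)
  diseased[1:25] <- 2L          # 25 x 2 + 19 x 1 = 69 over 44 transects
  diseased[26:44] <- 1L
  stopifnot(sum(counts) == 2492L, sum(diseased) == 69L,
            sum(diseased > 0) == 44L, all(diseased <= counts))
  survey_dataset(data.frame(
    id = sprintf("r%03d", 1:n),
    x = runif(n, 0, 7300), y = runif(n, 0, 3800),
    n_colonies = counts, n_diseased = diseased
  ), region = region_rectangle(0, 7300, 0, 3800))
}

expect_rel_equal <- function(got, want, tol) {
  expect_true(all(abs(got - want) <= tol * pmax(abs(want), 1e-12)))
}
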