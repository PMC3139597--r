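#' Distance bins for second-order analyses
#'
#' @param d_max maximum distance in metres (default 2500).
#' @param step bin width in metres (default 50); \code{d_max} must be a
#'   positive multiple of \code{step}.
#' @return an object of class \code{distance_bins} with the vector of bin
#'   upper edges at which L(d) is evaluated.
#' @export
distance_bins <- function(d_max = 2500, step = 50) {
  stopifnot(step > 0, d_max > 0)
  k <- d_max / step
  if (abs(k - round(k)) > 1e-9)
    stop("d_max must be a positive multiple of step")
  structure(list(d_max = d_max, step = step,
                 edges = seq(step, d_max, by = step)),
            class = "distance_bins")
}

bins_equal <- function(a, b) {
  isTRUE(all.equal(a$edges, b$edges)) && a$d_max == b$d_max && a$step == b$step
}

# precompute, for fixed locations, each unordered pair's distance-bin index.
# bin index = smallest k with edges[k] >= dist (closed upper bound: a pair at
# exactly an edge counts toward that edge); pairs beyond d_max get index 0.
# `torus = c(width, height)` wraps distances (toroidal-shift edge correction
# for rectangular regions).
pair_table <- function(x, y, edges, torus = NULL) {
  n <- length(x)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dx <- abs(x[ij[, 1L]] - x[ij[, 2L]])
  dy <- abs(y[ij[, 1L]] - y[ij[, 2L]])
  if (!is.null(torus)) {
    dx <- pmin(dx, torus[1L] - dx)
    dy <- pmin(dy, torus[2L] - dy)
  }
  d <- sqrt(dx^2 + dy^2)
  bin <- findInterval(d, edges, left.open = TRUE) + 1L
  bin[bin > length(edges)] <- 0L
  list(i = ij[, 1L], j = ij[, 2L], bin = bin, n = n, n_bins = length(edges))
}

# weighted pair sums S(d) (ordered pairs, hence the factor 2) cumulated over
# bins, from a precomputed pair table
pair_sums <- function(pt, w) {
  keep <- pt$bin > 0L
  pw <- w[pt$i[keep]] * w[pt$j[keep]]
  per_bin <- numeric(pt$n_bins)
  if (length(pw)) {
    agg <- rowsum(pw, group = pt$bin[keep])
    per_bin[as.integer(rownames(agg))] <- agg[, 1L]
  }
  2 * cumsum(per_bin)
}

#' Transformed Ripley's K (L-function), optionally weighted
#'
#' Computes \deqn{L(d) = \sqrt{A \, S(d) / (\pi W)}}{L(d) = sqrt(A S(d) / (pi W))}
#' where \eqn{S(d)} is the sum over ordered pairs \eqn{i \ne j} of
#' \eqn{w_i w_j \,1[\mathrm{dist}(i,j) \le d]} and
#' \eqn{W = \sum_{i \ne j} w_i w_j}. With unit weights this is the classical
#' transformed K, \eqn{\sqrt{A \cdot \#pairs / (\pi n (n-1))}}, for which
#' complete spatial randomness gives \eqn{E[L(d)] = d}. Weights carry colony
#' counts so that the same transect locations can be analysed at colony
#' resolution. No edge correction is applied by default; pairs at exactly a
#' bin edge count toward that bin.
#'
#' @param x,y planar point coordinates (metres).
#' @param weights nonnegative per-point weights; \code{NULL} for unit weights.
#' @param bins a [distance_bins()].
#' @param area study-region area \eqn{A} in square metres.
#' @param torus optional \code{c(width, height)} of a rectangular region:
#'   distances are then measured on the torus (toroidal-shift edge
#'   correction), useful as a sensitivity check on boundary bias.
#' @return numeric vector of L(d), one value per bin edge.
#' @examples
#' b <- distance_bins(100, 10)
#' l_function(c(0, 10), c(0, 0), bins = b, area = 1e4)
#' @export
l_function <- function(x, y, weights = NULL, bins, area, torus = NULL) {
  stopifnot(inherits(bins, "distance_bins"), area > 0)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(weights) != length(x)) stop("weights length must match points")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights > 0) < 2L)
    stop("need at least 2 points with positive weight")
  W <- sum(weights)^2 - sum(weights^2)
  pt <- pair_table(x, y, bins$edges, torus = torus)
  S <- pair_sums(pt, weights)
  sqrt(area * S / (pi * W))
}

classify_bins <- function(l, expected, lo, hi) {
  eps <- 1e-9 * pmax(1, abs(expected))
  cls <- ifelse(l > hi, "clustered_significant",
         ifelse(l < lo, "dispersed_significant",
         ifelse(l > expected + eps, "clustered_ns",
         ifelse(l < expected - eps, "dispersed_ns", "random"))))
  factor(cls, levels = c("dispersed_significant", "dispersed_ns", "random",
                         "clustered_ns", "clustered_significant"))
}

#' Simulation envelope of the L-function under complete spatial randomness
#'
#' Each simulation redraws the same number of points uniformly at random in
#' the study region (weights, if any, stay attached to points in a random
#' permutation), recomputes L(d), and the envelope is the per-bin minimum and
#' maximum over the \code{n_sims} curves. With the conventional 99
#' simulations, an observed curve exiting the envelope at a bin is
#' significant at about the 0.01 level pointwise.
#'
#' @param n number of points per simulation.
#' @param weights optional weights to permute onto simulated points.
#' @param region a \code{survey_region}.
#' @param bins a [distance_bins()].
#' @param n_sims number of simulations (default 99).
#' @param seed optional integer seed.
#' @return list with per-bin \code{low} and \code{high} vectors and
#'   \code{n_sims}.
#' @export
csr_envelope <- function(n, weights = NULL, region, bins, n_sims = 99,
                         seed = NULL) {
  stopifnot(inherits(region, "survey_region"), inherits(bins, "distance_bins"),
            n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  sims <- matrix(NA_real_, n_sims, length(bins$edges))
  for (s in seq_len(n_sims)) {
    pts <- runif_region(n, region)
    w <- if (is.null(weights)) NULL else sample(weights)
    sims[s, ] <- l_function(pts[, 1L], pts[, 2L], w, bins, region$area)
  }
  list(low = apply(sims, 2L, min), high = apply(sims, 2L, max),
       n_sims = n_sims)
}

#' L-function analysis of one survey view with a CSR envelope
#'
#' The survey is read at one of six views: the population (all transect
#' locations), the disease pattern (disease-positive transects) or the
#' disease-absent pattern, each either unweighted (transect level) or
#' weighted by the corresponding colony counts (colony level). The observed
#' L(d) is compared per bin against the benchmark \eqn{E[L(d)] = d} and a
#' min/max envelope from \code{n_sims} uniform redraws of the locations.
#'
#' @param dataset a \code{coral_survey}.
#' @param view \code{"population"}, \code{"disease"} or \code{"healthy"}
#'   (the disease-absent complement).
#' @param mode \code{"transect"} (unweighted) or \code{"colony"} (weighted).
#' @param bins a [distance_bins()].
#' @param n_sims envelope simulations (default 99).
#' @param seed integer seed for the envelope.
#' @return an object of class \code{coral_lfun}: bins, observed L, expected
#'   value, envelope bounds, per-bin significance class, weighting mode.
#' @export
lfun <- function(dataset, view = c("population", "disease", "healthy"),
                 mode = c("transect", "colony"),
                 bins = distance_bins(), n_sims = 99, seed = NULL) {
  stopifnot(inherits(dataset, "coral_survey"))
  view <- match.arg(view); mode <- match.arg(mode)
  v <- survey_view(dataset, view, mode)
  keep <- v$w > 0
  if (sum(keep) < 2L)
    stop("fewer than 2 transects with positive weight in the '", view,
         "'/'", mode, "' view")
  x <- v$x[keep]; y <- v$y[keep]
  w <- if (mode == "colony") v$w[keep] else NULL
  area <- dataset$region_area
  l_obs <- l_function(x, y, w, bins, area)
  env <- csr_envelope(length(x), w, dataset$region, bins, n_sims, seed)
  expected <- bins$edges
  structure(list(bins = bins, l_observed = l_obs, expected = expected,
                 envelope_low = env$low, envelope_high = env$high,
                 n_sims = n_sims, view = view,
                 weighting = if (mode == "colony") "colony" else "none",
                 mode = mode,
                 significance_class = classify_bins(l_obs, expected,
                                                   env$low, env$high)),
            class = "coral_lfun")
}

#' Disease-minus-population difference function with random-labeling envelope
#'
#' Subtracts the population's L-function from the disease pattern's,
#' \eqn{D(d) = L_{disease}(d) - L_{population}(d)}, to ask whether disease is
#' more or less aggregated than the susceptible population that hosts it
#' (zero means the disease simply mirrors the population's spatial
#' structure). The null envelope holds all locations fixed and randomly
#' relabels: at transect level each simulation samples the observed number of
#' positive transects without replacement; at colony level it redistributes
#' the observed total of diseased colonies by sampling colonies without
#' replacement from all colonies in the survey. Per-bin min/max of
#' \eqn{L_{sim} - L_{population}} over \code{n_sims} relabelings forms the
#' envelope.
#'
#' @inheritParams lfun
#' @param mode analysis resolution, \code{"transect"} or \code{"colony"}.
#' @return an object of class \code{coral_lfun_diff}: bins, per-bin D(d),
#'   envelope bounds, significance class (benchmark 0).
#' @export
difference_function <- function(dataset, mode = c("transect", "colony"),
                                bins = distance_bins(), n_sims = 99,
                                seed = NULL) {
  stopifnot(inherits(dataset, "coral_survey"), inherits(bins, "distance_bins"),
            n_sims >= 1)
  mode <- match.arg(mode)
  rec <- dataset$records
  if (nrow(rec) < 2L) stop("need at least 2 transects")
  pop <- survey_view(dataset, "population", mode)
  dis <- survey_view(dataset, "disease", mode)
  if (any(dis$w > pop$w))
    stop("disease view is not a subset of the population view")
  if (sum(dis$w > 0) < 2L)
    stop("fewer than 2 transects carry disease; difference function undefined")
  area <- dataset$region_area
  if (!is.null(seed)) set.seed(seed)
  pt <- pair_table(pop$x, pop$y, bins$edges)
  l_of <- function(w) {
    W <- sum(w)^2 - sum(w^2)
    sqrt(area * pair_sums(pt, w) / (pi * W))
  }
  l_pop <- l_of(pop$w)
  d_obs <- l_of(dis$w) - l_pop
  n <- nrow(rec)
  sims <- matrix(NA_real_, n_sims, length(bins$edges))
  if (mode == "transect") {
    m <- sum(dis$w > 0)
    for (s in seq_len(n_sims)) {
      w <- numeric(n); w[sample.int(n, m)] <- 1
      sims[s, ] <- l_of(w) - l_pop
    }
  } else {
    total <- sum(dis$w)
    colony_owner <- rep.int(seq_len(n), rec$n_colonies)
    for (s in seq_len(n_sims)) {
      lab <- sample(colony_owner, total)
      w <- numeric(n); tb <- tabulate(lab, nbins = n); w <- as.numeric(tb)
      if (sum(w > 0) < 2L) { s <- s; sims[s, ] <- NA; next }
      sims[s, ] <- l_of(w) - l_pop
    }
  }
  lo <- apply(sims, 2L, min, na.rm = TRUE)
  hi <- apply(sims, 2L, max, na.rm = TRUE)
  structure(list(bins = bins, d_values = d_obs, expected = rep(0, length(d_obs)),
                 envelope_low = lo, envelope_high = hi, n_sims = n_sims,
                 mode = mode,
                 significance_class = classify_bins(d_obs, 0, lo, hi)),
            class = "coral_lfun_diff")
}

#' Cross-resolution hypothesis tests
#'
#' Compares the two analysis resolutions of the same transect locations:
#' (a) is the colony-weighted observed L more clustered or dispersed than the
#' envelope of the unweighted (transect-level) pattern allows, and (b) is the
#' unweighted observed L outside the colony-weighted envelope. Rejection at a
#' bin means the two resolutions genuinely disagree about spatial structure
#' at that distance.
#'
#' @param l_weighted \code{coral_lfun} computed with \code{mode = "colony"}.
#' @param l_unweighted \code{coral_lfun} computed with \code{mode =
#'   "transect"} on the same points and bins.
#' @return data.frame with one row per bin: distance, both observed curves,
#'   both envelopes, and logical columns \code{reject_weighted_in_unweighted}
#'   and \code{reject_unweighted_in_weighted}.
#' @export
cross_resolution_test <- function(l_weighted, l_unweighted) {
  stopifnot(inherits(l_weighted, "coral_lfun"),
            inherits(l_unweighted, "coral_lfun"))
  if (!bins_equal(l_weighted$bins, l_unweighted$bins))
    stop("the two results use different distance bins")
  if (l_weighted$weighting != "colony" || l_unweighted$weighting != "none")
    stop("expected a colony-weighted and an unweighted result, in that order")
  data.frame(
    d = l_weighted$bins$edges,
    l_weighted = l_weighted$l_observed,
    l_unweighted = l_unweighted$l_observed,
    unweighted_env_low = l_unweighted$envelope_low,
    unweighted_env_high = l_unweighted$envelope_high,
    weighted_env_low = l_weighted$envelope_low,
    weighted_env_high = l_weighted$envelope_high,
    reject_weighted_in_unweighted =
      l_weighted$l_observed < l_unweighted$envelope_low |
      l_weighted$l_observed > l_unweighted$envelope_high,
    reject_unweighted_in_weighted =
      l_unweighted$l_observed < l_weighted$envelope_low |
      l_unweighted$l_observed > l_weighted$envelope_high
  )
}

#' Tidy table of an L-function or difference-function result
#'
#' @param x a \code{coral_lfun} or \code{coral_lfun_diff}.
#' @param ... unused.
#' @return data.frame with one row per bin: \code{d}, \code{l_obs} (or
#'   \code{d_value}), \code{expected}, \code{env_low}, \code{env_high},
#'   \code{class}.
#' @export
as.data.frame.coral_lfun <- function(x, ...) {
  data.frame(d = x$bins$edges, l_obs = x$l_observed, expected = x$expected,
             env_low = x$envelope_low, env_high = x$envelope_high,
             class = as.character(x$significance_class))
}

#' @rdname as.data.frame.coral_lfun
#' @export
as.data.frame.coral_lfun_diff <- function(x, ...) {
  data.frame(d = x$bins$edges, d_value = x$d_values, expected = 0,
             env_low = x$envelope_low, env_high = x$envelope_high,
             class = as.character(x$significance_class))
}

#' @export
print.coral_lfun <- function(x, ...) {
  cat(sprintf("L-function (%s view, %s level), %d bins to %g m, %d envelope sims\n",
              x$view, x$mode, length(x$bins$edges), x$bins$d_max, x$n_sims))
  tb <- table(x$significance_class)
  cat("  bins by class:",
      paste(sprintf("%s=%d", names(tb)[tb > 0], tb[tb > 0]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.coral_lfun_diff <- function(x, ...) {
  cat(sprintf("Difference function D(d) (%s level), %d bins, %d labelings\n",
              x$mode, length(x$bins$edges), x$n_sims))
  tb <- table(x$significance_class)
  cat("  bins by class:",
      paste(sprintf("%s=%d", names(tb)[tb > 0], tb[tb > 0]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Plot an L-function result against its CSR benchmark and envelope
#'
#' @param x a \code{coral_lfun}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.coral_lfun <- function(x, ...) {
  d <- x$bins$edges
  ylim <- range(x$l_observed, x$envelope_low, x$envelope_high, x$expected)
  graphics::plot(d, x$l_observed, type = "l", lwd = 2,
                 xlab = "distance d (m)", ylab = "L(d) (m)", ylim = ylim, ...)
  graphics::lines(d, x$expected, lty = 2)
  graphics::lines(d, x$envelope_low, col = "grey50")
  graphics::lines(d, x$envelope_high, col = "grey50")
  graphics::legend("topleft", bty = "n",
                   legend = c("observed", "CSR benchmark", "envelope"),
                   lty = c(1, 2, 1), lwd = c(2, 1, 1),
                   col = c("black", "black", "grey50"))
  invisible(x)
}

#' @rdname plot.coral_lfun
#' @param x a \code{coral_lfun_diff}.
#' @export
plot.coral_lfun_diff <- function(x, ...) {
  d <- x$bins$edges
  ylim <- range(x$d_values, x$envelope_low, x$envelope_high, 0)
  graphics::plot(d, x$d_values, type = "l", lwd = 2,
                 xlab = "distance d (m)", ylab = "D(d) (m)", ylim = ylim, ...)
  graphics::abline(h = 0, lty = 2)
  graphics::lines(d, x$envelope_low, col = "grey50")
  graphics::lines(d, x$envelope_high, col = "grey50")
  invisible(x)
}
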