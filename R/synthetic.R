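#' Configure a synthetic coral-survey scenario
#'
#' Describes a complete generative model for a transect survey: where the
#' transects fall, how many colonies each carries, and how disease is placed
#' on colonies. The defaults emulate the statistical structure of a large
#' Caribbean elkhorn-coral survey: 375 transects in a 7.3 km x 3.8 km region,
#' overdispersed colony counts with mean 6.65 and SD 5.99 (range 1-40), and a
#' colony-level disease probability of 0.0277 under the \code{random}
#' scenario.
#'
#' Disease scenarios:
#' \describe{
#'   \item{random}{every colony independently diseased with probability
#'     \code{p}; this is also the null model of the Monte Carlo hotspot test.}
#'   \item{focal}{a contagion-like alternative: colony-level probability is
#'     \code{base_p * relative_risk} within \code{radius} of any focus and
#'     \code{base_p} elsewhere; focus locations are drawn uniformly in the
#'     region (or supplied).}
#'   \item{ubiquitous}{a low uniform probability \code{p_low} everywhere,
#'     representing a ubiquitous environmental stressor.}
#' }
#'
#' @param n_transects number of transects to place.
#' @param region a [region_polygon()]; default 7300 m x 3800 m rectangle.
#' @param location_process \code{"uniform"} or \code{"clustered"}
#'   (Thomas-type parent/offspring process).
#' @param offspring_per_parent,offspring_sd clustered process: mean offspring
#'   per parent and the isotropic Gaussian displacement SD (metres).
#' @param colony_mean,colony_sd target mean and SD of colonies per transect
#'   (after zero-truncation and capping).
#' @param colony_dispersion negative-binomial size parameter; \code{NULL}
#'   (default) solves it from \code{colony_mean}/\code{colony_sd} by moment
#'   matching on the truncated, capped distribution.
#' @param colony_max cap on colonies per transect.
#' @param colony_cluster_effect SD of a lognormal per-clump multiplier on the
#'   colony mean (clustered process only); > 0 makes colony counts spatially
#'   correlated. Default 0 (off).
#' @param disease one of \code{"random"}, \code{"focal"}, \code{"ubiquitous"}.
#' @param p colony-level disease probability for the \code{random} scenario.
#' @param base_p,relative_risk,focus_radius,n_foci,foci focal-scenario
#'   parameters; \code{foci} may be a two-column matrix of focus locations
#'   (otherwise \code{n_foci} are drawn uniformly in the region). The default
#'   \code{base_p = NULL} calibrates the baseline so the scenario's expected
#'   overall prevalence equals \code{p} — the focal alternative then
#'   redistributes, rather than adds, risk relative to the random null.
#' @param p_low disease probability for the \code{ubiquitous} scenario.
#' @return an object of class \code{scenario_config}.
#' @export
scenario_config <- function(n_transects = 375,
                            region = region_rectangle(0, 7300, 0, 3800),
                            location_process = c("uniform", "clustered"),
                            offspring_per_parent = 15,
                            offspring_sd = 250,
                            colony_mean = 6.65,
                            colony_sd = 5.99,
                            colony_dispersion = NULL,
                            colony_max = 40,
                            colony_cluster_effect = 0,
                            disease = c("random", "focal", "ubiquitous"),
                            p = 0.0277,
                            base_p = NULL,
                            relative_risk = 10,
                            focus_radius = 300,
                            n_foci = 8,
                            foci = NULL,
                            p_low = 0.0277) {
  location_process <- match.arg(location_process)
  disease <- match.arg(disease)
  stopifnot(inherits(region, "survey_region"),
            n_transects >= 1, colony_mean > 1, colony_max >= 1,
            offspring_per_parent >= 1, offspring_sd > 0,
            colony_cluster_effect >= 0)
  if (is.null(base_p)) {
    # focal default: redistribute the overall colony-level risk p so that the
    # expected prevalence matches the random scenario despite the elevated
    # risk inside foci; coverage approximated as n_foci discs in the region
    coverage <- min(0.9, n_foci * pi * focus_radius^2 / region$area)
    base_p <- p / (1 + (relative_risk - 1) * coverage)
  }
  for (prob in c(p, base_p, p_low))
    if (prob < 0 || prob >= 1) stop("disease probabilities must lie in [0, 1)")
  if (relative_risk < 1) stop("relative_risk must be >= 1")
  if (colony_max == 1L) {
    colony_dispersion <- 1
    colony_mu <- 1
  } else if (is.null(colony_dispersion)) {
    fit <- ztnb_fit(colony_mean, colony_sd, colony_max)
    colony_dispersion <- fit$size
    colony_mu <- fit$mu
  } else {
    stopifnot(colony_dispersion > 0)
    colony_mu <- colony_mean
  }
  structure(list(n_transects = as.integer(n_transects), region = region,
                 location_process = location_process,
                 offspring_per_parent = offspring_per_parent,
                 offspring_sd = offspring_sd,
                 colony_mean = colony_mean, colony_sd = colony_sd,
                 colony_dispersion = colony_dispersion, colony_mu = colony_mu,
                 colony_max = as.integer(colony_max),
                 colony_cluster_effect = colony_cluster_effect,
                 disease = disease, p = p, base_p = base_p,
                 relative_risk = relative_risk, focus_radius = focus_radius,
                 n_foci = as.integer(n_foci), foci = foci, p_low = p_low),
            class = "scenario_config")
}

# pmf of the zero-truncated negative binomial capped at `cap` (the capped
# tail mass is lumped onto `cap`, matching a survey that records "40+" as 40)
ztnb_pmf <- function(mu, size, cap) {
  x <- seq_len(cap)
  p <- stats::dnbinom(x, mu = mu, size = size)
  p[cap] <- p[cap] + stats::pnbinom(cap, mu = mu, size = size, lower.tail = FALSE)
  p / sum(p)
}

# deterministic moment matching: find (mu, size) of the underlying NB so the
# truncated, capped distribution hits the target mean and SD
ztnb_fit <- function(mean_target, sd_target, cap) {
  if (sd_target^2 <= mean_target * (1 - mean_target / cap))
    stop("infeasible colony mean/SD combination (underdispersed beyond Poisson)")
  obj <- function(par) {
    mu <- exp(par[1L]); size <- exp(par[2L])
    pmf <- ztnb_pmf(mu, size, cap)
    x <- seq_len(cap)
    m <- sum(x * pmf)
    s <- sqrt(max(sum(x^2 * pmf) - m^2, 0))
    (m - mean_target)^2 + (s - sd_target)^2
  }
  fit <- stats::optim(c(log(mean_target), log(2)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (fit$value > 1e-4)
    stop("could not match the requested colony mean/SD within the cap")
  list(mu = exp(fit$par[1L]), size = exp(fit$par[2L]))
}

#' Draw transect locations for a scenario
#'
#' Uniform placement draws points uniformly over the study region; clustered
#' placement uses a Thomas-type parent/offspring process (uniform parents,
#' isotropic Gaussian offspring displacements, redrawn until inside the
#' region) to mimic transects concentrated along reef structure.
#'
#' @param config a [scenario_config()].
#' @param seed optional integer seed (set for reproducibility).
#' @return two-column matrix of planar coordinates; for the clustered process
#'   the parent index of each point is attached as attribute \code{"parent"}.
#' @export
generate_transect_locations <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_transects
  region <- config$region
  if (region$area < n * 1e-4)
    stop("region too small to place ", n, " distinct transects")
  if (config$location_process == "uniform") {
    pts <- runif_region(n, region)
    attr(pts, "parent") <- seq_len(n)
    return(pts)
  }
  n_parents <- max(1L, as.integer(round(n / config$offspring_per_parent)))
  parents <- runif_region(n_parents, region)
  parent_of <- sample(rep_len(seq_len(n_parents), n))
  x <- numeric(n); y <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    px <- parents[parent_of[todo], 1L]; py <- parents[parent_of[todo], 2L]
    cx <- px + stats::rnorm(length(todo), sd = config$offspring_sd)
    cy <- py + stats::rnorm(length(todo), sd = config$offspring_sd)
    ok <- region_contains(region, cx, cy)
    x[todo[ok]] <- cx[ok]; y[todo[ok]] <- cy[ok]
    todo <- todo[!ok]
  }
  pts <- cbind(x = x, y = y)
  attr(pts, "parent") <- parent_of
  pts
}

#' Draw per-transect colony counts
#'
#' Counts come from a zero-truncated negative binomial capped at
#' \code{colony_max}; only transects that contained at least one colony enter
#' a survey, and overdispersion (SD comparable to the mean) is typical of
#' colony counts along reef transects. With
#' \code{colony_cluster_effect > 0} and clustered locations, each parent
#' clump receives a lognormal multiplier on the mean, making counts spatially
#' correlated.
#'
#' @param points matrix from [generate_transect_locations()].
#' @param config a [scenario_config()].
#' @param seed optional integer seed.
#' @return integer vector of counts, one per transect.
#' @export
assign_colony_counts <- function(points, config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(points)
  cap <- config$colony_max
  if (cap == 1L) return(rep(1L, n))
  if (config$colony_cluster_effect > 0 && !is.null(attr(points, "parent"))) {
    parent <- attr(points, "parent")
    eff <- stats::rlnorm(max(parent), meanlog = -config$colony_cluster_effect^2 / 2,
                         sdlog = config$colony_cluster_effect)
    counts <- integer(n)
    for (pp in unique(parent)) {
      idx <- which(parent == pp)
      pmf <- ztnb_pmf(config$colony_mu * eff[pp], config$colony_dispersion, cap)
      counts[idx] <- sample.int(cap, length(idx), replace = TRUE, prob = pmf)
    }
    return(counts)
  }
  pmf <- ztnb_pmf(config$colony_mu, config$colony_dispersion, cap)
  sample.int(cap, n, replace = TRUE, prob = pmf)
}

#' Assign disease to colonies under a scenario
#'
#' Every colony is an independent Bernoulli draw whose probability depends on
#' the scenario: constant under \code{random} and \code{ubiquitous};
#' elevated by \code{relative_risk} within \code{focus_radius} of any focus
#' under \code{focal}.
#'
#' @param points transect locations.
#' @param counts per-transect colony counts.
#' @param config a [scenario_config()].
#' @param seed optional integer seed.
#' @return integer vector of diseased counts per transect. For the focal
#'   scenario the focus locations used are attached as attribute
#'   \code{"foci"}.
#' @export
assign_disease <- function(points, counts, config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"), nrow(points) == length(counts))
  if (!is.null(seed)) set.seed(seed)
  n <- length(counts)
  if (config$disease == "random") {
    prob <- rep(config$p, n)
    foci <- NULL
  } else if (config$disease == "ubiquitous") {
    prob <- rep(config$p_low, n)
    foci <- NULL
  } else {
    foci <- config$foci
    if (is.null(foci)) foci <- runif_region(config$n_foci, config$region)
    foci <- as.matrix(foci)
    d2 <- outer(points[, 1L], foci[, 1L], "-")^2 +
      outer(points[, 2L], foci[, 2L], "-")^2
    near <- apply(d2 <= config$focus_radius^2, 1L, any)
    prob <- ifelse(near, pmin(1, config$base_p * config$relative_risk),
                   config$base_p)
  }
  diseased <- stats::rbinom(n, size = counts, prob = prob)
  if (!is.null(foci)) attr(diseased, "foci") <- foci
  diseased
}

#' Simulate a complete synthetic survey
#'
#' Chains [generate_transect_locations()], [assign_colony_counts()] and
#' [assign_disease()] under a single seed and wraps the result as a
#' [survey_dataset()]. The generator is a pure function of
#' \code{(config, seed)}.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @return a \code{coral_survey}; ground truth for testing is attached as
#'   attributes \code{"foci"} (focal scenario) and \code{"scenario"}.
#' @examples
#' s <- simulate_survey(scenario_config(n_transects = 50), seed = 1)
#' summary(s)
#' @export
simulate_survey <- function(config = scenario_config(), seed = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(as.integer(seed))
  pts <- generate_transect_locations(config)
  counts <- assign_colony_counts(pts, config)
  diseased <- assign_disease(pts, counts, config)
  rec <- data.frame(id = sprintf("T%04d", seq_len(nrow(pts))),
                    x = pts[, 1L], y = pts[, 2L],
                    n_colonies = as.integer(counts),
                    n_diseased = as.integer(diseased))
  out <- survey_dataset(rec, region = config$region,
                        crs_note = sprintf("synthetic (%s placement, %s disease), seed %d",
                                           config$location_process, config$disease,
                                           as.integer(seed)))
  attr(out, "foci") <- attr(diseased, "foci")
  attr(out, "scenario") <- config$disease
  out
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Survey scenario: %d transects, %s placement, %s disease\n",
              x$n_transects, x$location_process, x$disease))
  cat(sprintf("  colonies/transect ~ capped ZT-NB(mu=%.3f, size=%.3f), cap %d\n",
              x$colony_mu, x$colony_dispersion, x$colony_max))
  invisible(x)
}
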