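#' Standard distance of a point pattern
#'
#' Root-mean-square distance of the points from their spatial mean — the
#' two-dimensional analogue of a standard deviation, used as the dispersion
#' input to the optimised-bandwidth calculation.
#'
#' @param x,y planar coordinates (metres).
#' @return sigma in metres.
#' @examples
#' standard_distance(c(0, 2), c(0, 0))  # 1
#' @export
standard_distance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 2L) stop("standard distance needs at least 2 points")
  sqrt((sum((x - mean(x))^2) + sum((y - mean(y))^2)) / length(x))
}

#' Optimised filter bandwidth
#'
#' Data-driven radius for the circular spatial filter,
#' \deqn{h_{opt} = \sigma \left(\frac{2}{3n}\right)^{1/4}}{h_opt = sigma * (2/(3n))^(1/4)}
#' with \eqn{n} the number of point locations and \eqn{\sigma} their standard
#' distance. Useful when nothing is known about the process scale (e.g. an
#' unknown disease-transmission distance), since it adapts the filter to the
#' spatial structure of the sample itself.
#'
#' @param n sample size (number of locations).
#' @param sigma standard distance in metres.
#' @return bandwidth in metres.
#' @examples
#' h_opt(375, 1688.2)  # about 347 m
#' @export
h_opt <- function(n, sigma) {
  if (!is.finite(n) || n < 2) stop("n must be a count >= 2")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  sigma * (2 / (3 * n))^0.25
}

#' Rectangular analysis grid
#'
#' Grid nodes sit at the cell corners (grid intersections); node \eqn{(i,j)}
#' is at \eqn{(x_{min} + i\,cell,\; y_{min} + j\,cell)}. For area accounting
#' each node owns the cell-sized square centred on it.
#'
#' @param x_min,y_min,x_max,y_max planar extent in metres.
#' @param cell cell edge length in metres (default 50).
#' @return an object of class \code{grid_spec}.
#' @export
grid_spec <- function(x_min, y_min, x_max, y_max, cell = 50) {
  stopifnot(x_max > x_min, y_max > y_min, cell > 0)
  xs <- seq(x_min, x_max, by = cell)
  ys <- seq(y_min, y_max, by = cell)
  structure(list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
                 cell = cell, node_x = xs, node_y = ys,
                 n_cols = length(xs), n_rows = length(ys)),
            class = "grid_spec")
}

#' Grid covering a survey's region
#'
#' @param dataset a \code{coral_survey}.
#' @param cell cell edge length (metres).
#' @return a [grid_spec()] over the region's bounding box.
#' @export
grid_for_survey <- function(dataset, cell = 50) {
  stopifnot(inherits(dataset, "coral_survey"))
  bb <- region_bbox(dataset$region)
  grid_spec(bb["x_min"], bb["y_min"], bb["x_max"], bb["y_max"], cell = cell)
}

# node x transect incidence (closed disc, dist <= radius) as a sparse matrix;
# node order is column-major over (rows = y, cols = x): index = (jx-1)*n_rows + jy
node_incidence <- function(grid, x, y, radius) {
  nodes_x <- rep(grid$node_x, each = grid$n_rows)
  nodes_y <- rep(grid$node_y, times = grid$n_cols)
  nn <- length(nodes_x); nt <- length(x)
  r2 <- radius^2
  ii <- vector("list", nt)
  # loop over transects: each touches only nodes in a local window
  for (t in seq_len(nt)) {
    jx <- which(abs(grid$node_x - x[t]) <= radius)
    if (!length(jx)) { ii[[t]] <- integer(); next }
    jy <- which(abs(grid$node_y - y[t]) <= radius)
    if (!length(jy)) { ii[[t]] <- integer(); next }
    dx2 <- (grid$node_x[jx] - x[t])^2
    dy2 <- (grid$node_y[jy] - y[t])^2
    hit <- outer(dy2, dx2, "+") <= r2          # rows = jy, cols = jx
    idx <- which(hit, arr.ind = TRUE)
    ii[[t]] <- (jx[idx[, 2L]] - 1L) * grid$n_rows + jy[idx[, 1L]]
  }
  Matrix::sparseMatrix(i = unlist(ii),
                       j = rep.int(seq_len(nt), lengths(ii)),
                       x = 1, dims = c(nn, nt))
}

#' Spatially filtered prevalence surface
#'
#' At every grid node a circular filter of the given radius collects the
#' transects within it and forms a local prevalence: in \code{transect} mode
#' the share of those transects that are disease-positive, in \code{colony}
#' mode the share of their colonies that are diseased. Overlapping filters
#' (radius well above the cell size) smooth the surface. Nodes whose filter
#' catches no transect are marked undefined (\code{NA}), never zero.
#'
#' @param dataset a \code{coral_survey}.
#' @param grid a [grid_spec()]; default covers the survey region with 50 m
#'   cells.
#' @param radius filter radius in metres, or \code{"auto"} to use
#'   [h_opt()] of the transect locations.
#' @param mode \code{"transect"} or \code{"colony"}.
#' @return an object of class \code{prevalence_surface} with per-node
#'   numerator, denominator and prevalence matrices (rows indexed by y,
#'   columns by x); p-values are added by [monte_carlo_significance()].
#' @export
filtered_prevalence <- function(dataset, grid = grid_for_survey(dataset),
                                radius = "auto",
                                mode = c("transect", "colony")) {
  stopifnot(inherits(dataset, "coral_survey"), inherits(grid, "grid_spec"))
  mode <- match.arg(mode)
  rec <- dataset$records
  if (nrow(rec) == 0L) stop("cannot filter an empty survey")
  if (identical(radius, "auto"))
    radius <- h_opt(nrow(rec), standard_distance(rec$x, rec$y))
  stopifnot(is.numeric(radius), radius > 0)
  if (radius < grid$cell)
    warning("filter radius below the cell size: filters will not overlap, ",
            "the surface will not be smoothed")
  inc <- node_incidence(grid, rec$x, rec$y, radius)
  num_w <- switch(mode, transect = as.numeric(rec$n_diseased > 0),
                  colony = as.numeric(rec$n_diseased))
  den_w <- switch(mode, transect = rep(1, nrow(rec)),
                  colony = as.numeric(rec$n_colonies))
  numerator <- as.numeric(inc %*% num_w)
  denominator <- as.numeric(inc %*% den_w)
  prevalence <- ifelse(denominator > 0, numerator / denominator, NA_real_)
  dim(numerator) <- dim(denominator) <- dim(prevalence) <-
    c(grid$n_rows, grid$n_cols)
  structure(list(grid = grid, radius = radius, mode = mode,
                 numerator = numerator, denominator = denominator,
                 prevalence = prevalence, p_value = NULL, n_sims = NULL,
                 global_p = NULL, incidence = inc),
            class = "prevalence_surface")
}

#' Monte Carlo significance of a prevalence surface
#'
#' Tests each node's smoothed prevalence against a constant-risk null that
#' keeps every transect location (and its colony count) fixed and redraws
#' disease: in \code{transect} mode each transect turns positive
#' independently with probability equal to the observed transect-level
#' prevalence; in \code{colony} mode each colony independently becomes
#' diseased with probability equal to the observed colony-level prevalence
#' (so a transect's simulated diseased count is Binomial in its colony
#' count). Each of the \code{n_sims} replicates rebuilds the surface with the
#' same filters; since denominators are fixed, a node's simulated prevalence
#' exceeds the observed one exactly when its simulated numerator does. The
#' per-node p-value is \eqn{(1 + \#\{sims \ge obs\}) / (1 + n_{sims})}, so a
#' node beaten by none of 1000 simulations gets \eqn{p = 1/1001}; nodes with
#' zero observed prevalence get \eqn{p = 1}.
#'
#' @param surface a [filtered_prevalence()] result.
#' @param dataset the \code{coral_survey} the surface was built from.
#' @param n_sims number of simulations (default 1000).
#' @param seed optional integer seed.
#' @param batch simulations per block (memory control).
#' @return the surface with \code{p_value}, \code{n_sims} and
#'   \code{global_p} filled in.
#' @export
monte_carlo_significance <- function(surface, dataset, n_sims = 1000,
                                     seed = NULL, batch = 250) {
  stopifnot(inherits(surface, "prevalence_surface"),
            inherits(dataset, "coral_survey"), n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  rec <- dataset$records
  s <- summary(dataset)
  global_p <- switch(surface$mode,
                     transect = s$prevalence_transect / 100,
                     colony = s$prevalence_colony / 100)
  inc <- surface$incidence
  obs_num <- as.numeric(surface$numerator)
  nn <- length(obs_num); nt <- nrow(rec)
  count_ge <- numeric(nn)
  done <- 0L
  while (done < n_sims) {
    b <- min(batch, n_sims - done)
    labels <- if (surface$mode == "transect")
      matrix(stats::rbinom(nt * b, 1L, global_p), nt, b)
    else
      matrix(stats::rbinom(nt * b, rep(rec$n_colonies, b), global_p), nt, b)
    sim_num <- as.matrix(inc %*% labels)
    count_ge <- count_ge + rowSums(sim_num >= obs_num)
    done <- done + b
  }
  p <- (1 + count_ge) / (1 + n_sims)
  p[obs_num == 0] <- 1
  p[is.na(as.numeric(surface$prevalence))] <- NA_real_
  dim(p) <- dim(surface$prevalence)
  surface$p_value <- p
  surface$n_sims <- n_sims
  surface$global_p <- global_p
  surface
}

#' Extract significant disease clusters from a tested surface
#'
#' Defined nodes with positive prevalence and \eqn{p \le \alpha} are grouped
#' into clusters by 8-connectivity (diagonal neighbours connect). Each
#' cluster's footprint is the union of its nodes' cell squares; cluster ids
#' are assigned by descending area.
#'
#' @param surface a surface with p-values from [monte_carlo_significance()].
#' @param alpha significance level (default 0.05).
#' @return an object of class \code{cluster_set}; empty when no node is
#'   significant.
#' @export
extract_clusters <- function(surface, alpha = 0.05) {
  stopifnot(inherits(surface, "prevalence_surface"))
  if (is.null(surface$p_value))
    stop("run monte_carlo_significance() before extracting clusters")
  grid <- surface$grid
  sig <- !is.na(surface$p_value) & surface$p_value <= alpha &
    !is.na(surface$prevalence) & surface$prevalence > 0
  lab <- matrix(0L, nrow(sig), ncol(sig))
  nxt <- 0L
  idx <- which(sig, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i0 <- idx[k, 1L]; j0 <- idx[k, 2L]
    if (lab[i0, j0] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(i0, j0), 1L)
    lab[i0, j0] <- nxt
    while (nrow(queue)) {
      cur <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        ii <- cur[1L] + di; jj <- cur[2L] + dj
        if (ii >= 1L && ii <= nrow(sig) && jj >= 1L && jj <= ncol(sig) &&
            sig[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nxt
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  cell_area_km2 <- (grid$cell^2) / 1e6
  clusters <- list()
  if (nxt > 0L) {
    raw <- lapply(seq_len(nxt), function(cl) {
      nodes <- which(lab == cl, arr.ind = TRUE)
      data.frame(x = grid$node_x[nodes[, 2L]], y = grid$node_y[nodes[, 1L]],
                 row = nodes[, 1L], col = nodes[, 2L])
    })
    ord <- order(vapply(raw, nrow, 0L), decreasing = TRUE)
    clusters <- lapply(seq_along(ord), function(r) {
      nodes <- raw[[ord[r]]]
      list(id = r, nodes = nodes, n_nodes = nrow(nodes),
           area_km2 = nrow(nodes) * cell_area_km2)
    })
  }
  structure(list(clusters = clusters, alpha = alpha, cell = grid$cell,
                 total_area_km2 = sum(vapply(clusters, `[[`, 0, "area_km2")),
                 n_clusters = length(clusters)),
            class = "cluster_set")
}

#' Distance from points to the nearest significant cluster
#'
#' Euclidean distance from each point to the nearest cell square of any
#' cluster; zero for points inside a cluster footprint, \code{Inf} when the
#' cluster set is empty.
#'
#' @param clusters a [extract_clusters()] result.
#' @param x,y point coordinates (metres).
#' @return numeric vector of distances (metres).
#' @export
cluster_distance <- function(clusters, x, y) {
  stopifnot(inherits(clusters, "cluster_set"))
  dist_to_clusters(clusters, x, y)
}

# distance from points to the nearest cell square of any cluster (0 = inside)
dist_to_clusters <- function(clusters, x, y) {
  if (clusters$n_clusters == 0L) return(rep(Inf, length(x)))
  half <- clusters$cell / 2
  cx <- unlist(lapply(clusters$clusters, function(cl) cl$nodes$x))
  cy <- unlist(lapply(clusters$clusters, function(cl) cl$nodes$y))
  vapply(seq_along(x), function(k) {
    dx <- pmax(abs(x[k] - cx) - half, 0)
    dy <- pmax(abs(y[k] - cy) - half, 0)
    sqrt(min(dx * dx + dy * dy))
  }, 0)
}

#' Summarise clusters against the survey
#'
#' Reports, for the disease-positive transects (and their diseased
#' colonies), the percentage located inside a significant cluster and the
#' percentage within a buffer distance of one, plus the total significant
#' area and the mean depth of transects inside clusters when depth was
#' recorded. Percentages are of the positive transects / diseased colonies,
#' matching how outbreak footprints are usually reported.
#'
#' @param clusters a [extract_clusters()] result.
#' @param dataset the originating \code{coral_survey}.
#' @param buffer buffer distance in metres (default 100).
#' @return an object of class \code{cluster_summary} (list of scalars plus a
#'   per-cluster data.frame).
#' @export
cluster_summary <- function(clusters, dataset, buffer = 100) {
  stopifnot(inherits(clusters, "cluster_set"), inherits(dataset, "coral_survey"))
  rec <- dataset$records
  pos <- rec$n_diseased > 0
  d_all <- dist_to_clusters(clusters, rec$x, rec$y)
  inside <- d_all == 0
  near <- d_all <= buffer
  pct <- function(num, den) if (den > 0) 100 * num / den else 0
  n_pos <- sum(pos); n_dis <- sum(rec$n_diseased)
  per_cluster <- if (clusters$n_clusters > 0L)
    do.call(rbind, lapply(clusters$clusters, function(cl) {
      half <- clusters$cell / 2
      in_cl <- vapply(seq_len(nrow(rec)), function(k)
        any(abs(rec$x[k] - cl$nodes$x) <= half &
              abs(rec$y[k] - cl$nodes$y) <= half), TRUE)
      data.frame(id = cl$id, n_nodes = cl$n_nodes, area_km2 = cl$area_km2,
                 n_transects = sum(in_cl),
                 n_positive_transects = sum(in_cl & pos),
                 mean_depth = if (any(in_cl & !is.na(rec$depth)))
                   mean(rec$depth[in_cl], na.rm = TRUE) else NA_real_)
    }))
  else data.frame(id = integer(), n_nodes = integer(), area_km2 = numeric(),
                  n_transects = integer(), n_positive_transects = integer(),
                  mean_depth = numeric())
  depth_inside <- rec$depth[inside & !is.na(rec$depth)]
  structure(list(
    n_clusters = clusters$n_clusters,
    total_area_km2 = clusters$total_area_km2,
    alpha = clusters$alpha,
    buffer = buffer,
    pct_positive_transects_inside = pct(sum(pos & inside), n_pos),
    pct_positive_transects_within_buffer = pct(sum(pos & near), n_pos),
    pct_diseased_colonies_inside = pct(sum(rec$n_diseased[inside]), n_dis),
    pct_diseased_colonies_within_buffer = pct(sum(rec$n_diseased[near]), n_dis),
    mean_depth_inside = if (length(depth_inside)) mean(depth_inside) else NA_real_,
    per_cluster = per_cluster
  ), class = "cluster_summary")
}

#' @export
print.prevalence_surface <- function(x, ...) {
  defined <- sum(!is.na(x$prevalence))
  cat(sprintf("Filtered prevalence surface (%s mode): %d x %d nodes (%d defined)\n",
              x$mode, x$grid$n_rows, x$grid$n_cols, defined))
  cat(sprintf("  cell %g m, filter radius %.2f m\n", x$grid$cell, x$radius))
  if (defined)
    cat(sprintf("  prevalence range %.4f - %.4f\n",
                min(x$prevalence, na.rm = TRUE), max(x$prevalence, na.rm = TRUE)))
  if (!is.null(x$p_value))
    cat(sprintf("  Monte Carlo: %d sims, null prevalence %.4f, %d nodes with p <= 0.05\n",
                x$n_sims, x$global_p, sum(x$p_value <= 0.05, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Significant disease clusters (p <= %g): %d cluster(s), %.4f km^2 total\n",
              x$alpha, x$n_clusters, x$total_area_km2))
  for (cl in x$clusters)
    cat(sprintf("  #%d: %d nodes, %.4f km^2\n", cl$id, cl$n_nodes, cl$area_km2))
  invisible(x)
}

#' @export
print.cluster_summary <- function(x, ...) {
  pct <- function(v) formatC(round(v, 2), format = "f", digits = 2)
  cat(sprintf("Cluster summary: %d cluster(s), %.4f km^2 (alpha %g, buffer %g m)\n",
              x$n_clusters, x$total_area_km2, x$alpha, x$buffer))
  cat(sprintf("  positive transects: %s%% inside, %s%% within buffer\n",
              pct(x$pct_positive_transects_inside),
              pct(x$pct_positive_transects_within_buffer)))
  cat(sprintf("  diseased colonies:  %s%% inside, %s%% within buffer\n",
              pct(x$pct_diseased_colonies_inside),
              pct(x$pct_diseased_colonies_within_buffer)))
  if (!is.na(x$mean_depth_inside))
    cat(sprintf("  mean depth inside clusters: %.2f m\n", x$mean_depth_inside))
  invisible(x)
}

#' Image plot of a prevalence (or p-value) surface
#'
#' @param x a \code{prevalence_surface}.
#' @param what \code{"prevalence"} or \code{"p_value"}.
#' @param ... passed to [graphics::image()].
#' @export
plot.prevalence_surface <- function(x, what = c("prevalence", "p_value"), ...) {
  what <- match.arg(what)
  z <- x[[what]]
  if (is.null(z)) stop("surface has no ", what, " layer")
  graphics::image(x$grid$node_x, x$grid$node_y, t(z),
                  xlab = "x (m)", ylab = "y (m)",
                  col = grDevices::hcl.colors(24, "Greens", rev = TRUE), ...)
  invisible(x)
}

#' Export a surface layer as an Esri ASCII grid
#'
#' Cell registration follows the node-owns-centred-cell convention, so the
#' lower-left corner sits half a cell below the first node.
#'
#' @param surface a \code{prevalence_surface}.
#' @param path output path.
#' @param what \code{"prevalence"} or \code{"p_value"}.
#' @return \code{path}, invisibly.
#' @export
write_ascii_grid <- function(surface, path, what = c("prevalence", "p_value")) {
  what <- match.arg(what)
  z <- surface[[what]]
  if (is.null(z)) stop("surface has no ", what, " layer")
  g <- surface$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", g$n_cols),
               sprintf("nrows %d", g$n_rows),
               sprintf("xllcorner %.6f", g$x_min - g$cell / 2),
               sprintf("yllcorner %.6f", g$y_min - g$cell / 2),
               sprintf("cellsize %.6f", g$cell),
               "NODATA_value -9999"), con)
  z[is.na(z)] <- -9999
  # ASCII grids run top row first
  for (i in rev(seq_len(g$n_rows)))
    writeLines(paste(formatC(z[i, ], format = "g", digits = 10),
                     collapse = " "), con)
  invisible(path)
}
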