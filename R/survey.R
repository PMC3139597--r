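#' Build a coral-disease transect survey dataset
#'
#' The central data container: one row per surveyed transect, with a planar
#' location in metres, the number of coral colonies found on the transect and
#' the number of those showing disease, plus an optional depth covariate. The
#' same object supports the two analysis resolutions used throughout the
#' package: the transect level (presence/absence of disease per transect) and
#' the colony level (each transect weighted by its colony counts).
#'
#' @param records data.frame with columns \code{id}, \code{x}, \code{y},
#'   \code{n_colonies}, \code{n_diseased} and optionally \code{depth}
#'   (metres; \code{NA} allowed).
#' @param region a [region_polygon()] / [region_rectangle()]; defaults to the
#'   bounding rectangle of the points.
#' @param crs_note free-text provenance of the planar coordinate frame.
#' @param boundary_tol tolerance (metres) allowed for records slightly outside
#'   the region, e.g. within one filter radius of the boundary.
#' @return an object of class \code{coral_survey}: a list with
#'   \code{records}, \code{region}, \code{region_area} (m^2), \code{crs_note}.
#' @examples
#' s <- survey_dataset(data.frame(id = 1:3, x = c(0, 50, 100), y = 0,
#'                                n_colonies = c(4, 6, 2),
#'                                n_diseased = c(1, 0, 0)))
#' summary(s)
#' @export
survey_dataset <- function(records, region = NULL, crs_note = "planar metres",
                           boundary_tol = 0) {
  records <- as.data.frame(records)
  required <- c("id", "x", "y", "n_colonies", "n_diseased")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (!"depth" %in% names(records))
    records[["depth"]] <- rep(NA_real_, nrow(records))
  records <- records[c(required, "depth")]
  if (nrow(records)) {
    for (col in c("x", "y", "n_colonies", "n_diseased"))
      if (any(!is.finite(records[[col]])))
        stop("non-finite values in column '", col, "'")
    if (any(records$n_colonies < 0) || any(records$n_diseased < 0))
      stop("colony counts must be non-negative")
    bad <- records$n_diseased > records$n_colonies
    if (any(bad))
      stop("n_diseased exceeds n_colonies for record(s): ",
           paste(records$id[bad], collapse = ", "))
  } else {
    warning("survey has no records; downstream analyses will reject it")
  }
  if (is.null(region)) {
    if (nrow(records) == 0L)
      region <- region_rectangle(0, 1, 0, 1)
    else {
      rx <- range(records$x); ry <- range(records$y)
      # a degenerate bounding box (collinear points) gets a 1 m pad
      if (diff(rx) <= 0) rx <- rx + c(-0.5, 0.5)
      if (diff(ry) <= 0) ry <- ry + c(-0.5, 0.5)
      region <- region_rectangle(rx[1L], rx[2L], ry[1L], ry[2L])
    }
  }
  stopifnot(inherits(region, "survey_region"))
  if (nrow(records)) {
    inside <- region_contains(region, records$x, records$y)
    if (!all(inside) && boundary_tol > 0) {
      # accept points within boundary_tol of the region (cheap check against
      # the outer ring's bounding box expanded by the tolerance)
      bb <- region_bbox(region)
      near <- records$x >= bb["x_min"] - boundary_tol &
        records$x <= bb["x_max"] + boundary_tol &
        records$y >= bb["y_min"] - boundary_tol &
        records$y <= bb["y_max"] + boundary_tol
      inside <- inside | near
    }
    if (!all(inside))
      stop("record(s) outside the study region: ",
           paste(utils::head(records$id[!inside], 5L), collapse = ", "))
  }
  structure(list(records = records, region = region,
                 region_area = region$area, crs_note = crs_note),
            class = "coral_survey")
}

#' Read a transect survey from delimited text or GeoJSON
#'
#' Delimited files need a header row; the delimiter is sniffed from comma or
#' tab. GeoJSON input must be a FeatureCollection of Points whose properties
#' carry the count columns. Geographic coordinates (lon/lat) are projected to
#' planar metres with the supplied projection, or with a local transverse
#' Mercator centred on the data if \code{projection = "auto"}.
#'
#' @param path file path.
#' @param schema named character vector mapping the canonical names
#'   (\code{id}, \code{x}, \code{y} or \code{lon}, \code{lat},
#'   \code{n_colonies}, \code{n_diseased}, \code{depth}) to the column names
#'   in the file; defaults assume canonical names.
#' @param projection \code{NULL} (coordinates already planar metres), a
#'   [local_projection()], or \code{"auto"}.
#' @param region optional [region_polygon()]; defaults to the points' bounding
#'   rectangle.
#' @param boundary_tol passed to [survey_dataset()].
#' @return a \code{coral_survey}.
#' @export
read_survey <- function(path, schema = NULL, projection = NULL,
                        region = NULL, boundary_tol = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  geojson <- grepl("\\.(geo)?json$", path, ignore.case = TRUE)
  if (geojson) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(raw$features))
      stop("GeoJSON input must be a FeatureCollection")
    feats <- raw$features
    tab <- do.call(rbind, lapply(feats, function(f) {
      props <- f$properties
      cc <- unlist(f$geometry$coordinates)
      data.frame(id = as.character(props$id),
                 lon = cc[1L], lat = cc[2L],
                 n_colonies = as.numeric(props$n_colonies),
                 n_diseased = as.numeric(props$n_diseased),
                 depth = if (is.null(props$depth)) NA_real_ else as.numeric(props$depth))
    }))
    if (is.null(projection)) projection <- "auto"
    names(tab)[names(tab) == "lon"] <- "x"
    names(tab)[names(tab) == "lat"] <- "y"
  } else {
    first <- readLines(path, n = 1L)
    if (length(first) == 0L) {
      warning("empty survey file: ", path)
      return(survey_dataset(data.frame(id = character(), x = numeric(),
                                       y = numeric(), n_colonies = numeric(),
                                       n_diseased = numeric())))
    }
    sep <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    if (nrow(tab) == 0L) {
      warning("survey file has a header but no rows: ", path)
      return(survey_dataset(data.frame(id = character(), x = numeric(),
                                       y = numeric(), n_colonies = numeric(),
                                       n_diseased = numeric())))
    }
    if (!is.null(schema)) {
      for (canon in names(schema)) {
        src <- schema[[canon]]
        if (!src %in% names(tab))
          stop("schema column '", src, "' (for '", canon, "') not in file")
        names(tab)[names(tab) == src] <- canon
      }
    }
    if (all(c("lon", "lat") %in% names(tab)) &&
        !all(c("x", "y") %in% names(tab))) {
      names(tab)[names(tab) == "lon"] <- "x"
      names(tab)[names(tab) == "lat"] <- "y"
      if (is.null(projection))
        stop("file carries lon/lat coordinates; supply a projection ",
             "(or projection = \"auto\")")
    }
    for (canon in c("id", "x", "y", "n_colonies", "n_diseased"))
      if (!canon %in% names(tab))
        stop("missing required column: ", canon)
  }
  if (!is.null(projection)) {
    if (identical(projection, "auto"))
      projection <- local_projection(mean(range(tab$x)), mean(range(tab$y)))
    xy <- project_coordinates(tab$x, tab$y, projection)
    tab$x <- xy[, "x"]; tab$y <- xy[, "y"]
    crs_note <- sprintf("local transverse Mercator, origin (%.5f, %.5f)",
                        projection$lon0, projection$lat0)
  } else crs_note <- "planar metres (as supplied)"
  out <- survey_dataset(tab, region = region, crs_note = crs_note,
                        boundary_tol = boundary_tol)
  attr(out, "projection") <- if (inherits(projection, "local_projection")) projection
  out
}

#' Write a survey back to file
#'
#' Round-trips all numeric fields exactly (15 significant digits in text).
#'
#' @param dataset a \code{coral_survey}.
#' @param path output path; format chosen by extension (\code{.csv},
#'   \code{.tsv} or \code{.geojson}/\code{.json}).
#' @return \code{path}, invisibly.
#' @export
write_survey <- function(dataset, path) {
  stopifnot(inherits(dataset, "coral_survey"))
  rec <- dataset$records
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
    proj <- attr(dataset, "projection")
    if (is.null(proj))
      stop("GeoJSON output needs the projection the survey was loaded with")
    ll <- unproject_coordinates(rec$x, rec$y, proj)
    feats <- lapply(seq_len(nrow(rec)), function(i) {
      props <- list(id = rec$id[i], n_colonies = rec$n_colonies[i],
                    n_diseased = rec$n_diseased[i])
      if (!is.na(rec$depth[i])) props$depth <- rec$depth[i]
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(ll[i, "lon"], ll[i, "lat"])),
           properties = props)
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    fmt <- rec
    for (col in c("x", "y", "depth"))
      fmt[[col]] <- formatC(rec[[col]], digits = 15, format = "g")
    fmt$depth[is.na(rec$depth)] <- NA
    utils::write.table(fmt, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Summarise a survey at both analysis resolutions
#'
#' Computes transect-level prevalence (percent of transects with at least one
#' diseased colony) and colony-level prevalence (percent of all colonies
#' diseased), together with the colony-count distribution across transects
#' and the diseased-count distribution across positive transects. Percentages
#' are stored at full precision and rounded to two decimals only when
#' printed.
#'
#' @param object a \code{coral_survey}.
#' @param ... unused.
#' @return an object of class \code{coral_survey_summary} (a list of named
#'   scalars).
#' @export
summary.coral_survey <- function(object, ...) {
  rec <- object$records
  if (nrow(rec) < 1L) stop("cannot summarise a survey with no records")
  if (sum(rec$n_colonies) < 1) stop("prevalence undefined: survey has no colonies")
  pos <- rec$n_diseased > 0
  dis_pos <- rec$n_diseased[pos]
  healthy <- rec$n_colonies - rec$n_diseased
  depth_ok <- !is.na(rec$depth)
  out <- list(
    n_transects = nrow(rec),
    n_transects_positive = sum(pos),
    n_colonies = sum(rec$n_colonies),
    n_colonies_diseased = sum(rec$n_diseased),
    prevalence_transect = 100 * sum(pos) / nrow(rec),
    prevalence_colony = 100 * sum(rec$n_diseased) / sum(rec$n_colonies),
    mean_colonies_per_transect = mean(rec$n_colonies),
    sd_colonies_per_transect = stats::sd(rec$n_colonies),
    min_colonies_per_transect = min(rec$n_colonies),
    max_colonies_per_transect = max(rec$n_colonies),
    mean_diseased_per_positive_transect =
      if (any(pos)) mean(dis_pos) else NA_real_,
    sd_diseased_per_positive_transect =
      if (sum(pos) > 1) stats::sd(dis_pos) else NA_real_,
    min_diseased_per_positive_transect =
      if (any(pos)) min(dis_pos) else NA_real_,
    max_diseased_per_positive_transect =
      if (any(pos)) max(dis_pos) else NA_real_,
    mean_healthy_per_transect = mean(healthy),
    mean_depth = if (any(depth_ok)) mean(rec$depth[depth_ok]) else NA_real_,
    region_area_km2 = object$region_area / 1e6
  )
  structure(out, class = "coral_survey_summary")
}

#' @export
print.coral_survey_summary <- function(x, ...) {
  pct <- function(v) formatC(round(v, 2), format = "f", digits = 2)
  cat("Coral disease survey summary\n")
  cat(sprintf("  transects: %d surveyed, %d disease-positive (prevalence %s%%)\n",
              x$n_transects, x$n_transects_positive, pct(x$prevalence_transect)))
  cat(sprintf("  colonies:  %d surveyed, %d diseased (prevalence %s%%)\n",
              x$n_colonies, x$n_colonies_diseased, pct(x$prevalence_colony)))
  cat(sprintf("  colonies/transect: mean %.2f (min %d, max %d, %.2f SD)\n",
              x$mean_colonies_per_transect, x$min_colonies_per_transect,
              x$max_colonies_per_transect, x$sd_colonies_per_transect))
  if (!is.na(x$mean_diseased_per_positive_transect))
    cat(sprintf("  diseased/positive transect: mean %.2f (min %d, max %d%s)\n",
                x$mean_diseased_per_positive_transect,
                x$min_diseased_per_positive_transect,
                x$max_diseased_per_positive_transect,
                if (is.na(x$sd_diseased_per_positive_transect)) ""
                else sprintf(", %.2f SD", x$sd_diseased_per_positive_transect)))
  if (!is.na(x$mean_depth))
    cat(sprintf("  mean depth: %.2f m\n", x$mean_depth))
  cat(sprintf("  study area: %.4f km^2\n", x$region_area_km2))
  invisible(x)
}

#' Serialise a survey summary as flat JSON
#'
#' @param summary a \code{coral_survey_summary}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "coral_survey_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @export
print.coral_survey <- function(x, ...) {
  cat(sprintf("Coral survey: %d transects, %d colonies (%d diseased)\n",
              nrow(x$records), sum(x$records$n_colonies),
              sum(x$records$n_diseased)))
  cat(sprintf("  region area %.4f km^2; %s\n", x$region_area / 1e6, x$crs_note))
  invisible(x)
}

# internal: the two analysis views of a survey -------------------------------

# returns list(x, y, w) for the requested view; zero-weight points are kept
# (they contribute nothing to weighted pair sums). "healthy" is the
# disease-absent complement: transects with no diseased colony, or weights
# n_colonies - n_diseased.
survey_view <- function(dataset, view = c("population", "disease", "healthy"),
                        mode = c("transect", "colony")) {
  view <- match.arg(view); mode <- match.arg(mode)
  rec <- dataset$records
  w <- switch(paste(view, mode, sep = "."),
              population.transect = rep(1, nrow(rec)),
              population.colony = rec$n_colonies,
              disease.transect = as.numeric(rec$n_diseased > 0),
              disease.colony = rec$n_diseased,
              healthy.transect = as.numeric(rec$n_diseased == 0),
              healthy.colony = rec$n_colonies - rec$n_diseased)
  list(x = rec$x, y = rec$y, w = w)
}
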