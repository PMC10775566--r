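#' Construct a track object
#'
#' A track is an ordered set of timestamped planar locations for one animal.
#' The working clock is numeric time in days (fractional days allowed); when
#' locations are read from ISO 8601 timestamps the original \code{POSIXct}
#' values are kept in a \code{timestamp} column and the numeric time is days
#' since the Unix epoch, so calendar operations (daily rarefaction, date
#' subsetting) remain exact. Coordinates are planar (projected), in km for
#' field data; simulator output uses dimensionless spatial units.
#'
#' @param df Data frame with columns \code{time} (numeric days), \code{x},
#'   \code{y}, and optionally \code{hdop}, \code{vdop}, \code{timestamp}
#'   (POSIXct), \code{state}.
#' @param id Track identifier (single string).
#' @param dt_nominal Nominal sampling interval in days (default 1).
#' @return An object of class \code{mmcp_track} (a data frame sorted by
#'   time, with \code{id} and \code{dt_nominal} attributes).
#' @export
mmcp_track <- function(df, id = "track", dt_nominal = 1) {
  stopifnot(is.data.frame(df), all(c("time", "x", "y") %in% names(df)))
  if (nrow(df) > 0) {
    if (!all(is.finite(df$time)) || !all(is.finite(df$x)) ||
        !all(is.finite(df$y))) {
      stop("track locations must have finite time, x and y")
    }
    df <- df[order(df$time), , drop = FALSE]
    if (any(diff(df$time) <= 0)) {
      stop("track times must be strictly increasing (collapse duplicates first)")
    }
  }
  rownames(df) <- NULL
  structure(df,
    id = as.character(id)[1], dt_nominal = dt_nominal,
    class = c("mmcp_track", "data.frame")
  )
}

#' @export
print.mmcp_track <- function(x, ...) {
  cat(sprintf(
    "<mmcp_track '%s': %d locations, dt = %g d, span [%g, %g]>\n",
    attr(x, "id"), nrow(x), attr(x, "dt_nominal"),
    if (nrow(x)) min(x$time) else NA, if (nrow(x)) max(x$time) else NA
  ))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

track_attrs <- function(df, template) {
  mmcp_track(df,
    id = attr(template, "id"),
    dt_nominal = attr(template, "dt_nominal")
  )
}

#' Read tracks from a CSV file
#'
#' One \code{mmcp_track} is returned per distinct id, sorted by time, with
#' duplicate timestamps collapsed to their first occurrence (a message
#' reports how many were dropped). Timestamps may be ISO 8601 strings or
#' numeric times in days; coordinates must already be planar (project
#' geographic coordinates upstream).
#'
#' @param path CSV file path.
#' @param column_map Named character vector mapping the roles \code{id},
#'   \code{timestamp}, \code{x}, \code{y}, \code{hdop}, \code{vdop} to column
#'   names in the file. Missing optional roles (\code{hdop}, \code{vdop}) are
#'   skipped.
#' @param dt_nominal Nominal sampling interval in days.
#' @param tz Time zone used when parsing ISO 8601 timestamps.
#' @return A named list of \code{mmcp_track} objects (one per id).
#' @export
read_track_csv <- function(path,
                           column_map = c(
                             id = "id", timestamp = "timestamp",
                             x = "x", y = "y",
                             hdop = "hdop", vdop = "vdop"
                           ),
                           dt_nominal = 1, tz = "UTC") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "timestamp", "x", "y")
  for (role in required) {
    col <- column_map[[role]]
    if (is.null(col) || !(col %in% names(raw))) {
      stop(sprintf(
        "input error: required column '%s' (role '%s') not found in %s",
        if (is.null(col)) role else col, role, path
      ))
    }
  }
  ts_raw <- raw[[column_map[["timestamp"]]]]
  if (is.numeric(ts_raw)) {
    time <- as.numeric(ts_raw)
    timestamp <- NULL
  } else {
    fmts <- c(
      "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
      "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d"
    )
    ts_chr <- as.character(ts_raw)
    timestamp <- tryCatch(
      as.POSIXct(ts_chr, tz = tz, tryFormats = fmts),
      error = function(e) {
        # locate the offending row for the error message
        one <- vapply(ts_chr, function(s) {
          tryCatch(as.numeric(as.POSIXct(s, tz = tz, tryFormats = fmts)),
            error = function(e) NA_real_
          )
        }, numeric(1), USE.NAMES = FALSE)
        as.POSIXct(one, tz = tz, origin = "1970-01-01")
      }
    )
    bad <- which(is.na(timestamp))
    if (length(bad)) {
      stop(sprintf(
        "input error: unparseable timestamp '%s' at row %d",
        ts_raw[bad[1]], bad[1]
      ))
    }
    time <- as.numeric(timestamp) / 86400
  }
  df <- data.frame(
    id = as.character(raw[[column_map[["id"]]]]),
    time = time, x = raw[[column_map[["x"]]]], y = raw[[column_map[["y"]]]]
  )
  for (role in c("hdop", "vdop")) {
    col <- column_map[[role]]
    if (!is.null(col) && !is.na(col) && col %in% names(raw)) df[[role]] <- raw[[col]]
  }
  if (!is.null(timestamp)) df$timestamp <- timestamp
  out <- lapply(split(df, df$id), function(d) {
    d <- d[order(d$time), , drop = FALSE]
    dup <- duplicated(d$time)
    if (any(dup)) {
      message(sprintf(
        "track '%s': collapsed %d duplicate timestamp(s) to first occurrence",
        d$id[1], sum(dup)
      ))
      d <- d[!dup, , drop = FALSE]
    }
    id <- d$id[1]
    d$id <- NULL
    mmcp_track(d, id = id, dt_nominal = dt_nominal)
  })
  out[order(names(out))]
}

#' Filter locations by dilution of precision
#'
#' Removes every location whose horizontal or vertical DOP exceeds the
#' threshold. Locations without DOP fields are retained.
#'
#' @param track An \code{mmcp_track}.
#' @param max_dop DOP threshold (default 5).
#' @return The filtered track.
#' @export
filter_dop <- function(track, max_dop = 5) {
  stopifnot(inherits(track, "mmcp_track"))
  keep <- rep(TRUE, nrow(track))
  if ("hdop" %in% names(track)) {
    keep <- keep & (is.na(track$hdop) | track$hdop <= max_dop)
  }
  if ("vdop" %in% names(track)) {
    keep <- keep & (is.na(track$vdop) | track$vdop <= max_dop)
  }
  track_attrs(as.data.frame(track)[keep, , drop = FALSE], track)
}

#' Rarefy a track to one location per day
#'
#' For each calendar day the fix nearest 12:00 is retained (ties broken in
#' favour of the earlier fix). The retained fixes' working times are snapped
#' to the integer day index so the rarefied track is exactly regular with
#' \code{dt_nominal = 1} day; original timestamps, when present, are kept in
#' the \code{timestamp} column.
#'
#' @param track An \code{mmcp_track}.
#' @return The rarefied track with \code{dt_nominal = 1}.
#' @export
rarefy_daily <- function(track) {
  stopifnot(inherits(track, "mmcp_track"), nrow(track) > 0)
  day <- floor(track$time)
  off <- abs(track$time - (day + 0.5))
  pick <- unlist(lapply(split(seq_len(nrow(track)), day), function(idx) {
    # earliest fix among those tied (to numerical precision) for nearest-noon
    idx[which(off[idx] <= min(off[idx]) + 1e-9)[1]]
  }), use.names = FALSE)
  d <- as.data.frame(track)[sort(pick), , drop = FALSE]
  d$time <- floor(d$time)
  mmcp_track(d, id = attr(track, "id"), dt_nominal = 1)
}

# Convert Date / POSIXct / numeric-day inputs to the numeric day clock.
as_time_days <- function(x) {
  if (inherits(x, "Date")) return(as.numeric(x))
  if (inherits(x, "POSIXt")) return(as.numeric(x) / 86400)
  as.numeric(x)
}

#' Subset a track to a date window
#'
#' Retains locations with \code{start <= time <= end}. \code{Date} bounds are
#' interpreted inclusively of the whole end day, so \code{end = "July 1"}
#' omits exactly the locations after July 1.
#'
#' @param track An \code{mmcp_track}.
#' @param start,end Window bounds (numeric days, \code{Date} or POSIXct).
#' @return The subsetted track (empty, with a warning, if no location falls
#'   in the window).
#' @export
subset_dates <- function(track, start, end) {
  stopifnot(inherits(track, "mmcp_track"))
  s <- as_time_days(start)
  e <- as_time_days(end)
  if (inherits(end, "Date")) e <- e + 1 - 1e-9 # whole final day
  stopifnot(s <= e)
  keep <- track$time >= s & track$time <= e
  if (!any(keep)) warning("subset_dates: no locations in window; empty track")
  track_attrs(as.data.frame(track)[keep, , drop = FALSE], track)
}

#' Screen a track for spatial and temporal gaps
#'
#' Lists every consecutive-fix displacement exceeding the spatial threshold
#' and every inter-fix interval exceeding the temporal threshold. The report
#' carries a pass/fail flag intended as a whole-track exclusion filter: a
#' track with any violation fails.
#'
#' @param track An \code{mmcp_track}.
#' @param max_spatial_gap Largest allowed consecutive displacement (km).
#' @param max_temporal_gap Largest allowed inter-fix interval (days).
#' @return A list of class \code{mmcp_gap_report}: \code{pass}, and data
#'   frames \code{spatial} / \code{temporal} describing each violation.
#' @export
check_gaps <- function(track, max_spatial_gap = 400, max_temporal_gap = 14) {
  stopifnot(inherits(track, "mmcp_track"))
  n <- nrow(track)
  if (n < 2) {
    rep0 <- data.frame(
      from_time = numeric(0), to_time = numeric(0),
      value = numeric(0)
    )
    return(structure(list(pass = TRUE, spatial = rep0, temporal = rep0),
      class = "mmcp_gap_report"
    ))
  }
  d <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  dt <- diff(track$time)
  sp <- which(d > max_spatial_gap)
  te <- which(dt > max_temporal_gap)
  spatial <- data.frame(
    from_time = track$time[sp], to_time = track$time[sp + 1], value = d[sp]
  )
  temporal <- data.frame(
    from_time = track$time[te], to_time = track$time[te + 1], value = dt[te]
  )
  structure(
    list(
      pass = length(sp) == 0 && length(te) == 0,
      spatial = spatial, temporal = temporal
    ),
    class = "mmcp_gap_report"
  )
}

#' @export
print.mmcp_gap_report <- function(x, ...) {
  cat(sprintf(
    "gap report: %s (%d spatial, %d temporal violations)\n",
    if (x$pass) "PASS" else "FAIL", nrow(x$spatial), nrow(x$temporal)
  ))
  invisible(x)
}

#' Split an annual track at its southernmost location
#'
#' For a track spanning one annual cycle that starts on the breeding grounds,
#' the fix with minimum northing separates the fall (outbound) and spring
#' (return) movements. The southernmost fix belongs to both halves; ties are
#' broken by the earliest date.
#'
#' @param track An \code{mmcp_track} with at least 3 locations.
#' @return A list with elements \code{fall} and \code{spring}.
#' @export
split_at_southernmost <- function(track) {
  stopifnot(inherits(track, "mmcp_track"))
  if (nrow(track) < 3) stop("input error: need at least 3 locations to split")
  i <- which.min(track$y) # first minimum = earliest on ties
  if (i == 1) {
    warning("southernmost location is the first fix; degenerate fall segment")
  }
  df <- as.data.frame(track)
  list(
    fall = track_attrs(df[seq_len(i), , drop = FALSE], track),
    spring = track_attrs(df[i:nrow(df), , drop = FALSE], track)
  )
}
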