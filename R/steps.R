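#' Construct a step series
#'
#' The step series is the data the likelihood consumes: for each location
#' after the first, the step length \eqn{r_t} (km) of the step arriving at
#' time \eqn{t}, and the signed turning angle \eqn{\phi_t} in
#' \eqn{(-\pi, \pi]} defined by three consecutive on-interval fixes. Validity
#' masks record where each quantity is defined; a valid turning angle
#' requires a valid step at the same index and at the previous index.
#'
#' @param time Arrival time of each step (days), strictly increasing.
#' @param r Step lengths (NA where invalid).
#' @param phi Turning angles (NA where invalid).
#' @param valid_r,valid_phi Logical validity masks.
#' @param dt_nominal Nominal sampling interval (days).
#' @param id Optional identifier carried from the track.
#' @return An object of class \code{mmcp_steps} (a data frame).
#' @export
mmcp_steps <- function(time, r, phi, valid_r = !is.na(r),
                       valid_phi = !is.na(phi), dt_nominal = 1, id = "steps") {
  n <- length(time)
  stopifnot(
    length(r) == n, length(phi) == n, length(valid_r) == n,
    length(valid_phi) == n
  )
  if (n > 1 && any(diff(time) <= 0)) stop("step times must be strictly increasing")
  if (any(valid_r & (!is.finite(r) | r < 0))) {
    stop("valid step lengths must be finite and non-negative")
  }
  if (any(valid_phi & (!is.finite(phi) | phi <= -pi | phi > pi))) {
    stop("valid turning angles must lie in (-pi, pi]")
  }
  if (any(valid_phi & !valid_r)) {
    stop("a valid turning angle requires a valid step at the same index")
  }
  if (any(valid_phi[-1] & !valid_r[-n]) || (n > 0 && valid_phi[1])) {
    stop("a valid turning angle requires a valid step at the previous index")
  }
  df <- data.frame(
    time = time, r = ifelse(valid_r, r, NA_real_),
    phi = ifelse(valid_phi, phi, NA_real_),
    valid_r = as.logical(valid_r), valid_phi = as.logical(valid_phi)
  )
  structure(df,
    dt_nominal = dt_nominal, id = as.character(id)[1],
    class = c("mmcp_steps", "data.frame")
  )
}

#' @export
print.mmcp_steps <- function(x, ...) {
  cat(sprintf(
    "<mmcp_steps '%s': %d entries (%d valid r, %d valid phi), dt = %g d>\n",
    attr(x, "id"), nrow(x), sum(x$valid_r), sum(x$valid_phi),
    attr(x, "dt_nominal")
  ))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Compute step lengths and turning angles from a regularized track
#'
#' For each location \eqn{z_t} whose predecessor lies within
#' \eqn{(1 \pm \code{tolerance}) \cdot \code{dt\_nominal}}, the step length
#' is the Euclidean distance between the last two locations. The turning
#' angle at \eqn{z_t} is the signed angle between the headings
#' \eqn{z_{t-2} \to z_{t-1}} and \eqn{z_{t-1} \to z_t}, wrapped to
#' \eqn{(-\pi, \pi]}; it is defined only when both steps are valid,
#' contiguous, and of positive length (the heading of a zero-length step is
#' undefined, so a zero step keeps \code{valid_r} but masks the dependent
#' angle). Steps spanning missing fixes are masked invalid by default;
#' \code{rescale_gaps = TRUE} instead normalizes the displacement by the
#' elapsed interval (r scaled to one nominal interval) and treats the step
#' as valid.
#'
#' @param track An \code{mmcp_track} regularized to its \code{dt_nominal}.
#' @param tolerance Allowed fractional deviation of an interval from
#'   \code{dt_nominal} (default 0.1).
#' @param rescale_gaps Normalize gap-spanning steps by elapsed time instead
#'   of masking them (default \code{FALSE}).
#' @return An \code{mmcp_steps} object with one entry per location after the
#'   first.
#' @export
compute_steps <- function(track, tolerance = 0.1, rescale_gaps = FALSE) {
  stopifnot(inherits(track, "mmcp_track"), nrow(track) >= 2)
  dtn <- attr(track, "dt_nominal")
  n <- nrow(track)
  dt <- diff(track$time)
  dx <- diff(track$x)
  dy <- diff(track$y)
  disp <- sqrt(dx^2 + dy^2)
  on_interval <- abs(dt - dtn) <= tolerance * dtn
  if (rescale_gaps) {
    r <- ifelse(on_interval, disp, disp * dtn / dt)
    valid_r <- dt > 0
  } else {
    r <- ifelse(on_interval, disp, NA_real_)
    valid_r <- on_interval
  }
  heading <- atan2(dy, dx) # undefined where disp == 0
  m <- n - 1 # entries; entry i is the step arriving at track time i+1
  phi <- rep(NA_real_, m)
  valid_phi <- rep(FALSE, m)
  if (m >= 2) {
    i <- 2:m
    contiguous <- on_interval[i] & on_interval[i - 1]
    ok <- valid_r[i] & valid_r[i - 1] & contiguous &
      disp[i] > 0 & disp[i - 1] > 0
    phi[i[ok]] <- wrap_angle(heading[i] - heading[i - 1])[ok]
    valid_phi[i] <- ok
  }
  mmcp_steps(
    time = track$time[-1], r = r, phi = phi, valid_r = valid_r,
    valid_phi = valid_phi, dt_nominal = dtn, id = attr(track, "id")
  )
}

#' Write / read a step series as CSV
#'
#' Columns: time, r, phi, valid_r, valid_phi. The nominal interval and id are
#' stored in a comment-free side channel: \code{read_steps_csv} takes them as
#' arguments (default dt 1 day).
#'
#' @param steps An \code{mmcp_steps} object.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_steps_csv <- function(steps, path) {
  stopifnot(inherits(steps, "mmcp_steps"))
  utils::write.csv(as.data.frame(steps), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_steps_csv
#' @param dt_nominal,id Metadata to attach on read.
#' @export
read_steps_csv <- function(path, dt_nominal = 1, id = "steps") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time", "r", "phi", "valid_r", "valid_phi") %in% names(d)))
  mmcp_steps(d$time, d$r, d$phi, as.logical(d$valid_r), as.logical(d$valid_phi),
    dt_nominal = dt_nominal, id = id
  )
}
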