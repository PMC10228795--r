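#' A 1D reporter intensity profile
#'
#' Positions on the rescaled center-to-periphery axis \[0, 1\] with
#' intensity values, an optional standard-error track, a channel label and
#' an optional excluded-region mask (used to drop, e.g., a domain of dead
#' cells from scaling, smoothing and correlation).
#'
#' @param position Strictly increasing positions in \[0, 1\].
#' @param intensity Non-negative intensities, same length.
#' @param sem Optional pointwise standard error of the mean.
#' @param channel Channel label (`"JNK"`, `"JAK"`, `"EdU"`, `"UPD"`, ...).
#' @param scaled Logical: has the profile been rescaled to max 1?
#' @param mask Optional numeric interval `c(lo, hi)` of excluded positions.
#' @return Object of class `wf_profile`.
#' @export
reporter_profile <- function(position, intensity, sem = NULL,
                             channel = "JNK", scaled = FALSE, mask = NULL) {
  position <- as.numeric(position); intensity <- as.numeric(intensity)
  if (length(position) != length(intensity)) stop("position/intensity length mismatch")
  if (any(diff(position) <= 0)) stop("positions must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  if (!is.null(mask)) {
    if (length(mask) != 2L || mask[1] > mask[2] || mask[1] < 0 || mask[2] > 1)
      stop("mask must be a sub-interval of [0, 1]")
  }
  p <- structure(list(position = position, intensity = intensity,
                      sem = if (!is.null(sem)) as.numeric(sem),
                      channel = channel, scaled = isTRUE(scaled),
                      mask = mask), class = "wf_profile")
  if (p$scaled && max(intensity[profile_unmasked(p)]) != 1)
    stop("scaled profile must peak at 1 over unmasked positions")
  p
}

#' Logical vector of unmasked positions
#' @param p A `wf_profile`.
#' @return Logical vector, `TRUE` where data is retained.
#' @export
profile_unmasked <- function(p) {
  if (is.null(p$mask)) rep(TRUE, length(p$position))
  else !(p$position >= p$mask[1] & p$position <= p$mask[2])
}

#' A set of traced reporter tracks
#'
#' `k >= 1` intensity tracks along the center-to-periphery axis, as traced
#' from confocal images (or generated synthetically).  Tracks with unequal
#' sampling are linearly resampled onto a common grid.
#'
#' @param tracks Numeric matrix, one row per track, or a list of
#'   two-column (position, intensity) matrices/data frames.
#' @param position Common positions for matrix input; defaults to a
#'   uniform grid on \[0, 1\].
#' @param channel Channel label.
#' @param grid_points Grid size when resampling list input (default 100).
#' @return Object of class `wf_trackset`.
#' @export
track_set <- function(tracks, position = NULL, channel = "JNK",
                      grid_points = 100L) {
  if (is.list(tracks) && !is.data.frame(tracks) && !is.matrix(tracks)) {
    grid <- seq(0, 1, length.out = grid_points)
    m <- t(vapply(tracks, function(tr) {
      tr <- as.matrix(tr)
      if (any(diff(tr[, 1]) <= 0)) stop("track distances must be monotone increasing")
      xs <- (tr[, 1] - min(tr[, 1])) / (max(tr[, 1]) - min(tr[, 1]))
      stats::approx(xs, tr[, 2], xout = grid, rule = 2)$y
    }, numeric(length(grid))))
    tracks <- m
    position <- grid
  }
  tracks <- as.matrix(tracks)
  if (is.null(position)) position <- seq(0, 1, length.out = ncol(tracks))
  if (length(position) != ncol(tracks)) stop("position length must match track length")
  if (any(diff(position) <= 0)) stop("positions must be monotone increasing")
  if (any(tracks < 0)) stop("intensities must be >= 0")
  structure(list(tracks = tracks, position = position, channel = channel),
            class = "wf_trackset")
}

#' Aggregate tracks into a scaled mean profile
#'
#' Pointwise mean across tracks, rescaled so the mean profile peaks at 1,
#' with the pointwise standard error of the mean carried along (scaled by
#' the same factor, for mean +/- SEM plots).
#'
#' @param ts A [track_set()].
#' @return A scaled [reporter_profile()] with `sem`.
#' @export
aggregate_tracks <- function(ts) {
  if (!inherits(ts, "wf_trackset")) stop("ts must be a wf_trackset")
  m <- colMeans(ts$tracks)
  peak <- max(m)
  if (peak <= 0) stop("all-zero tracks: scaling undefined")
  k <- nrow(ts$tracks)
  sem <- if (k > 1) apply(ts$tracks, 2, stats::sd) / sqrt(k) else rep(0, ncol(ts$tracks))
  xs <- (ts$position - min(ts$position)) / (max(ts$position) - min(ts$position))
  reporter_profile(xs, m / peak, sem = sem / peak, channel = ts$channel,
                   scaled = TRUE)
}

#' LOESS-smooth a reporter profile
#'
#' Locally weighted (tricube) regression over a neighbourhood containing
#' `span * n` points, evaluated at the input positions, with a 95%
#' pointwise confidence band.  Local degree 2 (quadratic, the ggplot2
#' `geom_smooth` default) is used: it reproduces constants and straight
#' lines exactly and keeps the bias low on steep sigmoid profiles at the
#' wide default span.  Masked positions are excluded from the fit.
#'
#' @param p A [reporter_profile()] with at least 10 unmasked points.
#' @param span Smoothing span in (0, 1\] (default 0.8).
#' @param level Confidence level of the band (default 0.95).
#' @return A `wf_profile` with smoothed intensities and attributes
#'   `ci_lower`, `ci_upper`.
#' @export
loess_smooth <- function(p, span = 0.8, level = 0.95) {
  if (!inherits(p, "wf_profile")) stop("p must be a wf_profile")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  keep <- profile_unmasked(p)
  if (sum(keep) < 10L) stop("need at least 10 unmasked points")
  x <- p$position[keep]; y <- p$intensity[keep]
  fit <- stats::loess(y ~ x, span = span, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  pr <- stats::predict(fit, newdata = data.frame(x = x), se = TRUE)
  # intensities are clamped at 0 for the profile contract; the raw fit
  # and its band are kept as attributes
  out <- reporter_profile(x, pmax(pr$fit, 0), channel = p$channel,
                          scaled = FALSE)
  tq <- stats::qt(1 - (1 - level) / 2, pr$df)
  attr(out, "fit") <- pr$fit
  attr(out, "ci_lower") <- pr$fit - tq * pr$se.fit
  attr(out, "ci_upper") <- pr$fit + tq * pr$se.fit
  out
}

#' Exclude a region of a profile
#'
#' Marks a sub-interval (e.g. a domain of dead cells) as carrying no data:
#' masked positions are ignored by scaling, smoothing and the
#' correlation-based classifier.  If the profile was scaled, it is rescaled
#' to the maximum over surviving positions; surviving values are otherwise
#' unchanged (up to that common factor).
#'
#' @param p A [reporter_profile()].
#' @param region Numeric interval `c(lo, hi)` within \[0, 1\].
#' @return A `wf_profile` with the mask applied.
#' @export
apply_mask <- function(p, region) {
  if (!inherits(p, "wf_profile")) stop("p must be a wf_profile")
  if (length(region) != 2L || region[1] > region[2]) stop("region must be c(lo, hi)")
  q <- p
  q$mask <- as.numeric(region)
  keep <- profile_unmasked(q)
  if (!any(keep)) stop("mask covers the whole profile")
  if (q$scaled) {
    peak <- max(q$intensity[keep])
    if (peak <= 0) stop("masked profile has no positive data to scale")
    q$intensity <- q$intensity / peak
    if (!is.null(q$sem)) q$sem <- q$sem / peak
  }
  q
}

#' Read/write tracks and profiles as CSV
#'
#' Tracks round-trip in long format (`track_id, position, intensity,
#' channel`); profiles as two/three-column tables (`position, intensity[,
#' sem]`).  Numbers are written with 17 significant digits so round-trips
#' are value-exact.
#'
#' @param ts A [track_set()]; `p` a [reporter_profile()]; `path` file path.
#' @return Readers return the reconstructed object; writers return the
#'   path invisibly.
#' @name profile_io
NULL

#' @rdname profile_io
#' @export
write_tracks <- function(ts, path) {
  df <- data.frame(
    track_id = rep(seq_len(nrow(ts$tracks)), each = ncol(ts$tracks)),
    position = rep(ts$position, nrow(ts$tracks)),
    intensity = as.numeric(t(ts$tracks)),
    channel = ts$channel)
  .write_csv_precise(df, path)
}

#' @rdname profile_io
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(df$track_id)
  pos <- df$position[df$track_id == ids[1]]
  m <- t(vapply(ids, function(i) df$intensity[df$track_id == i],
                numeric(length(pos))))
  track_set(m, position = pos, channel = df$channel[1])
}

#' @rdname profile_io
#' @export
write_profile <- function(p, path) {
  df <- data.frame(position = p$position, intensity = p$intensity)
  if (!is.null(p$sem)) df$sem <- p$sem
  .write_csv_precise(df, path)
}

#' @rdname profile_io
#' @param channel Channel label to attach on read.
#' @export
read_profile <- function(path, channel = "JNK") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  reporter_profile(df$position, df$intensity,
                   sem = if ("sem" %in% names(df)) df$sem,
                   channel = channel)
}
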