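#' Count changed pixels between successive frames of an image stack
#'
#' The optical method detects embolism as abrupt local changes in
#' transmitted light: for each consecutive pair of frames, the number of
#' pixels whose absolute intensity change exceeds `binarize_threshold` is
#' recorded.
#'
#' @param stack 3-d numeric array `(rows, cols, n_frames)` with at least 2
#'   frames, or a list of equally-shaped matrices.
#' @param binarize_threshold minimum absolute intensity change for a pixel
#'   to count as changed.
#' @return A `frame_diff_series` data frame with columns `frame_idx`
#'   (1-based index of the pair: frames `i` and `i + 1`), `time_min`
#'   (`NA` unless supplied later), `changed_pixels` and `kept` (all `TRUE`;
#'   see [filter_events()]).
#' @export
#' @examples
#' ev <- data.frame(frame_idx = c(2, 4), n_pixels = c(5, 3))
#' st <- gen_image_stack(ev, c(8, 8))
#' diff_stack(st)
diff_stack <- function(stack, binarize_threshold = 0.5) {
  if (is.list(stack) && !is.array(stack)) {
    shp <- unique(lapply(stack, dim))
    if (length(shp) != 1L) stop_hs("ragged stack: frames differ in shape")
    stack <- array(unlist(stack), dim = c(shp[[1]], length(stack)))
  }
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stop_hs("`stack` must be a (rows, cols, frames) array")
  n <- dim(stack)[3]
  if (n < 2L) stop_hs("a single frame cannot be differenced")
  check_number(binarize_threshold, "binarize_threshold", lower = 0)
  changed <- vapply(seq_len(n - 1L), function(i) {
    sum(abs(stack[, , i + 1L] - stack[, , i]) > binarize_threshold)
  }, integer(1))
  new_frame_diff_series(data.frame(
    frame_idx = seq_len(n - 1L), time_min = NA_real_,
    changed_pixels = changed, kept = TRUE))
}

new_frame_diff_series <- function(df) {
  check_columns(df, c("frame_idx", "changed_pixels"), "frame diff series")
  if (is.unsorted(df$frame_idx, strictly = TRUE))
    stop_hs("frame_idx must be strictly increasing")
  if (any(df$changed_pixels < 0)) stop_hs("changed_pixels must be >= 0")
  if (is.null(df$time_min)) df$time_min <- NA_real_
  if (is.null(df$kept)) df$kept <- TRUE
  class(df) <- c("frame_diff_series", "data.frame")
  df
}

#' Convert an event table to a frame-diff series
#'
#' Accepts the `(frame_idx, time_min, n_pixels)` event tables produced by
#' [gen_embolism_campaign()] (or read from `events.csv`) as a first-class
#' alternative to differencing an image stack.
#'
#' @param events data frame with columns `frame_idx`, `n_pixels` and
#'   optionally `time_min`.
#' @return A `frame_diff_series` (one row per listed frame; frames without
#'   events are implicit zeros).
#' @export
as_frame_diff_series <- function(events) {
  check_columns(events, c("frame_idx", "n_pixels"), "events")
  df <- data.frame(frame_idx = events$frame_idx,
                   time_min = if ("time_min" %in% names(events))
                     events$time_min else NA_real_,
                   changed_pixels = events$n_pixels, kept = TRUE)
  new_frame_diff_series(df[order(df$frame_idx), , drop = FALSE])
}

#' Filter movement artifacts from a frame-diff series
#'
#' Automated surrogate for the manual artifact screening of the optical
#' method: tiny pixel groups (below `min_size`) are treated as sensor noise
#' and very large ones (above the `max_size_quantile` quantile of nonzero
#' event sizes) as whole-leaf movement; both are flagged `kept = FALSE`.
#' Rows are never removed, so the original series is preserved.
#'
#' @param series a `frame_diff_series`.
#' @param min_size smallest changed-pixel count kept as a real event.
#' @param max_size_quantile quantile of nonzero sizes above which events
#'   are treated as movement artifacts.
#' @return The series with updated `kept` flags.
#' @export
filter_events <- function(series, min_size = 2, max_size_quantile = 0.995) {
  stopifnot(inherits(series, "frame_diff_series"))
  if (!nrow(series)) stop_hs("empty series")
  check_number(min_size, "min_size", lower = 0)
  check_number(max_size_quantile, "max_size_quantile", 0, 1)
  sizes <- series$changed_pixels
  nz <- sizes[sizes > 0]
  if (!length(nz)) stop_hs("no embolism signal: all frames unchanged")
  cap <- quantile(nz, max_size_quantile, names = FALSE, type = 7)
  kept <- sizes > 0 & sizes >= min_size & sizes <= cap
  if (!any(kept))
    stop_hs("no embolism signal: every event was filtered out")
  series$kept <- kept
  series
}

#' Interpolate psychrometer water potential onto image frames
#'
#' The psychrometer logs stem water potential on its own clock (typically
#' every 10 min) while images are captured more often (every 5 min); water
#' potential is linearly interpolated in time onto each frame. Because stem
#' and leaf were verified to equilibrate within 0.1 MPa during bench
#' drying, the stem log is taken as leaf water potential. Frames at most
#' one log interval outside the log are linearly extrapolated and flagged
#' via the `"extrapolated"` attribute.
#'
#' @param series a `frame_diff_series` with finite `time_min`.
#' @param psychrometer data frame `(time_min, psi_mpa)`.
#' @param isotonic if `TRUE`, enforce a monotone non-increasing trace by
#'   running-minimum cleanup (off by default).
#' @return Numeric vector of water potentials, one per series row.
#' @export
align_psi <- function(series, psychrometer, isotonic = FALSE) {
  stopifnot(inherits(series, "frame_diff_series"))
  check_columns(psychrometer, c("time_min", "psi_mpa"), "psychrometer log")
  if (any(!is.finite(series$time_min)))
    stop_hs("series has no usable time_min; supply an event table with ",
            "time stamps")
  log_t <- psychrometer$time_min
  log_p <- psychrometer$psi_mpa
  ord <- order(log_t)
  log_t <- log_t[ord]; log_p <- log_p[ord]
  if (length(log_t) < 2L) stop_hs("psychrometer log needs >= 2 points")
  interval <- max(diff(log_t))
  t <- series$time_min
  if (min(t) > max(log_t) + interval || max(t) < min(log_t) - interval)
    stop_hs("psychrometer log does not overlap the image series in time")
  if (min(t) < min(log_t) - interval || max(t) > max(log_t) + interval)
    stop_hs("frames extend more than one log interval beyond the ",
            "psychrometer record")
  psi <- approx(log_t, log_p, xout = t, rule = 1)$y
  extrap <- is.na(psi)
  if (any(extrap)) {
    # linear extrapolation from the terminal segment, at most one interval
    n <- length(log_t)
    lo <- t < log_t[1]
    sl1 <- (log_p[2] - log_p[1]) / (log_t[2] - log_t[1])
    sln <- (log_p[n] - log_p[n - 1]) / (log_t[n] - log_t[n - 1])
    psi[extrap & lo] <- log_p[1] + sl1 * (t[extrap & lo] - log_t[1])
    psi[extrap & !lo] <- log_p[n] + sln * (t[extrap & !lo] - log_t[n])
  }
  if (isotonic) psi <- cummin(psi)
  attr(psi, "extrapolated") <- which(extrap)
  psi
}

#' Build a cumulative percent-embolism trace
#'
#' Cumulative sum of embolized pixels over kept events, expressed as a
#' percentage of the total embolized pixels of the completely dried sample,
#' paired with the per-frame water potential.
#'
#' @param series a `frame_diff_series` (filtered or not).
#' @param psi numeric vector of water potentials per series row, e.g. from
#'   [align_psi()].
#' @return An `embolism_trace` data frame
#'   `(frame_idx, time_min, psi_mpa, cum_pct)` with attribute `n_events`.
#' @export
#' @examples
#' s <- as_frame_diff_series(
#'   data.frame(frame_idx = 1:3, n_pixels = c(10, 30, 60)))
#' cumulate(s, psi = c(-1, -2, -3))$cum_pct   # 10 40 100
cumulate <- function(series, psi) {
  stopifnot(inherits(series, "frame_diff_series"))
  if (length(psi) != nrow(series))
    stop_hs("psi must have one value per series row")
  px <- ifelse(series$kept, series$changed_pixels, 0L)
  total <- sum(px)
  if (total <= 0) stop_hs("zero total embolized pixels: nothing to cumulate")
  if (sum(series$kept & series$changed_pixels > 0) < 1L)
    stop_hs("no kept events")
  out <- data.frame(frame_idx = series$frame_idx,
                    time_min = series$time_min,
                    psi_mpa = as.numeric(psi),
                    cum_pct = 100 * cumsum(px) / total)
  attr(out, "n_events") <- sum(series$kept & series$changed_pixels > 0)
  attr(out, "total_pixels") <- total
  class(out) <- c("embolism_trace", "data.frame")
  out
}

#' One-call optical-vulnerability quantification
#'
#' Convenience wrapper: event table (or image stack) + psychrometer log to
#' cumulative percent-embolism trace, applying the default artifact filter.
#'
#' @param events event table (`frame_idx, time_min, n_pixels`), or `NULL`
#'   if `stack` is given.
#' @param psychrometer data frame `(time_min, psi_mpa)`.
#' @param stack optional image stack (used when `events` is `NULL`);
#'   `frame_times` must then give the capture time of every frame.
#' @param frame_times capture times (min) of stack frames.
#' @param min_size,max_size_quantile filter settings, see
#'   [filter_events()].
#' @param binarize_threshold see [diff_stack()].
#' @return An `embolism_trace`.
#' @export
ov_quantify <- function(events = NULL, psychrometer, stack = NULL,
                        frame_times = NULL, min_size = 2,
                        max_size_quantile = 0.995,
                        binarize_threshold = 0.5) {
  if (is.null(events)) {
    if (is.null(stack)) stop_hs("supply either `events` or `stack`")
    series <- diff_stack(stack, binarize_threshold)
    if (is.null(frame_times))
      stop_hs("`frame_times` is required with an image stack")
    if (length(frame_times) != dim(stack)[3])
      stop_hs("`frame_times` must have one entry per frame")
    # diff i spans frames i, i+1: stamp with the later frame's time
    series$time_min <- frame_times[series$frame_idx + 1L]
  } else {
    series <- as_frame_diff_series(events)
  }
  series <- filter_events(series, min_size, max_size_quantile)
  psi <- align_psi(series, psychrometer)
  cumulate(series, psi)
}
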