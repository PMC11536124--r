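# Centroid tracking of time-lapse footage: intensity-threshold
# segmentation, intensity-weighted sub-pixel centroids, nearest-neighbour
# frame linking, and the drift statistics that contrast freely drifting
# cells (monotone displacement growth) with droplet-rotated cells (bounded,
# periodic displacement).

#' Track object centroids through a time-lapse stack
#'
#' Segments each frame (Otsu threshold by default), labels connected
#' components, computes intensity-weighted sub-pixel centroids, and links
#' them frame-to-frame by nearest neighbour within `max_step_um`. Only
#' tracks persisting through at least `min_persistence` of the frames are
#' returned. Ambiguous links (two candidates inside the linking radius)
#' split the track rather than guessing.
#'
#' @param stack a [frame_stack()].
#' @param threshold `"otsu"` or a numeric absolute intensity threshold.
#' @param max_step_um maximum centroid displacement between consecutive
#'   frames, um.
#' @param min_persistence minimum fraction of frames a track must span.
#' @param min_area_px minimum object area, pixels.
#' @return list of `centroid_track` data.frames with columns `t` (s),
#'   `x`, `y` (um, absolute frame coordinates) and `rc` (um, displacement
#'   from the track's first position). Frames with no objects simply do not
#'   extend any track; an objectless stack gives an empty list.
#' @export
track_centroids <- function(stack, threshold = "otsu", max_step_um = 5,
                            min_persistence = 0.8, min_area_px = 4L) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  px <- stack$pixel_size
  detections <- vector("list", d[3])
  for (k in seq_len(d[3])) {
    fr <- stack$frames[, , k]
    th <- if (identical(threshold, "otsu")) {
      rng <- range(fr)
      if (diff(rng) == 0) Inf
      else rng[1] + diff(rng) *
        EBImage::otsu(EBImage::Image((fr - rng[1]) / diff(rng)), range = c(0, 1))
    } else threshold
    bw <- fr > th
    if (!any(bw)) { detections[k] <- list(NULL); next }
    lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
    lab <- as.matrix(lab)
    ids <- setdiff(unique(as.vector(lab)), 0)
    cent <- NULL
    for (id in ids) {
      w <- which(lab == id, arr.ind = TRUE)
      if (nrow(w) < min_area_px) next
      wt <- fr[lab == id]
      cent <- rbind(cent, c(x = sum(w[, 2] * wt) / sum(wt) * px,
                            y = sum(w[, 1] * wt) / sum(wt) * px))
    }
    detections[k] <- list(cent)
  }
  # nearest-neighbour linking
  tracks <- list()        # active: list(frames, xs, ys)
  finished <- list()
  active <- list()
  for (k in seq_len(d[3])) {
    det <- detections[[k]]
    ndet <- if (is.null(det)) 0 else nrow(det)
    taken <- rep(FALSE, max(ndet, 0))
    nxt <- list()
    for (tr in active) {
      lx <- tr$x[length(tr$x)]; ly <- tr$y[length(tr$y)]
      if (ndet > 0) {
        dist <- sqrt((det[, 1] - lx)^2 + (det[, 2] - ly)^2)
        cand <- which(dist <= max_step_um & !taken)
        if (length(cand) == 1) {
          i <- cand
          taken[i] <- TRUE
          tr$frames <- c(tr$frames, k); tr$x <- c(tr$x, det[i, 1])
          tr$y <- c(tr$y, det[i, 2])
          nxt[[length(nxt) + 1]] <- tr
          next
        }
        # 0 candidates: track ends; >= 2: ambiguous, split (end here)
      }
      finished[[length(finished) + 1]] <- tr
    }
    if (ndet > 0) for (i in which(!taken))
      nxt[[length(nxt) + 1]] <- list(frames = k, x = det[i, 1], y = det[i, 2])
    active <- nxt
  }
  finished <- c(finished, active)
  out <- list()
  for (tr in finished) {
    if (length(tr$frames) < min_persistence * d[3]) next
    df <- data.frame(t = (tr$frames - 1) / stack$fps, x = tr$x, y = tr$y)
    df$rc <- sqrt((df$x - df$x[1])^2 + (df$y - df$y[1])^2)
    class(df) <- c("centroid_track", "data.frame")
    out[[length(out) + 1]] <- df
  }
  out
}

#' Drift statistics of a set of centroid tracks
#'
#' Mean and SD of the displacement rc at a time horizon, plus two
#' behavioural flags: `monotone` (Spearman correlation of time vs the mean
#' rc curve exceeds 0.9 -- the signature of substrate-free drifting cells)
#' and `periodic` (the rc autocorrelation has a dominant peak with
#' prominence above 3 baseline SDs -- the signature of cells orbiting a
#' rotation axis). The amplitude (max rc) is reported alongside the
#' time-averaged rc since either may be the quantity of interest for
#' bounded motion.
#'
#' @param tracks list of tracks from [track_centroids()] (or data.frames
#'   with `t` and `rc`).
#' @param horizon time horizon, s; every used track must reach it.
#' @return list with `mean_rc`, `sd_rc` (displacement at horizon),
#'   `mean_rc_timeavg`, `max_rc`, `monotone`, `periodic`.
#' @export
drift_statistics <- function(tracks, horizon) {
  if (!length(tracks)) .dt_stop("drift_statistics: no tracks supplied")
  reach <- Filter(function(tr) max(tr$t) >= horizon, tracks)
  if (!length(reach))
    .dt_stop("drift_statistics: no track reaches the %.3g s horizon", horizon)
  at_h <- vapply(reach, function(tr) {
    stats::approx(tr$t, tr$rc, xout = horizon, rule = 2)$y
  }, numeric(1))
  tt <- reach[[1]]$t[reach[[1]]$t <= horizon]
  mean_curve <- rowMeans(vapply(reach, function(tr)
    stats::approx(tr$t, tr$rc, xout = tt, rule = 2)$y,
    numeric(length(tt))))
  rho <- suppressWarnings(stats::cor(tt, mean_curve, method = "spearman"))
  monotone <- is.finite(rho) && rho > 0.9
  # periodicity from the longest track's rc series: linear detrend (so a
  # monotone ramp does not register), unbiased autocorrelation, and a
  # dominant peak criterion
  longest <- reach[[which.max(vapply(reach, nrow, numeric(1)))]]
  periodic <- FALSE
  x <- stats::residuals(stats::lm(longest$rc ~ longest$t))
  n <- length(x)
  if (n >= 16 && var(x) > 1e-24) {
    L <- 2^ceiling(log2(2 * n))
    fx <- fft(c(x, numeric(L - n)))
    ac <- Re(fft(fx * Conj(fx), inverse = TRUE))[seq_len(floor(0.75 * n))]
    ac <- (ac / (n - (seq_along(ac) - 1))) / (ac[1] / n)
    lo <- max(3L, ceiling(n / 10))
    seg <- ac[lo:length(ac)]
    # dominant peak: above an absolute correlation threshold and well clear
    # of the ~1/sqrt(n) noise floor of a non-periodic series
    periodic <- max(seg) > 0.5 && max(seg) > 4 / sqrt(n)
  }
  list(mean_rc = mean(at_h), sd_rc = if (length(at_h) > 1) sd(at_h) else 0,
       mean_rc_timeavg = mean(mean_curve), max_rc = max(mean_curve),
       monotone = monotone, periodic = periodic)
}
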