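#' Reference-corrected z-scoring of a photometry signal
#'
#' The motion/bleaching reference channel is fit to the signal by ordinary
#' least squares (slope and intercept) and the fitted reference is
#' subtracted; the corrected trace is then z-scored over the session. The
#' least-squares fit (rather than plain subtraction) makes the correction
#' robust to gain differences between channels. When no reference is
#' supplied, only z-scoring is applied. A constant corrected trace (SD 0)
#' yields z = 0 everywhere rather than dividing by zero.
#'
#' @param signal raw signal channel.
#' @param reference raw reference channel, or `NULL`.
#' @param t optional time stamps (checked for uniform sampling).
#' @return z-scored corrected signal (mean 0, SD 1 unless degenerate).
#' @export
preprocess_photometry <- function(signal, reference = NULL, t = NULL) {
  if (!is.null(t)) {
    if (length(t) != length(signal)) stop("t and signal lengths differ")
    check_uniform(t)
  }
  if (!is.null(reference)) {
    if (length(reference) != length(signal)) {
      stop("signal and reference lengths differ")
    }
    if (stats::sd(reference) == 0) {
      corrected <- signal - mean(reference)
    } else {
      fit <- stats::lm(signal ~ reference)
      corrected <- signal - stats::fitted(fit)
    }
  } else {
    corrected <- signal
  }
  s <- stats::sd(corrected)
  if (s < 1e-12) return(rep(0, length(signal)))
  (corrected - mean(corrected)) / s
}

check_uniform <- function(t, tol = 1e-6) {
  dts <- diff(t)
  if (length(dts) && (max(dts) - min(dts)) > tol * stats::median(dts)) {
    stop("time stamps must be uniformly sampled")
  }
  invisible(stats::median(dts))
}

#' Photometry recording container
#'
#' Bundles a uniformly sampled session: time, optional raw channels, the
#' z-scored corrected signal (computed via [preprocess_photometry()] when not
#' supplied), and an optional locomotion-speed channel on the same grid.
#'
#' @param t time stamps, seconds, uniform.
#' @param signal,reference raw channels (optional if `z` given).
#' @param z pre-computed z-scored signal (optional).
#' @param speed optional speed channel, cm/s.
#' @return An object of class `photometry_recording`.
#' @export
photometry_recording <- function(t, signal = NULL, reference = NULL,
                                 z = NULL, speed = NULL) {
  dt <- check_uniform(t)
  lens <- vapply(Filter(Negate(is.null), list(signal, reference, z, speed)),
                 length, integer(1))
  if (any(lens != length(t))) stop("all channels must have the length of t")
  if (is.null(z)) {
    if (is.null(signal)) stop("either z or signal must be supplied")
    z <- preprocess_photometry(signal, reference, t)
  }
  structure(list(t = t, dt = dt, signal = signal, reference = reference,
                 z = z, speed = speed),
            class = "photometry_recording")
}

#' @export
print.photometry_recording <- function(x, ...) {
  cat(sprintf("Photometry recording: %.0f s at %.1f Hz%s%s\n",
              max(x$t) - min(x$t), 1 / x$dt,
              if (is.null(x$reference)) "" else ", reference-corrected",
              if (is.null(x$speed)) "" else ", with speed channel"))
  invisible(x)
}

#' Read a photometry export (tabular text)
#'
#' Expects a header with a `t` column plus either `z` or `signal`
#' (optionally `reference`), and optionally `speed`.
#'
#' @param path file path (comma- or tab-delimited; sniffed).
#' @return A [photometry_recording()].
#' @export
read_photometry <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep)
  if (!"t" %in% names(d)) stop("photometry file must have a 't' column")
  photometry_recording(t = d$t, signal = d$signal, reference = d$reference,
                       z = d$z, speed = d$speed)
}

#' Peri-event extraction and two-level average
#'
#' Extracts z-signal windows around event onsets onto a common lag grid
#' (lag 0 at onset). Events whose window is not fully inside the recording
#' are dropped (their count is reported). Overlapping windows are all kept.
#' The mean trace is computed per subject first and then across subjects,
#' matching the usual presentation of photometry averages; without subject
#' ids the mean is across events.
#'
#' @param rec a [photometry_recording()].
#' @param event_times event onsets, seconds.
#' @param pre,post window extents before and after the event, seconds.
#' @param subjects optional subject id per event for two-level averaging.
#' @return List with `matrix` (events x lags), `lag`, `mean`, `sem`,
#'   `n_used`, `n_dropped`, and `subjects` (ids of retained events).
#' @export
align_events <- function(rec, event_times, pre = 10, post = 20,
                         subjects = NULL) {
  stopifnot(inherits(rec, "photometry_recording"))
  dt <- rec$dt
  lag <- seq(-round(pre / dt), round(post / dt)) * dt
  k0 <- round((event_times - rec$t[1]) / dt) + 1L
  lo <- k0 - round(pre / dt); hi <- k0 + round(post / dt)
  ok <- lo >= 1 & hi <= length(rec$z)
  if (!any(ok)) stop("no event has a complete window inside the recording")
  rows <- t(vapply(which(ok), function(j) rec$z[lo[j]:hi[j]],
                   numeric(length(lag))))
  subj <- if (is.null(subjects)) NULL else subjects[ok]
  if (!is.null(subj) && length(unique(subj)) > 1) {
    per_sub <- do.call(rbind, lapply(split(seq_len(nrow(rows)), subj),
                                     function(ix) colMeans(rows[ix, , drop = FALSE])))
    m <- colMeans(per_sub)
    sem <- apply(per_sub, 2, stats::sd) / sqrt(nrow(per_sub))
  } else {
    m <- colMeans(rows)
    sem <- apply(rows, 2, stats::sd) / sqrt(nrow(rows))
  }
  list(matrix = rows, lag = lag, mean = m, sem = sem,
       n_used = sum(ok), n_dropped = sum(!ok), subjects = subj)
}

#' Baseline-corrected AUC response to an event
#'
#' AUC = mean z over `[start, start + min(cap, duration))` minus the mean z
#' over the `[start - baseline, start)` baseline window. The post window is
#' capped at `cap` seconds (default 20) or the behavior's duration, whichever
#' is shorter. Invariant to adding a constant to the whole trace. Vectorized
#' over events.
#'
#' @param rec a [photometry_recording()].
#' @param start event onset(s), seconds.
#' @param duration behavior duration(s), seconds.
#' @param baseline baseline window length before the event, seconds.
#' @param cap maximum post-event window, seconds.
#' @return AUC value(s).
#' @export
auc_response <- function(rec, start, duration, baseline = 10, cap = 20) {
  stopifnot(inherits(rec, "photometry_recording"))
  dt <- rec$dt
  mapply(function(st, du) {
    k0 <- round((st - rec$t[1]) / dt) + 1L
    nb <- round(baseline / dt)
    np <- round(min(cap, du) / dt)
    if (k0 - nb < 1) stop("insufficient pre-event data for the baseline window")
    if (np < 1) stop("post-event window is empty")
    post <- rec$z[k0:min(k0 + np - 1L, length(rec$z))]
    base <- rec$z[(k0 - nb):(k0 - 1L)]
    mean(post) - mean(base)
  }, start, duration)
}

#' Regression of the photometry signal on feeding and speed
#'
#' Ordinary least squares of z on a feeding indicator and (optionally) a
#' speed series. Reports each coefficient with its absolute value, the total
#' R-squared, and each predictor's uniquely explained variance as the
#' semi-partial R-squared (drop in R-squared when that predictor is removed);
#' variance shared between correlated predictors is reported separately as
#' `shared_R2 = total - sum(unique)`.
#'
#' @param z z-scored signal.
#' @param feeding feeding indicator series (0/1 or logical), same grid.
#' @param speed optional speed series.
#' @param collinearity_tol warn when |cor(feeding, speed)| exceeds this.
#' @return List with `coefficients` (data frame: predictor, estimate,
#'   abs_estimate, unique_R2), `total_R2`, `shared_R2`, `model`.
#' @export
regress_signal <- function(z, feeding, speed = NULL,
                           collinearity_tol = 0.99) {
  feeding <- as.numeric(feeding)
  if (length(feeding) != length(z)) stop("series lengths differ")
  d <- data.frame(z = z, feeding = feeding)
  preds <- "feeding"
  if (!is.null(speed)) {
    if (length(speed) != length(z)) stop("series lengths differ")
    d$speed <- speed
    preds <- c(preds, "speed")
    if (abs(stats::cor(feeding, speed)) > collinearity_tol) {
      warning("feeding and speed are nearly collinear; unique R2 is unstable ",
              "and most explained variance will appear as shared")
    }
  }
  full <- stats::lm(stats::reformulate(preds, "z"), data = d)
  R2 <- summary(full)$r.squared
  unique_R2 <- vapply(preds, function(p) {
    others <- setdiff(preds, p)
    reduced <- if (length(others)) {
      stats::lm(stats::reformulate(others, "z"), data = d)
    } else {
      stats::lm(z ~ 1, data = d)
    }
    R2 - summary(reduced)$r.squared
  }, numeric(1))
  est <- stats::coef(full)[preds]
  list(coefficients = data.frame(predictor = preds,
                                 estimate = unname(est),
                                 abs_estimate = unname(abs(est)),
                                 unique_R2 = unname(unique_R2)),
       total_R2 = R2,
       shared_R2 = R2 - sum(unique_R2),
       model = full)
}
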