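#' Specification of a synthetic fasted-refeeding session
#'
#' Describes how to generate behavior annotations and photometry-like traces
#' with the statistical structure the analysis pipeline assumes: feeding
#' bouts with lognormally distributed inter-interruption intervals, brief
#' (< 4 s) intra-bout pauses, inter-bout gaps of at least 4 s, a calcium-like
#' z trace that is low during bouts, shows transient rises at interruptions
#' and a sustained rise back to baseline at terminations, and a locomotion
#' speed channel anticorrelated with feeding.
#'
#' Bouts can be drawn either from the parametric laws below (`source =
#' "parametric"`, analytics testable independently of the dynamical model) or
#' from the stochastic attractor model (`source = "simulator"`).
#'
#' @param n_subjects number of subjects (defaults mirror typical cohort
#'   sizes of 5-10 animals).
#' @param session_length seconds of recording (default one 20-minute
#'   refeeding session).
#' @param condition condition label stamped on the output.
#' @param source `"parametric"` or `"simulator"`.
#' @param bout_log_mean,bout_log_sd lognormal law of the target bout
#'   duration, log-seconds.
#' @param interbout_rate rate (1/s) of the exponential part of inter-bout
#'   gaps; every gap additionally has a `gap_min` floor so it always reads as
#'   a termination.
#' @param gap_min minimum inter-bout gap, seconds.
#' @param renewal a [renewal_params()] law for intra-bout interruption
#'   intervals.
#' @param int_gap_min,int_gap_max uniform law of interruption pause
#'   durations, seconds; must stay below the 4 s segmentation threshold.
#' @param food_intro food-introduction timestamp, seconds into the session.
#' @param subject_sd SD of a per-subject random shift applied to
#'   `bout_log_mean` (between-animal variability).
#' @param model,reentry_rate simulator-source knobs: a [model_params()] set
#'   and the forced re-entry rate handed to [simulate_wc()].
#' @param fs photometry sampling rate, Hz (>= 5).
#' @param dip_amp depth of the in-bout drop of the z trace, z units.
#' @param dip_tau,rise_tau time constants (s) of the exponential onset of the
#'   in-bout dip and of the sustained rise after termination.
#' @param trans_amp,trans_width amplitude (z) and Gaussian SD (s) of the
#'   transient at each interruption.
#' @param noise_sd white-noise SD added to the trace, z units.
#' @param speed_out,speed_in mean locomotion speed outside / inside bouts,
#'   cm/s.
#' @param speed_sd,speed_tau speed noise SD (cm/s) and smoothing time
#'   constant (s).
#' @param seed base RNG seed.
#' @return An object of class `synth_session_spec`.
#' @export
synth_session_spec <- function(n_subjects = 6, session_length = 1200,
                               condition = "ctrl",
                               source = c("parametric", "simulator"),
                               bout_log_mean = log(25), bout_log_sd = 0.7,
                               interbout_rate = 1 / 26, gap_min = 4,
                               renewal = renewal_params(),
                               int_gap_min = 0.5, int_gap_max = 3.5,
                               food_intro = 60, subject_sd = 0.15,
                               model = model_params(), reentry_rate = 0.05,
                               fs = 20, dip_amp = 1, dip_tau = 1,
                               rise_tau = 1, trans_amp = 0.8,
                               trans_width = 0.5, noise_sd = 0.3,
                               speed_out = 6, speed_in = 1,
                               speed_sd = 1, speed_tau = 2,
                               seed = 1) {
  source <- match.arg(source)
  if (fs < 5) stop("sampling rate must be at least 5 Hz")
  if (int_gap_max >= 4) stop("interruption pauses must stay below the 4 s threshold")
  if (int_gap_min <= 0 || int_gap_min > int_gap_max) stop("invalid interruption pause range")
  amps <- c(dip_amp, trans_amp, noise_sd, speed_out, speed_in, speed_sd)
  if (!all(is.finite(amps))) stop("all amplitudes must be finite")
  spec <- as.list(environment())
  structure(spec, class = "synth_session_spec")
}

#' Generate behavior annotations for a synthetic cohort
#'
#' Parametric source: each subject's session alternates inter-bout gaps
#' (`gap_min` + exponential) and bouts. A bout is assembled from feeding
#' segments whose durations are full draws of the renewal interval law,
#' accumulated until the subject's target bout duration (lognormal) is
#' reached, separated by uniform sub-4 s interruption pauses; every segment
#' is a complete renewal draw so refitting the interval law is unbiased.
#' Simulator source: each subject is one stochastic model session whose
#' below-threshold stretches become feeding intervals (crossings shorter
#' than 0.3 s are smoothed out, emulating annotator time resolution).
#'
#' @param spec a [synth_session_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return Annotation data frame (`subject`, `condition`, `label`, `start`,
#'   `stop`, `food_intro`) ready for [segment_bouts()], with attribute
#'   `n_bouts` recording the number of bouts generated.
#' @export
make_annotations <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synth_session_spec"))
  rows <- list(); n_bouts <- 0L
  for (j in seq_len(spec$n_subjects)) {
    subj <- sprintf("sub%02d", j)
    if (spec$source == "parametric") {
      set.seed(seed + j)
      shift <- stats::rnorm(1, 0, spec$subject_sd)
      tcur <- spec$food_intro + stats::rexp(1, spec$interbout_rate)
      iv <- list()
      while (tcur < spec$session_length) {
        target <- stats::rlnorm(1, spec$bout_log_mean + shift, spec$bout_log_sd)
        acc <- 0; first <- TRUE
        while ((acc < target || first) && tcur < spec$session_length) {
          seg <- exp(stats::rnorm(1, spec$renewal$log_mean, spec$renewal$log_sd)) /
            spec$renewal$rate_scale
          stop_t <- min(tcur + seg, spec$session_length)
          if (stop_t - tcur >= 0.5) {
            iv[[length(iv) + 1L]] <- c(tcur, stop_t)
            if (first) n_bouts <- n_bouts + 1L
          } else if (first) break
          first <- FALSE
          acc <- acc + seg
          tcur <- stop_t
          if (acc < target && tcur < spec$session_length) {
            pause <- stats::runif(1, spec$int_gap_min, spec$int_gap_max)
            tcur <- tcur + pause
          }
        }
        tcur <- tcur + spec$gap_min + stats::rexp(1, spec$interbout_rate)
      }
      if (length(iv)) {
        m <- do.call(rbind, iv)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj, condition = spec$condition, label = "feeding",
          start = m[, 1], stop = m[, 2], food_intro = spec$food_intro)
      }
    } else {
      traj <- simulate_wc(spec$model, spec$renewal,
                          duration = spec$session_length - spec$food_intro,
                          seed = seed + j, reentry_rate = spec$reentry_rate)
      iv <- trajectory_intervals(traj)
      n_bouts <- n_bouts + attr(iv, "n_bouts")
      if (nrow(iv)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj, condition = spec$condition, label = "feeding",
          start = iv$start + spec$food_intro, stop = iv$stop + spec$food_intro,
          food_intro = spec$food_intro)
      }
    }
  }
  ann <- do.call(rbind, rows)
  rownames(ann) <- NULL
  attr(ann, "n_bouts") <- n_bouts
  ann
}

# Debounced feeding intervals from a simulated trajectory: below-threshold
# stretches, with crossings shorter than `resolution` absorbed (an annotator
# cannot time-stamp sub-300-ms blips).
trajectory_intervals <- function(traj, resolution = 0.3) {
  dt <- traj$params$dt
  feed <- traj$E < traj$E_th
  r <- rle(feed)
  r$values[!r$values & r$lengths * dt < resolution] <- TRUE
  r <- rle(inverse.rle(r))
  r$values[r$values & r$lengths * dt < resolution] <- FALSE
  r <- rle(inverse.rle(r))
  ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1L) + 1L)
  iv <- data.frame(start = traj$t[starts[r$values]], stop = traj$t[ends[r$values]])
  gaps <- if (nrow(iv) > 1) iv$start[-1] - iv$stop[-nrow(iv)] else numeric(0)
  attr(iv, "n_bouts") <- if (nrow(iv)) 1L + sum(gaps >= 4) else 0L
  iv
}

#' Generate a photometry-like recording locked to annotations
#'
#' Builds the calcium-like trace of a single subject-session: baseline 0,
#' an additive dip of `-dip_amp` during bouts with exponential onset
#' (`dip_tau`) and a sustained exponential return to baseline after
#' termination (`rise_tau`), Gaussian-bump transients at interruption times,
#' plus white noise. Raw channels are synthesized around the trace (a shared
#' slow artifact in signal and reference) so the reference-correction path is
#' exercised; the anticorrelated speed channel relaxes between its
#' out-of-bout and in-bout means. The noiseless kernel is kept in the
#' `truth` field for validation.
#'
#' @param ann annotation rows of one subject-session (one subject only).
#' @param spec a [synth_session_spec()].
#' @param seed RNG seed.
#' @return A [photometry_recording()] with extra fields `truth`, `feeding`
#'   (feeding-interval indicator on the sample grid) and `bout` (in-bout
#'   indicator, including intra-bout pauses; the natural regressor for
#'   bout-locked activity).
#' @export
make_photometry <- function(ann, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synth_session_spec"))
  if (length(unique(ann$subject)) != 1) {
    stop("make_photometry expects the annotations of a single subject")
  }
  set.seed(seed)
  dt <- 1 / spec$fs
  t <- seq(0, spec$session_length, by = dt)
  fi <- ann[ann$label == "feeding", , drop = FALSE]
  fi <- fi[order(fi$start), , drop = FALSE]
  feeding <- rep(0, length(t))
  for (r in seq_len(nrow(fi))) {
    feeding[t >= fi$start[r] & t < fi$stop[r]] <- 1
  }
  # bout indicator: feeding plus intra-bout pauses (< 4 s gaps)
  bt <- segment_bouts(fi, gap_threshold = 4)
  inbout <- rep(0, length(t))
  for (r in seq_len(nrow(bt$bouts))) {
    inbout[t >= bt$bouts$start[r] & t < bt$bouts$end[r]] <- 1
  }
  # first-order relaxation toward the in-bout dip, asymmetric time constants
  dip <- numeric(length(t))
  for (k in 2:length(t)) {
    target <- -spec$dip_amp * inbout[k]
    tau <- if (target < dip[k - 1]) spec$dip_tau else spec$rise_tau
    dip[k] <- dip[k - 1] + (target - dip[k - 1]) * dt / tau
  }
  truth <- dip
  int_times <- bt$events$time[bt$events$kind == "interruption"]
  for (tm in int_times) {
    truth <- truth + spec$trans_amp *
      exp(-(t - tm)^2 / (2 * spec$trans_width^2))
  }
  trace <- truth + stats::rnorm(length(t), 0, spec$noise_sd)
  # raw channels share a slow artifact; correction must remove it
  artifact <- 3 * sin(2 * pi * t / 300) + 0.001 * t
  signal <- 100 + 10 * trace + artifact
  reference <- 50 + artifact
  speed_target <- spec$speed_out + (spec$speed_in - spec$speed_out) * inbout
  speed <- numeric(length(t)); speed[1] <- speed_target[1]
  for (k in 2:length(t)) {
    speed[k] <- speed[k - 1] +
      (speed_target[k] - speed[k - 1]) * dt / spec$speed_tau
  }
  speed <- pmax(0, speed + stats::rnorm(length(t), 0, spec$speed_sd))
  rec <- photometry_recording(t, signal = signal, reference = reference,
                              speed = speed)
  rec$truth <- truth
  rec$feeding <- feeding
  rec$bout <- inbout # in-bout indicator: feeding plus intra-bout pauses
  rec
}

#' Write a synthetic multi-condition cohort to disk
#'
#' Generates annotations and photometry for each condition and subject and
#' writes them as comma-delimited text under `dir/<condition>/`, plus a
#' plain-text manifest of specs and seeds. Output is byte-identical for a
#' given seed.
#'
#' @param spec base [synth_session_spec()].
#' @param conditions named list; each element is a list of spec fields to
#'   override for that condition (empty list for "as the base spec").
#' @param dir output directory; must not already contain files.
#' @param seed base seed; condition `c`, subject `j` uses
#'   `seed + 1000 * c + j`.
#' @return The directory, invisibly.
#' @export
make_cohort <- function(spec, conditions, dir, seed = spec$seed) {
  stopifnot(inherits(spec, "synth_session_spec"))
  if (length(conditions) == 0) stop("need at least one condition")
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    stop("conditions must be a named list")
  }
  if (dir.exists(dir) && length(list.files(dir, recursive = TRUE))) {
    stop("output directory exists and is not empty: ", dir)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c("# synthetic cohort manifest")
  for (ci in seq_along(conditions)) {
    cname <- names(conditions)[ci]
    cspec <- utils::modifyList(unclass(spec), conditions[[ci]])
    cspec$condition <- cname
    cspec <- do.call(synth_session_spec,
                     cspec[names(cspec) %in% names(formals(synth_session_spec))])
    cdir <- file.path(dir, cname)
    dir.create(cdir, showWarnings = FALSE)
    for (j in seq_len(cspec$n_subjects)) {
      sj_seed <- seed + 1000 * ci + j
      one <- cspec; one$n_subjects <- 1
      one <- do.call(synth_session_spec,
                     one[names(one) %in% names(formals(synth_session_spec))])
      ann <- make_annotations(one, seed = sj_seed - 1) # inner loop adds +1
      ann$subject <- sprintf("sub%02d", j)
      rec <- make_photometry(ann, one, seed = sj_seed + 500000)
      write_annotations(ann, file.path(cdir, sprintf("sub%02d_annotations.csv", j)))
      utils::write.table(
        data.frame(t = rec$t, signal = rec$signal, reference = rec$reference,
                   speed = rec$speed),
        file.path(cdir, sprintf("sub%02d_photometry.csv", j)),
        sep = ",", row.names = FALSE, quote = FALSE)
      manifest <- c(manifest,
                    sprintf("condition=%s subject=sub%02d seed=%d", cname, j, sj_seed))
    }
    manifest <- c(manifest, sprintf(
      "spec condition=%s bout_log_mean=%.6g bout_log_sd=%.6g renewal=(%.6g,%.6g) source=%s",
      cname, cspec$bout_log_mean, cspec$bout_log_sd,
      cspec$renewal$log_mean, cspec$renewal$log_sd, cspec$source))
  }
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
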