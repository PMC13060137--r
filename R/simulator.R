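#' Renewal-process parameters for interruption pulses
#'
#' Intra-bout interruptions are modeled as a renewal process: while the system
#' sits in the feeding attractor, waiting times to the next pulse are i.i.d.
#' lognormal, \eqn{\log(interval/s) \sim N(log\_mean, log\_sd^2)}, and each
#' pulse kicks the excitatory population by \eqn{\Delta \sim
#' N(pulse\_mean, pulse\_sd^2)} (applied as drawn; negative draws are rare and
#' not truncated). `rate_scale` divides every sampled interval, so values > 1
#' raise the interruption rate without touching the attractor landscape —
#' the manipulation used to emulate a threat-cue (looming) condition.
#'
#' @param log_mean,log_sd mean and SD of log(interval/s); `log_sd > 0`.
#' @param pulse_mean,pulse_sd mean and SD of the pulse amplitude.
#' @param rate_scale multiplicative factor dividing sampled intervals.
#' @return An object of class `renewal_params`.
#' @export
renewal_params <- function(log_mean = 2.22, log_sd = 0.99,
                           pulse_mean = 0.56, pulse_sd = 0.11,
                           rate_scale = 1) {
  if (log_sd <= 0) stop("log_sd must be > 0")
  if (pulse_sd < 0) stop("pulse_sd must be >= 0")
  if (rate_scale <= 0) stop("rate_scale must be > 0")
  structure(list(log_mean = log_mean, log_sd = log_sd,
                 pulse_mean = pulse_mean, pulse_sd = pulse_sd,
                 rate_scale = rate_scale),
            class = "renewal_params")
}

#' Sample renewal intervals
#'
#' Draws i.i.d. lognormal waiting times \eqn{\exp(N(log\_mean, log\_sd^2)) /
#' rate\_scale}. With a fixed seed, changing only `rate_scale` rescales the
#' identical draws.
#'
#' @param rp a [renewal_params()] object.
#' @param n number of intervals (>= 1).
#' @param seed optional RNG seed for reproducibility.
#' @return Vector of `n` positive intervals, seconds.
#' @export
sample_renewal_intervals <- function(rp, n, seed = NULL) {
  stopifnot(inherits(rp, "renewal_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  exp(stats::rnorm(n, rp$log_mean, rp$log_sd)) / rp$rate_scale
}

#' Sample pulse amplitudes
#'
#' @inheritParams sample_renewal_intervals
#' @return Vector of `n` pulse amplitudes.
#' @export
sample_pulse_amplitudes <- function(rp, n, seed = NULL) {
  stopifnot(inherits(rp, "renewal_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(n, rp$pulse_mean, rp$pulse_sd)
}

#' Stochastic simulation of the bistable feeding model
#'
#' Euler-Maruyama integration of the Wilson-Cowan pair with additive Gaussian
#' noise: per step, `state += drift * dt + noise_sd * sqrt(dt) * xi` with
#' independent standard-normal `xi` for E and I. While the system is in the
#' feeding state (E below the landscape threshold), a renewal clock accrues;
#' when it reaches the next sampled interval, E jumps instantaneously by a
#' sampled pulse amplitude and the event is logged. The clock pauses while E
#' is above threshold and restarts (fresh interval draw) at each feeding
#' entry, i.e. after an above-threshold excursion at least `commit_time` long.
#'
#' Re-entry into feeding after a termination is noise-driven by default,
#' which is slow at realistic noise levels. For generating bout rasters of
#' realistic density, an optional forced re-entry resets the state to the
#' feeding fixed point after an exponential non-feeding dwell
#' (`reentry_rate`, events/s, measured after the excursion commits); this
#' extension is off by default (`reentry_rate = NULL`).
#'
#' A guard aborts if |E| or |I| leaves [-0.5, 1.5], which indicates a mis-set
#' noise amplitude. States are never clipped.
#'
#' @param params a [model_params()] object; must define a bistable landscape.
#' @param rp a [renewal_params()] object, or `NULL` to disable pulses.
#' @param duration session length, seconds; at least `10 * tau_E`.
#' @param seed RNG seed (the whole trajectory is deterministic given it).
#' @param init optional `c(E, I)` initial state; defaults to the feeding
#'   fixed point.
#' @param landscape optional precomputed [compute_potential()] result for
#'   `params` (computed if missing).
#' @param commit_time seconds an excursion above threshold must last to count
#'   as a bout termination; mirrors the behavioral interruption rule.
#' @param reentry_rate optional rate (1/s) of forced re-entry into feeding.
#' @return An object of class `wc_trajectory`: list with `t`, `E`, `I`,
#'   `state` (feeding/non-feeding labels), `pulses` (data frame `time`,
#'   `amplitude`), `reentries` (times), `seed`, `params`, `rp`, `E_th`,
#'   `commit_time`.
#' @examples
#' tr <- simulate_wc(model_params(), renewal_params(), duration = 60, seed = 1)
#' nrow(tr$pulses)
#' @export
simulate_wc <- function(params = model_params(), rp = renewal_params(),
                        duration, seed = NULL, init = NULL, landscape = NULL,
                        commit_time = 4, reentry_rate = NULL) {
  validate_model_params(params)
  if (duration < 10 * params$tau_E) {
    stop("duration must be at least 10 * tau_E")
  }
  if (is.null(landscape)) landscape <- compute_potential(params)
  if (!landscape$bistable) {
    stop("simulation requires a bistable landscape; got a monostable one")
  }
  if (!is.null(seed)) set.seed(seed)
  dt <- params$dt
  n <- round(duration / dt)
  E_th <- landscape$E_th
  E_feed <- landscape$fixed_points$E[1]
  I_feed <- solve_I_steady(E_feed, params)
  if (is.null(init)) init <- c(E_feed, I_feed)

  # pre-drawn diffusion increments; event randoms are drawn lazily from the
  # same stream, so the trajectory is fully determined by the seed
  sig <- params$noise_sd * sqrt(dt)
  nzE <- if (sig > 0) stats::rnorm(n, sd = sig) else numeric(n)
  nzI <- if (sig > 0) stats::rnorm(n, sd = sig) else numeric(n)

  a <- params$a; th <- params$theta
  wEE <- params$w_EE; wEI <- params$w_EI; wIE <- params$w_IE; wII <- params$w_II
  tauE <- params$tau_E; tauI <- params$tau_I; cur <- params$current

  do_pulses <- !is.null(rp)
  draw_interval <- function() exp(stats::rnorm(1, rp$log_mean, rp$log_sd)) / rp$rate_scale
  E <- numeric(n + 1); I <- numeric(n + 1)
  e <- init[1]; i <- init[2]
  E[1] <- e; I[1] <- i
  pulse_t <- numeric(0); pulse_amp <- numeric(0)
  reentry_t <- numeric(0)
  clock <- 0
  nxt <- if (do_pulses) draw_interval() else Inf
  above_t <- 0
  reentry_at <- Inf
  for (k in 1:n) {
    sE <- 1 / (1 + exp(-a * (wEE * e - wIE * i + cur - th)))
    sI <- 1 / (1 + exp(-a * (wEI * e - wII * i - th)))
    e <- e + (-e + sE) / tauE * dt + nzE[k]
    i <- i + (-i + sI) / tauI * dt + nzI[k]
    if (e < E_th) {
      if (above_t >= commit_time) { # feeding (re-)entry: restart the clock
        clock <- 0
        if (do_pulses) nxt <- draw_interval()
      }
      above_t <- 0
      reentry_at <- Inf
      clock <- clock + dt
      if (clock >= nxt) {
        amp <- stats::rnorm(1, rp$pulse_mean, rp$pulse_sd)
        e <- e + amp
        pulse_t <- c(pulse_t, k * dt)
        pulse_amp <- c(pulse_amp, amp)
        clock <- 0
        nxt <- draw_interval()
      }
    } else {
      above_t <- above_t + dt
      if (!is.null(reentry_rate) && above_t >= commit_time &&
          !is.finite(reentry_at)) {
        reentry_at <- k * dt + stats::rexp(1, reentry_rate)
      }
      if (k * dt >= reentry_at) {
        e <- E_feed; i <- I_feed
        reentry_t <- c(reentry_t, k * dt)
        above_t <- 0; reentry_at <- Inf
        clock <- 0
        if (do_pulses) nxt <- draw_interval()
      }
    }
    if (abs(e - 0.5) > 1 || abs(i - 0.5) > 1) {
      stop("state left [-0.5, 1.5]; noise amplitude appears mis-set")
    }
    E[k + 1] <- e; I[k + 1] <- i
  }
  traj <- structure(
    list(t = (0:n) * dt, E = E, I = I, state = NULL,
         pulses = data.frame(time = pulse_t, amplitude = pulse_amp),
         reentries = reentry_t, seed = seed, params = params, rp = rp,
         E_th = E_th, commit_time = commit_time),
    class = "wc_trajectory")
  traj$state <- label_states(traj, landscape, commit_time)
  traj
}

#' @export
print.wc_trajectory <- function(x, ...) {
  cat(sprintf("Wilson-Cowan trajectory: %.0f s at dt = %g s, %d pulses, seed %s\n",
              max(x$t), x$params$dt, nrow(x$pulses),
              if (is.null(x$seed)) "unset" else x$seed))
  cat(sprintf("  feeding occupancy: %.1f%%\n",
              100 * mean(x$state == "feeding")))
  invisible(x)
}

#' Label samples as feeding or non-feeding with hysteresis
#'
#' Low E is the feeding state. To mirror the behavioral bout rule, an
#' excursion above the threshold E_th only counts as leaving the bout if it
#' lasts at least `commit_time` seconds; shorter excursions are intra-bout
#' interruptions and stay labeled feeding.
#'
#' @param x a `wc_trajectory`, or a numeric E series (then `dt` is required).
#' @param landscape a bistable `wc_landscape` (optional for trajectories,
#'   which carry their threshold).
#' @param commit_time hysteresis time, seconds.
#' @param dt sample spacing when `x` is a bare numeric series.
#' @return Character vector, `"feeding"` or `"non-feeding"`, one per sample.
#' @export
label_states <- function(x, landscape = NULL, commit_time = 4, dt = NULL) {
  if (inherits(x, "wc_trajectory")) {
    E <- x$E
    dt <- x$params$dt
    E_th <- if (is.null(landscape)) x$E_th else landscape$E_th
  } else {
    E <- x
    if (is.null(dt)) stop("dt is required when labeling a bare E series")
    if (is.null(landscape)) stop("a landscape is required when labeling a bare E series")
    E_th <- landscape$E_th
  }
  if (!is.null(landscape) && !landscape$bistable) {
    stop("state labeling requires a bistable landscape")
  }
  if (is.na(E_th)) stop("state labeling requires a bistable landscape")
  above <- E >= E_th
  r <- rle(above)
  nonfeed <- r$values & (r$lengths * dt >= commit_time)
  rep(ifelse(nonfeed, "non-feeding", "feeding"), r$lengths)
}

#' Condition specification for batched simulations
#'
#' Named presets mirror the study's manipulations: `"eOPN3"` (tonic
#' inhibition, current -0.7), `"ChR2"` (tonic activation, current +0.85),
#' `"looming"` (current 0, interruption rate doubled), and `"ctrl"` /
#' `"baseline"` (defaults). Any field can be overridden.
#'
#' @param name condition name (free-form; presets recognized as above).
#' @param current tonic current; `NULL` takes the preset (or 0).
#' @param rate_scale interval divisor; `NULL` takes the preset (or 1).
#' @param n_sessions number of independent sessions.
#' @param session_length seconds per session.
#' @param seed base seed; session `i` uses `seed + i`.
#' @param reentry_rate forced re-entry rate passed to [simulate_wc()];
#'   presets enable it (mean non-feeding dwell 20 s) so sessions contain
#'   realistic numbers of bouts.
#' @param commit_time hysteresis/termination rule, seconds.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(name = "ctrl", current = NULL, rate_scale = NULL,
                           n_sessions = 20, session_length = 600,
                           seed = 1, reentry_rate = 0.05, commit_time = 4) {
  presets <- list(eOPN3 = list(current = -0.7, rate_scale = 1),
                  ChR2 = list(current = 0.85, rate_scale = 1),
                  looming = list(current = 0, rate_scale = 2))
  pre <- presets[[name]]
  if (is.null(current)) current <- if (is.null(pre)) 0 else pre$current
  if (is.null(rate_scale)) rate_scale <- if (is.null(pre)) 1 else pre$rate_scale
  structure(list(name = name, current = current, rate_scale = rate_scale,
                 n_sessions = n_sessions, session_length = session_length,
                 seed = seed, reentry_rate = reentry_rate,
                 commit_time = commit_time),
            class = "condition_spec")
}

#' Run a batch of seeded sessions under one condition
#'
#' Applies the condition's tonic current to the model and its `rate_scale` to
#' the renewal process, runs `n_sessions` independent simulations, and
#' assembles their bout and event tables (see [trajectory_bouts()]) with the
#' session index as the subject id.
#'
#' @param spec a [condition_spec()].
#' @param params base [model_params()] (current is overridden by the spec).
#' @param rp base [renewal_params()] (rate_scale is overridden by the spec).
#' @return An object of class `wc_condition`: list with `name`, `spec`,
#'   `trajectories`, and `bouts` (a `bout_table` pooling all sessions).
#' @export
run_condition <- function(spec, params = model_params(), rp = renewal_params()) {
  stopifnot(inherits(spec, "condition_spec"))
  params$current <- spec$current
  validate_model_params(params)
  rp$rate_scale <- spec$rate_scale
  landscape <- compute_potential(params)
  trajs <- lapply(seq_len(spec$n_sessions), function(i) {
    simulate_wc(params, rp, duration = spec$session_length,
                seed = spec$seed + i, landscape = landscape,
                commit_time = spec$commit_time,
                reentry_rate = spec$reentry_rate)
  })
  tabs <- lapply(seq_along(trajs), function(i) {
    trajectory_bouts(trajs[[i]], subject = sprintf("s%02d", i),
                     condition = spec$name)
  })
  bouts <- do.call(rbind_bout_tables, tabs)
  structure(list(name = spec$name, spec = spec, trajectories = trajs,
                 bouts = bouts),
            class = "wc_condition")
}

#' Bout and event tables from a simulated trajectory
#'
#' Converts a trajectory into the same tabular form that behavioral
#' segmentation produces. Bouts are maximal feeding-labeled stretches. Events
#' come from the pulse log: every renewal pulse is an interruption unless it
#' is the last pulse of its bout and the above-threshold excursion it
#' triggered committed the termination (the excursion reached `commit_time`);
#' a bout whose terminal escape was purely noise-driven gets a termination
#' event at the bout end. For each event, `interval` is the feeding time
#' (below-threshold samples) accumulated since the previous event in the same
#' bout — the renewal process's own clock — and `gap` is the duration of the
#' above-threshold excursion following the pulse (0 if it never crossed).
#'
#' @param traj a `wc_trajectory`.
#' @param subject,condition identifiers stamped on the rows.
#' @return A `bout_table` (see [segment_bouts()]): list with `bouts`, `events`
#'   and `sessions` data frames. The final bout of a session is marked
#'   `complete = FALSE` if the session ended inside it; incomplete bouts are
#'   excluded from duration summaries but their events still count.
#' @export
trajectory_bouts <- function(traj, subject = "s01", condition = "model") {
  stopifnot(inherits(traj, "wc_trajectory"))
  dt <- traj$params$dt
  tt <- traj$t
  lab <- traj$state
  commit <- traj$commit_time
  r <- rle(lab == "feeding")
  ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1L) + 1L)
  fs <- starts[r$values]; fe <- ends[r$values]
  if (length(fs) == 0) {
    return(new_bout_table(
      bouts = data.frame(subject = character(), condition = character(),
                         start = numeric(), end = numeric(),
                         duration = numeric(), n_interruptions = integer(),
                         complete = logical()),
      events = data.frame(subject = character(), condition = character(),
                          time = numeric(), kind = character(),
                          interval = numeric(), gap = numeric()),
      sessions = data.frame(subject = subject, condition = condition,
                            t0 = tt[1], t1 = tt[length(tt)], food_intro = tt[1])))
  }
  bstart <- tt[fs]; bend <- tt[fe]
  complete <- fe < length(tt)
  below_cum <- cumsum(traj$E < traj$E_th) * dt # feeding-clock time
  below_idx <- which(traj$E < traj$E_th)

  p <- traj$pulses
  ev_time <- numeric(0); ev_kind <- character(0)
  ev_interval <- numeric(0); ev_gap <- numeric(0)
  n_int <- integer(length(fs))
  for (b in seq_along(fs)) {
    # a pulse that immediately crosses the threshold is logged one sample
    # past the last feeding-labeled sample, hence the + 1.5 dt margin
    inb <- which(p$time >= bstart[b] - dt / 2 & p$time <= bend[b] + 1.5 * dt)
    times <- p$time[inb]
    kinds <- rep("interruption", length(times))
    term_time <- NA_real_
    if (complete[b]) {
      if (length(times) && bend[b] - times[length(times)] <= commit + dt / 2) {
        kinds[length(kinds)] <- "termination"
      } else {
        times <- c(times, bend[b]) # noise-driven termination, no pulse
        kinds <- c(kinds, "termination")
      }
    }
    # renewal clock reading at each event, relative to previous event/bout start
    idx <- pmin(round(times / dt) + 1L, length(below_cum))
    clocks <- below_cum[idx]
    prev <- c(below_cum[fs[b]], clocks[-length(clocks)])
    intervals <- clocks - prev
    gaps <- vapply(times, function(tm) {
      k <- round(tm / dt) + 1L
      if (k <= length(traj$E) && traj$E[k] < traj$E_th) return(0)
      j <- findInterval(k, below_idx) + 1L
      if (j > length(below_idx)) return(tt[length(tt)] - tm)
      (below_idx[j] - k) * dt
    }, numeric(1))
    ev_time <- c(ev_time, times); ev_kind <- c(ev_kind, kinds)
    ev_interval <- c(ev_interval, intervals); ev_gap <- c(ev_gap, gaps)
    n_int[b] <- sum(kinds == "interruption")
  }
  new_bout_table(
    bouts = data.frame(subject = subject, condition = condition,
                       start = bstart, end = bend, duration = bend - bstart,
                       n_interruptions = n_int, complete = complete),
    events = data.frame(subject = subject, condition = condition,
                        time = ev_time, kind = ev_kind,
                        interval = ev_interval, gap = ev_gap),
    sessions = data.frame(subject = subject, condition = condition,
                          t0 = tt[1], t1 = tt[length(tt)], food_intro = tt[1]))
}

#' Re-estimate the diffusion amplitude from a simulated trajectory
#'
#' Self-consistency check of the noise convention: per Euler-Maruyama step,
#' the residual `(dE - drift_E * dt) / sqrt(dt)` is an independent
#' N(0, noise_sd^2) draw, so its standard deviation re-estimates `noise_sd`.
#' Steps containing a pulse or a forced re-entry are excluded (their
#' increments contain jumps).
#'
#' @param traj a `wc_trajectory`.
#' @param channel `"E"` or `"I"`.
#' @return List with `sd` (the estimate), `n` (residuals used), and `se`
#'   (approximate standard error of the estimate, `sd / sqrt(2 n)`).
#' @export
estimate_noise_sd <- function(traj, channel = c("E", "I")) {
  stopifnot(inherits(traj, "wc_trajectory"))
  channel <- match.arg(channel)
  p <- traj$params
  dt <- p$dt
  n <- length(traj$t) - 1
  d <- wc_drift(traj$E[1:n], traj$I[1:n], p)
  x <- if (channel == "E") traj$E else traj$I
  drift <- if (channel == "E") d$dE else d$dI
  resid <- (x[2:(n + 1)] - x[1:n] - drift * dt) / sqrt(dt)
  jump_times <- c(traj$pulses$time, traj$reentries)
  if (length(jump_times)) {
    resid <- resid[-round(jump_times / dt)]
  }
  s <- stats::sd(resid)
  list(sd = s, n = length(resid), se = s / sqrt(2 * length(resid)))
}

#' Write a trajectory to tabular text
#'
#' Writes the state table (t, E, I, state) and the pulse-event table
#' (time, amplitude) as tab-delimited files, plus a YAML parameter snapshot.
#'
#' @param traj a `wc_trajectory`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return The directory, invisibly.
#' @export
write_trajectory <- function(traj, dir, prefix = "session") {
  stopifnot(inherits(traj, "wc_trajectory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(t = traj$t, E = traj$E, I = traj$I, state = traj$state),
    file.path(dir, paste0(prefix, "_trajectory.tsv")),
    sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(traj$pulses,
                     file.path(dir, paste0(prefix, "_pulses.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  snap <- c(unclass(traj$params),
            if (!is.null(traj$rp)) unclass(traj$rp),
            list(seed = traj$seed, commit_time = traj$commit_time))
  yaml::write_yaml(snap, file.path(dir, paste0(prefix, "_params.yml")))
  invisible(dir)
}
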