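test_that("renewal intervals follow the fitted lognormal law", {
  rp <- renewal_params()
  iv <- sample_renewal_intervals(rp, 1e5, seed = 42)
  expect_true(all(iv > 0))
  expect_lt(abs(mean(log(iv)) - 2.22), 3 * 0.99 / sqrt(1e5))
  expect_lt(abs(sd(log(iv)) - 0.99), 3 * 0.99 / sqrt(2e5))
  # rate_scale divides the identical draws under the same seed
  iv2 <- sample_renewal_intervals(renewal_params(rate_scale = 2), 1e3, seed = 9)
  iv1 <- sample_renewal_intervals(renewal_params(rate_scale = 1), 1e3, seed = 9)
  expect_equal(iv2, iv1 / 2)
  expect_error(renewal_params(log_sd = 0), "log_sd")
})

test_that("trajectories are bit-identical under a fixed seed", {
  a <- simulate_wc(duration = 60, seed = 21, reentry_rate = 0.05)
  b <- simulate_wc(duration = 60, seed = 21, reentry_rate = 0.05)
  expect_identical(a$E, b$E)
  expect_identical(a$I, b$I)
  expect_identical(a$pulses, b$pulses)
  c <- simulate_wc(duration = 60, seed = 22, reentry_rate = 0.05)
  expect_false(identical(a$E, c$E))
})

test_that("noiseless dynamics hold the feeding fixed point and flip on a large pulse", {
  p <- model_params(noise_sd = 0)
  L <- compute_potential(p)
  tr <- simulate_wc(p, rp = NULL, duration = 60, landscape = L)
  expect_true(all(abs(tr$E - L$fixed_points$E[1]) < 1e-6))
  # a single pulse far above the threshold displacement commits the switch
  rp_big <- renewal_params(log_mean = log(5), log_sd = 1e-6,
                           pulse_mean = 1.2, pulse_sd = 0)
  tr2 <- simulate_wc(p, rp_big, duration = 60, landscape = L)
  expect_equal(nrow(tr2$pulses), 1) # clock pauses once in the high state
  expect_lt(abs(tr2$E[length(tr2$E)] - L$fixed_points$E[3]), 1e-6)
})

test_that("both attractors are metastable at the calibrated noise level", {
  p <- model_params()
  L <- compute_potential(p)
  for (r in c(1, 3)) {
    init <- c(L$fixed_points$E[r], solve_I_steady(L$fixed_points$E[r], p))
    occ <- vapply(1:5, function(s) {
      tr <- simulate_wc(p, rp = NULL, duration = 10 * p$tau_E, seed = 100 + s,
                        init = init, landscape = L)
      if (r == 1) mean(tr$E < L$E_th) else mean(tr$E >= L$E_th)
    }, numeric(1))
    expect_gt(mean(occ), 0.99)
  }
})

test_that("the declared noise convention is self-consistent", {
  tr <- simulate_wc(duration = 300, seed = 77, rp = NULL)
  est <- estimate_noise_sd(tr)
  expect_lt(abs(est$sd - 0.1055), 3 * est$se)
  est_I <- estimate_noise_sd(tr, channel = "I")
  expect_lt(abs(est_I$sd - 0.1055), 3 * est_I$se)
})

test_that("pulse bookkeeping is exact: on-grid times, feeding-labeled samples", {
  tr <- simulate_wc(duration = 400, seed = 31, reentry_rate = 0.05)
  dt <- tr$params$dt
  expect_true(all(abs(tr$pulses$time / dt - round(tr$pulses$time / dt)) < 1e-9))
  # the sample preceding each pulse is in a feeding-labeled stretch
  pre_idx <- round(tr$pulses$time / dt) # sample before the jump
  expect_true(all(tr$state[pre_idx] == "feeding"))
  # pulse count matches fired renewal events: every logged pulse moved E
  k <- round(tr$pulses$time / dt) + 1
  jumps <- tr$E[k] - tr$E[k - 1]
  d <- wc_drift(tr$E[k - 1], tr$I[k - 1], tr$params)
  resid <- jumps - d$dE * dt - tr$pulses$amplitude
  expect_true(all(abs(resid) < 5 * 0.1055 * sqrt(dt) + 1e-9))
})

test_that("state labeling applies the hysteresis rule", {
  L <- compute_potential(model_params())
  n <- 1000; dt <- 0.02
  low <- rep(L$E_th - 0.2, n)
  high <- rep(L$E_th + 0.2, n)
  expect_true(all(label_states(low, L, dt = dt) == "feeding"))
  expect_true(all(label_states(high, L, dt = dt) == "non-feeding"))
  # a 1 s supra-threshold excursion does not break the bout at commit 4 s
  exc <- low; exc[400:449] <- L$E_th + 0.3
  expect_true(all(label_states(exc, L, dt = dt, commit_time = 4) == "feeding"))
  # but a 4 s excursion does
  exc2 <- low; exc2[400:599] <- L$E_th + 0.3
  lab <- label_states(exc2, L, dt = dt, commit_time = 4)
  expect_equal(unique(lab[400:599]), "non-feeding")
  expect_equal(unique(lab[c(1:399, 600:n)]), "feeding")
  mono <- compute_potential(model_params(current = -100), grid_size = 1024)
  expect_error(label_states(low, mono, dt = dt), "bistable")
})

test_that("simulation refuses non-bistable parameters and short horizons", {
  expect_error(simulate_wc(model_params(current = -100), duration = 100),
               "bistable")
  expect_error(simulate_wc(duration = 5), "10 \\* tau_E")
})

test_that("condition presets carry the optogenetic currents and looming rate", {
  expect_equal(condition_spec("eOPN3")$current, -0.7)
  expect_equal(condition_spec("ChR2")$current, 0.85)
  lo <- condition_spec("looming")
  expect_equal(lo$current, 0)
  expect_gt(lo$rate_scale, 1)
  expect_equal(condition_spec("ctrl")$current, 0)
})

test_that("trajectory bout tables satisfy the event-structure invariants", {
  spec <- condition_spec("ctrl", n_sessions = 3, session_length = 400, seed = 5)
  cond <- run_condition(spec)
  bt <- cond$bouts
  expect_s3_class(bt, "bout_table")
  expect_true(all(bt$bouts$duration > 0))
  # each complete bout ends in exactly one termination
  n_complete <- sum(bt$bouts$complete)
  expect_equal(sum(bt$events$kind == "termination"), n_complete)
  # interruptions lie strictly inside a bout
  for (i in which(bt$events$kind == "interruption")) {
    e <- bt$events[i, ]
    b <- bt$bouts[bt$bouts$subject == e$subject, ]
    expect_true(any(e$time >= b$start - 0.05 & e$time <= b$end + 0.05))
  }
  # renewal intervals measured from the tables recover the generative law
  iv <- bt$events$interval[bt$events$interval > 0]
  fit <- fit_lognormal(iv)
  expect_lt(abs(fit$log_mean - 2.22), 3 * 0.99 / sqrt(length(iv)) + 0.1)
})

test_that("trajectory export writes state, pulses and a parameter snapshot", {
  tr <- simulate_wc(duration = 60, seed = 2, reentry_rate = 0.05)
  d <- withr::local_tempdir()
  write_trajectory(tr, d, prefix = "s1")
  tab <- read.table(file.path(d, "s1_trajectory.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(tab), length(tr$t))
  snap <- yaml::read_yaml(file.path(d, "s1_params.yml"))
  expect_equal(snap$noise_sd, 0.1055)
  expect_equal(snap$log_mean, 2.22)
})
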