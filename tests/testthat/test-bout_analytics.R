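toy_ann <- function(starts, stops, subject = "m1", condition = "ctrl") {
  data.frame(subject = subject, condition = condition, label = "feeding",
             start = starts, stop = stops)
}

test_that("segmentation applies the 4 s interruption rule exactly", {
  bt <- segment_bouts(toy_ann(c(0, 12, 30), c(10, 20, 40)))
  expect_equal(bt$bouts$start, c(0, 30))
  expect_equal(bt$bouts$end, c(20, 40))
  expect_equal(bt$bouts$n_interruptions, c(1L, 0L))
  expect_equal(bt$events$time[bt$events$kind == "interruption"], 10)
  expect_equal(bt$events$time[bt$events$kind == "termination"], c(20, 40))
  expect_equal(bt$events$gap[bt$events$kind == "interruption"], 2)

  one <- segment_bouts(toy_ann(0, 5))
  expect_equal(nrow(one$bouts), 1)
  expect_equal(one$bouts$n_interruptions, 0L)
  expect_equal(sum(one$events$kind == "termination"), 1)

  # degenerate threshold: every interval its own bout
  zero <- segment_bouts(toy_ann(c(0, 12, 30), c(10, 20, 40)), gap_threshold = 0)
  expect_equal(nrow(zero$bouts), 3)
  expect_equal(sum(zero$bouts$n_interruptions), 0L)
})

test_that("segmentation is idempotent and conserves feeding time", {
  set.seed(3)
  # random raster: alternating feeding intervals and gaps of mixed length
  gaps <- runif(30, 0.5, 8)
  durs <- runif(30, 1, 12)
  stops <- cumsum(gaps + durs)
  starts <- stops - durs
  ann <- toy_ann(starts, stops)
  bt <- segment_bouts(ann)
  # feeding time conservation: sum of intervals = sum over bouts of
  # (duration - interruption gap time)
  gap_time <- sum(bt$events$gap[bt$events$kind == "interruption"])
  expect_equal(sum(ann$stop - ann$start), sum(bt$bouts$duration) - gap_time)
  # re-expressing the bouts as annotations and re-segmenting changes nothing
  ann2 <- data.frame(subject = "m1", condition = "ctrl", label = "feeding",
                     start = bt$bouts$start, stop = bt$bouts$end)
  bt2 <- segment_bouts(ann2)
  expect_equal(bt2$bouts$start, bt$bouts$start)
  expect_equal(bt2$bouts$end, bt$bouts$end)
  expect_equal(sum(bt2$bouts$n_interruptions), 0L)
})

test_that("overlapping feeding intervals are rejected with offenders named", {
  expect_error(segment_bouts(toy_ann(c(0, 5), c(6, 10))), "overlapping")
  expect_error(segment_bouts(toy_ann(1, 1)), "stop > start")
})

test_that("summary statistics follow their definitions", {
  # 2 bouts of 10 and 20 s; second has all 6 interruptions
  ann <- toy_ann(c(0, 100, 103, 106, 109, 112, 115, 118),
                 c(10, 102, 105, 108, 111, 114, 117, 120))
  st <- bout_statistics(segment_bouts(ann))
  expect_equal(st$summary$mean_duration, 15)
  expect_equal(st$summary$termination_prop, 2 / 8) # 2 term + 6 intr
  ec <- st$ecdf$ctrl
  expect_equal(ec(c(9.99, 10, 19.99, 20)), c(0, 0.5, 0.5, 1))
  # event frequency: 8 events over 30 s of bout time
  expect_equal(st$summary$event_freq_per_min, 8 / (30 / 60))
})

test_that("lognormal fitting is the closed-form MLE", {
  expect_equal(fit_lognormal(exp(c(2, 2, 2))), list(log_mean = 2, log_sd = 0))
  set.seed(8)
  x <- exp(rnorm(1e5, 2.22, 0.99))
  fit <- fit_lognormal(x)
  expect_lt(abs(fit$log_mean - 2.22), 3 * 0.99 / sqrt(1e5))
  expect_lt(abs(fit$log_sd - 0.99), 3 * 0.99 / sqrt(2e5))
  expect_equal(fit_lognormal(rev(x)), fit)
  expect_error(fit_lognormal(c(1, -1)), "positive")
  expect_error(fit_lognormal(3), "at least 2")
})

test_that("permutation KS behaves at the degenerate extremes", {
  set.seed(12)
  x <- rlnorm(40)
  self <- permutation_ks(x, x, n_perm = 999, seed = 1)
  expect_equal(self$statistic, 0)
  expect_equal(self$p.value, 1)
  disj <- permutation_ks(1:50, 101:150, n_perm = 999, seed = 1)
  expect_equal(disj$statistic, 1)
  expect_equal(disj$p.value, 1 / 1000)
  expect_error(permutation_ks(x, x, n_perm = 99), "999")
  expect_error(permutation_ks(1, x), "at least 2")
})

test_that("the KS statistic matches the reference implementation", {
  set.seed(4)
  for (k in 1:5) {
    a <- rlnorm(30 + k); b <- rlnorm(45, meanlog = 0.3)
    D_ref <- unname(suppressWarnings(stats::ks.test(a, b)$statistic))
    expect_equal(permutation_ks(a, b, n_perm = 999, seed = 1)$statistic, D_ref)
  }
  # one-tailed statistics match ks.test's signed gaps: ks.test's "greater"
  # is max(F_a - F_b), our "less" (sample_a stochastically smaller)
  a <- rlnorm(40); b <- rlnorm(40, meanlog = 0.5)
  D_less <- unname(suppressWarnings(
    stats::ks.test(a, b, alternative = "greater")$statistic))
  expect_equal(permutation_ks(a, b, n_perm = 999, seed = 1,
                              alternative = "less")$statistic, D_less)
})

test_that("a clear distribution shift is detected one-tailed", {
  set.seed(9)
  long_dur <- rlnorm(120, meanlog = 3.4, sdlog = 0.7)
  short_dur <- rlnorm(120, meanlog = 2.8, sdlog = 0.7)
  res <- permutation_ks(short_dur, long_dur, n_perm = 999, seed = 2,
                        alternative = "less")
  expect_lt(res$p.value, 0.01)
})

test_that("termination GLM recovers the log odds and flags degeneracies", {
  # single subject, condition the only covariate: matches the 2x2 log OR
  ev <- data.frame(
    subject = "m1",
    condition = rep(c("ctrl", "stim"), c(40, 50)),
    kind = c(rep(c("termination", "interruption"), c(10, 30)),
             rep(c("termination", "interruption"), c(25, 25))))
  fit <- termination_glm(ev, reference = "ctrl")
  log_or <- log((25 / 25) / (10 / 30))
  expect_equal(fit$coefficients$estimate, log_or, tolerance = 1e-6)
  se_hand <- sqrt(1 / 25 + 1 / 25 + 1 / 10 + 1 / 30)
  expect_equal(fit$coefficients$se, se_hand, tolerance = 1e-6)
  expect_false(fit$separation)

  # identical proportions across conditions: coefficient ~ 0
  ev0 <- data.frame(subject = rep(c("m1", "m2"), each = 40),
                    condition = rep(rep(c("a", "b"), each = 20), 2),
                    kind = rep(rep(c("termination", "interruption"), times = 10), 4))
  fit0 <- termination_glm(ev0)
  expect_lt(abs(fit0$coefficients$estimate), 1e-8)

  # complete separation is flagged
  sep <- data.frame(subject = "m1",
                    condition = rep(c("a", "b"), each = 20),
                    kind = rep(c("interruption", "termination"), each = 20))
  expect_warning(fitS <- termination_glm(sep), "separation")
  expect_true(fitS$separation)
  expect_error(termination_glm(ev[ev$condition == "ctrl", ]), "2 conditions")
})

test_that("annotation tables round-trip through text files", {
  ann <- toy_ann(c(0, 12), c(10, 20))
  f <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, f)
  back <- read_annotations(f)
  expect_equal(back$start, ann$start)
  bt <- segment_bouts(back)
  d <- withr::local_tempdir()
  write_bout_table(bt, d)
  expect_true(file.exists(file.path(d, "bouts_events.tsv")))
})
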