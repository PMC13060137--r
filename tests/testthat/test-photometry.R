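make_rec <- function(z, fs = 20) {
  photometry_recording(t = seq(0, by = 1 / fs, length.out = length(z)), z = z)
}

test_that("reference correction removes shared artifacts and z-scores", {
  set.seed(15)
  t <- seq(0, 100, by = 0.05)
  artifact <- sin(2 * pi * t / 30) + 0.01 * t
  component <- -as.numeric(t %% 20 < 8) # bout-locked square wave
  # orthogonalize against the artifact so the reference fit cannot absorb it
  component <- stats::resid(stats::lm(component ~ artifact))
  z1 <- preprocess_photometry(signal = artifact, reference = artifact)
  expect_equal(z1, rep(0, length(t))) # degenerate-SD guard
  sig <- 2 * artifact + component + rnorm(length(t), 0, 0.01)
  z2 <- preprocess_photometry(signal = sig, reference = artifact, t = t)
  expect_equal(mean(z2), 0, tolerance = 1e-12)
  expect_equal(sd(z2), 1, tolerance = 1e-12)
  expect_gt(cor(z2, component), 0.999) # shape recovered up to scale
  expect_error(preprocess_photometry(1:5, t = c(0, 1, 2, 3, 10)), "uniform")
})

test_that("event alignment averages on the lag grid with complete windows", {
  z <- rep(3, 2001)
  rec <- make_rec(z)
  al <- align_events(rec, event_times = c(20, 40, 60), pre = 5, post = 10)
  expect_equal(al$mean, rep(3, length(al$lag)))
  expect_equal(al$lag[1], -5)
  expect_equal(al$lag[length(al$lag)], 10)
  expect_equal(al$lag[al$lag == 0], 0)

  # a -1 step at each event shows up at lag 0
  t <- seq(0, 100, by = 0.05)
  ev <- c(20, 50, 80)
  zstep <- rep(0, length(t))
  for (e in ev) zstep[t >= e] <- zstep[t >= e] - 1
  rec2 <- photometry_recording(t, z = zstep)
  al2 <- align_events(rec2, ev, pre = 5, post = 5)
  expect_lt(max(abs(diff(al2$mean)[al2$lag[-1] != 0])), 1e-12)
  k0 <- which(al2$lag == 0)
  expect_equal(al2$mean[k0] - al2$mean[k0 - 1], -1)

  # overlapping windows are both kept; incomplete ones dropped with a count
  al3 <- align_events(rec, c(1, 20, 20.5, 1995), pre = 5, post = 10)
  expect_equal(al3$n_used, 2)
  expect_equal(al3$n_dropped, 2)
  expect_error(align_events(rec, c(1), pre = 100, post = 100), "complete window")
})

test_that("two-level averaging weights subjects, not events", {
  t <- seq(0, 200, by = 0.05)
  z <- rep(1, length(t))
  rec <- photometry_recording(t, z = z)
  al <- align_events(rec, seq(20, 100, by = 10), pre = 2, post = 2,
                     subjects = rep("A", 9))
  expect_equal(unique(al$mean), 1)
  # mixed-subject matrix: mean must be the mean of per-subject means
  z2 <- z; z2[t > 150] <- 3
  rec2 <- photometry_recording(t, z = z2)
  al2 <- align_events(rec2, c(rep(c(20, 30, 40, 50), 1), 160),
                      pre = 2, post = 2,
                      subjects = c(rep("A", 4), "B"))
  expect_equal(unique(al2$mean), (1 + 3) / 2)
})

test_that("AUC uses a 10 s baseline and a post window capped by duration", {
  t <- seq(0, 200, by = 0.05)
  z <- rep(0, length(t)); z[t >= 50] <- 1
  rec <- photometry_recording(t, z = z)
  # step at the event, duration 30 -> window capped at 20 s
  expect_equal(auc_response(rec, 50, 30), 1)
  # duration 5 s with signal 1 only during the event
  z2 <- rep(0, length(t)); z2[t >= 50 & t < 55] <- 1
  rec2 <- photometry_recording(t, z = z2)
  expect_equal(auc_response(rec2, 50, 5), 1)
  # with the default 20 s window the same event dilutes to 1/4
  expect_equal(auc_response(rec2, 50, 30), 0.25)
  # constant trace and constant-shift invariance
  expect_equal(auc_response(make_rec(rep(2, 4001)), 50, 10), 0)
  rec3 <- photometry_recording(t, z = z + 7)
  expect_equal(auc_response(rec3, 50, 30), auc_response(rec, 50, 30))
  expect_error(auc_response(rec, 5, 10), "pre-event")
})

test_that("AUC agrees with window means of the aligned rows", {
  set.seed(22)
  t <- seq(0, 300, by = 0.05)
  rec <- photometry_recording(t, z = rnorm(length(t)))
  evs <- c(60, 120, 180)
  al <- align_events(rec, evs, pre = 10, post = 20)
  for (j in seq_along(evs)) {
    row <- al$matrix[j, ]
    eps <- 1e-9
    manual <- mean(row[al$lag >= -eps & al$lag < 20 - eps]) -
      mean(row[al$lag >= -10 - eps & al$lag < -eps])
    expect_equal(auc_response(rec, evs[j], 25), manual, tolerance = 1e-10)
  }
})

test_that("variance partitioning reports unique (semi-partial) R squared", {
  set.seed(31)
  n <- 4000
  feeding <- as.numeric(runif(n) < 0.4)
  speed <- rnorm(n)
  z <- feeding + rnorm(n, 0, 0.05)
  res <- regress_signal(z, feeding, speed)
  expect_equal(res$coefficients$estimate[1], 1, tolerance = 0.01)
  expect_lt(res$coefficients$unique_R2[2], 0.005)
  # orthonormal predictors: unique R2s add up to the total
  a <- rep(c(1, -1), n / 2) / sqrt(n)
  b <- rep(c(1, 1, -1, -1), n / 4) / sqrt(n)
  zz <- 3 * a + 1 * b + rnorm(n, 0, 0.01)
  r2 <- regress_signal(zz, a, b)
  expect_equal(r2$coefficients$unique_R2[1] + r2$coefficients$unique_R2[2],
               r2$total_R2, tolerance = 1e-10)
  expect_warning(regress_signal(z, feeding, feeding * 2 + 1e-9 * rnorm(n)),
                 "collinear")
})

test_that("regression recovers generative coefficients across replicates", {
  set.seed(44)
  errs <- replicate(30, {
    n <- 2000
    feeding <- as.numeric(runif(n) < 0.4)
    speed <- 2 - feeding + rnorm(n) # anticorrelated, as in real sessions
    z <- -1.0 * feeding + 0.2 * speed + rnorm(n, 0, 0.5)
    fit <- regress_signal(z, feeding, speed)
    fit$coefficients$estimate - c(-1.0, 0.2)
  })
  expect_lt(abs(mean(errs[1, ])), 3 * sd(errs[1, ]) / sqrt(30))
  expect_lt(abs(mean(errs[2, ])), 3 * sd(errs[2, ]) / sqrt(30))
})

test_that("photometry files round-trip", {
  t <- seq(0, 10, by = 0.1)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(t = t, signal = sin(t) + 10, reference = rep(5, length(t)),
                       speed = abs(cos(t))), f, row.names = FALSE)
  rec <- read_photometry(f)
  expect_s3_class(rec, "photometry_recording")
  expect_equal(length(rec$z), length(t))
  expect_equal(sd(rec$z), 1, tolerance = 1e-9)
})
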