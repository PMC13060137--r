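#' @title Bout tables
#' @description Internal constructor shared by behavioral segmentation and the
#'   simulator bridge. A `bout_table` carries three data frames: `bouts`
#'   (subject, condition, start, end, duration, n_interruptions, complete),
#'   `events` (subject, condition, time, kind, interval, gap) and `sessions`
#'   (subject, condition, t0, t1, food_intro).
#' @keywords internal
new_bout_table <- function(bouts, events, sessions) {
  structure(list(bouts = bouts, events = events, sessions = sessions),
            class = "bout_table")
}

rbind_bout_tables <- function(...) {
  xs <- list(...)
  new_bout_table(bouts = do.call(rbind, lapply(xs, `[[`, "bouts")),
                 events = do.call(rbind, lapply(xs, `[[`, "events")),
                 sessions = do.call(rbind, lapply(xs, `[[`, "sessions")))
}

#' @export
print.bout_table <- function(x, ...) {
  cat(sprintf("Bout table: %d bouts, %d events (%d terminations) over %d session(s)\n",
              nrow(x$bouts), nrow(x$events),
              sum(x$events$kind == "termination"), nrow(x$sessions)))
  invisible(x)
}

#' Segment annotated feeding intervals into bouts
#'
#' Applies the microstructure rule: within a subject/condition session,
#' feeding intervals separated by a gap shorter than `gap_threshold` seconds
#' belong to the same bout and the gap is an intra-bout interruption; a gap of
#' at least `gap_threshold` (or the end of the record) terminates the bout.
#' Each interruption event is stamped at the gap's start; each bout emits
#' exactly one termination event at the bout's end.
#'
#' @param ann annotation data frame with columns `subject`, `condition`,
#'   `label`, `start`, `stop` (seconds), and optionally `food_intro` (the
#'   session's food-introduction timestamp, constant within a session; used
#'   for latency).
#' @param gap_threshold interruption/termination boundary, seconds.
#' @param feeding_label the annotation label treated as feeding.
#' @return A `bout_table`. For every event, `interval` is the feeding time
#'   accumulated since the previous event of the same bout (or the bout
#'   start) — the empirical renewal interval — and `gap` is the pause
#'   duration (for terminations, the time to the next feeding interval, or
#'   `NA` at the end of the record).
#' @examples
#' ann <- data.frame(subject = "m1", condition = "ctrl", label = "feeding",
#'                   start = c(0, 12, 30), stop = c(10, 20, 40))
#' segment_bouts(ann)$bouts$duration # 20 and 10
#' @export
segment_bouts <- function(ann, gap_threshold = 4, feeding_label = "feeding") {
  required <- c("subject", "condition", "label", "start", "stop")
  if (!all(required %in% names(ann))) {
    stop("annotation table must have columns: ", paste(required, collapse = ", "))
  }
  if (any(ann$stop <= ann$start)) stop("every interval must have stop > start")
  feeding <- ann[ann$label == feeding_label, , drop = FALSE]
  if (nrow(feeding) == 0) stop("no feeding intervals in annotation table")
  keys <- interaction(feeding$subject, feeding$condition, drop = TRUE)
  per <- lapply(split(feeding, keys), function(fi) {
    fi <- fi[order(fi$start), , drop = FALSE]
    ov <- which(fi$start[-1] < fi$stop[-nrow(fi)])
    if (length(ov)) {
      stop("overlapping feeding intervals for subject ", fi$subject[1],
           ", condition ", fi$condition[1], " at rows starting ",
           paste(round(fi$start[ov + 1], 3), collapse = ", "))
    }
    gaps <- if (nrow(fi) > 1) fi$start[-1] - fi$stop[-nrow(fi)] else numeric(0)
    new_bout <- c(TRUE, gaps >= gap_threshold)
    bid <- cumsum(new_bout)
    bstart <- tapply(fi$start, bid, min)
    bend <- tapply(fi$stop, bid, max)
    n_int <- as.integer(tapply(fi$start, bid, length)) - 1L
    subj <- fi$subject[1]; cond <- fi$condition[1]
    # events: interruptions at internal gap starts, termination at bout end
    ev <- do.call(rbind, lapply(unique(bid), function(b) {
      rows <- fi[bid == b, , drop = FALSE]
      int_t <- utils::head(rows$stop, -1L)           # gap starts
      int_gap <- rows$start[-1] - int_t
      term_t <- rows$stop[nrow(rows)]
      times <- c(int_t, term_t)
      kinds <- c(rep("interruption", length(int_t)), "termination")
      # feeding time since previous event within the bout
      intervals <- rows$stop - rows$start
      data.frame(subject = subj, condition = cond, time = times, kinds = kinds,
                 interval = intervals, gap = c(int_gap, NA_real_))
    }))
    names(ev)[names(ev) == "kinds"] <- "kind"
    # termination gap: time to next feeding interval (NA at record end)
    term_idx <- which(ev$kind == "termination")
    nf <- fi$start
    ev$gap[term_idx] <- vapply(ev$time[term_idx], function(tm) {
      nxt <- nf[nf > tm]
      if (length(nxt)) min(nxt) - tm else NA_real_
    }, numeric(1))
    fintro <- if ("food_intro" %in% names(fi)) fi$food_intro[1] else NA_real_
    list(bouts = data.frame(subject = subj, condition = cond,
                            start = as.numeric(bstart), end = as.numeric(bend),
                            duration = as.numeric(bend - bstart),
                            n_interruptions = n_int, complete = TRUE),
         events = ev,
         sessions = data.frame(subject = subj, condition = cond,
                               t0 = min(fi$start), t1 = max(fi$stop),
                               food_intro = fintro))
  })
  out <- do.call(rbind_bout_tables, lapply(per, function(p) {
    new_bout_table(p$bouts, p$events, p$sessions)
  }))
  rownames(out$bouts) <- rownames(out$events) <- rownames(out$sessions) <- NULL
  out
}

#' Microstructure statistics of a bout table
#'
#' Per-condition summaries: mean bout duration, total event frequency
#' normalized per minute of time-in-bout, termination proportion
#' (terminations / all events), lognormal fit of the inter-interruption
#' intervals, inter-bout interval statistics, and latency from food
#' introduction to the first bout where the annotation provides the
#' timestamp. Bouts are pooled across subjects for ECDFs; per-subject means
#' are reported separately for subject-level comparisons.
#'
#' @param bt a `bout_table` from [segment_bouts()], [trajectory_bouts()] or
#'   [run_condition()]`$bouts`.
#' @return An object of class `bout_stats`: list with `summary` (one row per
#'   condition), `per_subject` (subject x condition means), `durations`
#'   (named list of pooled complete-bout durations per condition, for ECDF and
#'   KS comparisons), and `ecdf` (list of [stats::ecdf()] functions).
#' @export
bout_statistics <- function(bt) {
  stopifnot(inherits(bt, "bout_table"))
  if (nrow(bt$bouts) == 0) stop("empty bout table")
  conds <- unique(bt$bouts$condition)
  summ <- do.call(rbind, lapply(conds, function(cn) {
    b <- bt$bouts[bt$bouts$condition == cn, , drop = FALSE]
    e <- bt$events[bt$events$condition == cn, , drop = FALSE]
    s <- bt$sessions[bt$sessions$condition == cn, , drop = FALSE]
    durs <- b$duration[b$complete]
    time_in_bout <- sum(b$duration)
    n_term <- sum(e$kind == "termination")
    n_intr <- sum(e$kind == "interruption")
    iv <- e$interval[e$interval > 0]
    fit <- if (length(iv) >= 2) fit_lognormal(iv) else list(log_mean = NA_real_, log_sd = NA_real_)
    # inter-bout intervals within each subject session
    ibi <- unlist(lapply(split(b, b$subject), function(bb) {
      bb <- bb[order(bb$start), , drop = FALSE]
      if (nrow(bb) > 1) bb$start[-1] - bb$end[-nrow(bb)] else numeric(0)
    }))
    lat <- mapply(function(su, fi) {
      if (is.na(fi)) return(NA_real_)
      min(b$start[b$subject == su]) - fi
    }, s$subject, s$food_intro)
    data.frame(condition = cn,
               n_bouts = nrow(b),
               mean_duration = mean(durs),
               median_duration = stats::median(durs),
               time_in_bout_min = time_in_bout / 60,
               event_freq_per_min = (n_term + n_intr) / (time_in_bout / 60),
               termination_prop = n_term / (n_term + n_intr),
               log_mean = fit$log_mean, log_sd = fit$log_sd,
               mean_interbout = if (length(ibi)) mean(ibi) else NA_real_,
               mean_latency = mean(unlist(lat), na.rm = TRUE))
  }))
  per_subject <- do.call(rbind, lapply(split(bt$bouts, list(bt$bouts$subject, bt$bouts$condition), drop = TRUE), function(b) {
    e <- bt$events[bt$events$subject == b$subject[1] &
                     bt$events$condition == b$condition[1], , drop = FALSE]
    n_term <- sum(e$kind == "termination")
    n_all <- nrow(e)
    data.frame(subject = b$subject[1], condition = b$condition[1],
               n_bouts = nrow(b),
               mean_duration = mean(b$duration[b$complete]),
               event_freq_per_min = n_all / (sum(b$duration) / 60),
               termination_prop = if (n_all) n_term / n_all else NA_real_)
  }))
  rownames(summ) <- rownames(per_subject) <- NULL
  durations <- lapply(conds, function(cn) {
    b <- bt$bouts
    b$duration[b$condition == cn & b$complete]
  })
  names(durations) <- conds
  structure(list(summary = summ, per_subject = per_subject,
                 durations = durations,
                 ecdf = lapply(durations, stats::ecdf)),
            class = "bout_stats")
}

#' @export
print.bout_stats <- function(x, ...) {
  cat("Feeding-bout microstructure statistics\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

# Kolmogorov-Smirnov distance between two samples over the pooled support.
# alternative = "greater" measures evidence that `a` is stochastically
# larger than `b` (its ECDF lies below), "less" the reverse.
ks_distance <- function(a, b, alternative = "two_sided") {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  ord <- order(pooled)
  is_a <- c(rep(TRUE, na), rep(FALSE, nb))[ord]
  Fa <- cumsum(is_a) / na
  Fb <- cumsum(!is_a) / nb
  ps <- pooled[ord]
  keep <- c(diff(ps) > 0, TRUE) # evaluate after the last of any tied block
  diffs <- (Fa - Fb)[keep]
  switch(alternative,
         two_sided = max(abs(diffs)),
         greater = max(Fb[keep] - Fa[keep]),
         less = max(diffs),
         stop("unknown alternative"))
}

#' Permutation Kolmogorov-Smirnov test
#'
#' Compares two duration samples by the (possibly signed) maximal ECDF gap,
#' with significance from label permutations: `p = (1 + #{permuted D >=
#' observed D}) / (n_perm + 1)`, the +1-corrected estimator that is exactly
#' valid at finite `n_perm`.
#'
#' @param sample_a,sample_b numeric samples, each of length >= 2.
#' @param n_perm number of label permutations, at least 999.
#' @param seed optional RNG seed for the shuffles.
#' @param alternative `"two_sided"`, or one-tailed: `"greater"` tests whether
#'   `sample_a` is stochastically larger than `sample_b`, `"less"` the
#'   reverse.
#' @return List with `statistic` (D), `p.value`, `n_perm`, `alternative`.
#' @examples
#' x <- rlnorm(50); y <- rlnorm(50, meanlog = 0.8)
#' permutation_ks(x, y, n_perm = 999, seed = 1, alternative = "less")$p.value
#' @export
permutation_ks <- function(sample_a, sample_b, n_perm = 999, seed = NULL,
                           alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("both samples must have at least 2 observations")
  }
  if (n_perm < 999) stop("n_perm must be at least 999")
  if (!is.null(seed)) set.seed(seed)
  na <- length(sample_a); nb <- length(sample_b); n <- na + nb
  D_obs <- ks_distance(sample_a, sample_b, alternative)
  pooled <- c(sample_a, sample_b)
  ord <- order(pooled)
  ps <- pooled[ord]
  keep <- c(diff(ps) > 0, TRUE)
  rank_of <- integer(n); rank_of[ord] <- seq_len(n)
  exceed <- 0L
  for (r in seq_len(n_perm)) {
    idx_a <- sample.int(n, na)
    la <- logical(n)
    la[rank_of[idx_a]] <- TRUE # label vector in pooled sorted order
    Fa <- cumsum(la) / na
    Fb <- (seq_len(n) - cumsum(la)) / nb
    D <- switch(alternative,
                two_sided = max(abs(Fa[keep] - Fb[keep])),
                greater = max(Fb[keep] - Fa[keep]),
                less = max(Fa[keep] - Fb[keep]))
    if (D >= D_obs - 1e-12) exceed <- exceed + 1L
  }
  list(statistic = D_obs, p.value = (1 + exceed) / (n_perm + 1),
       n_perm = n_perm, alternative = alternative)
}

#' Maximum-likelihood lognormal fit
#'
#' For positive intervals, the lognormal MLE is the sample mean and the
#' population (divide-by-n) standard deviation of the log intervals.
#'
#' @param intervals positive values, at least 2.
#' @return List with `log_mean` and `log_sd`.
#' @examples
#' fit_lognormal(exp(c(2, 2, 2))) # log_mean 2, log_sd 0
#' @export
fit_lognormal <- function(intervals) {
  if (length(intervals) < 2) stop("need at least 2 intervals")
  if (any(intervals <= 0)) stop("all intervals must be positive")
  lx <- log(intervals)
  m <- mean(lx)
  list(log_mean = m, log_sd = sqrt(mean((lx - m)^2)))
}

#' Bernoulli GLM for termination probability by condition
#'
#' Models whether an event is a termination (vs an interruption) as a
#' Bernoulli GLM with a condition effect and fixed per-subject intercepts —
#' a fixed-effect approximation to a mixed-effects model that is standard at
#' small subject counts. With a single subject, this reduces to ordinary
#' logistic regression of outcome on condition.
#'
#' @param events event data frame with columns `subject`, `condition`,
#'   `kind` (values `"interruption"` / `"termination"`); typically
#'   `bout_table$events`, possibly row-bound across conditions.
#' @param reference condition treated as the baseline level (default: first
#'   condition in the data).
#' @return List with `coefficients` (data frame: condition, estimate
#'   (log-odds vs reference), se, z, p), `model` (the fitted [stats::glm()]),
#'   and `separation` (TRUE when the fit is degenerate; then a warning is
#'   issued and the coefficient is effectively unbounded).
#' @export
termination_glm <- function(events, reference = NULL) {
  stopifnot(all(c("subject", "condition", "kind") %in% names(events)))
  conds <- unique(events$condition)
  if (length(conds) < 2) stop("need at least 2 conditions")
  if (is.null(reference)) reference <- conds[1]
  d <- data.frame(y = as.integer(events$kind == "termination"),
                  condition = stats::relevel(factor(events$condition), reference),
                  subject = factor(events$subject))
  form <- if (nlevels(d$subject) > 1) y ~ condition + subject else y ~ condition
  fit <- suppressWarnings(stats::glm(form, data = d, family = stats::binomial()))
  cf <- summary(fit)$coefficients
  rows <- grep("^condition", rownames(cf))
  out <- data.frame(condition = sub("^condition", "", rownames(cf)[rows]),
                    estimate = cf[rows, 1], se = cf[rows, 2],
                    z = cf[rows, 3], p = cf[rows, 4])
  rownames(out) <- NULL
  separation <- any(abs(out$estimate) > 15 | out$se > 100) || !fit$converged
  if (separation) {
    warning("possible complete separation: condition coefficient is unbounded")
  }
  list(coefficients = out, model = fit, separation = separation)
}

#' Read / write annotation and bout tables
#'
#' Tabular text I/O (comma- or tab-delimited, header required). The delimiter
#' is sniffed from the header line.
#'
#' @param path file path.
#' @return `read_annotations()` returns the annotation data frame.
#' @export
read_annotations <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  ann <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  required <- c("subject", "condition", "label", "start", "stop")
  if (!all(required %in% names(ann))) {
    stop("annotation file must have columns: ", paste(required, collapse = ", "))
  }
  ann
}

#' @param ann annotation data frame.
#' @param sep field delimiter.
#' @rdname read_annotations
#' @export
write_annotations <- function(ann, path, sep = ",") {
  utils::write.table(ann, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param dir output directory.
#' @param prefix file-name prefix.
#' @rdname read_annotations
#' @export
read_bout_table <- function(dir, prefix = "bouts") {
  parts <- lapply(c("bouts", "events", "sessions"), function(part) {
    utils::read.table(file.path(dir, sprintf("%s_%s.tsv", prefix, part)),
                      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  })
  new_bout_table(parts[[1]], parts[[2]], parts[[3]])
}

#' @param bt a `bout_table`.
#' @rdname read_annotations
#' @export
write_bout_table <- function(bt, dir, prefix = "bouts") {
  stopifnot(inherits(bt, "bout_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (part in c("bouts", "events", "sessions")) {
    utils::write.table(bt[[part]],
                       file.path(dir, sprintf("%s_%s.tsv", prefix, part)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
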