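#' Steady-state inhibitory activity given E
#'
#' Solves \eqn{I = s(w_{EI} E - w_{II} I)} for the fast inhibitory variable.
#' For \eqn{w_{II} > 0} the residual \eqn{g(I) = I - s(\cdot)} is strictly
#' increasing, so the root is unique; it is bracketed on a conservative
#' interval and polished with [stats::uniroot()]. Vectorized over `E`.
#'
#' @param E excitatory activity (finite; any real value is accepted).
#' @param params a [model_params()] object.
#' @param tol residual tolerance (default well below 1e-10).
#' @return The steady-state inhibitory activity \eqn{\hat I(E)}, in (0, 1).
#' @export
solve_I_steady <- function(E, params = model_params(), tol = 1e-12) {
  if (!all(is.finite(E))) stop("E must be finite")
  g <- function(I, e) I - gain(params$w_EI * e - params$w_II * I,
                               params$a, params$theta)
  vapply(E, function(e) {
    # s maps into (0,1), so g(-eps) < 0 < g(1+eps); guard anyway
    lo <- -1e-9; hi <- 1 + 1e-9
    if (g(lo, e) > 0 || g(hi, e) < 0) stop("bracket failure in solve_I_steady")
    r <- stats::uniroot(g, c(lo, hi), e = e, tol = tol)$root
    if (abs(g(r, e)) > 1e-10) stop("solve_I_steady residual above tolerance")
    r
  }, numeric(1))
}

#' One-dimensional effective drift of E
#'
#' Quasi-static reduction: since `tau_I` is much smaller than `tau_E`, the
#' inhibitory variable is slaved to its E-conditional steady state
#' \eqn{\hat I(E)}, giving the scalar system
#' \deqn{\tau_E \dot E = -E + s(w_{EE} E - w_{IE} \hat I(E) + current).}
#'
#' @param E excitatory activity (vectorized).
#' @param params a [model_params()] object.
#' @return dE/dt values.
#' @export
effective_drift <- function(E, params = model_params()) {
  I_hat <- solve_I_steady(E, params)
  (-E + gain(params$w_EE * E - params$w_IE * I_hat + params$current,
             params$a, params$theta)) / params$tau_E
}

# Roots of the effective drift in [0, 1]: sign-change bracketing on a uniform
# grid, polished by uniroot. Returns E values sorted.
effective_drift_roots <- function(params, grid_size = 4096) {
  Eg <- seq(0, 1, length.out = grid_size)
  f <- effective_drift(Eg, params)
  sc <- which(diff(sign(f)) != 0)
  if (any(f == 0)) sc <- sort(unique(c(sc, which(f == 0))))
  roots <- vapply(sc, function(i) {
    stats::uniroot(effective_drift, c(Eg[i], Eg[min(i + 1, grid_size)]),
                   params = params, tol = 1e-12)$root
  }, numeric(1))
  roots <- sort(roots)
  if (length(roots) > 1) roots <- roots[c(TRUE, diff(roots) > 1e-6)]
  roots
}

#' Classify the 1-D fixed points of the effective drift
#'
#' Roots of [effective_drift()] with stability from the sign of its local
#' derivative: negative slope is stable, positive is unstable. In the bistable
#' regime the three roots are labeled `feeding` (lowest, stable), `threshold`
#' (unstable, the gate E_th) and `non-feeding` (highest, stable).
#'
#' @param params a [model_params()] object.
#' @param grid_size number of grid points used for bracketing.
#' @return Data frame with columns `E`, `stability`, `label`.
#' @export
classify_landscape <- function(params = model_params(), grid_size = 4096) {
  roots <- effective_drift_roots(params, grid_size)
  if (length(roots) > 3) {
    stop("more than 3 fixed points found; parameters outside the intended regime")
  }
  h <- 1e-6
  slope <- vapply(roots, function(r) {
    (effective_drift(r + h, params) - effective_drift(r - h, params)) / (2 * h)
  }, numeric(1))
  stability <- ifelse(slope < 0, "stable", "unstable")
  label <- rep(NA_character_, length(roots))
  if (length(roots) == 3 && identical(stability, c("stable", "unstable", "stable"))) {
    label <- c("feeding", "threshold", "non-feeding")
  } else if (length(roots) == 1 && stability == "stable") {
    label <- "monostable"
  }
  data.frame(E = roots, stability = stability, label = label)
}

#' Quasi-static potential landscape of the feeding/non-feeding system
#'
#' Computes the effective 1-D drift on a uniform E grid and its potential
#' \eqn{V(E) = -\int \dot E \, dE} by trapezoidal accumulation. When the
#' system is bistable, V is shifted so that \eqn{V(E_{th}) = 0} at the
#' unstable threshold; the barrier is the energy needed to leave the feeding
#' attractor, \eqn{V(E_{th}) - V(E_{feed}) = -V(E_{feed})}. When monostable,
#' V is zeroed at the global minimum and `bistable = FALSE`; downstream state
#' labeling refuses such landscapes.
#'
#' @param params a [model_params()] object.
#' @param grid_size number of grid points on [0, 1]; at least 256.
#' @return An object of class `wc_landscape`: list with `E_grid`, `I_hat`,
#'   `eff_drift`, `V`, `fixed_points` (data frame from [classify_landscape()]),
#'   `E_th`, `barrier`, `bistable`, and the `params` snapshot.
#' @examples
#' L <- compute_potential(model_params())
#' L$bistable
#' L$barrier
#' @export
compute_potential <- function(params = model_params(), grid_size = 4096) {
  if (grid_size < 256) stop("grid_size must be at least 256")
  Eg <- seq(0, 1, length.out = grid_size)
  I_hat <- solve_I_steady(Eg, params)
  f <- (-Eg + gain(params$w_EE * Eg - params$w_IE * I_hat + params$current,
                   params$a, params$theta)) / params$tau_E
  dE <- Eg[2] - Eg[1]
  V <- -c(0, cumsum((f[-1] + f[-grid_size]) / 2 * dE))
  fp <- classify_landscape(params, grid_size)
  n_stable <- sum(fp$stability == "stable")
  bistable <- nrow(fp) == 3 && n_stable == 2 && fp$stability[2] == "unstable"
  V_at <- function(E) stats::approx(Eg, V, E)$y
  if (bistable) {
    E_th <- fp$E[2]
    V <- V - V_at(E_th)
    barrier <- -stats::approx(Eg, V, fp$E[1])$y
  } else {
    E_th <- NA_real_
    V <- V - min(V)
    barrier <- NA_real_
  }
  structure(list(E_grid = Eg, I_hat = I_hat, eff_drift = f, V = V,
                 fixed_points = fp, E_th = E_th, barrier = barrier,
                 bistable = bistable, params = params),
            class = "wc_landscape")
}

#' @export
print.wc_landscape <- function(x, ...) {
  cat("Quasi-static potential landscape\n")
  cat(sprintf("  current = %g, grid = %d points\n",
              x$params$current, length(x$E_grid)))
  if (x$bistable) {
    cat(sprintf("  bistable: feeding E = %.5f, threshold E_th = %.5f, non-feeding E = %.5f\n",
                x$fixed_points$E[1], x$E_th, x$fixed_points$E[3]))
    cat(sprintf("  barrier (feeding -> threshold) = %.5f\n", x$barrier))
  } else {
    cat(sprintf("  monostable (%d fixed point%s); no threshold defined\n",
                nrow(x$fixed_points), if (nrow(x$fixed_points) == 1) "" else "s"))
  }
  invisible(x)
}

#' Export a landscape as tabular text
#'
#' Writes the grid profile (E, I_hat, eff_drift, V) as a tab-delimited table
#' preceded by commented summary lines (fixed points, barrier, current).
#'
#' @param landscape a `wc_landscape` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "wc_landscape"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# current: %g", landscape$params$current), con)
  writeLines(sprintf("# bistable: %s", landscape$bistable), con)
  fp <- landscape$fixed_points
  writeLines(sprintf("# fixed_point: E=%.8f stability=%s label=%s",
                     fp$E, fp$stability, fp$label), con)
  writeLines(sprintf("# barrier: %s",
                     format(landscape$barrier, digits = 8)), con)
  utils::write.table(
    data.frame(E = landscape$E_grid, I_hat = landscape$I_hat,
               eff_drift = landscape$eff_drift, V = landscape$V),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
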