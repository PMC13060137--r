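#' Wilson-Cowan model parameters
#'
#' Constructs the parameter set of the two-population Wilson-Cowan model used
#' throughout the package: an excitatory population E (slow, time constant
#' `tau_E`) and an inhibitory population I (fast, `tau_I`) coupled through
#' sigmoidal gains,
#' \deqn{\tau_E \dot E = -E + s(w_{EE} E - w_{IE} I + current)}
#' \deqn{\tau_I \dot I = -I + s(w_{EI} E - w_{II} I)}
#' with \eqn{s(x) = 1/(1 + e^{-a(x-\theta)})}. The defaults place the system
#' in a bistable regime with a low-E "feeding" attractor and a high-E
#' "non-feeding" attractor. A tonic `current` added inside the E gain emulates
#' optogenetic inhibition (negative) or activation (positive) of the pathway.
#'
#' @param tau_E,tau_I time constants, seconds.
#' @param w_EE,w_EI,w_IE,w_II dimensionless synaptic strengths. `w_XY` couples
#'   population Y into population X's gain argument.
#' @param a,theta gain slope and threshold.
#' @param current tonic input to the excitatory gain argument.
#' @param noise_sd diffusion amplitude of the additive Gaussian noise (the
#'   \eqn{\sigma} of \eqn{dX = f\,dt + \sigma\,dW}); used by [simulate_wc()].
#' @param dt Euler-Maruyama integration step, seconds. Must resolve the fast
#'   variable (`dt < tau_I`).
#' @return An object of class `model_params` (a validated named list).
#' @examples
#' p <- model_params()
#' p$tau_E
#' model_params(current = -0.7) # tonic inhibition preset value
#' @export
model_params <- function(tau_E = 2, tau_I = 0.4,
                         w_EE = 15, w_EI = 10, w_IE = 10, w_II = 15,
                         a = 1, theta = 8,
                         current = 0, noise_sd = 0.1055, dt = 0.02) {
  p <- list(tau_E = tau_E, tau_I = tau_I,
            w_EE = w_EE, w_EI = w_EI, w_IE = w_IE, w_II = w_II,
            a = a, theta = theta, current = current,
            noise_sd = noise_sd, dt = dt)
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) stop("model parameter '", nm, "' must be a single finite number")
  }
  if (p$tau_E <= 0) stop("tau_E must be > 0")
  if (p$tau_I <= 0) stop("tau_I must be > 0")
  if (p$dt <= 0) stop("dt must be > 0")
  if (p$dt >= p$tau_I) stop("dt must be smaller than tau_I to resolve the fast variable")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (p$a <= 0) stop("gain slope a must be > 0")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Wilson-Cowan model parameters\n")
  cat(sprintf("  tau_E = %g s, tau_I = %g s, dt = %g s\n", x$tau_E, x$tau_I, x$dt))
  cat(sprintf("  w_EE = %g, w_EI = %g, w_IE = %g, w_II = %g\n",
              x$w_EE, x$w_EI, x$w_IE, x$w_II))
  cat(sprintf("  gain: a = %g, theta = %g\n", x$a, x$theta))
  cat(sprintf("  current = %g, noise_sd = %g\n", x$current, x$noise_sd))
  invisible(x)
}

#' Sigmoidal population gain
#'
#' \eqn{s(x) = 1/(1 + e^{-a(x - \theta)})}: strictly increasing, limits 0 and
#' 1, value 1/2 at `x = theta`. Both populations share this gain.
#'
#' @param x input (any real; vectorized).
#' @param a slope, must be positive.
#' @param theta threshold.
#' @return Activation values in (0, 1).
#' @examples
#' gain(8, 1, 8)          # 0.5
#' gain(8 + log(3), 1, 8) # 0.75
#' @export
gain <- function(x, a = 1, theta = 8) {
  if (!all(is.finite(x))) stop("gain input must be finite")
  if (a <= 0) stop("gain slope a must be > 0")
  1 / (1 + exp(-a * (x - theta)))
}

#' Deterministic drift field of the Wilson-Cowan system
#'
#' Evaluates (dE/dt, dI/dt) at a state. The tonic `current` enters only inside
#' the excitatory gain argument. Vectorized over states.
#'
#' @param E,I state values (equal-length vectors).
#' @param params a [model_params()] object.
#' @return A list with components `dE` and `dI`.
#' @export
wc_drift <- function(E, I, params = model_params()) {
  if (!all(is.finite(E), is.finite(I))) stop("state must be finite")
  dE <- (-E + gain(params$w_EE * E - params$w_IE * I + params$current,
                   params$a, params$theta)) / params$tau_E
  dI <- (-I + gain(params$w_EI * E - params$w_II * I,
                   params$a, params$theta)) / params$tau_I
  list(dE = dE, dI = dI)
}

#' Jacobian of the drift field at a state
#'
#' @inheritParams wc_drift
#' @return 2x2 matrix of partial derivatives, rows (dE, dI), columns (E, I).
#' @keywords internal
wc_jacobian <- function(E, I, params = model_params()) {
  a <- params$a
  sE <- gain(params$w_EE * E - params$w_IE * I + params$current, a, params$theta)
  sI <- gain(params$w_EI * E - params$w_II * I, a, params$theta)
  dsE <- a * sE * (1 - sE)
  dsI <- a * sI * (1 - sI)
  matrix(c((-1 + dsE * params$w_EE) / params$tau_E,
           dsI * params$w_EI / params$tau_I,
           -dsE * params$w_IE / params$tau_E,
           (-1 - dsI * params$w_II) / params$tau_I),
         nrow = 2,
         dimnames = list(c("dE", "dI"), c("E", "I")))
}

#' Fixed points of the two-dimensional system
#'
#' Finds all steady states of the deterministic drift in the unit square.
#' Because the inhibitory steady state is unique given E (the map
#' \eqn{I \mapsto I - s(w_{EI}E - w_{II}I)} is strictly increasing for
#' \eqn{w_{II} > 0}), every 2-D fixed point lies on the curve
#' \eqn{I = \hat I(E)}; roots of the 1-D effective drift seed a damped Newton
#' polish of the full 2-D field. Stability is labeled from the eigenvalues of
#' the local Jacobian.
#'
#' @param params a [model_params()] object.
#' @param grid_size number of E-grid points used to bracket roots.
#' @param tol tolerance on the 2-D drift norm after polishing.
#' @return A data frame with columns `E`, `I`, `stability`
#'   (`"stable"`, `"unstable"` or `"saddle"`), and eigenvalue real parts
#'   `re1`, `re2`.
#' @examples
#' fp <- find_fixed_points(model_params())
#' fp$stability # two stable states separated by a saddle/unstable point
#' @export
find_fixed_points <- function(params = model_params(), grid_size = 4096,
                              tol = 1e-10) {
  E_roots <- effective_drift_roots(params, grid_size)
  pts <- lapply(E_roots, function(E0) {
    x <- c(E0, solve_I_steady(E0, params))
    for (iter in 1:100) {
      d <- wc_drift(x[1], x[2], params)
      f <- c(d$dE, d$dI)
      if (sqrt(sum(f^2)) < tol) break
      J <- wc_jacobian(x[1], x[2], params)
      step <- solve(J, -f)
      lambda <- 1
      repeat { # damped step: require drift norm to not blow up
        xn <- x + lambda * step
        dn <- wc_drift(xn[1], xn[2], params)
        if (sqrt(dn$dE^2 + dn$dI^2) <= sqrt(sum(f^2)) || lambda < 1e-4) break
        lambda <- lambda / 2
      }
      x <- x + lambda * step
    }
    d <- wc_drift(x[1], x[2], params)
    if (sqrt(d$dE^2 + d$dI^2) >= tol) {
      stop(sprintf("fixed-point polishing failed to converge from seed E = %.6g", E0))
    }
    x
  })
  # deduplicate: pairwise distance > 1e-6
  keep <- rep(TRUE, length(pts))
  if (length(pts) > 1) {
    for (i in seq_along(pts)[-1]) {
      for (j in seq_len(i - 1)) {
        if (keep[j] && sqrt(sum((pts[[i]] - pts[[j]])^2)) <= 1e-6) keep[i] <- FALSE
      }
    }
  }
  pts <- pts[keep]
  res <- do.call(rbind, lapply(pts, function(x) {
    ev <- eigen(wc_jacobian(x[1], x[2], params), only.values = TRUE)$values
    re <- sort(Re(ev))
    stab <- if (all(re < 0)) "stable" else if (all(re > 0)) "unstable" else "saddle"
    data.frame(E = x[1], I = x[2], stability = stab, re1 = re[1], re2 = re[2])
  }))
  res[order(res$E), , drop = FALSE]
}
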