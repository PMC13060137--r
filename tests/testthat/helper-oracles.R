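# Independent brute-force oracles, kept deliberately separate from the
# package's own solvers.

# Sigmoid, written out independently of gain()
sig <- function(x, a = 1, th = 8) 1 / (1 + exp(-a * (x - th)))

# Steady-state I by bisection directly on the raw 2-D dI/dt sign, per E value
# (does not call solve_I_steady).
oracle_I_steady <- function(E, p = model_params()) {
  vapply(E, function(e) {
    lo <- 0; hi <- 1
    for (k in 1:200) {
      m <- (lo + hi) / 2
      if (m - sig(p$w_EI * e - p$w_II * m, p$a, p$theta) > 0) hi <- m else lo <- m
    }
    (lo + hi) / 2
  }, numeric(1))
}

# Count/locate roots of the reduced E dynamics by dense sign-change scan over
# the raw 2-D drift field restricted to the I-nullcline.
oracle_E_roots <- function(p = model_params(), n_grid = 2000) {
  Eg <- seq(0, 1, length.out = n_grid)
  f <- -Eg + sig(p$w_EE * Eg - p$w_IE * oracle_I_steady(Eg, p) + p$current,
                 p$a, p$theta)
  sc <- which(diff(sign(f)) != 0)
  vapply(sc, function(i) {
    lo <- Eg[i]; hi <- Eg[i + 1]
    for (k in 1:200) {
      m <- (lo + hi) / 2
      fm <- -m + sig(p$w_EE * m - p$w_IE * oracle_I_steady(m, p) + p$current,
                     p$a, p$theta)
      if (sign(fm) == sign(f[i])) lo <- m else hi <- m
    }
    (lo + hi) / 2
  }, numeric(1))
}

# Forward-Euler of the noiseless 2-D system (independent of simulate_wc)
oracle_integrate_2d <- function(E0, I0, p, duration, dt = p$dt) {
  n <- round(duration / dt)
  E <- numeric(n + 1); I <- numeric(n + 1)
  E[1] <- E0; I[1] <- I0
  for (k in 1:n) {
    E[k + 1] <- E[k] + dt * (-E[k] + sig(p$w_EE * E[k] - p$w_IE * I[k] + p$current,
                                         p$a, p$theta)) / p$tau_E
    I[k + 1] <- I[k] + dt * (-I[k] + sig(p$w_EI * E[k] - p$w_II * I[k],
                                         p$a, p$theta)) / p$tau_I
  }
  list(E = E, I = I, t = (0:n) * dt)
}

# Frozen regression fixtures, computed with long-run independent iterations:
# I = s(-w_II I) solved by 1e6 damped fixed-point iterations, and the default
# 1-D roots from a 20001-point scan with per-point bisection.
IHAT0_FIXTURE <- 0.00033367640625
DEFAULT_ROOTS_FIXTURE <- c(0.0003359174, 0.5950775894, 0.9912230675)
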