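# Shared fixtures and independent oracles, built in code at test time.

# a clean double-sigmoid EVI series at the 46 composite dates
make_sigmoid_series <- function(V_b = 0.15, V_a = 0.55, p = 0.12, D_i = 160,
                                q = 0.10, D_d = 250, noise_sd = 0,
                                doy = doy_composites()) {
  evi <- double_sigmoid(doy, V_b, V_a, p, D_i, q, D_d)
  if (noise_sd > 0) evi <- evi + rnorm(length(doy), 0, noise_sd)
  data.frame(doy = doy, evi = evi)
}

# independent oracle for the transition dates: locate the extrema of the
# numerical second derivative (central differences, dense grid) of a fitted
# curve, searching each limb's half of the season separately
numeric_transition_dates <- function(fit, step = 0.02, h = 0.1) {
  par <- fit$par
  f <- function(t) predict(fit, t)
  d2 <- function(t) (f(t + h) - 2 * f(t) + f(t - h)) / h^2
  argext <- function(lo, hi, maximize) {
    g <- seq(lo, hi, by = step)
    v <- d2(g)
    g[if (maximize) which.max(v) else which.min(v)]
  }
  mid <- (par["D_i"] + par["D_d"]) / 2
  span <- 4 / par["p"]
  span_q <- 4 / par["q"]
  c(D_1 = unname(argext(par["D_i"] - span, par["D_i"], TRUE)),
    D_2 = unname(argext(par["D_i"], min(par["D_i"] + span, mid), FALSE)),
    D_3 = unname(argext(max(par["D_d"] - span_q, mid), par["D_d"], FALSE)),
    D_4 = unname(argext(par["D_d"], par["D_d"] + span_q, TRUE)))
}

# crop-plausible random curve parameters, well inside the fitting bounds.
# min_sep constrains the limb separation S = min(p, q) * (D_d - D_i): the
# limbs' mutual overlap scales as exp(-S), and the per-limb closed forms for
# the transition dates are only exact up to that overlap (second-derivative
# extrema are quartically flat, so they are displaced by residual overlap).
# S >= 6 keeps the curve crop-like; S >= 10 makes the closed forms valid at
# the 0.05-day level.
random_curve_params <- function(min_sep = 6) {
  repeat {
    par <- c(V_b = runif(1, 0.05, 0.25), V_a = runif(1, 0.3, 0.8),
             p = runif(1, 0.06, 0.25), D_i = runif(1, 130, 190),
             q = runif(1, 0.06, 0.25), D_d = runif(1, 230, 290))
    S <- min(par["p"], par["q"]) * (par["D_d"] - par["D_i"])
    if (S >= min_sep) return(par)
  }
}

# small, fast simulation configuration for unit tests
small_config <- function(seed = 11, ...) {
  sim_config(seed = seed, fine_dim = c(128L, 128L), county_grid = c(2L, 2L), ...)
}
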