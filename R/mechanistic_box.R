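# Two-compartment near-field/far-field mass-balance model.
#
# Topology: a single source in the near field (NF), an air-exchange flow
# beta between NF and far field (FF), and general ventilation Q exhausting
# from the FF only. Local exhaust captures a fraction of the emission at
# the source before it reaches the room air. The system is linear:
#
#   V_nf dC_nf/dt = G' + beta (C_ff - C_nf)
#   V_ff dC_ff/dt = beta (C_nf - C_ff) - Q C_ff
#
# with G' = G (1 - lev_efficiency).

#' Two-compartment model parameters
#'
#' @param V_nf Near-field volume, m\eqn{^3} (> 0).
#' @param V_ff Far-field volume, m\eqn{^3} (> 0).
#' @param Q General ventilation flow through the far field,
#'   m\eqn{^3} min\eqn{^{-1}} (>= 0).
#' @param beta NF--FF air exchange flow, m\eqn{^3} min\eqn{^{-1}} (> 0).
#' @param G Emission rate, mg min\eqn{^{-1}}: either a single non-negative
#'   number (constant source) or a function of time returning a
#'   non-negative rate (piecewise-constant profiles supported).
#' @param C0_nf,C0_ff Initial concentrations, mg m\eqn{^{-3}} (>= 0).
#' @param lev_efficiency Fraction of the emission captured at the source by
#'   local exhaust ventilation, in \[0, 1\].
#' @return A validated list of class `two_compartment_params`.
#' @export
two_compartment_params <- function(V_nf, V_ff, Q, beta, G,
                                   C0_nf = 0, C0_ff = 0,
                                   lev_efficiency = 0) {
  stopifnot(is.numeric(V_nf), V_nf > 0, is.numeric(V_ff), V_ff > 0,
            is.numeric(Q), Q >= 0, is.numeric(beta), beta > 0,
            is.numeric(C0_nf), C0_nf >= 0, is.numeric(C0_ff), C0_ff >= 0,
            is.numeric(lev_efficiency),
            lev_efficiency >= 0, lev_efficiency <= 1)
  if (is.function(G)) {
    Gfun <- G
  } else {
    stopifnot(is.numeric(G), length(G) == 1, G >= 0)
    Gfun <- NULL
  }
  structure(list(V_nf = V_nf, V_ff = V_ff, Q = Q, beta = beta, G = G,
                 Gfun = Gfun, C0_nf = C0_nf, C0_ff = C0_ff,
                 lev_efficiency = lev_efficiency),
            class = "two_compartment_params")
}

#' @export
print.two_compartment_params <- function(x, ...) {
  g <- if (is.function(x$G)) "time-varying" else paste0(x$G, " mg/min")
  cat("<two_compartment_params>\n")
  cat(sprintf("  V_nf = %g m3, V_ff = %g m3\n", x$V_nf, x$V_ff))
  cat(sprintf("  Q = %g m3/min, beta = %g m3/min\n", x$Q, x$beta))
  cat(sprintf("  G = %s, LEV efficiency = %g\n", g, x$lev_efficiency))
  invisible(x)
}

.effective_G <- function(p, t = 0) {
  g <- if (is.function(p$G)) p$G(t) else p$G
  g * (1 - p$lev_efficiency)
}

#' Steady-state concentrations of the two-compartment model
#'
#' For a constant source with effective emission
#' \eqn{G' = G(1 - \eta_{lev})}:
#' \deqn{C_{ff}^{ss} = G'/Q, \qquad
#'       C_{nf}^{ss} = G'/Q + G'/\beta.}
#'
#' @param p A `two_compartment_params` with constant `G`.
#' @return Named numeric vector `c(C_nf = ..., C_ff = ...)`,
#'   mg m\eqn{^{-3}}.
#' @examples
#' p <- two_compartment_params(V_nf = 1, V_ff = 29, Q = 1, beta = 5, G = 10)
#' steady_state(p)  # C_nf 12, C_ff 10
#' @export
steady_state <- function(p) {
  stopifnot(inherits(p, "two_compartment_params"))
  if (is.function(p$G)) stop("steady_state requires a constant emission rate")
  Geff <- .effective_G(p)
  if (Geff == 0) return(c(C_nf = 0, C_ff = 0))
  if (p$Q == 0) stop("no steady state exists: Q = 0 with a positive source")
  c(C_nf = Geff / p$Q + Geff / p$beta, C_ff = Geff / p$Q)
}

#' Simulate the transient two-compartment concentrations
#'
#' Integrates the coupled NF/FF mass balances with an adaptive
#' stiff-capable solver (relative tolerance 1e-8). For constant emission
#' the series converges to [steady_state()] as `t` grows.
#'
#' @param p A `two_compartment_params`.
#' @param t_end End of the simulation window, min (> 0).
#' @param dt Output grid spacing, min (> 0).
#' @return A data frame of class `concentration_series` with columns
#'   `time` (min), `C_nf`, `C_ff` (mg m\eqn{^{-3}}).
#' @export
simulate_transient <- function(p, t_end, dt) {
  stopifnot(inherits(p, "two_compartment_params"),
            is.numeric(t_end), t_end > 0, is.numeric(dt), dt > 0)
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  deriv <- function(t, y, parms) {
    Geff <- .effective_G(p, t)
    dnf <- (Geff + p$beta * (y[2] - y[1])) / p$V_nf
    dff <- (p$beta * (y[1] - y[2]) - p$Q * y[2]) / p$V_ff
    list(c(dnf, dff))
  }
  sol <- deSolve::lsoda(y = c(p$C0_nf, p$C0_ff), times = times,
                        func = deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-12)
  out <- data.frame(time = sol[, 1],
                    C_nf = pmax(sol[, 2], 0),
                    C_ff = pmax(sol[, 3], 0))
  class(out) <- c("concentration_series", "data.frame")
  out
}

#' Time-weighted average concentration over a window
#'
#' Trapezoidal mean of each compartment's concentration over
#' `[window[1], window[2]]`; window endpoints are interpolated linearly
#' onto the series grid.
#'
#' @param s A `concentration_series`.
#' @param window Numeric length-2 vector `(t0, t1)` within the series
#'   range, `t0 < t1`.
#' @return Named vector `c(C_nf = ..., C_ff = ...)`, mg m\eqn{^{-3}}.
#' @export
time_weighted_average <- function(s, window) {
  stopifnot(inherits(s, "concentration_series"),
            length(window) == 2)
  t0 <- window[1]; t1 <- window[2]
  if (!(t0 < t1)) stop("empty averaging window")
  if (t0 < min(s$time) || t1 > max(s$time)) {
    stop("averaging window outside the simulated time range")
  }
  avg <- function(col) {
    tt <- sort(unique(c(t0, t1, s$time[s$time > t0 & s$time < t1])))
    cc <- stats::approx(s$time, col, xout = tt)$y
    sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2) /
      (t1 - t0)
  }
  c(C_nf = avg(s$C_nf), C_ff = avg(s$C_ff))
}

#' Tiered worst-case/central parametrization
#'
#' Builds a `two_compartment_params` from plausible parameter ranges under
#' the tiered-assessment convention that a lower tier must be more
#' conservative: tier 1 takes the exposure-maximizing end of every range
#' (minimum ventilation `Q`, minimum inter-zonal flow `beta`, maximum
#' emission `G`, no local-exhaust credit), tier 2 takes central
#' (geometric-mean) values. By monotonicity of
#' \eqn{G'/Q + G'/\beta} this guarantees
#' `steady_state(tier 1) >= steady_state(tier 2)` componentwise.
#'
#' @param ranges A list with numeric length-2 elements `Q`, `beta`, `G`
#'   (each `c(low, high)` with `low <= high` and positive), scalar or
#'   length-2 `V_nf`, `V_ff`, and optionally `lev_efficiency`
#'   (`c(low, high)` in \[0,1\]).
#' @param tier 1 (worst case) or 2 (central).
#' @return A `two_compartment_params`.
#' @export
tiered_params <- function(ranges, tier) {
  stopifnot(tier %in% c(1, 2))
  need <- c("Q", "beta", "G")
  for (nm in need) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) < 1 || any(!is.finite(r))) {
      stop("range for '", nm, "' missing or empty")
    }
  }
  pick <- function(r, maximize) {
    r <- range(as.numeric(r))
    if (tier == 1) {
      if (maximize) r[2] else r[1]
    } else {
      exp(mean(log(pmax(r, .Machine$double.eps))))
    }
  }
  lev_r <- ranges$lev_efficiency
  if (is.null(lev_r)) lev_r <- c(0, 0)
  mid <- function(r) if (length(r) == 2) mean(range(r)) else as.numeric(r)
  two_compartment_params(
    V_nf = mid(ranges$V_nf %||% 8),
    V_ff = mid(ranges$V_ff %||% 100),
    Q = pick(ranges$Q, maximize = FALSE),
    beta = pick(ranges$beta, maximize = FALSE),
    G = pick(ranges$G, maximize = TRUE),
    lev_efficiency = if (tier == 1) 0 else mean(range(lev_r))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare simulated concentrations with observations
#'
#' Interpolates the simulated series onto the observation times and reports
#' log-scale residuals, geometric-mean bias (predicted/observed), and the
#' fraction of predictions within a factor of two of the observations.
#' Non-positive observations cannot be log-transformed and are excluded
#' with a warning count.
#'
#' @param p A `two_compartment_params` (simulated over the observation
#'   span), or a ready-made `concentration_series`.
#' @param observed A data frame with columns `time` and `C_obs`
#'   (mg m\eqn{^{-3}}); compared against the near-field channel by default.
#' @param compartment `"C_nf"` or `"C_ff"`.
#' @return A list of class `box_fit_report`: `log_residuals`
#'   (ln predicted - ln observed), `bias` (geometric mean of
#'   predicted/observed), `within_factor2`, `n_used`, `n_excluded`.
#' @export
external_validation <- function(p, observed, compartment = "C_nf") {
  stopifnot(compartment %in% c("C_nf", "C_ff"),
            is.data.frame(observed),
            all(c("time", "C_obs") %in% names(observed)))
  if (inherits(p, "two_compartment_params")) {
    tmax <- max(observed$time)
    sim <- simulate_transient(p, t_end = tmax,
                              dt = max(tmax / 500, 1e-3))
  } else if (inherits(p, "concentration_series")) {
    sim <- p
  } else stop("p must be two_compartment_params or a concentration_series")

  keep <- observed$C_obs > 0
  n_excl <- sum(!keep)
  if (n_excl > 0) warning(n_excl, " non-positive observation(s) excluded")
  obs <- observed[keep, , drop = FALSE]
  if (nrow(obs) == 0) stop("no positive observations to compare against")
  pred <- stats::approx(sim$time, sim[[compartment]], xout = obs$time)$y
  if (any(!is.finite(pred)) || any(pred <= 0)) {
    stop("simulated concentrations are non-positive at observation times")
  }
  lr <- log(pred) - log(obs$C_obs)
  structure(list(log_residuals = lr,
                 bias = exp(mean(lr)),
                 within_factor2 = mean(abs(lr) <= log(2)),
                 n_used = nrow(obs),
                 n_excluded = n_excl),
            class = "box_fit_report")
}

#' @export
print.box_fit_report <- function(x, ...) {
  cat("<box_fit_report>\n")
  cat(sprintf("  n = %d (excluded %d)\n", x$n_used, x$n_excluded))
  cat(sprintf("  geometric-mean bias (pred/obs): %.3g\n", x$bias))
  cat(sprintf("  within factor 2: %.1f%%\n", 100 * x$within_factor2))
  invisible(x)
}
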