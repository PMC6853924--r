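# Deterministic trajectory models for a selected subclone and its neutral
# hitch-hikers.
#
# Subclone fixation (two competing exponentials, equal initial sizes):
#   x(t) = e^{st} / (e^t + e^{st})
# Adaptive-mutation trajectory after establishment at frequency 1/(2Ns):
#   n(t) = e^{st} / (e^{st} + 2Ns)
# Frequency of the i-th neutral hitch-hiker on the sweeping clone:
#   n_i(t) = e^{-mu t} * (mu / (i s))^{1 - mu/s},  i >= 1,  0 < mu <= s
#
# All forms are evaluated in log space so large s*t never overflows.

#' Parameters of a selective sweep
#'
#' @param s relative fitness (growth-rate ratio) of the sweeping subclone,
#'   unitless, > 0; `s = 1` is neutral.
#' @param N constant population size in cells.
#' @param mu rate at which neutral mutations arise on the sweeping clone, per
#'   generation; must satisfy `0 < mu <= s` for the hitch-hiker model.
#' @param t time in generations (optional; filled per use).
#' @param t_sc generation at which the subclone arose.
#' @param f0 initial subclone fraction in `(0, 1)` for the generalized
#'   fixation model.
#' @return An object of class `sweep_params`.
#' @export
sweep_params <- function(s = 2, N = 1e6, mu = 1e-3, t = NA_real_,
                         t_sc = 0, f0 = 0.5) {
  stopifnot(s > 0, N >= 1, mu >= 0, f0 > 0, f0 < 1)
  structure(list(s = s, N = N, mu = mu, t = t, t_sc = t_sc, f0 = f0),
            class = "sweep_params")
}

#' Subclone fraction under competition with the host tumor
#'
#' `x(t) = e^{st} / (e^t + e^{st})`, i.e. two exponentially growing
#' populations of equal initial size (`x(0) = 0.5`). Computed as
#' `plogis((s - 1) t)` for numerical stability.
#'
#' @param s relative fitness (vectorized).
#' @param t time in generations (vectorized).
#' @return Fraction in `[0, 1]`.
#' @export
subclone_fraction <- function(s, t) {
  plogis((s - 1) * t)
}

#' Generalized subclone fraction with arbitrary origin time and size
#'
#' `f0 e^{s(t - t_sc)} / ((1 - f0) e^{(t - t_sc)} + f0 e^{s(t - t_sc)})`.
#' Reduces to [subclone_fraction()] when `f0 = 0.5`, `t_sc = 0`.
#'
#' @param s relative fitness.
#' @param t time in generations; must satisfy `t >= t_sc`.
#' @param t_sc generation at which the subclone arose.
#' @param f0 subclone fraction at `t = t_sc`, in `(0, 1)`.
#' @return Fraction in `[0, 1]`.
#' @export
subclone_fraction_general <- function(s, t, t_sc = 0, f0 = 0.5) {
  if (any(t < t_sc)) stop("t must be >= t_sc")
  stopifnot(all(f0 > 0), all(f0 < 1))
  tau <- t - t_sc
  plogis((s - 1) * tau + log(f0 / (1 - f0)))
}

#' Fixation grid over fitness and subclone origin time
#'
#' Evaluates [subclone_fraction_general()] at `tumor_age` for every
#' combination of `s_values` and `t_sc_values` and flags fixation as a
#' subclone fraction exceeding `fixation_ccf` (the clonality threshold).
#'
#' @param s_values vector of fitness values.
#' @param t_sc_values vector of subclone origin generations.
#' @param tumor_age tumor age in generations; must exceed `max(t_sc_values)`.
#' @param f0 initial subclone fraction at origin.
#' @param fixation_ccf fixation threshold (default 0.95).
#' @return A tibble with columns `s`, `t_sc`, `fraction`, `fixed`.
#' @export
fixation_grid <- function(s_values, t_sc_values, tumor_age, f0 = 0.5,
                          fixation_ccf = 0.95) {
  if (tumor_age <= max(t_sc_values)) stop("tumor_age must exceed max(t_sc_values)")
  grid <- expand.grid(s = s_values, t_sc = t_sc_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$fraction <- subclone_fraction_general(grid$s, tumor_age, grid$t_sc, f0)
  grid$fixed <- grid$fraction > fixation_ccf
  tibble::as_tibble(grid)
}

#' Establishment frequency of a beneficial variant
#'
#' `1 / (2 N s)`: the population frequency beyond which a fit variant
#' escapes stochastic loss.
#'
#' @param N population size.
#' @param s fitness.
#' @return Fraction.
#' @export
establishment_frequency <- function(N, s) {
  if (any(N * s <= 0)) stop("N * s must be > 0")
  1 / (2 * N * s)
}

#' Adaptive-mutation frequency trajectory
#'
#' Logistic growth from the establishment frequency:
#' `n(t) = e^{st} / (e^{st} + 2Ns)`, computed as `plogis(st - log(2Ns))`.
#'
#' @param s fitness.
#' @param t time in generations.
#' @param N population size.
#' @return Frequency in `[0, 1]`.
#' @export
adaptive_frequency <- function(s, t, N) {
  if (any(N * s <= 0)) stop("N * s must be > 0")
  plogis(s * t - log(2 * N * s))
}

#' Frequency of the i-th hitch-hiking passenger mutation
#'
#' `n_i(t) = e^{-mu t} (mu / (i s))^{1 - mu/s}` for `i >= 1`, clipped to
#' `[0, 1]`. The expression is outside its stated regime when `mu > s`
#' (the exponent changes sign), which is an error.
#'
#' @param i passenger index (integer >= 1, vectorized).
#' @param t time in generations.
#' @param s fitness of the sweeping subclone.
#' @param mu neutral mutation rate on the sweeping clone; `0 < mu <= s`.
#' @return Frequency in `[0, 1]`.
#' @export
passenger_frequency <- function(i, t, s, mu) {
  if (any(i < 1)) stop("passenger index i must be >= 1")
  if (any(mu <= 0) || any(mu > s)) stop("hitch-hiker model requires 0 < mu <= s")
  logv <- -mu * t + (1 - mu / s) * (log(mu) - log(i * s))
  pmin(pmax(exp(logv), 0), 1)
}

#' Time for the driver to reach a target frequency
#'
#' Solves `adaptive_frequency(s, t, N) = target` for `t >= 0` by bisection
#' (Brent's method, tolerance 1e-10). A target at or below the frequency at
#' `t = 0` (`1 / (1 + 2Ns)`) is unattainable and raises an error; a target of
#' exactly 1 is replaced by `1 - 1e-9` with a warning.
#'
#' @param s fitness.
#' @param N population size.
#' @param target driver frequency in `(0, 1]`.
#' @return Time in generations.
#' @export
solve_sweep_time <- function(s, N, target) {
  stopifnot(length(target) == 1, target > 0, target <= 1)
  if (target >= 1) {
    warning("driver frequency 1 is an asymptote; using 1 - 1e-9")
    target <- 1 - 1e-9
  }
  if (target <= 1 / (1 + 2 * N * s)) {
    stop("target driver frequency is at or below the establishment frequency")
  }
  upper <- (qlogis(target) + log(2 * N * s)) / s  # exact under the logistic form
  upper <- max(upper * 1.5, upper + 1)
  uniroot(function(t) adaptive_frequency(s, t, N) - target,
          lower = 0, upper = upper, tol = 1e-10)$root
}

#' Simulate a sweep frequency spectrum
#'
#' Deterministic driver + hitch-hiker spectrum at the moment the driver
#' reaches `stop_at_driver_ccf`: the observation time is solved with
#' [solve_sweep_time()] and the passenger frequencies are
#' `passenger_frequency(i, t_obs, s, mu)` for `i = 1..n_passengers`.
#' Randomness enters only downstream, in the read-count layer of
#' [simulate_tumor()].
#'
#' @param params a [sweep_params()] object.
#' @param n_passengers number of hitch-hiker classes to report.
#' @param stop_at_driver_ccf driver frequency at observation, in `(0, 1]`.
#' @return An object of class `sweep_spectrum`: list with `driver_freq`,
#'   `passenger_freqs` (non-increasing in `i`), `t_obs`, `params`.
#' @export
simulate_sweep_spectrum <- function(params, n_passengers = 100,
                                    stop_at_driver_ccf = 0.99) {
  stopifnot(inherits(params, "sweep_params"))
  t_obs <- solve_sweep_time(params$s, params$N, stop_at_driver_ccf)
  structure(
    list(driver_freq = adaptive_frequency(params$s, t_obs, params$N),
         passenger_freqs = passenger_frequency(seq_len(n_passengers), t_obs,
                                               params$s, params$mu),
         t_obs = t_obs,
         params = params),
    class = "sweep_spectrum"
  )
}

#' @export
print.sweep_spectrum <- function(x, ...) {
  cat(sprintf("<sweep_spectrum> s = %.3g, mu = %.3g, N = %.3g: driver %.4f at t = %.2f generations; %d hitch-hikers (n_1 = %.3g)\n",
              x$params$s, x$params$mu, x$params$N, x$driver_freq, x$t_obs,
              length(x$passenger_freqs), x$passenger_freqs[1]))
  invisible(x)
}
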