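#' Double-Hill ventricular driver function
#'
#' Normalised activation waveform e(t) of the time-varying ventricular
#' elastance: the product of a Hill-type contraction term and a Hill-type
#' relaxation term,
#' \deqn{e(t) = k \frac{(t/\alpha_1 T)^{n_1}}{1+(t/\alpha_1 T)^{n_1}}
#'              \frac{1}{1+(t/\alpha_2 T)^{n_2}}.}
#' The scale `k` is not a free parameter: it is set so that the maximum of
#' e over the cycle equals one, making `E_es` the true maximal elastance
#' (see [hill_norm_k()]).
#'
#' @param t time since ventricular activation (s); vectorised, non-negative.
#' @param params ventricle parameter block with elements `a1`, `a2`, `n1`,
#'   `n2` and the heart period is passed via `T`.
#' @param T heart period (s).
#' @param k driver scale; `NULL` (default) normalises the peak to 1.
#' @return driver values in \[0, 1\].
#' @export
driver_double_hill <- function(t, params, T, k = NULL) {
  if (any(t < 0)) stop("t must be >= 0 (time since activation)")
  if (is.null(k)) k <- hill_norm_k(params, T)
  x1 <- (t / (params$a1 * T))^params$n1
  x2 <- (t / (params$a2 * T))^params$n2
  k * (x1 / (1 + x1)) * (1 / (1 + x2))
}

#' Normalising scale of the double-Hill driver
#'
#' Returns k such that the peak of the raw double-Hill product over one
#' cycle equals 1.  Evaluated on a fine grid followed by local refinement;
#' the driver is smooth and unimodal so this is accurate to ~1e-10.
#'
#' @inheritParams driver_double_hill
#' @return scalar k > 1.
#' @export
hill_norm_k <- function(params, T = 1.0) {
  raw <- function(t) {
    x1 <- (t / (params$a1 * T))^params$n1
    x2 <- (t / (params$a2 * T))^params$n2
    (x1 / (1 + x1)) * (1 / (1 + x2))
  }
  g <- seq(0, T, length.out = 512)
  i <- which.max(raw(g))
  lo <- g[max(1, i - 1)]; hi <- g[min(length(g), i + 1)]
  opt <- stats::optimize(raw, c(lo, hi), maximum = TRUE, tol = 1e-12)
  1 / opt$objective
}

#' Instantaneous ventricular pressure
#'
#' Combination of the linear end-systolic and exponential end-diastolic
#' pressure-volume relationships, weighted by the driver:
#' \deqn{P(V,t) = e(t) E_{es} (V - V_d) +
#'   (1 - e(t)) P_0 (e^{\lambda (V - V_0)} - 1).}
#'
#' @param V ventricular volume (mL), > 0; vectorised with `t`.
#' @param t time since ventricular activation (s).
#' @param params ventricle block of a [cvs_params()] object (fields `E_es`,
#'   `V_d`, `P_0`, `lambda`, `V_0`, `a1`, `a2`, `n1`, `n2`).
#' @param T heart period (s).
#' @param e optional driver values to use instead of evaluating the
#'   double-Hill driver (used in tests to force end-systole/diastole).
#' @return pressure (mmHg).
#' @export
ventricle_pressure <- function(V, t, params, T = 1.0, e = NULL) {
  stopifnot(all(V > 0))
  if (is.null(e)) e <- driver_double_hill(t, params, T)
  p_es <- params$E_es * (V - params$V_d)
  p_ed <- params$P_0 * (exp(params$lambda * (V - params$V_0)) - 1)
  e * p_es + (1 - e) * p_ed
}

#' Time-varying atrial elastance and pressure
#'
#' The atrium follows a linear pressure-volume law whose slope cycles
#' between `E_min` (diastole) and a systolic peak through a Gaussian
#' driver centred at `C` with width controlled by `B`:
#' \deqn{E_{a}(t) = E_{max}\left(e^{-B (t-C)^2} + E_{min}/E_{max}\right).}
#' As written the peak slope is `E_max + E_min`; set
#' `peak_convention = "peak_emax"` to rescale the Gaussian so the peak is
#' exactly `E_max`.
#'
#' @param t time since atrial activation (s).
#' @param params atrium block (fields `E_max`, `E_min`, `V_d`, `B`, `C`).
#' @param peak_convention `"literal"` (default) or `"peak_emax"`.
#' @return elastance (mmHg/mL).
#' @export
atrial_elastance <- function(t, params, peak_convention = c("literal", "peak_emax")) {
  peak_convention <- match.arg(peak_convention)
  g <- exp(-params$B * (t - params$C)^2)
  if (peak_convention == "peak_emax")
    params$E_max * ((1 - params$E_min / params$E_max) * g +
                      params$E_min / params$E_max)
  else
    params$E_max * (g + params$E_min / params$E_max)
}

#' @rdname atrial_elastance
#' @param V_a atrial volume (mL), > 0.
#' @return `atrial_pressure`: pressure (mmHg).
#' @export
atrial_pressure <- function(V_a, t, params,
                            peak_convention = c("literal", "peak_emax")) {
  stopifnot(all(V_a > 0))
  atrial_elastance(t, params, peak_convention) * (V_a - params$V_d)
}
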