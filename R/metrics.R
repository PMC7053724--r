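#' Total relative pressure estimation error
#'
#' 50/50-weighted combination of the LV-trace error (vectorial 1-norm,
#' relative) and the systolic/diastolic aortic errors:
#' \deqn{e\% = 50 \frac{\|P^{exp}_{LV} - P^{model}_{LV}\|_1}
#'                    {\|P^{exp}_{LV}\|_1}
#'   + 50\left(\frac{|\Delta P_{ao,sys}|}{P^{exp}_{ao,sys}} +
#'             \frac{|\Delta P_{ao,dias}|}{P^{exp}_{ao,dias}}\right).}
#'
#' @param plv_exp,plv_model LV pressure traces on a common grid (mmHg).
#' @param pao_sys_exp,pao_sys_model systolic aortic pressures (mmHg).
#' @param pao_dias_exp,pao_dias_model diastolic aortic pressures (mmHg).
#' @return total relative error in percent.
#' @export
total_relative_error <- function(plv_exp, plv_model,
                                 pao_sys_exp, pao_sys_model,
                                 pao_dias_exp, pao_dias_model) {
  if (length(plv_exp) != length(plv_model))
    stop("LV traces must share one grid")
  n1 <- sum(abs(plv_exp))
  if (n1 == 0) stop("experimental LV trace has zero 1-norm")
  stopifnot(pao_sys_exp > 0, pao_dias_exp > 0)
  50 * sum(abs(plv_exp - plv_model)) / n1 +
    50 * (abs(pao_sys_exp - pao_sys_model) / abs(pao_sys_exp) +
            abs(pao_dias_exp - pao_dias_model) / abs(pao_dias_exp))
}

#' Linear-regression agreement between two series
#'
#' Ordinary least squares of `y` on `x`; returns the slope (beta),
#' intercept and coefficient of determination.
#'
#' @param x,y paired numeric series (>= 3 points, `x` with nonzero
#'   variance).
#' @return list with `beta`, `intercept`, `r_squared`.
#' @export
regression_agreement <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need >= 3 paired points")
  if (stats::var(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  list(beta = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Bland-Altman agreement of paired indices
#'
#' Differences are taken model minus experimental.  `bias` is the mean
#' difference, the limits of agreement are `bias +/- 1.96 sd(diff)`, and
#' the relative bias is the bias expressed as a percentage of the maximum
#' experimental value over the cohort.
#'
#' @param exp_values,model_values paired finite numeric vectors.
#' @return list with `bias`, `sd`, `loa` (length-2 vector), and
#'   `relative_bias_pct`.
#' @export
bland_altman <- function(exp_values, model_values) {
  if (length(exp_values) != length(model_values))
    stop("unpaired lengths")
  stopifnot(all(is.finite(exp_values)), all(is.finite(model_values)))
  d <- model_values - exp_values
  bias <- mean(d)
  s <- if (length(d) > 1) stats::sd(d) else 0
  list(bias = bias, sd = s, loa = bias + c(-1.96, 1.96) * s,
       relative_bias_pct = 100 * bias / max(abs(exp_values)))
}
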