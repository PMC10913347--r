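#' Generic effect-estimate container
#'
#' A light container used across the package for odds ratios, heritabilities,
#' genetic correlations and Mendelian-randomization effects: a point estimate,
#' its standard error on the estimation (log or linear) scale, a Wald 95%
#' confidence interval and a p-value.
#'
#' @param estimate Point estimate (on the reporting scale; ORs are reported on
#'   the OR scale with `se` on the log scale).
#' @param se Standard error on the estimation scale.
#' @param ci_low,ci_high 95% confidence bounds on the reporting scale.
#' @param p Two-sided p-value.
#' @param n_cases,n_total Optional stratum counts.
#' @param method Optional method label.
#' @param ... Further named ancillary fields kept as attributes of the record.
#'
#' @return An object of class `effect_estimate` (a named list).
#' @export
effect_estimate <- function(estimate, se, ci_low, ci_high, p,
                            n_cases = NA_integer_, n_total = NA_integer_,
                            method = NA_character_, ...) {
  stopifnot(is.numeric(estimate), is.numeric(se))
  out <- list(estimate = estimate, se = se,
              ci_low = ci_low, ci_high = ci_high, p = p,
              n_cases = n_cases, n_total = n_total, method = method,
              ancillary = list(...))
  class(out) <- "effect_estimate"
  out
}

#' @export
print.effect_estimate <- function(x, ...) {
  lab <- if (is.na(x$method)) "estimate" else x$method
  cat(sprintf("%s: %.4g (95%% CI %.4g-%.4g), SE %.3g, p = %.3g\n",
              lab, x$estimate, x$ci_low, x$ci_high, x$se, x$p))
  invisible(x)
}

#' @export
as.data.frame.effect_estimate <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, p = x$p,
             n_cases = x$n_cases, n_total = x$n_total,
             stringsAsFactors = FALSE)
}

# Wald 95% CI on the log scale, reported as an OR.
or_estimate <- function(log_or, se, n_cases = NA, n_total = NA,
                        method = NA_character_, ...) {
  z <- log_or / se
  effect_estimate(
    estimate = exp(log_or), se = se,
    ci_low = exp(log_or - 1.96 * se), ci_high = exp(log_or + 1.96 * se),
    p = 2 * stats::pnorm(-abs(z)),
    n_cases = n_cases, n_total = n_total, method = method, ...)
}

# beta-scale estimate with Wald CI (used by LDSC and MR).
beta_estimate <- function(beta, se, method = NA_character_, df = Inf, ...) {
  tstat <- beta / se
  p <- if (is.finite(df)) 2 * stats::pt(-abs(tstat), df = df) else
    2 * stats::pnorm(-abs(tstat))
  crit <- if (is.finite(df)) stats::qt(0.975, df = df) else 1.96
  effect_estimate(
    estimate = beta, se = se,
    ci_low = beta - crit * se, ci_high = beta + crit * se,
    p = p, method = method, ...)
}

check_finite <- function(x, name) {
  if (!all(is.finite(x)))
    stop(sprintf("`%s` must be finite (got non-finite values)", name),
         call. = FALSE)
  invisible(x)
}
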