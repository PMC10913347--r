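#' Odds ratio from a 2x2 contingency table
#'
#' Cross-product odds ratio with a Woolf (Wald) interval: the log-OR
#' variance is the sum of reciprocal cell counts,
#' `SE = sqrt(1/a + 1/(Te-a) + 1/c + 1/(Tr-c))`, and the 95% CI is
#' `exp(log OR +/- 1.96 SE)`. This is the closed form that an unadjusted
#' logistic regression on a single exposure factor reproduces.
#'
#' @param cases_exposed,total_exposed Case count and total in the exposed
#'   group.
#' @param cases_ref,total_ref Case count and total in the reference group.
#' @param haldane If `TRUE`, add 0.5 to every cell (Haldane-Anscombe
#'   correction); required when any cell is zero.
#' @return An [effect_estimate()] (OR scale).
#' @examples
#' or_from_counts(210, 1801, 118, 1602)  # OR 1.66 (1.31-2.11)
#' @export
or_from_counts <- function(cases_exposed, total_exposed, cases_ref, total_ref,
                           haldane = FALSE) {
  cnt <- c(cases_exposed, total_exposed, cases_ref, total_ref)
  if (any(cnt != round(cnt)) || any(cnt < 0))
    stop("counts must be non-negative integers", call. = FALSE)
  if (cases_exposed > total_exposed || cases_ref > total_ref)
    stop("cases cannot exceed totals", call. = FALSE)
  a <- cases_exposed; b <- total_exposed - cases_exposed
  c_ <- cases_ref;    d <- total_ref - cases_ref
  if (any(c(a, b, c_, d) == 0)) {
    if (!haldane)
      stop("zero cell in 2x2 table; rerun with haldane = TRUE to apply the ",
           "Haldane-Anscombe 0.5 correction", call. = FALSE)
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  log_or <- log(a / b) - log(c_ / d)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  or_estimate(log_or, se, n_cases = cases_exposed, n_total = total_exposed,
              method = "contingency OR (Woolf)")
}

#' Logistic regression with separation guard
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' `stats::glm`) returning Wald effect estimates per coefficient. Detects
#' (quasi-)separation — a coefficient diverging with an exploding standard
#' error — and fails naming the offending column rather than returning a
#' meaningless estimate.
#'
#' @param formula Model formula with a binary outcome.
#' @param data Data frame.
#' @return List with `fit` (the glm object) and `estimates` (a data.frame of
#'   per-coefficient OR-scale estimates: term, or, ci_low, ci_high, se, p).
#' @export
fit_logistic <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm(formula, data = data, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  co <- summary(fit)$coefficients
  diverged <- abs(co[, "Estimate"]) > 15 & co[, "Std. Error"] > 100
  if (any(diverged))
    stop("separation detected for column(s): ",
         paste(rownames(co)[diverged], collapse = ", "), call. = FALSE)
  est <- data.frame(
    term = rownames(co),
    or = exp(co[, "Estimate"]),
    se = co[, "Std. Error"],
    ci_low = exp(co[, "Estimate"] - 1.96 * co[, "Std. Error"]),
    ci_high = exp(co[, "Estimate"] + 1.96 * co[, "Std. Error"]),
    p = co[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  list(fit = fit, estimates = est)
}

# Adjustment sets for the three standard models.
model_adjustments <- function(model_id) {
  switch(as.character(model_id),
         "1" = character(0),
         "2" = c("age", "sex"),
         "3" = c("age", "sex", "bmi", "marital", "smoke", "sbp", "dbp",
                 "drink", "sleep", "hypertension", "hyperlipidemia",
                 "diabetes", "cvd"),
         stop("model id must be 1, 2 or 3", call. = FALSE))
}

#' Tertile model series (Models 1-3)
#'
#' Fits logistic models of a binary outcome on the hs-CRP tertile (reference
#' = low), unadjusted (Model 1), age/sex-adjusted (Model 2) and
#' multivariable-adjusted (Model 3: age, sex, BMI, marital state, smoking,
#' SBP, DBP, drinking, sleep duration, hypertension, hyperlipidemia,
#' diabetes, cardiovascular disease). Adjustment column names can be remapped
#' through `covariates`.
#'
#' @param data Data frame with the outcome, a `tertile` factor
#'   (levels low/middle/high) and any adjustment columns.
#' @param outcome Name of the binary outcome column.
#' @param models Integer vector of model ids among 1:3.
#' @param covariates Optional named list overriding the default adjustment
#'   sets per model id.
#' @return Data frame with one row per non-reference tertile per model:
#'   model, level, n_cases, n_total, or, ci_low, ci_high, se, p.
#' @export
run_model_series <- function(data, outcome = "event", models = 1:3,
                             covariates = NULL) {
  stopifnot(outcome %in% names(data), "tertile" %in% names(data))
  data$tertile <- factor(data$tertile, levels = c("low", "middle", "high"))
  out <- list()
  for (m in models) {
    adj <- if (!is.null(covariates) && !is.null(covariates[[as.character(m)]]))
      covariates[[as.character(m)]] else model_adjustments(m)
    missing_cols <- setdiff(adj, names(data))
    if (length(missing_cols))
      stop("missing covariate column(s) for model ", m, ": ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    rhs <- paste(c("tertile", adj), collapse = " + ")
    f <- stats::as.formula(paste(outcome, "~", rhs))
    est <- fit_logistic(f, data)$estimates
    rows <- est[grepl("^tertile", est$term), , drop = FALSE]
    rows$level <- sub("^tertile", "", rows$term)
    for (lv in rows$level) {
      sub <- data[data$tertile == lv & !is.na(data[[outcome]]), ]
      rows$n_cases[rows$level == lv] <- sum(sub[[outcome]], na.rm = TRUE)
      rows$n_total[rows$level == lv] <- nrow(sub)
    }
    rows$model <- m
    out[[length(out) + 1]] <-
      rows[, c("model", "level", "n_cases", "n_total",
               "or", "ci_low", "ci_high", "se", "p")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Trend test across ordered tertiles
#'
#' Refits the logistic model with the tertile entered as a single ordinal
#' score (low = 0, middle = 1, high = 2 by default; tertile medians can be
#' supplied instead) and reports the Wald p-value of the score term.
#'
#' @param data Data frame with outcome and `tertile`.
#' @param outcome Binary outcome column name.
#' @param adjust Character vector of adjustment columns.
#' @param scores Numeric scores for the ordered levels (default 0, 1, 2).
#' @return List with `p`, `beta` (per-level log-odds slope) and `fit`.
#' @export
trend_test <- function(data, outcome = "event", adjust = character(0),
                       scores = c(0, 1, 2)) {
  lv <- levels(factor(data$tertile, levels = c("low", "middle", "high")))
  present <- unique(as.character(data$tertile))
  if (length(present) < 2) stop("need >= 2 tertile levels", call. = FALSE)
  data$tertile_score <- scores[match(as.character(data$tertile), lv)]
  rhs <- paste(c("tertile_score", adjust), collapse = " + ")
  f <- stats::as.formula(paste(outcome, "~", rhs))
  fl <- fit_logistic(f, data)
  row <- fl$estimates[fl$estimates$term == "tertile_score", ]
  list(p = row$p, beta = log(row$or), fit = fl$fit)
}

#' Subgroup analysis with interaction test
#'
#' Fits the tertile model within each level of a stratifier and tests for
#' effect modification with a likelihood-ratio test of the
#' tertile-by-stratifier product terms in the pooled model.
#'
#' @param data Data frame with outcome, `tertile`, the stratifier and any
#'   adjustment columns.
#' @param stratifier Name of the stratifying column (>= 2 levels).
#' @param outcome Binary outcome column name.
#' @param adjust Adjustment columns for the stratum models (the stratifier
#'   itself is dropped from the adjustment set within strata by default).
#' @param drop_stratifier Drop the stratifier from within-stratum adjustment
#'   (default `TRUE`).
#' @return List with `strata` (data.frame of per-stratum tertile ORs, with a
#'   `flag` for strata without cases) and `p_interaction`.
#' @export
subgroup_interaction <- function(data, stratifier, outcome = "event",
                                 adjust = model_adjustments(3),
                                 drop_stratifier = TRUE) {
  s <- factor(data[[stratifier]])
  if (nlevels(s) < 2) stop("stratifier needs >= 2 levels", call. = FALSE)
  data$..s <- s
  adj_in <- if (drop_stratifier) setdiff(adjust, stratifier) else adjust
  adj_in <- intersect(adj_in, names(data))
  rows <- list()
  for (lev in levels(s)) {
    sub <- data[data$..s == lev, , drop = FALSE]
    if (sum(sub[[outcome]], na.rm = TRUE) == 0) {
      rows[[lev]] <- data.frame(stratum = lev, level = NA, or = NA, ci_low = NA,
                                ci_high = NA, se = NA, p = NA, flag = "no cases",
                                stringsAsFactors = FALSE)
      next
    }
    est <- run_model_series(sub, outcome = outcome, models = 1,
                            covariates = list("1" = adj_in))
    rows[[lev]] <- data.frame(stratum = lev, level = est$level, or = est$or,
                              ci_low = est$ci_low, ci_high = est$ci_high,
                              se = est$se, p = est$p, flag = "",
                              stringsAsFactors = FALSE)
  }
  # LRT for interaction in the pooled model
  adj_all <- intersect(if (drop_stratifier) setdiff(adjust, stratifier) else
    adjust, names(data))
  base_rhs <- paste(c("tertile", "..s", adj_all), collapse = " + ")
  f0 <- stats::as.formula(paste(outcome, "~", base_rhs))
  f1 <- stats::as.formula(paste(outcome, "~", base_rhs, "+ tertile:..s"))
  cc <- stats::complete.cases(data[, c(outcome, "tertile", "..s", adj_all)])
  d <- data[cc, , drop = FALSE]
  m0 <- suppressWarnings(stats::glm(f0, data = d, family = stats::binomial()))
  m1 <- suppressWarnings(stats::glm(f1, data = d, family = stats::binomial()))
  lrt <- stats::anova(m0, m1, test = "LRT")
  p_int <- lrt[2, "Pr(>Chi)"]
  list(strata = do.call(rbind, rows), p_interaction = p_int)
}

#' Restricted cubic spline basis
#'
#' Natural (restricted) cubic spline basis in the truncated-power form:
#' linear beyond the outermost knots, `k - 2` nonlinear columns for `k`
#' knots, each scaled by the squared outer-knot span.
#'
#' @param x Numeric vector.
#' @param knots Knot locations (length >= 3, increasing).
#' @return Matrix with `length(knots) - 1` columns (first column is `x`).
#' @export
rcs_basis <- function(x, knots) {
  knots <- sort(knots)
  k <- length(knots)
  if (k < 3) stop("need >= 3 knots", call. = FALSE)
  tk <- knots[k]; tk1 <- knots[k - 1]
  scale2 <- (tk - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    out[, j + 1] <- (pos3(x - tj) -
                       pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                       pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / scale2
  }
  colnames(out) <- paste0("rcs", seq_len(k - 1))
  out
}

#' Spline dose-response and non-linearity test
#'
#' Fits a logistic model with a restricted cubic spline in hs-CRP (default 4
#' knots at the 5/35/65/95% quantiles), reports the odds-ratio curve
#' normalized to OR = 1 at a reference concentration, and tests
#' non-linearity with a likelihood-ratio test of the nonlinear spline terms
#' against the linear model.
#'
#' @param data Data frame with outcome and `crp` (mg/L, positive).
#' @param outcome Binary outcome column name.
#' @param reference Reference concentration where OR is anchored at 1
#'   (default 1.46 mg/L).
#' @param knots Knot locations; default quantiles 0.05/0.35/0.65/0.95 of
#'   observed CRP.
#' @param adjust Adjustment columns.
#' @param grid Concentrations at which to evaluate the OR curve.
#' @return List with `curve` (data.frame: crp, or, ci_low, ci_high),
#'   `p_nonlinearity`, `knots`, `fit`.
#' @export
spline_nonlinearity <- function(data, outcome = "event", reference = 1.46,
                                knots = NULL, adjust = character(0),
                                grid = NULL) {
  crp <- data$crp
  if (any(!is.finite(crp)) || any(crp <= 0))
    stop("crp must be positive", call. = FALSE)
  if (is.null(knots))
    knots <- unname(stats::quantile(crp, c(0.05, 0.35, 0.65, 0.95)))
  if (length(unique(crp)) <= length(knots))
    stop("fewer distinct crp values than knots", call. = FALSE)
  B <- rcs_basis(crp, knots)
  d <- cbind(data, B)
  rhs_nl <- paste(c(colnames(B), adjust), collapse = " + ")
  rhs_lin <- paste(c("crp", adjust), collapse = " + ")
  m1 <- suppressWarnings(stats::glm(
    stats::as.formula(paste(outcome, "~", rhs_nl)), data = d,
    family = stats::binomial()))
  m0 <- suppressWarnings(stats::glm(
    stats::as.formula(paste(outcome, "~", rhs_lin)), data = d,
    family = stats::binomial()))
  lrt <- stats::anova(m0, m1, test = "LRT")
  p_nl <- lrt[2, "Pr(>Chi)"]

  if (is.null(grid))
    grid <- seq(stats::quantile(crp, 0.01), stats::quantile(crp, 0.99),
                length.out = 100)
  Bg <- rcs_basis(grid, knots)
  Br <- rcs_basis(reference, knots)
  idx <- match(colnames(B), names(stats::coef(m1)))
  beta <- stats::coef(m1)[idx]
  V <- stats::vcov(m1)[idx, idx]
  D <- sweep(Bg, 2, as.numeric(Br))            # contrast vs reference
  eta <- drop(D %*% beta)
  se <- sqrt(rowSums((D %*% V) * D))
  list(curve = data.frame(crp = grid, or = exp(eta),
                          ci_low = exp(eta - 1.96 * se),
                          ci_high = exp(eta + 1.96 * se)),
       p_nonlinearity = p_nl, knots = knots, fit = m1)
}
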