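#' Per-SNP Wald ratio estimates
#'
#' @param h A `harmonized_instruments` data.frame.
#' @return Data.frame with `ratio` (beta_outcome / beta_exposure) and
#'   first-order `se` (se_outcome / |beta_exposure|).
#' @export
wald_ratios <- function(h) {
  data.frame(SNP = h$SNP,
             ratio = h$beta_outcome / h$beta_exposure,
             se = h$se_outcome / abs(h$beta_exposure),
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted causal estimate
#'
#' Meta-analyzes the per-SNP Wald ratios with weights equal to the inverse
#' first-order variance, equivalent to a zero-intercept weighted regression
#' of outcome on exposure effects. In multiplicative random-effects mode
#' (the default, used when instrument heterogeneity is present) the fixed
#' standard error is inflated by `max(1, sqrt(Q / (k - 1)))`.
#'
#' @param h A `harmonized_instruments` data.frame.
#' @param mode `"multiplicative-random"` (default) or `"fixed"`.
#' @return An [effect_estimate()] (beta scale) with ancillary `or`, `Q`,
#'   `Q_p`, `k`.
#' @export
ivw <- function(h, mode = c("multiplicative-random", "fixed")) {
  mode <- match.arg(mode)
  k <- nrow(h)
  if (k < 1) stop("no instruments", call. = FALSE)
  wr <- wald_ratios(h)
  if (k == 1) {
    warning("single instrument: returning the Wald ratio")
    return(beta_estimate(wr$ratio, wr$se, method = "Wald ratio",
                         or = exp(wr$ratio), Q = NA, Q_p = NA, k = 1L))
  }
  w <- 1 / wr$se^2
  beta <- sum(w * wr$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  Q <- sum(w * (wr$ratio - beta)^2)
  Q_p <- stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
  se <- if (mode == "multiplicative-random")
    se_fixed * max(1, sqrt(Q / (k - 1))) else se_fixed
  beta_estimate(beta, se,
                method = sprintf("IVW (%s)", mode),
                or = exp(beta), Q = Q, Q_p = Q_p, k = k)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept, after orienting every instrument's exposure effect positive.
#' The slope is the causal estimate; a nonzero intercept indicates
#' directional horizontal pleiotropy (the intercept test). Standard errors
#' use a multiplicative overdispersion factor bounded below by 1, with
#' t-distribution inference on `k - 2` degrees of freedom.
#'
#' @param h A `harmonized_instruments` data.frame (>= 3 SNPs).
#' @return An [effect_estimate()] for the slope with ancillary
#'   `egger_intercept`, `intercept_se`, `intercept_p`, `or`, `k`.
#' @export
egger <- function(h) {
  k <- nrow(h)
  if (k < 3) stop("MR-Egger needs >= 3 instruments", call. = FALSE)
  flip <- sign(h$beta_exposure)
  bx <- h$beta_exposure * flip
  by <- h$beta_outcome * flip
  w <- 1 / h$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  co <- summary(fit)$coefficients
  # multiplicative random effects: residual scale floored at 1
  sigma <- max(1, summary(fit)$sigma)
  adj <- sigma / summary(fit)$sigma
  slope_se <- co["bx", "Std. Error"] * adj
  int_se <- co["(Intercept)", "Std. Error"] * adj
  slope <- co["bx", "Estimate"]
  intercept <- co["(Intercept)", "Estimate"]
  beta_estimate(slope, slope_se, method = "MR-Egger", df = k - 2,
                or = exp(slope),
                egger_intercept = intercept, intercept_se = int_se,
                intercept_p = 2 * stats::pt(-abs(intercept / int_se),
                                            df = k - 2),
                k = k)
}

# weight-interpolated p-th percentile of ratio estimates (weighted median
# convention: cumulative weights standardized and shifted by half a weight)
weighted_percentile <- function(x, w, prob = 0.5) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) - 0.5 * w
  cw <- cw / sum(w)
  stats::approx(cw, x, xout = prob, rule = 2)$y
}

#' Weighted-median causal estimate
#'
#' The weight-interpolated 50th percentile of the per-SNP Wald ratios with
#' inverse-variance weights; consistent when instruments carrying at least
#' half the weight are valid. The standard error comes from a parametric
#' bootstrap of the summary statistics.
#'
#' @param h A `harmonized_instruments` data.frame (>= 3 SNPs).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Bootstrap seed.
#' @param weighted If `FALSE`, the simple (unweighted) median.
#' @return An [effect_estimate()] with ancillary `or`, `k`.
#' @export
weighted_median <- function(h, n_boot = 1000, seed = 1L, weighted = TRUE) {
  k <- nrow(h)
  if (k < 3) stop("median estimator needs >= 3 instruments", call. = FALSE)
  wr <- wald_ratios(h)
  w <- if (weighted) 1 / wr$se^2 else rep(1, k)
  beta <- weighted_percentile(wr$ratio, w)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(k, h$beta_exposure, h$se_exposure)
    by <- stats::rnorm(k, h$beta_outcome, h$se_outcome)
    r <- by / bx
    s <- h$se_outcome / abs(bx)
    wb <- if (weighted) 1 / s^2 else rep(1, k)
    weighted_percentile(r, wb)
  }, numeric(1))
  se <- stats::sd(boots)
  beta_estimate(beta, se,
                method = if (weighted) "weighted median" else "simple median",
                or = exp(beta), k = k)
}

# modified Silverman bandwidth on (possibly weighted) ratio estimates
mode_bandwidth <- function(ratio, phi = 1) {
  s <- 0.9 * min(stats::sd(ratio), stats::mad(ratio)) * length(ratio)^(-1/5)
  if (s <= 0) s <- stats::sd(ratio) * length(ratio)^(-1/5)
  max(phi * s, .Machine$double.eps)
}

kde_mode <- function(ratio, w, bw) {
  d <- stats::density(ratio, weights = w / sum(w), bw = bw, n = 1024)
  d$x[which.max(d$y)]
}

#' Mode-based causal estimates
#'
#' The mode of the kernel-smoothed density of per-SNP Wald ratios
#' (modified Silverman bandwidth scaled by `phi`), unweighted
#' (`simple_mode`) or with inverse-variance weights (`weighted_mode`);
#' consistent when the largest group of instruments sharing a ratio is
#' valid. Standard errors by parametric bootstrap.
#'
#' @param h A `harmonized_instruments` data.frame (>= 3 SNPs).
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Bootstrap seed.
#' @return An [effect_estimate()] with ancillary `or`, `k`.
#' @export
simple_mode <- function(h, phi = 1, n_boot = 1000, seed = 1L) {
  mode_estimate(h, weighted = FALSE, phi = phi, n_boot = n_boot, seed = seed)
}

#' @rdname simple_mode
#' @export
weighted_mode <- function(h, phi = 1, n_boot = 1000, seed = 1L) {
  mode_estimate(h, weighted = TRUE, phi = phi, n_boot = n_boot, seed = seed)
}

mode_estimate <- function(h, weighted, phi, n_boot, seed) {
  k <- nrow(h)
  if (k < 3) stop("mode estimator needs >= 3 instruments", call. = FALSE)
  wr <- wald_ratios(h)
  w <- if (weighted) 1 / wr$se^2 else rep(1, k)
  bw <- mode_bandwidth(wr$ratio, phi)
  beta <- kde_mode(wr$ratio, w, bw)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(k, h$beta_exposure, h$se_exposure)
    by <- stats::rnorm(k, h$beta_outcome, h$se_outcome)
    r <- by / bx
    s <- h$se_outcome / abs(bx)
    wb <- if (weighted) 1 / s^2 else rep(1, k)
    kde_mode(r, wb, mode_bandwidth(r, phi))
  }, numeric(1))
  se <- stats::sd(boots)
  beta_estimate(beta, se,
                method = if (weighted) "weighted mode" else "simple mode",
                or = exp(beta), k = k)
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (ratio_j - beta_IVW)^2` with inverse-variance weights,
#' compared to chi-square on `k - 1` degrees of freedom.
#'
#' @param h A `harmonized_instruments` data.frame (>= 2 SNPs).
#' @return List with `Q`, `df`, `p`.
#' @export
cochran_q <- function(h) {
  if (nrow(h) < 2) stop("Q needs >= 2 instruments", call. = FALSE)
  est <- ivw(h, mode = "fixed")
  list(Q = est$ancillary$Q, df = nrow(h) - 1, p = est$ancillary$Q_p)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate with each instrument removed in turn and
#' flags removals that change the sign of the estimate or move it by more
#' than one pooled standard error.
#'
#' @param h A `harmonized_instruments` data.frame (>= 3 SNPs).
#' @return Data.frame with one row per removed SNP: SNP, beta, se, p,
#'   flagged.
#' @export
leave_one_out <- function(h) {
  k <- nrow(h)
  if (k < 3) stop("leave-one-out needs >= 3 instruments", call. = FALSE)
  full <- ivw(h)
  rows <- lapply(seq_len(k), function(j) {
    e <- ivw(h[-j, , drop = FALSE])
    data.frame(SNP = h$SNP[j], beta = e$estimate, se = e$se, p = e$p,
               flagged = sign(e$estimate) != sign(full$estimate) ||
                 abs(e$estimate - full$estimate) > full$se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_estimate") <- full$estimate
  out
}

#' Maximum-likelihood causal estimate
#'
#' Joint bivariate-normal likelihood over the per-SNP true exposure
#' effects, profiled out analytically: the causal effect minimizes
#' `sum_j (by_j - theta bx_j)^2 / (sy_j^2 + theta^2 sx_j^2)` (plus the log
#' of the denominators), accounting for measurement error in the
#' SNP-exposure associations. Solved by 1-D numerical optimization; the
#' standard error comes from the numeric second derivative at the optimum.
#'
#' @param h A `harmonized_instruments` data.frame (>= 3 SNPs).
#' @return An [effect_estimate()] with ancillary `or`, `k`.
#' @export
maximum_likelihood <- function(h) {
  k <- nrow(h)
  if (k < 3) stop("ML needs >= 3 instruments", call. = FALSE)
  bx <- h$beta_exposure; by <- h$beta_outcome
  sx2 <- h$se_exposure^2; sy2 <- h$se_outcome^2
  nll <- function(theta) {
    v <- sy2 + theta^2 * sx2
    0.5 * sum((by - theta * bx)^2 / v + log(v))
  }
  start <- ivw(h, mode = "fixed")$estimate
  opt <- stats::optim(start, nll, method = "Brent",
                      lower = start - 10 * abs(start) - 1,
                      upper = start + 10 * abs(start) + 1, hessian = TRUE)
  if (opt$convergence != 0)
    stop("ML optimizer failed to converge: code ", opt$convergence,
         call. = FALSE)
  se <- sqrt(1 / opt$hessian[1, 1])
  beta_estimate(opt$par, se, method = "maximum likelihood",
                or = exp(opt$par), k = k)
}

#' Penalized inverse-variance-weighted estimate
#'
#' IVW with weights down-scaled for instruments whose heterogeneity
#' contribution is improbably large under chi-square(1): each weight is
#' multiplied by `min(1, penalty_scale * p_j)` where `p_j` is the upper
#' chi-square(1) tail of the SNP's Q contribution, penalizing pleiotropic
#' outliers while leaving concordant instruments untouched.
#'
#' @param h A `harmonized_instruments` data.frame (>= 3 SNPs).
#' @param penalty_scale Multiplier on the per-SNP tail probability
#'   (default 20).
#' @return An [effect_estimate()] with ancillary `or`, `k`,
#'   `n_penalized`.
#' @export
penalized_ivw <- function(h, penalty_scale = 20) {
  k <- nrow(h)
  if (k < 3) stop("penalized IVW needs >= 3 instruments", call. = FALSE)
  wr <- wald_ratios(h)
  w <- 1 / wr$se^2
  beta0 <- sum(w * wr$ratio) / sum(w)
  q_j <- w * (wr$ratio - beta0)^2
  pen <- pmin(1, penalty_scale * stats::pchisq(q_j, 1, lower.tail = FALSE))
  w2 <- w * pen
  beta <- sum(w2 * wr$ratio) / sum(w2)
  se <- sqrt(1 / sum(w2))
  # multiplicative overdispersion on the penalized fit
  Q2 <- sum(w2 * (wr$ratio - beta)^2)
  se <- se * max(1, sqrt(Q2 / (k - 1)))
  beta_estimate(beta, se, method = "penalized IVW", or = exp(beta), k = k,
                n_penalized = sum(pen < 1))
}

#' Robust adjusted profile-score estimate
#'
#' Profile-score estimating equations with a multiplicative overdispersion
#' parameter and an optional Huber robust loss: standardized residuals
#' `t_j = (by_j - theta bx_j) / sqrt(sy_j^2 + theta^2 sx_j^2 + tau2)` enter
#' a (robustified) score; `theta` and the overdispersion `tau2` are solved
#' by alternating a 1-D minimization in `theta` with a method-of-moments
#' update of `tau2` (so that the mean squared standardized residual is 1).
#' Robust to modest violations of instrument validity under balanced
#' pleiotropy.
#'
#' @param h A `harmonized_instruments` data.frame (>= 3 SNPs).
#' @param robust Use the Huber loss (default `TRUE`).
#' @param huber_k Huber tuning constant (default 1.345).
#' @param max_iter,tol Outer-loop controls.
#' @return An [effect_estimate()] with ancillary `or`, `tau2`, `k`.
#' @export
mr_raps <- function(h, robust = TRUE, huber_k = 1.345, max_iter = 50,
                    tol = 1e-8) {
  k <- nrow(h)
  if (k < 3) stop("RAPS needs >= 3 instruments", call. = FALSE)
  bx <- h$beta_exposure; by <- h$beta_outcome
  sx2 <- h$se_exposure^2; sy2 <- h$se_outcome^2
  rho <- if (robust) {
    function(t) ifelse(abs(t) <= huber_k, 0.5 * t^2,
                       huber_k * abs(t) - 0.5 * huber_k^2)
  } else function(t) 0.5 * t^2

  theta <- ivw(h, mode = "fixed")$estimate
  tau2 <- 0
  for (it in seq_len(max_iter)) {
    obj <- function(th) {
      v <- sy2 + th^2 * sx2 + tau2
      sum(rho((by - th * bx) / sqrt(v)) + 0.5 * log(v))
    }
    o <- stats::optimize(obj, interval = theta + c(-1, 1) * (abs(theta) + 1))
    theta_new <- o$minimum
    v <- sy2 + theta_new^2 * sx2 + tau2
    t2 <- (by - theta_new * bx)^2 / v
    # moment update: inflate tau2 until E[t^2] = 1
    tau2_new <- max(0, tau2 + (mean(t2) - 1) * mean(v))
    conv <- abs(theta_new - theta) < tol && abs(tau2_new - tau2) < tol
    theta <- theta_new; tau2 <- tau2_new
    if (conv) break
  }
  if (it == max_iter && !conv)
    warning("RAPS outer loop did not fully converge")
  # sandwich-style SE from the profile score
  v <- sy2 + theta^2 * sx2 + tau2
  score_grad <- sum(bx^2 / v)
  se <- sqrt(sum(bx^2 * (by - theta * bx)^2 / v^2)) / score_grad
  beta_estimate(theta, se, method = "MR-RAPS", or = exp(theta),
                tau2 = tau2, k = k)
}
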