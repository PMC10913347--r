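#' Standardize raw summary statistics to z-scores
#'
#' Reformats a raw summary-statistics table for LD-score regression:
#' computes `z = BETA/SE`, drops rows with missing or invalid alleles,
#' non-positive SE or non-finite statistics, optionally drops
#' strand-ambiguous (A/T, C/G) SNPs, and logs how many rows each filter
#' removed.
#'
#' @param raw Data.frame with columns SNP, A1, A2, BETA, SE (P, N optional).
#' @param drop_ambiguous Drop palindromic SNPs (default `FALSE`; cross-trait
#'   analyses use `TRUE`).
#' @return List with `z` (data.frame SNP, z, N) and `dropped` (named counts).
#' @export
munge_sumstats <- function(raw, drop_ambiguous = FALSE) {
  need <- c("SNP", "A1", "A2", "BETA", "SE")
  if (!all(need %in% names(raw)))
    stop("missing columns: ", paste(setdiff(need, names(raw)), collapse = ", "),
         call. = FALSE)
  n0 <- nrow(raw)
  bases <- c("A", "C", "G", "T")
  ok_allele <- raw$A1 %in% bases & raw$A2 %in% bases & raw$A1 != raw$A2
  ok_stats <- is.finite(raw$BETA) & is.finite(raw$SE) & raw$SE > 0
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ambiguous <- ok_allele & raw$A2 == unname(comp[raw$A1])
  keep <- ok_allele & ok_stats
  dropped <- c(invalid_alleles = sum(!ok_allele),
               invalid_stats = sum(ok_allele & !ok_stats),
               strand_ambiguous = 0L)
  if (drop_ambiguous) {
    dropped["strand_ambiguous"] <- sum(keep & ambiguous)
    keep <- keep & !ambiguous
  }
  if (!any(keep)) stop("no usable rows after munging", call. = FALSE)
  out <- data.frame(SNP = raw$SNP[keep], z = raw$BETA[keep] / raw$SE[keep],
                    N = if ("N" %in% names(raw)) raw$N[keep] else NA,
                    stringsAsFactors = FALSE)
  list(z = out, dropped = dropped)
}

# weighted least squares of y on (1, x); returns c(intercept, slope)
wls_fit <- function(x, y, w) {
  sw <- sum(w); mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  sxx <- sum(w * (x - mx)^2)
  if (sxx <= 0) stop("regressor is constant: slope unidentifiable",
                     call. = FALSE)
  slope <- sum(w * (x - mx) * (y - my)) / sxx
  c(intercept = my - slope * mx, slope = slope)
}

# delete-one-block jackknife of a statistic computed by `fn(keep_idx)`
block_jackknife <- function(n, n_blocks, fn) {
  n_blocks <- min(n_blocks, n)
  bounds <- floor(seq(0, n, length.out = n_blocks + 1))
  full <- fn(seq_len(n))
  pseudo <- matrix(NA_real_, n_blocks, length(full))
  for (b in seq_len(n_blocks)) {
    keep <- setdiff(seq_len(n), (bounds[b] + 1):bounds[b + 1])
    del <- fn(keep)
    pseudo[b, ] <- n_blocks * full - (n_blocks - 1) * del
  }
  est <- colMeans(pseudo)
  se <- sqrt(apply(pseudo, 2, stats::var) / n_blocks)
  list(full = full, est = est, se = se, n_blocks = n_blocks)
}

# two-step LDSC heteroskedasticity weights: 1/max(l,1), then refit and
# reweight by the squared predicted mean
ldsc_weights <- function(x, y, base_w) {
  fit1 <- wls_fit(x, y, base_w)
  pred <- pmax(fit1[1] + fit1[2] * x, 0.1)
  base_w / pred^2
}

#' SNP heritability by LD-score regression
#'
#' Regresses per-SNP chi-square statistics on LD scores:
#' `E[chi2_j] = 1 + N h2 l_j / M + a`, so the fitted slope times `M/N` is
#' the observed-scale SNP heritability and the free intercept absorbs
#' confounding inflation. Weights are `1/max(l_j, 1)` with a second-step
#' reweighting by the squared fitted mean; uncertainty comes from a
#' delete-one-block jackknife over contiguous SNP blocks.
#'
#' @param z Numeric vector of z-scores (aligned with `l2`).
#' @param l2 Per-SNP LD scores.
#' @param N GWAS sample size.
#' @param M Number of SNPs the heritability is spread over (default
#'   `length(z)`).
#' @param n_blocks Jackknife blocks (default 200).
#' @return List of class `ldsc_result`: `h2`, `h2_se`, `intercept`,
#'   `intercept_se`, `n_blocks`, `n_snps`.
#' @export
ldsc_h2 <- function(z, l2, N, M = length(z), n_blocks = 200) {
  stopifnot(length(z) == length(l2))
  if (length(z) < 200) stop("need >= 200 SNPs", call. = FALSE)
  if (any(!is.finite(l2))) stop("LD scores must be finite", call. = FALSE)
  if (length(z) < n_blocks) {
    warning("fewer SNPs than blocks; reducing block count")
    n_blocks <- length(z)
  }
  chi2 <- z^2
  base_w <- 1 / pmax(l2, 1)
  w <- ldsc_weights(l2, chi2, base_w)
  fn <- function(idx) {
    fit <- wls_fit(l2[idx], chi2[idx], w[idx])
    c(h2 = unname(fit["slope"]) * M / N, intercept = unname(fit["intercept"]))
  }
  jk <- block_jackknife(length(z), n_blocks, fn)
  structure(list(h2 = unname(jk$full["h2"]), h2_se = jk$se[1],
                 intercept = unname(jk$full["intercept"]),
                 intercept_se = jk$se[2],
                 n_blocks = jk$n_blocks, n_snps = length(z)),
            class = "ldsc_result")
}

#' Cross-trait LD-score regression (genetic correlation)
#'
#' Regresses the per-SNP product `z1 z2` on LD scores:
#' `E[z1 z2] = sqrt(N1 N2) rho_g l_j / M + c`, where the free intercept `c`
#' absorbs sample overlap. The genetic covariance `rho_g` is the slope times
#' `M/sqrt(N1 N2)` and the genetic correlation is
#' `rg = rho_g / sqrt(h2_1 h2_2)` with both heritabilities estimated by
#' [ldsc_h2()] on the same SNPs. `rg` and its standard error are jackknifed
#' jointly (the heritabilities are re-estimated within every delete-block
#' replicate).
#'
#' @param z1,z2 z-score vectors on the shared SNP set, allele-aligned.
#' @param l2 Per-SNP LD scores.
#' @param N1,N2 Sample sizes.
#' @param M SNP count carrying the heritability (default `length(z1)`).
#' @param n_blocks Jackknife blocks (default 200).
#' @return List of class `ldsc_rg_result`: `rg`, `rg_se`, `rg_p`, `gcov`,
#'   `gcov_se`, `intercept` (cross-trait), `intercept_se`, `h2_1`, `h2_2`,
#'   `n_blocks`. `|rg| > 1` is flagged with a warning, not an error.
#' @export
ldsc_rg <- function(z1, z2, l2, N1, N2, M = length(z1), n_blocks = 200) {
  stopifnot(length(z1) == length(z2), length(z1) == length(l2))
  if (length(z1) < 200) stop("traits must share >= 200 SNPs", call. = FALSE)
  if (length(z1) < n_blocks) {
    warning("fewer SNPs than blocks; reducing block count")
    n_blocks <- length(z1)
  }
  y12 <- z1 * z2
  base_w <- 1 / pmax(l2, 1)
  w1 <- ldsc_weights(l2, z1^2, base_w)
  w2 <- ldsc_weights(l2, z2^2, base_w)
  w12 <- sqrt(w1 * w2)
  fn <- function(idx) {
    f1 <- wls_fit(l2[idx], z1[idx]^2, w1[idx])
    f2 <- wls_fit(l2[idx], z2[idx]^2, w2[idx])
    fx <- wls_fit(l2[idx], y12[idx], w12[idx])
    h2a <- unname(f1["slope"]) * M / N1
    h2b <- unname(f2["slope"]) * M / N2
    gcov <- unname(fx["slope"]) * M / sqrt(N1 * N2)
    if (h2a <= 0 || h2b <= 0)
      stop("estimated heritability <= 0: rg undefined", call. = FALSE)
    c(rg = gcov / sqrt(h2a * h2b), gcov = gcov,
      intercept = unname(fx["intercept"]), h2_1 = h2a, h2_2 = h2b)
  }
  jk <- block_jackknife(length(z1), n_blocks, fn)
  rg <- unname(jk$full["rg"])
  rg_se <- jk$se[1]
  if (abs(rg) > 1) warning("|rg| exceeds 1 (estimation noise)")
  structure(list(rg = rg, rg_se = rg_se,
                 rg_p = 2 * stats::pnorm(-abs(rg / rg_se)),
                 gcov = unname(jk$full["gcov"]), gcov_se = jk$se[2],
                 intercept = unname(jk$full["intercept"]),
                 intercept_se = jk$se[3],
                 h2_1 = unname(jk$full["h2_1"]),
                 h2_2 = unname(jk$full["h2_2"]),
                 n_blocks = jk$n_blocks),
            class = "ldsc_rg_result")
}

#' Bonferroni significance helper
#'
#' @param p P-values.
#' @param n_tests Number of tests in the family (default 14, the number of
#'   correlated-trait tests a typical screen of this kind runs).
#' @param alpha Family-wise error rate (default 0.05).
#' @return Logical vector: p below `alpha / n_tests` (0.05/14 = 3.571e-3 at
#'   the defaults).
#' @export
bonferroni_significant <- function(p, n_tests = 14, alpha = 0.05) {
  p < alpha / n_tests
}

#' @export
print.ldsc_result <- function(x, ...) {
  cat(sprintf("LDSC h2 = %.4f (SE %.4f), intercept = %.4f (SE %.4f) [%d SNPs, %d blocks]\n",
              x$h2, x$h2_se, x$intercept, x$intercept_se, x$n_snps, x$n_blocks))
  invisible(x)
}

#' @export
print.ldsc_rg_result <- function(x, ...) {
  cat(sprintf("LDSC rg = %.4f (SE %.4f, p = %.3g); gcov = %.4g; cross-trait intercept = %.4f\n",
              x$rg, x$rg_se, x$rg_p, x$gcov, x$intercept))
  invisible(x)
}
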