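#' Extreme-statistic prefilter
#'
#' Removes SNPs whose squared z-score exceeds 80 on either trait before
#' pleiotropy testing; such SNPs have overwhelming single-trait signal and
#' would dominate variance estimation.
#'
#' @param z1,z2 z-score vectors.
#' @param threshold Squared-z threshold (default 80; strictly greater is
#'   removed).
#' @return List with `keep` (logical index), `n_removed`.
#' @export
prefilter_z <- function(z1, z2, threshold = 80) {
  check_finite(z1, "z1"); check_finite(z2, "z2")
  keep <- z1^2 <= threshold & z2^2 <= threshold
  if (!any(keep)) stop("prefilter removed every SNP", call. = FALSE)
  list(keep = keep, n_removed = sum(!keep))
}

#' Cross-trait z-score correlation matrix
#'
#' Estimates the 2x2 correlation matrix of the two traits' z-scores over
#' SNPs that look null for both traits (|z| below 1.96 on each), the
#' subset where the correlation reflects shared samples rather than shared
#' genetic signal. Falls back to all SNPs with a warning when too few null
#' SNPs remain.
#'
#' @param z1,z2 z-score vectors (after [prefilter_z()]).
#' @param null_cut Absolute-z cutoff defining "null-ish" SNPs (default 1.96).
#' @param min_null Minimum null SNPs required (default 1000).
#' @return 2x2 correlation matrix.
#' @export
estimate_z_corr <- function(z1, z2, null_cut = 1.96, min_null = 1000) {
  stopifnot(length(z1) == length(z2))
  nullish <- abs(z1) < null_cut & abs(z2) < null_cut
  if (sum(nullish) < min_null) {
    warning("fewer than ", min_null,
            " null-ish SNPs; using all SNPs for the Z correlation")
    nullish <- rep(TRUE, length(z1))
  }
  r <- stats::cor(z1[nullish], z2[nullish])
  matrix(c(1, r, r, 1), 2, 2)
}

#' Decorrelate paired z-scores
#'
#' Applies the symmetric inverse square root of the 2x2 z correlation
#' matrix to each (z1, z2) pair, removing overlap-induced correlation
#' before product-based testing.
#'
#' @param z1,z2 z-score vectors.
#' @param R 2x2 correlation matrix from [estimate_z_corr()].
#' @return List with decorrelated `z1`, `z2`.
#' @export
decorrelate_z <- function(z1, z2, R) {
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-10)
    stop("z correlation matrix is (near-)singular; cannot decorrelate",
         call. = FALSE)
  Rinv_sqrt <- ev$vectors %*% diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  zz <- Rinv_sqrt %*% rbind(z1, z2)
  list(z1 = zz[1, ], z2 = zz[2, ])
}

#' Two-sided tail of the normal product distribution
#'
#' For independent standard normals Z, Z', the density of the product is
#' `K0(|t|)/pi` (modified Bessel function of the second kind, order zero),
#' which has an integrable log singularity at 0. The two-sided tail is
#' `F(x) = P(|Z Z'| >= |x|) = (2/pi) * integral_{|x|}^Inf K0(t) dt`,
#' evaluated by adaptive quadrature split at the singularity: `F(0) = 1`
#' exactly, and for `x != 0` the integral starts above the singular point.
#' For large |x| the exponentially scaled Bessel function keeps the
#' integrand well-conditioned.
#'
#' @param x Numeric vector (finite).
#' @return Tail probabilities: 1 at 0, symmetric in x, non-increasing in
#'   |x|; absolute accuracy near 1e-12 over |x| <= 40.
#' @export
normal_product_tail <- function(x) {
  check_finite(x, "x")
  one <- function(a) {
    a <- abs(a)
    if (a == 0) return(1)
    # integral of K0 from a to a+1 (direct), then a+1 to Inf via the
    # exponentially scaled form: K0(t) = e^{-t} K0e(t)
    i1 <- stats::integrate(function(t) besselK(t, 0), a, a + 1,
                           rel.tol = 1e-13, abs.tol = 1e-15,
                           subdivisions = 500L)$value
    i2 <- stats::integrate(function(u) {
      t <- a + 1 + u
      exp(-(t - a)) * besselK(t, 0, expon.scaled = TRUE) * exp(-a)
    }, 0, Inf, rel.tol = 1e-13, abs.tol = 1e-15, subdivisions = 500L)$value
    min(1, (2 / pi) * (i1 + i2))
  }
  vapply(x, one, numeric(1))
}

#' Composite-null pleiotropy p-value from a z-score product
#'
#' Tests the composite null that at most one of two traits is associated
#' with a variant, using the product of the traits' z-scores. The p-value
#' combines the normal-product tail F at three scalings of the product:
#' `p = F(z1 z2 / sqrt(var1)) + F(z1 z2 / sqrt(var2)) - F(z1 z2)`,
#' where `var1`, `var2` are the genome-wide variances of each trait's
#' z-scores (estimated after the extreme-statistic prefilter). When both
#' variances are 1 this reduces algebraically to `F(z1 z2)`. The
#' combination is an asymptotic approximation and can exceed 1 for small
#' products when the variances exceed 1; the result is clamped to (0, 1]
#' (values beyond the formula's algebraic range of (0, 2) raise an
#' internal error).
#'
#' @param z1,z2 z-score vectors.
#' @param var1,var2 Genome-wide z variances (positive).
#' @return P-value vector.
#' @export
placo_pvalue <- function(z1, z2, var1, var2) {
  if (any(c(var1, var2) <= 0)) stop("variances must be > 0", call. = FALSE)
  prod_z <- z1 * z2
  xs <- unique(c(prod_z / sqrt(var1), prod_z / sqrt(var2), prod_z))
  Fv <- normal_product_tail(xs)
  lookup <- function(v) Fv[match(v, xs)]
  p <- lookup(prod_z / sqrt(var1)) + lookup(prod_z / sqrt(var2)) -
    lookup(prod_z)
  if (any(p > 2 + 1e-9) || any(p < -1e-9))
    stop("internal error: composite p-value outside the formula's range",
         call. = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Genome-wide pleiotropy scan with locus definition
#'
#' Runs the composite-null product test on two munged z-score sets over
#' shared SNPs: applies the extreme-statistic (`z^2 > 80`) prefilter,
#' estimates the cross-trait z correlation (decorrelating when its
#' magnitude exceeds `decorrelate_above`), estimates genome-wide z
#' variances, computes per-SNP p-values, and organizes significant SNPs
#' (p < `p_threshold`) into loci: greedy clumping by ascending p absorbing
#' SNPs with `r² >= clump_r2`, then merging clumps whose lead SNPs lie
#' within `merge_kb` kilobases on the same chromosome.
#'
#' @param z1,z2 z-score vectors on the shared, allele-aligned SNP set.
#' @param ld An `ld_reference` (positions and pairwise r²) matching the
#'   SNP set.
#' @param p_threshold Genome-wide significance (default 5e-8).
#' @param clump_r2 r² at or above which a SNP joins a clump (default 0.2).
#' @param merge_kb Distance in kb within which clumps merge (default 500).
#' @param decorrelate_above Apply z decorrelation when the |off-diagonal|
#'   of the z correlation exceeds this value (default 0.05).
#' @return List of class `placo_result`: `snp_results` (data.frame: SNP,
#'   CHR, BP, z1, z2, stat, p, significant, lead, locus), `loci`
#'   (per-locus summary), `R` (z correlation), `var1`, `var2`,
#'   `n_prefiltered`.
#' @export
placo_scan <- function(z1, z2, ld, p_threshold = 5e-8, clump_r2 = 0.2,
                       merge_kb = 500, decorrelate_above = 0.05) {
  stopifnot(length(z1) == length(z2), length(z1) == length(ld$snp))
  pf <- prefilter_z(z1, z2)
  keep <- which(pf$keep)
  z1k <- z1[keep]; z2k <- z2[keep]
  R <- estimate_z_corr(z1k, z2k)
  if (abs(R[1, 2]) > decorrelate_above) {
    dz <- decorrelate_z(z1k, z2k, R)
    z1k <- dz$z1; z2k <- dz$z2
  }
  var1 <- stats::var(z1k); var2 <- stats::var(z2k)
  p <- placo_pvalue(z1k, z2k, var1, var2)

  res <- data.frame(SNP = ld$snp[keep], CHR = ld$chr[keep],
                    BP = ld$bp[keep], z1 = z1k, z2 = z2k,
                    stat = z1k * z2k, p = p,
                    significant = p < p_threshold,
                    lead = FALSE, locus = NA_integer_,
                    stringsAsFactors = FALSE)

  sig <- which(res$significant)
  if (length(sig)) {
    cl <- clump_snps(p = res$p[sig], idx = keep[sig], ld = ld,
                     r2_threshold = clump_r2, kb_window = Inf,
                     r2_rule = "ge")
    lead_rows <- match(keep[sig][cl$lead_local], keep)
    res$lead[lead_rows] <- TRUE
    # merge lead clumps into loci by chromosome/distance
    lr <- res[lead_rows, c("CHR", "BP")]
    ord <- order(lr$CHR, lr$BP)
    locus_id <- integer(length(ord))
    cur <- 0L
    for (i in seq_along(ord)) {
      if (i == 1 || lr$CHR[ord[i]] != lr$CHR[ord[i - 1]] ||
          lr$BP[ord[i]] - lr$BP[ord[i - 1]] > merge_kb * 1000)
        cur <- cur + 1L
      locus_id[ord[i]] <- cur
    }
    res$locus[lead_rows] <- locus_id
    # members inherit their clump lead's locus
    res$locus[match(keep[sig], keep)] <-
      locus_id[cl$assignment]
  }
  loci <- NULL
  if (any(res$lead)) {
    leads <- res[res$lead, ]
    agg <- split(leads, leads$locus)
    loci <- do.call(rbind, lapply(agg, function(d) {
      best <- d[which.min(d$p), ]
      data.frame(locus = best$locus, chr = best$CHR,
                 bp_min = min(d$BP), bp_max = max(d$BP),
                 n_leads = nrow(d), lead_snp = best$SNP, lead_p = best$p,
                 stringsAsFactors = FALSE)
    }))
    rownames(loci) <- NULL
  }
  structure(list(snp_results = res, loci = loci, R = R,
                 var1 = var1, var2 = var2, n_prefiltered = pf$n_removed),
            class = "placo_result")
}

#' Greedy LD clumping
#'
#' Orders candidate SNPs by ascending p-value; each unassigned SNP in turn
#' becomes an index (lead) SNP and absorbs every remaining SNP within
#' `kb_window` kilobases whose r² with it meets the rule: `"ge"` absorbs
#' r² >= `r2_threshold` (locus-definition convention), `"gt"` absorbs
#' r² > `r2_threshold` (instrument-pruning convention, where SNPs with
#' r² strictly below the threshold are kept as independent).
#'
#' @param p P-values of the candidate SNPs.
#' @param idx Indices of the candidates within the LD reference.
#' @param ld An `ld_reference` (or `NULL`: distance-only pruning, with a
#'   warning).
#' @param r2_threshold r² threshold.
#' @param kb_window Window in kb (Inf = no distance restriction).
#' @param r2_rule `"ge"` or `"gt"` (see above).
#' @return List with `lead_local` (positions of lead SNPs within the input
#'   order) and `assignment` (for every candidate, the ordinal of its
#'   lead among `lead_local`).
#' @export
clump_snps <- function(p, idx, ld, r2_threshold, kb_window = Inf,
                       r2_rule = c("ge", "gt")) {
  r2_rule <- match.arg(r2_rule)
  stopifnot(length(p) == length(idx))
  if (is.null(ld))
    warning("no LD reference supplied: clumping by distance only")
  n <- length(p)
  ord <- order(p)
  assigned <- rep(NA_integer_, n)
  leads <- integer(0)
  for (o in ord) {
    if (!is.na(assigned[o])) next
    leads <- c(leads, o)
    lead_no <- length(leads)
    assigned[o] <- lead_no
    open <- which(is.na(assigned))
    if (!length(open)) next
    if (is.null(ld)) {
      hit <- rep(TRUE, length(open))
    } else {
      same_chr <- ld$chr[idx[open]] == ld$chr[idx[o]]
      within <- same_chr & (is.infinite(kb_window) |
        abs(ld$bp[idx[open]] - ld$bp[idx[o]]) <= kb_window * 1000)
      r2 <- ld_r2(ld, rep.int(idx[o], length(open)), idx[open])
      hit <- within & (if (r2_rule == "ge") r2 >= r2_threshold else
        r2 > r2_threshold)
    }
    assigned[open[hit]] <- lead_no
  }
  list(lead_local = leads, assignment = assigned)
}

#' @export
print.placo_result <- function(x, ...) {
  n_sig <- sum(x$snp_results$significant)
  n_lead <- sum(x$snp_results$lead)
  n_loci <- if (is.null(x$loci)) 0 else nrow(x$loci)
  cat(sprintf("pleiotropy scan: %d SNPs tested (%d prefiltered), %d significant, %d lead SNPs in %d loci\n",
              nrow(x$snp_results), x$n_prefiltered, n_sig, n_lead, n_loci))
  cat(sprintf("z correlation = %.3f; Var(z) = %.3f / %.3f\n",
              x$R[1, 2], x$var1, x$var2))
  invisible(x)
}
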