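#' Configuration for a paired GWAS summary-statistics simulation
#'
#' Parameterizes two traits measured on (partially) overlapping samples with
#' given SNP heritabilities, genetic correlation, polygenicity, an optional
#' exposure-to-outcome causal effect (for Mendelian-randomization
#' scenarios) and optional horizontal pleiotropy.
#'
#' @param n_snps Number of SNPs (M).
#' @param n1,n2 GWAS sample sizes of trait 1 and trait 2.
#' @param h2_1,h2_2 SNP heritabilities in `[0, 1]`.
#' @param rg Genetic correlation in `[-1, 1]` (used when `causal_beta = 0`;
#'   with a causal effect the correlation is implied by the effect).
#' @param prop_causal Fraction of SNPs with nonzero trait-1 effects.
#' @param causal_beta True causal effect of trait 1 on trait 2 (per SD).
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean direct effects on
#'   trait 2) or `"directional"` (positive-mean direct effects).
#' @param pleiotropy_frac Fraction of causal SNPs carrying pleiotropic
#'   effects (default 0.3).
#' @param pleiotropy_scale SD of the pleiotropic direct effect relative to
#'   the SD of trait-1 causal effects (default 0.5).
#' @param n_overlap Number of samples shared between the two GWAS.
#' @param pheno_cor Phenotypic correlation among overlapping samples (drives
#'   the cross-trait correlation of null z-scores,
#'   `pheno_cor * n_overlap / sqrt(n1 n2)`).
#' @param ld_block_size SNPs per exchangeable LD block.
#' @param ld_r Within-block correlation r (so within-block r² = `ld_r^2`).
#' @param seed Integer seed.
#' @return An object of class `gwas_pair_config`.
#' @export
gwas_pair_config <- function(n_snps = 20000, n1 = 204402, n2 = 175226,
                             h2_1 = 0.0442, h2_2 = 0.1094, rg = -0.39,
                             prop_causal = 0.01, causal_beta = 0,
                             pleiotropy_mode = c("none", "balanced",
                                                 "directional"),
                             pleiotropy_frac = 0.3, pleiotropy_scale = 0.5,
                             n_overlap = 0, pheno_cor = 0,
                             ld_block_size = 50, ld_r = 0.55, seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (h2_1 < 0 || h2_1 > 1 || h2_2 < 0 || h2_2 > 1)
    stop("heritabilities must lie in [0, 1]", call. = FALSE)
  if (abs(rg) > 1) stop("|rg| must be <= 1", call. = FALSE)
  if (n_overlap > min(n1, n2))
    stop("n_overlap cannot exceed min(n1, n2)", call. = FALSE)
  if (prop_causal <= 0 || prop_causal > 1)
    stop("prop_causal must be in (0, 1]", call. = FALSE)
  structure(list(n_snps = as.integer(n_snps), n1 = n1, n2 = n2,
                 h2_1 = h2_1, h2_2 = h2_2, rg = rg,
                 prop_causal = prop_causal, causal_beta = causal_beta,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_frac = pleiotropy_frac,
                 pleiotropy_scale = pleiotropy_scale,
                 n_overlap = n_overlap, pheno_cor = pheno_cor,
                 ld_block_size = as.integer(ld_block_size), ld_r = ld_r,
                 seed = as.integer(seed)),
            class = "gwas_pair_config")
}

#' Block-diagonal LD reference
#'
#' SNPs are laid out along chromosomes in exchangeable blocks: within a
#' block every pair has the block's correlation `r_b` (r² = `r_b^2`),
#' across blocks zero. Block sizes and correlations cycle deterministically
#' over a spread around `block_size` and `r`, so that LD scores
#' `l_j = 1 + (B_b - 1) r_b^2` vary across the genome (a constant LD score
#' would make LD-score regression unidentifiable). Positions are 1-based
#' with a fixed spacing so that physical-distance clumping rules can act.
#'
#' @param n_snps Number of SNPs.
#' @param block_size Average SNPs per block (sizes cycle over roughly
#'   0.2x to 1.8x this value).
#' @param r Central within-block correlation (per-block values cycle over
#'   roughly +/- 0.25 around it, clamped to `[0.05, 0.95]`).
#' @param spacing Base-pair spacing between adjacent SNPs (default 20 kb).
#' @param n_chr Number of chromosomes to spread blocks over.
#' @return List of class `ld_reference`: `snp`, `chr`, `bp`, `l2`
#'   (LD scores), `block` (block index), `block_r` (per-block correlation),
#'   `block_size`, `r`.
#' @export
make_ld_reference <- function(n_snps, block_size = 50, r = 0.55,
                              spacing = 20000, n_chr = 22) {
  size_cycle <- pmax(1L, round(block_size *
                                 c(0.2, 1.4, 0.6, 1.8, 1.0, 0.4, 1.6, 0.8, 1.2)))
  r_cycle <- pmin(0.95, pmax(0.05,
                             r + c(0, -0.2, 0.15, -0.1, 0.25, -0.25, 0.1, 0.2, -0.15)))
  sizes <- integer(0); i <- 0L
  while (sum(sizes) < n_snps) {
    i <- i + 1L
    sizes <- c(sizes, size_cycle[(i - 1L) %% length(size_cycle) + 1L])
  }
  n_blocks <- length(sizes)
  block <- rep(seq_len(n_blocks), times = sizes)[seq_len(n_snps)]
  bs <- tabulate(block)
  block_r <- r_cycle[(seq_len(n_blocks) - 1L) %% length(r_cycle) + 1L]
  chr <- ((block - 1L) %% n_chr) + 1L
  # restart positions per chromosome
  bp <- integer(n_snps)
  for (cc in unique(chr)) {
    idx <- which(chr == cc)
    bp[idx] <- seq_along(idx) * spacing
  }
  l2 <- 1 + (bs[block] - 1) * block_r[block]^2
  structure(list(snp = paste0("rs", seq_len(n_snps)), chr = chr, bp = bp,
                 l2 = l2, block = block, block_r = block_r,
                 block_size = block_size, r = r),
            class = "ld_reference")
}

#' Pairwise r-squared from a block LD reference
#'
#' @param ld An `ld_reference`.
#' @param i,j SNP indices (vectors, recycled).
#' @return r² values (1 on the diagonal, the block's r² within a block,
#'   0 across blocks).
#' @export
ld_r2 <- function(ld, i, j) {
  same <- ld$block[i] == ld$block[j]
  rb <- ld$block_r[ld$block[i]]
  ifelse(i == j, 1, ifelse(same, rb^2, 0))
}

# Dense r² matrix (small references only, used by clumping oracles).
ld_r2_matrix <- function(ld) {
  n <- length(ld$snp)
  outer(seq_len(n), seq_len(n), function(i, j) ld_r2(ld, i, j))
}

random_alleles <- function(n, palindromic_frac = 0.1) {
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, n, replace = TRUE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # draw the other allele among non-complement bases, then impose the
  # palindromic (complement) pairs at exactly the requested fraction
  a2 <- vapply(a1, function(b) {
    sample(setdiff(bases, c(b, unname(comp[b]))), 1)
  }, character(1))
  pal <- stats::runif(n) < palindromic_frac
  a2[pal] <- comp[a1[pal]]
  list(a1 = a1, a2 = unname(a2), palindromic = a2 == comp[a1])
}

#' Generate paired GWAS summary statistics with known truth
#'
#' Simulates z-scores under the standard polygenic summary-statistic model
#' `z = sqrt(N) R beta + eps`, `eps ~ N(0, R)` per LD block, where `R` is the
#' block LD matrix and per-SNP true effects `beta` carry the configured
#' heritability, genetic correlation (or causal effect plus pleiotropy) and
#' polygenicity. Sample overlap makes the noise of the two traits correlated
#' with coefficient `pheno_cor * n_overlap / sqrt(n1 n2)`. This yields the
#' LD-score regression moments `E[chi2_j] = 1 + N h2 l_j / M` and
#' `E[z1 z2] = sqrt(n1 n2) rho_g l_j / M + pheno_cor n_overlap / sqrt(n1 n2)`.
#'
#' BETA, SE and P are mutually consistent: `SE = 1/sqrt(N)`,
#' `BETA = z * SE`, `P` the two-sided normal tail of z. A fraction of SNPs
#' receives palindromic (A/T or C/G) alleles with effect allele frequency
#' near 0.5 to exercise harmonization; a fraction of outcome rows is stored
#' with swapped or strand-flipped alleles (consistently sign-flipped), which
#' harmonization must undo.
#'
#' @param config A [gwas_pair_config()].
#' @param ld An `ld_reference` of matching length (built automatically if
#'   `NULL`).
#' @return List with `sumstats1`, `sumstats2` (data.frames with columns SNP,
#'   CHR, BP, A1, A2, EAF, BETA, SE, P, N), `ld`, and `truth` (per-SNP true
#'   effects and flags).
#' @export
generate_sumstats_pair <- function(config, ld = NULL) {
  stopifnot(inherits(config, "gwas_pair_config"))
  set.seed(config$seed)
  M <- config$n_snps
  if (is.null(ld))
    ld <- make_ld_reference(M, config$ld_block_size, config$ld_r)
  if (length(ld$snp) != M)
    stop("LD reference length does not match n_snps", call. = FALSE)

  n_causal <- max(1L, round(config$prop_causal * M))
  causal <- sort(sample.int(M, n_causal))
  is_causal <- seq_len(M) %in% causal

  # per-SNP true effects on the standardized scale
  b1 <- numeric(M); b2 <- numeric(M)
  s1 <- sqrt(config$h2_1 / n_causal)
  if (config$causal_beta == 0) {
    s2 <- sqrt(config$h2_2 / n_causal)
    rho <- config$rg
    z1 <- stats::rnorm(n_causal); zz <- stats::rnorm(n_causal)
    b1[causal] <- s1 * z1
    b2[causal] <- s2 * (rho * z1 + sqrt(max(0, 1 - rho^2)) * zz)
  } else {
    b1[causal] <- s1 * stats::rnorm(n_causal)
    b2 <- config$causal_beta * b1
  }
  pleio <- rep(FALSE, M)
  if (config$pleiotropy_mode != "none") {
    k <- round(config$pleiotropy_frac * n_causal)
    if (k > 0) {
      idx <- sample(causal, k)
      pleio[idx] <- TRUE
      sc <- config$pleiotropy_scale * s1
      if (config$pleiotropy_mode == "directional") {
        # direct effects aligned with the exposure-increasing allele, so
        # every affected Wald ratio is pushed the same way (the scenario
        # median/mode estimators defend against)
        b2[idx] <- b2[idx] + sign(b1[idx]) * stats::rnorm(k, sc, sc)
      } else {
        b2[idx] <- b2[idx] + stats::rnorm(k, 0, sc)
      }
    }
  }

  # noise correlation from sample overlap
  c_ov <- config$pheno_cor * config$n_overlap / sqrt(config$n1 * config$n2)
  if (abs(c_ov) >= 1) stop("overlap-induced correlation must be < 1",
                           call. = FALSE)

  z1 <- numeric(M); z2 <- numeric(M)
  for (b in unique(ld$block)) {
    idx <- which(ld$block == b)
    nb <- length(idx)
    r <- ld$block_r[b]
    # exchangeable R = (1-r) I + r J: use its structure directly
    mean1 <- sqrt(config$n1) * ((1 - r) * b1[idx] + r * sum(b1[idx]))
    mean2 <- sqrt(config$n2) * ((1 - r) * b2[idx] + r * sum(b2[idx]))
    # eps ~ N(0, R): eps = sqrt(1-r) u + sqrt(r) v 1 with u iid, v shared
    u1 <- stats::rnorm(nb); v1 <- stats::rnorm(1)
    uu <- stats::rnorm(nb); vv <- stats::rnorm(1)
    u2 <- c_ov * u1 + sqrt(1 - c_ov^2) * uu
    v2 <- c_ov * v1 + sqrt(1 - c_ov^2) * vv
    e1 <- sqrt(1 - r) * u1 + sqrt(r) * v1
    e2 <- sqrt(1 - r) * u2 + sqrt(r) * v2
    z1[idx] <- mean1 + e1
    z2[idx] <- mean2 + e2
  }

  al <- random_alleles(M)
  eaf <- stats::runif(M, 0.05, 0.95)
  eaf[al$palindromic] <- stats::runif(sum(al$palindromic), 0.40, 0.60)

  mk <- function(z, n) {
    se <- rep(1 / sqrt(n), M)
    data.frame(SNP = ld$snp, CHR = ld$chr, BP = ld$bp,
               A1 = al$a1, A2 = al$a2, EAF = eaf,
               BETA = z * se, SE = se,
               P = 2 * stats::pnorm(-abs(z)), N = n,
               stringsAsFactors = FALSE)
  }
  ss1 <- mk(z1, config$n1)
  ss2 <- mk(z2, config$n2)

  # scramble a subset of outcome rows: allele swap (consistent sign flip)
  # and/or strand complement, for harmonization to resolve
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  swap <- stats::runif(M) < 0.25
  ss2$A1[swap] <- ss1$A2[swap]; ss2$A2[swap] <- ss1$A1[swap]
  ss2$BETA[swap] <- -ss2$BETA[swap]
  ss2$EAF[swap] <- 1 - ss2$EAF[swap]
  flip <- stats::runif(M) < 0.15 & !al$palindromic
  ss2$A1[flip] <- comp[ss2$A1[flip]]
  ss2$A2[flip] <- comp[ss2$A2[flip]]

  list(sumstats1 = ss1, sumstats2 = ss2, ld = ld,
       truth = data.frame(SNP = ld$snp, beta1 = b1, beta2 = b2,
                          causal = is_causal, pleiotropic = pleio,
                          palindromic = al$palindromic,
                          swapped = swap, strand_flipped = flip,
                          stringsAsFactors = FALSE))
}

#' Write / read GWAS summary statistics as TSV
#'
#' Columns: SNP, CHR, BP, A1, A2, EAF, BETA, SE, P, N (1-based positions).
#'
#' @param ss Summary-statistics data.frame.
#' @param path File path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_sumstats_tsv <- function(ss, path) {
  utils::write.table(ss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats_tsv
#' @export
read_sumstats_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read LD scores as TSV (columns SNP, L2)
#' @param ld An `ld_reference`.
#' @param path File path.
#' @return `path` (write) or a data.frame with SNP and L2 (read).
#' @export
write_ldscores_tsv <- function(ld, path) {
  utils::write.table(data.frame(SNP = ld$snp, L2 = ld$l2), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ldscores_tsv
#' @export
read_ldscores_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
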