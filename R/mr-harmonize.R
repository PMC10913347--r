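#' Select genetic instruments from exposure summary statistics
#'
#' Keeps genome-wide significant SNPs (default P < 5e-8) and prunes them to
#' approximate linkage-equilibrium by greedy clumping: candidates are
#' visited by ascending p-value and any remaining SNP within the physical
#' window whose r² with the current index SNP is **not** below the r²
#' threshold is removed (instrument convention: `r² < 0.01` within 5000 kb
#' survives).
#'
#' @param exposure Summary-statistics data.frame (SNP, CHR, BP, P, ...).
#' @param ld An `ld_reference` aligned with `exposure` rows, or `NULL` for
#'   distance-only pruning (warns loudly).
#' @param p_threshold Significance threshold (default 5e-8).
#' @param clump_r2 r² threshold; SNPs with r² >= this are pruned
#'   (default 0.01).
#' @param clump_kb Physical window in kb (default 5000).
#' @return Character vector of retained instrument SNP ids.
#' @export
select_instruments <- function(exposure, ld = NULL, p_threshold = 5e-8,
                               clump_r2 = 0.01, clump_kb = 5000) {
  stopifnot(all(c("SNP", "P") %in% names(exposure)))
  sig <- which(exposure$P < p_threshold)
  if (!length(sig))
    stop("no SNPs reach the significance threshold ", p_threshold,
         call. = FALSE)
  cl <- clump_snps(p = exposure$P[sig], idx = sig, ld = ld,
                   r2_threshold = clump_r2, kb_window = clump_kb,
                   r2_rule = "ge")
  exposure$SNP[sig[cl$lead_local]]
}

is_palindromic <- function(a1, a2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  a2 == unname(comp[a1])
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect allele for the shared
#' SNP set. Allele pairs matching directly are kept; swapped pairs
#' (exposure A1/A2 = outcome A2/A1) have the outcome effect sign-flipped
#' and EAF complemented; strand-complement matches (direct or swapped after
#' complementing both outcome alleles) are resolved the same way.
#' Palindromic (A/T, C/G) SNPs with intermediate effect-allele frequency —
#' within `palindrome_eaf_window` — are dropped, since their strand cannot
#' be resolved; irreconcilable allele pairs are dropped and counted.
#'
#' @param exposure,outcome Summary-statistics data.frames (SNP, A1, A2,
#'   EAF, BETA, SE, P, N).
#' @param snps Optional SNP subset (e.g. from [select_instruments()]).
#' @param palindrome_eaf_window Intermediate-frequency window for dropping
#'   palindromic SNPs (default `c(0.42, 0.58)`).
#' @return Data.frame of class `harmonized_instruments`: SNP, effect_allele,
#'   other_allele, beta_exposure, se_exposure, p_exposure, beta_outcome,
#'   se_outcome, p_outcome, eaf, flipped; with attributes
#'   `n_palindromic_dropped` and `n_irreconcilable`.
#' @export
harmonize <- function(exposure, outcome, snps = NULL,
                      palindrome_eaf_window = c(0.42, 0.58)) {
  if (!is.null(snps)) exposure <- exposure[exposure$SNP %in% snps, ]
  shared <- intersect(exposure$SNP, outcome$SNP)
  if (!length(shared)) stop("no shared SNPs to harmonize", call. = FALSE)
  ex <- exposure[match(shared, exposure$SNP), ]
  ou <- outcome[match(shared, outcome$SNP), ]
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  direct <- ou$A1 == ex$A1 & ou$A2 == ex$A2
  swapped <- ou$A1 == ex$A2 & ou$A2 == ex$A1
  flip_direct <- unname(comp[ou$A1]) == ex$A1 & unname(comp[ou$A2]) == ex$A2
  flip_swapped <- unname(comp[ou$A1]) == ex$A2 & unname(comp[ou$A2]) == ex$A1
  pal <- is_palindromic(ex$A1, ex$A2)
  # for palindromic SNPs "swapped" and "flipped-direct" are the same pair;
  # orientation is ambiguous and intermediate-EAF ones must go
  resolvable <- direct | swapped | flip_direct | flip_swapped
  intermediate <- ex$EAF >= palindrome_eaf_window[1] &
    ex$EAF <= palindrome_eaf_window[2]
  drop_pal <- pal & intermediate
  keep <- resolvable & !drop_pal

  n_irr <- sum(!resolvable)
  n_pal <- sum(drop_pal & resolvable)

  # sign flip when alleles are swapped relative to the exposure orientation;
  # palindromic kept SNPs are aligned by frequency (EAF agreement)
  needs_flip <- (swapped | flip_swapped) & !pal
  pal_keep <- pal & keep
  if (any(pal_keep)) {
    eaf_mismatch <- abs(ou$EAF - ex$EAF) > abs((1 - ou$EAF) - ex$EAF)
    needs_flip[pal_keep] <- eaf_mismatch[pal_keep]
  }

  h <- data.frame(
    SNP = shared, effect_allele = ex$A1, other_allele = ex$A2,
    beta_exposure = ex$BETA, se_exposure = ex$SE, p_exposure = ex$P,
    beta_outcome = ifelse(needs_flip, -ou$BETA, ou$BETA),
    se_outcome = ou$SE, p_outcome = ou$P,
    eaf = ex$EAF, flipped = needs_flip,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(h) <- NULL
  if (any(h$se_exposure <= 0 | h$se_outcome <= 0))
    stop("non-positive standard errors after harmonization", call. = FALSE)
  attr(h, "n_palindromic_dropped") <- n_pal
  attr(h, "n_irreconcilable") <- n_irr
  class(h) <- c("harmonized_instruments", "data.frame")
  h
}
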