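# Shared fixture builders; everything is generated in code at test time.

# A small harmonized instrument set with a known causal slope and optional
# per-SNP direct (pleiotropic) effects on the outcome.
make_instruments <- function(k = 20, theta = 0.1, se_x = 0.01, se_y = 0.01,
                             pleiotropy = rep(0, k), seed = 1) {
  set.seed(seed)
  bx_true <- stats::runif(k, 0.05, 0.2)
  bx <- stats::rnorm(k, bx_true, se_x)
  by <- stats::rnorm(k, theta * bx_true + pleiotropy, se_y)
  h <- data.frame(SNP = paste0("rs", seq_len(k)),
                  effect_allele = "A", other_allele = "G",
                  beta_exposure = bx, se_exposure = se_x,
                  p_exposure = 2 * stats::pnorm(-abs(bx / se_x)),
                  beta_outcome = by, se_outcome = se_y,
                  p_outcome = 2 * stats::pnorm(-abs(by / se_y)),
                  eaf = 0.3, flipped = FALSE, stringsAsFactors = FALSE)
  class(h) <- c("harmonized_instruments", "data.frame")
  h
}

# Independent brute-force clumping oracle: works on an explicit r2 matrix
# and p-values; repeatedly takes the globally smallest remaining p as a
# lead and deletes everything linked to it (distance + r2 rule).
brute_force_clump <- function(p, chr, bp, r2mat, r2_threshold, kb_window,
                              rule = c("ge", "gt")) {
  rule <- match.arg(rule)
  remaining <- seq_along(p)
  leads <- integer(0)
  while (length(remaining)) {
    lead <- remaining[which.min(p[remaining])]
    leads <- c(leads, lead)
    linked <- vapply(remaining, function(j) {
      if (j == lead) return(TRUE)
      if (chr[j] != chr[lead]) return(FALSE)
      if (is.finite(kb_window) && abs(bp[j] - bp[lead]) > kb_window * 1000)
        return(FALSE)
      if (rule == "ge") r2mat[lead, j] >= r2_threshold else
        r2mat[lead, j] > r2_threshold
    }, logical(1))
    remaining <- remaining[!linked]
  }
  sort(leads)
}

# small random LD reference for clumping comparisons
random_toy_ld <- function(n, seed) {
  set.seed(seed)
  make_ld_reference(n, block_size = sample(2:6, 1),
                    r = stats::runif(1, 0.2, 0.9),
                    spacing = sample(c(5e4, 3e5, 7e5), 1), n_chr = 3)
}
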