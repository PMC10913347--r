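test_that("instrument selection applies the significance threshold and the clumping oracle", {
  p <- generate_sumstats_pair(gwas_pair_config(n_snps = 2000, n1 = 3e5,
                                               h2_1 = 0.1, prop_causal = 0.05,
                                               causal_beta = 0.05,
                                               ld_block_size = 20, seed = 71))
  iv <- select_instruments(p$sumstats1, ld = p$ld)
  expect_gt(length(iv), 10)
  sel <- p$sumstats1[match(iv, p$sumstats1$SNP), ]
  expect_true(all(sel$P < 5e-8))
  # no two retained instruments share a block (within-block r2 >= 0.01 here)
  blocks <- p$ld$block[match(iv, p$ld$snp)]
  expect_equal(anyDuplicated(blocks), 0L)

  # brute-force equivalence on toy instances, instrument rule (r2 >= thr pruned)
  for (s in 1:8) {
    ld <- random_toy_ld(n = sample(10:40, 1), seed = 900 + s)
    n <- length(ld$snp)
    set.seed(950 + s)
    ss <- data.frame(SNP = ld$snp, CHR = ld$chr, BP = ld$bp,
                     P = 10^-runif(n, 6, 12), stringsAsFactors = FALSE)
    got <- select_instruments(ss, ld, p_threshold = 1e-5,
                              clump_r2 = 0.01, clump_kb = 5000)
    r2mat <- outer(seq_len(n), seq_len(n), function(i, j) ld_r2(ld, i, j))
    want <- brute_force_clump(ss$P, ld$chr, ld$bp, r2mat, 0.01, 5000, "ge")
    expect_equal(sort(match(got, ld$snp)), want)
  }

  ss_ns <- data.frame(SNP = "rs1", CHR = 1, BP = 1, P = 1e-4)
  expect_error(select_instruments(ss_ns, NULL), "threshold")
})

test_that("two significant SNPs just under the r2 rule both survive", {
  ld <- structure(list(snp = c("rs1", "rs2"), chr = c(1L, 1L),
                       bp = c(1L, 100001L), l2 = c(1.0064, 1.0064),
                       block = c(1L, 1L), block_r = sqrt(0.0064),
                       block_size = 2, r = sqrt(0.0064)),
                  class = "ld_reference")
  ss <- data.frame(SNP = c("rs1", "rs2"), CHR = 1, BP = c(1, 100001),
                   P = c(1e-10, 1e-9), stringsAsFactors = FALSE)
  # within-block r2 = 0.0064 < 0.01 -> kept apart
  expect_equal(sort(select_instruments(ss, ld)), c("rs1", "rs2"))
})

test_that("harmonization aligns alleles, drops ambiguous palindromes, and is idempotent", {
  ex <- data.frame(SNP = c("s1", "s2", "s3", "s4", "s5"),
                   A1 = c("A", "A", "A", "C", "A"),
                   A2 = c("G", "T", "G", "G", "C"),
                   EAF = c(0.3, 0.50, 0.3, 0.45, 0.2),
                   BETA = c(0.1, 0.2, 0.15, 0.12, 0.08),
                   SE = rep(0.01, 5), P = rep(1e-10, 5), N = 1e5,
                   stringsAsFactors = FALSE)
  ou <- ex
  ou$BETA <- c(0.05, 0.1, -0.07, 0.06, 0.04)
  # s3: swapped alleles; s4: strand-complemented; s5: irreconcilable
  ou$A1[3] <- "G"; ou$A2[3] <- "A"; ou$EAF[3] <- 0.7
  ou$A1[4] <- "G"; ou$A2[4] <- "C"
  ou$A2[5] <- "T"
  h <- harmonize(ex, ou)
  expect_false("s2" %in% h$SNP)            # A/T with EAF 0.5 dropped
  expect_false("s5" %in% h$SNP)
  expect_equal(attr(h, "n_palindromic_dropped"), 2L)  # s2 and s4
  expect_equal(attr(h, "n_irreconcilable"), 1L)
  expect_equal(h$beta_outcome[h$SNP == "s3"], 0.07)   # sign restored
  expect_true(h$flipped[h$SNP == "s3"])
  # s4 is palindromic C/G at EAF 0.45 -> inside the default window, dropped?
  # no: window is [0.42, 0.58]; 0.45 falls inside, so s4 is dropped too
  expect_false("s4" %in% h$SNP)

  # idempotence: re-harmonizing the aligned tables changes nothing
  ex2 <- data.frame(SNP = h$SNP, A1 = h$effect_allele, A2 = h$other_allele,
                    EAF = h$eaf, BETA = h$beta_exposure, SE = h$se_exposure,
                    P = h$p_exposure, N = 1e5, stringsAsFactors = FALSE)
  ou2 <- data.frame(SNP = h$SNP, A1 = h$effect_allele, A2 = h$other_allele,
                    EAF = h$eaf, BETA = h$beta_outcome, SE = h$se_outcome,
                    P = h$p_outcome, N = 1e5, stringsAsFactors = FALSE)
  h2 <- harmonize(ex2, ou2)
  expect_equal(h2$beta_outcome, h$beta_outcome)
  expect_equal(h2$beta_exposure, h$beta_exposure)
  expect_false(any(h2$flipped))
})

test_that("generator truth survives harmonization without spurious flips", {
  p <- generate_sumstats_pair(gwas_pair_config(n_snps = 1500, n1 = 3e5,
                                               n2 = 3e5, h2_1 = 0.15,
                                               prop_causal = 0.1,
                                               causal_beta = 0.1,
                                               ld_block_size = 10, seed = 73))
  h <- harmonize(p$sumstats1, p$sumstats2)
  tr <- p$truth[match(h$SNP, p$truth$SNP), ]
  # non-palindromic SNPs: the flip flag reconstructs exactly the allele
  # swaps the generator applied
  nonpal <- !tr$palindromic
  expect_equal(h$flipped[nonpal], tr$swapped[nonpal])
  # alignment check via regression: slope near the causal effect
  fit <- lm(h$beta_outcome ~ 0 + h$beta_exposure,
            weights = 1 / h$se_outcome^2)
  expect_lt(abs(unname(coef(fit)) - 0.1), 0.02)
})

test_that("IVW: Wald-ratio limit, recovery, and the fixed/random relationship", {
  h1 <- make_instruments(k = 1, theta = 0.1, seed = 1)
  expect_warning(e1 <- ivw(h1), "single instrument")
  expect_equal(e1$estimate, h1$beta_outcome / h1$beta_exposure)

  h <- make_instruments(k = 50, theta = 0.1, seed = 2)
  e <- ivw(h)
  expect_lt(abs(e$estimate - 0.1), 3 * e$se)
  ef <- ivw(h, mode = "fixed")
  expect_equal(e$estimate, ef$estimate)
  expect_gte(e$se, ef$se * 0.999999)

  # identical ratios: Q = 0 and fixed = random
  hid <- make_instruments(k = 10, theta = 0.2, se_x = 1e-12, se_y = 1e-12,
                          seed = 3)
  hid$beta_outcome <- 0.2 * hid$beta_exposure
  eid <- ivw(hid)
  expect_equal(eid$ancillary$Q, 0, tolerance = 1e-6)
  expect_equal(eid$estimate, 0.2, tolerance = 1e-10)
})

test_that("estimators are equivariant under exposure rescaling", {
  h <- make_instruments(k = 30, theta = 0.08, seed = 4)
  hs <- h
  hs$beta_exposure <- h$beta_exposure * 4
  hs$se_exposure <- h$se_exposure * 4
  expect_equal(ivw(hs)$estimate, ivw(h)$estimate / 4, tolerance = 1e-10)
  expect_equal(egger(hs)$estimate, egger(h)$estimate / 4, tolerance = 1e-10)
  expect_equal(weighted_median(hs, n_boot = 50)$estimate,
               weighted_median(h, n_boot = 50)$estimate / 4,
               tolerance = 1e-10)
  expect_equal(maximum_likelihood(hs)$estimate,
               maximum_likelihood(h)$estimate / 4, tolerance = 1e-6)
})

test_that("Egger: intercept recovers injected directional pleiotropy; constrained slope equals IVW", {
  ints <- vapply(1:20, function(s) {
    h <- make_instruments(k = 60, theta = 0.1,
                          pleiotropy = rep(0.01, 60), seed = 100 + s)
    egger(h)$ancillary$egger_intercept
  }, numeric(1))
  expect_lt(abs(mean(ints) - 0.01), 0.004)

  h0 <- make_instruments(k = 60, theta = 0.1, seed = 5)
  e0 <- egger(h0)
  expect_lt(abs(e0$ancillary$egger_intercept),
            2 * e0$ancillary$intercept_se)

  # algebraic oracle: zero-intercept weighted regression reproduces IVW
  w <- 1 / h0$se_outcome^2
  slope0 <- sum(w * h0$beta_exposure * h0$beta_outcome) /
    sum(w * h0$beta_exposure^2)
  expect_equal(slope0, ivw(h0, mode = "fixed")$estimate, tolerance = 1e-12)

  expect_error(egger(make_instruments(k = 2)), ">= 3")
})

test_that("weighted median resists 40% invalid instruments where IVW does not", {
  res <- t(vapply(1:20, function(s) {
    k <- 50
    plei <- c(rep(0.08, 20), rep(0, 30))   # 40% pleiotropic
    h <- make_instruments(k = k, theta = 0.1, pleiotropy = plei,
                          seed = 200 + s)
    c(ivw = ivw(h)$estimate,
      med = weighted_median(h, n_boot = 100, seed = s)$estimate)
  }, numeric(2)))
  bias_ivw <- abs(res[, "ivw"] - 0.1)
  bias_med <- abs(res[, "med"] - 0.1)
  expect_gt(mean(bias_med < bias_ivw), 0.85)

  # degenerate: uniform weights make weighted = simple median
  h <- make_instruments(k = 15, theta = 0.1, seed = 6)
  h$se_outcome <- rep(0.01, 15)
  h$beta_exposure <- rep(0.1, 15)   # equal ratio SEs
  wm <- weighted_median(h, n_boot = 50, seed = 1)
  sm <- weighted_median(h, n_boot = 50, seed = 1, weighted = FALSE)
  expect_equal(wm$estimate, sm$estimate, tolerance = 1e-10)
})

test_that("all estimators agree on clean data; constant ratios return the constant", {
  h <- make_instruments(k = 80, theta = 0.06, se_x = 0.002, se_y = 0.002,
                        seed = 7)
  e_ivw <- ivw(h)
  for (f in list(egger, function(x) weighted_median(x, n_boot = 100),
                 maximum_likelihood, penalized_ivw, mr_raps)) {
    e <- f(h)
    expect_lt(abs(e$estimate - e_ivw$estimate), 2 * e_ivw$se + 2 * e$se)
  }

  hc <- make_instruments(k = 12, theta = 0.3, se_x = 1e-12, se_y = 1e-12,
                         seed = 8)
  hc$beta_outcome <- 0.3 * hc$beta_exposure
  expect_equal(ivw(hc)$estimate, 0.3, tolerance = 1e-8)
  expect_equal(weighted_median(hc, n_boot = 20)$estimate, 0.3,
               tolerance = 1e-8)
  expect_equal(simple_mode(hc, n_boot = 20)$estimate, 0.3, tolerance = 0.01)
  expect_equal(maximum_likelihood(hc)$estimate, 0.3, tolerance = 1e-6)
})

test_that("Cochran's Q: zero under homogeneity, k=2 hand-algebra oracle, power under overdispersion", {
  hc <- make_instruments(k = 8, theta = 0.2, se_x = 1e-12, se_y = 1e-12,
                         seed = 9)
  hc$beta_outcome <- 0.2 * hc$beta_exposure
  q0 <- cochran_q(hc)
  expect_equal(q0$Q, 0, tolerance = 1e-6)
  expect_equal(q0$p, 1, tolerance = 1e-6)

  # k = 2 with equal weights: Q = ((r1 - r2)/se)^2 / 2
  h2 <- make_instruments(k = 2, theta = 0.1, seed = 10)
  h2$beta_exposure <- c(0.1, 0.1); h2$se_outcome <- c(0.01, 0.01)
  h2$beta_outcome <- c(0.012, 0.007)
  r <- h2$beta_outcome / h2$beta_exposure
  se_r <- h2$se_outcome / h2$beta_exposure
  expect_equal(cochran_q(h2)$Q, ((r[1] - r[2]) / se_r[1])^2 / 2,
               tolerance = 1e-10)

  # overdispersed ratios: Q detects heterogeneity in most replicates
  hits <- mean(vapply(1:20, function(s) {
    h <- make_instruments(k = 40, theta = 0.1,
                          pleiotropy = rnorm(40, 0, 0.05), seed = 300 + s)
    cochran_q(h)$p < 0.05
  }, logical(1)))
  expect_gte(hits, 0.8)
})

test_that("MR-PRESSO flags a planted outlier and its correction moves toward truth", {
  h <- make_instruments(k = 30, theta = 0.1, seed = 11)
  h$beta_outcome[7] <- h$beta_outcome[7] + 0.12   # gross pleiotropy
  pr <- mr_presso(h, n_sim = 300, seed = 12)
  expect_true(pr$outliers$significant[7])
  expect_lt(pr$global_p, 0.05)
  expect_lt(abs(pr$corrected$estimate - 0.1), abs(pr$raw$estimate - 0.1))

  # determinism
  pr2 <- mr_presso(h, n_sim = 300, seed = 12)
  expect_identical(pr$global_p, pr2$global_p)
  expect_identical(pr$corrected$estimate, pr2$corrected$estimate)

  expect_error(mr_presso(h, n_sim = 50), "n_sim")
  expect_error(mr_presso(make_instruments(k = 3)), ">= 4")
})

test_that("MR-PRESSO global p is well calibrated without outliers", {
  ps <- vapply(1:15, function(s) {
    h <- make_instruments(k = 25, theta = 0.1, seed = 400 + s)
    mr_presso(h, n_sim = 200, seed = s)$global_p
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.7)
})

test_that("leave-one-out is stable for homogeneous sets and flags a dominant outlier", {
  h <- make_instruments(k = 3, theta = 0.1, seed = 13)
  expect_equal(nrow(leave_one_out(h)), 3)

  hh <- make_instruments(k = 30, theta = 0.1, se_x = 0.002, se_y = 0.002,
                         seed = 14)
  loo <- leave_one_out(hh)
  expect_false(any(loo$flagged))

  ho <- hh
  ho$beta_outcome[5] <- ho$beta_outcome[5] + 0.3
  loo2 <- leave_one_out(ho)
  expect_true(loo2$flagged[5])
  expect_equal(sum(loo2$flagged), 1)
})

test_that("ML handles exposure measurement error better than the naive ratio mean", {
  # moderate exposure-side error: the plain ratio mean is biased upward by
  # the 1/bx expansion, ML models the error explicitly
  res <- t(vapply(1:20, function(s) {
    h <- make_instruments(k = 100, theta = 0.1, se_x = 0.02, se_y = 0.005,
                          seed = 500 + s)
    c(ml = maximum_likelihood(h)$estimate,
      naive = mean(h$beta_outcome / h$beta_exposure))
  }, numeric(2)))
  expect_lt(abs(mean(res[, "ml"]) - 0.1), abs(mean(res[, "naive"]) - 0.1))
})

test_that("penalized IVW and RAPS resist 10% outliers better than fixed IVW", {
  res <- t(vapply(1:15, function(s) {
    k <- 50
    plei <- c(rep(0.15, 5), rep(0, 45))
    h <- make_instruments(k = k, theta = 0.1, pleiotropy = plei,
                          seed = 600 + s)
    c(ivw = ivw(h, mode = "fixed")$estimate,
      pen = penalized_ivw(h)$estimate,
      raps = mr_raps(h)$estimate)
  }, numeric(3)))
  expect_lt(abs(mean(res[, "pen"]) - 0.1), abs(mean(res[, "ivw"]) - 0.1))
  expect_lt(abs(mean(res[, "raps"]) - 0.1), abs(mean(res[, "ivw"]) - 0.1))
})

test_that("the full suite reports every named method and surfaces pleiotropy tension", {
  h <- make_instruments(k = 40, theta = 0.1,
                        pleiotropy = rep(0.03, 40), seed = 15)
  s <- mr_suite(h, n_boot = 100, n_sim = 150, seed = 16)
  expect_setequal(
    s$estimates$method,
    c("IVW (multiplicative-random)", "MR-Egger", "weighted median",
      "simple mode", "weighted mode", "maximum likelihood",
      "penalized IVW", "MR-RAPS"))
  expect_true(all(s$estimates$or > 0))
  expect_true(all(s$estimates$or_ci_low <= s$estimates$or))
  expect_true(all(s$estimates$or_ci_high >= s$estimates$or))
})
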