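#' Configuration for the synthetic two-wave cohort
#'
#' Defines a cohort of middle-aged/older subjects with a right-skewed
#' (lognormal) hs-CRP distribution, 41 binary health-deficit items measured
#' at two waves, and a controllable true effect of the high (vs low) hs-CRP
#' tertile on the follow-up frailty state.
#'
#' Defaults emulate a Chinese middle-aged/older community cohort:
#' lognormal CRP with mean
#' ~2.4 mg/L and tertile boundaries near 0.90 and 2.00 mg/L; baseline
#' frailty propensity from Beta(2, 14) giving a health/pre-frailty mix with
#' a small frail tail.
#'
#' @param n_subjects Number of subjects.
#' @param n_deficits Number of deficit items (default 41).
#' @param crp_lognormal_mu,crp_lognormal_sigma Log-scale location and scale
#'   of hs-CRP (mg/L).
#' @param baseline_fi_beta_params Shape pair of the Beta distribution for
#'   the baseline per-subject deficit propensity.
#' @param crp_effect_logodds True log-odds effect of the high-vs-low CRP
#'   tertile on the follow-up frailty state (middle tertile gets half the
#'   effect on the log-odds scale).
#' @param covariate_spec Optional list of covariates; each element is a list
#'   with `name`, `dist` ("normal" or "binary"), `params` (mean/sd or
#'   prevalence), `beta_outcome` (effect on the wave-2 state log-odds) and
#'   `beta_crp` (effect on log hs-CRP, creating confounding when both are
#'   nonzero).
#' @param missing_rate MCAR missingness proportion applied to deficit items.
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 6890, n_deficits = 41,
                          crp_lognormal_mu = 0.378,
                          crp_lognormal_sigma = 0.985,
                          baseline_fi_beta_params = c(2, 14),
                          crp_effect_logodds = 0,
                          covariate_spec = list(),
                          missing_rate = 0, seed = 1L) {
  stopifnot(n_subjects >= 1, n_deficits >= 1)
  vals <- c(crp_lognormal_mu, crp_lognormal_sigma, baseline_fi_beta_params,
            crp_effect_logodds, missing_rate)
  if (any(!is.finite(vals)))
    stop("cohort_config parameters must be finite", call. = FALSE)
  if (crp_lognormal_sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  if (any(baseline_fi_beta_params <= 0))
    stop("beta params must be positive", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_deficits = as.integer(n_deficits),
                 crp_lognormal_mu = crp_lognormal_mu,
                 crp_lognormal_sigma = crp_lognormal_sigma,
                 baseline_fi_beta_params = baseline_fi_beta_params,
                 crp_effect_logodds = crp_effect_logodds,
                 covariate_spec = covariate_spec,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# deficit count drawn from Binomial(n_items, q) conditioned to the count
# range of a frailty category; inversion on the truncated pmf
rtrunc_binom_count <- function(n, size, prob, lo, hi) {
  ks <- lo:hi
  pmf <- stats::dbinom(ks, size, prob)
  if (sum(pmf) <= 0) pmf <- rep(1, length(ks))
  ks[sample.int(length(ks), n, replace = TRUE, prob = pmf)]
}

# count range per category for a given item count (FI thresholds 0.10/0.25)
category_count_range <- function(category, n_items) {
  lo_pre <- ceiling(0.10 * n_items)
  lo_frail <- ceiling(0.25 * n_items)
  switch(category,
         health = c(0L, lo_pre - 1L),
         `pre-frailty` = c(lo_pre, lo_frail - 1L),
         frailty = c(lo_frail, n_items))
}

#' Generate a synthetic two-wave deficit cohort
#'
#' Baseline deficit counts come from per-subject propensities drawn from a
#' Beta distribution; hs-CRP is lognormal (optionally shifted by covariates).
#' The wave-2 frailty state (health / pre-frailty / frailty) is drawn from a
#' proportional-odds model whose linear predictor contains the baseline
#' category, the CRP-tertile score scaled by `crp_effect_logodds`, and any
#' covariate effects; the wave-2 deficit count is then drawn from a
#' category-consistent truncated binomial so that the recomputed FI always
#' matches the drawn state. Under this construction the true high-vs-low
#' conditional odds ratio for any dichotomized state boundary equals
#' `exp(crp_effect_logodds)`.
#'
#' @param config A [cohort_config()].
#' @return List with `cohort` (data.frame: id, crp, tertile, covariates,
#'   fi_w1/fi_w2 and categories from complete data) and `deficits_w1`,
#'   `deficits_w2` (binary matrices with `NA`s at `missing_rate`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  m <- config$n_deficits

  # covariates
  covs <- list()
  eta_cov <- numeric(n)
  crp_shift <- numeric(n)
  for (cs in config$covariate_spec) {
    x <- switch(cs$dist,
                normal = stats::rnorm(n, cs$params[1], cs$params[2]),
                binary = stats::rbinom(n, 1, cs$params[1]),
                stop("unknown covariate distribution: ", cs$dist,
                     call. = FALSE))
    covs[[cs$name]] <- x
    if (!is.null(cs$beta_outcome)) eta_cov <- eta_cov + cs$beta_outcome * x
    if (!is.null(cs$beta_crp)) crp_shift <- crp_shift + cs$beta_crp * x
  }

  crp <- exp(stats::rnorm(n, config$crp_lognormal_mu + crp_shift,
                          config$crp_lognormal_sigma))
  tertile <- assign_crp_tertile(crp, mode = "fixed")
  tert_score <- c(low = 0, middle = 0.5, high = 1)[as.character(tertile)]

  # wave 1
  p1 <- stats::rbeta(n, config$baseline_fi_beta_params[1],
                     config$baseline_fi_beta_params[2])
  count1 <- stats::rbinom(n, m, p1)
  cat1 <- as.character(categorize_fi(count1 / m))

  # wave 2: proportional-odds state model; cutpoints tuned so that a
  # pre-frail baseline subject has ~10% frailty / ~31% regression odds at
  # the reference (low) tertile, and a healthy baseline subject ~3% / ~55%
  eta_base <- c(health = -1.2, `pre-frailty` = 0.9, frailty = 2.2)[cat1]
  eta <- eta_base + config$crp_effect_logodds * tert_score + eta_cov
  c_frail <- 3.1   # P(frailty)      = plogis(eta - c_frail)
  c_pre <- 0.1     # P(>= pre-frail) = plogis(eta - c_pre)
  u <- stats::runif(n)
  p_frail <- stats::plogis(eta - c_frail)
  p_ge_pre <- stats::plogis(eta - c_pre)
  cat2 <- ifelse(u < p_frail, "frailty",
                 ifelse(u < p_ge_pre, "pre-frailty", "health"))

  # wave-2 deficit count consistent with the drawn state
  q_cat <- c(health = 0.05, `pre-frailty` = 0.16, frailty = 0.32)
  count2 <- integer(n)
  for (cc in c("health", "pre-frailty", "frailty")) {
    idx <- which(cat2 == cc)
    if (!length(idx)) next
    rg <- category_count_range(cc, m)
    count2[idx] <- rtrunc_binom_count(length(idx), m, q_cat[[cc]],
                                      rg[1], rg[2])
  }

  # scatter counts into item matrices
  fill_items <- function(counts) {
    mat <- matrix(0L, n, m,
                  dimnames = list(paste0("s", seq_len(n)),
                                  paste0("item", seq_len(m))))
    for (i in seq_len(n))
      if (counts[i] > 0) mat[i, sample.int(m, counts[i])] <- 1L
    mat
  }
  d1 <- fill_items(count1)
  d2 <- fill_items(count2)

  if (config$missing_rate > 0) {
    for (mm in c("d1", "d2")) {
      mat <- get(mm)
      mask <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
      # never blank out a full row
      full_row <- rowSums(mask) == m
      mask[full_row, 1] <- FALSE
      mat[mask] <- NA
      assign(mm, mat)
    }
  }

  cohort <- data.frame(id = paste0("s", seq_len(n)), crp = crp,
                       tertile = tertile,
                       fi_w1 = count1 / m, fi_w2 = count2 / m,
                       cat_w1 = cat1, cat_w2 = cat2,
                       stringsAsFactors = FALSE)
  for (nm in names(covs)) cohort[[nm]] <- covs[[nm]]
  cohort$transition <- classify_transition(cat1, cat2)
  list(cohort = cohort, deficits_w1 = d1, deficits_w2 = d2,
       config = config)
}

#' Write / read a cohort table
#'
#' The cohort is stored as a plain CSV with a header row and one row per
#' subject; deficit matrices are stored wide with `w1_`/`w2_` prefixes.
#'
#' @param x Result of [generate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(x, path) {
  d1 <- x$deficits_w1; colnames(d1) <- paste0("w1_", colnames(d1))
  d2 <- x$deficits_w2; colnames(d2) <- paste0("w2_", colnames(d2))
  utils::write.csv(cbind(x$cohort, d1, d2), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  w1 <- as.matrix(df[, grepl("^w1_", names(df)), drop = FALSE])
  w2 <- as.matrix(df[, grepl("^w2_", names(df)), drop = FALSE])
  colnames(w1) <- sub("^w1_", "", colnames(w1))
  colnames(w2) <- sub("^w2_", "", colnames(w2))
  list(cohort = df[, !grepl("^w[12]_", names(df)), drop = FALSE],
       deficits_w1 = w1, deficits_w2 = w2)
}
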