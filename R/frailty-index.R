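#' Deficit-accumulation frailty index
#'
#' The frailty index (FI) of a subject is the proportion of health deficits
#' present out of a fixed item list: the number of deficits divided by the
#' number of items considered, a value between 0 and 1 with higher values
#' indicating a more vulnerable state.
#'
#' @param deficits Numeric or logical vector of binary deficit indicators
#'   (0/1), possibly with `NA` for unmeasured items.
#' @param n_items Total number of items in the index. Defaults to the length
#'   of `deficits`. Missing items are excluded from both numerator and
#'   denominator, so the FI is the deficit proportion among measured items.
#' @param subject Optional subject label used in error messages.
#'
#' @return FI as a single number in `[0, 1]`.
#' @examples
#' compute_fi(c(1, 0, 0, 1, 0))      # 0.4
#' compute_fi(rep(0, 41))            # 0
#' @export
compute_fi <- function(deficits, n_items = length(deficits), subject = NULL) {
  x <- as.numeric(deficits)
  if (any(!is.na(x) & !(x %in% c(0, 1))))
    stop("deficit items must be binary (0/1) or NA", call. = FALSE)
  obs <- !is.na(x)
  if (!any(obs))
    stop(sprintf("all %d deficit items missing%s", n_items,
                 if (is.null(subject)) "" else paste0(" for subject ", subject)),
         call. = FALSE)
  # missing items shrink the denominator; with complete data this is
  # sum(deficits)/n_items
  sum(x[obs]) / sum(obs)
}

#' Compute frailty indices for a deficit matrix
#'
#' @param mat subjects x items matrix of binary deficits (NA allowed).
#' @return Numeric vector of FIs, one per row.
#' @export
compute_fi_matrix <- function(mat) {
  mat <- as.matrix(mat)
  ids <- rownames(mat)
  vapply(seq_len(nrow(mat)), function(i) {
    compute_fi(mat[i, ], subject = if (is.null(ids)) i else ids[i])
  }, numeric(1))
}

#' Categorize a frailty index
#'
#' Thresholds follow the deficit-accumulation convention: FI below 0.10 is
#' health, 0.10 up to (but excluding) 0.25 is pre-frailty, and 0.25 or above
#' is frailty.
#'
#' @param fi Numeric vector of frailty indices in `[0, 1]`.
#' @return Factor with levels `health`, `pre-frailty`, `frailty`.
#' @examples
#' categorize_fi(c(0.05, 0.10, 0.25))
#' @export
categorize_fi <- function(fi) {
  if (any(!is.finite(fi)) || any(fi < 0 | fi > 1))
    stop("fi must lie in [0, 1]", call. = FALSE)
  cut(fi, breaks = c(-Inf, 0.10, 0.25, Inf), right = FALSE,
      labels = c("health", "pre-frailty", "frailty"))
}

#' Label a pre-frailty transition
#'
#' Transitions are defined for subjects who are pre-frail at baseline:
#' moving to frailty at follow-up is `progressed`, moving to health is
#' `regressed`, staying pre-frail is `unchanged`. Any other baseline state
#' yields `n/a`.
#'
#' @param baseline,followup Category labels (`health`, `pre-frailty`,
#'   `frailty`), vectors of equal length.
#' @return Character vector in `{progressed, regressed, unchanged, n/a}`.
#' @export
classify_transition <- function(baseline, followup) {
  lv <- c("health", "pre-frailty", "frailty")
  baseline <- as.character(baseline); followup <- as.character(followup)
  bad <- !(baseline %in% lv) | !(followup %in% lv)
  if (any(bad))
    stop("unknown category: ",
         paste(unique(c(baseline[bad], followup[bad])), collapse = ", "),
         call. = FALSE)
  out <- rep("n/a", length(baseline))
  pre <- baseline == "pre-frailty"
  out[pre & followup == "frailty"] <- "progressed"
  out[pre & followup == "health"] <- "regressed"
  out[pre & followup == "pre-frailty"] <- "unchanged"
  out
}

#' Assign hs-CRP tertiles
#'
#' In fixed mode the cut points are 0.90 and 2.00 mg/L (low below 0.90,
#' middle from 0.90 through 2.00, high above 2.00), the tertile boundaries
#' of the study population this package models. In data-driven mode the
#' sample's own 33.3%/66.7% quantiles are used.
#'
#' @param crp Positive hs-CRP concentrations in mg/L.
#' @param mode `"fixed"` or `"data-driven"`.
#' @return Factor with levels `low`, `middle`, `high`.
#' @examples
#' assign_crp_tertile(c(0.5, 1.46, 2.5))
#' @export
assign_crp_tertile <- function(crp, mode = c("fixed", "data-driven")) {
  mode <- match.arg(mode)
  if (any(!is.finite(crp)) || any(crp <= 0))
    stop("crp must be positive (mg/L)", call. = FALSE)
  cuts <- if (mode == "fixed") c(0.90, 2.00) else
    unname(stats::quantile(crp, c(1, 2) / 3))
  if (cuts[1] >= cuts[2]) stop("tertile boundaries must be increasing", call. = FALSE)
  # 0.90 and 2.00 both fall in the middle band (brackets: <0.90 / 0.90-2.00 / >2.00)
  factor(ifelse(crp < cuts[1], "low", ifelse(crp <= cuts[2], "middle", "high")),
         levels = c("low", "middle", "high"))
}

#' Chained-equation imputation of binary deficit items
#'
#' Fills missing deficit indicators by iterated logistic draws: each
#' incomplete item is regressed (logistic) on the mean of the remaining
#' items, coefficients are perturbed by a draw from their asymptotic normal
#' distribution (proper imputation), and the missing cells are drawn as
#' Bernoulli from the fitted probabilities. The cycle is repeated a few
#' times per imputed data set; `m` completed matrices are returned.
#'
#' @param mat subjects x items binary matrix with `NA` for missing cells.
#' @param m Number of imputed data sets (default 5).
#' @param n_iter Chained-update sweeps per data set (default 5).
#' @param seed Integer seed; the run is reproducible under a fixed seed.
#'
#' @return List with `imputations` (list of `m` complete matrices),
#'   `fi` (n x m matrix of per-imputation FIs) and `fi_pooled`
#'   (per-subject mean FI over imputations).
#' @export
impute_deficits <- function(mat, m = 5L, n_iter = 5L, seed = 1L) {
  mat <- as.matrix(mat)
  if (any(!is.na(mat) & !(mat %in% c(0, 1))))
    stop("deficit items must be binary (0/1) or NA", call. = FALSE)
  n_obs_item <- colSums(!is.na(mat))
  if (any(n_obs_item == 0))
    stop("item(s) with zero observed values: ",
         paste(which(n_obs_item == 0), collapse = ", "), call. = FALSE)
  if (any(rowSums(!is.na(mat)) == 0))
    stop("subject(s) with all items missing", call. = FALSE)

  miss <- is.na(mat)
  if (!any(miss)) {
    fi <- compute_fi_matrix(mat)
    return(list(imputations = list(mat), fi = matrix(fi, ncol = 1),
                fi_pooled = fi))
  }
  set.seed(seed)
  items_missing <- which(colSums(miss) > 0)
  imps <- vector("list", m)
  for (k in seq_len(m)) {
    cur <- mat
    # initialize by item-wise observed-frequency draws
    for (j in items_missing) {
      pj <- mean(mat[, j], na.rm = TRUE)
      cur[miss[, j], j] <- stats::rbinom(sum(miss[, j]), 1, pj)
    }
    for (it in seq_len(n_iter)) {
      for (j in items_missing) {
        other <- rowMeans(cur[, -j, drop = FALSE])
        yobs <- mat[!miss[, j], j]
        xobs <- other[!miss[, j]]
        fit <- suppressWarnings(
          stats::glm(yobs ~ xobs, family = stats::binomial()))
        co <- stats::coef(fit)
        vc <- stats::vcov(fit)
        if (any(!is.finite(co)) || any(!is.finite(vc))) {
          p_draw <- rep(mean(yobs), sum(miss[, j]))
        } else {
          # perturb coefficients (proper MI parameter draw)
          L <- tryCatch(chol(vc), error = function(e) NULL)
          co_star <- if (is.null(L)) co else
            co + drop(t(L) %*% stats::rnorm(length(co)))
          eta <- co_star[1] + co_star[2] * other[miss[, j]]
          p_draw <- stats::plogis(eta)
        }
        cur[miss[, j], j] <- stats::rbinom(sum(miss[, j]), 1, p_draw)
      }
    }
    imps[[k]] <- cur
  }
  fim <- vapply(imps, compute_fi_matrix, numeric(nrow(mat)))
  fim <- matrix(fim, nrow = nrow(mat))
  list(imputations = imps, fi = fim, fi_pooled = rowMeans(fim))
}

#' Build per-subject frailty records from a two-wave cohort
#'
#' Computes per-wave FIs, the mean FI over the study period, per-wave
#' categories, the mean-FI category, and the pre-frailty transition label.
#'
#' @param deficits_w1,deficits_w2 subjects x items binary matrices.
#' @param impute If `TRUE`, missing cells are multiply imputed
#'   ([impute_deficits()]) and pooled FIs used; otherwise missing items are
#'   dropped per subject.
#' @param seed Seed for imputation.
#' @return A data.frame with columns `fi_w1`, `fi_w2`, `fi_mean`,
#'   `cat_w1`, `cat_w2`, `cat_mean`, `transition`.
#' @export
frailty_records <- function(deficits_w1, deficits_w2, impute = FALSE, seed = 1L) {
  stopifnot(nrow(deficits_w1) == nrow(deficits_w2))
  if (impute) {
    fi1 <- impute_deficits(deficits_w1, seed = seed)$fi_pooled
    fi2 <- impute_deficits(deficits_w2, seed = seed + 1L)$fi_pooled
  } else {
    fi1 <- compute_fi_matrix(deficits_w1)
    fi2 <- compute_fi_matrix(deficits_w2)
  }
  cat1 <- categorize_fi(fi1)
  cat2 <- categorize_fi(fi2)
  data.frame(
    fi_w1 = fi1, fi_w2 = fi2, fi_mean = (fi1 + fi2) / 2,
    cat_w1 = cat1, cat_w2 = cat2,
    cat_mean = categorize_fi((fi1 + fi2) / 2),
    transition = classify_transition(cat1, cat2),
    stringsAsFactors = FALSE)
}
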