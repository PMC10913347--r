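#' Configuration for an end-to-end pipeline run
#'
#' Bundles the cohort and GWAS generator configurations, stage toggles and
#' stage parameters. Every stochastic stage derives its seed from the
#' single top-level `seed`.
#'
#' @param cohort A [cohort_config()] (or `NULL` to skip cohort stages).
#' @param gwas A [gwas_pair_config()] (or `NULL` to skip genetic stages).
#' @param stages Character subset of
#'   `c("cohort", "observational", "ldsc", "placo", "mr")`.
#' @param seed Master seed.
#' @param ldsc_blocks Jackknife blocks for LDSC.
#' @param placo_p,placo_clump_r2,placo_merge_kb Pleiotropy-scan thresholds
#'   (defaults 5e-8, 0.2, 500).
#' @param mr_p,mr_clump_r2,mr_clump_kb Instrument-selection thresholds
#'   (defaults 5e-8, 0.01, 5000).
#' @param out_dir Optional directory for per-stage CSV/JSON outputs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       gwas = gwas_pair_config(),
                       stages = c("cohort", "observational", "ldsc",
                                  "placo", "mr"),
                       seed = 1L, ldsc_blocks = 200,
                       placo_p = 5e-8, placo_clump_r2 = 0.2,
                       placo_merge_kb = 500,
                       mr_p = 5e-8, mr_clump_r2 = 0.01, mr_clump_kb = 5000,
                       out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if ("observational" %in% stages && !"cohort" %in% stages)
    stop("the observational stage requires the cohort stage", call. = FALSE)
  structure(list(cohort = cohort, gwas = gwas, stages = stages,
                 seed = as.integer(seed), ldsc_blocks = ldsc_blocks,
                 placo_p = placo_p, placo_clump_r2 = placo_clump_r2,
                 placo_merge_kb = placo_merge_kb,
                 mr_p = mr_p, mr_clump_r2 = mr_clump_r2,
                 mr_clump_kb = mr_clump_kb, out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in analysis order — synthesize the cohort,
#' frailty-index construction and tertile models (incident frailty plus the
#' pre-frailty progression and regression arms), LD-score regression,
#' pleiotropy scan, Mendelian randomization — on synthetic data with known
#' ground truth, and returns a consolidated report. When `out_dir` is set,
#' per-stage tables are written as CSV/TSV and the report as JSON.
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_report` with elements per enabled stage
#'   (`observational`, `ldsc`, `placo`, `mr`), a `log` of parameters and
#'   dropped-record counts, and `seed`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  report <- list(seed = config$seed, log = list(), errors = list())
  od <- config$out_dir
  if (!is.null(od) && !dir.exists(od)) dir.create(od, recursive = TRUE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      warning("stage '", name, "' failed: ", conditionMessage(e),
              call. = FALSE)
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  if ("cohort" %in% config$stages) {
    cc <- config$cohort
    cc$seed <- config$seed
    gen <- generate_cohort(cc)
    report$log$cohort <- list(n_subjects = cc$n_subjects,
                              n_deficits = cc$n_deficits,
                              missing_rate = cc$missing_rate)
    if (!is.null(od)) write_cohort_csv(gen, file.path(od, "cohort.csv"))

    if ("observational" %in% config$stages) {
      co <- gen$cohort
      arms <- list(
        incident = within(co[co$cat_w1 != "frailty", ],
                          event <- as.integer(cat_w2 == "frailty")),
        progression = within(co[co$cat_w1 == "pre-frailty", ],
                             event <- as.integer(cat_w2 == "frailty")),
        regression = within(co[co$cat_w1 == "pre-frailty", ],
                            event <- as.integer(cat_w2 == "health")))
      obs <- lapply(names(arms), function(a) {
        d <- arms[[a]]
        adj <- intersect(model_adjustments(3), names(d))
        models <- run_model_series(
          d, outcome = "event", models = 1,
          covariates = list("1" = character(0)))
        tt <- trend_test(d, outcome = "event")
        list(arm = a, models = models, p_trend = tt$p,
             n = nrow(d), n_cases = sum(d$event))
      })
      names(obs) <- names(arms)
      report$observational <- obs
      if (!is.null(od)) {
        tab <- do.call(rbind, lapply(obs, function(o)
          cbind(arm = o$arm, o$models)))
        utils::write.csv(tab, file.path(od, "observational.csv"),
                         row.names = FALSE)
      }
    }
  }

  if (any(c("ldsc", "placo", "mr") %in% config$stages)) {
    gc <- config$gwas
    gc$seed <- config$seed + 1L
    pair <- generate_sumstats_pair(gc)
    m1 <- munge_sumstats(pair$sumstats1)
    m2 <- munge_sumstats(pair$sumstats2)
    report$log$gwas <- list(n_snps = gc$n_snps,
                            dropped_trait1 = m1$dropped,
                            dropped_trait2 = m2$dropped)
    shared <- intersect(m1$z$SNP, m2$z$SNP)
    ild <- match(shared, pair$ld$snp)
    z1 <- m1$z$z[match(shared, m1$z$SNP)]
    z2 <- m2$z$z[match(shared, m2$z$SNP)]
    # align outcome z to the exposure allele orientation
    flipped <- pair$truth$swapped[ild]
    z2[flipped] <- -z2[flipped]
    l2 <- pair$ld$l2[ild]

    if ("ldsc" %in% config$stages) {
      report$ldsc <- run_stage("ldsc", {
        h2a <- ldsc_h2(z1, l2, N = gc$n1, M = gc$n_snps,
                       n_blocks = config$ldsc_blocks)
        h2b <- ldsc_h2(z2, l2, N = gc$n2, M = gc$n_snps,
                       n_blocks = config$ldsc_blocks)
        rg <- ldsc_rg(z1, z2, l2, N1 = gc$n1, N2 = gc$n2, M = gc$n_snps,
                      n_blocks = config$ldsc_blocks)
        list(h2_trait1 = h2a, h2_trait2 = h2b, rg = rg)
      })
      if (!is.null(od) && !is.null(report$ldsc)) {
        h2a <- report$ldsc$h2_trait1; h2b <- report$ldsc$h2_trait2
        rg <- report$ldsc$rg
        jsonlite::write_json(
          list(h2_1 = h2a$h2, h2_1_se = h2a$h2_se,
               h2_2 = h2b$h2, h2_2_se = h2b$h2_se,
               intercept_1 = h2a$intercept, intercept_2 = h2b$intercept,
               rg = rg$rg, rg_se = rg$rg_se, rg_p = rg$rg_p),
          file.path(od, "ldsc.json"), auto_unbox = TRUE, digits = NA)
      }
    }

    if ("placo" %in% config$stages) {
      sub_ld <- pair$ld
      sub_ld$snp <- sub_ld$snp[ild]; sub_ld$chr <- sub_ld$chr[ild]
      sub_ld$bp <- sub_ld$bp[ild]; sub_ld$l2 <- sub_ld$l2[ild]
      sub_ld$block <- sub_ld$block[ild]
      report$placo <- run_stage("placo",
        placo_scan(z1, z2, sub_ld, p_threshold = config$placo_p,
                   clump_r2 = config$placo_clump_r2,
                   merge_kb = config$placo_merge_kb))
      pl <- report$placo
      if (!is.null(od) && !is.null(pl)) {
        utils::write.table(pl$snp_results,
                           file.path(od, "placo_snps.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        if (!is.null(pl$loci))
          utils::write.table(pl$loci, file.path(od, "placo_loci.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }

    if ("mr" %in% config$stages) {
      mr_res <- run_stage("mr", {
        iv <- select_instruments(pair$sumstats1, ld = pair$ld,
                                 p_threshold = config$mr_p,
                                 clump_r2 = config$mr_clump_r2,
                                 clump_kb = config$mr_clump_kb)
        h <- harmonize(pair$sumstats1, pair$sumstats2, snps = iv)
        list(suite = mr_suite(h, seed = config$seed + 2L),
             log = list(
               n_selected = length(iv), n_harmonized = nrow(h),
               n_palindromic_dropped = attr(h, "n_palindromic_dropped"),
               n_irreconcilable = attr(h, "n_irreconcilable")))
      })
      report$mr <- mr_res$suite
      report$log$mr <- mr_res$log
      if (!is.null(od) && !is.null(report$mr)) {
        utils::write.table(report$mr$estimates,
                           file.path(od, "mr_estimates.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        jsonlite::write_json(report$mr$sensitivity,
                             file.path(od, "mr_sensitivity.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }
  class(report) <- "pipeline_report"
  if (!is.null(od))
    jsonlite::write_json(report_summary(report),
                         file.path(od, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  report
}

#' Flatten a pipeline report to plain named values
#'
#' @param report A `pipeline_report`.
#' @return Nested list of plain numbers suitable for JSON serialization.
#' @export
report_summary <- function(report) {
  out <- list(seed = report$seed, log = report$log)
  if (length(report$errors)) out$errors <- report$errors
  if (!is.null(report$observational)) {
    out$observational <- lapply(report$observational, function(o)
      list(arm = o$arm, n = o$n, n_cases = o$n_cases, p_trend = o$p_trend,
           or = stats::setNames(o$models$or, o$models$level)))
  }
  if (!is.null(report$ldsc)) {
    out$ldsc <- list(h2_1 = report$ldsc$h2_trait1$h2,
                     h2_2 = report$ldsc$h2_trait2$h2,
                     rg = report$ldsc$rg$rg, rg_p = report$ldsc$rg$rg_p)
  }
  if (!is.null(report$placo)) {
    out$placo <- list(
      n_significant = sum(report$placo$snp_results$significant),
      n_lead = sum(report$placo$snp_results$lead),
      n_loci = if (is.null(report$placo$loci)) 0 else
        nrow(report$placo$loci))
  }
  if (!is.null(report$mr)) {
    ivw_row <- report$mr$estimates[grepl("^IVW", report$mr$estimates$method), ][1, ]
    out$mr <- list(ivw_beta = ivw_row$beta, ivw_or = ivw_row$or,
                   ivw_p = ivw_row$p,
                   sensitivity = report$mr$sensitivity,
                   warnings = report$mr$warnings)
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report (seed", x$seed, ")\n")
  if (!is.null(x$observational))
    for (o in x$observational)
      cat(sprintf("  %s: %d/%d cases; OR(high) = %.3f; p_trend = %.3g\n",
                  o$arm, o$n_cases, o$n,
                  o$models$or[o$models$level == "high"], o$p_trend))
  if (!is.null(x$ldsc)) {
    cat("  "); print(x$ldsc$rg)
  }
  if (!is.null(x$placo)) {
    cat("  "); print(x$placo)
  }
  if (!is.null(x$mr)) print(x$mr)
  for (nm in names(x$errors))
    cat("  FAILED stage", nm, ":", x$errors[[nm]], "\n")
  invisible(x)
}
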