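test_that("contingency odds ratios reproduce the published unadjusted table", {
  prog_mid <- or_from_counts(170, 1838, 118, 1602)
  prog_high <- or_from_counts(210, 1801, 118, 1602)
  reg_mid <- or_from_counts(581, 1838, 543, 1602)
  reg_high <- or_from_counts(505, 1801, 543, 1602)
  expect_equal(round(prog_mid$estimate, 2), 1.28)
  expect_equal(round(prog_high$estimate, 2), 1.66)
  expect_equal(round(reg_mid$estimate, 2), 0.90)
  expect_equal(round(reg_high$estimate, 2), 0.76)
  # Woolf interval bounds
  expect_equal(round(prog_high$ci_low, 2), 1.31)
  expect_equal(round(reg_high$ci_high, 2), 0.88)
  expect_equal(round(reg_high$ci_low, 2), 0.66)
})

test_that("contingency OR edge behavior: equal proportions, zero cells", {
  expect_equal(or_from_counts(50, 200, 100, 400)$estimate, 1.0)
  expect_error(or_from_counts(0, 100, 10, 100), "Haldane")
  ha <- or_from_counts(0, 100, 10, 100, haldane = TRUE)
  expect_true(is.finite(ha$estimate) && ha$estimate < 1)
  expect_error(or_from_counts(5, 4, 1, 10), "exceed")
  expect_error(or_from_counts(2.5, 10, 1, 10), "integers")
})

test_that("single-factor logistic ORs equal the closed-form contingency ORs", {
  # expand the published 2x3 progression table to subject level
  counts <- data.frame(level = c("low", "middle", "high"),
                       cases = c(118, 170, 210), total = c(1602, 1838, 1801))
  d <- do.call(rbind, lapply(seq_len(3), function(i) {
    data.frame(tertile = counts$level[i],
               event = rep(c(1, 0), c(counts$cases[i],
                                      counts$total[i] - counts$cases[i])))
  }))
  d$tertile <- factor(d$tertile, levels = c("low", "middle", "high"))
  fl <- fit_logistic(event ~ tertile, d)$estimates
  for (lv in c("middle", "high")) {
    oc <- or_from_counts(counts$cases[counts$level == lv],
                         counts$total[counts$level == lv], 118, 1602)
    expect_equal(fl$or[fl$term == paste0("tertile", lv)], oc$estimate,
                 tolerance = 1e-6)
    expect_equal(fl$se[fl$term == paste0("tertile", lv)], oc$se,
                 tolerance = 1e-6)
  }
})

test_that("intercept-only logistic recovers logit(k/n); separation is caught", {
  d <- data.frame(event = rep(c(1, 0), c(30, 70)))
  fl <- fit_logistic(event ~ 1, d)$estimates
  expect_equal(log(fl$or[1]), qlogis(0.3), tolerance = 1e-8)

  sep <- data.frame(event = rep(c(0, 1), each = 50),
                    x = rep(c(0, 1), each = 50))
  expect_error(fit_logistic(event ~ x, sep), "separation.*x")
})

test_that("null logistic p-values are uniform", {
  set.seed(101)
  p <- replicate(400, {
    d <- data.frame(event = rbinom(120, 1, 0.3), x = rnorm(120))
    fit_logistic(event ~ x, d)$estimates$p[2]
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("model series adjusts away a known confounder", {
  # confounder raises both CRP and the outcome; true tertile effect is null
  cfg <- cohort_config(
    n_subjects = 20000, crp_effect_logodds = 0, seed = 31,
    covariate_spec = list(
      list(name = "age", dist = "normal", params = c(0, 1),
           beta_outcome = 0.8, beta_crp = 0.6)))
  g <- generate_cohort(cfg)
  # restrict to one baseline stratum so the adjusted model is correctly
  # specified (a single latent baseline level)
  d <- g$cohort[g$cohort$cat_w1 == "pre-frailty", ]
  d$event <- as.integer(d$cat_w2 == "frailty")
  res <- run_model_series(d, models = c(1, 2),
                          covariates = list("1" = character(0),
                                            "2" = "age"))
  or1 <- res$or[res$model == 1 & res$level == "high"]
  or2 <- res$or[res$model == 2 & res$level == "high"]
  expect_gt(or1, 1.2)              # confounded
  expect_lt(abs(log(or2)), 0.15)   # adjustment restores the null
})

test_that("model series matches the published progression arm and errors on missing covariates", {
  counts <- data.frame(level = c("low", "middle", "high"),
                       cases = c(118, 170, 210), total = c(1602, 1838, 1801))
  d <- do.call(rbind, lapply(seq_len(3), function(i) {
    data.frame(tertile = counts$level[i],
               event = rep(c(1, 0), c(counts$cases[i],
                                      counts$total[i] - counts$cases[i])))
  }))
  res <- run_model_series(d, models = 1, covariates = list("1" = character(0)))
  expect_equal(round(res$or[res$level == "middle"], 2), 1.28)
  expect_equal(round(res$or[res$level == "high"], 2), 1.66)
  expect_equal(res$n_cases[res$level == "high"], 210)
  expect_error(run_model_series(d, models = 3), "missing covariate")
})

test_that("trend test: published counts give p < 0.001; permuted labels are uniform", {
  counts <- data.frame(level = c("low", "middle", "high"),
                       cases = c(118, 170, 210), total = c(1602, 1838, 1801))
  d <- do.call(rbind, lapply(seq_len(3), function(i) {
    data.frame(tertile = counts$level[i],
               event = rep(c(1, 0), c(counts$cases[i],
                                      counts$total[i] - counts$cases[i])))
  }))
  expect_lt(trend_test(d)$p, 0.001)

  set.seed(55)
  p <- replicate(300, {
    d2 <- d
    d2$event <- sample(d2$event)
    trend_test(d2)$p
  })
  # permutations can repeat a contingency table, so allow ties in the KS
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)

  expect_error(trend_test(data.frame(tertile = "low", event = c(0, 1))),
               ">= 2")
})

test_that("subgroup analysis recovers sex-specific effects and a calibrated interaction test", {
  set.seed(77)
  n <- 12000
  sex <- rbinom(n, 1, 0.5)
  tert <- factor(sample(c("low", "middle", "high"), n, replace = TRUE),
                 levels = c("low", "middle", "high"))
  ts <- c(low = 0, middle = 0.5, high = 1)[as.character(tert)]
  # effect only in females (sex == 1)
  eta <- -2.2 + 0.9 * ts * sex
  d <- data.frame(event = rbinom(n, 1, plogis(eta)), tertile = tert,
                  sex = sex)
  res <- subgroup_interaction(d, "sex", adjust = character(0))
  or_f <- res$strata$or[res$strata$stratum == "1" &
                          res$strata$level == "high"]
  or_m <- res$strata$or[res$strata$stratum == "0" &
                          res$strata$level == "high"]
  expect_gt(or_f, or_m)
  expect_lt(res$p_interaction, 0.01)

  # identical strata yield identical ORs
  half <- d[d$sex == 1, ]
  both <- rbind(transform(half, grp = "a"), transform(half, grp = "b"))
  res2 <- subgroup_interaction(both, "grp", adjust = character(0))
  a <- res2$strata[res2$strata$stratum == "a", c("level", "or")]
  b <- res2$strata[res2$strata$stratum == "b", c("level", "or")]
  expect_equal(a$or, b$or)
})

test_that("interaction p-value is uniform when the stratifier is inert", {
  set.seed(78)
  p <- replicate(150, {
    n <- 800
    tert <- factor(sample(c("low", "middle", "high"), n, replace = TRUE),
                   levels = c("low", "middle", "high"))
    d <- data.frame(
      event = rbinom(n, 1, plogis(-1.5 + 0.4 * (tert == "high"))),
      tertile = tert, grp = rbinom(n, 1, 0.5))
    subgroup_interaction(d, "grp", adjust = character(0))$p_interaction
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("spline curve is anchored at the reference and the linearity test is calibrated", {
  set.seed(91)
  n <- 4000
  crp <- exp(rnorm(n, 0.4, 1))
  d_lin <- data.frame(crp = crp,
                      event = rbinom(n, 1, plogis(-2 + 0.15 * log(crp))))
  sp <- spline_nonlinearity(d_lin, reference = 1.46,
                            grid = c(0.5, 1.46, 3))
  expect_equal(sp$curve$or[sp$curve$crp == 1.46], 1, tolerance = 1e-12)

  # linear truth (in crp itself): non-linearity p roughly uniform
  set.seed(92)
  p_lin <- replicate(60, {
    crp <- exp(rnorm(1500, 0.4, 0.8))
    d <- data.frame(crp = crp, event = rbinom(1500, 1,
                                              plogis(-2 + 0.3 * crp)))
    spline_nonlinearity(d)$p_nonlinearity
  })
  expect_gt(mean(p_lin < 0.05), 0)  # sanity of scale
  expect_gt(ks.test(p_lin, "punif")$p.value, 0.005)

  # inverted-L truth: risk rises steeply then plateaus; detected and shaped
  set.seed(93)
  crp <- exp(rnorm(6000, 0.4, 1))
  eta <- -2 + 1.2 * pmin(crp, 1.5) / 1.5
  d_nl <- data.frame(crp = crp, event = rbinom(6000, 1, plogis(eta)))
  sp_nl <- spline_nonlinearity(d_nl, grid = c(0.3, 1.46, 4, 8))
  expect_lt(sp_nl$p_nonlinearity, 0.05)
  rise <- diff(log(sp_nl$curve$or[1:2]))   # 0.3 -> 1.46 climbs
  plateau <- diff(log(sp_nl$curve$or[3:4]))  # 4 -> 8 flat-ish
  expect_gt(rise, plateau)

  expect_error(spline_nonlinearity(data.frame(crp = c(1, 2, 1, 2),
                                              event = c(0, 1, 0, 1))),
               "distinct")
})
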