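test_that("logistic fits reproduce closed-form oracles", {
  # intercept-only: logit of the case fraction
  y <- rep(c(1, 0), c(30, 70))
  fit <- fit_logistic(y, matrix(nrow = 100, ncol = 0))
  expect_equal(unname(fit$coef[1]), log(30 / 70), tolerance = 1e-8)

  # 2x2 cross-product odds ratio: (a,b,c,d) = (20,10,10,20) -> OR = 4
  y2 <- rep(c(1, 1, 0, 0), c(20, 10, 10, 20))
  x2 <- rep(c(1, 0, 1, 0), c(20, 10, 10, 20))
  fit2 <- fit_logistic(y2, data.frame(x = x2))
  expect_equal(exp(unname(fit2$coef["x"])), 4, tolerance = 1e-8)
  # allele-flip reparameterization: beta negates, Wald P unchanged
  fit3 <- fit_logistic(y2, data.frame(x = 1 - x2))
  expect_equal(unname(fit3$coef["x"]), -unname(fit2$coef["x"]), tolerance = 1e-8)
  expect_equal(unname(fit3$p["x"]), unname(fit2$p["x"]), tolerance = 1e-10)
})

test_that("singular designs error with column names; separation is flagged", {
  y <- rep(c(1, 0), 25)
  err <- tryCatch(fit_logistic(y, data.frame(geno = rep(0, 50))),
                  error = function(e) e)
  expect_s3_class(err, "adx_singular_error")
  expect_match(conditionMessage(err), "geno")

  sep <- fit_logistic(rep(c(1, 0), c(25, 25)),
                      data.frame(z = rep(c(1, 0), c(25, 25))))
  expect_true(sep$separation["z"])
})

test_that("marker association is oriented to the risk allele and flags sparse markers", {
  set.seed(61)
  n <- 400
  g <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-0.5 + 0.5 * g))
  panel <- make_panel(0.9, 0.1)
  chrt <- make_cohort(matrix(as.integer(g), ncol = 1),
                      status = ifelse(y == 1, "case", "control"))
  a <- marker_association(chrt, panel, "m001", risk_allele = "A",
                          covariates = character(0))
  b <- marker_association(chrt, panel, "m001", risk_allele = "C",
                          covariates = character(0))
  expect_equal(b$or, 1 / a$or, tolerance = 1e-10)
  expect_equal(b$p, a$p, tolerance = 1e-12)
  expect_true(a$or_ci_low < a$or && a$or < a$or_ci_high)
  expect_false(a$low_information)

  rare <- chrt
  rare$genotypes[, 1] <- c(1L, rep(0L, n - 1))
  expect_warning(r <- marker_association(rare, panel, "m001", "A",
                                         covariates = character(0)),
                 regexp = NA)
  expect_true(r$low_information)

  tiny <- make_cohort(matrix(rep(0:1, 10), ncol = 1))
  expect_error(marker_association(tiny, panel, "m001", "A",
                                  covariates = character(0)),
               class = "adx_model_error")
})

test_that("allelic effects are recovered without bias at study scale", {
  set.seed(71)
  ors <- replicate(50, {
    n <- 1200
    g <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, plogis(-0.8 + 0.6 * g))
    panel <- make_panel(0.9, 0.1)
    chrt <- make_cohort(matrix(as.integer(g), ncol = 1),
                        status = ifelse(y == 1, "case", "control"))
    marker_association(chrt, panel, "m001", "A", covariates = character(0))$or
  })
  expect_gt(mean(ors), 1.70)
  expect_lt(mean(ors), 1.95)
})

test_that("covariate analysis reports the confounding diagnostics", {
  cfg <- sim_config(n_case = 300, n_control = 300, n_markers = 60,
                    ses_ancestry_slope = -3, ses_disease_effect = -0.6,
                    seed = 15)
  sim <- simulate_cohort(cfg)
  th <- estimate_theta(sim$cohort, sim$panel)
  ca <- covariate_analysis(sim$cohort, th)
  expect_named(ca$models, c("ancestry", "ses", "ancestry_ses", "ancestry_ses_bmi"))
  expect_lt(ca$ancestry_ses_cor$estimate, 0)   # sign matches generator slope
  expect_lt(ca$models$ses$coef["ses"], 0)
  expect_length(ca$models$ancestry_ses_bmi$coef, 4L)
})

test_that("BMI trend handles constant input and recovers a simulated slope", {
  panel <- make_panel(0.9, 0.1)
  g <- rep(0:2, each = 40)
  chrt <- make_cohort(matrix(as.integer(g), ncol = 1),
                      bmi = rep(27, 120))
  flat <- bmi_trend_test(chrt, panel, "m001", "A")
  expect_equal(flat$slope, 0)
  expect_gte(flat$p, 0.99)

  set.seed(19)
  hits <- replicate(20, {
    g <- rbinom(1200, 2, 0.4)
    bmi <- 26 + 0.25 * g + rnorm(1200, sd = 1)
    chrt <- make_cohort(matrix(as.integer(g), ncol = 1), bmi = bmi)
    tr <- bmi_trend_test(chrt, panel, "m001", "A")
    abs(tr$slope - 0.25) < 0.1
  })
  expect_gte(sum(hits), 16)

  # permuted genotypes carry no trend: P rarely small
  set.seed(20)
  perm_p <- replicate(200, {
    g <- rbinom(300, 2, 0.4)
    bmi <- 26 + 0.5 * g + rnorm(300, sd = 2)
    chrt <- make_cohort(matrix(as.integer(sample(g)), ncol = 1), bmi = bmi)
    bmi_trend_test(chrt, panel, "m001", "A")$p
  })
  expect_gt(mean(perm_p < 0.05), 0.005)
  expect_lt(mean(perm_p < 0.05), 0.12)
})

test_that("sign test matches exhaustive binomial enumeration", {
  enum_p <- function(k, n) sum(choose(n, k:n)) / 2^n
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(1:25, 1)
    ors <- exp(rnorm(n, 0, 0.5))
    ors[sample(n, min(n, 2))] <- 1      # OR = 1 must not count as > 1
    st <- sign_test_or(ors)
    expect_identical(st$count_gt_1, sum(ors > 1))
    expect_equal(st$p, enum_p(st$count_gt_1, n), tolerance = 1e-12)
  }
  all_up <- sign_test_or(rep(1.5, 12))
  expect_equal(all_up$p, 2^-12)
  expect_error(sign_test_or(c(1.2, -1)), class = "adx_domain_error")
})

test_that("bonferroni flags use the family size as the corrected threshold", {
  fl <- bonferroni_flags(c(0.001, 0.02, 0.2, 1), alpha = 0.05)
  expect_equal(fl$threshold, 0.05 / 4)
  expect_equal(sum(fl$nominal), 2L)
  expect_equal(sum(fl$corrected), 1L)
  expect_equal(sum(bonferroni_flags(rep(1, 5))$nominal), 0L)
  expect_error(bonferroni_flags(c(0.5, 0)), class = "adx_domain_error")
})

test_that("analytic power matches its null value, a huge-effect bound, and simulation", {
  expect_lt(abs(power_single_marker(0.3, 1, 876, 399) - 0.05), 0.005)
  expect_gt(power_single_marker(0.3, 3, 876, 399), 0.99)
  for (case in list(c(0.3, 1.5), c(0.15, 1.3))) {
    analytic <- power_single_marker(case[1], case[2], 876, 399)
    mc <- sim_power_oracle(case[1], case[2], 876, 399, 0.05, reps = 10000)
    expect_lt(abs(analytic - mc), 0.02)
  }
  expect_warning(power_single_marker(1e-4, 1e-6, 876, 399),
                 class = "adx_clamp_warning")
})
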