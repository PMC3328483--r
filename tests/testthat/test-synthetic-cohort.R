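test_that("simulated panels are deterministic with the requested differential", {
  cfg <- sim_config(n_markers = 1536, freq_diff_mean = 0.5, seed = 21)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1, p2)
  expect_gt(mean(abs(p1$freq_pop1 - p1$freq_pop2)), 0.45)
  expect_lt(mean(abs(p1$freq_pop1 - p1$freq_pop2)), 0.55)
  expect_setequal(unique(p1$chromosome), 1:22)

  single <- simulate_panel(sim_config(n_markers = 1, seed = 1))
  expect_identical(nrow(single), 1L)
  expect_gte(single$genetic_pos, 0)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(freq_diff_mean = 1.2), class = "adx_config_error")
  expect_error(sim_config(theta_mean = 0), class = "adx_config_error")
  expect_error(sim_config(lambda_gens = 0), class = "adx_config_error")
  expect_error(sim_config(risk_locus = list(marker = 1, R = -1)),
               class = "adx_config_error")
  expect_error(sim_config(n_markers = 0), class = "adx_config_error")
})

test_that("local-ancestry chains respect boundary cases", {
  panel <- make_panel(rep(0.9, 5), rep(0.1, 5))
  expect_identical(simulate_local_ancestry(panel, 1, 10, seed = 4), rep(2L, 5))
  expect_identical(simulate_local_ancestry(panel, 0, 10, seed = 4), rep(0L, 5))

  # zero genetic distance: state cannot switch between the two markers
  tied <- make_panel(c(0.9, 0.9), c(0.1, 0.1), gpos = c(0.05, 0.05))
  for (s in 1:50) {
    cnt <- simulate_local_ancestry(tied, 0.4, 10, seed = s)
    expect_identical(cnt[1], cnt[2])
  }

  unsorted <- data.frame(chromosome = 1, genetic_pos = c(0.2, 0.1))
  expect_error(simulate_local_ancestry(unsorted, 0.3, 10, seed = 1),
               class = "adx_validation_error")
})

test_that("stationary Native fraction matches theta over a long map", {
  # 10,000 markers spread over 35 Morgans: law of large numbers on tracts
  panel <- data.frame(chromosome = 1L,
                      genetic_pos = seq(0, 35, length.out = 10000))
  cnt <- simulate_local_ancestry(panel, 0.3, 10, seed = 17)
  expect_lt(abs(mean(cnt) / 2 - 0.3), 0.03)
})

test_that("genotypes follow the binomial ancestry mixture law", {
  cfg <- sim_config(n_case = 400, n_control = 400, n_markers = 30,
                    ses_disease_effect = 0, seed = 5)
  sim <- simulate_cohort(cfg)
  G <- sim$cohort$genotypes
  L <- sim$cohort$true_local
  for (m in c(3L, 11L, 25L)) {
    f1 <- sim$panel$freq_pop1[m]
    f2 <- sim$panel$freq_pop2[m]
    for (j in 0:2) {
      sel <- L[, m] == j
      if (sum(sel) < 40) next
      expected <- j * f1 + (2 - j) * f2
      mc_err <- 4 * sqrt(0.5 / sum(sel))   # generous binomial-mixture bound
      expect_lt(abs(mean(G[sel, m]) - expected), mc_err)
    }
  }
})

test_that("null generators are symmetric in ancestry between cases and controls", {
  cfg <- sim_config(n_case = 1000, n_control = 1000, n_markers = 40,
                    ses_disease_effect = 0, seed = 9)
  sim <- simulate_cohort(cfg)
  is_case <- sim$cohort$ind$status == "case"
  expect_lt(abs(mean(sim$cohort$true_theta[is_case]) -
                  mean(sim$cohort$true_theta[!is_case])), 0.01)
})

test_that("SES confounding raises case ancestry without any genetic effect", {
  cfg <- sim_config(n_case = 600, n_control = 400, n_markers = 40,
                    ses_ancestry_slope = -3, ses_disease_effect = -0.6,
                    seed = 23)
  sim <- simulate_cohort(cfg)
  is_case <- sim$cohort$ind$status == "case"
  expect_gt(mean(sim$cohort$true_theta[is_case]),
            mean(sim$cohort$true_theta[!is_case]))
  expect_lt(cor(sim$cohort$ind$ses, sim$cohort$true_theta), 0)
})

test_that("an ancestry risk locus enriches case local ancestry there", {
  cfg <- sim_config(n_case = 400, n_control = 100, n_markers = 100,
                    ses_disease_effect = 0,
                    risk_locus = list(marker = 10, R = 2), seed = 31)
  sim <- simulate_cohort(cfg)
  is_case <- sim$cohort$ind$status == "case"
  L <- sim$cohort$true_local[is_case, ]
  expect_gt(mean(L[, 10]), mean(L))
  # consistency: anchored tracks must reproduce the status-generating counts
  expect_gt(cor(L[, 10], 2 * sim$cohort$true_theta[is_case]), 0)
})

test_that("cohort simulation is deterministic and fails cleanly when quotas are unreachable", {
  cfg <- sim_config(n_case = 50, n_control = 50, n_markers = 25, seed = 77)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort$genotypes, s2$cohort$genotypes)
  expect_identical(s1$cohort$ind, s2$cohort$ind)

  hopeless <- sim_config(n_case = 200, n_control = 10, n_markers = 10,
                         base_prevalence_logit = -30, seed = 1)
  expect_error(simulate_cohort(hopeless), class = "adx_sim_error")
})
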