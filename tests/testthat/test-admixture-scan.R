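test_that("case Bayes factors obey their closed forms", {
  pi <- c(0.25, 0.5, 0.25)
  expect_equal(case_bayes_factor(c(0.1, 0.2, 0.7), pi, 1), 1)
  expect_equal(case_bayes_factor(c(0, 0, 1), pi, 2), 4 / 2.25)
  for (r in c(0.3, 1, 2.7)) {
    expect_equal(case_bayes_factor(pi, pi, r), 1)
  }
  expect_error(case_bayes_factor(pi, pi, 0), class = "adx_domain_error")
  # matrix form agrees with rowwise evaluation
  qm <- rbind(c(0.2, 0.3, 0.5), c(0.6, 0.3, 0.1))
  pm <- rbind(pi, pi)
  expect_equal(case_bayes_factor(qm, pm, 1.5),
               c(case_bayes_factor(qm[1, ], pi, 1.5),
                 case_bayes_factor(qm[2, ], pi, 1.5)))
})

test_that("locus LOD is null at R = 1 and doubles when cases are duplicated", {
  set.seed(3)
  q <- matrix(runif(30), 10, 3)
  q <- q / rowSums(q)
  theta <- runif(10, 0.2, 0.4)
  pi <- cbind((1 - theta)^2, 2 * theta * (1 - theta), theta^2)

  null_model <- risk_model(scan_set = 1, grid = c(0.5, 1, 2))
  res <- locus_lod(q, pi, null_model)
  expect_equal(res$lod, 0, tolerance = 1e-12)
  expect_equal(unname(res$lod_by_R[2]), 0, tolerance = 1e-12)

  model <- risk_model()
  one <- locus_lod(q, pi, model)
  two <- locus_lod(rbind(q, q), rbind(pi, pi), model)
  expect_equal(two$lod_by_R, 2 * one$lod_by_R, tolerance = 1e-10)
  expect_error(locus_lod(q[0, ], pi[0, ], model), class = "adx_domain_error")
})

test_that("genome-wide LOD averages likelihood ratios and is bounded by the maximum", {
  expect_equal(genome_lod(c(0, 0, 0)), 0)
  expect_equal(genome_lod(c(0, 1)), log10((1 + 10) / 2))
  set.seed(8)
  for (rep in 1:5) {
    lods <- rnorm(50, sd = 2)
    expect_lte(genome_lod(lods), max(lods))
  }
})

test_that("risk grids are inclusive arithmetic sequences", {
  expect_length(risk_grid(0.2, 3.00, 0.02), 141L)
  expect_equal(risk_grid(1, 1, 0.02), 1)
  expect_equal(risk_grid(0.5, 1.0, 0.25), c(0.5, 0.75, 1.0))
  expect_error(risk_grid(0.2, 3, 0), class = "adx_config_error")
})

test_that("chi-square calibration of the confidence-interval LOD offset", {
  expect_equal(lod_offset_from_chisq(0.05), 0.834, tolerance = 5e-4)
  expect_equal(lod_offset_from_chisq(0.01), 1.441, tolerance = 5e-4)
  expect_lt(lod_offset_from_chisq(1 - 1e-9), 1e-6)
  expect_error(lod_offset_from_chisq(0), class = "adx_config_error")
  expect_error(lod_offset_from_chisq(1), class = "adx_config_error")
})

test_that("exclusion mapping: flat profiles span the grid, ties resolve to the null", {
  grid <- risk_grid(0.2, 3, 0.02)
  flat <- matrix(0, 1, length(grid))
  em <- exclusion_map(flat, grid, ci_offset = 0.834)
  expect_equal(em$r_ml, 1)                       # tie broken toward R = 1
  expect_equal(em$r_ci_low, 0.2)
  expect_equal(em$r_ci_high, 3)
  expect_error(exclusion_map(matrix(0, 1, 1), 1), class = "adx_config_error")

  # a peaked profile cuts the interval at the offset
  lods <- -(grid - 1.4)^2 * 10
  em2 <- exclusion_map(rbind(lods), grid, ci_offset = 0.834)
  expect_equal(em2$r_ml, 1.4, tolerance = 1e-9)
  expect_true(em2$r_ci_low > 0.2 && em2$r_ci_high < 3)
  expect_true(em2$r_ci_low <= 1.4 && 1.4 <= em2$r_ci_high)
})

test_that("excluded fraction is genetic-length weighted and monotone in the threshold", {
  pts <- data.frame(point_id = sprintf("p%d", 1:5), chromosome = c(1, 1, 1, 2, 2),
                    genetic_pos = c(0, 0.01, 0.02, 0, 0.03), position_bp = 1:5,
                    lod = 0, r_ml = 1,
                    r_ci_low = 0.2, r_ci_high = c(1.1, 1.3, 1.8, 1.1, 2.5))
  scan <- structure(list(points = pts, spacing_morgans = 0.01),
                    class = "scan_result")
  f122 <- excluded_fraction(scan, 1.22)
  f20 <- excluded_fraction(scan, 2.0)
  f30 <- excluded_fraction(scan, 3.0)
  expect_lte(f122, f20)
  expect_lte(f20, f30)
  expect_equal(f30, 1)
  # chr2 carries 3x the genetic length of each chr1 point-pair half
  w_total <- 0.02 + 0.03
  expect_equal(f122, (0.005 + 0.015) / w_total)
})

test_that("scans handle chromosomes carrying a single marker", {
  cfg <- sim_config(n_case = 40, n_control = 20, n_markers = 30, seed = 2)
  sim <- simulate_cohort(cfg)   # 30 markers over 22 chromosomes: singletons
  expect_true(any(table(sim$panel$chromosome) == 1))
  scan <- admixture_scan(sim$cohort, sim$panel, spacing_cm = 5,
                         model = risk_model(grid = c(0.5, 1, 2)))
  expect_false(anyNA(scan$points$position_bp))
  expect_true(is.finite(scan$genome_lod))
})

test_that("a strong simulated risk locus dominates the scan LOD profile", {
  cfg <- sim_config(n_case = 300, n_control = 50, n_markers = 400,
                    ses_disease_effect = 0,
                    risk_locus = list(marker = 100, R = 3), seed = 41)
  sim <- simulate_cohort(cfg)
  scan <- admixture_scan(sim$cohort, sim$panel, spacing_cm = 2)
  expect_equal(dim(scan$lod_by_R), c(nrow(scan$points), 141L))
  expect_lt(max(abs(scan$lod_by_R[, match(1, scan$grid)])), 1e-9)
  expect_true(all(scan$points$r_ci_low <= scan$points$r_ml))
  expect_true(all(scan$points$r_ml <= scan$points$r_ci_high))
  top <- scan$points[which.max(scan$points$lod), ]
  expect_equal(top$chromosome, sim$panel$chromosome[100])
  expect_lt(abs(top$genetic_pos - sim$panel$genetic_pos[100]), 0.2)
  expect_gt(top$lod, 1)
  expect_lte(scan$genome_lod, max(scan$points$lod))
})
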