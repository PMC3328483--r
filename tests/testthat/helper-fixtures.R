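# Shared fixtures and independent oracles for the test suite.

# Quick panel builder: markers on one chromosome unless stated.
make_panel <- function(f1, f2, gpos = NULL, chromosome = 1L) {
  m <- length(f1)
  if (is.null(gpos)) gpos <- seq(0.01, by = 0.02, length.out = m)
  as_marker_panel(data.frame(
    marker_id = sprintf("m%03d", seq_len(m)),
    chromosome = chromosome,
    position_bp = seq(1e6, by = 1e6, length.out = m),
    genetic_pos = gpos,
    freq_pop1 = f1, freq_pop2 = f2,
    counted_allele = "A", other_allele = "C",
    stringsAsFactors = FALSE))
}

make_cohort <- function(G, status = NULL, ses = NULL, bmi = NULL) {
  n <- nrow(G)
  if (is.null(status)) status <- rep(c("case", "control"), length.out = n)
  ind <- data.frame(id = sprintf("i%04d", seq_len(n)), status = status,
                    stringsAsFactors = FALSE)
  if (!is.null(ses)) ind$ses <- ses
  if (!is.null(bmi)) ind$bmi <- bmi
  cohort(ind, G)
}

# Independent smoothing oracle: sums the joint probability over every pair
# of haplotype ancestry paths (2^m x 2^m), i.e. brute-force enumeration of
# the hidden chain rather than any forward-backward recursion.
enum_posterior <- function(g, panel, theta, lambda) {
  m <- nrow(panel)
  d <- diff(panel$genetic_pos)
  s <- exp(-lambda * d)
  f1 <- pmin(pmax(panel$freq_pop1, 1e-4), 1 - 1e-4)
  f2 <- pmin(pmax(panel$freq_pop2, 1e-4), 1 - 1e-4)
  hap_step <- function(from, to, k) {
    s[k] * (from == to) + (1 - s[k]) * (if (to == 1) theta else 1 - theta)
  }
  emis <- function(gg, j, k) {
    if (is.na(gg)) return(1)
    if (j == 0) return(dbinom(gg, 2, f2[k]))
    if (j == 2) return(dbinom(gg, 2, f1[k]))
    if (gg == 0) return((1 - f1[k]) * (1 - f2[k]))
    if (gg == 1) return(f1[k] + f2[k] - 2 * f1[k] * f2[k])
    f1[k] * f2[k]
  }
  paths <- as.matrix(expand.grid(rep(list(0:1), 2 * m)))
  post <- matrix(0, m, 3)
  total <- 0
  for (r in seq_len(nrow(paths))) {
    h1 <- paths[r, 1:m]
    h2 <- paths[r, (m + 1):(2 * m)]
    pr <- (if (h1[1] == 1) theta else 1 - theta) *
      (if (h2[1] == 1) theta else 1 - theta)
    if (m > 1) for (k in seq_len(m - 1)) {
      pr <- pr * hap_step(h1[k], h1[k + 1], k) * hap_step(h2[k], h2[k + 1], k)
    }
    for (k in seq_len(m)) pr <- pr * emis(g[k], h1[k] + h2[k], k)
    total <- total + pr
    for (k in seq_len(m)) {
      j <- h1[k] + h2[k]
      post[k, j + 1] <- post[k, j + 1] + pr
    }
  }
  post / total
}

# Monte-Carlo oracle for single-marker power: allele-count 2x2 tables and
# the Wald test on the log cross-product odds ratio.
sim_power_oracle <- function(freq_ctrl, or, n_case, n_control, alpha, reps,
                             seed = 42) {
  set.seed(seed)
  p1 <- or * freq_ctrl / (1 - freq_ctrl + or * freq_ctrl)
  a <- rbinom(reps, 2 * n_case, p1)
  b <- 2 * n_case - a
  cc <- rbinom(reps, 2 * n_control, freq_ctrl)
  d <- 2 * n_control - cc
  lor <- log(a) - log(b) - log(cc) + log(d)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  mean(abs(lor / se) > qnorm(1 - alpha / 2), na.rm = TRUE)
}

# Triplet files for the 3-marker x 2-individual transcription example.
write_tiny_triplet <- function(dir) {
  # individuals x markers: [[2,1,0],[0,NA,2]]
  writeLines(c("20", "19", "02"), file.path(dir, "t.geno"))
  writeLines(c("m1\t1\t0.01\t1000000",
               "m2\t1\t0.02\t2000000",
               "m3\t1\t0.03\t3000000"), file.path(dir, "t.snp"))
  writeLines(c("ind1\tF\tCase", "ind2\tM\tControl"), file.path(dir, "t.ind"))
  writeLines(c("marker_id\tcounted_allele\tother_allele\tfreq_pop1\tfreq_pop2",
               "m1\tA\tC\t0.9\t0.1",
               "m2\tG\tT\t0.8\t0.2",
               "m3\tA\tG\t0.7\t0.3"), file.path(dir, "t.freq.tsv"))
  file.path(dir, c("t.geno", "t.snp", "t.ind", "t.freq.tsv"))
}
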