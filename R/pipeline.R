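#' Default end-to-end run configuration
#'
#' A small demonstration configuration: a 200-case / 200-control cohort on
#' a 400-AIM panel, null genome, full scan and association stages. Settings
#' mirror the YAML schema accepted by [read_run_config()]: top-level
#' `seed`, `stages`, and per-stage `sim`, `scan`, `assoc` sections.
#'
#' @return nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "ancestry", "scan", "assoc"),
    sim = list(n_case = 200, n_control = 200, n_markers = 400),
    scan = list(lambda_gens = 10, spacing_cm = 1,
                grid = c(0.2, 3, 0.02), ci_alpha = 0.05,
                exclusion_thresholds = c(1.22, 1.5, 2)),
    assoc = list(covariates = c("ses", "bmi", "ancestry"), alpha = 0.05,
                 n_candidates = 20))
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified settings fall back to [default_run_config()]; the `sim`
#' section accepts every [sim_config()] argument.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_adx(sprintf("config file not found: '%s'", path),
                                   "adx_io_error")
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), user)
  cfg
}

manifest_entry <- function(outputs) {
  md5 <- tools::md5sum(outputs)
  list(status = "ok",
       outputs = as.list(stats::setNames(unname(md5), basename(outputs))))
}

#' Run the full pipeline
#'
#' Executes the requested stages in dependency order -- simulate (write the
#' genotype triplet, frequency, covariate and ground-truth tables), ancestry
#' (re-read the triplet, estimate per-individual global ancestry), scan
#' (admixture-mapping LOD scan plus exclusion map and genome summary) and
#' assoc (candidate-marker association table with sign test and Bonferroni
#' bookkeeping) -- and writes a reproducibility manifest with the seed,
#' package version, configuration and an MD5 checksum of every output.
#' Reruns with the same configuration and seed reproduce all tables
#' bit-for-bit. On stage failure the manifest records the failed stage and
#' the error is re-thrown; earlier outputs are retained.
#'
#' @param config configuration list (see [default_run_config()]) or path to
#'   a YAML file.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  manifest <- list(package = "admixscan",
                   version = as.character(utils::packageVersion("admixscan")),
                   seed = seed, config = config, stages = list())
  prefix <- file.path(out_dir, "cohort")
  finish <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  fail <- function(stage, err) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      error = conditionMessage(err))
    finish()
    stop(err)
  }
  stages <- config$stages

  if ("simulate" %in% stages) {
    tryCatch({
      sc <- do.call(sim_config, c(config$sim, list(seed = seed)))
      sim <- simulate_cohort(sc)
      paths <- write_genotriplet(sim$panel, sim$cohort, prefix)
      truth_path <- file.path(out_dir, "truth.tsv")
      truth <- data.frame(id = sim$cohort$ind$id,
                          true_theta = sim$cohort$true_theta)
      utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest$stages$simulate <- manifest_entry(c(paths, truth_path))
    }, error = function(e) fail("simulate", e))
  }

  dat <- NULL
  load_data <- function() {
    if (is.null(dat)) {
      dat <<- read_genotriplet(paste0(prefix, ".geno"), paste0(prefix, ".snp"),
                               paste0(prefix, ".ind"), paste0(prefix, ".freq.tsv"),
                               cov_path = paste0(prefix, ".cov.tsv"))
    }
    dat
  }

  theta_hat <- NULL
  if ("ancestry" %in% stages) {
    tryCatch({
      d <- load_data()
      theta_hat <- estimate_theta(d$cohort, d$panel)
      theta_path <- file.path(out_dir, "theta.tsv")
      utils::write.table(data.frame(id = names(theta_hat),
                                    theta_hat = round(theta_hat, 6)),
                         theta_path, sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$ancestry <- manifest_entry(theta_path)
    }, error = function(e) fail("ancestry", e))
  }

  if ("scan" %in% stages) {
    tryCatch({
      d <- load_data()
      gr <- config$scan$grid
      mdl <- risk_model(grid = risk_grid(gr[1], gr[2], gr[3]))
      if (!is.null(config$scan$scan_set)) mdl$scan_set <- config$scan$scan_set
      scan <- admixture_scan(d$cohort, d$panel,
                             lambda_gens = config$scan$lambda_gens,
                             spacing_cm = config$scan$spacing_cm,
                             model = mdl, ci_alpha = config$scan$ci_alpha,
                             theta_hat = theta_hat)
      scan_path <- file.path(out_dir, "scan.tsv")
      write_scan_table(scan, scan_path)
      thr <- config$scan$exclusion_thresholds
      summ <- data.frame(genome_lod = round(scan$genome_lod, 6),
                         max_locus_lod = round(max(scan$points$lod), 6),
                         t(vapply(thr, function(tt) round(excluded_fraction(scan, tt), 6),
                                  numeric(1))))
      names(summ)[-(1:2)] <- sprintf("excluded_R_gt_%s", format(thr))
      summary_path <- file.path(out_dir, "scan_summary.tsv")
      utils::write.table(summ, summary_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest$stages$scan <- manifest_entry(c(scan_path, summary_path))
    }, error = function(e) fail("scan", e))
  }

  if ("assoc" %in% stages) {
    tryCatch({
      d <- load_data()
      if (!is.null(config$assoc$candidates)) {
        cand <- utils::read.delim(config$assoc$candidates, stringsAsFactors = FALSE)
      } else {
        # evenly spaced panel markers as a stand-in candidate set
        k <- min(config$assoc$n_candidates %||% 20, nrow(d$panel))
        idx <- unique(round(seq(1, nrow(d$panel), length.out = k)))
        cand <- data.frame(marker_id = d$panel$marker_id[idx],
                           risk_allele = d$panel$counted_allele[idx],
                           stringsAsFactors = FALSE)
      }
      res <- association_table(d$cohort, d$panel, cand,
                               covariates = config$assoc$covariates,
                               theta_hat = theta_hat,
                               alpha = config$assoc$alpha)
      assoc_path <- file.path(out_dir, "association.tsv")
      write_association_table(res$table, assoc_path)
      st <- res$sign_test
      summ <- data.frame(n_markers = nrow(res$table),
                         bonferroni_alpha = res$bonferroni_alpha,
                         n_nominal = sum(res$table$nominal),
                         n_bonferroni = sum(res$table$bonferroni),
                         or_gt_1 = st$count_gt_1, sign_test_n = st$n,
                         sign_test_p = st$p)
      assoc_summary_path <- file.path(out_dir, "association_summary.tsv")
      utils::write.table(summ, assoc_summary_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest$stages$assoc <- manifest_entry(c(assoc_path, assoc_summary_path))
    }, error = function(e) fail("assoc", e))
  }

  finish()
  invisible(manifest)
}
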