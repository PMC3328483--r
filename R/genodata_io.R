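#' Marker panel constructor
#'
#' A marker panel describes the ancestry-informative markers (AIMs) the
#' analysis runs on: map positions plus the counted-allele frequency in each
#' of the two parental populations (population 1 = Native American,
#' population 2 = Old World). Frequencies are treated as known constants
#' supplied with the panel; genetic positions are stored in Morgans from the
#' chromosome start.
#'
#' @param df data.frame with columns `marker_id`, `chromosome` (1-22),
#'   `position_bp` (1-based physical position), `genetic_pos` (Morgans),
#'   `freq_pop1`, `freq_pop2`, `counted_allele`, `other_allele`.
#' @param sort if `TRUE`, rows are reordered by (chromosome, position_bp)
#'   with a warning when a reorder was needed.
#' @return the validated panel, a data.frame of class `marker_panel`.
#' @export
as_marker_panel <- function(df, sort = FALSE) {
  needed <- c("marker_id", "chromosome", "position_bp", "genetic_pos",
              "freq_pop1", "freq_pop2", "counted_allele", "other_allele")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop_adx(sprintf("marker panel is missing columns: %s",
                     paste(missing_cols, collapse = ", ")),
             "adx_validation_error")
  }
  df <- as.data.frame(df)[needed]
  df$chromosome <- as.integer(df$chromosome)
  df$position_bp <- as.integer(df$position_bp)
  df$marker_id <- as.character(df$marker_id)

  ord <- order(df$chromosome, df$position_bp)
  if (is.unsorted(ord) || any(ord != seq_len(nrow(df)))) {
    if (!sort) {
      stop_adx("markers are not sorted by (chromosome, position_bp)",
               "adx_validation_error")
    }
    warn_adx("marker rows were not positionally sorted; reordering",
             "adx_reorder_warning")
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
  }
  validate_marker_panel(df)
}

validate_marker_panel <- function(df) {
  if (anyDuplicated(df$marker_id)) {
    stop_adx("duplicate marker identifiers in panel", "adx_validation_error")
  }
  if (any(df$freq_pop1 < 0 | df$freq_pop1 > 1 |
          df$freq_pop2 < 0 | df$freq_pop2 > 1, na.rm = FALSE)) {
    stop_adx("ancestral allele frequencies must lie in [0, 1]",
             "adx_validation_error")
  }
  if (any(!df$chromosome %in% 1:22)) {
    stop_adx("chromosome labels must be autosomes 1-22", "adx_validation_error")
  }
  for (ch in unique(df$chromosome)) {
    sel <- df$chromosome == ch
    if (any(diff(df$position_bp[sel]) <= 0)) {
      stop_adx(sprintf("physical positions not strictly increasing on chromosome %d", ch),
               "adx_validation_error")
    }
    if (any(diff(df$genetic_pos[sel]) < 0)) {
      stop_adx(sprintf("genetic positions decrease on chromosome %d", ch),
               "adx_validation_error")
    }
  }
  class(df) <- c("marker_panel", "data.frame")
  df
}

#' Cohort constructor
#'
#' Bundles the genotype matrix (individuals x markers, counted-allele dosage
#' 0/1/2, `NA` = missing) with case-control status and the covariates the
#' association models use (socioeconomic band 1-6, BMI, age, sex). Simulated
#' cohorts may carry ground truth: the generating global ancestry proportion
#' and the per-marker Native-copy counts.
#'
#' @param ind data.frame with columns `id`, `status` ("case"/"control") and
#'   optionally `ses`, `bmi`, `age`, `sex`.
#' @param genotypes integer matrix, one row per individual in `ind` order.
#' @param true_theta,true_local optional simulation ground truth.
#' @return an object of class `cohort`.
#' @export
cohort <- function(ind, genotypes, true_theta = NULL, true_local = NULL) {
  ind <- as.data.frame(ind)
  if (!all(c("id", "status") %in% names(ind))) {
    stop_adx("cohort table needs `id` and `status` columns", "adx_validation_error")
  }
  ind$id <- as.character(ind$id)
  ind$status <- tolower(as.character(ind$status))
  if (!all(ind$status %in% c("case", "control"))) {
    stop_adx("status must be 'case' or 'control'", "adx_validation_error")
  }
  for (cv in c("ses", "bmi", "age")) if (!cv %in% names(ind)) ind[[cv]] <- NA_real_
  if (!"sex" %in% names(ind)) ind$sex <- NA_character_
  if (any(!is.na(ind$ses) & !ind$ses %in% 1:6)) {
    stop_adx("SES bands must be integers 1-6", "adx_validation_error")
  }
  if (any(!is.na(ind$bmi) & ind$bmi <= 0)) {
    stop_adx("BMI must be positive where present", "adx_validation_error")
  }
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) != nrow(ind)) {
    stop_adx("genotype matrix rows do not match the individual table",
             "adx_dimension_error")
  }
  if (any(!genotypes %in% c(0L, 1L, 2L, NA))) {
    stop_adx("genotypes must be 0, 1, 2 or missing", "adx_validation_error")
  }
  if (ncol(genotypes) > 0 && any(colSums(!is.na(genotypes)) == 0)) {
    stop_adx("a marker has no observed genotypes", "adx_validation_error")
  }
  rownames(genotypes) <- ind$id
  structure(list(ind = ind, genotypes = genotypes,
                 true_theta = true_theta, true_local = true_local),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d individuals (%d cases / %d controls), %d markers\n",
              nrow(x$ind), sum(x$ind$status == "case"),
              sum(x$ind$status == "control"), ncol(x$genotypes)))
  invisible(x)
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> %d markers on %d chromosomes, mean |freq differential| %.3f\n",
              nrow(x), length(unique(x$chromosome)),
              mean(abs(x$freq_pop1 - x$freq_pop2))))
  invisible(x)
}

parse_error <- function(path, line, what) {
  stop_adx(sprintf("%s (file '%s', line %d)", what, path, line),
           "adx_parse_error")
}

#' Read a genotype triplet plus ancestral frequencies
#'
#' Reads EIGENSTRAT-style files: a `geno` file with one row per marker and
#' one character per individual (0/1/2 counted-allele copies, 9 = missing),
#' a `snp` file (marker_id, chromosome, genetic position in Morgans,
#' physical position, optionally alleles), an `ind` file (id, sex, label)
#' and a tab-separated frequency file giving the counted allele and its
#' frequency in each parental population. Case-control status is taken from
#' the `ind` label column unless a covariate table is supplied.
#'
#' @param geno_path,snp_path,ind_path,freq_path input files.
#' @param cov_path optional covariate TSV (see [read_covariates()]); merged
#'   by individual id.
#' @return `list(panel = marker_panel, cohort = cohort)`.
#' @export
read_genotriplet <- function(geno_path, snp_path, ind_path, freq_path,
                             cov_path = NULL) {
  for (p in c(geno_path, snp_path, ind_path, freq_path)) {
    if (!file.exists(p)) stop_adx(sprintf("file not found: '%s'", p), "adx_io_error")
  }
  geno_lines <- readLines(geno_path)
  geno_lines <- geno_lines[nzchar(geno_lines)]
  if (length(geno_lines) == 0) parse_error(geno_path, 1L, "empty genotype file")

  snp_raw <- utils::read.table(snp_path, header = FALSE, comment.char = "#",
                               stringsAsFactors = FALSE)
  if (ncol(snp_raw) < 4) {
    parse_error(snp_path, 1L, "snp file needs at least 4 columns")
  }
  names(snp_raw)[1:4] <- c("marker_id", "chromosome", "genetic_pos", "position_bp")

  ind <- utils::read.table(ind_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(ind) < 3) parse_error(ind_path, 1L, "ind file needs 3 columns")
  names(ind)[1:3] <- c("id", "sex", "label")

  if (length(geno_lines) != nrow(snp_raw)) {
    parse_error(geno_path, length(geno_lines), sprintf(
      "genotype rows (%d) do not match snp rows (%d)",
      length(geno_lines), nrow(snp_raw)))
  }
  n_ind <- nrow(ind)
  widths <- nchar(geno_lines)
  bad <- which(widths != n_ind)
  if (length(bad) > 0) {
    parse_error(geno_path, bad[1], sprintf(
      "genotype row width %d does not match %d individuals", widths[bad[1]], n_ind))
  }
  chars <- strsplit(geno_lines, "", fixed = TRUE)
  allowed <- c("0", "1", "2", "9")
  for (i in seq_along(chars)) {
    off <- !chars[[i]] %in% allowed
    if (any(off)) {
      parse_error(geno_path, i, sprintf("invalid genotype symbol '%s'",
                                        chars[[i]][off][1]))
    }
  }
  # markers x individuals, then transpose to cohort orientation
  gmat <- t(vapply(chars, function(x) as.integer(x), integer(n_ind)))
  if (n_ind == 1L) gmat <- matrix(gmat, ncol = 1L)
  gmat[gmat == 9L] <- NA_integer_

  freq <- utils::read.delim(freq_path, stringsAsFactors = FALSE)
  fneed <- c("marker_id", "counted_allele", "other_allele", "freq_pop1", "freq_pop2")
  if (!all(fneed %in% names(freq))) {
    stop_adx(sprintf("frequency file '%s' needs columns: %s", freq_path,
                     paste(fneed, collapse = ", ")), "adx_parse_error")
  }
  miss <- setdiff(snp_raw$marker_id, freq$marker_id)
  if (length(miss) > 0) {
    stop_adx(sprintf("no ancestral frequencies for %d markers (first: %s)",
                     length(miss), miss[1]), "adx_validation_error")
  }
  freq <- freq[match(snp_raw$marker_id, freq$marker_id), ]
  pdf <- data.frame(marker_id = snp_raw$marker_id,
                    chromosome = snp_raw$chromosome,
                    position_bp = snp_raw$position_bp,
                    genetic_pos = snp_raw$genetic_pos,
                    freq_pop1 = freq$freq_pop1,
                    freq_pop2 = freq$freq_pop2,
                    counted_allele = freq$counted_allele,
                    other_allele = freq$other_allele,
                    stringsAsFactors = FALSE)
  ord <- order(pdf$chromosome, pdf$position_bp)
  reordered <- any(ord != seq_len(nrow(pdf)))
  panel <- as_marker_panel(pdf, sort = TRUE)
  if (reordered) gmat <- gmat[ord, , drop = FALSE]

  ctab <- data.frame(id = ind$id, status = ind$label, stringsAsFactors = FALSE)
  if (!is.null(cov_path)) {
    cv <- read_covariates(cov_path)
    hit <- match(ctab$id, cv$id)
    if (anyNA(hit)) {
      stop_adx(sprintf("covariate table lacks %d individuals (first: %s)",
                       sum(is.na(hit)), ctab$id[is.na(hit)][1]),
               "adx_validation_error")
    }
    cv <- cv[hit, ]
    ctab <- data.frame(id = ctab$id, status = cv$status, ses = cv$ses,
                       bmi = cv$bmi, age = cv$age, sex = cv$sex,
                       stringsAsFactors = FALSE)
  } else {
    ctab$sex <- ind$sex
  }
  list(panel = panel, cohort = cohort(ctab, t(gmat)))
}

#' Write a genotype triplet plus frequency and covariate tables
#'
#' Inverse of [read_genotriplet()]: writes `<prefix>.geno`, `<prefix>.snp`,
#' `<prefix>.ind`, `<prefix>.freq.tsv` and `<prefix>.cov.tsv`.
#'
#' @param panel a `marker_panel`.
#' @param chrt a `cohort`.
#' @param prefix output path prefix.
#' @return invisibly, the named vector of written paths.
#' @export
write_genotriplet <- function(panel, chrt, prefix) {
  g <- t(chrt$genotypes)                 # markers x individuals
  g[is.na(g)] <- 9L
  paths <- c(geno = paste0(prefix, ".geno"), snp = paste0(prefix, ".snp"),
             ind = paste0(prefix, ".ind"), freq = paste0(prefix, ".freq.tsv"),
             cov = paste0(prefix, ".cov.tsv"))
  writeLines(apply(g, 1, paste, collapse = ""), paths["geno"])
  snp <- data.frame(panel$marker_id, panel$chromosome,
                    format(panel$genetic_pos, digits = 10, scientific = FALSE, trim = TRUE),
                    panel$position_bp, panel$counted_allele, panel$other_allele)
  utils::write.table(snp, paths["snp"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ind <- data.frame(chrt$ind$id, ifelse(is.na(chrt$ind$sex), "U", chrt$ind$sex),
                    ifelse(chrt$ind$status == "case", "Case", "Control"))
  utils::write.table(ind, paths["ind"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(panel[c("marker_id", "counted_allele", "other_allele",
                             "freq_pop1", "freq_pop2")],
                     paths["freq"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_covariates(chrt, paths["cov"])
  invisible(paths)
}

#' Read / write a covariate table
#'
#' Tab-separated with header `id status ses bmi age sex`; missing values as
#' `NA`.
#'
#' @param path file path.
#' @return data.frame of covariates.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop_adx(sprintf("file not found: '%s'", path), "adx_io_error")
  cv <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "status")
  if (!all(need %in% names(cv))) {
    stop_adx(sprintf("covariate table '%s' needs columns id, status", path),
             "adx_parse_error")
  }
  for (col in c("ses", "bmi", "age")) if (!col %in% names(cv)) cv[[col]] <- NA_real_
  if (!"sex" %in% names(cv)) cv$sex <- NA_character_
  cv$id <- as.character(cv$id)
  cv
}

#' @rdname read_covariates
#' @param chrt a `cohort`.
#' @export
write_covariates <- function(chrt, path) {
  utils::write.table(chrt$ind[c("id", "status", "ses", "bmi", "age", "sex")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an admixture-scan result table
#'
#' One row per genome evaluation point: LOD score of the averaged disease
#' models, the maximum-likelihood ancestry risk ratio and its 95%
#' likelihood-ratio confidence bounds.
#'
#' @param scan a `scan_result` (or its `points` data.frame).
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_scan_table <- function(scan, path) {
  pts <- if (inherits(scan, "scan_result")) scan$points else as.data.frame(scan)
  cols <- c("point_id", "chromosome", "position_bp", "lod", "r_ml",
            "r_ci_low", "r_ci_high")
  out <- pts[cols]
  ok <- tryCatch(suppressWarnings({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }), error = function(e) FALSE)
  if (!ok) stop_adx(sprintf("cannot write scan table to '%s'", path), "adx_io_error")
  invisible(path)
}

#' @rdname write_scan_table
#' @export
read_scan_table <- function(path) {
  if (!file.exists(path)) stop_adx(sprintf("file not found: '%s'", path), "adx_io_error")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write an association result table
#'
#' @param result data.frame as returned by [association_table()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_association_table <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
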