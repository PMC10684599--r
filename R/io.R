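#' Write a cohort to a directory of delimited tables
#'
#' Emits one tab-separated file per cohort component plus a flat
#' `key=value` config file, so a cohort round-trips losslessly through
#' [read_cohort()].  Doubles are written with 17 significant digits (exact
#' read-back); dosages are written as stored.
#'
#' @param cohort A `bcaa_cohort`.
#' @param directory Output directory (created if missing).
#' @param vcf Also emit `dosages.vcf`, a VCF v4.2 file carrying the dosage
#'   matrix in the per-genotype `DS` field.
#' @return `directory`, invisibly.
#' @export
write_cohort <- function(cohort, directory, vcf = FALSE) {
  stopifnot(inherits(cohort, "bcaa_cohort"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  fw <- function(df, file) {
    data.table::fwrite(.fmt_df(as.data.frame(df)),
                       file.path(directory, file), sep = "\t", na = "NA",
                       quote = FALSE)
  }
  fw(as.data.frame(cohort$dosages), "dosages.tsv")
  fw(cohort$variant_info, "variants.tsv")
  fw(as.data.frame(cohort$exposures), "exposures.tsv")
  fw(as.data.frame(cohort$exposures_raw), "exposures_raw.tsv")
  fw(cohort$covariates, "covariates.tsv")
  fw(data.frame(latent_confounder = cohort$latent_confounder),
     "confounder.tsv")
  fw(cohort$phenotypes, "phenotypes.tsv")
  fw(cohort$phenotype_info, "phenotype_info.tsv")
  tr <- cohort$truth
  fw(as.data.frame(tr$effects), "effects.tsv")
  if (length(tr$liabilities)) {
    fw(as.data.frame(tr$liabilities), "liabilities.tsv")
    fw(data.frame(name = names(tr$liability_thresholds),
                  threshold = unname(tr$liability_thresholds)),
       "liability_thresholds.tsv")
  }
  .write_flat_config(tr$config, file.path(directory, "config.txt"))
  .write_phenotype_specs(tr$config$phenotype_specs,
                         file.path(directory, "phenotype_specs.tsv"))
  if (vcf) {
    write_dosage_vcf(cohort, file.path(directory, "dosages.vcf"))
  }
  invisible(directory)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory Directory produced by [write_cohort()].
#' @return A `bcaa_cohort`.  Dosages outside `[0, 2]` are rejected with an
#'   error naming the offending variant.
#' @export
read_cohort <- function(directory) {
  fr <- function(file, required = TRUE) {
    path <- file.path(directory, file)
    if (!file.exists(path)) {
      if (required) stop("missing cohort file: ", path)
      return(NULL)
    }
    tryCatch(
      as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA")),
      error = function(e) stop("failed to parse ", path, ": ",
                               conditionMessage(e), call. = FALSE),
      warning = function(w) stop("failed to parse ", path, ": ",
                                 conditionMessage(w), call. = FALSE)
    )
  }
  dos <- as.matrix(fr("dosages.tsv"))
  .check_dosage_range(dos)
  variant_info <- fr("variants.tsv")
  cfg <- .read_flat_config(file.path(directory, "config.txt"),
                           file.path(directory, "phenotype_specs.tsv"))
  eff <- as.matrix(fr("effects.tsv"))
  colnames(eff) <- bcaa_names()
  liab_df <- fr("liabilities.tsv", required = FALSE)
  thr_df <- fr("liability_thresholds.tsv", required = FALSE)
  thresholds <- NULL
  if (!is.null(thr_df)) {
    thresholds <- stats::setNames(thr_df$threshold, thr_df$name)
  }
  maf <- variant_info$maf
  structure(list(
    dosages = dos,
    variant_info = variant_info,
    exposures = as.matrix(fr("exposures.tsv")),
    exposures_raw = as.matrix(fr("exposures_raw.tsv")),
    covariates = fr("covariates.tsv"),
    latent_confounder = fr("confounder.tsv")$latent_confounder,
    phenotypes = fr("phenotypes.tsv"),
    phenotype_info = fr("phenotype_info.tsv"),
    truth = list(config = cfg, effects = eff,
                 effects_per_allele = eff / sqrt(2 * maf * (1 - maf)),
                 genetic_values = NULL,
                 genetic_covariance = crossprod(eff),
                 liabilities = if (is.null(liab_df)) list()
                               else as.list(liab_df),
                 liability_thresholds = thresholds,
                 residual_sd = NULL)
  ), class = "bcaa_cohort")
}

.check_dosage_range <- function(dos) {
  bad <- which(colSums(dos < 0 | dos > 2 | !is.finite(dos)) > 0)
  if (length(bad)) {
    stop("dosages outside [0, 2] for variant ",
         paste(colnames(dos)[bad[seq_len(min(3, length(bad)))]],
               collapse = ", "), call. = FALSE)
  }
  invisible(dos)
}

.write_flat_config <- function(cfg, path) {
  num <- function(x) paste(.fmt_full(as.numeric(x)), collapse = ",")
  lines <- c(
    paste0("n_individuals=", cfg$n_individuals),
    paste0("n_shared_loci=", cfg$n_shared_loci),
    paste0("n_specific_loci=", paste(cfg$n_specific_loci, collapse = ",")),
    paste0("n_background_loci=", cfg$n_background_loci),
    paste0("n_null_variants=", cfg$n_null_variants),
    paste0("maf_range=", num(cfg$maf_range)),
    paste0("heritability=", num(cfg$heritability)),
    paste0("genetic_correlation=", num(cfg$genetic_correlation)),
    paste0("specific_variance_fraction=",
           num(cfg$specific_variance_fraction)),
    paste0("background_variance_fraction=",
           num(cfg$background_variance_fraction)),
    paste0("confounder_loading=", num(cfg$confounder_loading)),
    paste0("residual_correlation=",
           paste(apply(cfg$residual_correlation, 1, num), collapse = ";")),
    paste0("covariate_effect=", num(cfg$covariate_effect)),
    paste0("quality_range=", num(cfg$quality_range)),
    paste0("seed=", cfg$seed)
  )
  writeLines(lines, path)
}

.read_flat_config <- function(path, specs_path) {
  if (!file.exists(path)) stop("missing cohort file: ", path)
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad)) {
    stop("failed to parse ", path, " at line ", bad[1],
         ": expected key=value", call. = FALSE)
  }
  vals <- stats::setNames(lapply(kv, function(p) p[2]),
                          vapply(kv, `[[`, "", 1))
  num <- function(key) as.numeric(strsplit(vals[[key]], ",")[[1]])
  rc <- do.call(rbind, lapply(strsplit(vals[["residual_correlation"]],
                                       ";")[[1]],
                              function(r) as.numeric(strsplit(r, ",")[[1]])))
  simulation_config(
    n_individuals = num("n_individuals"),
    n_shared_loci = num("n_shared_loci"),
    n_specific_loci = num("n_specific_loci"),
    n_background_loci = num("n_background_loci"),
    n_null_variants = num("n_null_variants"),
    maf_range = num("maf_range"),
    heritability = num("heritability"),
    genetic_correlation = num("genetic_correlation"),
    specific_variance_fraction = num("specific_variance_fraction"),
    background_variance_fraction = num("background_variance_fraction"),
    confounder_loading = num("confounder_loading"),
    residual_correlation = rc,
    covariate_effect = num("covariate_effect"),
    quality_range = num("quality_range"),
    phenotype_specs = .read_phenotype_specs(specs_path),
    seed = num("seed")
  )
}

.write_phenotype_specs <- function(specs, path) {
  if (is.null(specs) || !length(specs)) {
    writeLines(paste(c("name", "category", "kind", "beta_leucine",
                       "beta_isoleucine", "beta_valine", "confounder_beta",
                       "prevalence", "noise_sd", "liability_sd",
                       "covariate_beta"), collapse = "\t"), path)
    return(invisible(path))
  }
  df <- do.call(rbind, lapply(specs, function(sp) {
    data.frame(name = sp$name, category = sp$category, kind = sp$kind,
               beta_leucine = sp$causal_betas[1],
               beta_isoleucine = sp$causal_betas[2],
               beta_valine = sp$causal_betas[3],
               confounder_beta = sp$confounder_beta,
               prevalence = sp$prevalence %||% NA_real_,
               noise_sd = sp$noise_sd %||% NA_real_,
               liability_sd = sp$liability_sd,
               covariate_beta = sp$covariate_beta,
               stringsAsFactors = FALSE)
  }))
  data.table::fwrite(.fmt_df(df), path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

.read_phenotype_specs <- function(path) {
  if (!file.exists(path)) stop("missing cohort file: ", path)
  df <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
  if (nrow(df) == 0L) return(NULL)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    phenotype_spec(r$name, r$category, r$kind,
                   causal_betas = c(r$beta_leucine, r$beta_isoleucine,
                                    r$beta_valine),
                   confounder_beta = r$confounder_beta,
                   prevalence = if (r$kind == "binary") r$prevalence,
                   noise_sd = if (r$kind == "continuous") r$noise_sd,
                   liability_sd = r$liability_sd,
                   covariate_beta = r$covariate_beta)
  })
}

#' Write cohort dosages as a VCF with per-genotype dosage values
#'
#' Emits a minimal VCF v4.2 whose only FORMAT field is `DS` (estimated
#' alternate allele dosage), one sample column per individual.
#'
#' @param cohort A `bcaa_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(cohort, path) {
  stopifnot(inherits(cohort, "bcaa_cohort"))
  vi <- cohort$variant_info
  n <- nrow(cohort$dosages)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bcaamvmr",
    paste0("##FORMAT=<ID=DS,Number=1,Type=Float,Description=",
           "\"Estimated alternate allele dosage\">"),
    paste0("##INFO=<ID=Q,Number=1,Type=Float,Description=",
           "\"Imputation quality\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("ind_%05d", seq_len(n))), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(vi)), function(l) {
    paste(c(vi$chrom[l], vi$pos[l], vi$id[l], "A", "G", ".", "PASS",
            sprintf("Q=%s", format(vi$q[l], digits = 6)), "DS",
            format(cohort$dosages[, l], digits = 6, trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a dosage matrix from a VCF with a DS genotype field
#'
#' @param path A VCF file whose FORMAT includes `DS`.
#' @return List with `dosages` (n x L numeric matrix, individuals by
#'   variants) and `info` (variant id, chrom, pos, and `Q` where present).
#'   Dosages outside `[0, 2]` raise an error naming the variant.
#' @export
read_dosage_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  if (is.null(ds) || nrow(ds) == 0L) stop("no DS field found in ", path)
  dos <- t(ds)
  dimnames(dos) <- list(rownames(dos), unname(v@fix[, "ID"]))
  .check_dosage_range(dos)
  qstr <- sub(".*Q=([0-9.eE+-]+).*", "\\1", v@fix[, "INFO"])
  info <- data.frame(id = v@fix[, "ID"],
                     chrom = v@fix[, "CHROM"],
                     pos = as.integer(v@fix[, "POS"]),
                     q = suppressWarnings(as.numeric(qstr)),
                     stringsAsFactors = FALSE)
  list(dosages = dos, info = info)
}
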