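## Text interchange: PLINK-dialect pedigrees (FAM), TSV score / covariate /
## variant / trio tables, long-format diagnosis tables, YAML parameter files.

sex_to_code <- function(sex) ifelse(sex == "male", 1L, 2L)
code_to_sex <- function(code) ifelse(code == 1L, "male", "female")

#' Write and read a FAM-dialect pedigree
#'
#' Six whitespace-separated columns without header: family id, individual
#' id, father id, mother id, sex (1 = male, 2 = female) and phenotype
#' (2 = affected, 1 = unaffected, -9 = missing). Missing parents are coded 0.
#'
#' @param cohort A cohort tibble; the ASD diagnosis is written as the
#'   phenotype.
#' @param path File path.
#' @return `write_fam()` returns `path` invisibly; `read_fam()` returns a
#'   tibble with columns `fid`, `iid`, `father_iid`, `mother_iid`, `sex`,
#'   `phenotype` (logical, `NA` for missing).
#' @export
write_fam <- function(cohort, path) {
  df <- data.frame(
    fid = cohort$fid,
    iid = cohort$iid,
    pat = ifelse(is.na(cohort$father_iid), 0L, cohort$father_iid),
    mat = ifelse(is.na(cohort$mother_iid), 0L, cohort$mother_iid),
    sex = sex_to_code(cohort$sex),
    pheno = ifelse(is.na(cohort$dx_asd), -9L, ifelse(cohort$dx_asd, 2L, 1L))
  )
  readr::write_delim(df, path, delim = " ", col_names = FALSE)
  invisible(path)
}

#' @rdname write_fam
#' @export
read_fam <- function(path) {
  df <- readr::read_table(
    path,
    col_names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
    col_types = "iiiiii"
  )
  tibble::tibble(
    fid = df$fid,
    iid = df$iid,
    father_iid = ifelse(df$pat == 0L, NA_integer_, df$pat),
    mother_iid = ifelse(df$mat == 0L, NA_integer_, df$mat),
    sex = code_to_sex(df$sex),
    phenotype = dplyr::case_when(df$pheno == 2L ~ TRUE,
                                 df$pheno == 1L ~ FALSE,
                                 .default = NA)
  )
}

#' Score, covariate, diagnosis, variant and trio tables (TSV)
#'
#' Thin readers/writers for the tab-separated interchange formats: score
#' tables (`FID`, `IID`, `SCORE`), covariate tables (`IID`, `PC1` ...
#' `PCk`), long-format diagnosis tables (`IID`, `diagnosis`), annotated
#' variant tables (`IID`, `gene`, `class`, `pli`, `mpc`,
#' `constrained_genes_hit`, `de_novo`) and trio score tables.
#'
#' @param scores Tibble with columns `fid` (optional), `iid`, `score`.
#' @param path File path.
#' @return Readers return tibbles in the package's lower-case column
#'   conventions; writers return `path` invisibly.
#' @name table-io
NULL

#' @rdname table-io
#' @export
write_score_table <- function(scores, path) {
  df <- tibble::tibble(
    FID = scores$fid %||% scores$iid,
    IID = scores$iid,
    SCORE = scores$score
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname table-io
#' @export
read_score_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  tibble::tibble(fid = df$FID, iid = df$IID, score = df$SCORE)
}

#' @rdname table-io
#' @param covariates Tibble with column `iid` plus `PC1..PCk` columns.
#' @export
write_covariate_table <- function(covariates, path) {
  df <- covariates
  names(df)[names(df) == "iid"] <- "IID"
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname table-io
#' @export
read_covariate_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  names(df)[names(df) == "IID"] <- "iid"
  df
}

#' @rdname table-io
#' @param cohort A cohort tibble.
#' @export
write_diagnosis_table <- function(cohort, path) {
  long <- dplyr::bind_rows(
    tibble::tibble(IID = cohort$iid[cohort$dx_asd], diagnosis = "ASD"),
    tibble::tibble(IID = cohort$iid[cohort$dx_id], diagnosis = "ID")
  )
  readr::write_tsv(long, path)
  invisible(path)
}

#' @rdname table-io
#' @export
read_diagnosis_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  tibble::tibble(iid = df$IID, diagnosis = df$diagnosis)
}

#' @rdname table-io
#' @param variants Variant tibble (see [is_high_impact()]).
#' @export
write_variant_table <- function(variants, path) {
  df <- variants
  names(df)[names(df) == "iid"] <- "IID"
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname table-io
#' @export
read_variant_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          pli = readr::col_double(),
                          mpc = readr::col_double(),
                          constrained_genes_hit = readr::col_integer(),
                          de_novo = readr::col_logical()
                        ))
  names(df)[names(df) == "IID"] <- "iid"
  df
}

#' @rdname table-io
#' @param trios Trio tibble from [cohort_trios()].
#' @export
write_trio_table <- function(trios, path) {
  readr::write_tsv(trios, path)
  invisible(path)
}

#' @rdname table-io
#' @export
read_trio_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a simulated cohort as a directory of interchange files
#'
#' Emits `cohort.fam` (pedigree), `scores.tsv` (observed polygenic scores),
#' `diagnoses.tsv` (long format) and `params.yaml` (generating parameters).
#'
#' @param cohort A cohort tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fam(cohort, file.path(dir, "cohort.fam"))
  write_score_table(
    tibble::tibble(fid = cohort$fid, iid = cohort$iid, score = cohort$pgs_obs),
    file.path(dir, "scores.tsv")
  )
  write_diagnosis_table(cohort, file.path(dir, "diagnoses.tsv"))
  p <- cohort_params(cohort)
  if (!is.null(p)) write_liability_params(p, file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Serialize liability parameters to YAML
#'
#' @param params A [liability_params()] object.
#' @param path File path.
#' @return `write_liability_params()` returns `path` invisibly;
#'   `read_liability_params()` returns a reconstructed
#'   [liability_params()] object (the round trip is lossless).
#' @export
write_liability_params <- function(params, path) {
  stopifnot(inherits(params, "liability_params"))
  yaml::write_yaml(list(
    h2_common = params$h2_common,
    dnv_rate = params$dnv_rate,
    dnv_effect = params$dnv_effect,
    rg_asd_id = params$rg_asd_id,
    prevalence = list(
      asd = as.list(params$prevalence$asd),
      id = as.list(params$prevalence$id)
    ),
    score_r2 = params$score_r2,
    birth_years = as.integer(params$birth_years)
  ), path)
  invisible(path)
}

#' @rdname write_liability_params
#' @export
read_liability_params <- function(path) {
  y <- yaml::read_yaml(path)
  liability_params(
    h2_common = y$h2_common,
    dnv_rate = y$dnv_rate,
    dnv_effect = y$dnv_effect,
    rg_asd_id = y$rg_asd_id,
    prevalence = list(
      asd = unlist(y$prevalence$asd),
      id = unlist(y$prevalence$id)
    ),
    score_r2 = y$score_r2,
    birth_years = y$birth_years
  )
}
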