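#' Linear polygenic scoring
#'
#' Computes, for every sample, the weighted sum of allele dosages over the
#' variants shared between the dosage table and the weight table (linear
#' scoring). Variants present in the dosage table but absent from the
#' weights are ignored, with the count reported via a message and the
#' `"n_ignored_variants"` attribute.
#'
#' @param dosages Long-format tibble with columns `iid`, `variant_id`,
#'   `dosage` (dosages in `[0, 2]`, no missing values).
#' @param weights Tibble with columns `variant_id`, `weight`.
#' @return A tibble with columns `iid`, `score`, one row per sample.
#' @examples
#' d <- tibble::tibble(iid = c("a", "a"), variant_id = c("v1", "v2"),
#'                     dosage = c(2, 1))
#' w <- tibble::tibble(variant_id = c("v1", "v2"), weight = c(0.1, -0.2))
#' score_samples(d, w)
#' @export
score_samples <- function(dosages, weights) {
  need <- c("iid", "variant_id", "dosage")
  if (!all(need %in% names(dosages))) {
    abort("`dosages` needs columns iid, variant_id, dosage.")
  }
  if (!all(c("variant_id", "weight") %in% names(weights))) {
    abort("`weights` needs columns variant_id, weight.")
  }
  if (anyNA(dosages$dosage) || any(dosages$dosage < 0 | dosages$dosage > 2)) {
    abort("Dosages must be non-missing and within [0, 2].")
  }
  known <- dosages$variant_id %in% weights$variant_id
  n_ignored <- length(unique(dosages$variant_id[!known]))
  if (!any(known)) {
    abort("No variants in common between dosages and weights.")
  }
  if (n_ignored > 0) {
    inform(sprintf("%d variant(s) without weights ignored.", n_ignored))
  }
  out <- dosages[known, ] |>
    dplyr::mutate(w = weights$weight[match(.data$variant_id, weights$variant_id)]) |>
    dplyr::group_by(.data$iid) |>
    dplyr::summarise(score = sum(.data$w * .data$dosage), .groups = "drop")
  ## samples whose variants were all unweighted still get a (zero) score
  missing_iid <- setdiff(unique(dosages$iid), out$iid)
  if (length(missing_iid)) {
    out <- dplyr::bind_rows(out, tibble::tibble(iid = missing_iid, score = 0))
  }
  attr(out, "n_ignored_variants") <- n_ignored
  out
}

#' Standardize scores against a reference population
#'
#' Expresses scores in reference-population standard deviations:
#' `(score - mean(reference)) / sd(reference)`, with the sample (n-1) SD. The
#' reference cohort itself maps to mean 0 and SD 1. Group differences in
#' standardized scores are therefore on the reference-SD scale used when
#' reporting polygenic-score contrasts against a population cohort.
#'
#' @param scores Tibble with a `score` column.
#' @param reference Tibble with a `score` column (at least 2 rows, positive
#'   SD).
#' @return `scores` with an added `std_score` column.
#' @export
standardize_scores <- function(scores, reference) {
  if (!"score" %in% names(scores) || !"score" %in% names(reference)) {
    abort("Both tables need a `score` column.")
  }
  if (nrow(reference) < 2) abort("Reference must contain at least 2 scores.")
  ref_sd <- sd(reference$score)
  if (!is.finite(ref_sd) || ref_sd <= 0) {
    abort("Reference score SD must be positive.")
  }
  dplyr::mutate(scores,
                std_score = (.data$score - mean(reference$score)) / ref_sd)
}

new_prs_contrast <- function(fit, term, n0, n1, k_cov, label) {
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm)) {
    abort(sprintf("Term '%s' absent from the fitted model.", term))
  }
  structure(
    list(
      label = label,
      difference = sm[term, "Estimate"],
      standard_error = sm[term, "Std. Error"],
      t = sm[term, "t value"],
      p_value = sm[term, "Pr(>|t|)"],
      n_group0 = n0,
      n_group1 = n1,
      n_covariates = k_cov
    ),
    class = "prs_contrast"
  )
}

check_full_rank <- function(mm) {
  qr_d <- qr(mm)
  if (qr_d$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_d$pivot[(qr_d$rank + 1):ncol(mm)]]
    abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
}

#' Polygenic-score contrast between two groups
#'
#' Ordinary least squares of the score on a 0/1 group indicator plus optional
#' principal-component covariates: `score ~ group + PC1 + ... + PCk`. The
#' reported difference is the indicator coefficient (group 1 minus group 0);
#' with no covariates it equals the difference of group means exactly.
#'
#' @param data Data frame with one row per sample.
#' @param score Name of the (standardized) score column.
#' @param group Name of the 0/1 indicator column (logical or numeric).
#' @param pcs Character vector of covariate column names (e.g.
#'   `paste0("PC", 1:15)`), or `NULL` for none.
#' @return A `prs_contrast` object; see [tidy()] and [glance()].
#' @export
compare_prs_groups <- function(data, score = "std_score", group = "group",
                               pcs = NULL) {
  for (col in c(score, group, pcs)) {
    if (!col %in% names(data)) abort(sprintf("Column '%s' not found.", col))
  }
  g <- as.numeric(data[[group]])
  if (!all(g %in% c(0, 1))) abort("`group` must be coded 0/1.")
  if (sum(g == 0) == 0 || sum(g == 1) == 0) {
    abort("Both groups must be non-empty.")
  }
  rhs <- paste(c(sprintf("`%s`", group), sprintf("`%s`", pcs)), collapse = " + ")
  fml <- stats::as.formula(sprintf("`%s` ~ %s", score, rhs))
  df <- data
  df[[group]] <- g
  check_full_rank(stats::model.matrix(fml, data = df))
  fit <- lm(fml, data = df)
  new_prs_contrast(fit, term = group, n0 = sum(g == 0), n1 = sum(g == 1),
                   k_cov = length(pcs), label = group)
}

#' Male-versus-female proband polygenic comparison controlling for ID
#'
#' Because comorbid intellectual disability is more frequent in female
#' probands and is associated with lower polygenic load, the male-female
#' comparison adjusts for ID status:
#' `score ~ sex + ID + PC1 + ... + PCk`, with sex coded female = 1, male = 0.
#' The reported difference is the sex coefficient (female minus male).
#'
#' @param data Data frame of probands.
#' @param score Name of the score column.
#' @param sex Name of the sex column (`"male"` / `"female"`).
#' @param id_status Name of the logical/0-1 ID indicator column.
#' @param pcs Covariate column names or `NULL`.
#' @return A `prs_contrast` object.
#' @export
proband_sex_comparison <- function(data, score = "std_score", sex = "sex",
                                   id_status = "dx_id", pcs = NULL) {
  for (col in c(score, sex, id_status, pcs)) {
    if (!col %in% names(data)) abort(sprintf("Column '%s' not found.", col))
  }
  if (anyNA(data[[sex]]) || anyNA(data[[id_status]])) {
    abort("Every proband needs sex and ID status.")
  }
  df <- data
  df[[".female"]] <- as.numeric(df[[sex]] == "female")
  if (all(df$.female == 0) || all(df$.female == 1)) {
    abort("Both sexes must be present among probands.")
  }
  df[[".id"]] <- as.numeric(df[[id_status]])
  rhs <- paste(c(".female", ".id", sprintf("`%s`", pcs)), collapse = " + ")
  fml <- stats::as.formula(sprintf("`%s` ~ %s", score, rhs))
  check_full_rank(stats::model.matrix(fml, data = df))
  fit <- lm(fml, data = df)
  new_prs_contrast(fit, term = ".female",
                   n0 = sum(df$.female == 0), n1 = sum(df$.female == 1),
                   k_cov = length(pcs) + 1L, label = "female_vs_male")
}

#' @export
print.prs_contrast <- function(x, ...) {
  cat(sprintf(
    "<prs_contrast> %s: difference %.4g (SE %.3g), t = %.3f, p = %.3g (n = %d vs %d, %d covariates)\n",
    x$label, x$difference, x$standard_error, x$t, x$p_value,
    x$n_group0, x$n_group1, x$n_covariates
  ))
  invisible(x)
}
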