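#' Mid-parent polygenic score
#'
#' The Mendelian expectation for an offspring's additive genetic value: the
#' arithmetic mean of the mother's and father's scores.
#'
#' @param mother,father Numeric vectors of parental scores (no missing
#'   values: a trio with a missing parent is incomplete).
#' @return Numeric vector of mid-parent values.
#' @examples
#' midparent(c(0, -0.3), c(2, 0.5))
#' @export
midparent <- function(mother, father) {
  if (anyNA(mother) || anyNA(father) ||
      any(!is.finite(mother)) || any(!is.finite(father))) {
    abort("Incomplete trio: both parental scores must be present and finite.")
  }
  (mother + father) / 2
}

#' Standardized polygenic transmission deviations
#'
#' For each trio, the deviation of the child's score from the mid-parent
#' expectation, scaled to mid-parent standard deviations:
#' `(child - midparent) / scale_sd`. By convention the scale is the SD of the
#' mid-parent distribution over all families entering the analysis (computed
#' before any stratification); a fixed constant can be supplied instead to
#' mirror a published scaling.
#'
#' @param trios Tibble with columns `child_score`, `mother_score`,
#'   `father_score` (one row per child).
#' @param scale_sd `"from-data"` (default) or a positive number.
#' @return `trios` with added columns `midparent` and `deviation`; the scale
#'   used is attached as attribute `"scale_sd"`.
#' @export
ptdt_deviations <- function(trios, scale_sd = "from-data") {
  need <- c("child_score", "mother_score", "father_score")
  if (!all(need %in% names(trios))) {
    abort("`trios` needs columns child_score, mother_score, father_score.")
  }
  mid <- midparent(trios$mother_score, trios$father_score)
  if (identical(scale_sd, "from-data")) {
    scale_sd <- sd(mid)
  }
  if (!is.numeric(scale_sd) || length(scale_sd) != 1L ||
      !is.finite(scale_sd) || scale_sd <= 0) {
    abort("`scale_sd` must be a positive number (or 'from-data').")
  }
  out <- dplyr::mutate(trios,
                       midparent = mid,
                       deviation = (.data$child_score - mid) / scale_sd)
  attr(out, "scale_sd") <- scale_sd
  out
}

#' One-sample polygenic transmission disequilibrium test
#'
#' Tests whether the mean standardized transmission deviation differs from
#' the Mendelian null of zero: `t = mean / (sd / sqrt(n))` with `n - 1`
#' degrees of freedom, two-sided. A positive mean indicates polygenic
#' over-inheritance in the ascertained children.
#'
#' @param deviations Numeric vector of standardized deviations (n >= 2,
#'   nonzero variance), or a tibble from [ptdt_deviations()].
#' @param stratum Optional stratum label carried into the result.
#' @return An object of class `ptdt_test`; see [tidy()] and [glance()].
#' @examples
#' ptdt_test(c(0.1, 0.3, 0.2, 0.0, 0.4))
#' @export
ptdt_test <- function(deviations, stratum = NA_character_) {
  if (is.data.frame(deviations)) deviations <- deviations$deviation
  n <- length(deviations)
  if (n < 2) abort("pTDT needs at least 2 trios.")
  s <- sd(deviations)
  if (!is.finite(s) || s == 0) {
    abort("Degenerate input: deviations have zero variance.")
  }
  m <- mean(deviations)
  se <- s / sqrt(n)
  tt <- m / se
  structure(
    list(
      stratum = stratum,
      n = n,
      mean_deviation = m,
      standard_error = se,
      t = tt,
      df = n - 1,
      p_value = 2 * pt(-abs(tt), df = n - 1)
    ),
    class = "ptdt_test"
  )
}

#' Two-sample comparison of pTDT deviation distributions
#'
#' Compares the mean standardized deviation between two strata with a
#' two-sided two-sample t test; Welch's unequal-variance form by default
#' (set `var_equal = TRUE` for the pooled-variance test).
#'
#' @param dev_a,dev_b Numeric vectors of standardized deviations (each
#'   n >= 2).
#' @param labels Optional character vector of length 2 naming the strata.
#' @param var_equal Assume equal variances (pooled test)?
#' @return An object of class `ptdt_comparison` with the difference in mean
#'   deviation (a minus b), t, df and two-sided p.
#' @export
ptdt_compare <- function(dev_a, dev_b, labels = c("a", "b"), var_equal = FALSE) {
  if (is.data.frame(dev_a)) dev_a <- dev_a$deviation
  if (is.data.frame(dev_b)) dev_b <- dev_b$deviation
  if (length(dev_a) < 2 || length(dev_b) < 2) {
    abort("Both strata need at least 2 trios.")
  }
  va <- var(dev_a)
  vb <- var(dev_b)
  if ((!is.finite(va) || va == 0) && (!is.finite(vb) || vb == 0)) {
    abort("Degenerate input: both strata have zero variance.")
  }
  na <- length(dev_a)
  nb <- length(dev_b)
  diff <- mean(dev_a) - mean(dev_b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tt <- diff / se
  structure(
    list(
      stratum_a = labels[1],
      stratum_b = labels[2],
      n_a = na,
      n_b = nb,
      difference = diff,
      standard_error = se,
      t = tt,
      df = df,
      p_value = 2 * pt(-abs(tt), df = df),
      var_equal = var_equal
    ),
    class = "ptdt_comparison"
  )
}

#' @export
print.ptdt_test <- function(x, ...) {
  cat(sprintf(
    "<ptdt_test>%s n = %d: mean deviation %.4g (SE %.3g), t(%d) = %.3f, p = %.3g\n",
    if (is.na(x$stratum)) "" else paste0(" [", x$stratum, "]"),
    x$n, x$mean_deviation, x$standard_error, x$df, x$t, x$p_value
  ))
  invisible(x)
}

#' @export
print.ptdt_comparison <- function(x, ...) {
  cat(sprintf(
    "<ptdt_comparison> %s vs %s: difference %.4g, t(%.1f) = %.3f, p = %.3g (%s)\n",
    x$stratum_a, x$stratum_b, x$difference, x$df, x$t, x$p_value,
    if (x$var_equal) "pooled" else "Welch"
  ))
  invisible(x)
}

#' Trio score table from a simulated family cohort
#'
#' Joins each child to their parents' scores, producing the one-row-per-child
#' table consumed by the pTDT functions. For trio cohorts the proband and
#' designated-sibling flags are carried along; the sibling designee is the
#' oldest unaffected child of each family.
#'
#' @param cohort A cohort tibble whose founders are present.
#' @param score Column used as the polygenic score: `"pgs_asd"` (default,
#'   the error-free polygenic component on the liability scale) or
#'   `"pgs_obs"` (the noisy score proxy).
#' @return A tibble with columns `fid`, `iid`, `child_score`, `mother_score`,
#'   `father_score`, `sex`, `affected`, `dnv`, and, when available,
#'   `proband` and `designated_sibling`.
#' @export
cohort_trios <- function(cohort, score = c("pgs_asd", "pgs_obs")) {
  score <- match.arg(score)
  kids <- cohort[cohort$role == "offspring", ]
  frow <- match(kids$father_iid, cohort$iid)
  mrow <- match(kids$mother_iid, cohort$iid)
  if (anyNA(frow) || anyNA(mrow)) {
    abort("Cohort is missing parents for some offspring.")
  }
  out <- tibble::tibble(
    fid = kids$fid,
    iid = kids$iid,
    child_score = kids[[score]],
    mother_score = cohort[[score]][mrow],
    father_score = cohort[[score]][frow],
    sex = kids$sex,
    affected = kids$dx_asd,
    dnv = kids$dnv
  )
  if ("proband" %in% names(kids)) out$proband <- kids$proband
  if ("designated_sibling" %in% names(kids)) {
    out$designated_sibling <- kids$designated_sibling
  }
  out
}

ptdt_stratum_labels <- list(
  affected_by_sex_dnv = function(trios) {
    dplyr::case_when(
      trios$affected & trios$sex == "male" & trios$dnv ~ "male case, dnv",
      trios$affected & trios$sex == "male" & !trios$dnv ~ "male case, no dnv",
      trios$affected & trios$sex == "female" & trios$dnv ~ "female case, dnv",
      trios$affected & trios$sex == "female" & !trios$dnv ~ "female case, no dnv",
      .default = NA_character_
    )
  },
  unaffected_by_sex = function(trios) {
    keep <- if ("designated_sibling" %in% names(trios)) {
      trios$designated_sibling
    } else {
      !trios$affected
    }
    dplyr::case_when(
      keep & trios$sex == "male" ~ "male unaffected sibling",
      keep & trios$sex == "female" ~ "female unaffected sibling",
      .default = NA_character_
    )
  }
)

#' Run the pTDT over a set of strata
#'
#' Computes standardized deviations for all trios (the scaling SD is taken
#' from the mid-parent distribution of the full table, before any
#' stratification, unless a constant is given) and performs a one-sample
#' pTDT per stratum. Available stratifications: `"affected_by_sex_dnv"`
#' (affected probands split by sex and high-impact de novo carrier status;
#' restricted to probands when a `proband` column is present) and
#' `"unaffected_by_sex"` (designated unaffected siblings by sex). Pairwise
#' stratum comparisons can be requested and are attached as the
#' `"comparisons"` attribute (see [ptdt_comparisons()]).
#'
#' @param trios Trio table from [cohort_trios()] or [read_trio_table()].
#' @param strata Character vector of stratification names.
#' @param scale_sd `"from-data"` or a positive constant.
#' @param comparisons Optional list of 2-element character vectors naming
#'   stratum pairs to compare with [ptdt_compare()].
#' @return Tibble with one row per non-empty stratum: n, mean deviation, SE,
#'   t, df and p. Empty strata are omitted with a warning.
#' @export
run_ptdt <- function(trios,
                     strata = c("affected_by_sex_dnv", "unaffected_by_sex"),
                     scale_sd = "from-data",
                     comparisons = NULL) {
  unknown <- setdiff(strata, names(ptdt_stratum_labels))
  if (length(unknown)) {
    abort(paste0("Unknown strata: ", paste(unknown, collapse = ", ")))
  }
  dev <- ptdt_deviations(trios, scale_sd = scale_sd)
  if ("proband" %in% names(dev)) {
    dev_aff <- dev[dev$proband, ]
  } else {
    dev_aff <- dev[dev$affected, ]
  }

  labelled <- purrr::map(strata, function(sname) {
    base <- if (sname == "affected_by_sex_dnv") dev_aff else dev
    lab <- ptdt_stratum_labels[[sname]](base)
    tibble::tibble(label = lab, deviation = base$deviation)[!is.na(lab), ]
  }) |> dplyr::bind_rows()

  expected <- unlist(purrr::map(strata, function(sname) {
    switch(sname,
      affected_by_sex_dnv = c("male case, dnv", "male case, no dnv",
                              "female case, dnv", "female case, no dnv"),
      unaffected_by_sex = c("male unaffected sibling", "female unaffected sibling")
    )
  }))
  by_stratum <- split(labelled$deviation, labelled$label)
  for (lab in setdiff(expected, names(by_stratum))) {
    warn(sprintf("Stratum '%s' is empty; omitted.", lab))
  }
  results <- purrr::imap(by_stratum, function(d, lab) {
    if (length(d) < 2) {
      warn(sprintf("Stratum '%s' has fewer than 2 trios; omitted.", lab))
      return(NULL)
    }
    tidy(ptdt_test(d, stratum = lab))
  }) |> dplyr::bind_rows()

  if (!is.null(comparisons)) {
    cmp <- purrr::map(comparisons, function(pair) {
      if (!all(pair %in% names(by_stratum))) {
        abort(sprintf("Unknown stratum label in comparison: %s",
                      paste(pair, collapse = " vs ")))
      }
      tidy(ptdt_compare(by_stratum[[pair[1]]], by_stratum[[pair[2]]],
                        labels = pair))
    }) |> dplyr::bind_rows()
    attr(results, "comparisons") <- cmp
  }
  attr(results, "scale_sd") <- attr(dev, "scale_sd")
  results
}

#' Pairwise comparisons attached to a [run_ptdt()] result
#'
#' @param results Tibble returned by [run_ptdt()].
#' @return The comparisons tibble, or `NULL` when none were requested.
#' @export
ptdt_comparisons <- function(results) attr(results, "comparisons")
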