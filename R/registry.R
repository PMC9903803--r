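## outcome matching: the three mutually exclusive groups, plus the pooled
## "ASD" (any ASD) and "ID" (any ID) outcomes used in the sibling-sex analysis
outcome_status <- function(group, outcome) {
  switch(outcome,
    ASDnoID = group == "ASDnoID",
    ASDandID = group == "ASDandID",
    IDnoASD = group == "IDnoASD",
    ASD = group %in% c("ASDnoID", "ASDandID"),
    ID = group %in% c("ASDandID", "IDnoASD"),
    abort(sprintf("Unknown outcome '%s'.", outcome))
  )
}

match_group <- function(group, target) {
  if (target == "any") rep(TRUE, length(group)) else outcome_status(group, target)
}

match_sex <- function(sex, target) {
  if (target == "any") rep(TRUE, length(sex)) else sex == target
}

#' Select one index case per family
#'
#' Within every family, children matching the index criteria (sex and
#' diagnosis group) are identified and one is chosen uniformly at random.
#' Families with no eligible child are dropped.
#'
#' @param cohort A cohort tibble (see [simulate_registry()]).
#' @param sex `"male"`, `"female"` or `"any"`.
#' @param group One of `"ASDnoID"`, `"ASDandID"`, `"IDnoASD"`, or `"ASD"` for
#'   any ASD diagnosis regardless of comorbid ID.
#' @param seed Optional integer seed.
#' @return A tibble with columns `fid` and `iid`, one row per family that
#'   contributed an index case.
#' @export
select_index_cases <- function(cohort, sex = "any", group = "ASD", seed = NULL) {
  sex <- match.arg(sex, c("any", "male", "female"))
  kids <- cohort$role == "offspring" &
    match_sex(cohort$sex, sex) &
    match_group(cohort$group, group)
  elig <- which(kids)
  with_stage_seed(seed, {
    take <- elig[pick_one_per_group(cohort$fid[elig])]
    tibble::tibble(fid = cohort$fid[take], iid = cohort$iid[take])
  })
}

#' Select one sibling per index case
#'
#' Picks, uniformly at random and independently of diagnosis, one full
#' sibling of each index case born within the analysis window. Families whose
#' siblings all fall outside the window contribute nothing.
#'
#' @param cohort A cohort tibble.
#' @param index Index-case tibble from [select_index_cases()] (columns `fid`,
#'   `iid`).
#' @param birth_year_window Inclusive birth-year range for eligible siblings.
#' @param seed Optional integer seed.
#' @return A tibble with columns `fid`, `index_iid`, `sibling_iid`.
#' @export
select_siblings <- function(cohort, index,
                            birth_year_window = c(1981L, 2005L),
                            seed = NULL) {
  if (!all(index$iid %in% cohort$iid)) {
    abort("Index ids not found in the cohort; inconsistent selection input.")
  }
  idx_fid <- cohort$fid[match(index$iid, cohort$iid)]
  if (!isTRUE(all(idx_fid == index$fid))) {
    abort("Index family ids disagree with the cohort pedigree.")
  }
  sibs <- which(
    cohort$role == "offspring" &
      cohort$fid %in% index$fid &
      !(cohort$iid %in% index$iid) &
      !is.na(cohort$birth_year) &
      cohort$birth_year >= birth_year_window[1] &
      cohort$birth_year <= birth_year_window[2]
  )
  with_stage_seed(seed, {
    take <- sibs[pick_one_per_group(cohort$fid[sibs])]
    tibble::tibble(
      fid = cohort$fid[take],
      index_iid = index$iid[match(cohort$fid[take], index$fid)],
      sibling_iid = cohort$iid[take]
    )
  })
}

#' Match population controls to siblings on sex and birth year
#'
#' Each sibling receives `ratio` controls of identical sex and birth year,
#' sampled without replacement from the cohort's offspring after removing the
#' exclusion set. A control is never reused across siblings within one call.
#'
#' @param cohort A cohort tibble.
#' @param siblings Tibble from [select_siblings()], or a vector of sibling
#'   ids.
#' @param ratio Controls per sibling (the registry design uses 2).
#' @param exclude Ids to remove from the control pool before matching
#'   (typically all siblings of index cases).
#' @param seed Optional integer seed.
#' @return A tibble with columns `sibling_iid`, `control_iid`.
#' @export
match_controls <- function(cohort, siblings, ratio = 2, exclude = integer(),
                           seed = NULL) {
  if (is.data.frame(siblings)) siblings <- siblings$sibling_iid
  if (!is.numeric(ratio) || ratio < 1) abort("`ratio` must be at least 1.")
  ratio <- as.integer(ratio)
  sib_rows <- match(siblings, cohort$iid)
  if (anyNA(sib_rows)) abort("Some sibling ids are not in the cohort.")
  pool_ok <- cohort$role == "offspring" &
    !is.na(cohort$birth_year) &
    !(cohort$iid %in% exclude) &
    !(cohort$iid %in% siblings)

  sib_sex <- cohort$sex[sib_rows]
  sib_year <- cohort$birth_year[sib_rows]
  strata <- paste(sib_sex, sib_year, sep = "/")

  with_stage_seed(seed, {
    out <- vector("list", length(unique(strata)))
    names(out) <- unique(strata)
    for (st in unique(strata)) {
      in_st <- strata == st
      sx <- sib_sex[in_st][1]
      yr <- sib_year[in_st][1]
      pool <- cohort$iid[pool_ok & cohort$sex == sx & cohort$birth_year == yr]
      need <- ratio * sum(in_st)
      if (length(pool) < need) {
        abort(sprintf(
          "Matching failure in stratum %s: %d eligible controls for %d needed.",
          st, length(pool), need
        ))
      }
      picked <- sample(pool, need)
      out[[st]] <- tibble::tibble(
        sibling_iid = rep(siblings[in_st], each = ratio),
        control_iid = picked
      )
    }
    dplyr::bind_rows(out)
  })
}

#' Sibling-recurrence odds ratio from a matched case-control design
#'
#' Fits the logistic regression of diagnosis status on an indicator of being
#' a sibling of an index case (versus a matched population control), exactly
#' the model `status ~ sib_of_case` with no further covariates. The odds
#' ratio is the exponentiated coefficient with a 95% Wald interval; with no
#' covariates it equals the 2x2 cross-product ratio. When any cell of the
#' 2x2 table is zero the estimate is reported from the Haldane-Anscombe
#' correction (+0.5 to every cell) and flagged as degenerate rather than
#' returned silently.
#'
#' @param cohort A cohort tibble.
#' @param siblings,controls Disjoint vectors of individual ids.
#' @param outcome Outcome class: `"ASDnoID"`, `"ASDandID"`, `"IDnoASD"`,
#'   `"ASD"` or `"ID"`.
#' @return An object of class `recurrence_fit`; see [tidy()] and [glance()]
#'   methods.
#' @export
fit_recurrence <- function(cohort, siblings, controls, outcome) {
  if (is.data.frame(siblings)) siblings <- siblings$sibling_iid
  if (is.data.frame(controls)) controls <- controls$control_iid
  if (length(intersect(siblings, controls))) {
    abort("Siblings and controls must be disjoint.")
  }
  grp <- cohort$group[match(c(siblings, controls), cohort$iid)]
  if (anyNA(grp)) abort("Some ids are missing from the cohort.")
  status <- outcome_status(grp, outcome)
  is_sib <- c(rep(TRUE, length(siblings)), rep(FALSE, length(controls)))

  a <- sum(status & is_sib)
  b <- sum(!status & is_sib)
  cc <- sum(status & !is_sib)
  d <- sum(!status & !is_sib)
  counts <- c(sib_affected = a, sib_unaffected = b,
              ctrl_affected = cc, ctrl_unaffected = d)

  degenerate <- any(counts == 0)
  if (degenerate) {
    ## Haldane-Anscombe correction, for reporting only
    est <- log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5)))
    se <- sqrt(1 / (a + 0.5) + 1 / (b + 0.5) + 1 / (cc + 0.5) + 1 / (d + 0.5))
  } else {
    fit <- glm(cbind(c(a, cc), c(b, d)) ~ c(1, 0), family = binomial(),
               control = list(epsilon = 1e-10, maxit = 25))
    est <- coef(fit)[[2]]
    se <- sqrt(vcov(fit)[2, 2])
  }
  z <- est / se
  structure(
    list(
      outcome = outcome,
      odds_ratio = exp(est),
      ci_low = exp(est - 1.96 * se),
      ci_high = exp(est + 1.96 * se),
      log_or = est,
      se_log_or = se,
      p_value = 2 * pnorm(-abs(z)),
      counts = counts,
      n_siblings = length(siblings),
      n_controls = length(controls),
      degenerate = degenerate
    ),
    class = "recurrence_fit"
  )
}

#' Build a recurrence result from a published OR and confidence interval
#'
#' Reconstructs the log-odds-ratio standard error from a printed 95%
#' interval, `SE = (log(hi) - log(lo)) / (2 * 1.96)`, so published odds
#' ratios can be compared with [compare_or()] when the underlying counts are
#' unavailable.
#'
#' @param odds_ratio,ci_low,ci_high Printed OR and 95% CI bounds.
#' @param outcome Optional outcome label.
#' @return A `recurrence_fit` object without counts.
#' @examples
#' or_from_ci(7.19, 5.09, 10.09)
#' @export
or_from_ci <- function(odds_ratio, ci_low, ci_high, outcome = NA_character_) {
  if (!(ci_low <= odds_ratio && odds_ratio <= ci_high) || ci_low <= 0) {
    abort("Need 0 < ci_low <= odds_ratio <= ci_high.")
  }
  se <- (log(ci_high) - log(ci_low)) / (2 * 1.96)
  z <- log(odds_ratio) / se
  structure(
    list(
      outcome = outcome,
      odds_ratio = odds_ratio,
      ci_low = ci_low,
      ci_high = ci_high,
      log_or = log(odds_ratio),
      se_log_or = se,
      p_value = 2 * pnorm(-abs(z)),
      counts = c(sib_affected = NA_integer_, sib_unaffected = NA_integer_,
                 ctrl_affected = NA_integer_, ctrl_unaffected = NA_integer_),
      n_siblings = NA_integer_,
      n_controls = NA_integer_,
      degenerate = FALSE
    ),
    class = "recurrence_fit"
  )
}

#' Wald test for the difference of two odds ratios
#'
#' Tests whether two independently estimated odds ratios differ:
#' `z = (log OR_a - log OR_b) / sqrt(SE_a^2 + SE_b^2)` with a two-sided
#' normal p value. Standard errors come from the fitted models (or are
#' reconstructed from printed intervals via [or_from_ci()]).
#'
#' @param a,b `recurrence_fit` objects.
#' @return An object of class `or_comparison`.
#' @examples
#' compare_or(or_from_ci(7.19, 5.09, 10.09), or_from_ci(3.76, 3.10, 4.54))
#' @export
compare_or <- function(a, b) {
  stopifnot(inherits(a, "recurrence_fit"), inherits(b, "recurrence_fit"))
  if (isTRUE(a$degenerate) || isTRUE(b$degenerate)) {
    abort("Cannot compare degenerate odds ratios.")
  }
  diff <- a$log_or - b$log_or
  se <- sqrt(a$se_log_or^2 + b$se_log_or^2)
  z <- diff / se
  structure(
    list(
      log_or_difference = diff,
      standard_error = se,
      z = z,
      p_value = 2 * pnorm(-abs(z)),
      or_a = a$odds_ratio,
      or_b = b$odds_ratio
    ),
    class = "or_comparison"
  )
}

#' @export
print.recurrence_fit <- function(x, ...) {
  cat(sprintf(
    "<recurrence_fit> outcome %s: OR %.3g (95%% CI %.3g-%.3g), p = %.3g%s\n",
    x$outcome, x$odds_ratio, x$ci_low, x$ci_high, x$p_value,
    if (x$degenerate) " [degenerate: Haldane-Anscombe]" else ""
  ))
  invisible(x)
}

#' @export
print.or_comparison <- function(x, ...) {
  cat(sprintf(
    "<or_comparison> OR %.3g vs %.3g: z = %.3f, p = %.3g\n",
    x$or_a, x$or_b, x$z, x$p_value
  ))
  invisible(x)
}

recurrence_row <- function(fit, index_sex = NA, index_group = NA) {
  tibble::tibble(
    index_sex = index_sex,
    index_group = index_group,
    outcome = fit$outcome,
    n_sib = fit$n_siblings,
    n_ctrl = fit$n_controls,
    sib_affected = fit$counts[["sib_affected"]],
    ctrl_affected = fit$counts[["ctrl_affected"]],
    odds_ratio = fit$odds_ratio,
    ci_low = fit$ci_low,
    ci_high = fit$ci_high,
    se_log_or = fit$se_log_or,
    p_value = fit$p_value,
    degenerate = fit$degenerate
  )
}

empty_recurrence_table <- function() {
  tibble::tibble(
    index_sex = character(), index_group = character(), outcome = character(),
    n_sib = integer(), n_ctrl = integer(), sib_affected = integer(),
    ctrl_affected = integer(), odds_ratio = double(), ci_low = double(),
    ci_high = double(), se_log_or = double(), p_value = double(),
    degenerate = logical()
  )
}

#' Run the full sibling-recurrence analysis
#'
#' For every index-case cell (sex by diagnosis group), selects one index case
#' per family, one sibling per index case, `ratio` age- and sex-matched
#' controls per sibling (excluding all siblings of index cases from the
#' control pool), and fits the sibling-versus-control logistic regression for
#' each requested outcome.
#'
#' @param cohort A cohort tibble.
#' @param criteria Tibble of index-case cells with columns `sex` and `group`.
#'   Defaults to the six cells: male/female crossed with ASDnoID, ASDandID
#'   and IDnoASD.
#' @param outcomes Outcome classes to fit per cell.
#' @param ratio Controls per sibling.
#' @param birth_year_window Sibling birth-year window.
#' @param seed Optional integer root seed; each cell uses its own substream.
#' @return A tidy tibble with one row per cell and outcome: counts, odds
#'   ratio, Wald CI, p value and a degeneracy flag. Use
#'   [sex_or_comparisons()] for the gated female-versus-male Wald tests.
#' @export
run_recurrence_analysis <- function(cohort,
                                    criteria = tidyr::crossing(
                                      sex = c("female", "male"),
                                      group = c("ASDnoID", "ASDandID", "IDnoASD")
                                    ),
                                    outcomes = c("ASDnoID", "ASDandID", "IDnoASD"),
                                    ratio = 2,
                                    birth_year_window = c(1981L, 2005L),
                                    seed = NULL) {
  if (nrow(criteria) == 0L) return(empty_recurrence_table())
  purrr::pmap(criteria, function(sex, group, ...) {
    cell_seed <- stage_seed(seed, paste("recurrence", sex, group))
    index <- select_index_cases(cohort, sex = sex, group = group,
                                seed = stage_seed(cell_seed, "index"))
    sibs <- select_siblings(cohort, index, birth_year_window,
                            seed = stage_seed(cell_seed, "sibling"))
    if (nrow(sibs) == 0L) {
      warn(sprintf("No eligible siblings for cell %s/%s; cell skipped.", sex, group))
      return(NULL)
    }
    ## exclusion: every sibling of an index case, i.e. all non-index children
    ## of index families (the paper removes them from the control pool)
    excl <- cohort$iid[cohort$role == "offspring" &
                         cohort$fid %in% index$fid &
                         !(cohort$iid %in% index$iid)]
    ctrl <- match_controls(cohort, sibs, ratio = ratio, exclude = excl,
                           seed = stage_seed(cell_seed, "controls"))
    purrr::map(outcomes, function(oc) {
      recurrence_row(
        fit_recurrence(cohort, sibs$sibling_iid, ctrl$control_iid, oc),
        index_sex = sex, index_group = group
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Female-versus-male Wald comparisons of recurrence odds ratios
#'
#' Compares, within each diagnosis group and outcome, the odds ratio for
#' siblings of female index cases against that for siblings of male index
#' cases. Following the analysis rule of the registry design, a comparison
#' is only reported when both odds ratios are individually significant (both
#' 95% intervals exclude 1) and neither is degenerate.
#'
#' @param results Result tibble from [run_recurrence_analysis()].
#' @return A tibble with one row per gated comparison: both ORs, the log-OR
#'   difference, its standard error, z and the two-sided p value.
#' @export
sex_or_comparisons <- function(results) {
  out <- results |>
    dplyr::filter(!.data$degenerate, is.finite(.data$odds_ratio)) |>
    dplyr::group_by(.data$index_group, .data$outcome) |>
    dplyr::filter(dplyr::n_distinct(.data$index_sex) == 2) |>
    dplyr::summarise(
      or_female = .data$odds_ratio[.data$index_sex == "female"],
      or_male = .data$odds_ratio[.data$index_sex == "male"],
      both_significant = all(.data$ci_low > 1 | .data$ci_high < 1),
      standard_error = sqrt(sum(.data$se_log_or^2)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$both_significant) |>
    dplyr::select(-"both_significant") |>
    dplyr::mutate(
      log_or_difference = log(.data$or_female) - log(.data$or_male),
      z = .data$log_or_difference / .data$standard_error,
      p_value = 2 * pnorm(-abs(.data$z))
    )
  out
}

#' Sibling recurrence stratified by sibling sex
#'
#' Selects one index case per family among all ASD cases (any sex, with or
#' without comorbid ID), one sibling each, then estimates the recurrence odds
#' ratio separately for male and female siblings, each against their own
#' sex-matched controls, so each stratum is compared with a sex-specific
#' general-population rate.
#'
#' @inheritParams run_recurrence_analysis
#' @param outcome Outcome class for the siblings (default any ASD).
#' @return A tidy tibble with one row per sibling-sex stratum. Strata with no
#'   siblings are reported with `n_sib = 0` and flagged degenerate.
#' @export
recurrence_by_sibling_sex <- function(cohort, ratio = 2, outcome = "ASD",
                                      birth_year_window = c(1981L, 2005L),
                                      seed = NULL) {
  index <- select_index_cases(cohort, sex = "any", group = "ASD",
                              seed = stage_seed(seed, "index"))
  sibs <- select_siblings(cohort, index, birth_year_window,
                          seed = stage_seed(seed, "sibling"))
  excl <- cohort$iid[cohort$role == "offspring" &
                       cohort$fid %in% index$fid &
                       !(cohort$iid %in% index$iid)]
  ctrl <- match_controls(cohort, sibs, ratio = ratio, exclude = excl,
                         seed = stage_seed(seed, "controls"))
  sib_sex <- cohort$sex[match(sibs$sibling_iid, cohort$iid)]
  ctrl_sex <- cohort$sex[match(ctrl$control_iid, cohort$iid)]

  purrr::map(c("male", "female"), function(sx) {
    s_ids <- sibs$sibling_iid[sib_sex == sx]
    if (length(s_ids) == 0L) {
      warn(sprintf("No %s siblings; stratum flagged.", sx))
      return(tibble::tibble(
        sibling_sex = sx, outcome = outcome, n_sib = 0L, n_ctrl = 0L,
        sib_affected = NA_integer_, ctrl_affected = NA_integer_,
        odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        se_log_or = NA_real_, p_value = NA_real_, degenerate = TRUE
      ))
    }
    c_ids <- ctrl$control_iid[ctrl$sibling_iid %in% s_ids]
    stopifnot(all(ctrl_sex[ctrl$sibling_iid %in% s_ids] == sx))
    fit <- fit_recurrence(cohort, s_ids, c_ids, outcome)
    dplyr::mutate(recurrence_row(fit), sibling_sex = sx, .before = 1) |>
      dplyr::select(-"index_sex", -"index_group")
  }) |> dplyr::bind_rows()
}
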