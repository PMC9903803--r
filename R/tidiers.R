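#' Tidy methods for fpefam result objects
#'
#' `tidy()` returns a one-row tibble of estimates; `glance()` returns a
#' one-row tibble of fit-level summaries (sample sizes, flags).
#'
#' @param x A `recurrence_fit`, `or_comparison`, `prs_contrast`,
#'   `ptdt_test` or `ptdt_comparison` object.
#' @param ... Unused.
#' @return A tibble.
#' @name fpefam-tidiers
NULL

#' @rdname fpefam-tidiers
#' @method tidy recurrence_fit
#' @export
tidy.recurrence_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome,
    odds_ratio = x$odds_ratio,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    se_log_or = x$se_log_or,
    p_value = x$p_value,
    degenerate = x$degenerate
  )
}

#' @rdname fpefam-tidiers
#' @method glance recurrence_fit
#' @export
glance.recurrence_fit <- function(x, ...) {
  tibble::tibble(
    n_sib = x$n_siblings,
    n_ctrl = x$n_controls,
    sib_affected = x$counts[["sib_affected"]],
    sib_unaffected = x$counts[["sib_unaffected"]],
    ctrl_affected = x$counts[["ctrl_affected"]],
    ctrl_unaffected = x$counts[["ctrl_unaffected"]],
    degenerate = x$degenerate
  )
}

#' @rdname fpefam-tidiers
#' @method tidy or_comparison
#' @export
tidy.or_comparison <- function(x, ...) {
  tibble::tibble(
    or_a = x$or_a,
    or_b = x$or_b,
    log_or_difference = x$log_or_difference,
    standard_error = x$standard_error,
    z = x$z,
    p_value = x$p_value
  )
}

#' @rdname fpefam-tidiers
#' @method tidy prs_contrast
#' @export
tidy.prs_contrast <- function(x, ...) {
  tibble::tibble(
    contrast = x$label,
    difference = x$difference,
    standard_error = x$standard_error,
    t = x$t,
    p_value = x$p_value
  )
}

#' @rdname fpefam-tidiers
#' @method glance prs_contrast
#' @export
glance.prs_contrast <- function(x, ...) {
  tibble::tibble(
    n_group0 = x$n_group0,
    n_group1 = x$n_group1,
    n_covariates = x$n_covariates
  )
}

#' @rdname fpefam-tidiers
#' @method tidy ptdt_test
#' @export
tidy.ptdt_test <- function(x, ...) {
  tibble::tibble(
    stratum = x$stratum,
    n = x$n,
    mean_deviation = x$mean_deviation,
    standard_error = x$standard_error,
    t = x$t,
    df = x$df,
    p_value = x$p_value
  )
}

#' @rdname fpefam-tidiers
#' @method glance ptdt_test
#' @export
glance.ptdt_test <- function(x, ...) {
  tibble::tibble(n = x$n, df = x$df)
}

#' @rdname fpefam-tidiers
#' @method tidy ptdt_comparison
#' @export
tidy.ptdt_comparison <- function(x, ...) {
  tibble::tibble(
    stratum_a = x$stratum_a,
    stratum_b = x$stratum_b,
    n_a = x$n_a,
    n_b = x$n_b,
    difference = x$difference,
    standard_error = x$standard_error,
    t = x$t,
    df = x$df,
    p_value = x$p_value
  )
}
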