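#' Convert sex-specific prevalences to liability thresholds
#'
#' Under the liability threshold model, an individual is diagnosed when a
#' standard-normal latent liability exceeds a threshold. The threshold
#' implied by a population prevalence \eqn{K} is \eqn{T = \Phi^{-1}(1 - K)}.
#' A lower prevalence in females than in males therefore encodes the female
#' protective effect as a higher female threshold.
#'
#' @param prevalence Named numeric vector of prevalences in (0, 1), e.g.
#'   `c(male = 0.02, female = 0.0055)`. Names are preserved.
#' @return Named numeric vector of thresholds in liability SD units.
#' @examples
#' calibrate_thresholds(c(male = 0.02, female = 0.0055))
#' @export
calibrate_thresholds <- function(prevalence) {
  if (!is.numeric(prevalence) || length(prevalence) == 0L) {
    abort("`prevalence` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(prevalence)) || any(prevalence <= 0) || any(prevalence >= 1)) {
    abort("All prevalences must lie strictly between 0 and 1.")
  }
  qnorm(1 - prevalence)
}

#' Parameters of the liability-threshold family model
#'
#' Bundles the generative parameters shared by [simulate_registry()] and
#' [simulate_trio_cohort()]. Liability for each phenotype decomposes as a
#' common polygenic component (variance `h2_common`), an independent residual
#' (variance `1 - h2_common`), and, in offspring only, an additive shift of
#' `dnv_effect` for carriers of a high-impact de novo variant. Founder
#' liability is standard normal; diagnosis requires liability above the
#' sex-specific threshold implied by `prevalence`.
#'
#' @param h2_common Fraction of founder liability variance attributable to the
#'   common polygenic component, in `[0, 1]`. The default 0.85 anchors on
#'   twin-study additive heritability of ASD, since this single component
#'   stands in for all inherited liability.
#' @param dnv_rate Per-child probability of carrying a high-impact de novo
#'   variant (never transmitted; founders carry none).
#' @param dnv_effect Liability shift per high-impact de novo variant, in
#'   liability SD units, applied to both phenotypes.
#' @param rg_asd_id Correlation between the common polygenic components of the
#'   ASD and ID liabilities. Default 0: the estimated ASD-ID genetic
#'   correlation does not differ significantly from zero.
#' @param prevalence Named list with numeric elements `asd` and `id`, each a
#'   vector `c(male = , female = )` of prevalences in (0, 1). Defaults: ASD
#'   2% in males and 0.55% in females (a ~3.6:1 sex ratio), ID 1.5% / 1.0%.
#' @param score_r2 Squared correlation between the noisy observed polygenic
#'   score and the true common component. The default 0.05 emulates a
#'   weak-proxy score of the kind produced by current ASD GWAS.
#' @param birth_years Integer range (length 2) over which offspring birth
#'   years are drawn uniformly; defaults to the 1981-2005 registry window.
#' @return An object of class `liability_params`.
#' @examples
#' p <- liability_params()
#' p$thresholds$asd
#' @export
liability_params <- function(h2_common = 0.85,
                             dnv_rate = 0.01,
                             dnv_effect = 1.5,
                             rg_asd_id = 0,
                             prevalence = list(
                               asd = c(male = 0.02, female = 0.0055),
                               id = c(male = 0.015, female = 0.010)
                             ),
                             score_r2 = 0.05,
                             birth_years = c(1981L, 2005L)) {
  if (!is.numeric(h2_common) || length(h2_common) != 1L ||
      !is.finite(h2_common) || h2_common < 0 || h2_common > 1) {
    abort("`h2_common` must be a single value in [0, 1].")
  }
  if (!is.numeric(dnv_rate) || dnv_rate < 0 || dnv_rate > 1) {
    abort("`dnv_rate` must lie in [0, 1].")
  }
  if (!is.numeric(dnv_effect) || !is.finite(dnv_effect)) {
    abort("`dnv_effect` must be finite.")
  }
  if (!is.numeric(rg_asd_id) || abs(rg_asd_id) > 1) {
    abort("`rg_asd_id` must lie in [-1, 1].")
  }
  if (!is.list(prevalence) || !all(c("asd", "id") %in% names(prevalence))) {
    abort("`prevalence` must be a list with elements `asd` and `id`.")
  }
  for (ph in c("asd", "id")) {
    pv <- prevalence[[ph]]
    if (!all(c("male", "female") %in% names(pv))) {
      abort(sprintf("`prevalence$%s` needs named entries `male` and `female`.", ph))
    }
  }
  if (!is.numeric(score_r2) || score_r2 <= 0 || score_r2 > 1) {
    abort("`score_r2` must lie in (0, 1].")
  }
  birth_years <- as.integer(birth_years)
  if (length(birth_years) != 2L || birth_years[1] > birth_years[2]) {
    abort("`birth_years` must be an increasing integer range of length 2.")
  }

  thresholds <- list(
    asd = calibrate_thresholds(prevalence$asd[c("male", "female")]),
    id  = calibrate_thresholds(prevalence$id[c("male", "female")])
  )

  structure(
    list(
      h2_common = h2_common,
      dnv_rate = dnv_rate,
      dnv_effect = dnv_effect,
      rg_asd_id = rg_asd_id,
      prevalence = prevalence,
      thresholds = thresholds,
      score_r2 = score_r2,
      birth_years = birth_years
    ),
    class = "liability_params"
  )
}

#' @export
print.liability_params <- function(x, ...) {
  cat("<liability_params>\n")
  cat(sprintf("  h2_common: %.3g   dnv_rate: %.3g   dnv_effect: %.3g   rg(ASD,ID): %.3g\n",
              x$h2_common, x$dnv_rate, x$dnv_effect, x$rg_asd_id))
  cat(sprintf("  ASD prevalence: male %.4g, female %.4g (thresholds %.3f / %.3f)\n",
              x$prevalence$asd[["male"]], x$prevalence$asd[["female"]],
              x$thresholds$asd[["male"]], x$thresholds$asd[["female"]]))
  cat(sprintf("  ID  prevalence: male %.4g, female %.4g (thresholds %.3f / %.3f)\n",
              x$prevalence$id[["male"]], x$prevalence$id[["female"]],
              x$thresholds$id[["male"]], x$thresholds$id[["female"]]))
  cat(sprintf("  observed-score r2: %.3g   birth years: %d-%d\n",
              x$score_r2, x$birth_years[1], x$birth_years[2]))
  invisible(x)
}

## Variance of the observed-score noise implied by score_r2:
## cor^2(obs, g) = h2 / (h2 + v_noise) = r2  =>  v_noise = h2 (1 - r2) / r2.
score_noise_var <- function(params) {
  params$h2_common * (1 - params$score_r2) / params$score_r2
}
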