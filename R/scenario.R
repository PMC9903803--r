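#' Synthetic annotated de novo variant table for a simulated cohort
#'
#' Builds a variant table consistent with a cohort's de novo carrier flags:
#' every carrier child receives one qualifying high-impact record (a
#' protein-truncating variant in a constrained gene, a CNV hitting a
#' constrained gene, or a missense variant with MPC >= 2, chosen at random),
#' and a random subset of children receive benign records that must not
#' qualify. Useful as a fixture for the variant classification rules.
#'
#' @param cohort A cohort tibble.
#' @param benign_rate Probability that a child carries an additional benign
#'   record.
#' @param seed Optional integer seed.
#' @return A variant tibble (see [is_high_impact()]).
#' @export
simulate_variant_table <- function(cohort, benign_rate = 0.3, seed = NULL) {
  kids <- cohort[cohort$role == "offspring", ]
  with_stage_seed(seed, {
    qual <- purrr::map(kids$iid[kids$dnv], function(id) {
      cls <- sample(c("PTV", "missense", "CNV-del", "CNV-dup"), 1)
      tibble::tibble(
        iid = id,
        gene = sprintf("GENE%04d", sample.int(9999, 1)),
        class = cls,
        pli = if (cls == "PTV") runif(1, 0.901, 1) else runif(1),
        mpc = if (cls == "missense") runif(1, 2, 4) else NA_real_,
        constrained_genes_hit = if (cls %in% c("CNV-del", "CNV-dup")) {
          sample(1:3, 1)
        } else {
          NA_integer_
        },
        de_novo = TRUE
      )
    })
    benign_ids <- kids$iid[runif(nrow(kids)) < benign_rate]
    benign <- purrr::map(benign_ids, function(id) {
      cls <- sample(c("PTV", "missense", "other"), 1)
      tibble::tibble(
        iid = id,
        gene = sprintf("GENE%04d", sample.int(9999, 1)),
        class = cls,
        pli = if (cls == "PTV") runif(1, 0, 0.9) else runif(1),
        mpc = if (cls == "missense") runif(1, 0, 1.99) else NA_real_,
        constrained_genes_hit = NA_integer_,
        de_novo = sample(c(TRUE, FALSE), 1)
      )
    })
    dplyr::bind_rows(c(qual, benign))
  })
}

#' Run an end-to-end female-protective-effect scenario
#'
#' Simulates a registry population and an ascertained trio cohort under one
#' parameter set and one root seed (each stage draws from its own named
#' substream), then runs the three analysis arms: sibling recurrence with
#' gated female-versus-male Wald comparisons, the mother-versus-father
#' polygenic contrast, and the pTDT over the proband sex-by-de-novo strata
#' and the unaffected-sibling strata.
#'
#' @param params A [liability_params()] object.
#' @param n_registry_families,n_trio_families Cohort sizes. Defaults match
#'   the analysis-cell sizes of the emulated studies (about 1,700 siblings
#'   of female ASDnoID cases; about 4,800 ascertained trios).
#' @param ratio Controls per sibling in the recurrence arm.
#' @param seed Integer root seed; the run is deterministic given it.
#' @param out_dir Optional directory: result tables are written as TSV plus
#'   a `run_log.yaml` with parameters and stage seeds.
#' @return An object of class `fpe_scenario`: a list with elements
#'   `recurrence`, `or_comparisons`, `ptdt`, `ptdt_comparisons`,
#'   `parent_gap`, `summary`, `params`, `seed`.
#' @export
run_fpe_scenario <- function(params = liability_params(),
                             n_registry_families = 200000,
                             n_trio_families = 4800,
                             ratio = 2,
                             seed = 1,
                             out_dir = NULL) {
  registry <- simulate_registry(params, n_registry_families,
                                seed = stage_seed(seed, "registry"))
  recurrence <- run_recurrence_analysis(registry, ratio = ratio,
                                        birth_year_window = params$birth_years,
                                        seed = stage_seed(seed, "recurrence"))
  comparisons <- sex_or_comparisons(recurrence)

  trio <- simulate_trio_cohort(params, n_trio_families,
                               seed = stage_seed(seed, "trio"))
  founders <- trio[trio$role == "founder", ]
  founders$is_mother <- founders$sex == "female"
  parent_gap <- tidy(compare_prs_groups(founders, score = "pgs_asd",
                                        group = "is_mother"))

  trios <- cohort_trios(trio, score = "pgs_asd")
  ptdt <- run_ptdt(
    trios,
    comparisons = list(c("female case, no dnv", "male case, dnv"))
  )

  asd_cells <- dplyr::filter(recurrence,
                             .data$index_group == "ASDnoID",
                             .data$outcome == "ASDnoID")
  or_f <- asd_cells$odds_ratio[asd_cells$index_sex == "female"]
  or_m <- asd_cells$odds_ratio[asd_cells$index_sex == "male"]
  prob <- dplyr::filter(ptdt, grepl("case", .data$stratum))
  sib_m <- dplyr::filter(ptdt, .data$stratum == "male unaffected sibling")
  first_or_na <- function(x) if (length(x)) x[[1]] else NA_real_
  summary_tbl <- tibble::tibble(
    or_female_index = first_or_na(or_f),
    or_male_index = first_or_na(or_m),
    female_minus_male_log_or = first_or_na(log(or_f) - log(or_m)),
    mother_father_gap = parent_gap$difference,
    mother_father_p = parent_gap$p_value,
    proband_mean_deviation =
      sum(prob$mean_deviation * prob$n) / sum(prob$n),
    male_sibling_mean_deviation =
      if (nrow(sib_m)) sib_m$mean_deviation else NA_real_,
    ptdt_gradient_holds = ptdt_gradient_holds(ptdt)
  )

  out <- structure(
    list(
      recurrence = recurrence,
      or_comparisons = comparisons,
      ptdt = ptdt,
      ptdt_comparisons = ptdt_comparisons(ptdt),
      parent_gap = parent_gap,
      summary = summary_tbl,
      params = params,
      seed = seed
    ),
    class = "fpe_scenario"
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(recurrence, file.path(out_dir, "recurrence.tsv"))
    readr::write_tsv(comparisons, file.path(out_dir, "or_comparisons.tsv"))
    readr::write_tsv(ptdt, file.path(out_dir, "ptdt.tsv"))
    readr::write_tsv(ptdt_comparisons(ptdt) %||% tibble::tibble(),
                     file.path(out_dir, "ptdt_comparisons.tsv"))
    readr::write_tsv(parent_gap, file.path(out_dir, "parent_gap.tsv"))
    readr::write_tsv(summary_tbl, file.path(out_dir, "summary.tsv"))
    yaml::write_yaml(list(
      seed = seed,
      stage_seeds = list(
        registry = stage_seed(seed, "registry"),
        recurrence = stage_seed(seed, "recurrence"),
        trio = stage_seed(seed, "trio")
      ),
      n_registry_families = n_registry_families,
      n_trio_families = n_trio_families,
      ratio = ratio,
      params = yaml::yaml.load(yaml::as.yaml(unclass(params)))
    ), file.path(out_dir, "run_log.yaml"))
  }
  out
}

## The liability-space ordering implied by the FPE plus de novo shocks:
## male carriers over-inherit least, female non-carriers most.
ptdt_gradient_holds <- function(ptdt) {
  labs <- c("male case, dnv", "male case, no dnv",
            "female case, dnv", "female case, no dnv")
  if (!all(labs %in% ptdt$stratum)) return(NA)
  m <- setNames(ptdt$mean_deviation[match(labs, ptdt$stratum)], labs)
  m[["male case, dnv"]] == min(m) && m[["female case, no dnv"]] == max(m)
}

#' @export
print.fpe_scenario <- function(x, ...) {
  cat("<fpe_scenario> seed", x$seed, "\n\nSummary diagnostics:\n")
  print(x$summary)
  invisible(x)
}

#' Write fixture files exercising every interchange format
#'
#' Generates a small simulated registry cohort and trio cohort and writes
#' FAM, score, covariate, diagnosis, variant, trio and parameter files.
#' `tiny` fixtures are hand-checkable (at most 10 families in total);
#' `medium` fixtures are large enough that recurrence odds ratios are
#' estimable.
#'
#' @param dir Output directory.
#' @param size `"tiny"`, `"small"` or `"medium"`.
#' @param seed Integer seed; the fixture set is deterministic given it.
#' @return `dir` invisibly, with the written file names as attribute
#'   `"files"`.
#' @export
make_fixtures <- function(dir, size = c("tiny", "small", "medium"), seed = 1) {
  size <- match.arg(size)
  ns <- switch(size,
    tiny = list(registry = 7, trio = 3),
    small = list(registry = 500, trio = 50),
    medium = list(registry = 5000, trio = 300)
  )
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  params <- liability_params()

  registry <- simulate_registry(params, ns$registry,
                                seed = stage_seed(seed, "fixture registry"))
  write_cohort(registry, file.path(dir, "registry"))

  trio <- simulate_trio_cohort(params, ns$trio,
                               seed = stage_seed(seed, "fixture trio"))
  write_fam(trio, file.path(dir, "trio.fam"))
  write_trio_table(cohort_trios(trio, score = "pgs_obs"),
                   file.path(dir, "trios.tsv"))

  kids <- trio[trio$role == "offspring", ]
  covars <- tibble::as_tibble(
    setNames(as.data.frame(matrix(
      withr::with_seed(stage_seed(seed, "fixture pcs"),
                       rnorm(nrow(kids) * 15, 0, 0.02)),
      ncol = 15
    )), paste0("PC", 1:15))
  )
  covars <- dplyr::bind_cols(tibble::tibble(iid = kids$iid), covars)
  write_covariate_table(covars, file.path(dir, "covariates.tsv"))

  variants <- simulate_variant_table(trio,
                                     seed = stage_seed(seed, "fixture variants"))
  write_variant_table(variants, file.path(dir, "variants.tsv"))

  files <- c(
    file.path("registry", c("cohort.fam", "scores.tsv", "diagnoses.tsv",
                            "params.yaml")),
    "trio.fam", "trios.tsv", "covariates.tsv", "variants.tsv"
  )
  structure(invisible(dir), files = files)
}
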