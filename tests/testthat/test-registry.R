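params <- liability_params()

test_that("index-case selection matches the eligibility criteria", {
  co <- toy_cohort(list(
    child("female", 1990, asd = TRUE),
    child("male", 1992, asd = TRUE),
    child("female", 1994)
  ))
  ## one eligible child: deterministic
  idx <- select_index_cases(co, sex = "female", group = "ASDnoID", seed = 1)
  expect_equal(idx$iid, 101L)
  ## no eligible child: empty
  idx0 <- select_index_cases(co, sex = "female", group = "IDnoASD", seed = 1)
  expect_equal(nrow(idx0), 0)
})

test_that("selection among equally eligible children is uniform", {
  co <- toy_cohort(list(
    child("male", 1990, asd = TRUE),
    child("male", 1991, asd = TRUE)
  ))
  picks <- vapply(seq_len(10000), function(s) {
    select_index_cases(co, sex = "male", group = "ASDnoID", seed = s)$iid
  }, integer(1))
  p_hat <- mean(picks == 101L)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("sibling selection respects the birth-year window and ignores diagnosis", {
  co <- toy_cohort(list(
    child("female", 1990, asd = TRUE),
    child("male", 1979),          # out of window
    child("male", 2006)           # out of window
  ))
  idx <- select_index_cases(co, "female", "ASDnoID", seed = 1)
  expect_equal(nrow(select_siblings(co, idx)), 0)

  co2 <- toy_cohort(list(
    child("female", 1990, asd = TRUE),
    child("male", 1991, asd = TRUE),   # affected sibling
    child("male", 1992)                # unaffected sibling
  ))
  idx2 <- tibble::tibble(fid = 1L, iid = 101L)
  picks <- vapply(seq_len(4000), function(s) {
    select_siblings(co2, idx2, seed = s)$sibling_iid
  }, integer(1))
  ## affected and unaffected siblings drawn with equal probability
  expect_lt(abs(mean(picks == 102L) - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("sibling selection validates its index input", {
  co <- toy_cohort(list(child("female", 1990, asd = TRUE)))
  expect_error(select_siblings(co, tibble::tibble(fid = 1L, iid = 999L)),
               "not found")
})

test_that("controls are matched on sex and birth year without reuse", {
  co <- simulate_registry(params, n_families = 4000, seed = 11)
  idx <- select_index_cases(co, "any", "ASD", seed = 1)
  sibs <- select_siblings(co, idx, seed = 2)
  excl <- co$iid[co$role == "offspring" & co$fid %in% idx$fid &
                   !(co$iid %in% idx$iid)]
  ctl <- match_controls(co, sibs, ratio = 2, exclude = excl, seed = 3)
  expect_equal(nrow(ctl), 2 * nrow(sibs))
  expect_false(any(duplicated(ctl$control_iid)))
  expect_false(any(ctl$control_iid %in% excl))
  sib_row <- match(ctl$sibling_iid, co$iid)
  ctl_row <- match(ctl$control_iid, co$iid)
  expect_true(all(co$sex[sib_row] == co$sex[ctl_row]))
  expect_true(all(co$birth_year[sib_row] == co$birth_year[ctl_row]))
})

test_that("matching fails loudly when the pool is exhausted", {
  co <- toy_cohort(list(
    child("female", 1990, asd = TRUE),   # iid 101
    child("female", 1990)                # iid 102, the sibling
  ))
  ## pool of one eligible control (101) for a 2:1 request
  expect_error(
    match_controls(co, tibble::tibble(sibling_iid = 102L), ratio = 2),
    "Matching failure"
  )
  ## exclusions can empty the pool entirely
  expect_error(
    match_controls(co, tibble::tibble(sibling_iid = 102L), ratio = 1,
                   exclude = 101L),
    "Matching failure"
  )
})

test_that("the logistic odds ratio reproduces hand-computed 2x2 results", {
  ## 150 affected of 1,707 siblings vs 45 affected of 3,414 controls
  co <- tibble::tibble(
    fid = seq_len(5121), iid = seq_len(5121),
    father_iid = NA_integer_, mother_iid = NA_integer_,
    sex = "male", birth_year = 1990L, role = "offspring",
    pgs_asd = 0, pgs_id = 0, pgs_obs = 0, dnv = FALSE,
    liab_asd = 0, liab_id = 0,
    dx_asd = c(rep(TRUE, 150), rep(FALSE, 1557), rep(TRUE, 45), rep(FALSE, 3369)),
    dx_id = FALSE,
    group = diagnosis_group(
      c(rep(TRUE, 150), rep(FALSE, 1557), rep(TRUE, 45), rep(FALSE, 3369)),
      rep(FALSE, 5121)
    )
  )
  fit <- fit_recurrence(co, siblings = 1:1707, controls = 1708:5121, "ASDnoID")
  ora <- oracle_or(150, 1557, 45, 3369)
  expect_equal(fit$odds_ratio, ora$or, tolerance = 1e-6)
  expect_equal(fit$se_log_or, ora$se, tolerance = 1e-6)
  expect_equal(fit$odds_ratio, 7.21, tolerance = 0.001)
  expect_equal(fit$ci_low, 5.14, tolerance = 0.001)
  expect_equal(fit$ci_high, 10.12, tolerance = 0.001)
  expect_false(fit$degenerate)
})

test_that("equal affected fractions give an odds ratio of one", {
  co <- toy_cohort(purrr::map(seq_len(40), function(i) {
    child("male", 1990, asd = i %% 4 == 0)
  }))
  kids <- co$iid[co$role == "offspring"]
  fit <- fit_recurrence(co, kids[1:20], kids[21:40], "ASDnoID")
  expect_equal(fit$odds_ratio, 1, tolerance = 1e-9)
})

test_that("zero cells are flagged degenerate, not silently estimated", {
  co <- toy_cohort(purrr::map(seq_len(30), function(i) {
    child("male", 1990, asd = i <= 5)   # all affected individuals in arm 1
  }))
  kids <- co$iid[co$role == "offspring"]
  fit <- fit_recurrence(co, kids[1:15], kids[16:30], "ASDnoID")
  expect_true(fit$degenerate)
  expect_true(is.finite(fit$odds_ratio))  # Haldane-Anscombe report
  expect_error(compare_or(fit, fit), "degenerate")
})

test_that("fit_recurrence matches the closed-form oracle on random tables", {
  withr::with_seed(99, {
    for (i in seq_len(200)) {
      n <- sample(50:400, 4, replace = TRUE)
      co <- tibble::tibble(
        iid = seq_len(sum(n)), fid = seq_len(sum(n)),
        father_iid = NA_integer_, mother_iid = NA_integer_,
        sex = "male", birth_year = 1990L, role = "offspring",
        pgs_asd = 0, pgs_id = 0, pgs_obs = 0, dnv = FALSE,
        liab_asd = 0, liab_id = 0,
        dx_asd = rep(c(TRUE, FALSE, TRUE, FALSE), n), dx_id = FALSE,
        group = diagnosis_group(rep(c(TRUE, FALSE, TRUE, FALSE), n),
                                rep(FALSE, sum(n)))
      )
      sibs <- seq_len(n[1] + n[2])
      ctls <- (n[1] + n[2] + 1):sum(n)
      fit <- fit_recurrence(co, sibs, ctls, "ASDnoID")
      ora <- oracle_or(n[1], n[2], n[3], n[4])
      expect_equal(fit$odds_ratio, ora$or, tolerance = 1e-6)
      expect_equal(fit$se_log_or, ora$se, tolerance = 1e-6)
    }
  })
})

test_that("published odds ratios can be compared from their intervals", {
  cmp <- compare_or(or_from_ci(7.19, 5.09, 10.09), or_from_ci(3.76, 3.10, 4.54))
  expect_equal(cmp$p_value, 0.0012, tolerance = 0.02)
  expect_lt(cmp$p_value, 0.01)
  ## antisymmetry
  rev <- compare_or(or_from_ci(3.76, 3.10, 4.54), or_from_ci(7.19, 5.09, 10.09))
  expect_equal(rev$log_or_difference, -cmp$log_or_difference)
  expect_equal(rev$p_value, cmp$p_value)
  ## identical inputs: no difference
  same <- compare_or(or_from_ci(2, 1.5, 2.67), or_from_ci(2, 1.5, 2.67))
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
})

test_that("the recurrence Wald test is calibrated on an exchangeable null", {
  ## one child per family (no ascertainment), randomly split 1:2 into the
  ## "sibling" and "control" arms: both arms share one diagnosis rate, so
  ## rejections of OR != 1 must occur at the nominal level
  p0 <- null_params()
  reps <- 1000
  pvals <- vapply(seq_len(reps), function(r) {
    co <- simulate_registry(p0, n_families = 400, seed = 20000 + r)
    kids <- co[co$role == "offspring", ]
    one <- kids[!duplicated(kids$fid), ]
    arm <- withr::with_seed(
      30000 + r,
      sample(rep(c(TRUE, FALSE, FALSE), length.out = nrow(one)))
    )
    fit <- fit_recurrence(co, one$iid[arm], one$iid[!arm], "ASD")
    fit$p_value
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("single-index ascertainment is conservative under the null", {
  ## with complete ascertainment and the index consumed per family, the null
  ## sibling rate is p/(2-p) < p, so the procedure's null OR sits below 1 and
  ## never manufactures spurious excess recurrence
  p0 <- null_params()
  lors <- vapply(1:60, function(r) {
    co <- simulate_registry(p0, n_families = 400, seed = 40000 + r)
    idx <- select_index_cases(co, "any", "ASD", seed = 1)
    sibs <- select_siblings(co, idx, birth_year_window = c(1990L, 1990L), seed = 2)
    excl <- co$iid[co$role == "offspring" & co$fid %in% idx$fid &
                     !(co$iid %in% idx$iid)]
    ctl <- match_controls(co, sibs, ratio = 2, exclude = excl, seed = 3)
    log(fit_recurrence(co, sibs$sibling_iid, ctl$control_iid, "ASD")$odds_ratio)
  }, numeric(1))
  ## two-child-family theory: sibling rate p/(2-p) gives null OR ~ 0.5;
  ## mixed 2-4-child families sit between that and 1
  expect_lt(mean(lors), -0.2)
  expect_gt(mean(lors), -1.2)
})

test_that("the full recurrence analysis returns a tidy gated table", {
  co <- simulate_registry(params, n_families = 40000, seed = 111)
  res <- run_recurrence_analysis(co, seed = 5)
  expect_true(all(c("index_sex", "index_group", "outcome", "odds_ratio",
                    "ci_low", "ci_high", "p_value", "degenerate") %in% names(res)))
  expect_true(all(res$n_ctrl == 2 * res$n_sib))
  ## empty criteria produce an empty table
  expect_equal(nrow(run_recurrence_analysis(co, criteria = tibble::tibble(
    sex = character(), group = character()
  ))), 0)
  ## gating: comparisons only where both ORs are individually significant
  cmp <- sex_or_comparisons(res)
  if (nrow(cmp)) {
    for (i in seq_len(nrow(cmp))) {
      rows <- res[res$index_group == cmp$index_group[i] &
                    res$outcome == cmp$outcome[i], ]
      expect_true(all(rows$ci_low > 1 | rows$ci_high < 1))
    }
  }
  ## ASDnoID cells carry elevated recurrence in an FPE cohort
  asd <- res[res$index_group == "ASDnoID" & res$outcome == "ASDnoID", ]
  expect_true(all(asd$odds_ratio > 1))
})

test_that("sibling-sex stratified recurrence uses sex-matched controls", {
  co <- simulate_registry(params, n_families = 40000, seed = 121)
  res <- recurrence_by_sibling_sex(co, seed = 6)
  expect_equal(sort(res$sibling_sex), c("female", "male"))
  expect_true(all(res$odds_ratio > 1))
  ## the two strata agree within Monte-Carlo error (CI overlap)
  expect_true(res$ci_low[1] < res$ci_high[2] && res$ci_low[2] < res$ci_high[1])
})

test_that("an all-male sibling set flags the empty female stratum", {
  co <- toy_cohort(list(
    child("female", 1990, asd = TRUE),
    child("male", 1991)
  ))
  extra <- purrr::map(3:60, function(i) child("male", 1991))
  pool <- toy_cohort(extra, fid = 2L)
  pool$iid <- pool$iid + 1000L
  both <- dplyr::bind_rows(co, pool)
  expect_warning(res <- recurrence_by_sibling_sex(both, seed = 1),
                 "No female siblings")
  expect_true(res$degenerate[res$sibling_sex == "female"])
  expect_equal(res$n_sib[res$sibling_sex == "female"], 0L)
})
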