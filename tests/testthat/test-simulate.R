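params <- liability_params()

test_that("simulation is byte-identical under a repeated seed", {
  a <- simulate_registry(params, n_families = 300, seed = 7)
  b <- simulate_registry(params, n_families = 300, seed = 7)
  expect_identical(a, b)
  d <- simulate_registry(params, n_families = 300, seed = 8)
  expect_false(identical(a$pgs_asd, d$pgs_asd))
  t1 <- simulate_trio_cohort(params, n_families = 40, seed = 7)
  t2 <- simulate_trio_cohort(params, n_families = 40, seed = 7)
  expect_identical(t1, t2)
})

test_that("cohorts satisfy pedigree invariants", {
  co <- simulate_registry(params, n_families = 500, seed = 21)
  kids <- co[co$role == "offspring", ]
  expect_true(all(kids$father_iid %in% co$iid))
  expect_true(all(kids$mother_iid %in% co$iid))
  expect_true(all(co$sex[match(kids$father_iid, co$iid)] == "male"))
  expect_true(all(co$sex[match(kids$mother_iid, co$iid)] == "female"))
  expect_false(any(duplicated(co$iid)))
  ## diagnoses present iff liability exceeds the sex-specific threshold
  thr <- ifelse(co$sex == "male", params$thresholds$asd[["male"]],
                params$thresholds$asd[["female"]])
  expect_identical(co$dx_asd, co$liab_asd > thr)
  ## founders carry no de novo shocks; birth years inside the window
  expect_false(any(co$dnv[co$role == "founder"]))
  expect_true(all(kids$birth_year >= 1981 & kids$birth_year <= 2005))
})

test_that("founder liability is standard normal at scale", {
  co <- simulate_registry(params, n_families = 50000, seed = 31)
  fl <- co$liab_asd[co$role == "founder"]
  n <- length(fl)
  expect_gte(n, 1e5)
  expect_lt(abs(mean(fl)), 3 / sqrt(n))
  expect_lt(abs(var(fl) - 1), 3 * sqrt(2 / (n - 1)))
})

test_that("sex-specific prevalences are recovered without de novo shocks", {
  p0 <- liability_params(dnv_rate = 0)
  co <- simulate_registry(p0, n_families = 30000, seed = 41)
  kids <- co[co$role == "offspring", ]
  for (sx in c("male", "female")) {
    k <- kids[kids$sex == sx, ]
    target <- p0$prevalence$asd[[sx]]
    se <- sqrt(target * (1 - target) / nrow(k))
    expect_lt(abs(mean(k$dx_asd) - target), 3 * se)
    target_id <- p0$prevalence$id[[sx]]
    se_id <- sqrt(target_id * (1 - target_id) / nrow(k))
    expect_lt(abs(mean(k$dx_id) - target_id), 3 * se_id)
  }
})

test_that("parent-offspring polygenic regression has slope 1/2 per parent", {
  co <- simulate_registry(params, n_families = 20000, seed = 51)
  kids <- co[co$role == "offspring", ]
  df <- data.frame(
    child = kids$pgs_asd,
    father = co$pgs_asd[match(kids$father_iid, co$iid)],
    mother = co$pgs_asd[match(kids$mother_iid, co$iid)]
  )
  fit <- summary(lm(child ~ father + mother, data = df))$coefficients
  expect_lt(abs(fit["father", "Estimate"] - 0.5), 3 * fit["father", "Std. Error"])
  expect_lt(abs(fit["mother", "Estimate"] - 0.5), 3 * fit["mother", "Std. Error"])
})

test_that("diagnosis groups are the four mutually exclusive outcome classes", {
  expect_equal(as.character(diagnosis_group(TRUE, FALSE)), "ASDnoID")
  expect_equal(as.character(diagnosis_group(TRUE, TRUE)), "ASDandID")
  expect_equal(as.character(diagnosis_group(FALSE, TRUE)), "IDnoASD")
  expect_equal(as.character(diagnosis_group(FALSE, FALSE)), "none")
  expect_error(diagnosis_group(1, 0), "logical")
})

test_that("de novo carriers are enriched among cases, more so in females", {
  co <- simulate_registry(params, n_families = 60000, seed = 61)
  kids <- co[co$role == "offspring", ]
  carrier_f <- mean(kids$dnv[kids$dx_asd & kids$sex == "female"])
  carrier_m <- mean(kids$dnv[kids$dx_asd & kids$sex == "male"])
  expect_gt(carrier_m, params$dnv_rate)  # enrichment over the population rate
  expect_gt(carrier_f, carrier_m)        # stronger under the higher threshold
})

test_that("trio ascertainment honours its flags", {
  tr <- simulate_trio_cohort(params, n_families = 150, seed = 71)
  kids <- tr[tr$role == "offspring", ]
  ## every family has exactly one proband, and the proband is affected
  expect_equal(sum(tr$proband), 150)
  expect_true(all(table(tr$fid[tr$proband]) == 1L))
  expect_true(all(tr$dx_asd[tr$proband]))
  ## parents pass the sub-diagnostic screen
  founders <- tr[tr$role == "founder", ]
  margin <- 0.75
  lim <- ifelse(founders$sex == "male",
                params$thresholds$asd[["male"]] - margin,
                params$thresholds$asd[["female"]] - margin)
  expect_true(all(founders$liab_asd < lim))
  ## designated sibling is an unaffected non-proband child, oldest first
  des <- kids[kids$designated_sibling, ]
  expect_false(any(des$dx_asd))
  expect_false(any(des$proband))
  ## with the unaffected-sibling requirement every family has a designee
  tq <- simulate_trio_cohort(params, n_families = 60,
                             require_unaffected_sibling = TRUE, seed = 72)
  expect_equal(sum(tq$designated_sibling), 60)
})

test_that("trio cohort edge cases: empty request and infeasible screens", {
  e <- simulate_trio_cohort(params, n_families = 0, seed = 1)
  expect_equal(nrow(e), 0)
  expect_true(all(c("proband", "designated_sibling") %in% names(e)))
  ## all parents affected: unaffected-parent ascertainment cannot converge
  p_inf <- liability_params()
  p_inf$thresholds$asd[] <- -Inf
  expect_error(
    simulate_trio_cohort(p_inf, n_families = 5, ascertainment_floor = 1e-3,
                         seed = 2),
    "unaffected-parent"
  )
})

test_that("ascertained mothers carry more polygenic risk than fathers", {
  tr <- simulate_trio_cohort(params, n_families = 1500, seed = 81)
  founders <- tr[tr$role == "founder", ]
  founders$is_mother <- founders$sex == "female"
  gap <- tidy(compare_prs_groups(founders, score = "pgs_asd",
                                 group = "is_mother"))
  expect_gt(gap$difference, 0)
  expect_lt(gap$p_value, 0.05)
})

test_that("equal thresholds remove the parental asymmetry", {
  p_eq <- liability_params(
    prevalence = list(asd = c(male = 0.02, female = 0.02),
                      id = c(male = 0.015, female = 0.015))
  )
  tr <- simulate_trio_cohort(p_eq, n_families = 2000, seed = 91)
  founders <- tr[tr$role == "founder", ]
  founders$is_mother <- founders$sex == "female"
  gap <- tidy(compare_prs_groups(founders, score = "pgs_asd",
                                 group = "is_mother"))
  expect_lt(abs(gap$difference / gap$standard_error), 3)
})
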