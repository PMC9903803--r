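## Closed-form oracle for the 2x2 matched design: cross-product odds ratio
## and the standard Woolf log-OR standard error.
oracle_or <- function(a, b, c, d) {
  list(or = (a * d) / (b * c), se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}

## A null generative model: no familial aggregation at all.
null_params <- function(prev = 0.2) {
  liability_params(
    h2_common = 0, dnv_rate = 0, dnv_effect = 0,
    prevalence = list(asd = c(male = prev, female = prev),
                      id = c(male = prev / 2, female = prev / 2)),
    birth_years = c(1990L, 1990L)
  )
}

## Hand-built cohort rows for selection-logic tests. Each child is a list
## with fields sex, by (birth year), asd, id.
toy_cohort <- function(children, fid = 1L) {
  n <- length(children)
  kids <- tibble::tibble(
    fid = fid,
    iid = 100L + seq_len(n),
    father_iid = 1L,
    mother_iid = 2L,
    sex = purrr::map_chr(children, "sex"),
    birth_year = purrr::map_int(children, "by"),
    role = "offspring",
    pgs_asd = 0, pgs_id = 0, pgs_obs = 0,
    dnv = FALSE, liab_asd = 0, liab_id = 0,
    dx_asd = purrr::map_lgl(children, "asd"),
    dx_id = purrr::map_lgl(children, "id"),
    group = diagnosis_group(purrr::map_lgl(children, "asd"),
                            purrr::map_lgl(children, "id"))
  )
  founders <- tibble::tibble(
    fid = fid, iid = c(1L, 2L), father_iid = NA_integer_,
    mother_iid = NA_integer_, sex = c("male", "female"),
    birth_year = NA_integer_, role = "founder",
    pgs_asd = 0, pgs_id = 0, pgs_obs = 0, dnv = FALSE,
    liab_asd = 0, liab_id = 0, dx_asd = FALSE, dx_id = FALSE,
    group = diagnosis_group(c(FALSE, FALSE), c(FALSE, FALSE))
  )
  dplyr::bind_rows(founders, kids)
}

child <- function(sex = "male", by = 1990L, asd = FALSE, id = FALSE) {
  list(sex = sex, by = as.integer(by), asd = asd, id = id)
}
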