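#' Diagnosis groups from ASD and ID indicators
#'
#' Collapses the two diagnoses into the four mutually exclusive outcome
#' classes used throughout the recurrence analyses: `ASDnoID`, `ASDandID`,
#' `IDnoASD` and `none`.
#'
#' @param asd,id Logical vectors (recycled to a common length).
#' @return A factor with levels `ASDnoID`, `ASDandID`, `IDnoASD`, `none`.
#' @examples
#' diagnosis_group(c(TRUE, TRUE, FALSE, FALSE), c(FALSE, TRUE, TRUE, FALSE))
#' @export
diagnosis_group <- function(asd, id) {
  if (!is.logical(asd) || !is.logical(id)) {
    abort("`asd` and `id` must be logical vectors.")
  }
  n <- max(length(asd), length(id))
  asd <- rep_len(asd, n)
  id <- rep_len(id, n)
  out <- rep("none", n)
  out[asd & !id] <- "ASDnoID"
  out[asd & id] <- "ASDandID"
  out[!asd & id] <- "IDnoASD"
  out[is.na(asd) | is.na(id)] <- NA
  factor(out, levels = c("ASDnoID", "ASDandID", "IDnoASD", "none"))
}

## Draw the genetic and liability machinery for a block of nuclear families.
## `sizes` gives the number of children per family. Returns a plain list of
## vectors; assembly into a cohort tibble happens once, in the caller.
draw_family_block <- function(params, sizes) {
  nf <- length(sizes)
  n_child <- sum(sizes)
  fid_child <- rep.int(seq_len(nf), sizes)
  h2 <- params$h2_common
  rg <- params$rg_asd_id
  res_sd <- sqrt(1 - h2)

  ## founder common components: bivariate normal, var h2, correlation rg
  biv <- function(n, v) {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    list(asd = sqrt(v) * z1, id = sqrt(v) * (rg * z1 + sqrt(1 - rg^2) * z2))
  }
  gm <- biv(nf, h2) # mothers
  gf <- biv(nf, h2) # fathers

  founder_liab <- function(g) {
    list(asd = g$asd + rnorm(nf, 0, res_sd), id = g$id + rnorm(nf, 0, res_sd))
  }
  Lm <- founder_liab(gm)
  Lf <- founder_liab(gf)

  ## children: mid-parent plus Mendelian segregation noise (variance h2/2),
  ## preserving the cross-phenotype correlation of the common components
  seg <- biv(n_child, h2 / 2)
  gc_asd <- (gm$asd[fid_child] + gf$asd[fid_child]) / 2 + seg$asd
  gc_id <- (gm$id[fid_child] + gf$id[fid_child]) / 2 + seg$id
  dnv <- runif(n_child) < params$dnv_rate
  shock <- dnv * params$dnv_effect
  Lc_asd <- gc_asd + rnorm(n_child, 0, res_sd) + shock
  Lc_id <- gc_id + rnorm(n_child, 0, res_sd) + shock
  sex <- ifelse(runif(n_child) < 0.5, "male", "female")
  yrs <- seq(params$birth_years[1], params$birth_years[2])
  birth_year <- yrs[sample.int(length(yrs), n_child, replace = TRUE)]

  list(
    nf = nf, sizes = sizes, fid_child = fid_child,
    gm = gm, gf = gf, Lm = Lm, Lf = Lf,
    gc_asd = gc_asd, gc_id = gc_id, dnv = dnv,
    Lc_asd = Lc_asd, Lc_id = Lc_id, sex = sex, birth_year = birth_year
  )
}

## sex-specific threshold lookup for one phenotype
threshold_for <- function(params, phenotype, sex) {
  thr <- params$thresholds[[phenotype]]
  ifelse(sex == "male", thr[["male"]], thr[["female"]])
}

## Assemble a cohort tibble from a (possibly filtered) family block.
## `keep` indexes families within the block; ids are assigned densely.
assemble_cohort <- function(params, blk, keep = seq_len(blk$nf)) {
  nf <- length(keep)
  child_in <- blk$fid_child %in% keep
  fid_map <- match(blk$fid_child[child_in], keep)
  sizes <- tabulate(fid_map, nbins = nf)
  n_child <- sum(child_in)

  father_iid <- seq_len(nf)
  mother_iid <- nf + seq_len(nf)
  child_iid <- 2L * nf + seq_len(n_child)

  noise_sd <- sqrt(score_noise_var(params))
  obs <- function(g, n) g + rnorm(n, 0, noise_sd)

  sexes <- c(rep("male", nf), rep("female", nf), blk$sex[child_in])
  liab_asd <- c(blk$Lf$asd[keep], blk$Lm$asd[keep], blk$Lc_asd[child_in])
  liab_id <- c(blk$Lf$id[keep], blk$Lm$id[keep], blk$Lc_id[child_in])
  dx_asd <- liab_asd > threshold_for(params, "asd", sexes)
  dx_id <- liab_id > threshold_for(params, "id", sexes)

  tibble::tibble(
    fid = c(rep(seq_len(nf), 2L), fid_map),
    iid = c(father_iid, mother_iid, child_iid),
    father_iid = c(rep(NA_integer_, 2L * nf), father_iid[fid_map]),
    mother_iid = c(rep(NA_integer_, 2L * nf), mother_iid[fid_map]),
    sex = sexes,
    birth_year = c(rep(NA_integer_, 2L * nf), blk$birth_year[child_in]),
    role = c(rep("founder", 2L * nf), rep("offspring", n_child)),
    pgs_asd = c(blk$gf$asd[keep], blk$gm$asd[keep], blk$gc_asd[child_in]),
    pgs_id = c(blk$gf$id[keep], blk$gm$id[keep], blk$gc_id[child_in]),
    pgs_obs = obs(c(blk$gf$asd[keep], blk$gm$asd[keep], blk$gc_asd[child_in]),
                  2L * nf + n_child),
    dnv = c(rep(FALSE, 2L * nf), blk$dnv[child_in]),
    liab_asd = liab_asd,
    liab_id = liab_id,
    dx_asd = dx_asd,
    dx_id = dx_id,
    group = diagnosis_group(dx_asd, dx_id)
  )
}

empty_cohort <- function(extra = character()) {
  out <- tibble::tibble(
    fid = integer(), iid = integer(), father_iid = integer(),
    mother_iid = integer(), sex = character(), birth_year = integer(),
    role = character(), pgs_asd = double(), pgs_id = double(),
    pgs_obs = double(), dnv = logical(), liab_asd = double(),
    liab_id = double(), dx_asd = logical(), dx_id = logical(),
    group = factor(levels = c("ASDnoID", "ASDandID", "IDnoASD", "none"))
  )
  for (col in extra) out[[col]] <- logical()
  out
}

#' Simulate a registry-style population of multi-child families
#'
#' Generates founder couples and their children under the liability-threshold
#' model of [liability_params()]: founder polygenic components are drawn with
#' variance `h2_common`, each child's component is the mid-parent value plus
#' Mendelian segregation noise of variance `h2_common / 2`, high-impact de
#' novo variants arise in children at `dnv_rate` and shift both liabilities by
#' `dnv_effect`, and diagnoses follow sex-specific thresholds. The default
#' family count is sized so the sex-by-diagnosis analysis cells match a
#' national-registry ASD study (about 1,700 siblings of female ASDnoID index
#' cases).
#'
#' @param params A [liability_params()] object.
#' @param n_families Number of families to generate.
#' @param children_per_family Named probability vector over family sizes,
#'   names giving the number of children. The default emulates two-or-more
#'   child registry families (mean ~2.6 children).
#' @param seed Optional integer seed; the same seed reproduces the cohort
#'   exactly and the caller's RNG state is left untouched.
#' @return A tibble with one row per individual (founders and offspring):
#'   family and individual ids, parental links, sex, birth year, role, true
#'   polygenic components for ASD and ID (`pgs_asd`, `pgs_id`), a noisy
#'   observed score (`pgs_obs`), de novo carrier status, both liabilities,
#'   both diagnoses, and the [diagnosis_group()] outcome class. The
#'   generating parameters and seed are attached as attributes.
#' @examples
#' cohort <- simulate_registry(liability_params(), n_families = 500, seed = 1)
#' table(cohort$group[cohort$role == "offspring"])
#' @export
simulate_registry <- function(params = liability_params(),
                              n_families = 200000,
                              children_per_family = c(`2` = 0.55, `3` = 0.33, `4` = 0.12),
                              seed = NULL) {
  stopifnot(inherits(params, "liability_params"))
  if (!is.numeric(n_families) || n_families < 1) {
    abort("`n_families` must be at least 1.")
  }
  ks <- as.integer(names(children_per_family))
  if (anyNA(ks) || any(ks < 1) || any(children_per_family < 0) ||
      sum(children_per_family) <= 0) {
    abort("`children_per_family` must be named by positive child counts with nonnegative weights.")
  }
  out <- with_stage_seed(seed, {
    sizes <- sample(ks, n_families, replace = TRUE,
                    prob = children_per_family / sum(children_per_family))
    blk <- draw_family_block(params, sizes)
    assemble_cohort(params, blk)
  })
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  attr(out, "cohort_type") <- "registry"
  out
}

#' Simulate an ascertained trio/quad cohort
#'
#' Rejection-samples nuclear families until `n_families` satisfy the
#' ascertainment of family-based ASD collections: at least one ASD-affected
#' child, optionally two unaffected parents, and optionally at least one
#' unaffected sibling. Parental screening emulates cohorts that exclude not
#' only diagnosed parents but also parents with a substantial burden of
#' ASD-like traits: a parent passes when their ASD liability is at least
#' `parent_screen_margin` liability SD below their sex-specific diagnostic
#' threshold (margin 0 reproduces plain diagnostic screening).
#'
#' One affected child per family is marked as the `proband` (chosen uniformly
#' among affected children); the oldest unaffected child, when present, is
#' marked as the `designated_sibling`.
#'
#' @inheritParams simulate_registry
#' @param n_families Number of ascertained families to return (0 gives an
#'   empty cohort).
#' @param n_children Children per candidate family (default 2, a quad).
#' @param require_unaffected_parents Keep only families whose parents pass the
#'   ASD screen.
#' @param require_unaffected_sibling Keep only families with at least one
#'   unaffected child in addition to the proband.
#' @param parent_screen_margin Sub-diagnostic screening margin in liability SD
#'   units. The default 0.75 screens out roughly 10% of fathers and 4% of
#'   mothers at default thresholds, consistent with broader-autism-phenotype
#'   rates among parents of ASD children.
#' @param ascertainment_floor If the empirical acceptance rate falls below
#'   this value the sampler aborts naming the infeasible constraint.
#' @return A cohort tibble as in [simulate_registry()], with additional
#'   logical columns `proband` and `designated_sibling`.
#' @examples
#' trio <- simulate_trio_cohort(liability_params(), n_families = 50, seed = 1)
#' sum(trio$proband)
#' @export
simulate_trio_cohort <- function(params = liability_params(),
                                 n_families = 4800,
                                 n_children = 2,
                                 require_unaffected_parents = TRUE,
                                 require_unaffected_sibling = FALSE,
                                 parent_screen_margin = 0.75,
                                 ascertainment_floor = 1e-6,
                                 seed = NULL) {
  stopifnot(inherits(params, "liability_params"))
  if (!is.numeric(n_families) || n_families < 0) {
    abort("`n_families` must be nonnegative.")
  }
  if (n_children < 1) abort("`n_children` must be at least 1.")
  if (require_unaffected_sibling && n_children < 2) {
    abort("An unaffected sibling requires at least 2 children per family.")
  }
  if (n_families == 0) {
    out <- empty_cohort(extra = c("proband", "designated_sibling"))
    attr(out, "params") <- params
    attr(out, "seed") <- seed
    attr(out, "cohort_type") <- "trio"
    return(out)
  }

  out <- with_stage_seed(seed, {
    kept_blocks <- list()
    kept_probands <- list()
    n_kept <- 0
    n_tried <- 0
    repeat {
      b <- min(500000, max(5000, ceiling((n_families - n_kept) * 60)))
      blk <- draw_family_block(params, rep.int(as.integer(n_children), b))
      aff <- matrix(blk$Lc_asd > threshold_for(params, "asd", blk$sex),
                    nrow = n_children)
      ok <- colSums(aff) >= 1L
      if (require_unaffected_sibling) ok <- ok & colSums(!aff) >= 1L
      if (require_unaffected_parents) {
        thr_m <- params$thresholds$asd[["female"]] - parent_screen_margin
        thr_f <- params$thresholds$asd[["male"]] - parent_screen_margin
        ok <- ok & (blk$Lm$asd < thr_m) & (blk$Lf$asd < thr_f)
      }
      keep <- which(ok)
      n_tried <- n_tried + b
      if (length(keep) + n_kept > n_families) {
        keep <- keep[seq_len(n_families - n_kept)]
      }
      if (length(keep)) {
        ## proband: uniformly random among affected children of kept families
        aff_idx <- which(aff[, keep, drop = FALSE], arr.ind = TRUE)
        pick <- pick_one_per_group(aff_idx[, "col"])
        proband_row <- integer(length(keep))
        proband_row[aff_idx[pick, "col"]] <- aff_idx[pick, "row"]
        n_kept <- n_kept + length(keep)
        kept_blocks[[length(kept_blocks) + 1L]] <- list(blk = blk, keep = keep)
        kept_probands[[length(kept_probands) + 1L]] <- proband_row
      }
      if (n_kept >= n_families) break
      if (n_tried >= 3 / ascertainment_floor &&
          n_kept / n_tried < ascertainment_floor) {
        constraint <- if (require_unaffected_parents) {
          "affected child with parents passing the unaffected-parent screen"
        } else {
          "at least one affected child"
        }
        abort(sprintf(
          "Ascertainment did not converge: acceptance rate %.2g below floor %.2g for constraint '%s'.",
          n_kept / n_tried, ascertainment_floor, constraint
        ))
      }
    }

    pieces <- purrr::map(kept_blocks, ~ assemble_cohort(params, .x$blk, .x$keep))
    ## piece-local proband iids: children of dense family k occupy rows
    ## 2*nf + (k-1)*n_children + (1..n_children), in block child order
    proband_iid_local <- purrr::map2(pieces, kept_probands, function(p, rows) {
      nf <- max(p$fid)
      2L * nf + (seq_along(rows) - 1L) * as.integer(n_children) + rows
    })
    ## re-key ids so families are dense across pieces
    fam_off <- cumsum(c(0L, purrr::map_int(pieces, ~ max(.x$fid))))
    iid_off <- cumsum(c(0L, purrr::map_int(pieces, ~ nrow(.x))))
    pieces <- purrr::imap(pieces, function(p, i) {
      p$fid <- p$fid + fam_off[[i]]
      p$iid <- p$iid + iid_off[[i]]
      p$father_iid <- p$father_iid + iid_off[[i]]
      p$mother_iid <- p$mother_iid + iid_off[[i]]
      p
    })
    cohort <- dplyr::bind_rows(pieces)
    proband_iid <- unlist(purrr::imap(proband_iid_local, ~ .x + iid_off[[.y]]))
    cohort$proband <- cohort$iid %in% proband_iid

    ## designated sibling: oldest unaffected non-proband child per family
    child <- cohort[cohort$role == "offspring" & !cohort$proband & !cohort$dx_asd, ]
    if (nrow(child)) {
      o <- order(child$fid, child$birth_year, child$iid)
      designated <- child$iid[o][!duplicated(child$fid[o])]
    } else {
      designated <- integer(0)
    }
    cohort$designated_sibling <- cohort$iid %in% designated
    cohort
  })
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  attr(out, "cohort_type") <- "trio"
  out
}

#' Generating parameters attached to a simulated cohort
#'
#' @param cohort A cohort tibble from [simulate_registry()] or
#'   [simulate_trio_cohort()].
#' @return The [liability_params()] object used to generate it (or `NULL`).
#' @export
cohort_params <- function(cohort) attr(cohort, "params")
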