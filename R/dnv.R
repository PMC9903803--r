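variant_classes <- c("PTV", "missense", "CNV-del", "CNV-dup", "other")

validate_variants <- function(variants) {
  need <- c("iid", "gene", "class", "pli", "mpc", "constrained_genes_hit",
            "de_novo")
  missing <- setdiff(need, names(variants))
  if (length(missing)) {
    abort(paste0("Variant table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!all(variants$class %in% variant_classes)) {
    abort(paste0("Variant class must be one of: ",
                 paste(variant_classes, collapse = ", ")))
  }
  if (any(!is.na(variants$pli) & (variants$pli < 0 | variants$pli > 1))) {
    abort("pLI must lie in [0, 1].")
  }
  is_mis <- variants$class == "missense"
  if (any(!is.na(variants$mpc) & !is_mis)) {
    abort("Malformed record: MPC is defined for missense variants only.")
  }
  if (any(!is.na(variants$mpc) & variants$mpc < 0)) {
    abort("MPC must be nonnegative.")
  }
  is_cnv <- variants$class %in% c("CNV-del", "CNV-dup")
  if (any(!is.na(variants$constrained_genes_hit) & !is_cnv)) {
    abort("Malformed record: constrained_genes_hit is defined for CNVs only.")
  }
  invisible(variants)
}

#' Classify high-impact de novo variants
#'
#' A de novo variant is high impact when it falls in one of three classes:
#' a protein-truncating variant in a loss-of-function-intolerant gene
#' (pLI strictly greater than 0.9), a copy-number deletion or duplication
#' affecting at least one constrained gene, or a missense variant with an
#' MPC score of at least 2. Inherited variants never qualify.
#'
#' @param variants Tibble with columns `iid`, `gene`, `class` (one of
#'   `"PTV"`, `"missense"`, `"CNV-del"`, `"CNV-dup"`, `"other"`), `pli`,
#'   `mpc` (missense only), `constrained_genes_hit` (CNV only), `de_novo`.
#' @return Logical vector, one element per record.
#' @examples
#' v <- tibble::tibble(iid = "s1", gene = "SCN2A", class = "PTV", pli = 0.95,
#'                     mpc = NA, constrained_genes_hit = NA, de_novo = TRUE)
#' is_high_impact(v)
#' @export
is_high_impact <- function(variants) {
  validate_variants(variants)
  ptv_hit <- variants$class == "PTV" &
    !is.na(variants$pli) & variants$pli > 0.9
  cnv_hit <- variants$class %in% c("CNV-del", "CNV-dup") &
    !is.na(variants$constrained_genes_hit) & variants$constrained_genes_hit >= 1
  mis_hit <- variants$class == "missense" &
    !is.na(variants$mpc) & variants$mpc >= 2
  variants$de_novo & (ptv_hit | cnv_hit | mis_hit)
}

#' Flag carriers of at least one high-impact de novo variant
#'
#' @param variants Variant tibble (see [is_high_impact()]).
#' @param samples Vector of unique sample ids to flag; samples with no
#'   qualifying record are non-carriers.
#' @return Tibble with columns `iid`, `carrier`.
#' @export
flag_carriers <- function(variants, samples) {
  if (anyDuplicated(samples)) abort("Sample ids must be unique.")
  hits <- unique(variants$iid[is_high_impact(variants)])
  tibble::tibble(iid = samples, carrier = samples %in% hits)
}
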