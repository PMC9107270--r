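# Molecular subtyping, clonal-origin classification and clonal-fraction
# estimation.
#
# Subtype rule: a tumor with a somatic NF2 mutation and/or a chromosome 22
# deletion is "NF2-loss"; tumors driven by other genes are "non-NF2".
#
# Clonality rule: a patient's tumors are called monoclonal when at least one
# driver feature is shared by every lesion — an identical panel-gene
# SNV/INDEL (same chrom, pos, ref, alt) or a shared CNV/LOH event under the
# reciprocal-overlap rule. Otherwise the tumors are independent.

#' Classify the molecular subtype of one lesion
#'
#' @param profile A prepared lesion profile (filtered variants and called
#'   events, see [prepare_case()]).
#' @param panel Driver gene panel, see [driver_panel()].
#' @return A list with `lesion_id`, `subtype` (`"NF2_loss"` or
#'   `"non_NF2"`) and `evidence` (feature keys supporting the call).
#' @export
classify_subtype <- function(profile, panel = driver_panel()) {
  stopifnot(inherits(profile, "mm_lesion"))
  if (is.null(profile$events)) {
    stop("profile not prepared: run prepare_case() first")
  }
  v <- profile$variants
  nf2_snv <- v[v$gene == "NF2", , drop = FALSE]
  ev <- profile$events
  chr22_del <- ev[ev$kind == "deletion" & ev$chrom == "22", , drop = FALSE]
  evidence <- c(
    if (nrow(nf2_snv) > 0) paste0("SNV:NF2:", variant_key(nf2_snv)),
    if (nrow(chr22_del) > 0) paste0("CNV:deletion:", chr22_del$label)
  )
  list(
    lesion_id = profile$lesion_id,
    subtype = if (length(evidence) > 0) "NF2_loss" else "non_NF2",
    evidence = as.character(evidence)
  )
}

#' Classify a patient's tumors as monoclonal or of independent origin
#'
#' @param case A prepared `mm_case` with at least two lesions.
#' @param panel Driver gene panel for SNV driver features.
#' @param min_shared_drivers Minimum number of driver features that must be
#'   shared by every lesion for a monoclonal verdict (default 1).
#' @param overlap_fraction Reciprocal-overlap fraction for CNV feature
#'   matching.
#' @return A list with `patient_id`, `verdict` (`"monoclonal"` or
#'   `"independent"`) and `shared_driver_evidence` (feature keys).
#' @export
classify_patient_clonality <- function(case, panel = driver_panel(),
                                       min_shared_drivers = 1,
                                       overlap_fraction = 0.5) {
  stopifnot(inherits(case, "mm_case"))
  if (length(case$lesions) < 2) {
    stop("clonality classification needs at least 2 lesions")
  }
  part <- shared_private_partition(case, overlap_fraction)
  shared <- part$shared_by_all
  is_driver <- vapply(shared, function(k) {
    if (startsWith(k, "CNV:")) return(TRUE)
    gene <- strsplit(k, ":", fixed = TRUE)[[1]][2]
    gene %in% panel
  }, logical(1))
  evidence <- shared[is_driver]
  list(
    patient_id = case$patient_id,
    verdict = if (length(evidence) >= min_shared_drivers) "monoclonal"
              else "independent",
    shared_driver_evidence = as.character(evidence)
  )
}

#' Clonal fraction from a variant allele fraction
#'
#' Inverts the expected-VAF model of [expected_vaf()]: for a heterozygous
#' mutation at a diploid locus `c = 2 * vaf`; for a mutation on the retained
#' duplicated allele of a copy-neutral LOH region `c = vaf`; for a mutation
#' on the single retained copy of a hemizygous region `c = 2 vaf / (1 + vaf)`.
#' Results are clipped to `[0, 1]`.
#'
#' @param vaf Variant allele fraction in `[0, 1]`.
#' @param copy_state `"het_diploid"`, `"hemizygous"` or `"cn_loh"`.
#' @param male_x Set `TRUE` for a chrX variant in a male patient: the locus
#'   is single-copy so the hemizygous model is forced.
#' @return Estimated clonal fraction in `[0, 1]`.
#' @export
clonal_fraction_from_vaf <- function(vaf,
                                     copy_state = c("het_diploid",
                                                    "hemizygous", "cn_loh"),
                                     male_x = FALSE) {
  copy_state <- match.arg(copy_state)
  if (any(is.na(vaf)) || any(vaf < 0) || any(vaf > 1)) {
    stop("vaf must lie in [0, 1]")
  }
  if (male_x) copy_state <- "hemizygous"
  c_hat <- switch(copy_state,
    het_diploid = 2 * vaf,
    cn_loh = vaf,
    hemizygous = 2 * vaf / (1 + vaf)
  )
  pmin(pmax(c_hat, 0), 1)
}

#' Clonal fraction from the minor-allele fraction of an LOH segment
#'
#' Under the copy-neutral allelic-imbalance model a clone fraction `c` with
#' one lost parental allele leaves a minor-allele fraction
#' `maf = (1 - c) / 2`, hence `c = 1 - 2 maf` (the default). Under the
#' hemizygous-deletion model the lost allele also lowers total copy number,
#' giving `maf = (1 - c) / (2 - c)` and `c = (1 - 2 maf) / (1 - maf)`.
#'
#' @param maf Minor-allele fraction in `[0, 0.5]`.
#' @param model `"cn_loh"` (default) or `"deletion"`.
#' @return Estimated clonal fraction in `[0, 1]`.
#' @export
clonal_fraction_from_maf <- function(maf, model = c("cn_loh", "deletion")) {
  model <- match.arg(model)
  if (any(is.na(maf)) || any(maf < 0) || any(maf > 0.5)) {
    stop("maf must lie in [0, 0.5]")
  }
  c_hat <- switch(model,
    cn_loh = 1 - 2 * maf,
    deletion = (1 - 2 * maf) / (1 - maf)
  )
  pmin(pmax(c_hat, 0), 1)
}

#' Compare SNV- and LOH-derived clonal fractions per lesion
#'
#' For each lesion the clonal fraction is estimated twice: from the
#' minor-allele fraction of its called LOH event(s) and from the VAF of its
#' panel-gene mutation(s). Agreement of the two estimates within the
#' tolerance supports a single clone carrying both events.
#'
#' @param case A prepared `mm_case`.
#' @param panel Driver gene panel.
#' @param tolerance Absolute agreement tolerance (default 0.10).
#' @param maf_model MAF-to-clonality model, see [clonal_fraction_from_maf()].
#' @return A `data.frame` with one row per (lesion, event/mutation pairing):
#'   `lesion_id`, `loh_event`, `maf`, `cf_from_maf`, `snv`, `vaf`,
#'   `cf_from_vaf`, `concordant`. Missing halves are `NA` with
#'   `concordant = NA`.
#' @export
compare_event_clonality <- function(case, panel = driver_panel(),
                                    tolerance = 0.10,
                                    maf_model = c("cn_loh", "deletion")) {
  stopifnot(inherits(case, "mm_case"))
  maf_model <- match.arg(maf_model)
  rows <- list()
  for (l in case$lesions) {
    if (is.null(l$events)) stop("case not prepared: run prepare_case() first")
    loh <- l$events[l$events$kind == "loh" & !is.na(l$events$maf), ,
                    drop = FALSE]
    snv <- restrict_to_driver_panel(l$variants, panel)
    n <- max(nrow(loh), nrow(snv), 1)
    for (i in seq_len(n)) {
      maf <- if (i <= nrow(loh)) loh$maf[i] else NA_real_
      vaf <- if (i <= nrow(snv)) snv$vaf[i] else NA_real_
      cf_maf <- if (is.na(maf)) NA_real_ else
        clonal_fraction_from_maf(maf, maf_model)
      cf_vaf <- if (is.na(vaf)) NA_real_ else
        clonal_fraction_from_vaf(vaf, "het_diploid")
      rows[[length(rows) + 1]] <- data.frame(
        lesion_id = l$lesion_id,
        loh_event = if (i <= nrow(loh))
          paste0("CNV:loh:", loh$label[i]) else NA_character_,
        maf = maf, cf_from_maf = cf_maf,
        snv = if (i <= nrow(snv))
          paste0("SNV:", snv$gene[i], ":", variant_key(snv)[i])
          else NA_character_,
        vaf = vaf, cf_from_vaf = cf_vaf,
        concordant = if (is.na(cf_maf) || is.na(cf_vaf)) NA else
          abs(cf_maf - cf_vaf) <= tolerance,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
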