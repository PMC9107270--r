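# Somatic variant tables and post-calling filters.
#
# A variant table is a plain data.frame with one row per somatic SNV/INDEL
# call in one lesion. Columns: chrom, pos (1-based), ref, alt, gene,
# consequence, vaf, gnomad_af (NA when the variant is absent from gnomAD),
# lesion_id. Variant identity across lesions is keyed by
# (chrom, pos, ref, alt) only: annotation differences never split identity.

.variant_cols <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                   "vaf", "gnomad_af", "lesion_id")

#' Construct a somatic variant table
#'
#' @param chrom,pos,ref,alt Variant locus and alleles (`pos` is 1-based).
#' @param gene Gene symbol.
#' @param consequence Coding consequence term, see [functional_consequences()].
#' @param vaf Variant allele fraction in `[0, 1]`.
#' @param gnomad_af Population allele frequency in gnomAD, `NA` if absent.
#' @param lesion_id Lesion identifier.
#' @return A validated variant `data.frame`.
#' @export
somatic_variants <- function(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             gene = character(), consequence = character(),
                             vaf = numeric(), gnomad_af = NA_real_,
                             lesion_id = character()) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    gene = as.character(gene),
    consequence = as.character(consequence),
    vaf = as.numeric(vaf),
    gnomad_af = rep_len(as.numeric(gnomad_af), n),
    lesion_id = rep_len(as.character(lesion_id), n),
    stringsAsFactors = FALSE
  )
  validate_variants(df)
}

#' Validate a somatic variant table
#'
#' Checks the column set, 1-based positions, distinct ref/alt alleles, VAF
#' range and per-lesion uniqueness of the (chrom, pos, ref, alt) key.
#'
#' @param variants A variant `data.frame`.
#' @return The input, invisibly unchanged, for chaining.
#' @export
validate_variants <- function(variants) {
  missing_cols <- setdiff(.variant_cols, names(variants))
  if (length(missing_cols) > 0) {
    stop("variant table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(variants) == 0) return(variants)
  bad <- which(is.na(variants$pos) | variants$pos < 1)
  if (length(bad) > 0) {
    stop("invalid position (must be >= 1, 1-based) at row(s): ",
         paste(bad, collapse = ", "))
  }
  bad <- which(variants$ref == variants$alt)
  if (length(bad) > 0) {
    stop("ref equals alt at row(s): ", paste(bad, collapse = ", "))
  }
  bad <- which(is.na(variants$vaf) | variants$vaf < 0 | variants$vaf > 1)
  if (length(bad) > 0) {
    stop("vaf outside [0, 1] at row(s): ", paste(bad, collapse = ", "))
  }
  bad <- which(!is.na(variants$gnomad_af) &
                 (variants$gnomad_af < 0 | variants$gnomad_af > 1))
  if (length(bad) > 0) {
    stop("gnomad_af outside [0, 1] at row(s): ", paste(bad, collapse = ", "))
  }
  key <- paste(variants$lesion_id, variant_key(variants))
  if (anyDuplicated(key)) {
    stop("duplicated (chrom, pos, ref, alt) key within a lesion at row(s): ",
         paste(which(duplicated(key)), collapse = ", "))
  }
  variants
}

#' Variant identity keys
#'
#' Identity of a variant across lesions is `chrom:pos:ref>alt`; the gene and
#' consequence annotation play no part in it.
#'
#' @param variants A variant `data.frame`.
#' @return Character vector of keys, one per row.
#' @export
variant_key <- function(variants) {
  if (nrow(variants) == 0) return(character())
  paste0(variants$chrom, ":", variants$pos, ":",
         variants$ref, ">", variants$alt)
}

#' Read a tab-delimited somatic variant table
#'
#' Expects a header row with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#' `consequence`, `vaf`, `gnomad_af`. Empty or `NA` `gnomad_af` fields are
#' parsed as missing (the variant is absent from the population database),
#' never as zero.
#'
#' @param path Path to the file.
#' @param lesion_id Lesion identifier to attach; defaults to the file name
#'   without extension when the table has no `lesion_id` column.
#' @return A validated variant `data.frame`.
#' @export
read_variant_table <- function(path, lesion_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          na.strings = c("NA", ""))
  required <- setdiff(.variant_cols, "lesion_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("malformed variant table ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  parse_num <- function(x, what) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      # +1 for the header row so the number matches the file line
      stop("malformed ", what, " in ", path, " at line(s): ",
           paste(bad + 1L, collapse = ", "))
    }
    out
  }
  pos <- parse_num(df$pos, "pos")
  if (any(is.na(pos))) {
    stop("malformed pos in ", path, " at line(s): ",
         paste(which(is.na(pos)) + 1L, collapse = ", "))
  }
  if (is.null(lesion_id)) {
    lesion_id <- if ("lesion_id" %in% names(df) && nrow(df) > 0) {
      df$lesion_id
    } else {
      sub("\\.[^.]*$", "", basename(path))
    }
  }
  somatic_variants(
    chrom = df$chrom, pos = pos, ref = df$ref, alt = df$alt,
    gene = df$gene, consequence = df$consequence,
    vaf = parse_num(df$vaf, "vaf"),
    gnomad_af = parse_num(df$gnomad_af, "gnomad_af"),
    lesion_id = lesion_id
  )
}

#' Write a somatic variant table
#'
#' Inverse of [read_variant_table()]; missing `gnomad_af` is written as `NA`.
#'
#' @param variants A variant `data.frame`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  validate_variants(variants)
  utils::write.table(variants[, .variant_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Consequence terms counted as functional coding impacts
#'
#' The default set kept by [filter_functional_impact()]: protein-altering
#' coding changes. Synonymous, intronic and UTR changes are excluded.
#'
#' @return Character vector of consequence terms.
#' @export
functional_consequences <- function() {
  c("missense", "nonsense", "frameshift", "inframe_indel",
    "splice_site", "start_loss", "stop_loss")
}

.known_consequences <- function() {
  c(functional_consequences(),
    "synonymous", "intronic", "utr_3", "utr_5", "upstream", "downstream",
    "intergenic", "noncoding")
}

#' Filter on population allele frequency
#'
#' Removes variants with a population allele frequency strictly greater than
#' the threshold; variants at exactly the threshold are kept, and variants
#' absent from the population database (missing `gnomad_af`) are always kept.
#'
#' @param variants A variant `data.frame`.
#' @param threshold Maximum allowed population AF (default 0.01).
#' @return The filtered table, row order preserved.
#' @export
filter_population_af <- function(variants, threshold = 0.01) {
  validate_variants(variants)
  keep <- is.na(variants$gnomad_af) | variants$gnomad_af <= threshold
  variants[keep, , drop = FALSE]
}

#' Filter on functional coding impact
#'
#' Keeps variants whose consequence term is in the impactful set. Terms not
#' in the controlled vocabulary trigger a warning and are excluded.
#'
#' @param variants A variant `data.frame`.
#' @param impactful Non-empty set of consequence terms to keep; defaults to
#'   [functional_consequences()].
#' @return The filtered table, row order preserved.
#' @export
filter_functional_impact <- function(variants,
                                     impactful = functional_consequences()) {
  if (length(impactful) == 0) stop("impactful consequence set must be non-empty")
  validate_variants(variants)
  unknown <- setdiff(unique(variants$consequence),
                     union(.known_consequences(), impactful))
  if (length(unknown) > 0) {
    warning("unknown consequence term(s) excluded: ",
            paste(unknown, collapse = ", "))
  }
  variants[variants$consequence %in% impactful, , drop = FALSE]
}

#' Filter on estimated cross-sample contamination
#'
#' Removes variants whose VAF is strictly below the estimated contamination
#' rate; variants at exactly the rate are kept.
#'
#' @param variants A variant `data.frame`.
#' @param contamination_rate Estimated contamination fraction in `[0, 1]`.
#' @return The filtered table, row order preserved.
#' @export
filter_contamination <- function(variants, contamination_rate) {
  stopifnot(length(contamination_rate) == 1,
            contamination_rate >= 0, contamination_rate <= 1)
  validate_variants(variants)
  variants[variants$vaf >= contamination_rate, , drop = FALSE]
}

#' Restrict variants to the driver gene panel
#'
#' @param variants A variant `data.frame`.
#' @param panel Non-empty character vector of gene symbols; defaults to
#'   [driver_panel()].
#' @return The filtered table, row order preserved.
#' @export
restrict_to_driver_panel <- function(variants, panel = driver_panel()) {
  if (length(panel) == 0) stop("driver panel must be non-empty")
  if (anyDuplicated(panel)) stop("driver panel symbols must be unique")
  validate_variants(variants)
  variants[variants$gene %in% panel, , drop = FALSE]
}
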