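# GRCh37 chromosome arm coordinates.
#
# Arm boundaries are taken from the UCSC hg19 centromere gap track: the p arm
# runs from the start of the chromosome to the start of the centromeric gap,
# the q arm from the end of the gap to the chromosome end. Coordinates are
# stored in the package's internal convention, 0-based half-open.

.grch37 <- local({
  # chrom, length, gap start, gap end (0-based)
  tab <- rbind(
    c("1",  249250621L, 121535434L, 124535434L),
    c("2",  243199373L,  92326171L,  95326171L),
    c("3",  198022430L,  90504854L,  93504854L),
    c("4",  191154276L,  49660117L,  52660117L),
    c("5",  180915260L,  46405641L,  49405641L),
    c("6",  171115067L,  58830166L,  61830166L),
    c("7",  159138663L,  58054331L,  61054331L),
    c("8",  146364022L,  43838887L,  46838887L),
    c("9",  141213431L,  47367679L,  50367679L),
    c("10", 135534747L,  39254935L,  42254935L),
    c("11", 135006516L,  51644205L,  54644205L),
    c("12", 133851895L,  34856694L,  37856694L),
    c("13", 115169878L,  16000000L,  19000000L),
    c("14", 107349540L,  16000000L,  19000000L),
    c("15", 102531392L,  17000000L,  20000000L),
    c("16",  90354753L,  35335801L,  38335801L),
    c("17",  81195210L,  22263006L,  25263006L),
    c("18",  78077248L,  15460898L,  18460898L),
    c("19",  59128983L,  24681782L,  27681782L),
    c("20",  63025520L,  26369569L,  29369569L),
    c("21",  48129895L,  11288129L,  14288129L),
    c("22",  51304566L,  13000000L,  16000000L),
    c("X",  155270560L,  58632012L,  61632012L)
  )
  data.frame(
    chrom = tab[, 1],
    length = as.numeric(tab[, 2]),
    cen_start = as.numeric(tab[, 3]),
    cen_end = as.numeric(tab[, 4]),
    stringsAsFactors = FALSE
  )
})

#' Chromosome arm coordinate table (GRCh37)
#'
#' Returns one row per chromosome arm with 0-based half-open coordinates.
#' The p arm spans from position 0 to the start of the centromeric gap, the
#' q arm from the end of the gap to the chromosome end.
#'
#' @param chroms Character vector of chromosome names to include (without the
#'   `"chr"` prefix). Defaults to all autosomes plus X.
#' @return A `data.frame` with columns `chrom`, `arm` (e.g. `"22q"`),
#'   `start`, `end` and `chrom_length`.
#' @export
grch37_arms <- function(chroms = .grch37$chrom) {
  unknown <- setdiff(chroms, .grch37$chrom)
  if (length(unknown) > 0) {
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  g <- .grch37[.grch37$chrom %in% chroms, , drop = FALSE]
  out <- rbind(
    data.frame(chrom = g$chrom, arm = paste0(g$chrom, "p"),
               start = 0, end = g$cen_start, chrom_length = g$length,
               stringsAsFactors = FALSE),
    data.frame(chrom = g$chrom, arm = paste0(g$chrom, "q"),
               start = g$cen_end, end = g$length, chrom_length = g$length,
               stringsAsFactors = FALSE)
  )
  out <- out[order(match(out$chrom, .grch37$chrom), out$arm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chromosome lengths (GRCh37)
#'
#' @param chroms Chromosome names; defaults to all autosomes plus X.
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
grch37_chrom_lengths <- function(chroms = .grch37$chrom) {
  g <- grch37_arms(chroms)
  len <- tapply(g$chrom_length, g$chrom, unique)
  out <- as.numeric(len[chroms])
  names(out) <- chroms
  out
}

# Approximate GRCh37 start coordinates of the meningioma driver genes, used
# by the simulator to place driver SNVs at plausible loci. Positions need
# only be inside the right chromosome band, not transcript-accurate.
.panel_gene_loci <- data.frame(
  gene = c("NF2", "TRAF7", "AKT1", "KLF4", "PIK3CA", "PIK3R1",
           "SMO", "SUFU", "POLR2A", "SMARCB1", "PRKAR1A"),
  chrom = c("22", "16", "14", "9", "3", "5",
            "7", "10", "17", "22", "17"),
  pos = c(29999545, 2199564, 105235686, 110247133, 178916614, 67584251,
          128828713, 104263744, 7389357, 24129150, 66507921),
  stringsAsFactors = FALSE
)

#' Meningioma driver gene panel
#'
#' The set of genes recurrently mutated in meningioma that is used to
#' restrict SNV/INDEL features for phylogeny reconstruction and to identify
#' shared driver mutations for clonality assessment.
#'
#' @return Character vector of gene symbols.
#' @export
driver_panel <- function() {
  .panel_gene_loci$gene
}

#' Genomic coordinates of the driver panel genes
#'
#' @return A `data.frame` with columns `gene`, `chrom` and `pos` (1-based
#'   representative position on GRCh37).
#' @export
driver_panel_loci <- function() {
  .panel_gene_loci
}
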