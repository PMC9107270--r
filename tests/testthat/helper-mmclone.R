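# Shared fixtures for the test suite: tiny constructed tables and cases.

# a small well-formed variant table
mk_variants <- function(lesion = "L1", n = 3, seed = 1) {
  set.seed(seed)
  somatic_variants(
    chrom = sample(c("1", "2", "22"), n, replace = TRUE),
    pos = sample.int(1e6, n),
    ref = rep("A", n), alt = rep("G", n),
    gene = paste0("GENE", seq_len(n)),
    consequence = sample(c("missense", "synonymous", "nonsense"), n,
                         replace = TRUE),
    vaf = round(runif(n, 0.05, 0.6), 3),
    gnomad_af = ifelse(runif(n) < 0.5, NA, round(runif(n, 0, 0.05), 4)),
    lesion_id = lesion
  )
}

# whole-chromosome / arm segment in one call
mk_seg <- function(lesion, label, log2 = -0.5, maf = 0.2) {
  arms <- grch37_arms()
  if (label %in% arms$chrom) {
    a <- arms[arms$chrom == label, ]
    cnv_segments(chrom = label, start = 0, end = a$chrom_length[1],
                 log2_copy_ratio = log2, maf = maf, lesion_id = lesion)
  } else {
    a <- arms[arms$arm == label, ]
    cnv_segments(chrom = a$chrom, start = a$start, end = a$end,
                 log2_copy_ratio = log2, maf = maf, lesion_id = lesion)
  }
}

# prepared two-lesion case with configurable shared / private alterations
mk_case <- function(patient = "P1",
                    shared_snv = NULL, private_genes = NULL,
                    shared_seg_label = NULL, seg_kind_log2 = -0.6) {
  loci <- driver_panel_loci()
  lesions <- lapply(1:2, function(i) {
    lid <- paste0(patient, "-T", i)
    v <- somatic_variants()
    if (!is.null(shared_snv)) {
      g <- loci[loci$gene == shared_snv, ]
      v <- rbind(v, somatic_variants(g$chrom, g$pos + 100, "C", "T",
                                     shared_snv, "missense", 0.4, NA, lid))
    }
    if (!is.null(private_genes)) {
      g <- loci[loci$gene == private_genes[i], ]
      v <- rbind(v, somatic_variants(g$chrom, g$pos + 100 + i, "G", "A",
                                     private_genes[i], "missense", 0.4,
                                     NA, lid))
    }
    s <- if (!is.null(shared_seg_label)) {
      mk_seg(lid, shared_seg_label, log2 = seg_kind_log2, maf = 0.2)
    } else {
      mk_seg(lid, "7", log2 = 0, maf = 0.5)
    }
    lesion_profile(lid, v, s)
  })
  prepare_case(patient_case(patient, lesions))
}

prepared_fixture <- function() {
  lapply(build_inpaper_fixture(), prepare_case)
}
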