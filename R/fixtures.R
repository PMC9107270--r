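# Built-in six-patient cohort fixture.
#
# Encodes, per tumor, the somatic alterations reported for the six
# multiple-meningioma patients S1-S6 (15 tumors plus one uninvolved dura
# specimen): driver SNV/INDELs with their genes and, where reported, exact
# VAFs, and arm/chromosome-level CNV and LOH events with, where reported,
# exact minor-allele fractions. Coordinates are representative GRCh37
# positions inside the named genes; unreported VAFs and copy-ratio depths
# are plausible placeholders and are not used by any published-number
# check.

.fx_lens <- function() grch37_chrom_lengths()

# one SNV row
.fx_snv <- function(lesion, gene, chrom, pos, ref, alt,
                    consequence = "missense", vaf = 0.45) {
  somatic_variants(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   gene = gene, consequence = consequence, vaf = vaf,
                   gnomad_af = NA_real_, lesion_id = lesion)
}

# one whole-chromosome or arm-level segment row
.fx_seg <- function(lesion, label, log2 = -0.5, maf = 0.2) {
  iv <- .label_interval(label, grch37_arms())
  cnv_segments(chrom = iv$chrom, start = iv$start, end = iv$end,
               log2_copy_ratio = log2, maf = maf, lesion_id = lesion)
}

.fx_bind <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, nrow, integer(1)) > 0]
  if (length(parts) == 0) return(NULL)
  do.call(rbind, parts)
}

#' Built-in six-patient multiple-meningioma cohort
#'
#' Returns the six patient cases (15 tumors, plus the uninvolved dura
#' control of patient S1) with the alteration structure of the cohort:
#'
#' * **S1** - five tumors, all sharing the same `NF2` mutation and a
#'   chromosome 22 deletion; S1-T5 additionally carries `SMARCB1` p.R377H
#'   and CNV events on chromosomes 8 and 18. The dura specimen carries no
#'   meningioma-associated alteration.
#' * **S2** - two tumors sharing an `NF2` mutation and deletions of 1p, 2
#'   and 22; S2-T1 additionally `TRAF7` p.G560D, S2-T2 additional CNV
#'   events on chromosomes 8 and 15.
#' * **S3** - two tumors sharing the same multi-chromosome CNV profile
#'   including the chromosome 22 deletion; no panel SNV.
#' * **S4** - two tumors sharing a chromosome 22 deletion but carrying two
#'   distinct `NF2` mutations (p.Q410X and p.F62fs); S4-T1 additionally a
#'   1p deletion.
#' * **S5** - two tumors sharing a chromosome X LOH segment (minor-allele
#'   fraction 0.30 and 0.11) but carrying two distinct `TRAF7` mutations
#'   (p.N520S at VAF 0.22 and p.I634S at VAF 0.40).
#' * **S6** - two tumors with completely distinct profiles: one `TRAF7`-
#'   and one `POLR2A`-mutant tumor, nothing shared.
#'
#' @return Named list of six unprepared [patient_case()] objects.
#' @export
build_inpaper_fixture <- function() {
  neutral <- function(lesion) .fx_seg(lesion, "7", log2 = 0, maf = 0.5)

  # ---- S1: 5 lesions + dura -------------------------------------------
  s1_nf2 <- function(lid) .fx_snv(lid, "NF2", "22", 30050000, "C", "T",
                                  "nonsense", vaf = 0.55)
  s1_lesions <- lapply(sprintf("S1-T%d", 1:5), function(lid) {
    variants <- s1_nf2(lid)
    segments <- .fx_bind(.fx_seg(lid, "22", -0.6, 0.15), neutral(lid))
    if (lid == "S1-T5") {
      variants <- rbind(variants,
                        .fx_snv(lid, "SMARCB1", "22", 24175000, "G", "A",
                                "missense", vaf = 0.45))
      segments <- .fx_bind(segments,
                           .fx_seg(lid, "8", -0.4, 0.25),
                           .fx_seg(lid, "18", -0.4, 0.25))
    }
    lesion_profile(lid, validate_variants(variants),
                   validate_segments(segments))
  })
  s1_dura <- lesion_profile("S1-dura", somatic_variants(),
                            neutral("S1-dura"))
  s1 <- patient_case("S1", s1_lesions, normal = s1_dura)

  # ---- S2: 2 lesions ---------------------------------------------------
  s2_shared_snv <- function(lid) .fx_snv(lid, "NF2", "22", 30060000, "G",
                                         "A", "nonsense", vaf = 0.60)
  s2_shared_seg <- function(lid) .fx_bind(
    .fx_seg(lid, "1p", -0.5, 0.2),
    .fx_seg(lid, "2", -0.5, 0.2),
    .fx_seg(lid, "22", -0.6, 0.15))
  s2 <- patient_case("S2", list(
    lesion_profile("S2-T1",
                   rbind(s2_shared_snv("S2-T1"),
                         .fx_snv("S2-T1", "TRAF7", "16", 2220000, "G", "A",
                                 "missense", vaf = 0.35)),
                   s2_shared_seg("S2-T1")),
    lesion_profile("S2-T2", s2_shared_snv("S2-T2"),
                   .fx_bind(s2_shared_seg("S2-T2"),
                            .fx_seg("S2-T2", "8", -0.4, 0.25),
                            .fx_seg("S2-T2", "15", -0.4, 0.25)))
  ))

  # ---- S3: 2 lesions, shared CNVs only ---------------------------------
  s3_seg <- function(lid) .fx_bind(
    .fx_seg(lid, "1p", -0.5, 0.2),
    .fx_seg(lid, "2", -0.5, 0.2),
    .fx_seg(lid, "22", -0.6, 0.15))
  s3 <- patient_case("S3", list(
    lesion_profile("S3-T1", somatic_variants(), s3_seg("S3-T1")),
    lesion_profile("S3-T2", somatic_variants(), s3_seg("S3-T2"))
  ))

  # ---- S4: shared chr22 del, distinct NF2 mutations --------------------
  s4 <- patient_case("S4", list(
    lesion_profile("S4-T1",
                   .fx_snv("S4-T1", "NF2", "22", 30077000, "C", "T",
                           "nonsense", vaf = 0.50),  # p.Q410X
                   .fx_bind(.fx_seg("S4-T1", "22", -0.6, 0.15),
                            .fx_seg("S4-T1", "1p", -0.5, 0.2))),
    lesion_profile("S4-T2",
                   .fx_snv("S4-T2", "NF2", "22", 30003000, "CT", "C",
                           "frameshift", vaf = 0.50),  # p.F62fs
                   .fx_seg("S4-T2", "22", -0.6, 0.15))
  ))

  # ---- S5: shared chrX LOH, distinct TRAF7 mutations -------------------
  s5 <- patient_case("S5", list(
    lesion_profile("S5-T1",
                   .fx_snv("S5-T1", "TRAF7", "16", 2216000, "A", "G",
                           "missense", vaf = 0.22),  # p.N520S
                   .fx_bind(.fx_seg("S5-T1", "X", 0, 0.30),
                            neutral("S5-T1"))),
    lesion_profile("S5-T2",
                   .fx_snv("S5-T2", "TRAF7", "16", 2224000, "T", "G",
                           "missense", vaf = 0.40),  # p.I634S
                   .fx_bind(.fx_seg("S5-T2", "X", 0, 0.11),
                            neutral("S5-T2")))
  ), sex = "female")

  # ---- S6: completely distinct profiles --------------------------------
  s6 <- patient_case("S6", list(
    lesion_profile("S6-T1",
                   .fx_snv("S6-T1", "POLR2A", "17", 7400000, "G", "A",
                           "missense", vaf = 0.38),
                   neutral("S6-T1")),
    lesion_profile("S6-T2",
                   .fx_snv("S6-T2", "TRAF7", "16", 2218000, "C", "T",
                           "missense", vaf = 0.42),
                   neutral("S6-T2"))
  ))

  list(S1 = s1, S2 = s2, S3 = s3, S4 = s4, S5 = s5, S6 = s6)
}
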