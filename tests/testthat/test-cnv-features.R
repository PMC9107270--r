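# Segment I/O, arm-level event calling and shared-segment algebra.

test_that("SEG coordinates convert to 0-based half-open and back", {
  path <- withr::local_tempfile(fileext = ".seg")
  writeLines(c(
    "sample\tchrom\tstart\tend\tlog2_copy_ratio\tmaf",
    "L1\t22\t1\t100\t-0.5\t0.2"
  ), path)
  seg <- read_segments(path)
  expect_equal(seg$start, 0)
  expect_equal(seg$end, 100)
  expect_equal(seg$end - seg$start, 100)

  out <- withr::local_tempfile(fileext = ".seg")
  write_segments(seg, out)
  expect_equal(read_segments(out), seg, ignore_attr = TRUE)
})

test_that("overlapping segments within one lesion are rejected", {
  expect_error(
    cnv_segments(chrom = c("1", "1"), start = c(0, 50), end = c(100, 150),
                 log2_copy_ratio = 0, maf = 0.5, lesion_id = "L1"),
    "partition"
  )
  # same interval in different lesions is fine
  expect_silent(
    cnv_segments(chrom = c("1", "1"), start = c(0, 0), end = c(100, 100),
                 log2_copy_ratio = 0, maf = 0.5,
                 lesion_id = c("L1", "L2"))
  )
})

test_that("shared-segment intersection matches interval arithmetic", {
  del <- function(lesion, start, end) {
    cnv_segments("22", start, end, -0.8, 0.1, lesion)
  }
  is_del <- function(seg) seg$log2_copy_ratio <= -0.3
  shared <- intersect_shared_segments(
    list(A = del("A", 0, 30e6), B = del("B", 10e6, 50e6)), is_del)
  expect_equal(shared$start, 10e6)
  expect_equal(shared$end, 30e6)

  # identical segments in every lesion come back unchanged
  same <- intersect_shared_segments(
    list(A = del("A", 5e6, 9e6), B = del("B", 5e6, 9e6)), is_del)
  expect_equal(same$start, 5e6)
  expect_equal(same$end, 9e6)

  expect_error(intersect_shared_segments(list(A = del("A", 0, 10)), is_del),
               "at least 2")
})

test_that("multi-lesion intersection equals a per-base oracle", {
  # random small deletion segments on a 1 kb toy interval of chr1
  set.seed(11)
  is_del <- function(seg) seg$log2_copy_ratio <= -0.3
  for (rep in 1:10) {
    lesions <- lapply(1:3, function(i) {
      # non-overlapping random intervals per lesion
      cuts <- sort(sample(0:1000, 6))
      pick <- seq(1, 6, by = 2)
      cnv_segments(chrom = "1", start = cuts[pick], end = cuts[pick + 1],
                   log2_copy_ratio = -0.8, maf = 0.2,
                   lesion_id = paste0("L", i))
    })
    names(lesions) <- paste0("L", 1:3)
    ok <- !vapply(lesions, function(s) any(s$start == s$end), logical(1))
    if (!all(ok)) next
    shared <- intersect_shared_segments(lesions, is_del)
    # oracle: per-base coverage count over the toy interval
    base_hit <- rep(TRUE, 1000)
    for (s in lesions) {
      hit <- rep(FALSE, 1000)
      for (k in seq_len(nrow(s))) {
        if (s$end[k] > s$start[k]) hit[(s$start[k] + 1):s$end[k]] <- TRUE
      }
      base_hit <- base_hit & hit
    }
    shared_bases <- rep(FALSE, 1000)
    for (k in seq_len(nrow(shared))) {
      shared_bases[(shared$start[k] + 1):shared$end[k]] <- TRUE
    }
    expect_identical(shared_bases, base_hit)
  }
})

test_that("intersection is commutative and associative over lesions", {
  set.seed(21)
  is_del <- function(seg) seg$log2_copy_ratio <= -0.3
  mk <- function(lesion) {
    cuts <- sort(sample(seq(0, 5e7, by = 1e5), 4))
    cnv_segments("22", cuts[c(1, 3)], cuts[c(2, 4)], -0.8, 0.2, lesion)
  }
  a <- mk("A"); b <- mk("B"); c <- mk("C")
  abc <- intersect_shared_segments(list(A = a, B = b, C = c), is_del)
  cba <- intersect_shared_segments(list(C = c, B = b, A = a), is_del)
  expect_equal(abc, cba)
  # pairwise-then-third equals three-way
  ab <- intersect_shared_segments(list(A = a, B = b), is_del)
  ab_seg <- cnv_segments("22", ab$start, ab$end, -0.8, 0.2, "AB")
  abc2 <- intersect_shared_segments(list(AB = ab_seg, C = c), is_del)
  expect_equal(abc2, abc)
  # shared length never exceeds any single lesion's event length
  for (s in list(a, b, c)) {
    expect_lte(sum(abc$end - abc$start), sum(s$end - s$start))
  }
})

test_that("arm-level events are called at the documented thresholds", {
  # whole chr22 deep deletion -> chromosome-level deletion, fraction 1
  seg <- mk_seg("L1", "22", log2 = -0.8, maf = 0.1)
  ev <- call_events(seg)
  del <- ev[ev$kind == "deletion", ]
  expect_equal(del$label, "22")
  expect_equal(del$covered_fraction, 1.0)

  # chrX LOH from a low minor-allele fraction, irrespective of copy ratio
  seg <- mk_seg("L1", "X", log2 = 0, maf = 0.11)
  ev <- call_events(seg)
  expect_equal(ev$kind, "loh")
  expect_equal(ev$label, "X")

  # neutral genome -> no events
  seg <- mk_seg("L1", "7", log2 = 0, maf = 0.5)
  expect_equal(nrow(call_events(seg)), 0)

  # arm-level granularity: 1p deletion only
  seg <- mk_seg("L1", "1p", log2 = -0.6, maf = 0.2)
  ev <- call_events(seg)
  expect_equal(ev$label[ev$kind == "deletion"], "1p")

  expect_error(call_events(cnv_segments("99", 0, 100, -1, 0.2, "L1")),
               "unknown chromosome")
})

test_that("deepening a deletion never removes the deletion event", {
  set.seed(5)
  for (log2_depth in c(-0.31, -0.5, -1, -2)) {
    ev <- call_events(mk_seg("L1", "22", log2 = log2_depth, maf = 0.2))
    expect_true(any(ev$kind == "deletion" & ev$label == "22"))
  }
})

test_that("shared/private partition matches the cohort structure", {
  fx <- prepared_fixture()

  s6 <- shared_private_partition(fx$S6)
  expect_length(s6$shared_by_all, 0)

  s1 <- shared_private_partition(fx$S1)
  expect_true(any(grepl("^SNV:NF2:", s1$shared_by_all)))
  expect_true("CNV:deletion:22" %in% s1$shared_by_all)
  smarcb1 <- grep("^SNV:SMARCB1:", s1$private, value = TRUE)
  expect_length(smarcb1, 1)
  expect_equal(rownames(s1$presence)[s1$presence[, smarcb1] == 1], "S1-T5")

  # every feature lands in exactly one category
  expect_equal(
    sort(c(s1$shared_by_all, s1$partially_shared, s1$private)),
    sort(colnames(s1$presence))
  )

  # degenerate single-lesion case
  single <- patient_case("P", fx$S1$lesions[1])
  expect_warning(part <- shared_private_partition(single), "single-lesion")
  expect_length(part$private, 0)
})
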