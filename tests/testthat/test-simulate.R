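# Synthetic multi-lesion call sets and their ground truth.

test_that("simulation is deterministic given (config, patient index)", {
  cfg <- simulation_config(seed = 17)
  a <- simulate_patient(cfg, 2)
  b <- simulate_patient(cfg, 2)
  expect_identical(a, b)
  # different substreams differ
  c <- simulate_patient(cfg, 3)
  expect_false(identical(a$case, c$case))
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(lesions_per_patient = 1), ">= 2")
  expect_error(simulation_config(clonal_fraction_range = c(0, 1)), "lo")
  expect_error(simulation_config(clonal_fraction_range = c(0.9, 0.5)), "lo")
  expect_error(simulation_config(sequencing_depth = 0), "depth")
  expect_error(simulation_config(scenario = "polyclonal"), "arg")
  expect_error(
    simulation_config(truncal_cnv_events = list(list(label = "22",
                                                     kind = "gain"))),
    "kind")
})

test_that("independent scenario shares no truncal features", {
  cfg <- simulation_config(scenario = "independent",
                           sequencing_depth = Inf, seed = 4)
  sim <- simulate_patient(cfg, 1)
  expect_length(sim$truth$truncal, 0)
  part <- shared_private_partition(prepare_case(sim$case))
  expect_length(part$shared_by_all, 0)
})

test_that("a truncal chr22 deletion with distinct private drivers is monoclonal", {
  # branched-evolution structure: founder CNV, then divergent mutations
  cfg <- simulation_config(scenario = "monoclonal_branched",
                           n_truncal_snv = 0,
                           driver_panel_injection = FALSE,
                           n_private_snv_per_lesion = 3,
                           truncal_cnv_events = list(list(label = "22",
                                                          kind = "deletion")),
                           sequencing_depth = Inf, seed = 12)
  sim <- simulate_patient(cfg, 1)
  expect_identical(sim$truth$truncal, "CNV:deletion:22")
  res <- analyze_case(sim$case)
  expect_equal(res$clonality$verdict, "monoclonal")
  expect_true("CNV:deletion:22" %in% res$clonality$shared_driver_evidence)
})

test_that("observed VAFs follow the binomial read model", {
  # clonal fraction 0.8, diploid het, depth 1e4: E(VAF) = 0.4
  cfg <- simulation_config(lesions_per_patient = 2, n_truncal_snv = 10,
                           n_private_snv_per_lesion = 0,
                           truncal_cnv_events = list(),
                           private_cnv_events_per_lesion = 0,
                           driver_panel_injection = FALSE,
                           clonal_fraction_range = c(0.8, 0.8),
                           sequencing_depth = 1e4, seed = 31)
  vafs <- unlist(lapply(1:10, function(i) {
    sim <- simulate_patient(cfg, i)
    unlist(lapply(sim$case$lesions, function(l) l$variants$vaf))
  }))
  expect_gte(length(vafs), 200)
  expect_gt(mean(vafs), 0.39)
  expect_lt(mean(vafs), 0.41)

  # convergence to the expected VAF at depth 1e5 within 3 standard errors
  cfg5 <- simulation_config(lesions_per_patient = 2, n_truncal_snv = 25,
                            n_private_snv_per_lesion = 0,
                            truncal_cnv_events = list(),
                            private_cnv_events_per_lesion = 0,
                            driver_panel_injection = FALSE,
                            clonal_fraction_range = c(0.8, 0.8),
                            sequencing_depth = 1e5, seed = 32)
  sim <- simulate_patient(cfg5, 1)
  vafs <- unlist(lapply(sim$case$lesions, function(l) l$variants$vaf))
  se <- sqrt(0.4 * 0.6 / 1e5 / length(vafs))
  expect_lte(abs(mean(vafs) - 0.4), 3 * se)
})

test_that("noiseless fixtures round-trip losslessly through the readers", {
  cfg <- simulation_config(sequencing_depth = Inf, seed = 8)
  sim <- simulate_patient(cfg, 1)
  dir <- withr::local_tempdir()
  manifest <- write_fixture(sim$case, sim$truth, dir)
  expect_true(file.exists(manifest))
  for (l in sim$case$lesions) {
    v <- read_variant_table(file.path(dir, paste0(l$lesion_id,
                                                  ".variants.tsv")))
    expect_equal(v, l$variants, ignore_attr = TRUE)
    s <- read_segments(file.path(dir, paste0(l$lesion_id, ".seg")))
    expect_equal(s, l$segments, ignore_attr = TRUE)
  }
  # truth record serialized alongside
  truth <- jsonlite::read_json(file.path(dir, "P001.truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$scenario, "monoclonal_branched")
})

test_that("an empty lesion writes a valid header-only file", {
  case <- patient_case("E1", list(
    lesion_profile("E1-T1", somatic_variants(), mk_seg("E1-T1", "7", 0, 0.5)),
    lesion_profile("E1-T2", somatic_variants(), mk_seg("E1-T2", "7", 0, 0.5))
  ))
  dir <- withr::local_tempdir()
  write_fixture(case, directory = dir)
  v <- read_variant_table(file.path(dir, "E1-T1.variants.tsv"))
  expect_equal(nrow(v), 0)
})

test_that("a five-lesion case writes five table pairs and one manifest", {
  cfg <- simulation_config(lesions_per_patient = 5, seed = 2)
  sim <- simulate_patient(cfg, 1)
  dir <- withr::local_tempdir()
  mpath <- write_fixture(sim$case, sim$truth, dir)
  expect_length(list.files(dir, pattern = "\\.variants\\.tsv$"), 5)
  expect_length(list.files(dir, pattern = "\\.seg$"), 5)
  manifest <- jsonlite::read_json(mpath)
  expect_length(manifest$patients[[1]]$lesions, 5)
})

test_that("in-paper fixture encodes the published cohort structure", {
  fx <- build_inpaper_fixture()
  expect_length(fx, 6)
  # fifteen tumors in total, dura excluded
  expect_equal(sum(vapply(fx, function(cs) length(cs$lesions),
                          integer(1))), 15)
  expect_false(is.null(fx$S1$normal))
  expect_equal(nrow(fx$S1$normal$variants), 0)
  # S5 exact printed values
  s5t2 <- fx$S5$lesions[["S5-T2"]]$variants
  expect_equal(s5t2$vaf[s5t2$gene == "TRAF7"], 0.40)
  s5t1 <- fx$S5$lesions[["S5-T1"]]$variants
  expect_equal(s5t1$vaf[s5t1$gene == "TRAF7"], 0.22)
  segX <- fx$S5$lesions[["S5-T1"]]$segments
  expect_equal(segX$maf[segX$chrom == "X"], 0.30)
})
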