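# Simulator for multi-lesion somatic call sets with known clonal ground
# truth.
#
# Two generative scenarios:
#   monoclonal_branched - all lesions descend from one founding clone: they
#     share a truncal feature set (SNVs and/or CNV events) and then each
#     acquires private alterations (branched evolution);
#   independent - each lesion arises separately with its own founder and
#     private alterations; no feature is shared across lesions.
#
# Observed VAFs follow a binomial read-count model at the configured depth
# around the expected VAF implied by each event's true clonal fraction and
# local copy state; sequencing_depth = Inf yields noiseless fractions.

.sim_scenarios <- c("monoclonal_branched", "independent")

#' Simulation configuration
#'
#' @param lesions_per_patient Number of tumors per patient (>= 2).
#' @param scenario `"monoclonal_branched"` or `"independent"`.
#' @param n_truncal_snv Founder SNV count (shared under the monoclonal
#'   scenario; per-lesion founder count under the independent scenario).
#' @param n_private_snv_per_lesion Additional private SNVs per lesion.
#' @param truncal_cnv_events List of founder CNV events, each a list with
#'   `label` (chromosome such as `"22"` or arm such as `"1p"`) and `kind`
#'   (`"deletion"`, `"amplification"` or `"loh"`). Under the independent
#'   scenario the same number of founder events is drawn separately (and
#'   disjointly) for each lesion.
#' @param private_cnv_events_per_lesion Additional private CNV events per
#'   lesion, drawn from unused arms.
#' @param clonal_fraction_range Range `(lo, hi]` in `(0, 1]` from which each
#'   event's true clonal fraction is drawn per lesion.
#' @param sequencing_depth Reads per site for the binomial VAF noise model;
#'   `Inf` gives noiseless expected fractions.
#' @param driver_panel_injection Guarantee at least one driver-panel SNV per
#'   founding clone (default `TRUE`).
#' @param frac_synonymous,frac_common Fractions of passenger SNVs emitted as
#'   synonymous or as common population variants (gnomAD AF > 0.01), to
#'   exercise the downstream filters.
#' @param chroms Miniature genome: chromosomes (GRCh37 coordinates) on which
#'   SNVs and CNV events are placed.
#' @param seed Root seed; patient `i` uses substream `seed + i`.
#' @return A validated list of class `mm_sim_config`.
#' @export
simulation_config <- function(lesions_per_patient = 2,
                              scenario = c("monoclonal_branched",
                                           "independent"),
                              n_truncal_snv = 8,
                              n_private_snv_per_lesion = 4,
                              truncal_cnv_events =
                                list(list(label = "22", kind = "deletion")),
                              private_cnv_events_per_lesion = 1,
                              clonal_fraction_range = c(0.6, 1),
                              sequencing_depth = 150,
                              driver_panel_injection = TRUE,
                              frac_synonymous = 0.15,
                              frac_common = 0.05,
                              chroms = c("1", "2", "7", "8", "15", "18",
                                         "22", "X"),
                              seed = 1L) {
  scenario <- match.arg(scenario)
  if (lesions_per_patient < 2) stop("lesions_per_patient must be >= 2")
  r <- clonal_fraction_range
  if (length(r) != 2 || r[1] <= 0 || r[1] > r[2] || r[2] > 1) {
    stop("clonal_fraction_range must satisfy 0 < lo <= hi <= 1")
  }
  if (!(is.infinite(sequencing_depth) || sequencing_depth >= 1)) {
    stop("sequencing_depth must be >= 1 (or Inf)")
  }
  for (ev in truncal_cnv_events) {
    if (!all(c("label", "kind") %in% names(ev)) ||
        !ev$kind %in% c("deletion", "amplification", "loh")) {
      stop("truncal_cnv_events entries need label and kind in ",
           "{deletion, amplification, loh}")
    }
  }
  structure(
    list(lesions_per_patient = as.integer(lesions_per_patient),
         scenario = scenario,
         n_truncal_snv = as.integer(n_truncal_snv),
         n_private_snv_per_lesion = as.integer(n_private_snv_per_lesion),
         truncal_cnv_events = truncal_cnv_events,
         private_cnv_events_per_lesion =
           as.integer(private_cnv_events_per_lesion),
         clonal_fraction_range = as.numeric(r),
         sequencing_depth = sequencing_depth,
         driver_panel_injection = isTRUE(driver_panel_injection),
         frac_synonymous = frac_synonymous,
         frac_common = frac_common,
         chroms = chroms,
         seed = as.integer(seed)),
    class = "mm_sim_config"
  )
}

#' Expected variant allele fraction given clonal fraction and copy state
#'
#' For a fraction `c` of cells carrying the mutation: heterozygous at a
#' diploid locus gives `c/2`; a mutation on the retained, duplicated allele
#' of a copy-neutral LOH region gives `c`; a mutation on the single retained
#' copy of a hemizygously deleted region (the other cells diploid) gives
#' `c / (2 - c)`.
#'
#' @param clonal_fraction Fraction of tumor cells carrying the event, in
#'   `[0, 1]`.
#' @param copy_state `"het_diploid"`, `"hemizygous"` or `"cn_loh"`.
#' @return Expected VAF in `[0, 1]`.
#' @export
expected_vaf <- function(clonal_fraction,
                         copy_state = c("het_diploid", "hemizygous",
                                        "cn_loh")) {
  copy_state <- match.arg(copy_state)
  if (any(is.na(clonal_fraction)) || any(clonal_fraction < 0) ||
      any(clonal_fraction > 1)) {
    stop("clonal_fraction must lie in [0, 1]")
  }
  switch(copy_state,
    het_diploid = clonal_fraction / 2,
    cn_loh = clonal_fraction,
    hemizygous = clonal_fraction / (2 - clonal_fraction)
  )
}

# Genomic interval (0-based half-open) of an event label ("22" or "1p").
.label_interval <- function(label, arms) {
  if (label %in% arms$chrom) {
    a <- arms[arms$chrom == label, , drop = FALSE]
    return(list(chrom = label, start = 0, end = a$chrom_length[1]))
  }
  a <- arms[arms$arm == label, , drop = FALSE]
  if (nrow(a) == 0) stop("unknown chromosome/arm label: ", label)
  list(chrom = a$chrom[1], start = a$start[1], end = a$end[1])
}

.random_bases <- function(n) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  list(ref = ref, alt = unname(alt))
}

#' Simulate one multi-lesion patient
#'
#' Generates per-lesion somatic variant and segment tables under the
#' configured scenario, together with the ground-truth record of truncal and
#' private features and each event's true clonal fraction. Deterministic
#' given `(config$seed, patient_index)`.
#'
#' @param config An `mm_sim_config`, see [simulation_config()].
#' @param patient_index Positive integer selecting the per-patient random
#'   substream.
#' @return A list with `case` (an unprepared [patient_case()]) and `truth`
#'   (patient id, scenario, truncal/private feature keys, and a `fractions`
#'   data.frame with one row per event per lesion: `lesion_id`, `feature`,
#'   `true_cf`, `copy_state`, `class`).
#' @export
simulate_patient <- function(config, patient_index = 1) {
  stopifnot(inherits(config, "mm_sim_config"), patient_index >= 1)
  set.seed((config$seed + as.integer(patient_index)) %% .Machine$integer.max)
  arms <- grch37_arms(config$chroms)
  lens <- grch37_chrom_lengths(config$chroms)
  patient_id <- sprintf("P%03d", as.integer(patient_index))
  n_les <- config$lesions_per_patient
  lesion_ids <- sprintf("%s-T%d", patient_id, seq_len(n_les))
  cfr <- config$clonal_fraction_range
  draw_cf <- function(n) stats::runif(n, cfr[1], cfr[2])

  # ---- CNV event assignment -------------------------------------------
  all_arm_labels <- arms$arm
  used_labels <- character()
  cnv_by_lesion <- stats::setNames(
    replicate(n_les, list(), simplify = FALSE), lesion_ids)
  if (config$scenario == "monoclonal_branched") {
    for (ev in config$truncal_cnv_events) {
      for (lid in lesion_ids) {
        cnv_by_lesion[[lid]][[length(cnv_by_lesion[[lid]]) + 1]] <-
          list(label = ev$label, kind = ev$kind, truncal = TRUE)
      }
      used_labels <- c(used_labels, ev$label)
    }
  } else {
    # each lesion draws its own disjoint founder events
    n_founder <- length(config$truncal_cnv_events)
    kinds <- vapply(config$truncal_cnv_events, `[[`, character(1), "kind")
    for (lid in lesion_ids) {
      avail <- setdiff(all_arm_labels, used_labels)
      if (n_founder > length(avail)) stop("not enough arms for founder CNVs")
      labs <- sample(avail, n_founder)
      used_labels <- c(used_labels, labs)
      for (k in seq_len(n_founder)) {
        cnv_by_lesion[[lid]][[length(cnv_by_lesion[[lid]]) + 1]] <-
          list(label = labs[k], kind = kinds[k], truncal = FALSE)
      }
    }
  }
  for (lid in lesion_ids) {
    n_priv <- config$private_cnv_events_per_lesion
    if (n_priv > 0) {
      avail <- setdiff(all_arm_labels, used_labels)
      if (n_priv > length(avail)) stop("not enough arms for private CNVs")
      labs <- sample(avail, n_priv)
      used_labels <- c(used_labels, labs)
      for (lab in labs) {
        cnv_by_lesion[[lid]][[length(cnv_by_lesion[[lid]]) + 1]] <-
          list(label = lab,
               kind = sample(c("deletion", "amplification", "loh"), 1),
               truncal = FALSE)
      }
    }
  }

  # ---- SNV generation --------------------------------------------------
  used_pos <- character()
  sample_locus <- function() {
    for (try in 1:100) {
      chrom <- sample(config$chroms, 1)
      pos <- sample.int(lens[[chrom]], 1)
      key <- paste0(chrom, ":", pos)
      if (!key %in% used_pos) {
        used_pos <<- c(used_pos, key)
        return(list(chrom = chrom, pos = pos))
      }
    }
    stop("could not sample a collision-free SNV locus after 100 retries")
  }
  passenger_snv <- function() {
    loc <- sample_locus()
    b <- .random_bases(1)
    cons <- if (stats::runif(1) < config$frac_synonymous) "synonymous" else
      sample(c("missense", "nonsense", "frameshift"), 1,
             prob = c(0.8, 0.1, 0.1))
    gaf <- if (stats::runif(1) < config$frac_common) {
      stats::runif(1, 0.02, 0.3)
    } else if (stats::runif(1) < 0.2) {
      stats::runif(1, 0, 0.005)
    } else NA_real_
    list(chrom = loc$chrom, pos = loc$pos, ref = b$ref, alt = b$alt,
         gene = paste0("GENE_", loc$chrom, "_", loc$pos),
         consequence = cons, gnomad_af = gaf)
  }
  driver_snv <- function(exclude_genes = character()) {
    loci <- driver_panel_loci()
    loci <- loci[loci$chrom %in% config$chroms &
                   !loci$gene %in% exclude_genes, , drop = FALSE]
    if (nrow(loci) == 0) stop("no driver-panel gene available on the ",
                              "configured chromosomes")
    g <- loci[sample.int(nrow(loci), 1), ]
    b <- .random_bases(1)
    pos <- g$pos + sample.int(20000, 1)
    used_pos <<- c(used_pos, paste0(g$chrom, ":", pos))
    list(chrom = g$chrom, pos = pos, ref = b$ref, alt = b$alt,
         gene = g$gene, consequence = "missense", gnomad_af = NA_real_)
  }
  make_snv_set <- function(n, inject_driver, exclude_genes = character()) {
    out <- list()
    if (inject_driver && n > 0) {
      out[[1]] <- driver_snv(exclude_genes)
      n <- n - 1
    }
    for (i in seq_len(n)) out[[length(out) + 1]] <- passenger_snv()
    out
  }

  truncal_snvs <- list()
  founder_snvs <- stats::setNames(
    replicate(n_les, list(), simplify = FALSE), lesion_ids)
  if (config$scenario == "monoclonal_branched") {
    truncal_snvs <- make_snv_set(config$n_truncal_snv,
                                 config$driver_panel_injection)
  } else {
    used_driver_genes <- character()
    for (lid in lesion_ids) {
      founder_snvs[[lid]] <- make_snv_set(config$n_truncal_snv,
                                          config$driver_panel_injection,
                                          used_driver_genes)
      if (config$driver_panel_injection && config$n_truncal_snv > 0) {
        used_driver_genes <- c(used_driver_genes,
                               founder_snvs[[lid]][[1]]$gene)
      }
    }
  }
  private_snvs <- lapply(lesion_ids, function(lid) {
    make_snv_set(config$n_private_snv_per_lesion, FALSE)
  })
  names(private_snvs) <- lesion_ids

  # ---- assemble per-lesion observed tables -----------------------------
  snv_key <- function(s) paste0("SNV:", s$gene, ":", s$chrom, ":", s$pos,
                                ":", s$ref, ">", s$alt)
  cnv_key <- function(e) paste0("CNV:", e$kind, ":", e$label)
  depth <- config$sequencing_depth
  observe_vaf <- function(p) {
    if (is.infinite(depth)) return(p)
    stats::rbinom(1, depth, p) / depth
  }
  fractions <- list()
  lesions <- list()
  for (lid in lesion_ids) {
    cnvs <- cnv_by_lesion[[lid]]
    cnv_cf <- draw_cf(length(cnvs))
    # segment table: event regions carved out of neutral chromosomes
    seg_rows <- list()
    for (chrom in config$chroms) {
      evs <- which(vapply(cnvs, function(e) {
        .label_interval(e$label, arms)$chrom == chrom
      }, logical(1)))
      cuts <- c(0, lens[[chrom]])
      for (i in evs) {
        iv <- .label_interval(cnvs[[i]]$label, arms)
        cuts <- c(cuts, iv$start, iv$end)
      }
      cuts <- sort(unique(cuts))
      for (k in seq_len(length(cuts) - 1)) {
        s <- cuts[k]; e <- cuts[k + 1]
        log2r <- 0; maf <- 0.5
        for (i in evs) {
          iv <- .label_interval(cnvs[[i]]$label, arms)
          if (iv$start <= s && e <= iv$end) {
            cf <- cnv_cf[i]
            log2r <- switch(cnvs[[i]]$kind,
              deletion = log2(1 - cf / 2),
              amplification = log2(1 + cf / 2),
              loh = 0)
            maf <- switch(cnvs[[i]]$kind,
              deletion = (1 - cf) / (2 - cf),
              amplification = 1 / (2 + cf),
              loh = (1 - cf) / 2)
          }
        }
        seg_rows[[length(seg_rows) + 1]] <- data.frame(
          chrom = chrom, start = s, end = e, log2_copy_ratio = log2r,
          maf = maf, lesion_id = lid, stringsAsFactors = FALSE)
      }
    }
    segments <- validate_segments(do.call(rbind, seg_rows))
    for (i in seq_along(cnvs)) {
      fractions[[length(fractions) + 1]] <- data.frame(
        lesion_id = lid, feature = cnv_key(cnvs[[i]]), true_cf = cnv_cf[i],
        copy_state = cnvs[[i]]$kind, class = "cnv",
        truncal = isTRUE(cnvs[[i]]$truncal), stringsAsFactors = FALSE)
    }
    # copy state of an SNV given the lesion's CNV events
    snv_state <- function(s) {
      for (i in seq_along(cnvs)) {
        iv <- .label_interval(cnvs[[i]]$label, arms)
        if (iv$chrom == s$chrom && iv$start < s$pos && s$pos <= iv$end) {
          return(switch(cnvs[[i]]$kind,
                        deletion = "hemizygous",
                        loh = "cn_loh",
                        amplification = "het_diploid"))
        }
      }
      "het_diploid"
    }
    lesion_snvs <- c(
      if (config$scenario == "monoclonal_branched") truncal_snvs
      else founder_snvs[[lid]],
      private_snvs[[lid]]
    )
    truncal_flags <- c(
      rep(config$scenario == "monoclonal_branched",
          length(if (config$scenario == "monoclonal_branched") truncal_snvs
                 else founder_snvs[[lid]])),
      rep(FALSE, length(private_snvs[[lid]]))
    )
    vrows <- list()
    for (i in seq_along(lesion_snvs)) {
      s <- lesion_snvs[[i]]
      cf <- draw_cf(1)
      state <- snv_state(s)
      vaf <- observe_vaf(expected_vaf(cf, state))
      vrows[[length(vrows) + 1]] <- data.frame(
        chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
        gene = s$gene, consequence = s$consequence, vaf = vaf,
        gnomad_af = s$gnomad_af, lesion_id = lid, stringsAsFactors = FALSE)
      fractions[[length(fractions) + 1]] <- data.frame(
        lesion_id = lid, feature = snv_key(s), true_cf = cf,
        copy_state = state, class = "snv", truncal = truncal_flags[i],
        stringsAsFactors = FALSE)
    }
    variants <- if (length(vrows) > 0) {
      validate_variants(do.call(rbind, vrows))
    } else somatic_variants()
    lesions[[lid]] <- lesion_profile(lid, variants, segments)
  }

  fractions <- do.call(rbind, fractions)
  rownames(fractions) <- NULL
  truncal_keys <- unique(fractions$feature[fractions$truncal])
  private_keys <- lapply(lesion_ids, function(lid) {
    unique(fractions$feature[fractions$lesion_id == lid &
                               !fractions$truncal])
  })
  names(private_keys) <- lesion_ids
  list(
    case = patient_case(patient_id, lesions),
    truth = list(patient_id = patient_id, scenario = config$scenario,
                 truncal = truncal_keys, private = private_keys,
                 fractions = fractions)
  )
}

#' Write a simulated (or constructed) patient case to disk
#'
#' Emits one tab-delimited variant table and one SEG file per lesion, a
#' ground-truth JSON (when a truth record is supplied) and a manifest JSON
#' that [run_pipeline()] can consume directly. Files round-trip losslessly
#' through [read_variant_table()] and [read_segments()].
#'
#' @param case An `mm_case`.
#' @param truth Optional truth record from [simulate_patient()].
#' @param directory Output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
write_fixture <- function(case, truth = NULL, directory) {
  stopifnot(inherits(case, "mm_case"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  one_lesion <- function(l) {
    vpath <- file.path(directory, paste0(l$lesion_id, ".variants.tsv"))
    spath <- file.path(directory, paste0(l$lesion_id, ".seg"))
    write_variant_table(l$variants, vpath)
    write_segments(l$segments, spath)
    list(lesion_id = l$lesion_id, variants = basename(vpath),
         segments = basename(spath))
  }
  entry <- list(
    patient_id = case$patient_id,
    sex = case$sex,
    lesions = lapply(unname(case$lesions), one_lesion)
  )
  if (!is.null(case$normal)) entry$normal <- one_lesion(case$normal)
  manifest <- list(patients = list(entry))
  mpath <- file.path(directory, paste0(case$patient_id, ".manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", na = "null")
  if (!is.null(truth)) {
    tpath <- file.path(directory, paste0(case$patient_id, ".truth.json"))
    jsonlite::write_json(truth, tpath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, dataframe = "columns", na = "null")
  }
  invisible(mpath)
}
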