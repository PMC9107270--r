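# End-to-end orchestration: manifest -> filter -> events -> partition ->
# subtype -> clonality -> feature matrix -> distances -> NJ tree -> report.

#' Pipeline configuration
#'
#' Bundles every tunable threshold of the analysis with its default.
#'
#' @param max_pop_af Population-AF filter threshold (default 0.01).
#' @param impactful Consequence terms kept by the functional-impact filter.
#' @param contamination Contamination rate for the VAF filter (default 0;
#'   supply the per-sample estimate when available).
#' @param thresholds Event-calling thresholds, see [event_thresholds()].
#' @param panel Driver gene panel, see [driver_panel()].
#' @param min_shared_drivers Shared driver features required for a
#'   monoclonal verdict (default 1).
#' @param include_outgroup Append the all-zero germline row to feature
#'   matrices (default `TRUE`).
#' @param concordance_tolerance Absolute tolerance for MAF- vs VAF-derived
#'   clonal-fraction concordance (default 0.10).
#' @param maf_model MAF-to-clonal-fraction model, see
#'   [clonal_fraction_from_maf()].
#' @return A named list of class `mm_config`.
#' @export
pipeline_config <- function(max_pop_af = 0.01,
                            impactful = functional_consequences(),
                            contamination = 0,
                            thresholds = event_thresholds(),
                            panel = driver_panel(),
                            min_shared_drivers = 1,
                            include_outgroup = TRUE,
                            concordance_tolerance = 0.10,
                            maf_model = c("cn_loh", "deletion")) {
  structure(
    list(max_pop_af = max_pop_af, impactful = impactful,
         contamination = contamination, thresholds = thresholds,
         panel = panel, min_shared_drivers = min_shared_drivers,
         include_outgroup = include_outgroup,
         concordance_tolerance = concordance_tolerance,
         maf_model = match.arg(maf_model)),
    class = "mm_config"
  )
}

#' Read a patient manifest (JSON or YAML)
#'
#' The manifest lists, per patient, the lesion ids and the paths of their
#' variant and segment tables (relative paths are resolved against the
#' manifest's directory), plus an optional normal/dura entry and sex.
#'
#' @param path Manifest file; `.json`, `.yaml` or `.yml`.
#' @return The validated manifest list.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  manifest <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  manifest$.dir <- dirname(normalizePath(path))
  validate_manifest(manifest)
}

#' Validate a patient manifest
#'
#' Schema check performed before any computation: a non-empty `patients`
#' list, per patient a `patient_id` and at least one lesion with
#' `lesion_id`, `variants` and `segments` entries, and existing files.
#'
#' @param manifest Manifest list (as from [read_manifest()]).
#' @return The manifest, unchanged.
#' @export
validate_manifest <- function(manifest) {
  if (is.null(manifest$patients) || length(manifest$patients) == 0) {
    stop("manifest validation: empty or missing 'patients' list")
  }
  resolve <- function(p) {
    if (!is.null(manifest$.dir) && !grepl("^(/|[A-Za-z]:)", p)) {
      file.path(manifest$.dir, p)
    } else p
  }
  seen <- character()
  for (pt in manifest$patients) {
    if (is.null(pt$patient_id)) {
      stop("manifest validation: patient without patient_id")
    }
    if (is.null(pt$lesions) || length(pt$lesions) == 0) {
      stop("manifest validation: patient ", pt$patient_id, " has no lesions")
    }
    entries <- c(pt$lesions, if (!is.null(pt$normal)) list(pt$normal))
    for (l in entries) {
      if (is.null(l$lesion_id) || is.null(l$variants) ||
          is.null(l$segments)) {
        stop("manifest validation: lesion entries need lesion_id, ",
             "variants and segments (patient ", pt$patient_id, ")")
      }
      if (l$lesion_id %in% seen) {
        stop("manifest validation: duplicated lesion_id ", l$lesion_id)
      }
      seen <- c(seen, l$lesion_id)
      for (p in c(l$variants, l$segments)) {
        if (!file.exists(resolve(p))) {
          stop("manifest validation: missing file ", resolve(p))
        }
      }
    }
  }
  manifest
}

.manifest_to_cases <- function(manifest) {
  resolve <- function(p) {
    if (!is.null(manifest$.dir) && !grepl("^(/|[A-Za-z]:)", p)) {
      file.path(manifest$.dir, p)
    } else p
  }
  load_lesion <- function(l) {
    lesion_profile(
      l$lesion_id,
      read_variant_table(resolve(l$variants), lesion_id = l$lesion_id),
      read_segments(resolve(l$segments), lesion_id = l$lesion_id)
    )
  }
  lapply(manifest$patients, function(pt) {
    patient_case(
      pt$patient_id,
      lapply(pt$lesions, load_lesion),
      normal = if (!is.null(pt$normal)) load_lesion(pt$normal),
      sex = if (!is.null(pt$sex)) pt$sex else NA_character_
    )
  })
}

#' Analyze one patient case
#'
#' Runs the per-patient stage chain: variant filtering, event calling,
#' shared/private partition, per-lesion subtype, clonality verdict,
#' clonal-fraction comparison, binary feature matrix, Manhattan distances
#' and the neighbor-joining tree (when at least three matrix rows are
#' available).
#'
#' @param case An `mm_case` (unprepared; filtering is applied here).
#' @param config An `mm_config`, see [pipeline_config()].
#' @return A list with `case` (prepared), `subtype_calls`, `clonality`,
#'   `partition`, `clonal_fractions`, `feature_matrix`, `distance_matrix`
#'   and `newick`.
#' @export
analyze_case <- function(case, config = pipeline_config()) {
  stopifnot(inherits(case, "mm_case"))
  case <- prepare_case(case, max_pop_af = config$max_pop_af,
                       impactful = config$impactful,
                       contamination = config$contamination,
                       thresholds = config$thresholds)
  subtype_calls <- lapply(case$lesions, classify_subtype,
                          panel = config$panel)
  ovf <- config$thresholds$overlap_fraction
  clonality <- if (length(case$lesions) >= 2) {
    classify_patient_clonality(case, panel = config$panel,
                               min_shared_drivers =
                                 config$min_shared_drivers,
                               overlap_fraction = ovf)
  }
  partition <- if (length(case$lesions) >= 2) {
    shared_private_partition(case, overlap_fraction = ovf)
  }
  cf <- compare_event_clonality(case, panel = config$panel,
                                tolerance = config$concordance_tolerance,
                                maf_model = config$maf_model)
  fm <- tryCatch(
    build_feature_matrix(case, include_outgroup = config$include_outgroup,
                         panel = config$panel, overlap_fraction = ovf),
    error = function(e) NULL
  )
  dm <- NULL; nwk <- NULL
  if (!is.null(fm) && nrow(fm) >= 3) {
    dm <- manhattan_distance_matrix(fm)
    nwk <- write_newick(neighbor_joining(dm))
  }
  list(case = case, subtype_calls = subtype_calls, clonality = clonality,
       partition = partition, clonal_fractions = cf, feature_matrix = fm,
       distance_matrix = dm, newick = nwk)
}

#' Run the full pipeline over a patient manifest
#'
#' Executes [analyze_case()] for every patient in the manifest. A failure
#' in one patient is recorded and does not abort the others. Deterministic
#' given inputs and configuration.
#'
#' @param manifest Manifest file path, a manifest list, or a list of
#'   `mm_case` objects.
#' @param config An `mm_config`, see [pipeline_config()].
#' @return A list of class `mm_cohort_report` with elements
#'   `subtype_calls` (data.frame), `clonality_calls` (data.frame),
#'   `sharing` (per-lesion shared/partial/private counts and the shared
#'   fraction), `clonal_fractions` (data.frame), `trees` (named list of
#'   Newick strings), `results` (full per-patient results), `errors`
#'   (named list) and `metadata`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config()) {
  cases <- if (is.character(manifest)) {
    .manifest_to_cases(read_manifest(manifest))
  } else if (is.list(manifest) && all(vapply(manifest, inherits,
                                             logical(1), "mm_case"))) {
    manifest
  } else {
    .manifest_to_cases(validate_manifest(manifest))
  }
  results <- list(); errors <- list()
  for (case in cases) {
    res <- tryCatch(analyze_case(case, config), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[case$patient_id]] <- conditionMessage(res)
    } else {
      results[[case$patient_id]] <- res
    }
  }
  subtype_calls <- do.call(rbind, unlist(lapply(names(results), function(p) {
    lapply(results[[p]]$subtype_calls, function(s) {
      data.frame(patient_id = p, lesion_id = s$lesion_id,
                 subtype = s$subtype,
                 evidence = paste(s$evidence, collapse = ";"),
                 stringsAsFactors = FALSE)
    })
  }), recursive = FALSE))
  clonality_calls <- do.call(rbind, lapply(names(results), function(p) {
    cl <- results[[p]]$clonality
    if (is.null(cl)) return(NULL)
    data.frame(patient_id = p, verdict = cl$verdict,
               n_shared_drivers = length(cl$shared_driver_evidence),
               evidence = paste(cl$shared_driver_evidence, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  sharing <- do.call(rbind, lapply(names(results), function(p) {
    part <- results[[p]]$partition
    if (is.null(part)) return(NULL)
    cnt <- part$counts
    tot <- cnt$n_shared + cnt$n_partial + cnt$n_private
    data.frame(patient_id = p, cnt,
               shared_fraction = ifelse(tot > 0, cnt$n_shared / tot, NA),
               stringsAsFactors = FALSE)
  }))
  clonal_fractions <- do.call(rbind, lapply(names(results), function(p) {
    cf <- results[[p]]$clonal_fractions
    if (is.null(cf) || nrow(cf) == 0) return(NULL)
    cbind(data.frame(patient_id = p, stringsAsFactors = FALSE), cf)
  }))
  trees <- lapply(results, `[[`, "newick")
  structure(
    list(subtype_calls = subtype_calls, clonality_calls = clonality_calls,
         sharing = sharing, clonal_fractions = clonal_fractions,
         trees = trees, results = results, errors = errors,
         metadata = list(config = config,
                         package_version =
                           as.character(utils::packageVersion("mmclone")))),
    class = "mm_cohort_report"
  )
}

#' @export
print.mm_cohort_report <- function(x, ...) {
  s <- summarize_cohort(x)
  cat("<cohort report>\n")
  cat("  tumors: ", s$n_tumors, " (", s$n_nf2_loss, " NF2-loss, ",
      s$n_non_nf2, " non-NF2)\n", sep = "")
  cat("  patients with verdict: ", s$n_monoclonal + s$n_independent,
      " (", s$n_monoclonal, " monoclonal, ", s$n_independent,
      " independent)\n", sep = "")
  if (length(x$errors) > 0) {
    cat("  failed patients:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarize a cohort report
#'
#' @param report An `mm_cohort_report` from [run_pipeline()].
#' @return A list with `n_tumors`, `n_nf2_loss`, `n_non_nf2`,
#'   `n_monoclonal`, `n_independent` and the per-lesion `sharing` table.
#' @export
summarize_cohort <- function(report) {
  stopifnot(inherits(report, "mm_cohort_report"))
  st <- report$subtype_calls
  cl <- report$clonality_calls
  list(
    n_tumors = if (is.null(st)) 0L else nrow(st),
    n_nf2_loss = if (is.null(st)) 0L else sum(st$subtype == "NF2_loss"),
    n_non_nf2 = if (is.null(st)) 0L else sum(st$subtype == "non_NF2"),
    n_monoclonal = if (is.null(cl)) 0L else sum(cl$verdict == "monoclonal"),
    n_independent = if (is.null(cl)) 0L else
      sum(cl$verdict == "independent"),
    sharing = report$sharing
  )
}

#' Write a cohort report to disk
#'
#' Emits the per-lesion subtype table, the per-patient clonality table, the
#' sharing table and the clonal-fraction table as TSV, one Newick file per
#' patient, and a consolidated JSON report.
#'
#' @param report An `mm_cohort_report`.
#' @param directory Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, directory) {
  stopifnot(inherits(report, "mm_cohort_report"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(directory, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wt(report$subtype_calls, "subtype_calls.tsv")
  wt(report$clonality_calls, "clonality_calls.tsv")
  wt(report$sharing, "sharing.tsv")
  wt(report$clonal_fractions, "clonal_fractions.tsv")
  for (p in names(report$trees)) {
    if (!is.null(report$trees[[p]])) {
      writeLines(report$trees[[p]],
                 file.path(directory, paste0(p, ".nwk")))
    }
  }
  json <- list(
    summary = summarize_cohort(report)[c("n_tumors", "n_nf2_loss",
                                         "n_non_nf2", "n_monoclonal",
                                         "n_independent")],
    subtype_calls = report$subtype_calls,
    clonality_calls = report$clonality_calls,
    sharing = report$sharing,
    trees = report$trees,
    errors = report$errors,
    package_version = report$metadata$package_version
  )
  jsonlite::write_json(json, file.path(directory, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(directory)
}
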