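# Lesion profiles and patient cases.
#
# A lesion profile bundles the somatic calls of one tumor (or of the normal
# dura control): its variant table, its copy-number segment table and, once
# prepare_case() has run, the called arm/chromosome-level events. A patient
# case groups the lesion profiles of one individual.

#' Construct a lesion profile
#'
#' @param lesion_id Lesion identifier.
#' @param variants Variant `data.frame` (see [somatic_variants()]).
#' @param segments Segment `data.frame` (see [cnv_segments()]).
#' @param events Optional called-event `data.frame` (see [call_events()]).
#' @return A list of class `mm_lesion`.
#' @export
lesion_profile <- function(lesion_id, variants = somatic_variants(),
                           segments = cnv_segments(), events = NULL) {
  stopifnot(is.character(lesion_id), length(lesion_id) == 1)
  validate_variants(variants)
  validate_segments(segments)
  structure(
    list(lesion_id = lesion_id, variants = variants,
         segments = segments, events = events),
    class = "mm_lesion"
  )
}

#' Construct a patient case
#'
#' @param patient_id Patient identifier.
#' @param lesions List of lesion profiles (tumors only).
#' @param normal Optional lesion profile of a matched normal/dura specimen.
#'   It never contributes features to the tumor analysis; it is kept for
#'   negative-control checks.
#' @param sex `"female"`, `"male"` or `NA`. Only consulted for chrX
#'   variant-allele-fraction arithmetic.
#' @return A list of class `mm_case`.
#' @export
patient_case <- function(patient_id, lesions, normal = NULL,
                         sex = NA_character_) {
  stopifnot(is.character(patient_id), length(patient_id) == 1,
            is.list(lesions), length(lesions) >= 1)
  ids <- vapply(lesions, function(l) l$lesion_id, character(1))
  if (anyDuplicated(ids)) stop("duplicated lesion ids in case ", patient_id)
  names(lesions) <- ids
  structure(
    list(patient_id = patient_id, lesions = lesions,
         normal = normal, sex = sex),
    class = "mm_case"
  )
}

#' @export
print.mm_case <- function(x, ...) {
  cat("<patient case ", x$patient_id, ">: ", length(x$lesions),
      " lesion(s)", if (!is.null(x$normal)) " + normal", "\n", sep = "")
  for (l in x$lesions) {
    cat("  ", l$lesion_id, ": ", nrow(l$variants), " variant(s), ",
        nrow(l$segments), " segment(s)",
        if (!is.null(l$events)) paste0(", ", nrow(l$events), " event(s)"),
        "\n", sep = "")
  }
  invisible(x)
}

#' Filter variants and call events for every lesion of a case
#'
#' Applies the three post-calling variant filters (population allele
#' frequency, functional coding impact, contamination) and arm-level event
#' calling to every lesion, including the normal profile when present.
#'
#' @param case An `mm_case`.
#' @param max_pop_af Population-AF threshold passed to
#'   [filter_population_af()].
#' @param impactful Consequence set passed to [filter_functional_impact()].
#' @param contamination Contamination rate passed to [filter_contamination()].
#' @param thresholds Event-calling thresholds, see [event_thresholds()].
#' @param arms Chromosome arm table, see [grch37_arms()].
#' @return The case with filtered `variants` and populated `events` in each
#'   lesion profile.
#' @export
prepare_case <- function(case, max_pop_af = 0.01,
                         impactful = functional_consequences(),
                         contamination = 0,
                         thresholds = event_thresholds(),
                         arms = grch37_arms()) {
  stopifnot(inherits(case, "mm_case"))
  prep <- function(l) {
    v <- filter_population_af(l$variants, max_pop_af)
    v <- filter_functional_impact(v, impactful)
    v <- filter_contamination(v, contamination)
    l$variants <- v
    l$events <- call_events(l$segments, thresholds, arms)
    l
  }
  case$lesions <- lapply(case$lesions, prep)
  if (!is.null(case$normal)) case$normal <- prep(case$normal)
  case
}
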