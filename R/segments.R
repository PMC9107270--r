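# Copy-number / allelic segment tables and segment algebra.
#
# Internal coordinates are 0-based half-open (BED semantics); SEG files are
# 1-based inclusive and are converted at the I/O boundary. All interval
# arithmetic goes through IRanges (converted back to 1-based closed form at
# the call site).

.segment_cols <- c("chrom", "start", "end", "log2_copy_ratio", "maf",
                   "lesion_id")

# 0-based half-open [start, end) -> IRanges (1-based closed)
.as_iranges <- function(start, end) {
  IRanges::IRanges(start = start + 1, end = end)
}

.from_iranges <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
}

#' Construct a copy-number segment table
#'
#' @param chrom Chromosome name (no `"chr"` prefix).
#' @param start,end 0-based half-open interval.
#' @param log2_copy_ratio Log2 tumor/normal copy ratio.
#' @param maf Minor-allele fraction in `[0, 0.5]`, `NA` when the segment has
#'   no informative heterozygous sites.
#' @param lesion_id Lesion identifier.
#' @return A validated segment `data.frame`.
#' @export
cnv_segments <- function(chrom = character(), start = numeric(),
                         end = numeric(), log2_copy_ratio = numeric(),
                         maf = NA_real_, lesion_id = character()) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    log2_copy_ratio = as.numeric(log2_copy_ratio),
    maf = rep_len(as.numeric(maf), n),
    lesion_id = rep_len(as.character(lesion_id), n),
    stringsAsFactors = FALSE
  )
  validate_segments(df)
}

#' Validate a segment table
#'
#' Checks coordinates, the MAF range and that segments of one lesion form a
#' partition (no overlap) on every chromosome.
#'
#' @param segments A segment `data.frame`.
#' @return The input, unchanged, for chaining.
#' @export
validate_segments <- function(segments) {
  missing_cols <- setdiff(.segment_cols, names(segments))
  if (length(missing_cols) > 0) {
    stop("segment table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(segments) == 0) return(segments)
  bad <- which(is.na(segments$start) | is.na(segments$end) |
                 segments$start < 0 | segments$start >= segments$end)
  if (length(bad) > 0) {
    stop("invalid interval (need 0 <= start < end) at row(s): ",
         paste(bad, collapse = ", "))
  }
  bad <- which(!is.na(segments$maf) &
                 (segments$maf < 0 | segments$maf > 0.5))
  if (length(bad) > 0) {
    stop("maf outside [0, 0.5] at row(s): ", paste(bad, collapse = ", "))
  }
  for (grp in split(segments, paste(segments$lesion_id, segments$chrom))) {
    o <- order(grp$start)
    if (any(grp$start[o][-1] < grp$end[o][-nrow(grp)])) {
      stop("overlapping segments within lesion ", grp$lesion_id[1],
           " on chromosome ", grp$chrom[1],
           ": segmentation must be a partition")
    }
  }
  segments
}

#' Read a SEG-dialect segment file
#'
#' Expects tab-delimited columns `sample`, `chrom`, `start`, `end`,
#' `log2_copy_ratio`, `maf` with 1-based inclusive coordinates, which are
#' converted to the internal 0-based half-open convention.
#'
#' @param path Path to the file.
#' @param lesion_id Optional lesion id override; defaults to the `sample`
#'   column.
#' @return A validated segment `data.frame`.
#' @export
read_segments <- function(path, lesion_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = c("NA", ""))
  required <- c("sample", "chrom", "start", "end", "log2_copy_ratio", "maf")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("malformed SEG file ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  cnv_segments(
    chrom = as.character(df$chrom),
    start = as.numeric(df$start) - 1,  # 1-based inclusive -> 0-based half-open
    end = as.numeric(df$end),
    log2_copy_ratio = as.numeric(df$log2_copy_ratio),
    maf = as.numeric(df$maf),
    lesion_id = if (is.null(lesion_id)) as.character(df$sample) else lesion_id
  )
}

#' Write a SEG-dialect segment file
#'
#' Inverse of [read_segments()]: internal 0-based half-open coordinates are
#' written back as 1-based inclusive.
#'
#' @param segments A segment `data.frame`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_segments <- function(segments, path) {
  validate_segments(segments)
  out <- data.frame(
    sample = segments$lesion_id,
    chrom = segments$chrom,
    start = segments$start + 1,
    end = segments$end,
    log2_copy_ratio = segments$log2_copy_ratio,
    maf = segments$maf
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Event-calling thresholds
#'
#' Field-standard defaults for arm-level event calling: a segment is in the
#' deletion state when its log2 copy ratio is at most `del_log2`, amplified
#' at `amp_log2` or above, and in allelic imbalance (LOH) when its
#' minor-allele fraction is at most `loh_maf`, irrespective of copy ratio.
#' An arm-level event is emitted when the affected fraction of the arm
#' exceeds `arm_fraction`.
#'
#' @param del_log2,amp_log2 Log2 copy-ratio cut-offs (default -0.3 / +0.3).
#' @param loh_maf Minor-allele-fraction cut-off for LOH (default 0.40).
#' @param arm_fraction Minimum affected arm fraction (default 0.5).
#' @param overlap_fraction Reciprocal-overlap fraction required for two
#'   lesions' events to count as the same feature (default 0.5).
#' @return A named list of thresholds.
#' @export
event_thresholds <- function(del_log2 = -0.3, amp_log2 = 0.3,
                             loh_maf = 0.40, arm_fraction = 0.5,
                             overlap_fraction = 0.5) {
  stopifnot(del_log2 < 0, amp_log2 > 0, loh_maf >= 0, loh_maf <= 0.5,
            arm_fraction > 0, arm_fraction <= 1,
            overlap_fraction > 0, overlap_fraction <= 1)
  list(del_log2 = del_log2, amp_log2 = amp_log2, loh_maf = loh_maf,
       arm_fraction = arm_fraction, overlap_fraction = overlap_fraction)
}

.state_predicates <- function(thresholds) {
  list(
    deletion = function(seg) !is.na(seg$log2_copy_ratio) &
      seg$log2_copy_ratio <= thresholds$del_log2,
    amplification = function(seg) !is.na(seg$log2_copy_ratio) &
      seg$log2_copy_ratio >= thresholds$amp_log2,
    loh = function(seg) !is.na(seg$maf) & seg$maf <= thresholds$loh_maf
  )
}

.empty_events <- function() {
  data.frame(lesion_id = character(), kind = character(),
             label = character(), chrom = character(),
             covered_fraction = numeric(),
             footprint = I(list()), maf = numeric(),
             stringsAsFactors = FALSE)
}

#' Call arm/chromosome-level copy-number and LOH events
#'
#' For each lesion and each state (deletion, amplification, LOH), segments
#' in that state are merged and compared against the chromosome arm table.
#' An arm whose affected fraction exceeds the arm-coverage threshold yields
#' an arm event (label e.g. `"1p"`); when both arms of a chromosome carry
#' the same event kind they are merged into a single chromosome-level event
#' (label e.g. `"22"`). The `footprint` list column retains the merged
#' affected intervals (0-based half-open) for overlap comparisons across
#' lesions, and `maf` the length-weighted mean minor-allele fraction of the
#' contributing segments (informative for LOH events).
#'
#' @param segments A segment `data.frame` (may contain several lesions).
#' @param thresholds See [event_thresholds()].
#' @param arms Chromosome arm table, see [grch37_arms()].
#' @return An event `data.frame` with columns `lesion_id`, `kind`, `label`,
#'   `chrom`, `covered_fraction`, `footprint`, `maf`.
#' @export
call_events <- function(segments, thresholds = event_thresholds(),
                        arms = grch37_arms()) {
  validate_segments(segments)
  if (nrow(segments) == 0) return(.empty_events())
  unknown <- setdiff(unique(segments$chrom), unique(arms$chrom))
  if (length(unknown) > 0) {
    stop("unknown chromosome(s) in segment table: ",
         paste(unknown, collapse = ", "))
  }
  preds <- .state_predicates(thresholds)
  rows <- list()
  for (lesion in unique(segments$lesion_id)) {
    seg_l <- segments[segments$lesion_id == lesion, , drop = FALSE]
    for (kind in names(preds)) {
      hit <- seg_l[preds[[kind]](seg_l), , drop = FALSE]
      if (nrow(hit) == 0) next
      for (chrom in unique(hit$chrom)) {
        hit_c <- hit[hit$chrom == chrom, , drop = FALSE]
        merged <- IRanges::reduce(.as_iranges(hit_c$start, hit_c$end))
        arms_c <- arms[arms$chrom == chrom, , drop = FALSE]
        arm_hit <- logical(nrow(arms_c))
        for (i in seq_len(nrow(arms_c))) {
          arm_ir <- .as_iranges(arms_c$start[i], arms_c$end[i])
          cov <- sum(IRanges::width(IRanges::intersect(merged, arm_ir)))
          arm_hit[i] <- cov / (arms_c$end[i] - arms_c$start[i]) >
            thresholds$arm_fraction
        }
        if (!any(arm_hit)) next
        w <- hit_c$end - hit_c$start
        mean_maf <- if (all(is.na(hit_c$maf))) NA_real_ else {
          sum(hit_c$maf * w, na.rm = TRUE) / sum(w[!is.na(hit_c$maf)])
        }
        mk_row <- function(label, ir, denom) {
          data.frame(lesion_id = lesion, kind = kind, label = label,
                     chrom = chrom,
                     covered_fraction = sum(IRanges::width(ir)) / denom,
                     footprint = I(list(as.matrix(.from_iranges(ir)))),
                     maf = mean_maf, stringsAsFactors = FALSE)
        }
        if (all(arm_hit)) {
          rows[[length(rows) + 1]] <-
            mk_row(chrom, merged, arms_c$chrom_length[1])
        } else {
          for (i in which(arm_hit)) {
            arm_ir <- .as_iranges(arms_c$start[i], arms_c$end[i])
            rows[[length(rows) + 1]] <-
              mk_row(arms_c$arm[i], IRanges::intersect(merged, arm_ir),
                     arms_c$end[i] - arms_c$start[i])
          }
        }
      }
    }
  }
  if (length(rows) == 0) return(.empty_events())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Intersect event-state segments across the lesions of one patient
#'
#' Computes the maximal genomic intervals on which a predicate (for example
#' the deletion state) holds in every lesion — the shared-segment step of
#' the clonality analysis.
#'
#' @param segments_by_lesion Named list (one element per lesion, at least
#'   two) of segment `data.frame`s.
#' @param predicate Function mapping a segment `data.frame` to a logical
#'   vector marking rows in the state of interest.
#' @return A `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), disjoint and sorted.
#' @export
intersect_shared_segments <- function(segments_by_lesion, predicate) {
  if (length(segments_by_lesion) < 2) {
    stop("shared-segment intersection needs at least 2 lesions")
  }
  per_lesion <- lapply(segments_by_lesion, function(seg) {
    validate_segments(seg)
    hit <- seg[predicate(seg), , drop = FALSE]
    split(hit, hit$chrom)
  })
  chroms <- Reduce(intersect, lapply(per_lesion, names))
  rows <- list()
  for (chrom in sort(chroms)) {
    shared <- NULL
    for (lst in per_lesion) {
      ir <- IRanges::reduce(.as_iranges(lst[[chrom]]$start, lst[[chrom]]$end))
      shared <- if (is.null(shared)) ir else IRanges::intersect(shared, ir)
    }
    if (length(shared) > 0) {
      rows[[length(rows) + 1]] <-
        cbind(data.frame(chrom = chrom), .from_iranges(shared))
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Reciprocal overlap of two footprints (matrices of 0-based half-open
# intervals): the intersection length must be at least `fraction` of EACH
# footprint's total length.
.reciprocal_overlap <- function(fp1, fp2, fraction) {
  ir1 <- IRanges::reduce(.as_iranges(fp1[, 1], fp1[, 2]))
  ir2 <- IRanges::reduce(.as_iranges(fp2[, 1], fp2[, 2]))
  ov <- sum(IRanges::width(IRanges::intersect(ir1, ir2)))
  ov >= fraction * sum(IRanges::width(ir1)) &&
    ov >= fraction * sum(IRanges::width(ir2))
}

# Binary presence matrix (lesions x feature keys) for a prepared case.
# SNV features match on the exact (chrom, pos, ref, alt) key; CNV events
# with the same (kind, label) collapse into one feature when all pairwise
# reciprocal overlaps pass, and fall back to per-lesion features otherwise.
.feature_presence <- function(case, panel_only = FALSE,
                              panel = driver_panel(),
                              overlap_fraction = 0.5) {
  lesions <- case$lesions
  ids <- names(lesions)
  feat <- list()  # feature key -> lesion ids carrying it
  for (l in lesions) {
    if (is.null(l$events)) {
      stop("case not prepared: run prepare_case() first")
    }
    v <- l$variants
    if (panel_only) v <- restrict_to_driver_panel(v, panel)
    if (nrow(v) > 0) {
      for (k in paste0("SNV:", v$gene, ":", variant_key(v))) {
        feat[[k]] <- c(feat[[k]], l$lesion_id)
      }
    }
  }
  # group CNV events by (kind, label) across lesions
  ev_all <- do.call(rbind, lapply(lesions, function(l) l$events))
  if (!is.null(ev_all) && nrow(ev_all) > 0) {
    for (grp in split(ev_all, paste(ev_all$kind, ev_all$label))) {
      key <- paste0("CNV:", grp$kind[1], ":", grp$label[1])
      ok <- TRUE
      if (nrow(grp) > 1) {
        for (i in seq_len(nrow(grp) - 1)) {
          for (j in seq(i + 1, nrow(grp))) {
            if (!.reciprocal_overlap(grp$footprint[[i]], grp$footprint[[j]],
                                     overlap_fraction)) {
              ok <- FALSE
            }
          }
        }
      }
      if (ok) {
        feat[[key]] <- c(feat[[key]], grp$lesion_id)
      } else {
        for (i in seq_len(nrow(grp))) {
          feat[[paste0(key, "@", grp$lesion_id[i])]] <- grp$lesion_id[i]
        }
      }
    }
  }
  keys <- sort(names(feat))
  m <- matrix(0L, nrow = length(ids), ncol = length(keys),
              dimnames = list(ids, keys))
  for (k in keys) m[feat[[k]], k] <- 1L
  m
}

#' Partition a patient's alterations into shared and private features
#'
#' Every feature (SNV identity key or called CNV/LOH event) is assigned to
#' exactly one category: shared by all lesions, partially shared (present in
#' more than one lesion but not all), or private to a single lesion.
#'
#' @param case A prepared `mm_case` (see [prepare_case()]).
#' @param overlap_fraction Reciprocal-overlap fraction for matching CNV
#'   events across lesions (default 0.5).
#' @return A list with character vectors `shared_by_all`,
#'   `partially_shared`, `private`, the binary `presence` matrix, and a
#'   per-lesion `counts` data.frame with columns `lesion_id`, `n_shared`,
#'   `n_partial`, `n_private`.
#' @export
shared_private_partition <- function(case, overlap_fraction = 0.5) {
  stopifnot(inherits(case, "mm_case"))
  if (length(case$lesions) < 2) {
    warning("single-lesion case: every feature is trivially shared by all")
  }
  m <- .feature_presence(case, panel_only = FALSE,
                         overlap_fraction = overlap_fraction)
  n_lesions <- nrow(m)
  carried <- colSums(m)
  shared <- colnames(m)[carried == n_lesions]
  private <- colnames(m)[carried == 1 & n_lesions > 1]
  partial <- setdiff(colnames(m), c(shared, private))
  counts <- data.frame(
    lesion_id = rownames(m),
    n_shared = as.integer(m[, shared, drop = FALSE] %*%
                            rep(1, length(shared))),
    n_partial = as.integer(m[, partial, drop = FALSE] %*%
                             rep(1, length(partial))),
    n_private = as.integer(m[, private, drop = FALSE] %*%
                             rep(1, length(private))),
    stringsAsFactors = FALSE
  )
  list(shared_by_all = shared, partially_shared = partial,
       private = private, presence = m, counts = counts)
}
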