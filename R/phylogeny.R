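# Binary alteration matrices, Manhattan distances and neighbor-joining
# phylogenies.
#
# The tree method is the classical agglomerative algorithm of Saitou & Nei:
# at each step the pair (i, j) minimizing
#   Q(i, j) = (r - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k)
# is joined, with branch lengths from the standard closed forms. Ties are
# broken by the first minimal pair scanned in label-sorted row-major order,
# and negative branch lengths are clamped to zero with the deficit moved to
# the sister branch, so the output is fully deterministic.

#' Build the binary alteration matrix of a patient
#'
#' One row per lesion, one column per distinct feature: panel-gene SNV/INDEL
#' identity keys plus called CNV/LOH event keys (matched across lesions by
#' the reciprocal-overlap rule). Cells record presence (1) or absence (0).
#' Features carried by every lesion are retained — with the all-zero
#' germline outgroup row they separate the root from the tumor clade.
#'
#' @param case A prepared `mm_case` (see [prepare_case()]).
#' @param include_outgroup Append an all-zero row labelled `"germline"`
#'   (default `TRUE`); with it, a two-lesion patient still has the three
#'   rows needed for tree estimation.
#' @param panel Driver gene panel for SNV features.
#' @param overlap_fraction Reciprocal-overlap fraction for CNV matching.
#' @return Integer matrix with lesion ids as row names and feature keys as
#'   column names.
#' @export
build_feature_matrix <- function(case, include_outgroup = TRUE,
                                 panel = driver_panel(),
                                 overlap_fraction = 0.5) {
  stopifnot(inherits(case, "mm_case"))
  m <- .feature_presence(case, panel_only = TRUE, panel = panel,
                         overlap_fraction = overlap_fraction)
  if (ncol(m) == 0) {
    stop("no alteration features found for patient ", case$patient_id,
         ": review filter and event-calling thresholds")
  }
  if (include_outgroup) {
    if ("germline" %in% rownames(m)) {
      stop("a lesion is already labelled 'germline'")
    }
    m <- rbind(m, germline = 0L)
  }
  m
}

#' Manhattan distance matrix between lesion alteration profiles
#'
#' `d(i, j) = sum_k |x_ik - x_jk|`; on binary data this is the Hamming
#' count of differing features.
#'
#' @param matrix Feature matrix from [build_feature_matrix()] (any numeric
#'   matrix with at least two rows is accepted).
#' @return Square symmetric numeric matrix with zero diagonal.
#' @export
manhattan_distance_matrix <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 2)
  as.matrix(stats::dist(matrix, method = "manhattan"))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei neighbor joining with deterministic tie-breaking
#' and non-negative branch lengths (see the file-level notes). On an
#' additive (tree-metric) input the true topology and branch lengths are
#' recovered exactly. When a `"germline"` label is present the returned
#' tree is rooted on that leaf; otherwise it is unrooted (basal
#' trifurcation).
#'
#' @param dist Square symmetric numeric matrix with zero diagonal and row
#'   and column labels; at least 3 labels.
#' @return An [ape::ape-package] `phylo` object.
#' @export
neighbor_joining <- function(dist) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 labels")
  if (is.null(rownames(d))) stop("distance matrix must have labels")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)) ||
      any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  if (any(d < 0)) stop("distances must be non-negative")
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]

  # per active node: newick fragment and smallest leaf label in its subtree
  repr <- rownames(d)
  min_leaf <- rownames(d)
  fmt <- function(x) sprintf("%.17g", x)
  clamp2 <- function(li, lj) {
    # move any negative deficit to the sister branch (total preserved)
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(li + lj, 0); lj <- 0 }
    c(li, lj)
  }
  join_repr <- function(idx, len) {
    o <- order(min_leaf[idx])
    paste0("(", paste0(repr[idx][o], ":", fmt(len[o]), collapse = ","), ")")
  }

  while (nrow(d) > 3) {
    r <- nrow(d)
    rs <- rowSums(d)
    q <- (r - 2) * d - outer(rs, rs, `+`)
    best <- c(NA, NA); best_q <- Inf
    for (i in seq_len(r - 1)) {
      for (j in seq(i + 1, r)) {
        if (q[i, j] < best_q - 1e-12) { best_q <- q[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    l <- clamp2(li, lj)
    new_repr <- join_repr(c(i, j), l)
    new_min <- min(min_leaf[c(i, j)])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    repr <- c(repr[keep], new_repr)
    min_leaf <- c(min_leaf[keep], new_min)
    rownames(d) <- colnames(d) <- min_leaf
  }
  # resolve the final three nodes around one internal vertex
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  len <- pmax(c(l1, l2, l3), 0)
  o <- order(min_leaf)
  nwk <- paste0("(", paste0(repr[o], ":", fmt(len[o]), collapse = ","), ");")
  tree <- ape::read.tree(text = nwk)
  if ("germline" %in% tree$tip.label) {
    tree <- ape::root(tree, outgroup = "germline", resolve.root = TRUE)
  }
  tree
}

# Quote a label for Newick if it contains reserved characters.
.newick_label <- function(x) {
  if (grepl("[](){}:;,'\" \t\\[]", x)) {
    paste0("'", gsub("'", "''", x), "'")
  } else {
    x
  }
}

#' Write a tree as a canonical Newick string
#'
#' Serializes the tree with branch lengths, ordering the children of every
#' node lexicographically by the smallest leaf label in their subtree so
#' that equivalent trees always print identically. Labels containing
#' Newick-reserved characters are single-quoted.
#'
#' @param tree A `phylo` object.
#' @param path Optional output file; when `NULL` only the string is
#'   returned.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node) {
    if (node <= n_tip) {
      return(list(str = .newick_label(tree$tip.label[node]),
                  min_leaf = tree$tip.label[node]))
    }
    kids <- children[[as.character(node)]]
    sub <- lapply(kids, function(e) {
      s <- rec(tree$edge[e, 2])
      s$str <- paste0(s$str, ":", sprintf("%.17g", tree$edge.length[e]))
      s
    })
    o <- order(vapply(sub, `[[`, character(1), "min_leaf"))
    list(
      str = paste0("(", paste(vapply(sub[o], `[[`, character(1), "str"),
                              collapse = ","), ")"),
      min_leaf = min(vapply(sub, `[[`, character(1), "min_leaf"))
    )
  }
  root <- n_tip + 1L
  nwk <- paste0(rec(root)$str, ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
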