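# Feature matrices, Manhattan distances and neighbor joining.

test_that("feature matrix encodes the S4 alteration structure", {
  fx <- prepared_fixture()
  m <- build_feature_matrix(fx$S4)
  expect_setequal(rownames(m), c("S4-T1", "S4-T2", "germline"))
  expect_true("CNV:deletion:22" %in% colnames(m))
  expect_true("CNV:deletion:1p" %in% colnames(m))
  expect_equal(sum(grepl("^SNV:NF2:", colnames(m))), 2)  # two distinct SNVs
  # chr22 deletion column: all tumors, never germline
  expect_equal(unname(m[c("S4-T1", "S4-T2"), "CNV:deletion:22"]), c(1L, 1L))
  expect_true(all(m["germline", ] == 0))
  # identical lesions give identical rows
  fm1 <- build_feature_matrix(fx$S3)
  expect_equal(unname(fm1["S3-T1", ]), unname(fm1["S3-T2", ]))
  # without outgroup
  expect_false("germline" %in%
                 rownames(build_feature_matrix(fx$S4, FALSE)))
  # no features at all -> error
  empty <- prepare_case(patient_case("P", list(
    lesion_profile("P-T1", somatic_variants(), mk_seg("P-T1", "7", 0, 0.5)),
    lesion_profile("P-T2", somatic_variants(), mk_seg("P-T2", "7", 0, 0.5))
  )))
  expect_error(build_feature_matrix(empty), "no alteration features")
})

test_that("Manhattan distances equal a brute-force double loop", {
  expect_equal(manhattan_distance_matrix(
    rbind(a = c(1, 1, 0), b = c(1, 1, 1)))["a", "b"], 1)
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(rbinom(100, 1, 0.4), nrow = 5, ncol = 20,
                dimnames = list(paste0("L", 1:5), NULL))
    d <- manhattan_distance_matrix(m)
    brute <- matrix(0, 5, 5)
    for (i in 1:5) for (j in 1:5) {
      brute[i, j] <- sum(abs(m[i, ] - m[j, ]))
    }
    expect_equal(unname(d), brute)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    # triangle inequality
    for (i in 1:5) for (j in 1:5) for (k in 1:5) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("neighbor joining resolves the 3-leaf closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(d)
  expect_equal(write_newick(tree), "(A:1,B:1,C:3);")
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
  d_bad <- d; d_bad[1, 2] <- 99
  expect_error(neighbor_joining(d_bad), "symmetric")
})

test_that("neighbor joining is exact on additive tree metrics", {
  skip_if_not_installed("ape")
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    true_tree <- ape::unroot(ape::rtree(n, br = function(k)
      stats::runif(k, 0.05, 2)))
    d <- ape::cophenetic.phylo(true_tree)
    est <- neighbor_joining(d)
    # topology recovered
    expect_equal(ape::dist.topo(ape::unroot(est), true_tree), 0,
                 ignore_attr = TRUE)
    # branch lengths recovered: path lengths reproduce the input matrix
    d2 <- ape::cophenetic.phylo(est)[rownames(d), colnames(d)]
    expect_lt(max(abs(d2 - d)), 1e-9)
  }
})

test_that("neighbor joining agrees with the reference implementation", {
  skip_if_not_installed("ape")
  set.seed(33)
  for (rep in 1:10) {
    m <- matrix(rbinom(120, 1, 0.35), nrow = 6,
                dimnames = list(paste0("L", 1:6), NULL))
    d <- manhattan_distance_matrix(m)
    # integer distances tie frequently and the two implementations break
    # ties differently; a tiny symmetric jitter puts the matrix in generic
    # position where the join order is forced
    jit <- matrix(stats::runif(36, 0, 1e-6), 6, 6)
    jit <- jit + t(jit); diag(jit) <- 0
    d <- d + jit
    ours <- neighbor_joining(d)
    ref <- ape::nj(stats::as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("identical profiles are joined by zero-length branches", {
  d <- manhattan_distance_matrix(rbind(A = c(1, 1, 0), B = c(1, 1, 0),
                                       C = c(0, 0, 1)))
  expect_equal(write_newick(neighbor_joining(d)), "(A:0,B:0,C:3);")
})

test_that("Newick output is canonical and parses back exactly", {
  skip_if_not_installed("ape")
  set.seed(55)
  tr <- ape::rtree(6, br = function(k) round(stats::runif(k, 0.1, 3), 4))
  nwk <- write_newick(tr)
  back <- ape::read.tree(text = nwk)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr), tolerance = 1e-12)
  # canonical: a rotated but equivalent tree prints identically
  rot <- ape::rotate(tr, length(tr$tip.label) + 1)
  expect_identical(write_newick(rot), nwk)
  # reserved characters are quoted
  tr$tip.label[1] <- "lesion one"
  expect_match(write_newick(tr), "'lesion one'", fixed = TRUE)
  # file round trip
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  expect_identical(readLines(path), write_newick(tr))
})

test_that("the germline outgroup roots the tree outside the tumor clade", {
  fx <- prepared_fixture()
  for (pt in c("S1", "S2", "S4")) {
    tree <- neighbor_joining(
      manhattan_distance_matrix(build_feature_matrix(fx[[pt]])))
    expect_true(ape::is.rooted(tree))
    tumors <- setdiff(tree$tip.label, "germline")
    expect_true(ape::is.monophyletic(tree, tumors))
  }
})

test_that("a dominant truncal trunk separates germline from all tumors", {
  cfg <- simulation_config(lesions_per_patient = 4, n_truncal_snv = 12,
                           n_private_snv_per_lesion = 2,
                           sequencing_depth = Inf, seed = 9)
  sim <- simulate_patient(cfg, 1)
  res <- analyze_case(sim$case)
  tree <- ape::read.tree(text = res$newick)
  tumors <- setdiff(tree$tip.label, "germline")
  expect_true(ape::is.monophyletic(tree, tumors))
  # root-adjacent trunk edge carries (at least) the truncal feature count
  m <- res$feature_matrix
  truncal_cols <- colSums(m[tumors, , drop = FALSE]) == length(tumors)
  expect_gte(max(tree$edge.length), sum(truncal_cols) - 1)
})
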