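test_that("hierarchy generation is deterministic with the requested shape", {
  h1 <- generate_hierarchy(3, 2, seed = 11)
  h2 <- generate_hierarchy(3, 2, seed = 11)
  expect_identical(h1, h2)
  expect_identical(generate_hierarchy(1, 5, seed = 1)$labels, "F")
  # per-level branching vector and depth are respected
  h <- generate_hierarchy(4, c(6, 3, 2), seed = 5)
  depth_of <- vapply(h$labels, function(x)
    length(strsplit(x, ".", fixed = TRUE)[[1]]), integer(1))
  expect_lte(max(depth_of), 4)
  expect_lte(length(h$parents[["F"]]), 0)
})

test_that("DAG mode stays acyclic with multi-parent nodes", {
  for (s in 1:5) {
    h <- generate_hierarchy(4, 3, seed = 30 + s, dag_prob = 0.3)
    expect_silent(pillr:::assert_acyclic(h))
  }
  hs <- replicate(10, generate_hierarchy(4, 3, seed = 77, dag_prob = 0.5),
                  simplify = FALSE)
  expect_true(any(vapply(hs, function(h)
    any(lengths(h$parents) > 1), logical(1))))
})

test_that("generated annotations are closed, deterministic and root-free", {
  h <- generate_hierarchy(4, c(6, 3, 2), seed = 2)
  Y1 <- generate_annotations(h, 30, 0.6, seed = 9)
  Y2 <- generate_annotations(h, 30, 0.6, seed = 9)
  expect_identical(Y1, Y2)
  expect_false("F" %in% colnames(Y1))
  # closure restricted to the annotated columns is a fixed point
  expect_equal(true_path_closure(Y1, h), Y1)
  expect_true(all(rowSums(Y1) >= 1))
})

test_that("walks stop at top categories when continuation is improbable", {
  h <- generate_hierarchy(4, c(6, 3, 2), seed = 2)
  tops <- h$labels[vapply(h$parents, function(p) identical(p, "F"),
                          logical(1))]
  Y <- generate_annotations(h, 25, walk_continue_prob = 0, seed = 4)
  expect_true(all(colnames(Y)[colSums(Y) > 0] %in% tops))
})

test_that("unlabeled fraction reserves label-free proteins", {
  h <- generate_hierarchy(4, c(6, 3, 2), seed = 2)
  Y <- generate_annotations(h, 40, 0.6, seed = 9, unlabeled_fraction = 0.25)
  expect_equal(sum(rowSums(Y) == 0), 10)
})

test_that("network generation is seeded and respects the pair budget", {
  h <- generate_hierarchy(4, c(6, 3, 2), seed = 2)
  Y <- generate_annotations(h, 25, 0.6, seed = 9)
  e1 <- generate_network(Y, 60, 0.8, seed = 21)
  e2 <- generate_network(Y, 60, 0.8, seed = 21)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), 60)
  expect_true(all(e1$weight > 0 & e1$weight <= 1))
  expect_true(all(e1$protein_a != e1$protein_b))
  expect_error(generate_network(Y, 1e6, 0.5, seed = 1), "exceeds")
})

test_that("full homophily never joins proteins with disjoint label sets", {
  h <- label_hierarchy(c("R", "a", "b"), list(a = "R", b = "R"))
  Y <- matrix(0, 20, 2, dimnames = list(paste0("p", 1:20), c("a", "b")))
  Y[1:10, "a"] <- 1
  Y[11:20, "b"] <- 1
  for (s in 1:5) {
    e <- generate_network(Y, 30, homophily = 1, seed = s)
    ga <- rownames(Y)[1:10]
    expect_false(any(e$protein_a %in% ga != e$protein_b %in% ga))
  }
})

test_that("homophily raises label sharing across edges above background", {
  jac_pair <- function(Y, a, b) {
    u <- sum(Y[a, ] | Y[b, ])
    if (u == 0) 0 else sum(Y[a, ] & Y[b, ]) / u
  }
  mean_edge_jac <- function(hom, s) {
    ds <- simulate_dataset(n_proteins = 60, n_edges = 150, homophily = hom,
                           seed = s)
    mean(mapply(function(a, b) jac_pair(ds$Y_true, a, b),
                ds$edges$protein_a, ds$edges$protein_b))
  }
  bg <- function(s) {
    ds <- simulate_dataset(n_proteins = 60, n_edges = 150, homophily = 0,
                           seed = s)
    n <- nrow(ds$Y_true)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    mean(mapply(function(a, b) jac_pair(ds$Y_true, a, b),
                idx[, 1], idx[, 2]))
  }
  e0 <- mean(vapply(1:8, function(s) mean_edge_jac(0, s), numeric(1)))
  e8 <- mean(vapply(1:8, function(s) mean_edge_jac(0.8, s), numeric(1)))
  b <- mean(vapply(1:8, bg, numeric(1)))
  expect_gt(e8, e0)
  # homophily-free edges look like background pairs (within sampling error)
  expect_lt(abs(e0 - b), 0.03)
})

test_that("masking respects the dynamic leaf rule and retention guarantee", {
  h <- label_hierarchy(c("A", "A.1", "A.2"), list(A.1 = "A", A.2 = "A"))
  Y <- matrix(1, 1, 3, dimnames = list("p1", c("A", "A.1", "A.2")))
  for (s in 1:10) {
    mk <- mask_leaf_labels(Y, h, m = 2, seed = s)
    # both children go (in either order); the non-leaf parent survives
    expect_equal(mk$N_m, 2)
    expect_setequal(mk$masked_entries$label, c("A.1", "A.2"))
    expect_equal(unname(mk$Y_masked[1, ]), c(1, 0, 0))
  }
  # a protein with one label is never stripped
  Y1 <- matrix(c(1, 0, 0), 1, 3, dimnames = list("p1", c("A", "A.1", "A.2")))
  mk1 <- mask_leaf_labels(Y1, h, m = 5, seed = 1)
  expect_equal(mk1$N_m, 0)
  expect_equal(mk1$Y_masked, Y1)
  # m = 0 is the identity
  mk0 <- mask_leaf_labels(Y, h, m = 0, seed = 1)
  expect_equal(mk0$N_m, 0)
  expect_equal(mk0$Y_masked, Y)
})

test_that("masking a deep chain can cascade onto freed internal labels", {
  h <- label_hierarchy(c("A", "A.1", "A.1.1"), list(A.1 = "A", A.1.1 = "A.1"))
  Y <- matrix(1, 1, 3, dimnames = list("p1", c("A", "A.1", "A.1.1")))
  mk <- mask_leaf_labels(Y, h, m = 2, seed = 3)
  # A.1.1 is the only initial leaf; once gone, A.1 becomes maskable
  expect_equal(mk$masked_entries$label, c("A.1.1", "A.1"))
  expect_equal(unname(mk$Y_masked[1, ]), c(1, 0, 0))
})

test_that("masked matrices stay closed and masked entries were leaves", {
  for (s in 1:5) {
    ds <- simulate_dataset(n_proteins = 40, n_edges = 80, seed = 200 + s)
    mk <- mask_leaf_labels(ds$Y_true, ds$hierarchy, m = 3, seed = 300 + s)
    expect_equal(true_path_closure(mk$Y_masked, ds$hierarchy), mk$Y_masked)
    expect_true(all(rowSums(mk$Y_masked) >= 1))
    expect_equal(mk$N_m, nrow(mk$masked_entries))
    # masked and retained entries are disjoint
    expect_true(all(mk$Y_masked[
      as.matrix(mk$masked_entries[, c("protein", "label")])] == 0))
    # replay the removals: each masked label is a leaf at its removal time
    A <- ancestor_matrix(ds$hierarchy)[colnames(ds$Y_true),
                                       colnames(ds$Y_true)]
    Yr <- ds$Y_true
    for (r in seq_len(mk$N_m)) {
      p <- mk$masked_entries$protein[r]
      lab <- mk$masked_entries$label[r]
      expect_true(lab %in% pillr:::leaf_labels_row(Yr[p, ], A))
      Yr[p, lab] <- 0
    }
    expect_equal(Yr, mk$Y_masked)
  }
})

test_that("masked totals are monotone in m and reproducible", {
  ds <- simulate_dataset(n_proteins = 30, n_edges = 60, seed = 17)
  nms <- vapply(0:5, function(m)
    mask_leaf_labels(ds$Y_true, ds$hierarchy, m, seed = 99)$N_m, numeric(1))
  expect_true(all(diff(nms) >= 0))
  expect_equal(nms[1], 0)
  m1 <- mask_leaf_labels(ds$Y_true, ds$hierarchy, 2, seed = 5)
  m2 <- mask_leaf_labels(ds$Y_true, ds$hierarchy, 2, seed = 5)
  expect_identical(m1, m2)
})

test_that("datasets are reproducible from the seed and fixtures round-trip", {
  d1 <- simulate_dataset(n_proteins = 25, n_edges = 50, seed = 8)
  d2 <- simulate_dataset(n_proteins = 25, n_edges = 50, seed = 8)
  expect_identical(d1$Y_true, d2$Y_true)
  expect_identical(d1$edges, d2$edges)
  dir1 <- file.path(tempdir(), "fx1")
  dir2 <- file.path(tempdir(), "fx2")
  write_fixture(d1, dir1)
  write_fixture(d2, dir2)
  for (f in c("annotations.tsv", "network.tsv", "hierarchy.tsv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  # files reconstruct the dataset
  h <- read_hierarchy_tsv(file.path(dir1, "hierarchy.tsv"))
  expect_setequal(h$labels, d1$hierarchy$labels)
  ann <- read_annotations_tsv(file.path(dir1, "annotations.tsv"))
  Y <- annotation_matrix(ann, h, proteins = rownames(d1$Y_true))
  expect_equal(Y[, colnames(d1$Y_true)], d1$Y_true)
  ed <- read_edges_tsv(file.path(dir1, "network.tsv"))
  expect_equal(nrow(ed), nrow(d1$edges))
})
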