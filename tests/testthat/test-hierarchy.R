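test_that("FunCat dotted identifiers imply prefix hierarchy and annotations", {
  res <- parse_funcat_annotations(data.frame(protein = "p1",
                                             label = "01.03.02"))
  expect_setequal(res$hierarchy$labels, c("01", "01.03", "01.03.02"))
  expect_equal(res$hierarchy$parents[["01.03.02"]], "01.03")
  expect_equal(res$hierarchy$parents[["01.03"]], "01")
  expect_length(res$hierarchy$parents[["01"]], 0)
  expect_equal(res$Y["p1", "01.03.02"], 1)
  expect_equal(sum(res$Y), 1)   # not yet closed

  empty <- parse_funcat_annotations(data.frame(protein = character(0),
                                               label = character(0)))
  expect_length(empty$hierarchy$labels, 0)
  expect_equal(dim(empty$Y), c(0, 0))

  two <- parse_funcat_annotations(data.frame(protein = c("p1", "p2"),
                                             label = c("01", "01")))
  expect_equal(ncol(two$Y), 1)
  expect_equal(unname(colSums(two$Y)), 2)

  expect_error(parse_funcat_annotations(data.frame(p = "p1", l = "01..02")),
               "malformed")
})

test_that("OBO parsing keeps is_a edges, drops obsolete terms, filters namespace", {
  obo <- c("format-version: 1.2", "",
           "[Term]", "id: GO:1", "name: a", "namespace: biological_process",
           "",
           "[Term]", "id: GO:2", "name: b", "namespace: biological_process",
           "is_a: GO:1 ! a",
           "",
           "[Term]", "id: GO:3", "name: c", "namespace: molecular_function",
           "is_a: GO:1",
           "",
           "[Term]", "id: GO:4", "name: dead",
           "namespace: biological_process", "is_a: GO:1",
           "is_obsolete: true",
           "",
           "[Typedef]", "id: part_of")
  h <- parse_obo(obo, namespace = "biological_process")
  expect_setequal(h$labels, c("GO:1", "GO:2"))
  expect_equal(h$parents[["GO:2"]], "GO:1")

  hall <- parse_obo(obo)
  expect_setequal(hall$labels, c("GO:1", "GO:2", "GO:3"))
  expect_warning(parse_obo(obo, namespace = "no_such"), "namespace")
})

test_that("OBO diamond gives two parents and full ancestor set", {
  obo <- c("[Term]", "id: A", "",
           "[Term]", "id: B", "is_a: A", "",
           "[Term]", "id: C", "is_a: A", "",
           "[Term]", "id: D", "is_a: B", "is_a: C")
  h <- parse_obo(obo)
  expect_setequal(h$parents[["D"]], c("B", "C"))
  expect_setequal(label_ancestors(h, "D"), c("A", "B", "C"))
  expect_setequal(oracle_ancestors(h, "D"), c("A", "B", "C"))
})

test_that("cyclic parent relations are rejected", {
  expect_error(label_hierarchy(c("a", "b"), list(a = "b", b = "a")), "cycle")
})

test_that("true path closure adds all ancestors and is idempotent", {
  res <- parse_funcat_annotations(data.frame(p = "p1", l = "01.03.02"))
  Yc <- true_path_closure(res$Y, res$hierarchy)
  expect_equal(unname(Yc["p1", c("01", "01.03", "01.03.02")]), c(1, 1, 1))
  expect_equal(true_path_closure(Yc, res$hierarchy), Yc)

  # DAG diamond: annotating the sink implies all three upper labels
  h <- label_hierarchy(c("A", "B", "C", "D"),
                       list(B = "A", C = "A", D = c("B", "C")))
  Y <- matrix(c(0, 0, 0, 1), 1, 4, dimnames = list("p", c("A", "B", "C", "D")))
  expect_equal(unname(true_path_closure(Y, h)[1, ]), c(1, 1, 1, 1))

  Ybad <- matrix(1, 1, 1, dimnames = list("p", "zz"))
  expect_error(true_path_closure(Ybad, h), "zz")
})

test_that("closure is monotone and shrinks member counts down the hierarchy", {
  for (s in 1:5) {
    h <- rand_hierarchy(10, seed = 100 + s, dag = s %% 2 == 0)
    Y <- rand_closed_annotations(h, 25, seed = 200 + s)
    # adding an annotation never removes a closed one
    set.seed(300 + s)
    Y2 <- Y
    Y2[sample(length(Y2), 5)] <- 1
    Y2c <- true_path_closure(Y2, h)
    expect_true(all(Y2c >= Y))
    # |N(s)| <= |N(a)| for ancestors a
    cnt <- colSums(Y)
    for (lab in h$labels) {
      for (a in oracle_ancestors(h, lab)) {
        expect_lte(cnt[[lab]], cnt[[a]])
      }
    }
  }
})

test_that("leaf labels are per-protein and form an antichain", {
  rows <- data.frame(p = c("p1", "p1", "p2"),
                     l = c("01.03.02", "12.04.02", "12.04"))
  res <- parse_funcat_annotations(rows)
  Yc <- true_path_closure(res$Y, res$hierarchy)
  expect_setequal(protein_leaf_labels(Yc, res$hierarchy, "p1"),
                  c("01.03.02", "12.04.02"))
  # 12.04 has children in the hierarchy but is a leaf *for p2*
  expect_equal(protein_leaf_labels(Yc, res$hierarchy, "p2"), "12.04")
  expect_error(protein_leaf_labels(Yc, res$hierarchy, "nope"), "unknown")

  for (s in 1:5) {
    h <- rand_hierarchy(12, seed = 400 + s)
    Y <- rand_closed_annotations(h, 10, seed = 500 + s)
    for (p in rownames(Y)) {
      leaves <- protein_leaf_labels(Y, h, p)
      for (a in leaves) {
        expect_false(any(leaves %in% oracle_ancestors(h, a)))
      }
    }
  }
  Y0 <- rand_closed_annotations(rand_hierarchy(5, 1), 3, seed = 1,
                                density = 0)
  expect_length(protein_leaf_labels(Y0, rand_hierarchy(5, 1), "q1"), 0)
})

test_that("relationship statistics reproduce hand-counted ratios", {
  # chain A(10) -> B(4) -> C(2) with uncle B'(3), |N(C) n N(B')| = 1
  h <- label_hierarchy(c("A", "B", "C", "Bp"),
                       list(B = "A", C = "B", Bp = "A"))
  prot <- paste0("t", 1:10)
  Y <- matrix(0, 10, 4, dimnames = list(prot, c("A", "B", "C", "Bp")))
  Y[, "A"] <- 1
  Y[1:4, "B"] <- 1
  Y[1:2, "C"] <- 1
  Y[c(2, 5, 6), "Bp"] <- 1
  st <- relationship_statistics(Y, h)
  get <- function(s, rel, r) st$p[st$label == s & st$relation == rel &
                                  st$relative == r]
  expect_equal(get("C", "parent", "B"), 0.5)
  expect_equal(get("C", "grandparent", "A"), 0.2)
  expect_equal(get("C", "uncle", "Bp"), 1 / 3)
  # no grandparent row for depth-2 labels, no parent rows for roots
  expect_length(get("B", "grandparent", "A"), 0)
  expect_false(any(st$label == "A" & st$relation == "parent"))
})

test_that("top-level labels act as uncles through the virtual root", {
  cx <- worked_example_corpus()
  st <- relationship_statistics(cx$Y, cx$hierarchy)
  p <- st$p[st$label == "43.01" & st$relation == "uncle" &
            st$relative == "40"]
  expect_equal(p, 170 / 272)
  expect_equal(round(100 * p, 1), 62.5)
})

test_that("p(s|par) >= p(s|gpar) exactly on random closed annotations", {
  for (s in 1:10) {
    h <- rand_hierarchy(12, seed = 600 + s, dag = s %% 3 == 0)
    Y <- rand_closed_annotations(h, 30, seed = 700 + s)
    st <- relationship_statistics(Y, h)
    get_p <- function(lab, rel, r) st$p[st$label == lab &
                                        st$relation == rel &
                                        st$relative == r]
    # compare along each parent -> grandparent chain (set inclusion of
    # member sets holds chain-wise, not across unrelated parents in a DAG)
    for (lab in h$labels) {
      for (par in h$parents[[lab]]) {
        for (gpar in h$parents[[par]]) {
          pv <- get_p(lab, "parent", par)
          gv <- get_p(lab, "grandparent", gpar)
          if (length(pv) && length(gv)) expect_gte(pv, max(gv))
        }
      }
    }
  }
})

test_that("relationship summaries drop zero-valued likelihoods", {
  h <- label_hierarchy(c("A", "B", "Bp"), list(B = "A", Bp = "A"))
  Y <- matrix(c(1, 1, 1, 0, 0, 1), 2, 3,
              dimnames = list(c("u1", "u2"), c("A", "B", "Bp")))
  Y <- true_path_closure(Y, h)
  st <- relationship_statistics(Y, h)
  sm <- summarize_relationship_statistics(st)
  expect_true(all(sm$n <= table(st$relation)[sm$relation]))
  expect_true(all(sm$median > 0))
})
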