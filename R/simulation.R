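#' Generate a random rooted label hierarchy
#'
#' Builds a rooted tree: the root sits at depth 1 and each node above the
#' bottom level receives a child count drawn uniformly from `1:branching`.
#' `branching` may be a vector of per-level maxima (length `depth - 1`),
#' which allows FunCat-like shapes — a wide top level of function categories
#' with narrower specialization below. Labels are dotted identifiers below a
#' root label `"F"` (e.g. `"F.2.1"`). With `dag_prob > 0` extra cross-parent
#' edges are added (each non-root node gains, with that probability, one
#' additional parent drawn from the strictly shallower levels), producing a
#' DAG while preserving acyclicity.
#'
#' @param depth tree depth (>= 1); `depth = 1` yields the root alone.
#' @param branching maximum child count per node (>= 1), scalar or one value
#'   per level below the root.
#' @param seed integer seed; the result is fully determined by it.
#' @param dag_prob probability of an extra parent per non-root node.
#' @return A `label_hierarchy`.
#' @export
generate_hierarchy <- function(depth, branching, seed, dag_prob = 0) {
  stopifnot(depth >= 1, all(branching >= 1), dag_prob >= 0, dag_prob <= 1)
  set.seed(seed)
  br <- rep(branching, length.out = max(depth - 1, 1))
  labels <- "F"
  parents <- list(F = character(0))
  depth_of <- c(F = 1L)
  if (depth > 1) {
    current <- "F"
    for (d in 2:depth) {
      nxt <- character(0)
      for (node in current) {
        nk <- sample.int(br[[d - 1]], 1)
        kids <- paste(node, seq_len(nk), sep = ".")
        for (k in kids) {
          parents[[k]] <- node
          depth_of[[k]] <- d
        }
        nxt <- c(nxt, kids)
      }
      labels <- c(labels, nxt)
      current <- nxt
    }
  }
  if (dag_prob > 0 && length(labels) > 1) {
    for (nm in setdiff(labels, "F")) {
      if (stats::runif(1) < dag_prob) {
        shallower <- labels[depth_of[labels] < depth_of[[nm]]]
        cand <- setdiff(shallower, parents[[nm]])
        if (length(cand)) {
          parents[[nm]] <- c(parents[[nm]], sample_one(cand))
        }
      }
    }
  }
  label_hierarchy(labels, parents)
}

#' Generate true-path-closed annotations by hierarchical random walks
#'
#' Each protein receives between 1 and `max_walks` walks. A walk starts at
#' the root, steps to a top-level category, and keeps descending with
#' probability `walk_continue_prob` per level, choosing children uniformly.
#' The protein's annotation set is the true-path closure of all walk nodes.
#'
#' Two optional mechanisms make label sets resemble real corpora, where a
#' protein's functions are correlated rather than independent:
#' \describe{
#'   \item{cross-category affinity}{top-level categories are paired
#'     (category 1 with 2, 3 with 4, ...). After the first walk lands in a
#'     category, each later walk enters the *partner* category with
#'     probability `cross_affinity` and mirrors the first walk's child
#'     indices level by level. This creates strongly co-annotated label
#'     pairs with no shared ancestor — flat correlation that an
#'     ancestor-based similarity cannot see.}
#'   \item{coherence restarts}{with probability `coherence` a later walk
#'     restarts from a node the protein is already annotated with, deepening
#'     or branching an existing path instead of opening a new category.}
#' }
#'
#' The root label itself is dropped from the returned matrix: as in FunCat,
#' the top-level categories are the most general annotated labels, so pairs
#' of labels from unrelated categories genuinely share no annotated
#' ancestor. Set `include_root = TRUE` to keep a GO-like universal root
#' (annotated to every protein).
#'
#' @param h a `label_hierarchy` (rooted; walks start at the first root).
#' @param n_proteins number of proteins.
#' @param walk_continue_prob probability in (0, 1) of descending one more
#'   level after reaching a category.
#' @param seed integer seed.
#' @param max_walks maximum walks per protein (walk count uniform in
#'   `1:max_walks`).
#' @param coherence probability that a later walk restarts from an
#'   already-annotated node.
#' @param cross_affinity probability that a later walk enters the partner
#'   category of the protein's first category, mirroring its path.
#' @param unlabeled_fraction fraction of proteins left with no annotation
#'   (they stay in the network but carry no training labels), mirroring real
#'   interactomes that contain uncharacterized proteins.
#' @param include_root keep the root label as an annotated column.
#' @return Binary n x K annotation matrix (proteins `p1..pn`), closed under
#'   the true path rule.
#' @export
generate_annotations <- function(h, n_proteins, walk_continue_prob, seed,
                                 max_walks = 9, coherence = 0,
                                 cross_affinity = 0.83,
                                 unlabeled_fraction = 0,
                                 include_root = FALSE) {
  stopifnot(walk_continue_prob >= 0, walk_continue_prob < 1,
            coherence >= 0, coherence <= 1,
            cross_affinity >= 0, cross_affinity <= 1,
            unlabeled_fraction >= 0, unlabeled_fraction < 1)
  set.seed(seed)
  children <- stats::setNames(vector("list", length(h$labels)), h$labels)
  for (nm in h$labels) {
    for (p in h$parents[[nm]]) children[[p]] <- c(children[[p]], nm)
  }
  root <- hierarchy_roots(h)[1]
  tops <- children[[root]]
  # pair adjacent categories; an odd category out is its own partner
  partner <- stats::setNames(tops, tops)
  np <- 2L * (length(tops) %/% 2L)
  if (np >= 2) partner[tops[1:np]] <- tops[c(matrix(1:np, 2)[2:1, ])]
  proteins <- paste0("p", seq_len(n_proteins))
  Y <- matrix(0, n_proteins, length(h$labels),
              dimnames = list(proteins, h$labels))
  n_unlab <- round(unlabeled_fraction * n_proteins)
  unlabeled <- if (n_unlab > 0) sample(n_proteins, n_unlab) else integer(0)
  for (i in setdiff(seq_len(n_proteins), unlabeled)) {
    ann <- character(0)
    first_top <- NULL
    first_path <- integer(0)
    for (w in seq_len(sample.int(max_walks, 1))) {
      mirror <- NULL      # child-index path to follow, if mirroring
      recording <- FALSE  # whether this walk defines the mirror template
      if (w > 1 && length(ann) && stats::runif(1) < coherence) {
        node <- sample_one(ann)
      } else if (w > 1 && !is.null(first_top) &&
                 stats::runif(1) < cross_affinity) {
        node <- partner[[first_top]]
        mirror <- first_path
      } else if (length(tops)) {
        node <- sample_one(tops)
        if (is.null(first_top)) {
          first_top <- node
          recording <- TRUE
        }
      } else {
        node <- root
      }
      Y[i, node] <- 1
      lvl <- 1L
      while (length(children[[node]]) &&
             stats::runif(1) < walk_continue_prob) {
        kids <- children[[node]]
        idx <- if (!is.null(mirror) && lvl <= length(mirror)) {
          ((mirror[[lvl]] - 1L) %% length(kids)) + 1L
        } else {
          sample.int(length(kids), 1)
        }
        if (recording) first_path <- c(first_path, idx)
        node <- kids[[idx]]
        Y[i, node] <- 1
        lvl <- lvl + 1L
      }
      cur <- node
      while (cur != root) {
        ann <- unique(c(ann, cur))
        cur <- h$parents[[cur]][1]
      }
    }
  }
  Y <- true_path_closure(Y, h)
  if (!include_root) Y <- Y[, setdiff(colnames(Y), root), drop = FALSE]
  Y
}

#' Generate a homophilous weighted interaction network
#'
#' Samples `n_edges` distinct protein pairs with probability proportional to
#' `homophily * Jaccard(label sets) + (1 - homophily) * c`, where `c` is the
#' mean pairwise Jaccard (the uniform component, scaled so the two parts
#' mix on comparable footing); the sampled pair's weight is that mixing
#' score. With `homophily > 0` interacting proteins therefore tend to share
#' labels (the guilt-by-association structure); at `homophily = 1` pairs
#' with disjoint label sets are never joined.
#'
#' @param Y_true closed binary annotation matrix (defines the label sets).
#' @param n_edges number of edges to sample (<= n(n-1)/2).
#' @param homophily mixing coefficient in \[0, 1\].
#' @param seed integer seed.
#' @return data.frame with columns `protein_a`, `protein_b`, `weight`.
#' @export
generate_network <- function(Y_true, n_edges, homophily, seed) {
  stopifnot(homophily >= 0, homophily <= 1)
  n <- nrow(Y_true)
  npairs <- n * (n - 1) / 2
  if (n_edges > npairs) {
    stop("n_edges (", n_edges, ") exceeds the number of pairs (", npairs, ")")
  }
  set.seed(seed)
  cnt <- rowSums(Y_true)
  inter <- tcrossprod(Y_true)
  uni <- outer(cnt, cnt, "+") - inter
  jac <- matrix(0, n, n)
  nz <- uni > 0
  jac[nz] <- inter[nz] / uni[nz]
  ut <- which(upper.tri(jac))
  score <- homophily * jac[ut] + (1 - homophily) * mean(jac[ut])
  pick <- sample(length(ut), n_edges, prob = score)
  sel <- ut[pick]
  proteins <- rownames(Y_true)
  data.frame(protein_a = proteins[row(jac)[sel]],
             protein_b = proteins[col(jac)[sel]],
             weight = score[pick], stringsAsFactors = FALSE)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper producing a hierarchy, closed annotations, and a
#' homophilous network from a single base seed. The defaults emulate a small
#' curated interactome: 300 proteins, about 60 labels in a wide-topped
#' 4-level hierarchy, about 6 labels per protein, average degree about 17,
#' and strong (but imperfect) guilt-by-association structure.
#'
#' @param n_proteins number of proteins.
#' @param depth,branching hierarchy shape (see [generate_hierarchy()]).
#' @param walk_continue_prob annotation walk depth parameter.
#' @param n_edges number of network edges.
#' @param homophily network homophily in \[0, 1\].
#' @param seed base integer seed (sub-seeds for hierarchy/annotations/network
#'   are derived from it).
#' @param unlabeled_fraction fraction of label-free proteins kept in the
#'   network.
#' @param label_range admissible `c(min, max)` for the number of labels; the
#'   hierarchy is redrawn (deterministically, from derived sub-seeds) until
#'   its size falls in this band, keeping datasets comparable across seeds.
#' @param ... further arguments passed to [generate_annotations()].
#' @return List of class `synthetic_dataset`: `hierarchy`, `Y_true`, `edges`,
#'   `seed`, `params`.
#' @export
simulate_dataset <- function(n_proteins = 300, depth = 4,
                             branching = c(12, 4, 3),
                             walk_continue_prob = 0.75, n_edges = 2500,
                             homophily = 0.8, seed = 1,
                             unlabeled_fraction = 0,
                             label_range = c(45, 80), ...) {
  h <- NULL
  for (attempt in 0:99) {
    cand <- generate_hierarchy(depth, branching,
                               seed = seed * 13 + 1 + 1000003L * attempt)
    # label_range counts annotatable labels, i.e. excludes the root
    if (length(cand$labels) - 1 >= label_range[1] &&
        length(cand$labels) - 1 <= label_range[2]) { h <- cand; break }
  }
  if (is.null(h)) h <- cand
  Y <- generate_annotations(h, n_proteins, walk_continue_prob,
                            seed = seed * 13 + 2,
                            unlabeled_fraction = unlabeled_fraction, ...)
  edges <- generate_network(Y, n_edges, homophily, seed = seed * 13 + 3)
  structure(list(hierarchy = h, Y_true = Y, edges = edges, seed = seed,
                 params = list(n_proteins = n_proteins, depth = depth,
                               branching = branching,
                               walk_continue_prob = walk_continue_prob,
                               n_edges = n_edges, homophily = homophily,
                               unlabeled_fraction = unlabeled_fraction,
                               label_range = label_range)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$Y_true), "proteins,",
      ncol(x$Y_true), "labels,", nrow(x$edges), "edges (seed",
      paste0(x$seed, ")\n"))
  invisible(x)
}

# sample() treats a length-1 vector as 1:x; avoid that.
sample_one <- function(x) if (length(x) == 1) x else sample(x, 1)

#' Mask per-protein leaf labels
#'
#' Simulates incomplete annotation: for each protein, up to `m` labels are
#' removed, each drawn uniformly from the protein's *current* leaf labels.
#' The leaf set is recomputed after every single removal, so a label whose
#' annotated descendants have all been masked becomes a leaf and is itself
#' eligible — the dynamic-leaf rule. A protein is never stripped bare: at
#' least one label is always retained. Because only per-protein leaves are
#' ever removed, the masked matrix remains true-path closed.
#'
#' @param Y closed binary annotation matrix.
#' @param h a `label_hierarchy`.
#' @param m requested number of masked labels per protein (>= 0).
#' @param seed integer seed.
#' @return List of class `masking_result`: `Y_masked`, `masked_entries`
#'   (data.frame protein/label), `m`, `N_m` (total removals).
#' @export
mask_leaf_labels <- function(Y, h, m, seed) {
  stopifnot(m >= 0)
  set.seed(seed)
  A <- ancestor_matrix(h)[colnames(Y), colnames(Y), drop = FALSE]
  Ym <- Y
  masked <- list()
  for (i in seq_len(nrow(Y))) {
    for (rep in seq_len(m)) {
      if (sum(Ym[i, ]) <= 1) break
      leaves <- leaf_labels_row(Ym[i, ], A)
      pick <- sample_one(leaves)
      Ym[i, pick] <- 0
      masked[[length(masked) + 1L]] <-
        data.frame(protein = rownames(Y)[i], label = pick,
                   stringsAsFactors = FALSE)
    }
  }
  masked_df <- if (length(masked)) do.call(rbind, masked) else
    data.frame(protein = character(0), label = character(0))
  structure(list(Y_masked = Ym, masked_entries = masked_df, m = m,
                 N_m = nrow(masked_df)),
            class = "masking_result")
}

#' @export
print.masking_result <- function(x, ...) {
  cat("masking_result: m =", x$m, ", N_m =", x$N_m, "masked entries\n")
  invisible(x)
}

#' Write a synthetic dataset as standard input files
#'
#' Emits the three inputs the command-line interface reads — annotation TSV
#' (protein, label), edge TSV (protein_a, protein_b, weight), and the
#' hierarchy as a label/parent TSV — plus a JSON manifest of seed and
#' parameters.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_annotations_tsv(ds$Y_true, file.path(dir, "annotations.tsv"))
  utils::write.table(ds$edges, file.path(dir, "network.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  hdf <- data.frame(
    label = ds$hierarchy$labels,
    parents = vapply(ds$hierarchy$parents[ds$hierarchy$labels],
                     paste, character(1), collapse = ","))
  utils::write.table(hdf, file.path(dir, "hierarchy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(c(list(seed = ds$seed), ds$params),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a hierarchy written by [write_fixture()]
#' @param path hierarchy TSV (label, comma-separated parents).
#' @return A `label_hierarchy`.
#' @export
read_hierarchy_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                          colClasses = "character", comment.char = "#",
                          quote = "")
  parents <- lapply(df[[2]], function(x) {
    if (is.na(x) || !nzchar(x)) character(0)
    else strsplit(x, ",", fixed = TRUE)[[1]]
  })
  names(parents) <- df[[1]]
  label_hierarchy(df[[1]], parents)
}
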