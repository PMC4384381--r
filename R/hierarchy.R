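#' Construct a function-label hierarchy
#'
#' A `label_hierarchy` is a rooted DAG (Gene Ontology case) or tree (FunCat
#' case) of function labels, stored as a child-to-parent relation. A label may
#' have several parents in the DAG case and at most one in a tree. Roots are
#' the labels with no parent; FunCat has several top-level labels, which are
#' treated as siblings under an implicit virtual root for sibling/uncle
#' queries only (the virtual root never enters ancestor sets or annotations).
#'
#' @param labels character vector of unique label identifiers.
#' @param parents named list mapping each label to a character vector of its
#'   parent labels (possibly empty). Labels absent from the list are roots.
#' @return An object of class `label_hierarchy` with elements `labels`
#'   (character) and `parents` (named list).
#' @export
label_hierarchy <- function(labels, parents = list()) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("duplicate label identifiers: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  full <- stats::setNames(vector("list", length(labels)), labels)
  for (nm in names(parents)) {
    if (!nm %in% labels) stop("parent map names unknown label: ", nm)
    p <- as.character(parents[[nm]])
    if (!all(p %in% labels)) {
      stop("unknown parent label(s) for '", nm, "': ",
           paste(setdiff(p, labels), collapse = ", "))
    }
    full[[nm]] <- unique(p)
  }
  for (nm in labels) if (is.null(full[[nm]])) full[[nm]] <- character(0)
  h <- structure(list(labels = labels, parents = full),
                 class = "label_hierarchy")
  assert_acyclic(h)
  h
}

#' @export
print.label_hierarchy <- function(x, ...) {
  nr <- sum(lengths(x$parents) == 0)
  cat("label_hierarchy:", length(x$labels), "labels,", nr, "root(s)\n")
  invisible(x)
}

# Topological order (parents before children); errors on cycles.
topological_order <- function(h) {
  n <- length(h$labels)
  idx <- stats::setNames(seq_len(n), h$labels)
  indeg <- lengths(h$parents)[h$labels]
  children <- stats::setNames(vector("list", n), h$labels)
  for (nm in h$labels) {
    for (p in h$parents[[nm]]) children[[p]] <- c(children[[p]], nm)
  }
  queue <- h$labels[indeg == 0]
  out <- character(0)
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[[idx[[ch]]]] <- indeg[[idx[[ch]]]] - 1L
      if (indeg[[idx[[ch]]]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n) {
    stop("label hierarchy contains a cycle involving: ",
         paste(setdiff(h$labels, out), collapse = ", "))
  }
  out
}

assert_acyclic <- function(h) invisible(topological_order(h))

#' Roots of a hierarchy
#' @param h a `label_hierarchy`.
#' @return Character vector of labels with no parent.
#' @export
hierarchy_roots <- function(h) h$labels[lengths(h$parents[h$labels]) == 0]

#' Proper-ancestor indicator matrix
#'
#' Computes the K x K logical matrix `A` with `A[j, k] == TRUE` iff label `j`
#' is a proper ancestor of label `k` (transitively, over all parents).
#'
#' @param h a `label_hierarchy`.
#' @return Logical K x K matrix with label dimnames.
#' @export
ancestor_matrix <- function(h) {
  K <- length(h$labels)
  A <- matrix(FALSE, K, K, dimnames = list(h$labels, h$labels))
  for (nm in topological_order(h)) {
    for (p in h$parents[[nm]]) {
      A[p, nm] <- TRUE
      A[, nm] <- A[, nm] | A[, p]
    }
  }
  A
}

#' Ancestors of a label
#' @param h a `label_hierarchy`.
#' @param label a label identifier present in `h`.
#' @return Character vector of all proper ancestors (unordered).
#' @export
label_ancestors <- function(h, label) {
  if (!label %in% h$labels) stop("unknown label: ", label)
  seen <- character(0)
  frontier <- h$parents[[label]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(h$parents[new], use.names = FALSE))
  }
  seen
}

#' Parse FunCat-style dotted annotations
#'
#' FunCat identifiers encode the tree by prefixes: "01.03.02" is a child of
#' "01.03", which is a child of "01". The hierarchy returned contains every
#' annotated label plus every implied ancestor prefix. The annotation matrix
#' is *not* true-path closed; apply [true_path_closure()] separately.
#'
#' @param rows data.frame (or 2-column matrix) with columns protein and label,
#'   one row per (protein, dotted label) annotation.
#' @return List with elements `hierarchy` (a `label_hierarchy`) and `Y`
#'   (binary protein x label matrix, proteins in order of first appearance).
#' @export
parse_funcat_annotations <- function(rows) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (nrow(rows) == 0) {
    return(list(hierarchy = label_hierarchy(character(0)),
                Y = matrix(0, 0, 0)))
  }
  prot <- as.character(rows[[1]])
  lab <- as.character(rows[[2]])
  for (i in seq_along(lab)) {
    toks <- strsplit(lab[[i]], ".", fixed = TRUE)[[1]]
    if (length(toks) == 0 || any(!nzchar(toks))) {
      stop("malformed dotted identifier '", lab[[i]], "' at row ", i)
    }
  }
  all_labels <- unique(unlist(lapply(unique(lab), function(x) {
    toks <- strsplit(x, ".", fixed = TRUE)[[1]]
    vapply(seq_along(toks), function(d) paste(toks[1:d], collapse = "."),
           character(1))
  })))
  parents <- lapply(all_labels, function(x) {
    toks <- strsplit(x, ".", fixed = TRUE)[[1]]
    if (length(toks) == 1) character(0)
    else paste(toks[-length(toks)], collapse = ".")
  })
  names(parents) <- all_labels
  h <- label_hierarchy(all_labels, parents)
  proteins <- unique(prot)
  Y <- matrix(0, length(proteins), length(all_labels),
              dimnames = list(proteins, all_labels))
  Y[cbind(prot, lab)] <- 1
  list(hierarchy = h, Y = Y)
}

#' Parse an OBO 1.2 ontology file into a label hierarchy
#'
#' Reads `[Term]` stanzas, keeping `is_a` edges only. Obsolete terms are
#' dropped; when `namespace` is given, only terms of that namespace are kept
#' (with `is_a` edges restricted to retained terms).
#'
#' @param obo path to an OBO file, or a character vector of its lines.
#' @param namespace optional namespace filter, e.g. `"biological_process"`.
#' @return A `label_hierarchy`.
#' @export
parse_obo <- function(obo, namespace = NULL) {
  lines <- if (length(obo) == 1 && file.exists(obo)) readLines(obo, warn = FALSE) else obo
  lines <- sub("\\s*!.*$", "", lines)          # trailing comments
  stanza_starts <- grep("^\\[", lines)
  term_ids <- character(0)
  term_ns <- character(0)
  term_parents <- list()
  starts <- c(stanza_starts, length(lines) + 1L)
  for (si in seq_along(stanza_starts)) {
    if (trimws(lines[stanza_starts[si]]) != "[Term]") next
    body <- lines[(stanza_starts[si] + 1L):(starts[si + 1L] - 1L)]
    get <- function(tag) {
      v <- body[startsWith(body, paste0(tag, ":"))]
      trimws(sub(paste0("^", tag, ":"), "", v))
    }
    id <- get("id")
    if (length(id) != 1) next
    if (any(tolower(get("is_obsolete")) == "true")) next
    ns <- get("namespace")
    isa <- sub("\\s.*$", "", get("is_a"))
    term_ids <- c(term_ids, id)
    term_ns <- c(term_ns, if (length(ns)) ns[[1]] else NA_character_)
    term_parents[[id]] <- isa
  }
  if (!is.null(namespace)) {
    keep <- !is.na(term_ns) & term_ns == namespace
    if (!any(keep)) {
      warning("no terms in namespace '", namespace, "'")
    }
    term_ids <- term_ids[keep]
    term_parents <- term_parents[term_ids]
  }
  term_parents <- lapply(term_parents, function(p) intersect(p, term_ids))
  label_hierarchy(term_ids, term_parents)
}

#' Enforce the true path rule on an annotation matrix
#'
#' The true path rule states that annotation with a label implies annotation
#' with all of its ancestors. This returns the minimal closed superset of the
#' input: `Y[i, j] == 1` whenever `Y[i, k] == 1` for some descendant `k` of
#' `j`. The operation is idempotent.
#'
#' @param Y binary protein x label matrix (column names are labels of `h`).
#' @param h a `label_hierarchy` containing every column label of `Y`.
#' @return Closed binary matrix of the same shape.
#' @export
true_path_closure <- function(Y, h) {
  missing_labels <- setdiff(colnames(Y), h$labels)
  if (length(missing_labels)) {
    stop("annotation labels absent from hierarchy: ",
         paste(missing_labels, collapse = ", "))
  }
  if (nrow(Y) == 0 || ncol(Y) == 0) return(Y)
  A <- ancestor_matrix(h)[colnames(Y), colnames(Y), drop = FALSE]
  # reach[k, j]: j is k itself or an ancestor of k
  reach <- t(A) | diag(TRUE, ncol(Y))
  out <- (Y %*% (reach * 1) > 0) * 1
  dimnames(out) <- dimnames(Y)
  out
}

#' Per-protein leaf labels
#'
#' A label is a leaf *for a protein* when the protein is annotated with it but
#' with none of its descendants. The leaf/non-leaf status is therefore
#' relative to each protein, not to the hierarchy: a label with children in
#' the hierarchy is still a leaf for a protein annotated no deeper.
#'
#' @param Y true-path-closed binary annotation matrix.
#' @param h a `label_hierarchy`.
#' @param protein a row name of `Y`.
#' @return Character vector of leaf labels for that protein.
#' @export
protein_leaf_labels <- function(Y, h, protein) {
  if (!protein %in% rownames(Y)) stop("unknown protein: ", protein)
  A <- ancestor_matrix(h)[colnames(Y), colnames(Y), drop = FALSE]
  leaf_labels_row(Y[protein, ], A)
}

# Vector version: y is a 0/1 label vector, A the proper-ancestor matrix
# restricted to y's labels. Returns names of per-protein leaves.
leaf_labels_row <- function(y, A) {
  ann <- y > 0
  if (!any(ann)) return(character(0))
  # a label has an annotated descendant iff some annotated k has it as ancestor
  has_desc <- (A[, ann, drop = FALSE] %*% rep(1, sum(ann))) > 0
  names(y)[ann & !has_desc]
}

# Sibling map under the virtual-root convention: labels sharing a parent are
# siblings; labels with no parent (FunCat top levels) are mutual siblings.
sibling_sets <- function(h) {
  sibs <- stats::setNames(vector("list", length(h$labels)), h$labels)
  roots <- hierarchy_roots(h)
  for (r in roots) sibs[[r]] <- setdiff(roots, r)
  children_of <- stats::setNames(vector("list", length(h$labels)), h$labels)
  for (nm in h$labels) {
    for (p in h$parents[[nm]]) children_of[[p]] <- c(children_of[[p]], nm)
  }
  for (p in h$labels) {
    kids <- children_of[[p]]
    for (k in kids) sibs[[k]] <- unique(c(sibs[[k]], setdiff(kids, k)))
  }
  sibs
}

#' Hierarchical relationship statistics
#'
#' For every label `s`, estimates the conditional probability that a protein
#' carries `s` given that it carries a parent, grandparent, or uncle (parent's
#' sibling) of `s`, as member-count ratios on a true-path-closed annotation
#' matrix: `p(s | r) = |N(s) n N(r)| / |N(r)|`. Top-level labels are treated
#' as siblings of one another (virtual-root convention), so a top-level label
#' can be the uncle of another top-level label's children.
#'
#' Under closure `N(s)` is a subset of `N(par(s))`, so `p(s | par(s)) >=
#' p(s | gpar(s))` holds exactly for every label with a grandparent.
#'
#' @param Y true-path-closed binary annotation matrix.
#' @param h a `label_hierarchy` covering the columns of `Y`.
#' @return data.frame with columns `label`, `relation` (one of `"parent"`,
#'   `"grandparent"`, `"uncle"`), `relative`, `n_joint`, `n_relative`, `p`.
#'   One row per (label, relative) pair; pairs whose relative has no member
#'   protein are omitted (the ratio is undefined).
#' @export
relationship_statistics <- function(Y, h) {
  stopifnot(all(colnames(Y) %in% h$labels))
  cnt <- colSums(Y)
  joint <- crossprod(Y)                 # |N(a) n N(b)|
  sibs <- sibling_sets(h)
  rows <- list()
  add <- function(s, relation, r) {
    if (cnt[[r]] == 0) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      label = s, relation = relation, relative = r,
      n_joint = joint[s, r], n_relative = cnt[[r]],
      p = joint[s, r] / cnt[[r]], stringsAsFactors = FALSE)
  }
  for (s in colnames(Y)) {
    pars <- intersect(h$parents[[s]], colnames(Y))
    for (p in pars) add(s, "parent", p)
    gpars <- unique(unlist(h$parents[pars], use.names = FALSE))
    for (g in intersect(gpars, colnames(Y))) add(s, "grandparent", g)
    uncles <- unique(unlist(sibs[pars], use.names = FALSE))
    for (u in intersect(setdiff(uncles, s), colnames(Y))) add(s, "uncle", u)
  }
  if (!length(rows)) {
    return(data.frame(label = character(0), relation = character(0),
                      relative = character(0), n_joint = numeric(0),
                      n_relative = numeric(0), p = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Summarize relationship statistics per relation
#'
#' Drops zero-valued conditional probabilities (pairs that never co-annotate
#' a protein) and returns distribution summaries per relation type, the form
#' in which these likelihoods are usually compared.
#'
#' @param stats data.frame from [relationship_statistics()].
#' @return data.frame with one row per relation: n, median, q25, q75, mean.
#' @export
summarize_relationship_statistics <- function(stats) {
  stats <- stats[stats$p > 0, , drop = FALSE]
  out <- lapply(split(stats$p, stats$relation), function(p) {
    q <- stats::quantile(p, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(p), q25 = q[1], median = q[2], q75 = q[3],
               mean = mean(p))
  })
  res <- do.call(rbind, out)
  res$relation <- names(out)
  rownames(res) <- NULL
  res[, c("relation", "n", "q25", "median", "q75", "mean")]
}
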