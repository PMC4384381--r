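#' Build a row-normalized interaction weight matrix
#'
#' Edges are undirected; duplicate/reciprocal entries are symmetrized by
#' taking the maximum weight. Each row of the returned matrix sums to 1,
#' except rows of proteins with no interactions, which are all zero. The
#' diagonal is zero.
#'
#' @param edges data.frame (or 3-column matrix) with columns protein_a,
#'   protein_b, weight; weights must be nonnegative.
#' @param proteins ordered character vector of protein identifiers; defines
#'   the row/column order (must cover every edge endpoint).
#' @return Sparse `dgCMatrix` (n x n) with protein dimnames.
#' @export
build_weights <- function(edges, proteins) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  n <- length(proteins)
  if (nrow(edges) == 0) {
    W <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n), dimnames = list(proteins, proteins))
    return(W)
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  w <- as.numeric(edges[[3]])
  if (any(w < 0)) stop("negative edge weight(s)")
  bad <- setdiff(unique(c(a, b)), proteins)
  if (length(bad)) {
    stop("edge endpoint(s) not in protein list: ", paste(bad, collapse = ", "))
  }
  ia <- match(a, proteins)
  ib <- match(b, proteins)
  keep <- ia != ib
  ia <- ia[keep]; ib <- ib[keep]; w <- w[keep]
  # symmetrize by max over both orientations / duplicates of each pair
  key <- paste(pmin(c(ia, ib), c(ib, ia)), pmax(c(ia, ib), c(ib, ia)))
  mx <- tapply(c(w, w), key, max)
  ij <- do.call(rbind, strsplit(names(mx), " "))
  i1 <- as.integer(ij[, 1]); j1 <- as.integer(ij[, 2])
  W <- Matrix::sparseMatrix(i = c(i1, j1), j = c(j1, i1), x = c(mx, mx),
                            dims = c(n, n), use.last.ij = TRUE,
                            dimnames = list(proteins, proteins))
  rs <- Matrix::rowSums(W)
  iso <- sum(rs == 0)
  if (iso > 0) {
    message(iso, " isolated protein(s) with all-zero weight rows")
  }
  scale <- ifelse(rs > 0, 1 / rs, 0)
  W <- Matrix::Diagonal(x = scale) %*% W
  dimnames(W) <- list(proteins, proteins)
  W
}

#' Estimate likelihoods of missing labels
#'
#' For each labeled protein i and each label k: the estimate is 1 where
#' `Y[i, k] == 1` (a known label stays confirmed), and otherwise the inner
#' product of the protein's known label vector with column k of the
#' row-normalized correlation matrix — large when k is strongly correlated
#' with labels the protein already carries. Values are clipped to \[0, 1\].
#' Rows of unlabeled proteins are all zero (they carry no labels to propagate
#' from; the empirical loss masks them out).
#'
#' @param Y binary annotation matrix (n x K), rows of unlabeled proteins all
#'   zero.
#' @param corr a `label_correlation` (its `Cm` is used), labels matching
#'   `colnames(Y)`.
#' @param labeled logical vector of length n: which proteins count as
#'   (partially) labeled.
#' @return Numeric n x K matrix of estimated likelihoods.
#' @export
estimate_missing_labels <- function(Y, corr, labeled = rep(TRUE, nrow(Y))) {
  stopifnot(inherits(corr, "label_correlation"),
            identical(colnames(Y), corr$labels),
            length(labeled) == nrow(Y))
  if (sum(labeled) > nrow(Y)) stop("more labeled proteins than proteins")
  tilde <- Y %*% corr$Cm
  tilde[tilde > 1] <- 1
  tilde[tilde < 0] <- 0
  tilde[Y == 1] <- 1
  tilde[!labeled, ] <- 0
  dimnames(tilde) <- dimnames(Y)
  tilde
}

#' Solve the graph-regularized replenishment objective
#'
#' Minimizes
#' `Psi(F) = tr((F - Ytilde)' U (F - Ytilde)) + lambda tr(F' (I-W)'(I-W) F)`
#' where `U` is the diagonal indicator of labeled proteins. The objective is
#' an unconstrained convex quadratic; the unique minimizer solves the normal
#' equations `(U + lambda M) F = U Ytilde` with `M = (I-W)'(I-W)`, which are
#' solved exactly by sparse Cholesky factorization.
#'
#' @param tilde_Y n x K matrix of estimated label likelihoods.
#' @param W row-normalized weight matrix from [build_weights()].
#' @param lambda positive scalar balancing empirical loss and smoothness.
#' @param labeled logical vector (diagonal of U).
#' @return List of class `pill_fit`: `F` (n x K scores), `tilde_Y`, `lambda`,
#'   `labeled`, `residual` (relative stationarity residual).
#' @export
solve_propagation <- function(tilde_Y, W, lambda, labeled = rep(TRUE, nrow(tilde_Y))) {
  if (lambda <= 0) stop("lambda must be > 0")
  n <- nrow(tilde_Y)
  stopifnot(nrow(W) == n, length(labeled) == n)
  IW <- Matrix::Diagonal(n) - W
  M <- Matrix::crossprod(IW)
  A <- Matrix::Diagonal(x = as.numeric(labeled)) + lambda * M
  B <- as.numeric(labeled) * tilde_Y
  Fhat <- tryCatch(
    as.matrix(Matrix::solve(A, B)),
    error = function(e) {
      stop("singular propagation system (a connected component with no ",
           "labeled protein?): ", conditionMessage(e))
    })
  num <- norm(as.matrix(A %*% Fhat - B), "F")
  den <- norm(B, "F")
  dimnames(Fhat) <- dimnames(tilde_Y)
  structure(list(F = Fhat, tilde_Y = tilde_Y, lambda = lambda,
                 labeled = labeled,
                 residual = if (den > 0) num / den else num),
            class = "pill_fit")
}

#' @export
print.pill_fit <- function(x, ...) {
  cat("pill_fit: ", nrow(x$F), " proteins x ", ncol(x$F), " labels",
      if (!is.null(x$variant)) paste0(", variant ", x$variant),
      if (!is.null(x$lambda)) paste0(", lambda ", format(x$lambda)),
      if (!is.null(x$residual)) paste0(", residual ", format(x$residual, digits = 3)),
      "\n", sep = "")
  invisible(x)
}

#' Evaluate the replenishment objective
#'
#' Literal evaluation of the two trace terms:
#' `tr((F - Ytilde)' U (F - Ytilde)) + lambda tr(F' (I-W)'(I-W) F)`.
#' `lambda = 0` is accepted here (empirical term only).
#'
#' @param F n x K score matrix.
#' @param tilde_Y n x K likelihood matrix.
#' @param W row-normalized weight matrix.
#' @param lambda nonnegative scalar.
#' @param labeled logical vector (diagonal of U).
#' @return Nonnegative scalar objective value.
#' @export
objective_value <- function(F, tilde_Y, W, lambda, labeled = rep(TRUE, nrow(F))) {
  stopifnot(identical(dim(F), dim(tilde_Y)))
  D <- F - tilde_Y
  emp <- sum(as.numeric(labeled) * rowSums(D^2))
  IWF <- as.matrix(F - W %*% F)
  emp + lambda * sum(IWF^2)
}

#' Run a prediction variant
#'
#' The full method (`"pill"`) estimates missing-label likelihoods from the
#' ComSim correlation matrix and smooths them over the interaction network.
#' Ablation variants swap the correlation measure (`"pill_jcd"`,
#' `"pill_hsim"`, `"pill_lin"`), drop the network term (`"pill_fc"`, which
#' returns the estimated likelihoods as-is), or drop the correlation-based
#' estimation (`"pill_gba"`, which propagates the raw annotations). The
#' `"naive"` baseline scores every protein with the label-frequency vector of
#' the labeled proteins. Predicted scores are not post-processed with the
#' true path rule.
#'
#' @param Y binary annotation matrix in its training state (masked /
#'   incomplete), rows of unlabeled proteins all zero.
#' @param h a `label_hierarchy` covering the columns of `Y`.
#' @param W row-normalized weight matrix (ignored by `"pill_fc"`/`"naive"`).
#' @param variant one of `"pill"`, `"pill_jcd"`, `"pill_hsim"`, `"pill_lin"`,
#'   `"pill_fc"`, `"pill_gba"`, `"naive"`.
#' @param lambda positive smoothness weight (default 1).
#' @param labeled logical vector: which proteins are (partially) labeled.
#' @param corr optional precomputed `label_correlation` to reuse; its kind
#'   must match the variant's.
#' @return A `pill_fit` with the score matrix in `$F` and the variant
#'   recorded.
#' @export
run_variant <- function(Y, h, W = NULL,
                        variant = c("pill", "pill_jcd", "pill_hsim",
                                    "pill_lin", "pill_fc", "pill_gba", "naive"),
                        lambda = 1, labeled = rep(TRUE, nrow(Y)), corr = NULL) {
  variant <- match.arg(variant)
  kind <- switch(variant,
                 pill = "comsim", pill_fc = "comsim",
                 pill_jcd = "jcd", pill_hsim = "hsim", pill_lin = "lin",
                 pill_gba = NA_character_, naive = NA_character_)
  if (variant == "naive") {
    nl <- sum(labeled)
    freq <- if (nl > 0) colSums(Y[labeled, , drop = FALSE]) / nl else
      numeric(ncol(Y))
    Fhat <- matrix(freq, nrow(Y), ncol(Y), byrow = TRUE,
                   dimnames = dimnames(Y))
    return(structure(list(F = Fhat, tilde_Y = NULL, lambda = NA_real_,
                          labeled = labeled, variant = variant),
                     class = "pill_fit"))
  }
  if (variant == "pill_gba") {
    tilde <- Y
    tilde[!labeled, ] <- 0
  } else {
    if (is.null(corr)) {
      corr <- label_correlation(Y, h, kind)
    } else if (!identical(corr$kind, kind)) {
      stop("precomputed correlation kind '", corr$kind,
           "' does not match variant '", variant, "'")
    }
    tilde <- estimate_missing_labels(Y, corr, labeled)
  }
  if (variant == "pill_fc") {
    return(structure(list(F = tilde, tilde_Y = tilde, lambda = NA_real_,
                          labeled = labeled, variant = variant),
                     class = "pill_fit"))
  }
  if (is.null(W)) stop("variant '", variant, "' needs a weight matrix W")
  fit <- solve_propagation(tilde, W, lambda, labeled)
  fit$variant <- variant
  fit
}

#' Write predictions as TSV
#'
#' One row per (protein, label, score), sorted by protein then descending
#' score; optionally only the top `r` labels per protein.
#'
#' @param fit a `pill_fit`.
#' @param path output file.
#' @param top_r optional per-protein cutoff.
#' @export
write_predictions_tsv <- function(fit, path, top_r = NULL) {
  Fm <- fit$F
  rows <- lapply(rownames(Fm), function(p) {
    o <- order(Fm[p, ], decreasing = TRUE)
    if (!is.null(top_r)) o <- o[seq_len(min(top_r, length(o)))]
    data.frame(protein = p, label = colnames(Fm)[o], score = Fm[p, o],
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
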