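#' Label membership probability
#'
#' The probability that a protein carries a label, estimated as the fraction
#' of corpus proteins annotated with it: `|N(label)| / n`. The negative log of
#' this quantity is the label's information content.
#'
#' @param Y true-path-closed binary annotation matrix (n proteins x K labels).
#' @param label a column name of `Y`.
#' @return Numeric scalar in \[0, 1\].
#' @export
label_probability <- function(Y, label) {
  if (nrow(Y) == 0) stop("annotation matrix has no proteins")
  if (!label %in% colnames(Y)) stop("unknown label: ", label)
  sum(Y[, label]) / nrow(Y)
}

# Internal workhorse: p_ca and p_sa matrices for all label pairs.
#
# ca(s,t): proper ancestors common to s and t.  sa(s,t): ca(s,t) plus s when s
# is an ancestor of t (and vice versa).  p_ca / p_sa are the minimum label
# probability over those sets, 0 when the set is empty.  Diagonal entries are
# left NA: the s == t case is defined directly by the similarity functions.
min_subsumer_probs <- function(Y, h) {
  labs <- colnames(Y)
  K <- length(labs)
  p <- colSums(Y) / max(nrow(Y), 1L)
  A <- ancestor_matrix(h)[labs, labs, drop = FALSE]
  anc_idx <- lapply(seq_len(K), function(k) which(A[, k]))
  p_ca <- matrix(NA_real_, K, K, dimnames = list(labs, labs))
  p_sa <- matrix(NA_real_, K, K, dimnames = list(labs, labs))
  if (K < 2) return(list(p = p, A = A, p_ca = p_ca, p_sa = p_sa))
  for (s in 1:(K - 1)) {
    for (t in (s + 1):K) {
      ca <- intersect(anc_idx[[s]], anc_idx[[t]])
      sa <- ca
      if (A[s, t]) sa <- c(sa, s)
      if (A[t, s]) sa <- c(sa, t)
      vca <- if (length(ca)) min(p[ca]) else 0
      vsa <- if (length(sa)) min(p[sa]) else 0
      p_ca[s, t] <- p_ca[t, s] <- vca
      p_sa[s, t] <- p_sa[t, s] <- vsa
    }
  }
  list(p = p, A = A, p_ca = p_ca, p_sa = p_sa)
}

# Lin-style similarity from a subsumer probability: 2 log p_sub / (log p_s +
# log p_t). Zero when there is no informative subsumer (p_sub is 0 or 1) or
# when either label is uninformative (p of 0 or 1). Log base cancels.
lin_from_subsumer <- function(p_sub, p_s, p_t) {
  ok <- !is.na(p_sub) & p_sub > 0 & p_sub < 1 &
    p_s > 0 & p_s < 1 & p_t > 0 & p_t < 1
  out <- numeric(length(p_sub))
  out[ok] <- 2 * log(p_sub[ok]) / (log(p_s[ok]) + log(p_t[ok]))
  out
}

#' Pairwise label similarities
#'
#' Computes one of the four label-correlation measures for every label pair:
#' \describe{
#'   \item{`lin`}{Lin's information-content similarity,
#'     `2 log p_ca(s,t) / (log p(s) + log p(t))`, where `p_ca` is the minimum
#'     membership probability over the *common* (proper) ancestors of s, t.}
#'   \item{`hsim`}{Same formula with `p_sa`, the minimum over the *shared*
#'     ancestors: the common ancestors plus s itself when s is an ancestor of
#'     t (and vice versa). HSim >= LinSim on ancestor-descendant pairs and
#'     equals LinSim on siblings/cousins.}
#'   \item{`jcd`}{Jaccard coefficient of member-protein sets,
#'     `|N(s) n N(t)| / |N(s) u N(t)|`.}
#'   \item{`comsim`}{The combined switch: HSim when `p_sa(s,t)` lies strictly
#'     in (0, 1) — i.e. the pair has an informative shared ancestor — and
#'     JcdSim otherwise (no shared ancestor, or the most specific one is
#'     annotated to none/all proteins).}
#' }
#' Self-similarity is 1 for every label with at least one member protein and
#' 0 for memberless labels. Similarities are computed from the available
#' (possibly incomplete) annotation state, which is what the method sees at
#' training time.
#'
#' @param Y true-path-closed binary annotation matrix.
#' @param h a `label_hierarchy` covering the columns of `Y`.
#' @param kind one of `"comsim"`, `"hsim"`, `"lin"`, `"jcd"`.
#' @return An object of class `label_correlation`: list with `S` (K x K
#'   similarity matrix), `Cm` (row-normalized form, see
#'   [normalize_correlation()]), `kind`, and `labels`.
#' @export
label_correlation <- function(Y, h, kind = c("comsim", "hsim", "lin", "jcd")) {
  kind <- match.arg(kind)
  labs <- colnames(Y)
  K <- length(labs)
  cnt <- colSums(Y)
  inter <- crossprod(Y)
  uni <- outer(cnt, cnt, "+") - inter
  J <- matrix(0, K, K, dimnames = list(labs, labs))
  nz <- uni > 0
  J[nz] <- inter[nz] / uni[nz]
  if (kind == "jcd") {
    S <- J
  } else {
    ms <- min_subsumer_probs(Y, h)
    p <- ms$p
    ps <- matrix(p, K, K)                       # p(s) by row
    pt <- matrix(p, K, K, byrow = TRUE)         # p(t) by column
    if (kind == "lin") {
      S <- matrix(lin_from_subsumer(ms$p_ca, ps, pt), K, K,
                  dimnames = list(labs, labs))
    } else {
      H <- matrix(lin_from_subsumer(ms$p_sa, ps, pt), K, K,
                  dimnames = list(labs, labs))
      if (kind == "hsim") {
        S <- H
      } else {
        use_h <- !is.na(ms$p_sa) & ms$p_sa > 0 & ms$p_sa < 1
        S <- J
        S[use_h] <- H[use_h]
      }
    }
  }
  diag(S) <- as.numeric(cnt > 0)
  res <- structure(list(S = S, Cm = NULL, kind = kind, labels = labs),
                   class = "label_correlation")
  normalize_correlation(res)
}

#' Row-normalize a correlation matrix
#'
#' Fills the `Cm` slot: `Cm(s, t) = S(s, t) / sum_t S(s, t)` (the diagonal is
#' included in the row sum). Rows of `S` that are all zero stay all zero in
#' `Cm`. `Cm` is generally not symmetric.
#'
#' @param corr a `label_correlation`.
#' @return The same object with `Cm` filled.
#' @export
normalize_correlation <- function(corr) {
  stopifnot(inherits(corr, "label_correlation"))
  rs <- rowSums(corr$S)
  scale <- ifelse(rs > 0, 1 / rs, 0)
  corr$Cm <- corr$S * scale
  corr
}

#' @export
print.label_correlation <- function(x, ...) {
  cat("label_correlation (", x$kind, "): ", length(x$labels), " labels, ",
      sum(rowSums(x$S) == 0), " all-zero row(s)\n", sep = "")
  invisible(x)
}

# Pairwise convenience wrappers -------------------------------------------

pair_sim <- function(Y, h, s, t, kind) {
  for (lab in unique(c(s, t))) {
    if (!lab %in% colnames(Y)) stop("unknown label: ", lab)
  }
  label_correlation(Y, h, kind)$S[s, t]
}

#' @rdname label_correlation
#' @param s,t label identifiers (columns of `Y`).
#' @export
lin_similarity <- function(Y, h, s, t) pair_sim(Y, h, s, t, "lin")

#' @rdname label_correlation
#' @export
h_similarity <- function(Y, h, s, t) pair_sim(Y, h, s, t, "hsim")

#' @rdname label_correlation
#' @export
com_similarity <- function(Y, h, s, t) pair_sim(Y, h, s, t, "comsim")

#' Jaccard co-annotation similarity of two labels
#' @param Y binary annotation matrix.
#' @param s,t label identifiers (columns of `Y`).
#' @return `|N(s) n N(t)| / |N(s) u N(t)|`; 0 when both member sets are empty.
#' @export
jaccard_similarity <- function(Y, s, t) {
  for (lab in unique(c(s, t))) {
    if (!lab %in% colnames(Y)) stop("unknown label: ", lab)
  }
  ns <- Y[, s] > 0
  nt <- Y[, t] > 0
  u <- sum(ns | nt)
  if (u == 0) 0 else sum(ns & nt) / u
}

#' Write a correlation matrix as TSV
#' @param corr a `label_correlation`.
#' @param path output file path.
#' @param which `"S"` (raw) or `"Cm"` (row-normalized).
#' @export
write_correlation_tsv <- function(corr, path, which = c("S", "Cm")) {
  which <- match.arg(which)
  M <- corr[[which]]
  utils::write.table(data.frame(label = rownames(M), M, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
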