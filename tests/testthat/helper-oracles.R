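# Independent oracles, deliberately written by naive path-walking and
# element-wise loops so they share no code path with the package internals.

# All proper ancestors of `label`, found by recursive parent walking.
oracle_ancestors <- function(h, label) {
  out <- character(0)
  walk <- function(x) {
    for (p in h$parents[[x]]) {
      if (!p %in% out) {
        out <<- c(out, p)
        walk(p)
      }
    }
  }
  walk(label)
  sort(out)
}

# Pairwise similarity by direct evaluation of the definitions.
oracle_pair_similarity <- function(Y, h, s, t, kind) {
  n <- nrow(Y)
  members <- function(lab) rownames(Y)[Y[, lab] == 1]
  p_of <- function(lab) length(members(lab)) / n
  jcd <- function(a, b) {
    u <- union(members(a), members(b))
    if (length(u) == 0) return(0)
    length(intersect(members(a), members(b))) / length(u)
  }
  if (s == t) return(as.numeric(length(members(s)) > 0))
  anc_s <- oracle_ancestors(h, s)
  anc_t <- oracle_ancestors(h, t)
  ca <- intersect(intersect(anc_s, anc_t), colnames(Y))
  sa <- ca
  if (s %in% anc_t) sa <- c(sa, s)
  if (t %in% anc_s) sa <- c(sa, t)
  p_ca <- if (length(ca)) min(vapply(ca, p_of, numeric(1))) else 0
  p_sa <- if (length(sa)) min(vapply(sa, p_of, numeric(1))) else 0
  lin_formula <- function(p_sub) {
    ps <- p_of(s); pt <- p_of(t)
    if (p_sub <= 0 || p_sub >= 1 || ps <= 0 || ps >= 1 || pt <= 0 || pt >= 1)
      return(0)
    2 * log(p_sub) / (log(ps) + log(pt))
  }
  switch(kind,
         lin = lin_formula(p_ca),
         hsim = lin_formula(p_sa),
         jcd = jcd(s, t),
         comsim = if (p_sa > 0 && p_sa < 1) lin_formula(p_sa) else jcd(s, t))
}

# Literal element-wise evaluation of the regularized objective.
oracle_objective <- function(F, tilde_Y, W, lambda, labeled) {
  Wd <- as.matrix(W)
  n <- nrow(F); K <- ncol(F)
  emp <- 0
  for (i in seq_len(n)) {
    if (labeled[i]) emp <- emp + sum((F[i, ] - tilde_Y[i, ])^2)
  }
  smooth <- 0
  for (i in seq_len(n)) {
    nb <- numeric(K)
    for (j in seq_len(n)) nb <- nb + Wd[i, j] * F[j, ]
    smooth <- smooth + sum((F[i, ] - nb)^2)
  }
  emp + lambda * smooth
}

# Numerical minimizer of the objective (generic quasi-Newton on the
# vectorized score matrix, gradient by central finite differences).
oracle_minimize_objective <- function(tilde_Y, W, lambda, labeled) {
  n <- nrow(tilde_Y); K <- ncol(tilde_Y)
  fn <- function(x) oracle_objective(matrix(x, n, K), tilde_Y, W, lambda, labeled)
  gr <- function(x) pracma::grad(fn, x)
  res <- stats::optim(par = as.numeric(tilde_Y), fn = fn, gr = gr,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15))
  matrix(res$par, n, K, dimnames = dimnames(tilde_Y))
}

# Random tree or DAG over labels L1..LK: each later label gets one (tree) or
# occasionally two (DAG) parents among earlier labels.
rand_hierarchy <- function(K, seed, dag = FALSE) {
  set.seed(seed)
  labels <- paste0("L", seq_len(K))
  parents <- list()
  if (K > 1) {
    for (i in 2:K) {
      np <- if (dag && i > 2 && stats::runif(1) < 0.3) 2 else 1
      parents[[labels[i]]] <- sample(labels[seq_len(i - 1)], np)
    }
  }
  label_hierarchy(labels, parents)
}

# Random true-path-closed annotation matrix over a hierarchy.
rand_closed_annotations <- function(h, n, seed, density = 0.15) {
  set.seed(seed)
  K <- length(h$labels)
  Y <- matrix(as.numeric(stats::runif(n * K) < density), n, K,
              dimnames = list(paste0("q", seq_len(n)), h$labels))
  true_path_closure(Y, h)
}

# Corpus for the worked conditional-probability example: two top-level
# categories with 272 and 448 member proteins, 170 shared, and a child of
# the second category annotated to exactly the shared proteins.
worked_example_corpus <- function(n = 5700) {
  h <- label_hierarchy(c("40", "43", "43.01"), list(`43.01` = "43"))
  prot <- paste0("y", seq_len(n))
  Y <- matrix(0, n, 3, dimnames = list(prot, c("40", "43", "43.01")))
  Y[1:272, "40"] <- 1                 # members of '40'
  Y[103:550, "43"] <- 1               # 448 members of '43', 170 shared
  Y[103:272, "43.01"] <- 1            # the 170 proteins with both
  list(hierarchy = h, Y = true_path_closure(Y, h))
}

# Small complete dataset + weights for solver-level tests.
tiny_dataset <- function(seed = 42, n = 40) {
  ds <- simulate_dataset(n_proteins = n, depth = 3, branching = c(4, 2),
                         n_edges = 4 * n, seed = seed,
                         label_range = c(4, 40))
  ds
}
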