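# Multi-label evaluation: MicroF1, MacroF1, AvgROC, 1-RankLoss, Fmax.
#
# All metrics are computed on a caller-supplied evaluation scope (a logical
# protein x label mask): for replenishment this is the unknown entries of
# labeled proteins (masked entries are the positives), for the
# unlabeled-protein task it is every entry of the test proteins.

# Rank-based AUC (equivalent to the Wilcoxon statistic); ties get 0.5 credit.
binary_auc <- function(scores, truth) {
  pos <- truth > 0
  npos <- sum(pos)
  nneg <- sum(!pos)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# Per-protein ranking loss: fraction of (positive, negative) label pairs
# ordered discordantly; ties count one half.
ranking_loss_row <- function(scores, truth) {
  pos <- which(truth > 0)
  neg <- which(truth == 0)
  if (!length(pos) || !length(neg)) return(NA_real_)
  sp <- scores[pos]
  sn <- scores[neg]
  disc <- sum(vapply(sp, function(v) sum(sn > v) + 0.5 * sum(sn == v),
                     numeric(1)))
  disc / (length(pos) * length(neg))
}

# Oracle-r binarization: within each protein's in-scope entries, predict
# positive for the top r scores, r = that protein's true positive count.
# Deterministic under score ties (first by score order, then column order).
binarize_top_r <- function(scores, truth) {
  r <- sum(truth > 0)
  pred <- integer(length(scores))
  if (r > 0) pred[order(scores, decreasing = TRUE)[seq_len(r)]] <- 1L
  pred
}

f1_from_counts <- function(tp, fp, fn) {
  denom <- 2 * tp + fp + fn
  if (denom == 0) return(NA_real_)
  2 * tp / denom
}

#' Evaluate a prediction matrix
#'
#' Computes multi-label metrics over an evaluation scope:
#' \describe{
#'   \item{MicroF1 / MacroF1}{on binarized predictions; by default each
#'     protein's top-r in-scope scores are called positive, with r that
#'     protein's true positive count in scope ("oracle-r"); alternatively a
#'     fixed `threshold` binarizes scores directly. MacroF1 averages
#'     per-label F1 over labels with at least one in-scope positive.}
#'   \item{AvgROC}{mean per-label AUC over labels with both classes in scope.}
#'   \item{1-RankLoss}{one minus the mean, over proteins with both classes in
#'     scope, of the fraction of (positive, negative) label pairs ranked
#'     discordantly.}
#'   \item{Fmax}{maximum over thresholds 0, 0.01, ..., 1 of the
#'     protein-centric F-measure: precision averaged over proteins with at
#'     least one call at that threshold, recall over all in-scope proteins
#'     with at least one positive.}
#' }
#' Proteins (or labels) with a single class in scope are skipped by the
#' protein-centric (label-centric) metrics; their counts are recorded in the
#' result.
#'
#' @param F numeric protein x label score matrix.
#' @param truth binary ground-truth matrix of the same shape.
#' @param scope logical matrix of the same shape: which entries are scored.
#' @param metrics character subset of `c("MicroF1","MacroF1","AvgROC",
#'   "1-RankLoss","Fmax")`.
#' @param threshold optional fixed binarization threshold for MicroF1/MacroF1
#'   (replaces the oracle-r rule).
#' @return Named list of metric values in \[0, 1\] plus `skipped_proteins`
#'   and `skipped_labels`.
#' @export
evaluate_predictions <- function(F, truth, scope,
                                 metrics = c("MicroF1", "MacroF1", "AvgROC",
                                             "1-RankLoss", "Fmax"),
                                 threshold = NULL) {
  stopifnot(identical(dim(F), dim(truth)), identical(dim(F), dim(scope)))
  if (!any(scope)) stop("empty evaluation scope")
  metrics <- match.arg(metrics, several.ok = TRUE)
  out <- list()
  prot_idx <- which(rowSums(scope) > 0)
  lab_idx <- which(colSums(scope) > 0)

  # per-protein binarized predictions (shared by MicroF1/MacroF1)
  pred <- matrix(0L, nrow(F), ncol(F))
  for (i in prot_idx) {
    s <- scope[i, ]
    if (is.null(threshold)) {
      pred[i, s] <- binarize_top_r(F[i, s], truth[i, s])
    } else {
      pred[i, s] <- as.integer(F[i, s] >= threshold)
    }
  }

  if ("MicroF1" %in% metrics) {
    tp <- sum(pred == 1 & truth == 1 & scope)
    fp <- sum(pred == 1 & truth == 0 & scope)
    fn <- sum(pred == 0 & truth == 1 & scope)
    out$MicroF1 <- f1_from_counts(tp, fp, fn)
  }
  skipped_labels <- 0L
  if ("MacroF1" %in% metrics) {
    vals <- numeric(0)
    for (k in lab_idx) {
      s <- scope[, k]
      if (sum(truth[s, k]) == 0) { skipped_labels <- skipped_labels + 1L; next }
      tp <- sum(pred[s, k] == 1 & truth[s, k] == 1)
      fp <- sum(pred[s, k] == 1 & truth[s, k] == 0)
      fn <- sum(pred[s, k] == 0 & truth[s, k] == 1)
      vals <- c(vals, f1_from_counts(tp, fp, fn))
    }
    out$MacroF1 <- mean(vals)
  }
  if ("AvgROC" %in% metrics) {
    aucs <- vapply(lab_idx, function(k) {
      s <- scope[, k]
      binary_auc(F[s, k], truth[s, k])
    }, numeric(1))
    out$AvgROC <- mean(aucs, na.rm = TRUE)
  }
  skipped_proteins <- 0L
  if ("1-RankLoss" %in% metrics) {
    rls <- vapply(prot_idx, function(i) {
      s <- scope[i, ]
      ranking_loss_row(F[i, s], truth[i, s])
    }, numeric(1))
    skipped_proteins <- sum(is.na(rls))
    out[["1-RankLoss"]] <- 1 - mean(rls, na.rm = TRUE)
  }
  if ("Fmax" %in% metrics) {
    out$Fmax <- fmax_score(F, truth, scope, prot_idx)
  }
  out$skipped_proteins <- skipped_proteins
  out$skipped_labels <- skipped_labels
  out
}

# Protein-centric Fmax over a threshold grid (CAFA convention): at each
# threshold, precision is averaged over proteins with >= 1 call and recall
# over all proteins with >= 1 in-scope positive.
fmax_score <- function(F, truth, scope, prot_idx,
                       thresholds = seq(0, 1, by = 0.01)) {
  rows <- Filter(function(i) sum(truth[i, scope[i, ]]) > 0, prot_idx)
  if (!length(rows)) return(NA_real_)
  best <- 0
  for (tau in thresholds) {
    precs <- numeric(0)
    recs <- numeric(length(rows))
    for (ri in seq_along(rows)) {
      i <- rows[[ri]]
      s <- scope[i, ]
      call <- F[i, s] >= tau
      tr <- truth[i, s] > 0
      if (any(call)) precs <- c(precs, sum(call & tr) / sum(call))
      recs[ri] <- sum(call & tr) / sum(tr)
    }
    pr <- if (length(precs)) mean(precs) else 0
    rc <- mean(recs)
    if (pr + rc > 0) best <- max(best, 2 * pr * rc / (pr + rc))
  }
  best
}

#' Replenishment benchmark
#'
#' Runs the missing-label replenishment experiment on a synthetic dataset:
#' for each per-protein mask count `m` and each repeat, leaf labels are
#' masked with a fresh seed, label correlations are recomputed from the
#' masked state, each variant is fitted, and predictions are scored on the
#' unknown entries of the (fully in-sample) proteins — masked entries are
#' the positives, the remaining unknowns the negatives.
#'
#' @param ds a `synthetic_dataset` (or a list with `hierarchy`, `Y_true`,
#'   `edges`).
#' @param m_values integer vector of per-protein mask counts.
#' @param repeats number of masking repeats per `m`.
#' @param variants character vector of variant names (see [run_variant()]).
#' @param lambda smoothness weight passed to the solvers.
#' @param seed base seed; each repeat r uses `seed + r` for masking.
#' @param metrics metrics to compute.
#' @return data.frame with columns variant, m, metric, mean, sd; per-run
#'   values are attached as attribute `"runs"` (a data.frame in long form).
#' @export
run_replenish_experiment <- function(ds, m_values = 3, repeats = 5,
                                     variants = c("pill", "naive"),
                                     lambda = 1, seed = 1,
                                     metrics = c("MicroF1", "MacroF1",
                                                 "AvgROC", "1-RankLoss",
                                                 "Fmax")) {
  h <- ds$hierarchy
  Y_true <- ds$Y_true
  W <- build_weights(ds$edges, rownames(Y_true))
  labeled <- rowSums(Y_true) > 0
  runs <- list()
  for (m in m_values) {
    for (r in seq_len(repeats)) {
      mk <- mask_leaf_labels(Y_true, h, m, seed = seed + r)
      Ym <- mk$Y_masked
      Ym[!labeled, ] <- 0
      scope <- (Ym == 0) & labeled
      kinds_needed <- unique(stats::na.omit(vapply(
        variants, function(v) switch(v, pill = "comsim", pill_fc = "comsim",
                                     pill_jcd = "jcd", pill_hsim = "hsim",
                                     pill_lin = "lin", NA_character_),
        character(1))))
      corrs <- lapply(stats::setNames(nm = kinds_needed), function(k)
        label_correlation(Ym, h, k))
      for (v in variants) {
        kind <- switch(v, pill = "comsim", pill_fc = "comsim",
                       pill_jcd = "jcd", pill_hsim = "hsim",
                       pill_lin = "lin", NULL)
        fit <- run_variant(Ym, h, W, variant = v, lambda = lambda,
                           labeled = labeled,
                           corr = if (!is.null(kind)) corrs[[kind]])
        ev <- evaluate_predictions(fit$F, Y_true, scope, metrics)
        for (metric in metrics) {
          runs[[length(runs) + 1L]] <- data.frame(
            variant = v, m = m, repeat_ = r, metric = metric,
            value = ev[[metric]], stringsAsFactors = FALSE)
        }
      }
    }
  }
  runs_df <- do.call(rbind, runs)
  agg <- stats::aggregate(value ~ variant + m + metric, runs_df,
                          function(x) c(mean = mean(x), sd = stats::sd(x)))
  res <- data.frame(agg[c("variant", "m", "metric")],
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"])
  attr(res, "runs") <- runs_df
  res
}

#' Unlabeled-protein prediction benchmark
#'
#' Random train/test split: test proteins' labels are fully hidden, training
#' proteins are additionally masked at per-protein count `m`, correlations
#' are computed from the masked training annotations, and predictions are
#' scored on every entry of the test proteins.
#'
#' @param ds a `synthetic_dataset`.
#' @param train_fraction fraction of proteins used for training, in (0, 1).
#' @param m per-protein mask count applied to the training side.
#' @param repeats number of random splits.
#' @param variants variant names.
#' @param lambda smoothness weight.
#' @param seed base seed.
#' @param metrics metrics to compute.
#' @return As [run_replenish_experiment()], without the `m` column varying.
#' @export
run_unlabeled_experiment <- function(ds, train_fraction = 0.7, m = 3,
                                     repeats = 5,
                                     variants = c("pill", "naive"),
                                     lambda = 1, seed = 1,
                                     metrics = c("MicroF1", "MacroF1",
                                                 "AvgROC", "1-RankLoss",
                                                 "Fmax")) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1): both sides must be non-empty")
  }
  h <- ds$hierarchy
  Y_true <- ds$Y_true
  n <- nrow(Y_true)
  W <- build_weights(ds$edges, rownames(Y_true))
  runs <- list()
  for (r in seq_len(repeats)) {
    set.seed(seed + 1000L * r)
    train <- sort(sample(n, round(train_fraction * n)))
    labeled <- seq_len(n) %in% train & rowSums(Y_true) > 0
    mk <- mask_leaf_labels(Y_true, h, m, seed = seed + 1000L * r + 1L)
    Ym <- mk$Y_masked
    Ym[!labeled, ] <- 0
    scope <- matrix(FALSE, n, ncol(Y_true))
    test <- setdiff(seq_len(n), train)
    scope[test, ] <- TRUE
    scope[rowSums(Y_true) == 0, ] <- FALSE   # never test on label-free proteins
    for (v in variants) {
      fit <- run_variant(Ym, h, W, variant = v, lambda = lambda,
                         labeled = labeled)
      ev <- evaluate_predictions(fit$F, Y_true, scope, metrics)
      for (metric in metrics) {
        runs[[length(runs) + 1L]] <- data.frame(
          variant = v, m = m, repeat_ = r, metric = metric,
          value = ev[[metric]], stringsAsFactors = FALSE)
      }
    }
  }
  runs_df <- do.call(rbind, runs)
  agg <- stats::aggregate(value ~ variant + m + metric, runs_df,
                          function(x) c(mean = mean(x), sd = stats::sd(x)))
  res <- data.frame(agg[c("variant", "m", "metric")],
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"])
  attr(res, "runs") <- runs_df
  res
}
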