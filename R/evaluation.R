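as_pm1 <- function(labels) {
  u <- unique(labels)
  if (all(u %in% c(-1, 1))) return(as.numeric(labels))
  if (all(u %in% c(0, 1))) return(ifelse(labels == 1, 1, -1))
  stop_fmt("labels must be +/-1 (or 0/1)")
}

#' Area under the ROC curve
#'
#' Rank-based AUC with midrank tie handling; equals the Mann-Whitney U
#' statistic divided by `n_pos * n_neg`.
#'
#' @param scores Numeric decision scores.
#' @param labels Class labels, +/-1 (0/1 accepted).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_pm1(labels)
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop_fmt("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Area under the precision-recall step curve: thresholds sweep the unique
#' score values from high to low, and each recall increment is credited with
#' the precision at that threshold (no linear interpolation of precision,
#' which would be optimistic).
#'
#' @inheritParams roc_auc
#' @return AUPR in `(0, 1]`.
#' @export
aupr <- function(scores, labels) {
  labels <- as_pm1(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) stop_fmt("no positives")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o] == 1
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- !duplicated(s, fromLast = TRUE)  # last index of each tied block
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Classification metrics at the max-F threshold
#'
#' Scans every unique score as a decision threshold (predict "interacts" when
#' score >= threshold), computes accuracy, sensitivity, specificity, precision
#' and F-measure from the confusion table, and reports them at the threshold
#' where F is maximal (F ties broken toward higher sensitivity — recall is the
#' priority in repositioning).
#'
#' @inheritParams roc_auc
#' @return List with `acc`, `sn`, `sp`, `pre`, `f`, `threshold`.
#' @export
threshold_metrics <- function(scores, labels) {
  labels <- as_pm1(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == -1)
  if (n_pos == 0L || n_neg == 0L) stop_fmt("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o] == 1
  tp_cum <- cumsum(y); fp_cum <- cumsum(!y)
  last <- !duplicated(s, fromLast = TRUE)
  thr <- s[last]; tp <- tp_cum[last]; fp <- fp_cum[last]
  keep <- (tp + fp) > 0  # precision undefined otherwise; skip those cuts
  thr <- thr[keep]; tp <- tp[keep]; fp <- fp[keep]
  fn <- n_pos - tp; tn <- n_neg - fp
  sn <- tp / n_pos
  pre <- tp / (tp + fp)
  f <- ifelse(pre + sn > 0, 2 * pre * sn / (pre + sn), 0)
  best <- order(-f, -sn)[1L]
  list(acc = (tp[best] + tn[best]) / (n_pos + n_neg),
       sn = sn[best],
       sp = tn[best] / n_neg,
       pre = pre[best],
       f = f[best],
       threshold = thr[best])
}

fold_metrics <- function(scores, labels) {
  tm <- threshold_metrics(scores, labels)
  c(auc = roc_auc(scores, labels), aupr = aupr(scores, labels),
    acc = tm$acc, sn = tm$sn, sp = tm$sp, pre = tm$pre, f = tm$f,
    threshold = tm$threshold)
}

#' Stratified k-fold cross-validation of the pair-kernel SVM
#'
#' The gold-standard positives plus an equal number of sampled negatives are
#' split into k label-stratified folds of (drug, disease) pairs; the SVM is
#' trained on each fold complement and scored on the held-out fold. The
#' penalty C is optimized once by a 3-fold grid search ([select_C()]) before
#' the evaluation folds are run (the protocol of fixing one optimal C, rather
#' than re-tuning per fold); set `select_per_fold = TRUE` to re-select C on
#' each fold's training pairs instead. Per-fold, mean and pooled (scores
#' concatenated across folds) metrics are reported.
#'
#' @param a [association_table()] of gold-standard positives.
#' @param drug_kernel,disease_kernel Similarity matrix factors of the pair
#'   kernel.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for negative sampling and fold assignment.
#' @param C Fixed SVM penalty; `NULL` (default) selects via [select_C()].
#' @param grid,inner_folds Passed to [select_C()].
#' @param select_per_fold Re-run [select_C()] on each fold's training pairs
#'   (slower); default FALSE.
#' @param repair Apply [psd_repair()] to the factors.
#' @return Object of class `predr_cv`: `per_fold` data frame, `mean` and
#'   `pooled` metric vectors, `scores` (per-pair held-out scores with fold
#'   ids), `fold_of`, `dataset`, `seed`.
#' @export
kfold_cv <- function(a, drug_kernel, disease_kernel, k = 10, seed = 1,
                     C = NULL, grid = default_C_grid(), inner_folds = 3,
                     select_per_fold = FALSE, repair = TRUE) {
  stopifnot(inherits(a, "association_table"))
  if (nrow(a$edges) < k) stop_fmt("need at least k positives")
  kernel <- pair_kernel(drug_kernel, disease_kernel, repair = repair)
  negatives <- sample_negatives(a, seed = derive_seed(seed, 1L))
  ds <- pair_dataset(a$edges, negatives, seed = seed)
  fold_of <- stratified_folds(ds$label, k, derive_seed(seed, 2L),
                              require_both = TRUE)
  g <- pair_gram(kernel, ds)
  v <- gram_factor(g)
  if (is.null(C) && !select_per_fold) {
    C <- as.numeric(select_C(ds, kernel, grid = grid, folds = inner_folds,
                             seed = derive_seed(seed, 3L)))
  }
  per_fold <- vector("list", k)
  scores <- numeric(nrow(ds))
  for (f in seq_len(k)) {
    tr <- fold_of != f
    C_f <- C
    if (is.null(C_f)) {
      C_f <- as.numeric(select_C(ds[tr, , drop = FALSE], kernel, grid = grid,
                                 folds = inner_folds,
                                 seed = derive_seed(seed, 10L + f)))
    }
    fit <- fit_factor_svm(v[tr, , drop = FALSE], ds$label[tr], C_f)
    sc <- gram_decision(fit, g[!tr, tr, drop = FALSE][, fit$sv, drop = FALSE])
    scores[!tr] <- sc
    per_fold[[f]] <- c(fold = f, n_test = sum(!tr),
                       fold_metrics(sc, ds$label[!tr]), C = C_f)
  }
  per_fold <- as.data.frame(do.call(rbind, per_fold))
  metric_cols <- c("auc", "aupr", "acc", "sn", "sp", "pre", "f")
  structure(list(
    per_fold = per_fold,
    mean = colMeans(per_fold[, metric_cols]),
    pooled = fold_metrics(scores, ds$label)[metric_cols],
    scores = cbind(ds[, c("drug", "disease", "label")],
                   fold = fold_of, score = scores),
    fold_of = fold_of,
    dataset = ds,
    k = k, seed = seed
  ), class = "predr_cv")
}

#' @export
print.predr_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV over %d labeled pairs (seed %s)\n",
              x$k, nrow(x$dataset), format(x$seed)))
  cat(sprintf("  mean  : AUC %.3f  AUPR %.3f  Acc %.3f  Sn %.3f  Sp %.3f  Pre %.3f  F %.3f\n",
              x$mean["auc"], x$mean["aupr"], x$mean["acc"], x$mean["sn"],
              x$mean["sp"], x$mean["pre"], x$mean["f"]))
  cat(sprintf("  pooled: AUC %.3f  AUPR %.3f\n",
              x$pooled["auc"], x$pooled["aupr"]))
  invisible(x)
}

#' Leave-one-drug-out cross-validation
#'
#' For each drug with at least one gold-standard association, all of that
#' drug's pairs are removed from training (both from the positives and from
#' the negative-sampling candidates), the SVM is trained on the remaining
#' network, and the held-out drug's positives are ranked against its
#' non-associated diseases. Per-drug AUCs are macro-averaged; a pooled
#' (micro) AUC over all held-out scores is also reported. Drugs whose
#' positives cover every disease are skipped with a warning.
#'
#' @inheritParams kfold_cv
#' @param C Fixed penalty; `NULL` selects once on the full labeled set.
#' @param keep_training Record each held-out drug's training pairs (for
#'   leakage audits); default FALSE.
#' @return Object of class `predr_lodo`: `per_drug` data frame, `mean_auc`
#'   (macro), `micro_auc`, `skipped`, `C`, `seed` (and `training`, a named
#'   list of training pair frames, when `keep_training`).
#' @export
leave_one_drug_out <- function(a, drug_kernel, disease_kernel, seed = 1,
                               C = NULL, grid = default_C_grid(),
                               inner_folds = 3, repair = TRUE,
                               keep_training = FALSE) {
  stopifnot(inherits(a, "association_table"))
  kernel <- pair_kernel(drug_kernel, disease_kernel, repair = repair)
  if (is.null(C)) {
    ds0 <- pair_dataset(a$edges, sample_negatives(a, seed = derive_seed(seed, 1L)))
    C <- as.numeric(select_C(ds0, kernel, grid = grid, folds = inner_folds,
                             seed = derive_seed(seed, 2L)))
  }
  drugs <- unique(a$edges$drug)
  if (length(drugs) < 2L) stop_fmt("need positives for >= 2 drugs")
  rows <- list(); skipped <- character(); training <- list()
  all_scores <- numeric(); all_labels <- numeric()
  for (i in seq_along(drugs)) {
    d <- drugs[i]
    pos_dis <- a$edges$disease[a$edges$drug == d]
    if (length(setdiff(a$diseases, pos_dis)) == 0L) {
      warn_fmt("drug '%s' has positives for every disease; skipped", d)
      skipped <- c(skipped, d)
      next
    }
    train_pos <- a$edges[a$edges$drug != d, , drop = FALSE]
    held_out <- all_pairs(d, a$diseases)
    neg <- sample_negatives(a, n = nrow(train_pos),
                            seed = derive_seed(seed, 100L + i),
                            exclude = held_out)
    ds <- pair_dataset(train_pos, neg)
    if (keep_training) training[[d]] <- ds[, c("drug", "disease")]
    fit <- fit_gram_svm(pair_gram(kernel, ds), ds$label, C)
    sv_pairs <- ds[fit$sv, c("drug", "disease")]
    sc <- gram_decision(fit, pair_gram(kernel, held_out, sv_pairs))
    lab <- ifelse(held_out$disease %in% pos_dis, 1, -1)
    rows[[length(rows) + 1L]] <- data.frame(
      drug = d, n_pos = sum(lab == 1), n_neg = sum(lab == -1),
      auc = roc_auc(sc, lab), stringsAsFactors = FALSE)
    all_scores <- c(all_scores, sc); all_labels <- c(all_labels, lab)
  }
  per_drug <- do.call(rbind, rows)
  structure(list(per_drug = per_drug,
                 mean_auc = mean(per_drug$auc),
                 micro_auc = roc_auc(all_scores, all_labels),
                 skipped = skipped, C = C, seed = seed,
                 training = if (keep_training) training),
            class = "predr_lodo")
}

#' @export
print.predr_lodo <- function(x, ...) {
  cat(sprintf("Leave-one-drug-out CV over %d drugs (C = %g, seed %s)\n",
              nrow(x$per_drug), x$C, format(x$seed)))
  cat(sprintf("  macro mean AUC %.3f   pooled micro AUC %.3f\n",
              x$mean_auc, x$micro_auc))
  invisible(x)
}

#' Filter trivially predictable positives
#'
#' Removes gold-standard positives that are explainable by near-identical
#' targets: a pair (d, q) is dropped when another positive (d', q) exists
#' whose drug has maximum normalized Smith-Waterman target similarity to d of
#' at least `cutoff`. On symmetric conflicts the lexicographically smaller
#' drug's edge is retained, so removal is deterministic and minimal.
#'
#' @param a [association_table()].
#' @param targets Named list: drug id -> protein ids.
#' @param sequences Named character vector of protein sequences.
#' @param params [alignment_params()].
#' @param cutoff Similarity threshold in `(0, 1]`; default 0.8.
#' @return The filtered [association_table()], with the removal log (a data
#'   frame of removed edges and the conflicting drug) as attribute
#'   `"removed"`.
#' @export
filter_trivial_positives <- function(a, targets, sequences,
                                     params = alignment_params(),
                                     cutoff = 0.8) {
  stopifnot(inherits(a, "association_table"))
  if (!(cutoff > 0 && cutoff <= 1)) stop_fmt("cutoff must be in (0, 1]")
  sim <- target_set_similarity_matrix(targets, sequences, params = params,
                                      aggregator = "max",
                                      drugs = a$drugs, normalize = FALSE)
  keep <- rep(TRUE, nrow(a$edges))
  removed <- list()
  for (q in unique(a$edges$disease)) {
    idx <- which(a$edges$disease == q)
    idx <- idx[order(a$edges$drug[idx])]
    kept_drugs <- character()
    for (i in idx) {
      d <- a$edges$drug[i]
      conflict <- kept_drugs[sim[d, kept_drugs] >= cutoff & kept_drugs != d]
      if (length(conflict)) {
        keep[i] <- FALSE
        removed[[length(removed) + 1L]] <- data.frame(
          drug = d, disease = q, conflicting_drug = conflict[1L],
          stringsAsFactors = FALSE)
      } else {
        kept_drugs <- c(kept_drugs, d)
      }
    }
  }
  out <- association_table(a$edges[keep, , drop = FALSE],
                           drugs = a$drugs, diseases = a$diseases)
  attr(out, "removed") <- if (length(removed)) do.call(rbind, removed) else
    data.frame(drug = character(), disease = character(),
               conflicting_drug = character(), stringsAsFactors = FALSE)
  out
}
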