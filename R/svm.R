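#' All drug x disease candidate pairs
#'
#' @param drugs,diseases Character vectors of ids.
#' @return Pair data frame enumerating the full grid (drug varying fastest).
#' @export
all_pairs <- function(drugs, diseases) {
  pair_frame(rep(drugs, times = length(diseases)),
             rep(diseases, each = length(drugs)))
}

#' Balanced negative sampling from unlabeled pairs
#'
#' Known drug-disease associations are the gold-standard positives; all other
#' pairs are unlabeled. To avoid the class-imbalance problem, training
#' negatives are drawn uniformly without replacement from the unlabeled pairs,
#' by default as many as there are positives.
#'
#' @param a [association_table()] (defines the positives and the universes).
#' @param n Number of negatives; default `nrow(a$edges)` (balance).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param exclude Optional pair data frame of additional pairs to exclude
#'   (e.g. a test split, so no test pair leaks into training).
#' @return Pair data frame of `n` sampled negatives.
#' @export
sample_negatives <- function(a, n = NULL, seed = 1, exclude = NULL) {
  stopifnot(inherits(a, "association_table"))
  n <- n %||% nrow(a$edges)
  cand <- all_pairs(a$drugs, a$diseases)
  drop <- pair_key(a$edges)
  if (!is.null(exclude) && nrow(exclude)) drop <- c(drop, pair_key(exclude))
  cand <- cand[!(pair_key(cand) %in% drop), , drop = FALSE]
  if (nrow(cand) < n) {
    stop_fmt("only %d unlabeled pairs available, %d requested", nrow(cand), n)
  }
  idx <- with_seed(seed, sample.int(nrow(cand), n))
  out <- cand[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Labeled drug-disease pair dataset
#'
#' @param positives,negatives Pair data frames; must be disjoint.
#' @param seed Seed recorded as sampling provenance.
#' @return Object of class `pair_dataset`: data frame with columns `drug`,
#'   `disease`, `label` (+1/-1), `provenance`.
#' @export
pair_dataset <- function(positives, negatives, seed = NA_integer_) {
  if (any(pair_key(positives) %in% pair_key(negatives))) {
    stop_fmt("positives and negatives overlap")
  }
  block <- function(p, lab, prov) {
    data.frame(drug = p$drug, disease = p$disease, label = rep(lab, nrow(p)),
               provenance = rep(prov, nrow(p)), stringsAsFactors = FALSE)
  }
  out <- rbind(block(positives, 1, "positive"),
               block(negatives, -1, "sampled-negative"))
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  class(out) <- c("pair_dataset", "data.frame")
  out
}

#' Default penalty grid for the SVM
#'
#' Odd powers of two from 2^-5 to 2^1. The pair kernel is bounded in [0, 1]
#' with unit diagonal, so decision margins live on an O(1) scale and small
#' penalties suffice; very large C both degrades validation AUC and stalls
#' the SMO solver on near-separable Grams. Pass a wider grid explicitly if
#' the data call for it.
#' @return Numeric vector of candidate C values.
#' @export
default_C_grid <- function() 2^seq(-5, 1, by = 2)

# Factor a PSD Gram matrix as G = V V' (eigendecomposition with tiny negative
# eigenvalues clipped). The SVM dual on G equals a linear SVM on the rows of
# V, and any row subset of V factors the corresponding Gram submatrix, so one
# factorization serves every train/validation split of a CV.
gram_factor <- function(g) {
  e <- eigen(g, symmetric = TRUE)
  neg <- min(e$values)
  if (neg < -1e-6 * max(abs(e$values), 1)) {
    stop_fmt("training Gram is not positive semidefinite (min eigenvalue %.3g); apply psd_repair to the kernel factors", neg)
  }
  sweep(e$vectors, 2L, sqrt(pmax(e$values, 0)), `*`)
}

# Solve the soft-margin SVM dual on rows of a Gram factor V (so the linear
# kernel V V' reproduces the precomputed pair kernel). Returns duals oriented
# so that decision = G[, sv] %*% alpha - b is positive for the +1 class.
fit_factor_svm <- function(v, labels, C) {
  if (length(unique(labels)) < 2L) stop_fmt("training labels are single-class")
  y <- factor(labels, levels = c(-1, 1))
  m <- e1071::svm(v, y, type = "C-classification", kernel = "linear",
                  cost = C, scale = FALSE)
  alpha <- drop(m$coefs)
  b <- m$rho
  # libsvm orients decision values toward the first label it encodes
  if (m$levels[m$labels[1]] != "1") {
    alpha <- -alpha
    b <- -b
  }
  list(sv = m$index, alpha = alpha, b = b, C = C)
}

# Convenience wrapper when only a single fit on one Gram is needed.
fit_gram_svm <- function(g, labels, C) {
  fit_factor_svm(gram_factor(g), labels, C)
}

gram_decision <- function(fit, g_cols_sv) {
  drop(g_cols_sv %*% fit$alpha - fit$b)
}

#' Select the SVM penalty by inner cross-validation
#'
#' Grid search over candidate C values, scoring each by mean AUC over
#' stratified inner folds; ties are broken toward the smaller C. A fold that
#' ends up single-class triggers a re-randomized refold (at most 5 retries).
#'
#' @param ds [pair_dataset()].
#' @param kernel [pair_kernel()].
#' @param grid Candidate C values; default [default_C_grid()].
#' @param folds Number of inner folds (default 3).
#' @param seed Integer seed for fold assignment.
#' @return The selected C, with the per-C mean AUC table as attribute `"cv"`.
#' @export
select_C <- function(ds, kernel, grid = default_C_grid(), folds = 3, seed = 1) {
  if (!length(grid)) stop_fmt("empty C grid")
  if (folds < 2L) stop_fmt("need >= 2 inner folds")
  grid <- sort(grid)
  g <- pair_gram(kernel, ds)
  v <- gram_factor(g)
  fold_of <- stratified_folds(ds$label, folds, seed, require_both = TRUE)
  aucs <- matrix(NA_real_, length(grid), folds)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    vtr <- v[tr, , drop = FALSE]
    for (ci in seq_along(grid)) {
      fit <- fit_factor_svm(vtr, ds$label[tr], grid[ci])
      sc <- gram_decision(fit, g[!tr, tr, drop = FALSE][, fit$sv, drop = FALSE])
      aucs[ci, f] <- roc_auc(sc, ds$label[!tr])
    }
  }
  mean_auc <- rowMeans(aucs)
  best <- grid[which.max(mean_auc)]  # which.max takes the first (smallest C) on ties
  attr(best, "cv") <- data.frame(C = grid, mean_auc = mean_auc)
  best
}

# Stratified fold assignment; optionally retry until every fold (and its
# complement) contains both classes.
stratified_folds <- function(labels, k, seed, require_both = FALSE, retries = 5) {
  n <- length(labels)
  for (attempt in seq_len(retries)) {
    fold_of <- integer(n)
    with_seed(derive_seed(seed, attempt - 1L), {
      for (lv in unique(labels)) {
        idx <- which(labels == lv)
        fold_of[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    })
    ok <- all(vapply(seq_len(k), function(f) {
      if (!require_both) return(any(fold_of == f))
      length(unique(labels[fold_of == f])) == 2L &&
        length(unique(labels[fold_of != f])) == 2L
    }, TRUE))
    if (ok) return(fold_of)
  }
  stop_fmt("could not build %d folds with both classes after %d retries", k, retries)
}

#' Fit the kernel-fusion drug repositioning SVM
#'
#' The main fitting function. Drug-disease association prediction is treated
#' as binary classification over (drug, disease) pairs: known associations are
#' positives, an equal number of unlabeled pairs is sampled as negatives, and
#' a soft-margin SVM is trained on the Kronecker product pair kernel
#' `k((d,q),(d',q')) = K_dr(d,d') * K_di(q,q')`. The penalty C is chosen by
#' inner 3-fold cross-validated grid search unless given.
#'
#' @param associations [association_table()] of gold-standard positives.
#' @param drug_kernel Drug similarity matrix (one source or a
#'   [combine_drug_kernels()] fusion) covering `associations$drugs`.
#' @param disease_kernel Disease phenotype similarity matrix covering
#'   `associations$diseases`.
#' @param C SVM penalty; `NULL` (default) selects it via [select_C()].
#' @param grid Candidate C values for selection.
#' @param inner_folds Inner CV folds for C selection.
#' @param negatives Optional explicit negative pair data frame; sampled
#'   (balanced, seeded) when omitted.
#' @param exclude Pairs to exclude from negative sampling (e.g. test pairs).
#' @param seed Integer seed controlling sampling and fold assignment.
#' @param repair Apply [psd_repair()] to the kernel factors (default TRUE).
#' @return An object of class `predr` with `print`, `summary`, `coef`,
#'   `fitted` and `predict` methods.
#' @examples
#' bench <- generate_benchmark(benchmark_params(n_drugs = 20, n_diseases = 12,
#'                                              seed = 7))
#' s_chem <- weighted_cosine_matrix(bench$chem)
#' fit <- predr(bench$associations, s_chem, bench$pheno, C = 1, seed = 7)
#' head(predict(fit, rank_novel_predictions(fit, bench$associations, top_n = 5)))
#' @export
predr <- function(associations, drug_kernel, disease_kernel,
                  C = NULL, grid = default_C_grid(), inner_folds = 3,
                  negatives = NULL, exclude = NULL, seed = 1, repair = TRUE) {
  stopifnot(inherits(associations, "association_table"))
  kernel <- pair_kernel(drug_kernel, disease_kernel, repair = repair)
  positives <- associations$edges
  if (is.null(negatives)) {
    negatives <- sample_negatives(associations, seed = seed, exclude = exclude)
  }
  ds <- pair_dataset(positives, negatives, seed = seed)
  cv_table <- NULL
  if (is.null(C)) {
    C <- select_C(ds, kernel, grid = grid, folds = inner_folds,
                  seed = derive_seed(seed, 101L))
    cv_table <- attr(C, "cv")
    C <- as.numeric(C)
  }
  g <- pair_gram(kernel, ds)
  fit <- fit_gram_svm(g, ds$label, C)
  structure(list(
    call = match.call(),
    kernel = kernel,
    dataset = ds,
    support = ds[fit$sv, c("drug", "disease")],
    alpha = fit$alpha,
    b = fit$b,
    C = C,
    C_selection = cv_table,
    seed = seed
  ), class = "predr")
}

#' Decision scores of a fitted pair-kernel SVM
#'
#' Continuous SVM margins for arbitrary drug-disease pairs; the ranking these
#' induce is what all evaluation metrics consume. Positive margins indicate
#' predicted association.
#'
#' @param model A fitted [predr()] object.
#' @param pairs Pair data frame with columns `drug`, `disease`.
#' @param kernel Pair kernel to evaluate against; defaults to the model's own.
#' @return Numeric vector of decision values, one per pair.
#' @export
decision_scores <- function(model, pairs, kernel = model$kernel) {
  stopifnot(inherits(model, "predr"))
  g <- pair_gram(kernel, pairs, model$support)
  drop(g %*% model$alpha - model$b)
}

#' @rdname decision_scores
#' @method predict predr
#' @param object,newdata,type `predict` method arguments: `newdata` is a pair
#'   data frame; `type` is `"decision"` (margins) or `"label"` (+/-1).
#' @param ... Unused.
#' @export
predict.predr <- function(object, newdata, type = c("decision", "label"), ...) {
  type <- match.arg(type)
  sc <- decision_scores(object, newdata)
  if (type == "label") ifelse(sc > 0, 1, -1) else sc
}

#' @method fitted predr
#' @export
fitted.predr <- function(object, ...) {
  decision_scores(object, object$dataset)
}

#' @method coef predr
#' @export
coef.predr <- function(object, ...) {
  out <- object$alpha
  names(out) <- paste(object$support$drug, object$support$disease, sep = ":")
  attr(out, "intercept") <- object$b
  out
}

#' @export
print.predr <- function(x, ...) {
  n_pos <- sum(x$dataset$label == 1)
  cat("Kernel-fusion drug repositioning SVM\n")
  cat(sprintf("  training pairs: %d positives + %d sampled negatives\n",
              n_pos, sum(x$dataset$label == -1)))
  cat(sprintf("  support pairs: %d   C = %g   seed = %s\n",
              nrow(x$support), x$C, format(x$seed)))
  invisible(x)
}

#' @method summary predr
#' @export
summary.predr <- function(object, ...) {
  sc <- fitted(object)
  lab <- object$dataset$label
  out <- list(
    n_pos = sum(lab == 1), n_neg = sum(lab == -1),
    n_support = nrow(object$support), C = object$C,
    C_selection = object$C_selection,
    train_auc = roc_auc(sc, lab),
    train_metrics = threshold_metrics(sc, lab)
  )
  class(out) <- "summary.predr"
  out
}

#' @export
print.summary.predr <- function(x, ...) {
  cat("Kernel-fusion drug repositioning SVM\n")
  cat(sprintf("  %d positives, %d negatives, %d support pairs, C = %g\n",
              x$n_pos, x$n_neg, x$n_support, x$C))
  cat(sprintf("  training AUC %.3f; at max-F threshold: Acc %.3f Sn %.3f Sp %.3f Pre %.3f F %.3f\n",
              x$train_auc, x$train_metrics$acc, x$train_metrics$sn,
              x$train_metrics$sp, x$train_metrics$pre, x$train_metrics$f))
  invisible(x)
}
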