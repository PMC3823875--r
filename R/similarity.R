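#' Rarity weights for binary profile features
#'
#' Computes per-feature weights that down-weight frequent features: rare
#' substructures (or side-effect terms) are more informative for specific
#' function than common ones. With feature frequencies \eqn{h_k} (column sums)
#' and their population standard deviation \eqn{\sigma_h}, the weight is
#' \deqn{w_k = \exp(-h_k^2 / (d\,\sigma_h^2))}
#' so weights decrease strictly with frequency. When all features are equally
#' frequent (\eqn{\sigma_h = 0}) weights are uniform 1.
#'
#' @param f Binary fingerprint matrix (drugs x features).
#' @param d Positive smoothing parameter; default 10.
#' @return An object of class `weight_vector`: list with `feature_ids`,
#'   `weights`, `h` (frequencies), `sigma_h`, `d`.
#' @export
compute_feature_weights <- function(f, d = 10) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d <= 0) {
    stop_fmt("'d' must be a single positive number")
  }
  validate_fingerprints(f)
  if (!nrow(f) || !ncol(f)) stop_fmt("fingerprint matrix is empty")
  h <- colSums(f)
  sigma_h <- sqrt(mean((h - mean(h))^2))  # population sd
  w <- if (sigma_h > 0) exp(-h^2 / (d * sigma_h^2)) else rep(1, length(h))
  names(w) <- colnames(f)
  structure(list(feature_ids = colnames(f), weights = w, h = h,
                 sigma_h = sigma_h, d = d),
            class = "weight_vector")
}

#' Weighted cosine similarity matrix over binary profiles
#'
#' Drug-drug similarity from binary profiles (chemical substructures or
#' side-effects):
#' \deqn{S(d,d') = \frac{\sum_k w_k x_k x'_k}{\sqrt{\sum_k w_k x_k^2}\sqrt{\sum_k w_k x'^2_k}}}
#' With uniform weights this is the plain cosine similarity. Drugs with an
#' all-zero profile get similarity 0 to all others and 1 to themselves, with a
#' warning.
#'
#' @param f Binary fingerprint matrix (drugs x features).
#' @param w Optional [compute_feature_weights()] result; computed from `f`
#'   with parameter `d` when omitted.
#' @param d Weight smoothing parameter used when `w` is missing.
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
weighted_cosine_matrix <- function(f, w = NULL, d = 10) {
  validate_fingerprints(f)
  if (is.null(w)) w <- compute_feature_weights(f, d = d)
  if (!inherits(w, "weight_vector")) stop_fmt("'w' must be a weight_vector")
  if (!identical(w$feature_ids, colnames(f))) {
    stop_fmt("feature ids of weights and fingerprints differ")
  }
  x <- f
  storage.mode(x) <- "double"
  num <- tcrossprod(sweep(x, 2L, w$weights, `*`), x)
  nrm <- sqrt(diag(num))
  zero <- nrm == 0
  if (any(zero)) {
    warn_fmt("%d drug(s) with all-zero profile: %s (similarity set to 0 off-diagonal)",
             sum(zero), paste(rownames(f)[zero], collapse = ", "))
    nrm[zero] <- 1  # avoid 0/0; rows zeroed below
  }
  s <- num / outer(nrm, nrm)
  s[zero, ] <- 0
  s[, zero] <- 0
  diag(s) <- 1
  as_similarity_matrix(s, tol = 1e-8)
}

#' Local alignment scoring parameters
#'
#' Gap cost for a gap of length k is `gap_open + gap_extend * (k - 1)`; the
#' defaults (BLOSUM50, open 8, extend 8) give a linear per-residue cost of 8,
#' the convention of the MATLAB bioinformatics alignment routines.
#'
#' @param substitution_matrix Name of a Biostrings substitution matrix.
#' @param gap_open,gap_extend Nonnegative penalties, `gap_open >= gap_extend`.
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(substitution_matrix = "BLOSUM50",
                             gap_open = 8, gap_extend = 8) {
  if (!(gap_open >= gap_extend && gap_extend >= 0)) {
    stop_fmt("need gap_open >= gap_extend >= 0")
  }
  mat <- get_substitution_matrix(substitution_matrix)
  structure(list(substitution_matrix_name = substitution_matrix,
                 substitution_matrix = mat,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

get_substitution_matrix <- function(name) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = e)) stop_fmt("unknown substitution matrix '%s'", name)
  get(name, envir = e)
}

# Raw Smith-Waterman local-alignment score. Biostrings charges
# gapOpening + k * gapExtension for a gap of length k, so the affine
# convention open + (k-1) * extend maps to gapOpening = open - extend.
sw_score <- function(a, b, params) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "local",
    substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_open - params$gap_extend,
    gapExtension = params$gap_extend,
    scoreOnly = TRUE
  )
}

#' Normalized Smith-Waterman sequence similarity
#'
#' Local-alignment score normalized by the geometric mean of the two
#' self-alignment scores: `sw(a,b) / sqrt(sw(a,a) * sw(b,b))`. Identical
#' sequences score exactly 1 and the measure is symmetric.
#'
#' @param a,b Amino-acid sequences (standard 20-letter alphabet, uppercase).
#' @param params [alignment_params()].
#' @return Normalized similarity in `[0, 1]`.
#' @export
normalized_sw_score <- function(a, b, params = alignment_params()) {
  seqs <- c(a = a, b = b)
  validate_sequences(seqs)
  saa <- sw_score(a, a, params)
  sbb <- sw_score(b, b, params)
  if (saa <= 0 || sbb <= 0) stop_fmt("nonpositive self-alignment score")
  sw_score(a, b, params) / sqrt(saa * sbb)
}

#' Pairwise normalized Smith-Waterman matrix over a sequence store
#'
#' Computes all pairwise normalized local-alignment similarities once so that
#' target-set aggregation can reuse them.
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param params [alignment_params()].
#' @return Symmetric matrix of normalized scores with unit diagonal.
#' @export
sw_similarity_matrix <- function(sequences, params = alignment_params()) {
  validate_sequences(sequences)
  n <- length(sequences)
  ids <- names(sequences)
  set <- Biostrings::AAStringSet(sequences)
  raw <- matrix(0, n, n, dimnames = list(ids, ids))
  go <- params$gap_open - params$gap_extend
  for (i in seq_len(n)) {
    sc <- Biostrings::pairwiseAlignment(
      set[i:n], set[[i]], type = "local",
      substitutionMatrix = params$substitution_matrix,
      gapOpening = go, gapExtension = params$gap_extend,
      scoreOnly = TRUE
    )
    raw[i, i:n] <- sc
    raw[i:n, i] <- sc
  }
  selfs <- diag(raw)
  if (any(selfs <= 0)) {
    stop_fmt("nonpositive self-alignment score for: %s",
             paste(ids[selfs <= 0], collapse = ", "))
  }
  s <- raw / sqrt(outer(selfs, selfs))
  as_similarity_matrix(s, tol = 1e-8)
}

aggregate_cross <- function(vals, aggregator) {
  switch(aggregator, max = max(vals), mean = mean(vals),
         stop_fmt("unknown aggregator '%s'", aggregator))
}

#' Target-set drug similarity from protein sequences
#'
#' Drug-drug similarity aggregated over all cross pairs of the two drugs'
#' target sets, using normalized Smith-Waterman protein similarity. The
#' aggregated matrix need not be positive semidefinite, so it is re-normalized
#' by its diagonal ([diagonal_normalize()]) before being returned (disable via
#' `normalize = FALSE`). Drugs with an empty target set get 0 similarity to
#' all others (and 1 to themselves), with a warning.
#'
#' @param targets Named list: drug id -> character vector of protein ids.
#' @param sequences Named character vector covering all mapped proteins.
#' @param params [alignment_params()].
#' @param aggregator `"max"` (default, best cross-pair match) or `"mean"`.
#' @param drugs Optional drug universe (defaults to `names(targets)`); drugs
#'   absent from `targets` are treated as having empty target sets.
#' @param normalize Apply [diagonal_normalize()] to the aggregate (default TRUE).
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
target_set_similarity_matrix <- function(targets, sequences,
                                         params = alignment_params(),
                                         aggregator = c("max", "mean"),
                                         drugs = NULL, normalize = TRUE) {
  aggregator <- match.arg(aggregator)
  drugs <- drugs %||% names(targets)
  prot <- sw_similarity_matrix(sequences[unique(unlist(targets))], params)
  n <- length(drugs)
  s <- matrix(0, n, n, dimnames = list(drugs, drugs))
  tsets <- lapply(drugs, function(d) if (d %in% names(targets)) targets[[d]] else character())
  empty <- lengths(tsets) == 0L
  if (any(empty)) {
    warn_fmt("%d drug(s) with empty target set: %s",
             sum(empty), paste(drugs[empty], collapse = ", "))
  }
  for (i in seq_len(n)) {
    if (empty[i]) next
    for (j in i:n) {
      if (empty[j]) next
      s[i, j] <- s[j, i] <- aggregate_cross(prot[tsets[[i]], tsets[[j]]], aggregator)
    }
  }
  diag(s)[empty] <- 1
  if (normalize) s <- diagonal_normalize(s)
  diag(s) <- 1
  as_similarity_matrix(s, tol = 1e-8)
}

#' Diagonal (cosine) normalization of a similarity matrix
#'
#' Rescales `K` to `K'[i,j] = K[i,j] / sqrt(K[i,i] * K[j,j])`, giving a unit
#' diagonal. Idempotent; requires strictly positive diagonal entries.
#'
#' @param k Symmetric labeled matrix with positive diagonal.
#' @return The normalized matrix.
#' @export
diagonal_normalize <- function(k) {
  k <- as_similarity_matrix(k, tol = 1e-8)
  d <- diag(k)
  if (any(d <= 0)) {
    stop_fmt("nonpositive diagonal entries for: %s",
             paste(rownames(k)[d <= 0], collapse = ", "))
  }
  r <- sqrt(d)
  k / outer(r, r)
}

#' Drug similarity by disease profile
#'
#' Similarity of two drugs via the phenotype similarity of the diseases they
#' are known to treat: the aggregate over all cross pairs of the two drugs'
#' gold-standard disease sets. Used in the correlation analysis relating the
#' molecular similarity measures to therapeutic similarity.
#'
#' @param a [association_table()] of gold-standard positives.
#' @param pheno Disease phenotype similarity matrix.
#' @param aggregator `"max"` (default) or `"mean"`.
#' @return Symmetric similarity matrix (unit diagonal) over the drugs with at
#'   least one associated disease present in `pheno`; drugs with none are
#'   excluded with a warning.
#' @export
disease_profile_drug_similarity <- function(a, pheno,
                                            aggregator = c("max", "mean")) {
  aggregator <- match.arg(aggregator)
  stopifnot(inherits(a, "association_table"))
  pheno <- as_similarity_matrix(pheno, tol = 1e-8)
  dsets <- lapply(split(a$edges$disease, a$edges$drug),
                  function(q) intersect(unique(q), rownames(pheno)))
  dsets <- dsets[order(match(names(dsets), a$drugs))]
  keep <- lengths(dsets) > 0L
  dropped <- setdiff(a$drugs, names(dsets)[keep])
  if (length(dropped)) {
    warn_fmt("excluding %d drug(s) with no phenotype-resolved disease: %s",
             length(dropped), paste(dropped, collapse = ", "))
  }
  dsets <- dsets[keep]
  drugs <- names(dsets)
  n <- length(drugs)
  s <- matrix(0, n, n, dimnames = list(drugs, drugs))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s[i, j] <- s[j, i] <- aggregate_cross(pheno[dsets[[i]], dsets[[j]]], aggregator)
    }
  }
  diag(s) <- 1
  as_similarity_matrix(s, tol = 1e-8)
}
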