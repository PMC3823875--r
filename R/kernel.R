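#' Fuse several drug similarity matrices
#'
#' Weighted arithmetic mean of similarity matrices over an identical drug
#' universe. With the default uniform weights this is the "Comb" fusion of the
#' chemical, target and side-effect kernels.
#'
#' @param mats List of similarity matrices with identical ids in identical order.
#' @param weights Nonnegative weights, one per matrix; default uniform.
#' @return The fused symmetric similarity matrix.
#' @export
combine_drug_kernels <- function(mats, weights = NULL) {
  if (!length(mats)) stop_fmt("need at least one matrix")
  mats <- lapply(mats, as_similarity_matrix, tol = 1e-8)
  ids <- rownames(mats[[1L]])
  for (m in mats[-1L]) {
    if (!identical(rownames(m), ids)) stop_fmt("matrices have mismatched ids")
  }
  weights <- weights %||% rep(1, length(mats))
  if (length(weights) != length(mats) || any(weights < 0) || sum(weights) <= 0) {
    stop_fmt("weights must be nonnegative with positive sum, one per matrix")
  }
  out <- Reduce(`+`, Map(`*`, mats, weights)) / sum(weights)
  as_similarity_matrix(out, tol = 1e-8)
}

#' Repair a kernel matrix to positive semidefiniteness
#'
#' Aggregated sequence-similarity matrices need not be positive semidefinite,
#' which breaks SVM convexity. This clips negative eigenvalues to zero and
#' reconstructs — the nearest PSD matrix in Frobenius norm among spectral
#' clips. Matrices already PSD (minimum eigenvalue >= `-tol`) are returned
#' unchanged.
#'
#' @param k Symmetric labeled matrix.
#' @param tol Eigenvalue tolerance; default 1e-8.
#' @return A symmetric PSD matrix.
#' @export
psd_repair <- function(k, tol = 1e-8) {
  k <- as_similarity_matrix(k, tol = 1e-8)
  e <- eigen(k, symmetric = TRUE)
  if (min(e$values) >= -tol) return(k)
  lam <- pmax(e$values, 0)
  out <- e$vectors %*% (lam * t(e$vectors))
  dimnames(out) <- dimnames(k)
  as_similarity_matrix(out, tol = 1e-8)
}

#' Kronecker product pair kernel
#'
#' The kernel between two drug-disease pairs is the product of a drug-kernel
#' entry and a disease-kernel entry:
#' \deqn{k((d,q),(d',q')) = K_{dr}(d,d') \cdot K_{di}(q,q')}
#' so two pairs are similar only when both the drugs and the diseases are
#' simultaneously similar. The full Kronecker Gram over all drug x disease
#' pairs is never materialized; blocks are evaluated lazily for requested pair
#' lists via [pair_gram()].
#'
#' @param drug_kernel,disease_kernel Symmetric similarity matrices (the drug
#'   factor, e.g. chem/target/side-effect or their fusion, and the disease
#'   phenotype factor).
#' @param repair Apply [psd_repair()] to both factors (default TRUE); SVM
#'   training requires PSD factors.
#' @return An object of class `pair_kernel`.
#' @export
pair_kernel <- function(drug_kernel, disease_kernel, repair = TRUE) {
  drug_kernel <- as_similarity_matrix(drug_kernel, tol = 1e-8)
  disease_kernel <- as_similarity_matrix(disease_kernel, tol = 1e-8)
  if (repair) {
    drug_kernel <- psd_repair(drug_kernel)
    disease_kernel <- psd_repair(disease_kernel)
  }
  structure(list(drug_kernel = drug_kernel, disease_kernel = disease_kernel,
                 repaired = repair),
            class = "pair_kernel")
}

#' @export
print.pair_kernel <- function(x, ...) {
  cat(sprintf("Kronecker pair kernel: %d drugs x %d diseases%s\n",
              nrow(x$drug_kernel), nrow(x$disease_kernel),
              if (x$repaired) " (PSD-repaired factors)" else ""))
  invisible(x)
}

#' Gram block of the pair kernel
#'
#' @param k A [pair_kernel()].
#' @param rows,cols Pair lists: data frames with character columns `drug`,
#'   `disease`. `cols` defaults to `rows` (a square training Gram).
#' @return Numeric matrix `G[i, j] = K_dr(d_i, d_j) * K_di(q_i, q_j)`.
#' @export
pair_gram <- function(k, rows, cols = rows) {
  stopifnot(inherits(k, "pair_kernel"))
  check_pairs <- function(p, what) {
    bad_d <- setdiff(p$drug, rownames(k$drug_kernel))
    bad_q <- setdiff(p$disease, rownames(k$disease_kernel))
    if (length(bad_d)) stop_fmt("%s: unknown drug id(s): %s", what, paste(bad_d, collapse = ", "))
    if (length(bad_q)) stop_fmt("%s: unknown disease id(s): %s", what, paste(bad_q, collapse = ", "))
  }
  check_pairs(rows, "rows")
  check_pairs(cols, "cols")
  k$drug_kernel[rows$drug, cols$drug, drop = FALSE] *
    k$disease_kernel[rows$disease, cols$disease, drop = FALSE]
}
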