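#' Drug-drug distances in the bipartite association network
#'
#' Shortest-path lengths between drugs in the bipartite drug-disease graph of
#' gold-standard positives. Drug-drug distances are even: distance 2 means the
#' two drugs share at least one disease; unreachable pairs are `Inf`.
#'
#' @param a [association_table()].
#' @return Symmetric numeric matrix of distances over `a$drugs` (diagonal 0).
#' @export
drug_network_distances <- function(a) {
  stopifnot(inherits(a, "association_table"))
  if (!nrow(a$edges)) stop_fmt("empty association table")
  # Disease vertex names are prefixed to keep the two sides disjoint.
  g <- igraph::graph_from_data_frame(
    data.frame(from = a$edges$drug,
               to = paste0("disease::", a$edges$disease)),
    directed = FALSE,
    vertices = data.frame(name = c(a$drugs, paste0("disease::", a$diseases)))
  )
  d <- igraph::distances(g, v = a$drugs, to = a$drugs)
  dimnames(d) <- list(a$drugs, a$drugs)
  d
}

#' Correlation between molecular similarity and disease-profile similarity
#'
#' Pearson correlation between a drug similarity measure (chemical, target or
#' side-effect based) and the drugs' disease-profile similarity
#' ([disease_profile_drug_similarity()]), over unique off-diagonal drug pairs.
#' Besides the overall correlation, the PCC is recomputed on the cumulative
#' tails `s >= cutoff` for each cutoff in `bins` — similar drugs are expected
#' to show stronger therapeutic agreement. P-values come from the exact
#' t-transform of r with n-2 degrees of freedom (no multiplicity correction).
#'
#' @param s Drug similarity matrix (any single source or fusion).
#' @param dp Disease-profile drug similarity matrix; ids must overlap `s`.
#' @param bins Lower cutoffs defining the cumulative tails.
#' @return Data frame with columns `min_similarity`, `n_pairs`, `pcc`,
#'   `p_value`; the first row (`min_similarity = -Inf`) is the overall PCC.
#'   Tails with fewer than 3 pairs have `NA` entries.
#' @export
similarity_profile_correlation <- function(s, dp,
                                           bins = c(0, 0.2, 0.4, 0.6, 0.8)) {
  s <- as_similarity_matrix(s, tol = 1e-8)
  dp <- as_similarity_matrix(dp, tol = 1e-8)
  ids <- intersect(rownames(s), rownames(dp))
  if (length(ids) < 3L) stop_fmt("need >= 3 drugs common to both matrices")
  s <- s[ids, ids]; dp <- dp[ids, ids]
  ut <- upper.tri(s)
  x <- s[ut]; y <- dp[ut]
  one_bin <- function(cut) {
    keep <- if (is.finite(cut)) x >= cut else rep(TRUE, length(x))
    n <- sum(keep)
    if (n < 3L || stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) {
      return(data.frame(min_similarity = cut, n_pairs = n,
                        pcc = NA_real_, p_value = NA_real_))
    }
    r <- stats::cor(x[keep], y[keep])
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    data.frame(min_similarity = cut, n_pairs = n, pcc = r,
               p_value = 2 * stats::pt(-abs(tstat), df = n - 2))
  }
  out <- do.call(rbind, lapply(c(-Inf, sort(bins)), one_bin))
  rownames(out) <- NULL
  attr(out, "binning") <- "cumulative-tail"
  out
}

#' Rank novel drug-disease predictions
#'
#' Scores every non-positive drug x disease pair with a fitted model and
#' returns the top-ranked candidates — the repositioning predictions. Ties are
#' broken deterministically by (drug id, disease id).
#'
#' @param model A fitted [predr()] object.
#' @param a [association_table()] of known positives (excluded from ranking).
#' @param top_n Number of predictions to return (default 100); truncated with
#'   a warning if fewer candidates exist.
#' @return Data frame `drug`, `disease`, `score`, `rank`, ordered by
#'   decreasing score.
#' @export
rank_novel_predictions <- function(model, a, top_n = 100) {
  stopifnot(inherits(model, "predr"), inherits(a, "association_table"))
  cand <- all_pairs(a$drugs, a$diseases)
  cand <- cand[!(pair_key(cand) %in% pair_key(a$edges)), , drop = FALSE]
  if (top_n > nrow(cand)) {
    warn_fmt("top_n = %d exceeds the %d candidate pairs; truncating",
             top_n, nrow(cand))
    top_n <- nrow(cand)
  }
  cand$score <- decision_scores(model, cand)
  cand <- cand[order(-cand$score, cand$drug, cand$disease), , drop = FALSE]
  out <- utils::head(cand, top_n)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
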