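# Independent oracles used by the tests. These deliberately take the slow,
# brute-force route and share no code with the package implementation.

# Quadratic-DP Smith-Waterman with affine gaps (three-state recursion).
# Gap of length k costs open + (k - 1) * extend.
oracle_sw <- function(a, b, submat, open = 8, extend = 8) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- matrix(0, n + 1, m + 1)   # match/mismatch state
  Ix <- matrix(-Inf, n + 1, m + 1)  # gap in y (moving along x)
  Iy <- matrix(-Inf, n + 1, m + 1)  # gap in x
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open, Ix[i, j + 1] - extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open, Iy[i + 1, j] - extend)
      sub <- submat[x[i], y[j]]
      M[i + 1, j + 1] <- max(0,
                             M[i, j] + sub,
                             Ix[i, j] + sub,
                             Iy[i, j] + sub)
      best <- max(best, M[i + 1, j + 1], Ix[i + 1, j + 1], Iy[i + 1, j + 1])
    }
  }
  best
}

# AUC by exhaustive concordant/discordant pair counting (ties count 1/2).
oracle_auc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == -1)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Threshold metrics by brute force over every cut, mirroring the contract:
# predict positive when score >= t, maximize F, break ties toward higher Sn.
oracle_threshold_metrics <- function(scores, labels) {
  best <- NULL
  for (t in sort(unique(scores), decreasing = TRUE)) {
    pred <- ifelse(scores >= t, 1, -1)
    tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == -1)
    tn <- sum(pred == -1 & labels == -1); fn <- sum(pred == -1 & labels == 1)
    if (tp + fp == 0) next
    sn <- tp / (tp + fn); pre <- tp / (tp + fp)
    f <- if (pre + sn > 0) 2 * pre * sn / (pre + sn) else 0
    cand <- list(acc = (tp + tn) / length(labels), sn = sn,
                 sp = tn / (tn + fp), pre = pre, f = f, threshold = t)
    if (is.null(best) || f > best$f || (f == best$f && sn > best$sn)) best <- cand
  }
  best
}

# AUPR by explicit stepping down the ranked list, grouping tied scores.
oracle_aupr <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  area <- 0; prev_recall <- 0
  for (t in sort(unique(scores), decreasing = TRUE)) {
    sel <- scores >= t
    tp <- sum(sel & labels == 1)
    prec <- tp / sum(sel)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * prec
    prev_recall <- recall
  }
  area
}

# All-pairs shortest paths by Floyd-Warshall on the bipartite graph.
oracle_distances <- function(a) {
  nodes <- c(paste0("dr:", a$drugs), paste0("di:", a$diseases))
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (e in seq_len(nrow(a$edges))) {
    i <- paste0("dr:", a$edges$drug[e]); j <- paste0("di:", a$edges$disease[e])
    d[i, j] <- d[j, i] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  dd <- d[paste0("dr:", a$drugs), paste0("dr:", a$drugs)]
  dimnames(dd) <- list(a$drugs, a$drugs)
  dd
}

random_fingerprints <- function(n, p, seed, density = 0.4) {
  set.seed(seed)
  m <- matrix(rbinom(n * p, 1, density), n, p,
              dimnames = list(sprintf("d%02d", 1:n), sprintf("f%02d", 1:p)))
  storage.mode(m) <- "integer"
  m
}

random_sequence <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"), len, replace = TRUE),
        collapse = "")
}

# Small random symmetric positive-definite similarity-like matrix.
random_spd <- function(n, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * (n + 2)), n)
  m <- tcrossprod(x) / (n + 2) + diag(n) * 0.1
  dimnames(m) <- list(sprintf("i%d", 1:n), sprintf("i%d", 1:n))
  m
}

toy_associations <- function() {
  association_table(
    data.frame(drug = c("d1", "d1", "d2", "d2", "d3", "d3"),
               disease = c("q1", "q2", "q1", "q3", "q3", "q4")),
    drugs = c("d1", "d2", "d3"),
    diseases = c("q1", "q2", "q3", "q4"))
}
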