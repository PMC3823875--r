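#' Parameters for the synthetic benchmark
#'
#' The generator plants a "similar drugs treat similar diseases" structure:
#' drugs and diseases fall into latent classes; same-class drugs share a
#' chemical-fingerprint prototype, a side-effect prototype and a target
#' protein prototype (subject to bit flips and point mutations), disease
#' phenotype similarity is high within a class and low across, and
#' associations are dense within matching classes and sparse across. Defaults
#' are sized so a full cross-validation run completes in minutes on one CPU.
#'
#' @param n_drugs,n_diseases,n_classes Entity counts; classes are assigned in
#'   contiguous, near-equal blocks.
#' @param n_chem_features,n_se_features Fingerprint widths.
#' @param bit_density Probability a prototype fingerprint bit is set.
#' @param bit_noise Per-bit flip probability when a drug inherits its class
#'   prototype.
#' @param seq_length Protein prototype length (residues).
#' @param mutation_rate Per-residue substitution probability for a drug's
#'   target copies (substitutions only, no indels).
#' @param targets_per_drug Integer range `c(min, max)` of targets per drug.
#' @param assoc_prob_within,assoc_prob_between Association probabilities for
#'   matching / non-matching drug-disease classes (within must exceed between).
#' @param pheno_within,pheno_between Phenotype similarity means within/between
#'   disease classes (within must exceed between).
#' @param pheno_noise Standard deviation of the symmetric phenotype noise.
#' @param seed Integer seed; the benchmark is fully determined by it.
#' @return A validated `benchmark_params` list.
#' @export
benchmark_params <- function(n_drugs = 60, n_diseases = 40, n_classes = 4,
                             n_chem_features = 200, n_se_features = 100,
                             bit_density = 0.2, bit_noise = 0.1,
                             seq_length = 120, mutation_rate = 0.05,
                             targets_per_drug = c(1, 3),
                             assoc_prob_within = 0.5, assoc_prob_between = 0.02,
                             pheno_within = 0.7, pheno_between = 0.2,
                             pheno_noise = 0.05, seed = 0) {
  p <- as.list(environment())
  probs <- c(p$bit_density, p$bit_noise, p$mutation_rate,
             p$assoc_prob_within, p$assoc_prob_between,
             p$pheno_within, p$pheno_between)
  if (any(probs < 0 | probs > 1)) stop_fmt("probabilities must lie in [0, 1]")
  if (p$assoc_prob_within <= p$assoc_prob_between) {
    stop_fmt("assoc_prob_within must exceed assoc_prob_between")
  }
  if (p$pheno_within <= p$pheno_between) {
    stop_fmt("pheno_within must exceed pheno_between")
  }
  if (p$n_classes > min(p$n_drugs, p$n_diseases)) {
    stop_fmt("n_classes must not exceed min(n_drugs, n_diseases)")
  }
  if (length(p$targets_per_drug) != 2L || any(p$targets_per_drug < 1) ||
      p$targets_per_drug[1] > p$targets_per_drug[2]) {
    stop_fmt("targets_per_drug must be an increasing range of counts >= 1")
  }
  class(p) <- "benchmark_params"
  p
}

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

# Contiguous near-equal class blocks, e.g. 60 drugs / 4 classes -> 15 each.
class_blocks <- function(n, k) sort(rep_len(seq_len(k), n))

flip_bits <- function(proto, p_flip) {
  flip <- stats::runif(length(proto)) < p_flip
  ifelse(flip, 1L - proto, proto)
}

mutate_seq <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  chars
}

#' Generate a synthetic drug-repositioning benchmark
#'
#' @param p [benchmark_params()].
#' @return Object of class `synthetic_benchmark`: `chem` and `se` fingerprint
#'   matrices, `targets` (drug -> protein ids), `sequences`, `pheno` disease
#'   similarity matrix, `associations` ([association_table()]), and `truth`
#'   (class label per drug and disease).
#' @export
generate_benchmark <- function(p = benchmark_params()) {
  stopifnot(inherits(p, "benchmark_params"))
  with_seed(p$seed, {
    drugs <- sprintf("D%03d", seq_len(p$n_drugs))
    diseases <- sprintf("Q%03d", seq_len(p$n_diseases))
    drug_class <- class_blocks(p$n_drugs, p$n_classes)
    disease_class <- class_blocks(p$n_diseases, p$n_classes)

    proto_bits <- function(n_feat) {
      matrix(as.integer(stats::runif(p$n_classes * n_feat) < p$bit_density),
             p$n_classes, n_feat)
    }
    chem_proto <- proto_bits(p$n_chem_features)
    se_proto <- proto_bits(p$n_se_features)
    seq_proto <- replicate(p$n_classes,
                           sample(AA20, p$seq_length, replace = TRUE),
                           simplify = FALSE)

    inherit <- function(proto, n_feat, feat_prefix) {
      m <- t(vapply(seq_len(p$n_drugs),
                    function(i) flip_bits(proto[drug_class[i], ], p$bit_noise),
                    integer(n_feat)))
      dimnames(m) <- list(drugs, paste0(feat_prefix, seq_len(n_feat)))
      m
    }
    chem <- inherit(chem_proto, p$n_chem_features, "F")
    se <- inherit(se_proto, p$n_se_features, "E")

    targets <- list(); sequences <- character()
    for (i in seq_len(p$n_drugs)) {
      n_t <- sample(seq(p$targets_per_drug[1], p$targets_per_drug[2]), 1L)
      ids <- sprintf("P%s_%d", drugs[i], seq_len(n_t))
      for (j in seq_len(n_t)) {
        sequences[[ids[j]]] <- paste(
          mutate_seq(seq_proto[[drug_class[i]]], p$mutation_rate),
          collapse = "")
      }
      targets[[drugs[i]]] <- ids
    }

    same <- outer(disease_class, disease_class, `==`)
    pheno <- ifelse(same, p$pheno_within, p$pheno_between)
    noise <- matrix(stats::rnorm(p$n_diseases^2, sd = p$pheno_noise),
                    p$n_diseases, p$n_diseases)
    pheno <- pheno + (noise + t(noise)) / 2
    pheno <- pmin(pmax(pheno, 0), 1)
    diag(pheno) <- 1
    dimnames(pheno) <- list(diseases, diseases)

    prob <- ifelse(outer(drug_class, disease_class, `==`),
                   p$assoc_prob_within, p$assoc_prob_between)
    hit <- which(matrix(stats::runif(length(prob)), nrow(prob)) < prob,
                 arr.ind = TRUE)
    edges <- pair_frame(drugs[hit[, 1L]], diseases[hit[, 2L]])
    edges <- edges[order(edges$drug, edges$disease), , drop = FALSE]

    structure(list(
      chem = chem, se = se,
      targets = targets, sequences = sequences,
      pheno = as_similarity_matrix(pheno, tol = 1e-8),
      associations = association_table(edges, drugs = drugs, diseases = diseases),
      truth = list(drug_class = stats::setNames(drug_class, drugs),
                   disease_class = stats::setNames(disease_class, diseases)),
      params = p
    ), class = "synthetic_benchmark")
  })
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat(sprintf("Synthetic benchmark: %d drugs, %d diseases, %d classes, %d edges (seed %s)\n",
              length(x$associations$drugs), length(x$associations$diseases),
              x$params$n_classes, nrow(x$associations$edges),
              format(x$params$seed)))
  invisible(x)
}

mean_block <- function(s, classes) {
  same <- outer(classes, classes, `==`)
  ut <- upper.tri(s)
  c(within = mean(s[ut & same]), between = mean(s[ut & !same]))
}

#' Summarize a synthetic benchmark
#'
#' Counts, association density and mean within/between-class similarity for
#' each drug profile source (a quick check that the planted signal is there).
#'
#' @param b A [generate_benchmark()] result.
#' @param params [alignment_params()] for the target source.
#' @return A list with `counts`, `density` and a `similarity` data frame
#'   (source, within, between).
#' @export
benchmark_summary <- function(b, params = alignment_params()) {
  stopifnot(inherits(b, "synthetic_benchmark"))
  cls <- b$truth$drug_class
  sims <- list(
    chem = weighted_cosine_matrix(b$chem),
    side_effect = weighted_cosine_matrix(b$se),
    target = suppressWarnings(
      target_set_similarity_matrix(b$targets, b$sequences, params = params,
                                   drugs = b$associations$drugs))
  )
  tab <- do.call(rbind, lapply(names(sims), function(nm) {
    m <- mean_block(sims[[nm]], cls)
    data.frame(source = nm, within = m["within"], between = m["between"],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  n_dr <- length(b$associations$drugs)
  n_di <- length(b$associations$diseases)
  list(counts = c(drugs = n_dr, diseases = n_di,
                  edges = nrow(b$associations$edges)),
       density = nrow(b$associations$edges) / (n_dr * n_di),
       similarity = tab)
}

#' Write a synthetic benchmark to a directory
#'
#' Writes all standard input files (fingerprints, target map + FASTA,
#' phenotype matrix, association edge list) plus a truth table of the planted
#' class labels.
#'
#' @param b A [generate_benchmark()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_benchmark <- function(b, dir) {
  stopifnot(inherits(b, "synthetic_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fingerprints(b$chem, file.path(dir, "chem_fingerprints.tsv"))
  write_fingerprints(b$se, file.path(dir, "side_effects.tsv"))
  write_target_data(b$targets, b$sequences,
                    file.path(dir, "drug_targets.tsv"),
                    file.path(dir, "target_sequences.fasta"))
  write_similarity_matrix(b$pheno, file.path(dir, "phenotype_similarity.tsv"))
  write_associations(b$associations, file.path(dir, "associations.tsv"))
  truth <- data.frame(
    id = c(names(b$truth$drug_class), names(b$truth$disease_class)),
    type = rep(c("drug", "disease"),
               c(length(b$truth$drug_class), length(b$truth$disease_class))),
    class = c(b$truth$drug_class, b$truth$disease_class),
    stringsAsFactors = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
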