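# With assoc_prob_within = 1 and between = 0, positives are exactly the
# within-class pairs and every unlabeled pair is cross-class, so the planted
# block kernels separate the training set perfectly.
make_separable_fixture <- function(seed = 2) {
  generate_benchmark(benchmark_params(
    n_drugs = 14, n_diseases = 10, n_classes = 2, bit_noise = 0,
    assoc_prob_within = 1, assoc_prob_between = 0,
    pheno_noise = 0, seed = seed))
}

test_that("negative sampling is balanced, exhaustive at the boundary, and seeded", {
  a <- association_table(
    data.frame(drug = c("d1", "d1", "d2", "d3"),
               disease = c("q1", "q2", "q2", "q3")),
    drugs = paste0("d", 1:3), diseases = paste0("q", 1:3))
  # 3x3 universe with 4 positives: n = 5 must return exactly the complement
  neg <- sample_negatives(a, n = 5, seed = 1)
  expect_equal(nrow(neg), 5)
  expect_length(intersect(paste(neg$drug, neg$disease),
                          paste(a$edges$drug, a$edges$disease)), 0)
  expect_error(sample_negatives(a, n = 6, seed = 1), "unlabeled")

  # default n = |positives|; identical seed -> identical draw
  n1 <- sample_negatives(a, seed = 42)
  n2 <- sample_negatives(a, seed = 42)
  expect_equal(nrow(n1), nrow(a$edges))
  expect_identical(n1, n2)
  # different seed -> (almost surely) different draw on a larger universe
  b <- generate_benchmark(benchmark_params(n_drugs = 20, n_diseases = 15, seed = 1))
  expect_false(identical(sample_negatives(b$associations, seed = 1),
                         sample_negatives(b$associations, seed = 2)))

  # exclusion is honored
  excl <- pair_frame("d2", "q1")
  neg3 <- sample_negatives(a, n = 4, seed = 3, exclude = excl)
  expect_false("d2:q1" %in% paste(neg3$drug, neg3$disease, sep = ":"))
})

test_that("pair datasets reject overlapping positives and negatives", {
  pos <- pair_frame(c("d1", "d2"), c("q1", "q2"))
  expect_error(pair_dataset(pos, pair_frame("d1", "q1")), "overlap")
  ds <- pair_dataset(pos, pair_frame("d3", "q3"))
  expect_equal(ds$label, c(1, 1, -1))
})

test_that("the SVM separates a block-structured Gram and scores reproducibly", {
  b <- make_separable_fixture()
  s <- weighted_cosine_matrix(b$chem)
  fit <- predr(b$associations, s, b$pheno, C = 1, seed = 5)
  sc <- fitted(fit)
  lab <- fit$dataset$label
  expect_equal(roc_auc(sc, lab), 1)          # separable fixture
  expect_true(all(sc[lab == 1] > 0))         # positive margins on positives

  # reproducibility across runs with fixed inputs
  fit2 <- predr(b$associations, s, b$pheno, C = 1, seed = 5)
  expect_equal(fitted(fit2), sc, tolerance = 1e-6)

  # decision scores via predict agree with decision_scores
  pairs <- all_pairs(b$associations$drugs[1:3], b$associations$diseases[1:3])
  expect_equal(predict(fit, pairs), decision_scores(fit, pairs))
  expect_error(decision_scores(fit, pair_frame("nope", "q1")), "nope")
})

test_that("duplicating every training point leaves the decision function unchanged", {
  # duplicating each pair doubles the hinge-loss mass, so the exact invariance
  # is duplicate-with-C/2: 0.5|w|^2 + (C/2) sum_{2n} xi == 0.5|w|^2 + C sum_n xi
  b <- make_separable_fixture(seed = 6)
  s <- weighted_cosine_matrix(b$chem)
  a <- b$associations
  neg <- sample_negatives(a, seed = 9)
  kernel <- pair_kernel(s, b$pheno)
  ds1 <- pair_dataset(a$edges, neg)
  g1 <- pair_gram(kernel, ds1)
  idx2 <- rep(seq_len(nrow(ds1)), 2)
  f1 <- predr:::fit_gram_svm(g1, ds1$label, 1)
  f2 <- predr:::fit_gram_svm(g1[idx2, idx2], ds1$label[idx2], 0.5)
  test_pairs <- all_pairs(a$drugs[c(1, 2, 13, 14)], a$diseases[c(1, 2, 9, 10)])
  gt <- pair_gram(kernel, test_pairs, ds1)
  sc1 <- predr:::gram_decision(f1, gt[, f1$sv, drop = FALSE])
  sc2 <- predr:::gram_decision(f2, gt[, idx2, drop = FALSE][, f2$sv, drop = FALSE])
  expect_lt(max(abs(sc1 - sc2)), 2e-3)  # equal up to the solver's KKT tolerance
})

test_that("single-class training data is rejected", {
  b <- make_separable_fixture(seed = 7)
  kernel <- pair_kernel(weighted_cosine_matrix(b$chem), b$pheno)
  ds <- pair_dataset(b$associations$edges[1:4, ], pair_frame(character(), character()))
  expect_error(predr:::fit_gram_svm(pair_gram(kernel, ds), ds$label, 1),
               "single-class")
})

test_that("select_C returns the argmax of inner-CV AUC, ties toward smaller C", {
  b <- make_separable_fixture(seed = 8)
  kernel <- pair_kernel(weighted_cosine_matrix(b$chem), b$pheno)
  a <- b$associations
  ds <- pair_dataset(a$edges, sample_negatives(a, seed = 4))

  # singleton grid -> that value
  expect_equal(as.numeric(select_C(ds, kernel, grid = 0.25, seed = 1)), 0.25)

  got <- select_C(ds, kernel, grid = c(0.1, 1), folds = 2, seed = 3)
  tab <- attr(got, "cv")
  # argmax contract against the reported table (ties -> smaller C)
  best_by_table <- tab$C[which.max(tab$mean_auc)]
  expect_equal(as.numeric(got), best_by_table)
  expect_true(all(tab$mean_auc <= max(tab$mean_auc)))
})

test_that("kernel scale with compensating C preserves the ranking", {
  b <- make_separable_fixture(seed = 10)
  s <- weighted_cosine_matrix(b$chem)
  a <- b$associations
  kernel1 <- pair_kernel(s, b$pheno)  # repaired factors
  kernel2 <- pair_kernel(kernel1$drug_kernel * 0.5, kernel1$disease_kernel,
                         repair = FALSE)
  ds <- pair_dataset(a$edges, sample_negatives(a, seed = 2))
  f1 <- predr:::fit_gram_svm(pair_gram(kernel1, ds), ds$label, 1)
  f2 <- predr:::fit_gram_svm(pair_gram(kernel2, ds), ds$label, 2)
  test_pairs <- all_pairs(a$drugs, a$diseases[1:3])
  g1 <- pair_gram(kernel1, test_pairs, ds)
  g2 <- pair_gram(kernel2, test_pairs, ds)
  sc1 <- predr:::gram_decision(f1, g1[, f1$sv, drop = FALSE])
  sc2 <- predr:::gram_decision(f2, g2[, f2$sv, drop = FALSE])
  # the two decision functions are a positive affine map of each other, so
  # the induced ranking is preserved (Pearson 1 up to solver tolerance;
  # Spearman is looser only because near-ties scramble under the KKT eps)
  expect_gt(cor(sc1, sc2), 1 - 1e-6)
  expect_gt(cor(sc1, sc2, method = "spearman"), 0.98)
})

test_that("print, summary and coef methods expose the fitted model", {
  b <- make_separable_fixture(seed = 11)
  fit <- predr(b$associations, weighted_cosine_matrix(b$chem), b$pheno,
               C = 1, seed = 1)
  expect_output(print(fit), "support pairs")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.predr")
  expect_output(print(sm), "training AUC")
  cf <- coef(fit)
  expect_equal(length(cf), nrow(fit$support))
  expect_true(is.numeric(attr(cf, "intercept")))
  expect_true(all(abs(cf) <= fit$C + 1e-8))  # box constraint on duals
})
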