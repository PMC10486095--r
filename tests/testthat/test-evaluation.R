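entropy_bits <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

test_that("AUROC equals the all-pairs estimator, with ties worth one half", {
  expect_equal(auroc(c(0.9, 0.5, 0.5, 0.1), c(1, 1, 0, 0)), 0.875)
  expect_equal(auroc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_warning(a <- auroc(1:4, c(1, 1, 1, 1)), "single class")
  expect_equal(a, 0.5)
  for (rep in 1:20) {
    set.seed(rep)
    n <- sample(5:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), allpairs_auroc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("leave-one-chromosome-out prediction is perfect for separating annotations", {
  genes <- sprintf("G%02d", 1:40)
  md <- data.frame(chrom = rep(c("chr1", "chr2"), each = 20),
                   row.names = genes)
  # annotation 1 = expressed, annotation 2 = unexpressed, in every cell type
  assign <- matrix(rep(rep(c(1L, 2L), 20), 2), 40, 2,
                   dimnames = list(genes, c("CT1", "CT2")))
  expr <- matrix(ifelse(assign == 1L, 50, 0.01), 40, 2,
                 dimnames = dimnames(assign))
  asn <- make_assignment(assign, M = 2)
  res <- expression_prediction_eval(asn, expr,
                                    gene_chroms = setNames(md$chrom, genes))
  expect_equal(res$auroc, c(1, 1))
  expect_equal(res$pearson_r, c(1, 1), tolerance = 1e-12)
  expect_equal(res$mse, c(0, 0), tolerance = 1e-12)
})

test_that("constant predictions give AUROC 0.5 and a zero correlation with warning", {
  genes <- sprintf("G%02d", 1:20)
  assign <- matrix(1L, 20, 1, dimnames = list(genes, "CT1"))
  # the two chromosomes carry identical expression multisets, so the single
  # annotation's training median -- hence the prediction -- is the same
  # constant in both folds
  v <- c(2, 3, 4, 5, 6, 0.1, 0.2, 0.3, 0.4, 0.5)
  expr <- matrix(c(v, v), 20, 1, dimnames = list(genes, "CT1"))
  chroms <- setNames(rep(c("chr1", "chr2"), each = 10), genes)
  expect_warning(
    res <- expression_prediction_eval(make_assignment(assign, M = 1),
                                      expr, gene_chroms = chroms),
    "Pearson r undefined")
  expect_equal(res$auroc, 0.5)
  expect_equal(res$pearson_r, 0)
})

test_that("a fold whose annotation lacks training genes falls back to the global median", {
  genes <- sprintf("G%02d", 1:12)
  # annotation 2 exists only on chr1: when chr1 is held out, no training
  # genes carry it
  assign <- matrix(c(rep(2L, 6), rep(1L, 6)), 12, 1,
                   dimnames = list(genes, "CT1"))
  expr <- matrix(2^seq_len(12), 12, 1, dimnames = list(genes, "CT1"))
  chroms <- setNames(rep(c("chr1", "chr2"), each = 6), genes)
  expect_message(
    expression_prediction_eval(make_assignment(assign, M = 2), expr,
                               gene_chroms = chroms),
    "global median")
})

test_that("the one-sided binomial comparison has exact tails", {
  expect_equal(compare_methods_binomial(rep(1, 127), rep(0, 127)), 2^-127)
  expect_equal(compare_methods_binomial(rep(0, 10), rep(1, 10)), 1.0)
  expect_gt(compare_methods_binomial(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0.5)
  # ties count for the null
  expect_equal(compare_methods_binomial(c(1, 1), c(1, 1)), 1.0)
  expect_error(compare_methods_binomial(numeric(0), numeric(0)), "empty")
})

test_that("assignment/length mutual information matches hand-computed channels", {
  genes <- sprintf("G%02d", 1:40)
  # two equiprobable length bins mapped bijectively onto two annotations
  lengths <- setNames(rep(c(1500, 90000), 20), genes)
  assign <- matrix(rep(c(1L, 2L), 20), 40, 1, dimnames = list(genes, "CT1"))
  mi <- mutual_information_with_length(make_assignment(assign, 2), lengths)
  expect_equal(unname(mi), 1.0, tolerance = 1e-12)
  # four equiprobable bins mapped 2:1 onto two annotations -> still 1 bit
  lengths4 <- setNames(rep(c(1500, 5000, 90000, 400000), 10), genes)
  assign4 <- matrix(rep(c(1L, 1L, 2L, 2L), 10), 40, 1,
                    dimnames = list(genes, "CT1"))
  mi4 <- mutual_information_with_length(make_assignment(assign4, 2), lengths4)
  expect_equal(unname(mi4), 1.0, tolerance = 1e-12)
  # independence -> 0 bits (each length bin sees both labels equally often)
  assign0 <- matrix(rep(c(1L, 1L, 2L, 2L), 10), 40, 1,
                    dimnames = list(genes, "CT1"))
  mi0 <- mutual_information_with_length(make_assignment(assign0, 2), lengths)
  expect_equal(unname(mi0), 0, tolerance = 1e-12)
})

test_that("mutual information is relabeling-invariant and bounded by marginal entropies", {
  set.seed(5)
  genes <- sprintf("G%03d", 1:200)
  lengths <- setNames(10^runif(200, 3.2, 5.8), genes)
  assign <- matrix(sample.int(4, 200, replace = TRUE), 200, 1,
                   dimnames = list(genes, "CT1"))
  mi <- unname(mutual_information_with_length(make_assignment(assign, 4),
                                              lengths))
  relab <- matrix(c(3L, 1L, 4L, 2L)[assign], 200, 1,
                  dimnames = list(genes, "CT1"))
  mi_r <- unname(mutual_information_with_length(make_assignment(relab, 4),
                                                lengths))
  expect_equal(mi, mi_r, tolerance = 1e-12)
  expect_gte(mi, 0)
  expect_lte(mi, entropy_bits(assign[, 1]) + 1e-12)
  expect_lte(mi, entropy_bits(floor(log10(lengths) / 0.05)) + 1e-12)
})

test_that("confusion and contingency are row-stochastic with the specificity identity", {
  set.seed(6)
  genes <- sprintf("G%03d", 1:300)
  base <- sample.int(3, 300, replace = TRUE)
  jitter <- function(x, rate) ifelse(runif(300) < rate,
                                     sample.int(3, 300, replace = TRUE), x)
  assign <- cbind(CT1 = base, CT2 = jitter(base, 0.1),
                  CT3 = jitter(base, 0.5), CT4 = jitter(base, 0.5))
  rownames(assign) <- genes
  asn <- make_assignment(assign, 3)
  reps <- data.frame(a = "CT1", b = "CT2")
  cc <- confusion_and_contingency(asn, reps)
  expect_equal(unname(rowSums(cc$confusion)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(rowSums(cc$contingency)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(cc$specificity),
               unname(1 - diag(cc$contingency) / diag(cc$confusion)),
               tolerance = 1e-12)
  expect_gt(cc$replicate_concordance, cc$nonreplicate_concordance)
  # published-style numbers obey the same identity
  expect_equal(1 - 0.571 / 0.811, 0.2959, tolerance = 1e-3)
})

test_that("identical replicates give an identity confusion matrix and 100% reproducibility", {
  genes <- sprintf("G%03d", 1:100)
  set.seed(7)
  lab <- sample.int(3, 100, replace = TRUE)
  assign <- cbind(CT1 = lab, CT2 = lab, CT3 = sample.int(3, 100, TRUE))
  rownames(assign) <- genes
  asn <- make_assignment(assign, 3)
  cc <- confusion_and_contingency(asn, data.frame(a = "CT1", b = "CT2"))
  expect_equal(unname(cc$confusion), diag(3), tolerance = 1e-12)
  expect_equal(cc$replicate_concordance, 1.0)
  fits <- list(list(model = random_model(3, 2, 4, seed = 8), assignment = asn))
  hm <- hyperparameter_metrics(fits, data.frame(a = "CT1", b = "CT2"))
  expect_equal(hm$reproducibility, 100)
})

test_that("replicate pair validation rejects unknown members and self-pairs", {
  assign <- matrix(1L, 4, 2, dimnames = list(paste0("G", 1:4), c("A", "B")))
  asn <- make_assignment(assign, 1)
  expect_error(confusion_and_contingency(asn, data.frame(a = "A", b = "Z")),
               "not in assignment")
  expect_error(confusion_and_contingency(asn, data.frame(a = "A", b = "A")),
               "self-pairs")
})

test_that("co-assignment enrichment vanishes for independent assignments", {
  set.seed(9)
  pri <- c(0.4, 0.3, 0.2, 0.1)
  genes <- sprintf("G%05d", 1:20000)
  assign <- matrix(sample.int(4, 20000 * 5, replace = TRUE, prob = pri),
                   20000, 5, dimnames = list(genes, paste0("CT", 1:5)))
  asn <- make_assignment(assign, 4)
  enr <- coassignment_enrichment(asn)
  expect_true(all(abs(enr) < 0.1))
  expect_equal(enr, t(enr), tolerance = 1e-12)
})

test_that("degenerate single-component co-assignment is exactly zero", {
  assign <- matrix(1L, 50, 3,
                   dimnames = list(sprintf("G%02d", 1:50), paste0("CT", 1:3)))
  enr <- coassignment_enrichment(make_assignment(assign, 1))
  expect_equal(unname(enr[1, 1]), 0)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  genes <- sprintf("G%02d", 1:10)
  assign <- matrix(c(rep(1L, 4), rep(2L, 6)), 10, 1,
                   dimnames = list(genes, "CT1"))
  asn <- make_assignment(assign, 2)
  res <- gene_set_enrichment(asn, gene_set = genes[1:5])
  p14 <- res$p_value[res$component == 1]
  expect_equal(p14, 5 / 210, tolerance = 1e-12)
  expect_equal(p14, enumerated_hyper_p(4, 5, 10, 4), tolerance = 1e-12)
  # random small instances against enumeration
  for (rep in 1:15) {
    set.seed(rep + 40)
    uni <- sample(8:20, 1)
    g <- sprintf("g%02d", seq_len(uni))
    lab <- sample.int(3, uni, replace = TRUE)
    a2 <- make_assignment(matrix(lab, uni, 1, dimnames = list(g, "CT1")), 3)
    set_genes <- sample(g, sample(2:uni, 1))
    r <- gene_set_enrichment(a2, set_genes)
    for (m in 1:3) {
      comp_n <- sum(lab == m)
      overlap <- sum(g[lab == m] %in% set_genes)
      expect_equal(r$p_value[r$component == m],
                   enumerated_hyper_p(overlap, length(set_genes), uni, comp_n),
                   tolerance = 1e-10)
    }
  }
})

test_that("fold enrichment is the mean set proportion over the prior, saturating at 1", {
  genes <- sprintf("G%02d", 1:12)
  lab <- c(rep(1L, 3), rep(2L, 9))        # prior(1) = 0.25
  assign <- matrix(lab, 12, 1, dimnames = list(genes, "CT1"))
  asn <- make_assignment(assign, 2)
  res <- gene_set_enrichment(asn, gene_set = c(genes[1:3], genes[4]))
  smry <- attr(res, "summary")
  expect_equal(smry$fold[1], 0.75 / 0.25, tolerance = 1e-12)   # = 3
  full <- gene_set_enrichment(asn, gene_set = genes)
  fs <- attr(full, "summary")
  expect_equal(fs$fold, c(1, 1), tolerance = 1e-12)
  expect_equal(full$p_value, rep(1, 2), tolerance = 1e-12)
  expect_error(gene_set_enrichment(asn, c("NOPE")), "subset of the universe")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_p(c(0.001, 0.2), 100), c(0.1, 1))
})

test_that("true annotation splits beat size-matched random splits on planted sets", {
  set.seed(11)
  genes <- sprintf("G%03d", 1:300)
  lab <- setNames(rep(1:3, each = 100), genes)
  gene_sets <- list(s1 = genes[1:60], s2 = genes[101:160], s3 = genes[201:260])
  res <- random_split_comparison(lab, tested_genes = genes,
                                 gene_sets = gene_sets,
                                 annotation_order = c(1, 2, 3),
                                 n_rand = 20, seed = 3L)
  expect_gt(res$n_enriched_true, res$mean_n_enriched_random)
  expect_equal(res$n_enriched_true, 3L)
  # deterministic given the seed
  res2 <- random_split_comparison(lab, genes, gene_sets, c(1, 2, 3),
                                  n_rand = 20, seed = 3L)
  expect_identical(res$mean_n_enriched_random, res2$mean_n_enriched_random)
  # no structure, tiny sets: nothing passes either way
  empty <- random_split_comparison(lab, genes,
                                   list(s = genes[c(1, 101, 201)]),
                                   c(1, 2, 3), n_rand = 5, seed = 4L)
  expect_equal(empty$n_enriched_true, 0L)
  expect_equal(empty$mean_n_enriched_random, 0)
})

test_that("the 75% coverage rule keeps the minimal expression-ordered annotation subset", {
  genes <- sprintf("G%03d", 1:100)
  lab <- setNames(c(rep(1L, 60), rep(2L, 20), rep(3L, 20)), genes)
  res <- random_split_comparison(lab, genes, list(s = genes[1:10]),
                                 annotation_order = c(1, 2, 3), n_rand = 2,
                                 seed = 1L)
  expect_identical(res$annotations, c(1, 2))   # 60% then 80% >= 75%
})

test_that("the variance permutation test handles degenerate and separated inputs", {
  flat <- matrix(1.5, 3, 4)
  res <- variance_permutation_test(flat, n_perm = 50, seed = 1L)
  expect_equal(res$p_value, 1.0)
  sep <- rbind(c(1, 1.01, 1.02, 1.03), c(5, 5.01, 5.02, 5.03),
               c(9, 9.01, 9.02, 9.03))
  res2 <- variance_permutation_test(sep, n_perm = 200, seed = 2L)
  expect_equal(res2$p_value, 0)
  expect_match(res2$label, "^< ")
})

test_that("permutation p-values are calibrated under exchangeable input", {
  set.seed(12)
  ps <- vapply(1:200, function(i) {
    x <- matrix(rnorm(12), 3, 4)
    variance_permutation_test(x, n_perm = 99, seed = i)$p_value
  }, 0)
  expect_gt(mean(ps), 0.38)
  expect_lt(mean(ps), 0.62)
  expect_lt(abs(mean(ps <= 0.25) - 0.25), 0.12)
  expect_lt(abs(mean(ps <= 0.75) - 0.75), 0.12)
})

test_that("expression change matrices are zero for constant expression and antisymmetric", {
  genes <- sprintf("G%02d", 1:30)
  set.seed(13)
  assign <- matrix(sample.int(2, 60, replace = TRUE), 30, 2,
                   dimnames = list(genes, c("CT1", "CT2")))
  asn <- make_assignment(assign, 2)
  const <- matrix(5, 30, 2, dimnames = dimnames(assign))
  m0 <- expression_change_matrix(asn, const)
  expect_true(all(abs(m0) < 1e-12, na.rm = TRUE))
  expr <- matrix(rlnorm(60, 1, 1), 30, 2, dimnames = dimnames(assign))
  m <- expression_change_matrix(asn, expr)
  # simultaneous swap of cell types and bin indices flips the sign; with
  # both ordered pairs accumulated this is transpose-antisymmetry
  expect_equal(m, -t(m), tolerance = 1e-12)
  # hand-computed 2x2 case: two genes, two cell types
  a2 <- matrix(c(1L, 2L, 2L, 1L), 2, 2,
               dimnames = list(c("g1", "g2"), c("CT1", "CT2")))
  e2 <- matrix(c(0.9, 3.9, 7.9, 1.9), 2, 2, dimnames = dimnames(a2))
  mm <- expression_change_matrix(make_assignment(a2, 2), e2)
  # bin (1,2) collects g1's CT1->CT2 ratio (log2 8) and g2's CT2->CT1 ratio
  # (log2 2); bin (2,1) the mirrored ratios
  expect_equal(mm[1, 2], mean(c(log2(8), log2(2))), tolerance = 1e-12)
  expect_equal(mm[2, 1], mean(c(log2(1 / 8), log2(2 / 4))), tolerance = 1e-12)
})

test_that("pLI proportions, length normalization, and curves follow their definitions", {
  genes <- sprintf("G%02d", 1:3)
  assign <- matrix(1L, 3, 1, dimnames = list(genes, "CT1"))
  pli <- setNames(c(0.95, 0.2, 0.99), genes)
  lens <- setNames(c(5000, 6000, 7000), genes)
  res <- pli_analysis(make_assignment(assign, 1), pli, lens)
  expect_equal(res$proportion_high[1], 2 / 3, tolerance = 1e-12)

  # hand-built two-bin case: proportions (0.5, 0.25), density (0.4, 0.6)
  g2 <- sprintf("H%02d", 1:20)
  lens2 <- setNames(c(rep(1500, 8), rep(10^3.5, 12)), g2)  # bins 1 and 3
  pli2 <- setNames(c(rep(0.95, 4), rep(0.1, 4),            # bin 1: 4/8 high
                     rep(0.95, 3), rep(0.1, 9)), g2)       # bin 3: 3/12 high
  a2 <- matrix(1L, 20, 1, dimnames = list(g2, "CT1"))
  res2 <- pli_analysis(make_assignment(a2, 1), pli2, lens2)
  expect_equal(res2$length_normalized_proportion[1],
               0.5 * 0.4 + 0.25 * 0.6, tolerance = 1e-12)
  # uniform per-bin proportions are left unchanged by the normalization
  pli3 <- setNames(c(rep(0.95, 4), rep(0.1, 4), rep(0.95, 6), rep(0.1, 6)), g2)
  res3 <- pli_analysis(make_assignment(a2, 1), pli3, lens2)
  expect_equal(res3$length_normalized_proportion[1], 0.5, tolerance = 1e-12)

  # expression curve and Spearman correlation on a monotone relationship
  expr <- matrix(10^seq(-1, 2, length.out = 20) - 0.1 + 1e-6, 20, 1,
                 dimnames = list(g2, "CT1"))
  pli_mono <- setNames(seq(0, 1, length.out = 20), g2)
  res4 <- pli_analysis(make_assignment(a2, 1), pli_mono, lens2,
                       expression = expr)
  expect_equal(unname(res4$spearman_r["CT1"]), 1, tolerance = 1e-12)
  curve <- res4$expression_curve
  filled <- !is.na(curve$mean_pli)
  expect_true(all(diff(curve$mean_pli[filled]) >= 0))
  expect_equal(nrow(curve), 30L)
})

test_that("closest-state distances take the within-component minimum", {
  model <- random_model(2, 2, 2, seed = 14)
  model$emit[1, 1, ] <- c(1, 0)
  model$emit[1, 2, ] <- c(0, 1)
  d <- closest_state_distance(model)
  expect_equal(d$per_component[1], 2.0)
  m3 <- random_model(1, 3, 4, seed = 15)
  m3$emit[1, 1, ] <- c(0.1, 0.1, 0.1, 0.1)
  m3$emit[1, 2, ] <- c(0.1, 0.1, 0.1, 0.4)   # 0.3 from state 1
  m3$emit[1, 3, ] <- c(0.4, 0.4, 0.2, 0.2)   # 0.9 / 0.8 from the others
  expect_equal(closest_state_distance(m3)$per_component[1], 0.3,
               tolerance = 1e-12)
  expect_true(is.na(closest_state_distance(random_model(2, 1, 3, 16))$mean))
})

test_that("assignment distances are a semimetric with the indicator extremes", {
  assign <- rbind(G1 = c(1L, 2L, 1L), G2 = c(1L, 2L, 1L), G3 = c(2L, 1L, 2L))
  colnames(assign) <- paste0("CT", 1:3)
  d <- as.matrix(assignment_distance_matrix(make_assignment(assign, 2),
                                            n_sample = 10, seed = 1L))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d["G1", "G2"], 0)
  expect_equal(d["G1", "G3"], 1)
  expect_equal(d, t(d))
  # subsampling is seeded and bounded
  big <- matrix(sample.int(3, 400, replace = TRUE), 100, 4,
                dimnames = list(sprintf("G%03d", 1:100), paste0("CT", 1:4)))
  d1 <- assignment_distance_matrix(make_assignment(big, 3), n_sample = 20,
                                   seed = 9L)
  d2 <- assignment_distance_matrix(make_assignment(big, 3), n_sample = 20,
                                   seed = 9L)
  expect_identical(d1, d2)
  expect_identical(attr(d1, "Size"), 20L)
})
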