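#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney estimator with midrank tie correction: equals the proportion
#' of (positive, negative) pairs ranked correctly, ties counting one half.
#'
#' @param scores numeric prediction scores.
#' @param labels logical or 0/1 vector; `TRUE`/1 marks positives.
#' @return AUROC in `[0, 1]`; 0.5 (with a warning) when either class is
#'   absent.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    warning("AUROC undefined with a single class; returning 0.5")
    return(0.5)
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-chromosome-out expression prediction
#'
#' Per cell type: expression is transformed to `log10(RPKM + pseudocount)`;
#' genes on one chromosome at a time are held out, and each held-out gene's
#' prediction is the median transformed expression of training genes sharing
#' its annotation (falling back to the global training median for an
#' annotation with no training genes).  AUROC is computed for expressed
#' (`RPKM >= threshold`) versus unexpressed genes using the predictions as
#' scores; MSE and Pearson r compare predicted and observed transformed
#' values, pooled over the held-out folds.
#'
#' @param asn a `ghmm_assignment`.
#' @param expression genes x cell types RPKM matrix; rownames are gene ids,
#'   colnames cell types (a subset of the assignment's cell types).
#' @param gene_chroms chromosome per gene, named by gene id; defaults to the
#'   assignment metadata.
#' @param rpkm_threshold expressed/unexpressed cut (default 1).
#' @param pseudocount added before the log transform (default 0.1).
#' @return data.frame with one row per cell type: `auroc`, `mse`,
#'   `pearson_r`.
#' @export
expression_prediction_eval <- function(asn, expression, gene_chroms = NULL,
                                       rpkm_threshold = 1, pseudocount = 0.1) {
  stopifnot(inherits(asn, "ghmm_assignment"))
  if (is.null(gene_chroms)) {
    if (is.null(asn$metadata)) stop("gene chromosomes required")
    gene_chroms <- setNames(asn$metadata$chrom, rownames(asn$metadata))
  }
  genes <- intersect(rownames(asn$assign), rownames(expression))
  chroms <- gene_chroms[genes]
  if (length(unique(chroms)) < 2L)
    stop("leave-one-chromosome-out needs at least 2 chromosomes")
  cts <- intersect(colnames(expression), asn$cell_types)
  out <- data.frame(cell_type = cts, auroc = NA_real_, mse = NA_real_,
                    pearson_r = NA_real_)
  for (k in seq_along(cts)) {
    ct <- cts[k]
    lab <- asn$assign[genes, ct]
    y <- log10(expression[genes, ct] + pseudocount)
    ok <- !is.na(lab) & !is.na(y)
    pred <- rep(NA_real_, length(y))
    for (chrom in unique(chroms)) {
      test <- ok & chroms == chrom
      train <- ok & chroms != chrom
      if (!any(test)) next
      global_med <- median(y[train])
      meds <- tapply(y[train], lab[train], median)
      p <- meds[as.character(lab[test])]
      if (anyNA(p)) {
        message("fold '", chrom, "' in '", ct,
                "': annotation without training genes; using global median")
        p[is.na(p)] <- global_med
      }
      pred[test] <- p
    }
    use <- ok & !is.na(pred)
    expressed <- expression[genes, ct][use] >= rpkm_threshold
    out$auroc[k] <- if (length(unique(expressed)) < 2L) 0.5 else
      auroc(pred[use], expressed)
    out$mse[k] <- mean((pred[use] - y[use])^2)
    r <- suppressWarnings(cor(pred[use], y[use]))
    if (is.na(r)) {
      warning("Pearson r undefined for '", ct, "' (constant input); reporting 0")
      r <- 0
    }
    out$pearson_r[k] <- r
  }
  out
}

#' One-sided binomial comparison of per-cell-type metrics
#'
#' Counts the cell types in which method A strictly beats method B (ties
#' count for the null) and returns the upper-tail binomial probability of at
#' least that many wins under a fair coin.
#'
#' @param metric_a,metric_b equal-length numeric vectors, one entry per cell
#'   type.
#' @return p-value `P(Binomial(n, 1/2) >= k)` with `k` the number of strict
#'   wins for A.
#' @export
compare_methods_binomial <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b))
  n <- length(metric_a)
  if (n == 0L) stop("empty metric vectors")
  k <- sum(metric_a > metric_b)
  pbinom(k - 1, n, 0.5, lower.tail = FALSE)
}

# Mutual information in bits of two discrete vectors.
mi_bits <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  joint <- table(x[ok], y[ok]) / sum(ok)
  px <- rowSums(joint); py <- colSums(joint)
  ind <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / ind[nz]))
}

#' Mutual information between assignment and gene length
#'
#' Gene lengths are discretized as `log10(length)` in fixed-width bins
#' (default 0.05); the mutual information between the annotation label and
#' the length bin is computed from the empirical joint distribution, in
#' bits, separately per cell type.
#'
#' @param asn a `ghmm_assignment`.
#' @param lengths gene lengths in bp, named by gene id.
#' @param bin_width width of the `log10(length)` bins.
#' @return named numeric vector, one MI value (bits) per cell type.
#' @export
mutual_information_with_length <- function(asn, lengths, bin_width = 0.05) {
  stopifnot(all(lengths > 0))
  genes <- intersect(rownames(asn$assign), names(lengths))
  len_bin <- floor(log10(lengths[genes]) / bin_width)
  vapply(asn$cell_types, function(ct)
    mi_bits(asn$assign[genes, ct], len_bin), 0)
}

# Joint assignment-pair distribution over a list of cell-type pairs,
# accumulating both orientations of each pair.
pair_joint <- function(asn, pairs) {
  M <- asn$M
  joint <- matrix(0, M, M)
  for (p in seq_len(nrow(pairs))) {
    a <- asn$assign[, pairs[[1L]][p]]
    b <- asn$assign[, pairs[[2L]][p]]
    ok <- !is.na(a) & !is.na(b)
    tab <- table(factor(a[ok], levels = seq_len(M)),
                 factor(b[ok], levels = seq_len(M)))
    joint <- joint + tab + t(tab)
  }
  joint
}

# All unordered non-replicate cell-type pairs as a two-column data.frame.
nonreplicate_pairs <- function(cell_types, replicate_pairs) {
  cmb <- t(combn(cell_types, 2L))
  is_rep <- rep(FALSE, nrow(cmb))
  if (!is.null(replicate_pairs) && nrow(replicate_pairs) > 0L) {
    repkey <- c(paste(replicate_pairs[[1L]], replicate_pairs[[2L]]),
                paste(replicate_pairs[[2L]], replicate_pairs[[1L]]))
    is_rep <- paste(cmb[, 1L], cmb[, 2L]) %in% repkey
  }
  data.frame(a = cmb[!is_rep, 1L], b = cmb[!is_rep, 2L])
}

#' Replicate confusion matrix, non-replicate contingency table, and cell
#' type specificity
#'
#' Both matrices hold the conditional probability that a gene assigned to
#' annotation `i` in one cell type is assigned to annotation `j` in the
#' paired cell type, averaged over genes and pairs (both orientations): the
#' confusion matrix over designated replicate pairs, the contingency table
#' over all other unordered pairs.  The cell type specificity of annotation
#' `i` is `1 - contingency[i,i] / confusion[i,i]`.
#'
#' @param asn a `ghmm_assignment`.
#' @param replicate_pairs data.frame with two columns of cell-type labels.
#'   Which epigenomes count as replicates is a study-design choice supplied
#'   by the caller; an example list of seven same-tissue Roadmap epigenome
#'   pairs ships as
#'   `system.file("extdata", "replicate_pairs_example.tsv", package = "geneHMM")`
#'   for documentation.
#' @return list with `confusion`, `contingency` (row-stochastic `M x M`
#'   matrices), `specificity` (per annotation; `NA` where undefined),
#'   `replicate_concordance` and `nonreplicate_concordance` (diagonal mass of
#'   the corresponding joint distributions), and `expected_concordance`
#'   (under independent assignment from the empirical priors).
#' @export
confusion_and_contingency <- function(asn, replicate_pairs) {
  stopifnot(inherits(asn, "ghmm_assignment"), ncol(replicate_pairs) == 2L)
  missing <- setdiff(unlist(replicate_pairs), asn$cell_types)
  if (length(missing))
    stop("replicate pair member(s) not in assignment: ",
         paste(missing, collapse = ", "))
  if (any(replicate_pairs[[1L]] == replicate_pairs[[2L]]))
    stop("replicate pairs must not be self-pairs")
  joint_rep <- pair_joint(asn, replicate_pairs)
  nr <- nonreplicate_pairs(asn$cell_types, replicate_pairs)
  joint_non <- pair_joint(asn, nr)
  row_norm <- function(j) j / pmax(rowSums(j), .Machine$double.xmin)
  confusion <- row_norm(joint_rep)
  contingency <- row_norm(joint_non)
  spec <- ifelse(diag(confusion) > 0,
                 1 - diag(contingency) / diag(confusion), NA_real_)
  pri <- assignment_priors(asn)
  list(confusion = confusion, contingency = contingency,
       specificity = spec,
       replicate_concordance = sum(diag(joint_rep)) / sum(joint_rep),
       nonreplicate_concordance = sum(diag(joint_non)) / sum(joint_non),
       expected_concordance = sum(pri^2))
}

#' Empirical annotation priors from an assignment matrix
#'
#' Fraction of all (gene, cell type) entries carrying each annotation.
#'
#' @param asn a `ghmm_assignment`.
#' @return numeric vector of length `M` summing to 1.
#' @export
assignment_priors <- function(asn) {
  tab <- tabulate(asn$assign[!is.na(asn$assign)], asn$M)
  tab / sum(tab)
}

#' Co-assignment enrichment across non-replicate cell types
#'
#' The observed frequency with which a gene carries annotation `i` in one
#' cell type and `j` in another (over all unordered non-replicate pairs,
#' both orientations, normalized to sum 1) divided by the expectation under
#' independence (`pi_i * pi_j` from the full assignment matrix), as a
#' symmetric `log2` matrix.  Cells never observed are `NA`.
#'
#' @param asn a `ghmm_assignment`.
#' @param replicate_pairs data.frame of replicate pairs to exclude, or
#'   `NULL`.
#' @return `M x M` matrix of `log2(observed / expected)`, with the observed
#'   count matrix attached as attribute `"counts"`.
#' @export
coassignment_enrichment <- function(asn, replicate_pairs = NULL) {
  nr <- nonreplicate_pairs(asn$cell_types, replicate_pairs)
  if (nrow(nr) == 0L) stop("no non-replicate pairs available")
  joint <- pair_joint(asn, nr)
  obs <- joint / sum(joint)
  pri <- assignment_priors(asn)
  expd <- outer(pri, pri)
  out <- matrix(NA_real_, asn$M, asn$M)
  nz <- obs > 0 & expd > 0
  out[nz] <- log2(obs[nz] / expd[nz])
  attr(out, "counts") <- joint
  out
}

#' Upper-tail hypergeometric enrichment of a gene set in one annotation
#'
#' Per cell type, computes the probability of observing at least the given
#' overlap between the gene set and the genes carrying the annotation, plus
#' a fold enrichment defined as the mean (over cell types) proportion of the
#' set assigned to the annotation divided by the annotation's empirical
#' prior.
#'
#' @param asn a `ghmm_assignment`.
#' @param gene_set character vector of gene ids (must be contained in
#'   `universe`).
#' @param universe gene ids defining the tested universe; defaults to all
#'   assigned genes.
#' @return data.frame with one row per (cell type, annotation):
#'   `p_value`, `overlap`, `set_size`, `component_size`, `universe_size`;
#'   plus a `summary` attribute data.frame per annotation with `fold` and
#'   `median_p`.
#' @export
gene_set_enrichment <- function(asn, gene_set, universe = rownames(asn$assign)) {
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of the universe")
  M <- asn$M
  pri <- assignment_priors(asn)
  rows <- list()
  for (ct in asn$cell_types) {
    lab <- asn$assign[universe, ct]
    ok <- !is.na(lab)
    uni_n <- sum(ok)
    inset <- universe[ok] %in% gene_set
    set_n <- sum(inset)
    for (m in seq_len(M)) {
      comp <- lab[ok] == m
      comp_n <- sum(comp)
      overlap <- sum(comp & inset)
      p <- phyper(overlap - 1, set_n, uni_n - set_n, comp_n,
                  lower.tail = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(cell_type = ct, component = m, p_value = p,
                   overlap = overlap, set_size = set_n,
                   component_size = comp_n, universe_size = uni_n,
                   set_proportion = if (set_n > 0) overlap / set_n else NA_real_)
    }
  }
  tab <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(seq_len(M), function(m) {
    sub <- tab[tab$component == m, , drop = FALSE]
    usable <- sub$component_size > 0
    if (!all(usable))
      message("component ", m, " empty in ",
              sum(!usable), " cell type(s); skipped for the median p")
    data.frame(component = m,
               fold = mean(sub$set_proportion[usable]) / pri[m],
               median_p = median(sub$p_value[usable]))
  }))
  attr(tab, "summary") <- summary
  tab
}

#' Bonferroni adjustment with a caller-supplied test count
#'
#' The correction universe differs between analyses (annotations x sets,
#' optionally x cell types), so the multiplier is explicit.
#'
#' @param p raw p-values.
#' @param n_tests number of tests in the correction universe.
#' @return adjusted p-values, capped at 1.
#' @export
bonferroni_p <- function(p, n_tests) {
  pmin(p * n_tests, 1)
}

#' Compare gene-set enrichment counts for true versus random gene splits
#'
#' Restricted to one cell type: the tested genes (e.g. all genes below an
#' expression threshold) are split by their annotation, keeping the minimal
#' expression-ordered subset of annotations that covers at least the given
#' fraction of tested genes.  The number of gene sets significantly enriched
#' (Bonferroni-adjusted hypergeometric p below `alpha` in any tested group)
#' is compared with the mean count over random splits of the same group
#' sizes.
#'
#' @param labels named integer vector: annotation per gene for one cell type.
#' @param tested_genes gene ids to split (subset of `names(labels)`).
#' @param gene_sets named list of gene-id vectors.
#' @param annotation_order annotation indices ordered by expression (lowest
#'   first for unexpressed analyses, highest first for expressed ones).
#' @param coverage minimal fraction of tested genes the kept annotations
#'   must contain (default 0.75).
#' @param n_rand number of random splits (default 100).
#' @param seed integer seed.
#' @param alpha adjusted significance threshold (default 0.01).
#' @param n_tests Bonferroni multiplier; defaults to
#'   `length(gene_sets) * number of kept annotations`.
#' @return list with `n_enriched_true`, `mean_n_enriched_random`, and the
#'   kept `annotations`.
#' @export
random_split_comparison <- function(labels, tested_genes, gene_sets,
                                    annotation_order, coverage = 0.75,
                                    n_rand = 100, seed = 1L, alpha = 0.01,
                                    n_tests = NULL) {
  tested <- intersect(tested_genes, names(labels)[!is.na(labels)])
  lab <- labels[tested]
  sizes <- table(lab)[as.character(annotation_order)]
  sizes[is.na(sizes)] <- 0
  keep_n <- which(cumsum(sizes) / length(tested) >= coverage)[1L]
  if (is.na(keep_n)) keep_n <- length(annotation_order)
  kept <- annotation_order[seq_len(keep_n)]
  groups_true <- lapply(kept, function(m) tested[lab == m])
  if (is.null(n_tests)) n_tests <- length(gene_sets) * length(kept)
  universe <- names(labels)[!is.na(labels)]

  count_enriched <- function(groups) {
    sig <- 0L
    for (gs in gene_sets) {
      gs <- intersect(gs, universe)
      hit <- FALSE
      for (g in groups) {
        overlap <- sum(g %in% gs)
        p <- phyper(overlap - 1, length(gs), length(universe) - length(gs),
                    length(g), lower.tail = FALSE)
        if (bonferroni_p(p, n_tests) < alpha) { hit <- TRUE; break }
      }
      sig <- sig + hit
    }
    sig
  }

  n_true <- count_enriched(groups_true)
  group_sizes <- lengths(groups_true)
  grp_idx <- rep(seq_along(group_sizes), group_sizes)
  rand_counts <- with_seed(seed, vapply(seq_len(n_rand), function(i) {
    perm <- sample(tested)
    # groups of the same sizes as the kept annotations; any remainder of the
    # tested genes (annotations beyond the coverage cut) is left out, as in
    # the true split
    count_enriched(split(perm[seq_along(grp_idx)], grp_idx))
  }, 0L))
  list(n_enriched_true = n_true,
       mean_n_enriched_random = mean(rand_counts),
       annotations = kept)
}

#' Permutation test for within-annotation variance of median expression
#'
#' The statistic is the mean within-annotation variance of per-cell-type
#' median expression values.  The null shuffles the cell-type medians across
#' annotations while preserving the number of values per annotation; the
#' p-value is the fraction of permutations whose statistic does not exceed
#' the observed one.
#'
#' @param median_expr annotations x cell types matrix of median
#'   `log10(RPKM + 0.1)` values.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list with `p_value`, a display `label` (`"< 1/n_perm"` when no
#'   permutation was as small), `observed`, and `n_perm`.
#' @export
variance_permutation_test <- function(median_expr, n_perm = 10000, seed = 1L) {
  median_expr <- as.matrix(median_expr)
  if (anyNA(median_expr)) stop("median_expr must be complete")
  obs <- mean(apply(median_expr, 1L, var))
  vals <- as.vector(median_expr)
  nr <- nrow(median_expr); nc <- ncol(median_expr)
  smaller <- with_seed(seed, {
    count <- 0L
    for (i in seq_len(n_perm)) {
      perm <- matrix(sample(vals), nr, nc)
      if (mean(apply(perm, 1L, var)) <= obs) count <- count + 1L
    }
    count
  })
  p <- smaller / n_perm
  list(p_value = p,
       label = if (smaller == 0L) paste0("< ", format(1 / n_perm)) else
         format(p),
       observed = obs, n_perm = n_perm)
}

#' Mean expression log-ratio by annotation pair
#'
#' For every ordered pair of distinct cell types and every gene, the log2
#' ratio of pseudocounted expression between the two cell types is
#' accumulated into the bin indexed by the gene's annotations in the two
#' cell types; the per-bin mean is returned.
#'
#' @param asn a `ghmm_assignment`.
#' @param expression genes x cell types RPKM matrix.
#' @param pairs optional data.frame of ordered cell-type pairs; defaults to
#'   all ordered pairs of distinct cell types with expression.
#' @param pseudocount added before the ratio (default 0.1).
#' @return `M x M` matrix of mean log2 ratios (`NA` for empty bins).
#' @export
expression_change_matrix <- function(asn, expression, pairs = NULL,
                                     pseudocount = 0.1) {
  cts <- intersect(colnames(expression), asn$cell_types)
  if (is.null(pairs)) {
    grid <- expand.grid(a = cts, b = cts, stringsAsFactors = FALSE)
    pairs <- grid[grid$a != grid$b, , drop = FALSE]
  }
  genes <- intersect(rownames(asn$assign), rownames(expression))
  M <- asn$M
  num <- matrix(0, M, M); cnt <- matrix(0, M, M)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[[1L]][p]; j <- pairs[[2L]][p]
    ai <- asn$assign[genes, i]; aj <- asn$assign[genes, j]
    ratio <- log2((expression[genes, j] + pseudocount) /
                    (expression[genes, i] + pseudocount))
    ok <- !is.na(ai) & !is.na(aj) & is.finite(ratio)
    for (k in which(ok)) {
      num[ai[k], aj[k]] <- num[ai[k], aj[k]] + ratio[k]
      cnt[ai[k], aj[k]] <- cnt[ai[k], aj[k]] + 1
    }
  }
  out <- num / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Relationship between annotations and loss-of-function constraint
#'
#' Computes, per annotation: the raw proportion of assigned (gene, cell
#' type) entries with high pLI; a gene-length-normalized proportion
#' (high-pLI proportion per `log10(length)` bin, weighted by the all-gene
#' length density over 15 bins of width 0.2 spanning 1 kb to 1 Mb, genes
#' outside discarded); and, across expression, per-bin high-pLI proportion
#' and mean pLI over 30 bins of `log10(RPKM + 0.1)` in `[-1, 2]`.  Also
#' returns the per-cell-type Spearman correlation between expression and
#' pLI.
#'
#' @param asn a `ghmm_assignment`.
#' @param pli pLI scores in `[0, 1]`, named by gene id.
#' @param lengths gene lengths in bp, named by gene id.
#' @param expression optional genes x cell types RPKM matrix (needed for the
#'   expression curve and Spearman correlations).
#' @param high_threshold pLI cut for "high" (default 0.9).
#' @return list with `proportion_high` (per annotation),
#'   `length_normalized_proportion` (per annotation), `length_bins`,
#'   `expression_curve` (data.frame of bin centers, high-pLI proportion,
#'   mean pLI), and `spearman_r` (per cell type).
#' @export
pli_analysis <- function(asn, pli, lengths, expression = NULL,
                         high_threshold = 0.9) {
  stopifnot(all(pli >= 0 & pli <= 1, na.rm = TRUE))
  genes <- intersect(rownames(asn$assign), names(pli))
  high <- pli[genes] >= high_threshold
  M <- asn$M

  entry_prop <- function(weights = NULL) {
    num <- numeric(M); den <- numeric(M)
    for (ct in asn$cell_types) {
      lab <- asn$assign[genes, ct]
      ok <- !is.na(lab)
      num <- num + tabulate(lab[ok & high], M)
      den <- den + tabulate(lab[ok], M)
    }
    list(num = num, den = den, prop = num / pmax(den, 1))
  }
  raw <- entry_prop()
  proportion_high <- ifelse(raw$den > 0, raw$prop, NA_real_)

  # length-normalized proportion
  breaks <- seq(3, 6, by = 0.2)
  llen <- log10(lengths[genes])
  inrange <- !is.na(llen) & llen >= 3 & llen <= 6
  len_bin <- pmin(findInterval(llen, breaks, rightmost.closed = TRUE), 15L)
  ref <- tabulate(len_bin[inrange], 15L)
  ref_density <- ref / sum(ref)
  norm_prop <- rep(NA_real_, M)
  prop_bin <- matrix(NA_real_, M, 15L)
  for (m in seq_len(M)) {
    numb <- numeric(15L); denb <- numeric(15L)
    for (ct in asn$cell_types) {
      lab <- asn$assign[genes, ct]
      sel <- !is.na(lab) & lab == m & inrange
      numb <- numb + tabulate(len_bin[sel & high], 15L)
      denb <- denb + tabulate(len_bin[sel], 15L)
    }
    nonempty <- denb > 0
    prop_bin[m, nonempty] <- numb[nonempty] / denb[nonempty]
    norm_prop[m] <- sum(prop_bin[m, nonempty] * ref_density[nonempty])
  }

  expression_curve <- NULL
  spearman_r <- NULL
  if (!is.null(expression)) {
    eg <- intersect(genes, rownames(expression))
    ebreaks <- seq(-1, 2, length.out = 31L)
    centers <- (head(ebreaks, -1L) + tail(ebreaks, -1L)) / 2
    le <- log10(as.vector(expression[eg, , drop = FALSE]) + 0.1)
    pl <- rep(pli[eg], times = ncol(expression))
    bin <- findInterval(le, ebreaks, rightmost.closed = TRUE)
    ok <- bin >= 1L & bin <= 30L & !is.na(pl)
    prop <- tapply(pl[ok] >= high_threshold, bin[ok], mean)
    mean_pli <- tapply(pl[ok], bin[ok], mean)
    expression_curve <- data.frame(center = centers,
                                   proportion_high = NA_real_,
                                   mean_pli = NA_real_)
    expression_curve$proportion_high[as.integer(names(prop))] <- prop
    expression_curve$mean_pli[as.integer(names(mean_pli))] <- mean_pli
    spearman_r <- vapply(colnames(expression), function(ct)
      suppressWarnings(cor(expression[eg, ct], pli[eg], method = "spearman",
                           use = "complete.obs")), 0)
  }
  list(proportion_high = proportion_high,
       length_normalized_proportion = norm_prop,
       length_bin_proportions = prop_bin,
       length_reference_density = ref_density,
       expression_curve = expression_curve,
       spearman_r = spearman_r)
}

#' Smallest within-component emission distance between states
#'
#' Per component, the minimum over state pairs of the Manhattan (L1)
#' distance between emission vectors; the mean over components measures how
#' redundant the states of a model are.
#'
#' @param model a `ghmm_model`.
#' @return list with `per_component` minima and their `mean`; both `NA` when
#'   `S = 1`.
#' @export
closest_state_distance <- function(model) {
  if (model$S < 2L)
    return(list(per_component = rep(NA_real_, model$M), mean = NA_real_))
  per <- vapply(seq_len(model$M), function(m) {
    d <- Inf
    for (s in seq_len(model$S - 1L)) for (s2 in (s + 1L):model$S)
      d <- min(d, sum(abs(model$emit[m, s, ] - model$emit[m, s2, ])))
    d
  }, 0)
  list(per_component = per, mean = mean(per))
}

#' Reproducibility and state-redundancy metrics over a hyperparameter grid
#'
#' For each fitted (M, S) configuration: reproducibility is the replicate
#' concordance (confusion-matrix diagonal mass), and redundancy is the mean
#' closest-state Manhattan distance of the emission parameters (undefined
#' for `S = 1`).
#'
#' @param fits list of entries, each with elements `model` (a `ghmm_model`)
#'   and `assignment` (a `ghmm_assignment`).
#' @param replicate_pairs data.frame of replicate cell-type pairs.
#' @return data.frame with `M`, `S`, `reproducibility` (percent), and
#'   `mean_closest_state_distance`.
#' @export
hyperparameter_metrics <- function(fits, replicate_pairs) {
  do.call(rbind, lapply(fits, function(f) {
    cc <- confusion_and_contingency(f$assignment, replicate_pairs)
    data.frame(M = f$model$M, S = f$model$S,
               reproducibility = 100 * cc$replicate_concordance,
               mean_closest_state_distance = closest_state_distance(f$model)$mean)
  }))
}

#' Pairwise gene distance from assignment profiles
#'
#' Samples genes and computes `d(i, j) = 1 - mean_c I(assignment_i =
#' assignment_j)` across cell types -- 0 for genes always co-assigned, 1 for
#' fully discordant pairs.  The result feeds average-linkage (UPGMA)
#' hierarchical clustering for visualization.
#'
#' @param asn a `ghmm_assignment`.
#' @param n_sample number of genes to sample (default 2000; all genes when
#'   fewer).
#' @param seed integer seed for the sampling.
#' @return an object of class `dist` over the sampled genes.
#' @export
assignment_distance_matrix <- function(asn, n_sample = 2000, seed = 1L) {
  n_genes <- nrow(asn$assign)
  if (n_genes < 2L) stop("need at least 2 genes")
  sel <- if (n_genes > n_sample)
    sort(with_seed(seed, sample.int(n_genes, n_sample)))
  else seq_len(n_genes)
  a <- asn$assign[sel, , drop = FALSE]
  n <- length(sel)
  d <- matrix(0, n, n, dimnames = list(rownames(a), rownames(a)))
  for (i in seq_len(n - 1L)) {
    ai <- a[i, ]
    for (j in (i + 1L):n) {
      eq <- ai == a[j, ]
      d[i, j] <- d[j, i] <- 1 - mean(eq, na.rm = TRUE)
    }
  }
  as.dist(d)
}
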