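#' Sample a well-separated ground-truth mixture model
#'
#' Generates a mixture model whose components have distinct mark signatures:
#' each state of a component emits a random subset of marks at high
#' probability and the rest at low probability, transition rows are sticky
#' (high self-transition) with the standard 0.05 exit mass, and component
#' priors are moderately even.  Emission blocks are rejection-sampled until
#' every pair of components differs by at least `separation` in the L1
#' distance between mean emission vectors.
#'
#' @param M,S,E component, state, and mark counts.
#' @param separation minimal pairwise L1 distance between component mean
#'   emissions (default 2).
#' @param seed integer seed; the draw is deterministic given it.
#' @param exit_prob gene-end transition mass per state (default 0.05).
#' @param max_tries rejection-sampling budget before erroring.
#' @return a `ghmm_model`.
#' @export
sample_ground_truth_model <- function(M, S, E, separation = 2, seed = 1L,
                                      exit_prob = 0.05, max_tries = 1000L) {
  stopifnot(is_count(M), is_count(S), is_count(E), separation >= 0)
  with_seed(seed, {
    emit <- NULL
    for (try in seq_len(max_tries)) {
      cand <- array(0, c(M, S, E))
      for (m in seq_len(M)) for (s in seq_len(S)) {
        k <- sample(seq_len(max(1L, E - 1L)), 1L)
        on <- sample.int(E, k)
        cand[m, s, ] <- runif(E, 0.02, 0.10)
        cand[m, s, on] <- runif(k, 0.75, 0.95)
      }
      means <- apply(cand, c(1L, 3L), mean)
      dmin <- Inf
      if (M > 1L)
        for (i in seq_len(M - 1L)) for (j in (i + 1L):M)
          dmin <- min(dmin, sum(abs(means[i, ] - means[j, ])))
      if (M == 1L || dmin >= separation) { emit <- cand; break }
    }
    if (is.null(emit))
      stop("could not reach component separation ", separation, " after ",
           max_tries, " draws; increase E or lower the separation")
    pri <- rgamma(M, 5); pri <- pri / sum(pri)
    tau <- matrix(0, M, S)
    for (m in seq_len(M)) tau[m, ] <- rdirichlet1(S) * pri[m]
    trans <- array(0, c(M, S, S))
    for (m in seq_len(M)) for (s in seq_len(S)) {
      row <- rdirichlet1(S) * 0.25
      row[s] <- row[s] + 0.75
      trans[m, s, ] <- row / sum(row) * (1 - exit_prob)
    }
    ghmm_model(tau, trans, emit, array(exit_prob, c(M, S)) |> matrix(M, S),
               paste0("mark", seq_len(E)))
  })
}

#' Simulate a multi-cell-type binarized dataset from a known model
#'
#' Lays out genes on synthetic chromosomes (log-normal lengths, clamped;
#' spaced so extended regions never overlap), draws one true component per
#' (gene, cell type) -- the second member of each replicate pair copies its
#' partner's label with probability `replicate_concordance` -- simulates the
#' component HMM over the gene's extended bins, emits marks from the
#' Bernoulli parameters, flips every bin/mark observation independently with
#' probability `flip_noise`, and assembles dummy-separated concatenated
#' input files.
#'
#' @param model a `ghmm_model` ground truth; when `NULL` one is drawn with
#'   [sample_ground_truth_model()] (`M = 4`, `S = 2`, `E = 6`,
#'   separation 2).
#' @param n_genes number of genes (default 500).
#' @param n_cell_types number of cell types (default 4), labeled
#'   `CT1..CTn`.
#' @param replicate_pairs data.frame of replicate cell-type pairs; default
#'   one pair `(CT1, CT2)`.
#' @param replicate_concordance probability a replicate copies its
#'   partner's label (default 0.9).
#' @param n_chroms chromosomes to spread genes over (default 4).
#' @param length_meanlog,length_sdlog log-normal gene length parameters
#'   (median 30 kb by default).
#' @param min_length,max_length clamp on gene lengths in bp (2-60 kb).
#' @param flip_noise per-bin symmetric observation error rate (default
#'   0.02); must be below 0.5.
#' @param flank_bp,bin_width extraction conventions (2000 / 200 bp).
#' @param seed integer seed; one seed reproduces the whole fixture.
#' @param out_dir optional directory; when given, binarized files, the
#'   manifest, a gene BED file, and a JSON truth summary are written.
#' @return list with `dataset` (a `ghmm_dataset`), `tracks`, and `truth`
#'   (list: `model`, `assignment` genes x cell types true labels, `genes`
#'   annotation table, `replicate_pairs`, `seed`).
#' @export
simulate_dataset <- function(model = NULL, n_genes = 500, n_cell_types = 4,
                             replicate_pairs = NULL,
                             replicate_concordance = 0.9,
                             n_chroms = 4,
                             length_meanlog = log(30000),
                             length_sdlog = 0.6,
                             min_length = 2000, max_length = 60000,
                             flip_noise = 0.02,
                             flank_bp = 2000, bin_width = 200,
                             seed = 1L, out_dir = NULL) {
  stopifnot(flip_noise >= 0, flip_noise < 0.5)
  seeds <- split_seed(seed, 4L)
  if (is.null(model))
    model <- sample_ground_truth_model(4L, 2L, 6L, separation = 2,
                                       seed = seeds[1L])
  M <- model$M; S <- model$S; E <- model$E
  cell_types <- paste0("CT", seq_len(n_cell_types))
  if (is.null(replicate_pairs))
    replicate_pairs <- if (n_cell_types >= 2L)
      data.frame(a = "CT1", b = "CT2") else data.frame(a = character(0),
                                                       b = character(0))
  pri <- component_priors(model)

  with_seed(seeds[2L], {
    chroms <- paste0("chr", seq_len(n_chroms))
    lens <- pmin(pmax(round(rlnorm(n_genes, length_meanlog, length_sdlog)),
                      min_length), max_length)
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    gene_chrom <- rep(chroms, length.out = n_genes)
    gap <- 2L * flank_bp + 2L * bin_width
    genes <- vector("list", n_genes)
    cursor <- setNames(rep(flank_bp + bin_width, n_chroms), chroms)
    for (g in seq_len(n_genes)) {
      ch <- gene_chrom[g]
      start <- cursor[[ch]] + sample.int(bin_width, 1L) - 1L
      end <- start + lens[g]
      genes[[g]] <- data.frame(chrom = ch, start = start, end = end,
                               strand = strands[g],
                               gene_id = sprintf("G%04d", g),
                               gene_symbol = sprintf("G%04d", g))
      cursor[[ch]] <- end + gap
    }
    genes <- do.call(rbind, genes)
    chrom_len <- vapply(chroms, function(ch)
      ceiling((max(genes$end[genes$chrom == ch]) + gap) / bin_width) *
        bin_width, 0)

    # true labels: independent draws, then replicate copying
    truth_assign <- matrix(
      sample.int(M, n_genes * n_cell_types, replace = TRUE, prob = pri),
      n_genes, n_cell_types, dimnames = list(genes$gene_id, cell_types))
    for (p in seq_len(nrow(replicate_pairs))) {
      copy <- runif(n_genes) < replicate_concordance
      truth_assign[copy, replicate_pairs$b[p]] <-
        truth_assign[copy, replicate_pairs$a[p]]
    }

    # state-path simulation helpers
    sim_gene <- function(m, n_bins) {
      path <- integer(n_bins)
      p0 <- model$tau[m, ] / sum(model$tau[m, ])
      path[1L] <- sample.int(S, 1L, prob = p0)
      for (t in seq_len(n_bins - 1L)) {
        row <- model$trans[m, path[t], ]
        path[t + 1L] <- sample.int(S, 1L, prob = row / sum(row))
      }
      obs <- matrix(0L, n_bins, E)
      for (t in seq_len(n_bins))
        obs[t, ] <- rbinom(E, 1L, model$emit[m, path[t], ])
      obs
    }

    tracks <- list()
    for (ct in cell_types) {
      for (ch in chroms) {
        mat <- matrix(0L, chrom_len[[ch]] / bin_width, E)
        sub <- which(genes$chrom == ch)
        for (g in sub) {
          ext <- extended_bins(genes$start[g], genes$end[g], flank_bp,
                               bin_width, chrom_len[[ch]])
          obs <- sim_gene(truth_assign[genes$gene_id[g], ct], ext$n_bins)
          if (genes$strand[g] == "-")
            obs <- obs[rev(seq_len(nrow(obs))), , drop = FALSE]
          mat[(ext$ext_start / bin_width + 1L):(ext$ext_end / bin_width), ] <-
            obs
        }
        if (flip_noise > 0) {
          flip <- matrix(rbinom(length(mat), 1L, flip_noise), nrow(mat))
          mat <- abs(mat - flip)
        }
        colnames(mat) <- model$mark_names
        tracks[[length(tracks) + 1L]] <-
          ghmm_track(ct, ch, mat, model$mark_names, bin_width)
      }
    }

    # assemble the concatenated dataset in memory
    files <- list()
    for (tr in tracks) {
      sub <- genes[genes$chrom == tr$chrom, , drop = FALSE]
      obs_list <- lapply(seq_len(nrow(sub)), function(i)
        extract_observation(tr, sub[i, ], flank_bp, bin_width))
      cc <- concat_observations(obs_list)
      files[[length(files) + 1L]] <-
        list(file = paste0(tr$cell_type, "_", tr$chrom, "_binary.txt"),
             cell_type = tr$cell_type, chrom = tr$chrom, mat = cc$mat,
             genes = cc$genes)
    }
    dataset <- ghmm_dataset(files, model$mark_names)

    if (!is.null(out_dir)) {
      write_input_files(genes, tracks, out_dir, flank_bp, bin_width)
      bed <- genes[, c("chrom", "start", "end", "gene_id")]
      bed$score <- 0L
      bed$strand <- genes$strand
      write.table(bed, file.path(out_dir, "genes.bed"), sep = "\t",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
      write_model(model, file.path(out_dir, "truth_model.txt"))
      jsonlite::write_json(
        list(seed = seed, n_genes = n_genes, n_cell_types = n_cell_types,
             M = M, S = S, E = E, flip_noise = flip_noise,
             replicate_pairs = replicate_pairs,
             assignment = as.data.frame(truth_assign)),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    }

    list(dataset = dataset, tracks = tracks,
         truth = list(model = model, assignment = truth_assign,
                      genes = genes, replicate_pairs = replicate_pairs,
                      seed = seed))
  })
}

#' Simulate covariate tables linked to the true components
#'
#' Expression is drawn per (gene, cell type) from a log-normal whose
#' parameters depend on the entry's true component; pLI is drawn per gene
#' from its modal component's high-pLI rate (high genes uniform on
#' `[0.9, 1]`, others concentrated low); each planted gene set over-samples
#' genes whose modal component is its target at the stated odds ratio.
#'
#' @param truth the `truth` element returned by [simulate_dataset()].
#' @param expr_meanlog per-component log-normal location; default evenly
#'   spaced from silent (RPKM ~0.05) to highly expressed (~50).
#' @param expr_sdlog log-normal scale (default 0.8).
#' @param pli_high_rate per-component probability of a high-pLI gene;
#'   default evenly spaced over `[0.05, 0.6]`.
#' @param n_sets planted gene sets (default one per component).
#' @param set_size genes per planted set (default 50).
#' @param odds_ratio over-sampling odds of the target component's genes
#'   (default 8).
#' @param seed integer seed.
#' @return list with `expression` (genes x cell types RPKM matrix), `pli`
#'   (named vector), `gene_sets` (named list of gene ids, names
#'   `set_for_component_<m>`), and the parameters used.
#' @export
simulate_covariates <- function(truth, expr_meanlog = NULL, expr_sdlog = 0.8,
                                pli_high_rate = NULL, n_sets = NULL,
                                set_size = 50, odds_ratio = 8, seed = 1L) {
  M <- truth$model$M
  assign <- truth$assignment
  gene_ids <- rownames(assign)
  if (is.null(expr_meanlog))
    expr_meanlog <- seq(log(0.05), log(50), length.out = M)
  if (is.null(pli_high_rate))
    pli_high_rate <- seq(0.05, 0.6, length.out = M)
  if (is.null(n_sets)) n_sets <- M
  with_seed(seed, {
    expression <- matrix(rlnorm(length(assign),
                                expr_meanlog[assign], expr_sdlog),
                         nrow(assign), ncol(assign),
                         dimnames = dimnames(assign))
    modal <- apply(assign, 1L, function(r)
      which.max(tabulate(r, M)))
    is_high <- rbinom(length(modal), 1L, pli_high_rate[modal]) == 1L
    pli <- ifelse(is_high, runif(length(modal), 0.9, 1),
                  rbeta(length(modal), 0.5, 3) * 0.89)
    names(pli) <- gene_ids
    gene_sets <- list()
    for (k in seq_len(n_sets)) {
      target <- ((k - 1L) %% M) + 1L
      w <- ifelse(modal == target, odds_ratio, 1)
      gene_sets[[paste0("set_for_component_", target)]] <-
        gene_ids[sample.int(length(gene_ids), min(set_size, length(gene_ids)),
                            prob = w)]
    }
    list(expression = expression, pli = pli, gene_sets = gene_sets,
         params = list(expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
                       pli_high_rate = pli_high_rate,
                       odds_ratio = odds_ratio, seed = seed))
  })
}
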