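#' Build TSS-only input data
#'
#' Reduces each gene to the single 200-bp bin overlapping its transcription
#' start site (for negative-strand genes the TSS is the last genomic
#' coordinate of the gene, `end - 1` under half-open coordinates).  The
#' dummy-separated concatenated layout is identical to the full pipeline, so
#' the same training and assignment code applies.
#'
#' @param genes gene annotation table.
#' @param tracks list of `ghmm_track` objects.
#' @param out_dir optional directory; when given, files plus a manifest are
#'   written exactly as by [write_input_files()].
#' @param bin_width bin size in bp.
#' @return a `ghmm_dataset` (in memory), invisibly carrying `n_files`.
#' @export
make_tss_inputs <- function(genes, tracks, out_dir = NULL, bin_width = 200) {
  key <- vapply(tracks, function(t) paste(t$cell_type, t$chrom, sep = "\r"), "")
  names(tracks) <- key
  cell_types <- unique(vapply(tracks, function(t) t$cell_type, ""))
  chroms <- unique(genes$chrom)
  files <- list()
  mark_names <- NULL
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (ct in cell_types) {
    for (chrom in chroms) {
      sub <- genes[genes$chrom == chrom, , drop = FALSE]
      if (nrow(sub) == 0L) next
      tr <- tracks[[paste(ct, chrom, sep = "\r")]]
      if (is.null(tr))
        stop("missing track for cell type '", ct, "', chromosome '", chrom, "'")
      if (is.null(mark_names)) mark_names <- tr$mark_names
      obs_list <- lapply(seq_len(nrow(sub)), function(i) {
        g <- sub[i, ]
        tss <- if (g$strand == "+") g$start else g$end - 1L
        bin <- floor(tss / bin_width) + 1L
        if (bin < 1L || bin > nrow(tr$mat))
          stop("TSS of gene '", g$gene_id, "' outside track")
        list(gene_id = g$gene_id, cell_type = ct, strand = g$strand,
             n_bins = 1L, obs = tr$mat[bin, , drop = FALSE])
      })
      cc <- concat_observations(obs_list)
      fname <- paste0(ct, "_", chrom, "_tss_binary.txt")
      if (!is.null(out_dir)) {
        write_binarized_file(file.path(out_dir, fname), ct, chrom,
                             c(tr$mark_names, "DUMMY"), cc$mat)
        manifest[[length(manifest) + 1L]] <-
          data.frame(file = fname, cell_type = ct, chrom = chrom,
                     gene_id = cc$genes$gene_id,
                     row_start = cc$genes$row_start,
                     row_end = cc$genes$row_end)
      }
      files[[length(files) + 1L]] <-
        list(file = fname, cell_type = ct, chrom = chrom, mat = cc$mat,
             genes = cc$genes)
    }
  }
  if (!is.null(out_dir))
    write.table(do.call(rbind, manifest), file.path(out_dir, "manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- ghmm_dataset(files, mark_names)
  attr(ds, "n_files") <- length(files)
  ds
}

#' Train a baseline clustering model
#'
#' Both baselines are single-state-per-component mixtures (`S = 1`) trained
#' with the standard initialization and EM path -- the gene-average model on
#' the full gene inputs, the TSS model on inputs from [make_tss_inputs()].
#' There is no separate code path: a baseline is exactly the main pipeline
#' at `S = 1` on the corresponding inputs.
#'
#' @param kind `"tss"` or `"gene_average"`.
#' @param dataset a `ghmm_dataset` (TSS inputs for `kind = "tss"`).
#' @param M number of clusters (default 12, matching the main model).
#' @param iterations,subsample_files,seed passed to [em_train()].
#' @return list with the trained `model` and EM `trace`.
#' @export
train_baseline <- function(kind = c("tss", "gene_average"), dataset, M = 12,
                           iterations = 200, subsample_files = 100,
                           seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "tss") {
    lens <- unlist(lapply(dataset$files, function(f)
      f$genes$row_end - f$genes$row_start + 1L))
    if (any(lens != 1L))
      stop("TSS baseline expects single-bin observations; got longer genes")
  }
  init <- initialize_model(dataset, M = M, S = 1L, seed = seed)
  em_train(init, dataset, iterations = iterations,
           subsample_files = subsample_files, seed = seed)
}

#' Hard state and gene usage counts under a trained model
#'
#' For every gene: the gene is hard-assigned to its posterior-maximal
#' component, and each of its bins to the maximum-posterior state within
#' that component.  Counts are aggregated over all files (all cell types and
#' chromosomes).
#'
#' @param model a trained `ghmm_model`.
#' @param dataset a `ghmm_dataset`.
#' @return a `ghmm_usage` (see [component_usage()]).
#' @export
compute_component_usage <- function(model, dataset) {
  hmm <- expand_model(model)
  M <- model$M; S <- model$S
  x <- integer(M); n <- integer(M)
  state_counts <- matrix(0, M, S)
  for (f in dataset$files) {
    fb <- forward_backward(hmm, f$mat, want_gamma = TRUE)
    gp <- gene_component_posteriors(fb$gamma, f$genes, M, S)
    for (i in seq_len(nrow(f$genes))) {
      m <- gp$hard[i]
      rows <- f$genes$row_start[i]:f$genes$row_end[i]
      block <- fb$gamma[rows, ((m - 1L) * S + 1L):(m * S), drop = FALSE]
      st <- max.col(block, ties.method = "first")
      x[m] <- x[m] + length(rows)
      n[m] <- n[m] + 1L
      state_counts[m, ] <- state_counts[m, ] + tabulate(st, S)
    }
  }
  prior <- state_counts / pmax(rowSums(state_counts), 1)
  component_usage(x, n, prior)
}

#' Build the collapsed baseline from a trained multi-state model
#'
#' Computes hard per-bin state and per-gene component assignments under the
#' full model, aggregates usage over all cell types and genes, and collapses
#' each component's states into one prior-weighted state (see
#' [collapse_model()]).  The result is used directly, with no further EM.
#'
#' @param model a trained `ghmm_model` with `S >= 2`.
#' @param dataset a `ghmm_dataset`.
#' @return a `ghmm_model` with `S = 1`.
#' @export
build_collapsed_baseline <- function(model, dataset) {
  usage <- compute_component_usage(model, dataset)
  collapse_model(model, usage)
}
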