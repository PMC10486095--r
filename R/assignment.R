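#' Per-gene mixture component posteriors from a forward-backward result
#'
#' For each gene, the component posterior is the per-position state posterior
#' summed over the component's states.  Because cross-component transitions
#' are disallowed, this vector is constant along the gene; that constancy is
#' asserted (not assumed) before the value at the gene's first position is
#' returned.  Hard assignments take the argmax, with ties broken toward the
#' lowest component index.
#'
#' @param gamma `T x (M*S + 1)` posterior matrix from [forward_backward()].
#' @param genes data.frame with `gene_id`, `row_start`, `row_end` giving each
#'   gene's rows within the concatenated sequence.
#' @param M,S model dimensions.
#' @param tol maximal allowed within-gene posterior variation; larger
#'   deviations indicate a transition-mask defect and raise an error.
#' @return list with `posterior` (genes x M matrix, rows summing to 1) and
#'   `hard` (integer component labels in `1..M`).
#' @export
gene_component_posteriors <- function(gamma, genes, M, S, tol = 1e-9) {
  comp_of <- rep(seq_len(M), each = S)
  ind <- matrix(0, M * S, M)
  ind[cbind(seq_len(M * S), comp_of)] <- 1
  post <- matrix(NA_real_, nrow(genes), M,
                 dimnames = list(genes$gene_id, NULL))
  for (i in seq_len(nrow(genes))) {
    rows <- genes$row_start[i]:genes$row_end[i]
    cp <- gamma[rows, seq_len(M * S), drop = FALSE] %*% ind
    spread <- max(apply(cp, 2L, function(col) diff(range(col))))
    if (spread > tol)
      stop(sprintf(
        "component posterior varies by %.3g along gene '%s' (tolerance %g); cross-component transitions are leaking",
        spread, genes$gene_id[i], tol))
    post[i, ] <- cp[1L, ] / sum(cp[1L, ])
  }
  list(posterior = post, hard = max.col(post, ties.method = "first"))
}

#' Assign every gene in every cell type to a mixture component
#'
#' Runs the forward-backward pass per input file and reads off hard
#' component assignments.  Genes missing from a cell type are reported as
#' `NA`, never dropped.
#'
#' @param model a trained `ghmm_model`.
#' @param dataset a `ghmm_dataset` covering the (cell type, chromosome)
#'   pairs of interest.
#' @param genes optional gene annotation table supplying metadata columns
#'   (`chrom`, `start`, `end`, `gene_symbol`, `strand`) for the output.
#' @param keep_posteriors also return the per-gene component posterior
#'   matrices (one per cell type).
#' @return an object of class `ghmm_assignment`: list with `assign`
#'   (genes x cell types integer matrix of labels in `1..M`), `cell_types`,
#'   `metadata`, `M`, and optionally `posteriors`.
#' @export
assign_all <- function(model, dataset, genes = NULL, keep_posteriors = FALSE) {
  hmm <- expand_model(model)
  gene_ids <- unique(unlist(lapply(dataset$files, function(f) f$genes$gene_id)))
  cell_types <- unique(vapply(dataset$files, function(f) f$cell_type, ""))
  assign <- matrix(NA_integer_, length(gene_ids), length(cell_types),
                   dimnames = list(gene_ids, cell_types))
  posts <- if (keep_posteriors)
    lapply(setNames(cell_types, cell_types), function(ct)
      matrix(NA_real_, length(gene_ids), model$M,
             dimnames = list(gene_ids, NULL)))
  for (f in dataset$files) {
    fb <- forward_backward(hmm, f$mat, want_gamma = TRUE)
    gp <- gene_component_posteriors(fb$gamma, f$genes, model$M, model$S)
    assign[f$genes$gene_id, f$cell_type] <- gp$hard
    if (keep_posteriors)
      posts[[f$cell_type]][f$genes$gene_id, ] <- gp$posterior
  }
  metadata <- NULL
  if (!is.null(genes)) {
    metadata <- genes[match(gene_ids, genes$gene_id),
                      c("chrom", "start", "end", "gene_symbol", "strand")]
    rownames(metadata) <- gene_ids
  }
  structure(list(assign = assign, cell_types = cell_types,
                 metadata = metadata, M = model$M,
                 posteriors = if (keep_posteriors) posts),
            class = "ghmm_assignment")
}

#' Write an assignment table
#'
#' Tab-separated with a header row; the first five columns are the gene's
#' chromosome, start, end, symbol, and strand, followed by one column per
#' cell type holding the integer component label (`NA` for missing entries).
#'
#' @param asn a `ghmm_assignment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_assignment_table <- function(asn, path) {
  stopifnot(inherits(asn, "ghmm_assignment"))
  md <- asn$metadata
  if (is.null(md))
    md <- data.frame(chrom = NA, start = NA, end = NA,
                     gene_symbol = rownames(asn$assign), strand = NA)
  out <- cbind(md, as.data.frame(asn$assign, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read an assignment table written by [write_assignment_table()]
#'
#' @param path file path.
#' @param M component count (inferred from the labels when omitted).
#' @return a `ghmm_assignment`.
#' @export
read_assignment_table <- function(path, M = NULL) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  meta_cols <- c("chrom", "start", "end", "gene_symbol", "strand")
  stopifnot(all(meta_cols %in% names(tab)))
  assign <- as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE])
  storage.mode(assign) <- "integer"
  rownames(assign) <- tab$gene_symbol
  md <- tab[, meta_cols]
  rownames(md) <- tab$gene_symbol
  structure(list(assign = assign, cell_types = colnames(assign),
                 metadata = md,
                 M = M %||% max(assign, na.rm = TRUE),
                 posteriors = NULL),
            class = "ghmm_assignment")
}

#' @export
print.ghmm_assignment <- function(x, ...) {
  cat(sprintf("Gene assignments: %d genes x %d cell types, %d components\n",
              nrow(x$assign), ncol(x$assign), x$M))
  invisible(x)
}
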