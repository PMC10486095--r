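#' Default chromosome allow-list
#'
#' Autosomes 1-22 plus X, in both UCSC (`chr1`) and bare (`1`) spellings.
#' @export
default_chromosomes <- function() {
  base <- c(1:22, "X")
  c(paste0("chr", base), base)
}

#' Load a gene annotation as a table of intervals
#'
#' Reads either a 6-column BED file or a GTF/GFF file (gene-level records;
#' parsed with \pkg{rtracklayer}) into a table of gene intervals.
#' Coordinates are 0-based half-open internally; GTF 1-based inclusive input
#' is converted on read.
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension), `"bed"` or `"gtf"`.
#' @param allowed_chroms chromosomes to keep; defaults to autosomes plus X.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `gene_symbol`.  Duplicate gene ids and missing strands are
#'   errors.
#' @export
load_gene_annotation <- function(path, format = c("auto", "bed", "gtf"),
                                 allowed_chroms = default_chromosomes()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff3?)(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed"
  }
  genes <- if (format == "bed") read_gene_bed(path) else read_gene_gtf(path)
  genes <- genes[genes$chrom %in% allowed_chroms, , drop = FALSE]
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id(s): ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  rownames(genes) <- NULL
  genes
}

read_gene_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # also accept whitespace-delimited BED
  fields <- lapply(fields, function(f)
    if (length(f) == 1L) strsplit(trimws(f), "[ \t]+")[[1L]] else f)
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 6L)
      stop(sprintf("line %d: expected >= 6 BED columns, got %d", i, length(f)))
    start <- suppressWarnings(as.numeric(f[2L]))
    end <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(start) || is.na(end))
      stop(sprintf("line %d: unparseable coordinates", i))
    if (end <= start)
      stop(sprintf("line %d: end (%s) <= start (%s)", i, f[3L], f[2L]))
    if (!f[6L] %in% c("+", "-"))
      stop(sprintf("line %d: strand required ('+' or '-'), got '%s'", i, f[6L]))
    out[[i]] <- data.frame(chrom = f[1L], start = start, end = end,
                           strand = f[6L], gene_id = f[4L],
                           gene_symbol = f[4L], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

read_gene_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF/GFF requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  if ("type" %in% names(md)) {
    keep <- md$type == "gene"
    if (!any(keep)) stop("no gene-level records found in ", path)
    md <- md[keep, , drop = FALSE]
  }
  strand <- as.character(md$strand)
  if (any(!strand %in% c("+", "-"))) stop("strand required for all genes")
  gid <- if ("gene_id" %in% names(md)) md$gene_id else
    stop("gene_id attribute required in GTF input")
  sym <- if ("gene_name" %in% names(md)) md$gene_name else gid
  data.frame(chrom = as.character(md$seqnames),
             start = md$start - 1L,  # to 0-based half-open
             end = md$end,
             strand = strand, gene_id = gid, gene_symbol = sym,
             stringsAsFactors = FALSE)
}

#' Extended, bin-aligned interval for a gene
#'
#' Rounds the genomic start down and the genomic end up to multiples of the
#' bin width -- which realizes "round the TSS in the 5' direction and the TES
#' in the 3' direction" for genes on either strand -- then adds a fixed flank
#' on both sides and clamps to the chromosome.
#'
#' @param start,end 0-based half-open gene coordinates.
#' @param flank_bp flank added beyond TSS and TES (default 2000 bp); must be
#'   a multiple of `bin_width`.
#' @param bin_width bin size in bp (default 200).
#' @param chrom_len chromosome length for clamping; `Inf` to skip.
#' @return list with `ext_start`, `ext_end`, and `n_bins`.
#' @export
extended_bins <- function(start, end, flank_bp = 2000, bin_width = 200,
                          chrom_len = Inf) {
  stopifnot(flank_bp > 0, bin_width > 0, flank_bp %% bin_width == 0)
  if (start < 0 || end <= start)
    stop("invalid gene interval [", start, ", ", end, ")")
  if (is.finite(chrom_len) && end > chrom_len)
    stop("gene extends beyond chromosome (end ", end, " > ", chrom_len, ")")
  ext_start <- floor(start / bin_width) * bin_width - flank_bp
  ext_end <- ceiling(end / bin_width) * bin_width + flank_bp
  ext_start <- max(0, ext_start)
  if (is.finite(chrom_len))
    ext_end <- min(ext_end, floor(chrom_len / bin_width) * bin_width)
  list(ext_start = ext_start, ext_end = ext_end,
       n_bins = as.integer((ext_end - ext_start) / bin_width))
}

#' Construct a binarized chromosome track
#'
#' @param cell_type,chrom labels.
#' @param mat binary matrix, one row per `bin_width`-bp bin, one column per
#'   mark.
#' @param mark_names column labels.
#' @param bin_width bin size in bp.
#' @return an object of class `ghmm_track`.
#' @export
ghmm_track <- function(cell_type, chrom, mat, mark_names = colnames(mat),
                       bin_width = 200) {
  mat <- as.matrix(mat)
  if (!all(mat %in% c(0L, 1L))) stop("track entries must be 0/1")
  if (is.null(mark_names)) mark_names <- paste0("mark", seq_len(ncol(mat)))
  structure(list(cell_type = cell_type, chrom = chrom,
                 mat = mat, mark_names = mark_names, bin_width = bin_width),
            class = "ghmm_track")
}

#' Extract one gene's binned observation from a track
#'
#' Rows cover the extended (flanked, bin-aligned) interval; for genes on the
#' negative strand the row order is reversed so that row 1 is always the 5'
#' flank.  Mark columns are never reordered.
#'
#' @param track a `ghmm_track`.
#' @param gene one row of a gene annotation table (list-like with `chrom`,
#'   `start`, `end`, `strand`, `gene_id`).
#' @param flank_bp,bin_width as in [extended_bins()].
#' @return list with `gene_id`, `cell_type`, `strand`, `n_bins`, and the
#'   binary matrix `obs` (bins x marks, 5' to 3').
#' @export
extract_observation <- function(track, gene, flank_bp = 2000, bin_width = 200) {
  if (!identical(track$chrom, gene$chrom))
    stop("track chromosome (", track$chrom, ") does not match gene (",
         gene$chrom, ")")
  chrom_len <- nrow(track$mat) * bin_width
  ext <- extended_bins(gene$start, gene$end, flank_bp, bin_width, chrom_len)
  rows <- (ext$ext_start / bin_width + 1L):(ext$ext_end / bin_width)
  obs <- track$mat[rows, , drop = FALSE]
  if (gene$strand == "-") obs <- obs[rev(seq_len(nrow(obs))), , drop = FALSE]
  list(gene_id = gene$gene_id, cell_type = track$cell_type,
       strand = gene$strand, n_bins = ext$n_bins, obs = obs)
}

# Concatenate per-gene observation matrices into one input matrix:
# a dummy row, then each gene's rows followed by a dummy row.  The dummy
# column (last) is 1 exactly at dummy rows; real marks are 0 there.
concat_observations <- function(obs_list) {
  E <- ncol(obs_list[[1L]]$obs)
  n_rows <- 1L + sum(vapply(obs_list, function(o) nrow(o$obs) + 1L, 0L))
  mat <- matrix(0L, n_rows, E + 1L)
  mat[1L, E + 1L] <- 1L
  row <- 2L
  genes <- data.frame(gene_id = character(0), row_start = integer(0),
                      row_end = integer(0))
  for (o in obs_list) {
    Tg <- nrow(o$obs)
    mat[row:(row + Tg - 1L), seq_len(E)] <- o$obs
    genes <- rbind(genes, data.frame(gene_id = o$gene_id, row_start = row,
                                     row_end = row + Tg - 1L))
    mat[row + Tg, E + 1L] <- 1L
    row <- row + Tg + 1L
  }
  list(mat = mat, genes = genes)
}

#' Write concatenated binarized input files
#'
#' For every (cell type, chromosome) pair with genes, writes one file in the
#' two-header binarized text dialect with `E + 1` columns, the last being the
#' dummy mark.  The layout is: one dummy row, then each gene's extended
#' observation rows followed by a dummy row.  A manifest records the gene
#' order and row ranges per file.
#'
#' @param genes gene annotation table (see [load_gene_annotation()]).
#' @param tracks list of `ghmm_track` objects covering every
#'   (cell type, chromosome) pair that has genes.
#' @param out_dir output directory (created if needed).
#' @param flank_bp,bin_width as in [extended_bins()].
#' @return invisibly, a list with `n_files` and the `manifest` data.frame
#'   (also written to `manifest.tsv` in `out_dir`).
#' @export
write_input_files <- function(genes, tracks, out_dir, flank_bp = 2000,
                              bin_width = 200) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  key <- vapply(tracks, function(t) paste(t$cell_type, t$chrom, sep = "\r"), "")
  names(tracks) <- key
  cell_types <- unique(vapply(tracks, function(t) t$cell_type, ""))
  chroms <- unique(genes$chrom)
  manifest <- list()
  n_files <- 0L
  for (ct in cell_types) {
    for (chrom in chroms) {
      sub <- genes[genes$chrom == chrom, , drop = FALSE]
      if (nrow(sub) == 0L) next
      tr <- tracks[[paste(ct, chrom, sep = "\r")]]
      if (is.null(tr))
        stop("missing track for cell type '", ct, "', chromosome '", chrom, "'")
      obs_list <- lapply(seq_len(nrow(sub)), function(i)
        extract_observation(tr, sub[i, ], flank_bp, bin_width))
      cc <- concat_observations(obs_list)
      fname <- paste0(ct, "_", chrom, "_binary.txt")
      write_binarized_file(file.path(out_dir, fname), ct, chrom,
                           c(tr$mark_names, "DUMMY"), cc$mat)
      n_files <- n_files + 1L
      manifest[[length(manifest) + 1L]] <-
        data.frame(file = fname, cell_type = ct, chrom = chrom,
                   gene_id = cc$genes$gene_id,
                   row_start = cc$genes$row_start,
                   row_end = cc$genes$row_end)
    }
  }
  manifest <- do.call(rbind, manifest)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(n_files = n_files, manifest = manifest))
}

write_binarized_file <- function(path, cell_type, chrom, mark_names, mat) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cell_type, chrom, sep = "\t"), con)
  writeLines(paste(mark_names, collapse = "\t"), con)
  if (nrow(mat) > 0L)
    write.table(mat, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a binarized text file
#'
#' Expects two header lines (cell type and chromosome; mark names), then
#' tab-separated 0/1 rows of equal width.
#'
#' @param path file path (plain or gzip).
#' @return list with `cell_type`, `chrom`, `mark_names`, and integer matrix
#'   `mat`.
#' @export
read_binarized_file <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  if (length(lines) < 2L) stop("truncated binarized file: ", path)
  hd <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(hd) != 2L) stop("first header line must be 'cell_type<TAB>chrom'")
  mark_names <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    warning("binarized file has an empty data section: ", path)
    mat <- matrix(0L, 0L, length(mark_names))
  } else {
    toks <- strsplit(body, "\t", fixed = TRUE)
    widths <- lengths(toks)
    if (any(widths != length(mark_names)))
      stop(sprintf("row %d has %d columns, expected %d",
                   which(widths != length(mark_names))[1L],
                   widths[widths != length(mark_names)][1L],
                   length(mark_names)))
    flat <- unlist(toks, use.names = FALSE)
    bad <- !flat %in% c("0", "1")
    if (any(bad))
      stop(sprintf("non-binary token '%s' at row %d", flat[bad][1L],
                   ceiling(which(bad)[1L] / length(mark_names))))
    mat <- matrix(as.integer(flat), length(body), length(mark_names),
                  byrow = TRUE)
  }
  colnames(mat) <- mark_names
  list(cell_type = hd[1L], chrom = hd[2L], mark_names = mark_names, mat = mat)
}

# Recover per-gene row ranges from a concatenated matrix by splitting on
# dummy-mark rows (used for round-trip checks and manifest-free loading).
split_on_dummy <- function(mat) {
  dummy <- mat[, ncol(mat)] == 1L
  if (!dummy[1L] || !dummy[nrow(mat)])
    stop("concatenated file must start and end with a dummy position")
  bounds <- which(dummy)
  out <- data.frame(row_start = head(bounds, -1L) + 1L,
                    row_end = tail(bounds, -1L) - 1L)
  out[out$row_end >= out$row_start, , drop = FALSE]
}

#' Assemble a training dataset in memory
#'
#' @param files list of per-file entries, each with `cell_type`, `chrom`,
#'   integer matrix `mat` (rows x (E+1) columns, dummy mark last), and a
#'   `genes` data.frame (`gene_id`, `row_start`, `row_end`).
#' @param mark_names the `E` real mark names.
#' @return an object of class `ghmm_dataset`.
#' @export
ghmm_dataset <- function(files, mark_names) {
  structure(list(files = files, mark_names = mark_names),
            class = "ghmm_dataset")
}

#' Load a training dataset from a directory written by [write_input_files()]
#'
#' @param dir directory containing binarized files plus `manifest.tsv`.
#' @return a `ghmm_dataset`: one entry per file with its observation matrix
#'   and per-gene row ranges.
#' @export
load_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.tsv")
  if (!file.exists(mpath)) stop("no manifest.tsv under ", dir)
  manifest <- read.table(mpath, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  files <- list()
  mark_names <- NULL
  for (f in unique(manifest$file)) {
    sub <- manifest[manifest$file == f, , drop = FALSE]
    bf <- read_binarized_file(file.path(dir, f))
    mk <- head(bf$mark_names, -1L)
    if (is.null(mark_names)) mark_names <- mk
    else if (!identical(mark_names, mk))
      stop("mark columns differ across files (", f, ")")
    files[[length(files) + 1L]] <-
      list(file = f, cell_type = bf$cell_type, chrom = bf$chrom, mat = bf$mat,
           genes = data.frame(gene_id = sub$gene_id,
                              row_start = sub$row_start,
                              row_end = sub$row_end))
  }
  ghmm_dataset(files, mark_names)
}
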