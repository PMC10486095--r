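#' Scaled forward-backward pass over one observation sequence
#'
#' Runs the forward and backward recursions on the expanded HMM with the
#' numerical scheme required by long concatenated multi-gene sequences:
#' forward variables are rescaled by their per-position sum, backward
#' variables independently by their own per-position sum, and scaled values
#' below 1e-300 are floored (forward values whose emission probability
#' product is exactly zero are kept at zero).  The log-likelihood is the sum
#' of the log forward scale factors.
#'
#' @param hmm a `ghmm_hmm` from [expand_model()].
#' @param obs integer 0/1 matrix, `T x (E + 1)` with the dummy mark last
#'   (or `T x E` for a bare, dummy-free HMM of matching emission width).
#' @param want_gamma return the `T x n_states` posterior matrix.
#' @param want_stats return accumulated pairwise transition expectations
#'   (`xi`) and emission sufficient statistics.
#' @return list with `log_likelihood`, and optionally `gamma`, `xi`,
#'   `emit_num`, `emit_den`.
#' @export
forward_backward <- function(hmm, obs, want_gamma = TRUE, want_stats = FALSE) {
  stopifnot(inherits(hmm, "ghmm_hmm"))
  obs <- as.matrix(obs)
  storage.mode(obs) <- "integer"
  if (ncol(obs) != ncol(hmm$emit_full))
    stop("observation has ", ncol(obs), " mark columns; model expects ",
         ncol(hmm$emit_full))
  .fb_scaled(hmm$initial, hmm$trans_full, hmm$emit_full, obs,
             want_gamma, want_stats)
}

#' Total log-likelihood of a dataset under a model
#'
#' Sum of per-file sequence log-likelihoods under the expanded HMM.
#'
#' @param model a `ghmm_model`.
#' @param dataset a `ghmm_dataset`.
#' @return scalar natural-log likelihood.
#' @export
dataset_log_likelihood <- function(model, dataset) {
  hmm <- expand_model(model)
  ll <- 0
  for (f in dataset$files) {
    res <- tryCatch(
      forward_backward(hmm, f$mat, want_gamma = FALSE, want_stats = FALSE),
      error = function(e)
        stop("in file '", f$file %||% f$cell_type, "': ", conditionMessage(e),
             call. = FALSE))
    ll <- ll + res$log_likelihood
  }
  ll
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a mixture model with Baum-Welch EM
#'
#' Runs a fixed number of EM iterations on the expanded HMM.  Each iteration
#' draws a fresh uniform subsample of input files without replacement (all
#' files when `subsample_files` is at least the file count), accumulates
#' expectations over the subsample in a fixed file order, and re-estimates
#' initial, transition, and emission parameters.  Parameters that are exactly
#' 0 or 1 at the start of training stay fixed, which preserves the structural
#' zeros that disallow cross-component transitions and pin the dummy state
#' and mark.  The per-iteration log-likelihood is recorded as computed on
#' that iteration's subsample -- values from different subsamples are not
#' comparable across iterations -- and is never used for early stopping.
#'
#' @param model starting `ghmm_model`, e.g. from [initialize_model()].
#' @param dataset a `ghmm_dataset`.
#' @param iterations number of EM iterations (default 200).
#' @param subsample_files files drawn per iteration (default 100).
#' @param seed integer seed governing the subsampling.
#' @param verbose print the per-iteration log-likelihood.
#' @return list with the trained `model` and `trace`, a data.frame with one
#'   row per iteration (`iteration`, `log_likelihood`, `n_files`,
#'   `subsampled`).
#' @export
em_train <- function(model, dataset, iterations = 200, subsample_files = 100,
                     seed = 1L, verbose = FALSE) {
  stopifnot(is_count(iterations), is_count(subsample_files))
  n_files <- length(dataset$files)
  if (n_files == 0L) stop("dataset has no files")
  hmm <- expand_model(model)
  n <- hmm$n_states
  free_trans <- hmm$trans_full != 0 & hmm$trans_full != 1
  free_emit <- hmm$emit_full != 0 & hmm$emit_full != 1
  n_draw <- min(subsample_files, n_files)
  iter_seeds <- split_seed(seed, iterations)
  trace <- data.frame(iteration = seq_len(iterations),
                      log_likelihood = NA_real_,
                      n_files = n_draw,
                      subsampled = n_draw < n_files)
  warned_empty <- FALSE
  for (it in seq_len(iterations)) {
    sel <- if (n_draw < n_files)
      sort(with_seed(iter_seeds[it], sample.int(n_files, n_draw)))
    else seq_len(n_files)
    xi <- matrix(0, n, n)
    em_num <- matrix(0, n, ncol(hmm$emit_full))
    em_den <- numeric(n)
    ll <- 0
    for (fi in sel) {
      f <- dataset$files[[fi]]
      res <- forward_backward(hmm, f$mat, want_gamma = FALSE, want_stats = TRUE)
      ll <- ll + res$log_likelihood
      xi <- xi + res$xi
      em_num <- em_num + res$emit_num
      em_den <- em_den + res$emit_den
    }
    trace$log_likelihood[it] <- ll

    # M step: renormalize expected counts over the free entries of each row,
    # keeping frozen (exactly 0 or 1) entries at their values.
    for (i in seq_len(n)) {
      free <- free_trans[i, ]
      if (!any(free)) next
      tot <- sum(xi[i, free])
      if (tot > 0) {
        frozen_mass <- sum(hmm$trans_full[i, !free])
        hmm$trans_full[i, free] <- xi[i, free] / tot * (1 - frozen_mass)
      }
    }
    for (i in seq_len(n)) {
      free <- free_emit[i, ]
      if (!any(free)) next
      if (em_den[i] > 0) {
        hmm$emit_full[i, free] <- em_num[i, free] / em_den[i]
      } else if (!warned_empty) {
        warning("state ", i, " received zero expected mass in iteration ", it,
                "; its emissions were left unchanged")
        warned_empty <- TRUE
      }
    }
    if (verbose)
      message(sprintf("iteration %d: log-likelihood %.4f on %d file(s)",
                      it, ll, length(sel)))
  }
  list(model = contract_model(hmm, mark_names = dataset$mark_names %||%
                                head(hmm$mark_names, -1L)),
       trace = trace, seed = seed)
}
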