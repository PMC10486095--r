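#' @keywords internal
"_PACKAGE"

#' @useDynLib geneHMM, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rexp runif rbinom rlnorm rbeta median var cor phyper
#'   pbinom setNames complete.cases quantile as.dist
#' @importFrom utils read.table write.table head tail
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library functions never perturb user randomness.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one master seed.  All stochastic
# operations in the package draw their seeds through this so that a single
# integer reproduces every fixture bit-for-bit.
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

# All permutations of 1..n as a matrix (one per row); n is small (<= 8).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

# Sample one point from a flat Dirichlet (alpha = 1) of dimension n, i.e.
# uniformly on the simplex.
rdirichlet1 <- function(n) {
  g <- rexp(n)
  g / sum(g)
}

#' Match estimated mixture components to reference components
#'
#' Mixture components are identifiable only up to relabeling.  This finds the
#' component permutation that maximizes agreement between two hard assignment
#' matrices by exhaustive search over permutations (feasible for the small
#' component counts used here).
#'
#' @param est,ref integer matrices (genes x cell types) of component labels
#'   in `1..M`.  When both carry row names over the same gene set, `est` is
#'   reordered to `ref`'s row order before comparison.
#' @param M number of components.
#' @return list with `perm` (index `i` of `perm` gives the reference label for
#'   estimated label `i`) and `agreement`, the fraction of entries matching
#'   after relabeling.
#' @export
match_components <- function(est, ref, M) {
  stopifnot(all(dim(est) == dim(ref)), M <= 8L)
  if (!is.null(rownames(est)) && !is.null(rownames(ref)) &&
      setequal(rownames(est), rownames(ref)))
    est <- est[rownames(ref), , drop = FALSE]
  perms <- all_perms(M)
  best <- 0L
  best_agree <- -1
  for (p in seq_len(nrow(perms))) {
    relab <- matrix(perms[p, ][est], nrow(est), ncol(est))
    agree <- mean(relab == ref, na.rm = TRUE)
    if (agree > best_agree) {
      best_agree <- agree
      best <- p
    }
  }
  list(perm = perms[best, ], agreement = best_agree)
}

#' Align the emission parameters of two models
#'
#' Finds the component permutation (and, within each matched component pair,
#' the state permutation) minimizing the summed L1 distance between emission
#' parameters, and returns the maximal per-parameter absolute error after
#' alignment together with the permutation used.
#'
#' @param est,ref objects of class `ghmm_model` with equal `M`, `S`, `E`.
#' @param perm optional fixed component permutation (as from
#'   [match_components()]); when `NULL` all permutations are searched.
#' @return list with `perm`, `max_abs_error`, and `mean_abs_error` over all
#'   `M * S * E` emission parameters.
#' @export
align_emissions <- function(est, ref, perm = NULL) {
  stopifnot(est$M == ref$M, est$S == ref$S, est$E == ref$E)
  M <- est$M; S <- est$S
  state_perms <- all_perms(S)
  comp_cost <- function(m_est, m_ref) {
    # best state permutation for one component pair; returns c(cost, errors)
    best <- Inf; best_err <- NULL
    for (q in seq_len(nrow(state_perms))) {
      e1 <- est$emit[m_est, state_perms[q, ], , drop = FALSE]
      e2 <- ref$emit[m_ref, , , drop = FALSE]
      err <- abs(e1 - e2)
      if (sum(err) < best) { best <- sum(err); best_err <- err }
    }
    list(cost = best, err = best_err)
  }
  eval_perm <- function(pp) {
    tot <- 0; errs <- c()
    for (m in seq_len(M)) {
      cc <- comp_cost(m, pp[m])
      tot <- tot + cc$cost
      errs <- c(errs, cc$err)
    }
    list(cost = tot, errs = errs)
  }
  if (!is.null(perm)) {
    res <- eval_perm(perm)
    best_perm <- perm
  } else {
    perms <- all_perms(M)
    best <- Inf; res <- NULL; best_perm <- NULL
    for (p in seq_len(nrow(perms))) {
      cand <- eval_perm(perms[p, ])
      if (cand$cost < best) { best <- cand$cost; res <- cand; best_perm <- perms[p, ] }
    }
  }
  list(perm = best_perm,
       max_abs_error = max(res$errs),
       mean_abs_error = mean(res$errs))
}
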