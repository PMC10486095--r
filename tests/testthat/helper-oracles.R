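# Independent reference implementations used to check the scaled C++
# forward-backward pipeline.  These deliberately share no code with the
# package internals: path enumeration works in plain probability space and
# the log-space forward pass uses log-sum-exp throughout.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# Per-position emission probability products for a Bernoulli-product HMM.
emission_products <- function(emit, obs) {
  T <- nrow(obs); n <- nrow(emit)
  b <- matrix(0, T, n)
  for (t in seq_len(T)) for (s in seq_len(n))
    b[t, s] <- prod(ifelse(obs[t, ] == 1, emit[s, ], 1 - emit[s, ]))
  b
}

# Log-likelihood by exhaustive enumeration of all n^T state paths.
brute_force_loglik <- function(init, trans, emit, obs) {
  n <- length(init); T <- nrow(obs)
  b <- emission_products(emit, obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), T)))
  pr <- init[paths[, 1L]] * b[cbind(1L, paths[, 1L])]
  if (T > 1L) for (t in 2:T)
    pr <- pr * trans[cbind(paths[, t - 1L], paths[, t])] * b[cbind(t, paths[, t])]
  log(sum(pr))
}

# Log-space forward pass (log-sum-exp), an overflow-free reference for long
# sequences.
logspace_loglik <- function(init, trans, emit, obs) {
  n <- length(init); T <- nrow(obs)
  lb <- log(emission_products(emit, obs))
  lt <- log(trans)
  la <- log(init) + lb[1L, ]
  if (T > 1L) for (t in 2:T)
    la <- vapply(seq_len(n), function(s) logsumexp(la + lt[, s]), 0) + lb[t, ]
  logsumexp(la)
}

# Standalone per-component gene likelihood, including the gene-end exit
# factor, by exhaustive enumeration; returns the normalized posterior over
# components.
brute_force_component_posterior <- function(model, obs) {
  M <- model$M; S <- model$S
  L <- numeric(M)
  T <- nrow(obs)
  for (m in seq_len(M)) {
    b <- emission_products(matrix(model$emit[m, , ], S), obs)
    paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T)))
    pr <- model$tau[m, paths[, 1L]] * b[cbind(1L, paths[, 1L])]
    if (T > 1L) for (t in 2:T)
      pr <- pr * model$trans[m, , ][cbind(paths[, t - 1L], paths[, t])] *
        b[cbind(t, paths[, t])]
    pr <- pr * model$exit[m, paths[, T]]
    L[m] <- sum(pr)
  }
  L / sum(L)
}

# AUROC as the explicit all-pairs count, ties worth one half.
allpairs_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Hypergeometric upper tail by direct enumeration over achievable overlaps.
enumerated_hyper_p <- function(overlap, set_n, universe_n, comp_n) {
  ks <- max(0L, comp_n - (universe_n - set_n)):min(set_n, comp_n)
  probs <- choose(set_n, ks) * choose(universe_n - set_n, comp_n - ks) /
    choose(universe_n, comp_n)
  sum(probs[ks >= overlap])
}

# A small random (but valid) mixture model for property tests.
random_model <- function(M, S, E, seed, exit_prob = 0.05) {
  M <- as.integer(M); S <- as.integer(S); E <- as.integer(E)
  set.seed(seed)
  simplex <- function(n) { g <- rexp(n); g / sum(g) }
  tau <- matrix(simplex(M * S), M, S, byrow = TRUE)
  trans <- array(0, c(M, S, S))
  for (m in seq_len(M)) for (s in seq_len(S))
    trans[m, s, ] <- simplex(S) * (1 - exit_prob)
  emit <- array(runif(M * S * E, 0.05, 0.95), c(M, S, E))
  ghmm_model(tau, trans, emit, matrix(exit_prob, M, S),
             paste0("mk", seq_len(E)))
}

# Wrap a list of per-gene binary observation matrices (one cell type, one
# chromosome) into a concatenated in-memory dataset.
obs_to_dataset <- function(obs_list, mark_names = NULL,
                           cell_type = "CT1", chrom = "chr1") {
  if (is.null(mark_names)) mark_names <- paste0("mk", seq_len(ncol(obs_list[[1L]])))
  wrapped <- lapply(seq_along(obs_list), function(i)
    list(gene_id = sprintf("G%03d", i), cell_type = cell_type, strand = "+",
         n_bins = nrow(obs_list[[i]]), obs = obs_list[[i]]))
  cc <- geneHMM:::concat_observations(wrapped)
  ghmm_dataset(list(list(file = "mem", cell_type = cell_type, chrom = chrom,
                         mat = cc$mat, genes = cc$genes)), mark_names)
}

# Assignment object built directly from a label matrix, for evaluation tests.
make_assignment <- function(assign, M = max(assign, na.rm = TRUE),
                            metadata = NULL) {
  structure(list(assign = assign, cell_types = colnames(assign),
                 metadata = metadata, M = M, posteriors = NULL),
            class = "ghmm_assignment")
}

# Shared medium-size simulated fixture: built once per test run.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth_model <- sample_ground_truth_model(3L, 2L, 6L, separation = 2,
                                               seed = 421L)
      cache <<- simulate_dataset(truth_model, n_genes = 90, n_cell_types = 3,
                                 replicate_pairs = data.frame(a = "CT1",
                                                              b = "CT2"),
                                 replicate_concordance = 1,
                                 n_chroms = 3, length_meanlog = log(8000),
                                 length_sdlog = 0.5, min_length = 2000,
                                 max_length = 20000, flip_noise = 0.02,
                                 seed = 73L)
    }
    cache
  }
})
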