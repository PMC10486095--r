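#' Construct a gene-level mixture-of-HMMs model
#'
#' A model with `M` mixture components, each a fully connected HMM with `S`
#' states and product-Bernoulli emissions over `E` binary epigenomic marks.
#' Each gene is assumed generated by exactly one component; the prior that a
#' gene belongs to component `m` is the sum of the initial probabilities of
#' that component's states.
#'
#' @param tau `M x S` matrix of initial state probabilities, summing to 1
#'   over all entries.
#' @param trans `M x S x S` array; `trans[m, s, s2]` is the probability of
#'   moving from state `s` to state `s2` within component `m`.  Together with
#'   `exit[m, s]` each row sums to 1.
#' @param emit `M x S x E` array of Bernoulli mark emission probabilities.
#' @param exit `M x S` matrix; probability of leaving the gene (transitioning
#'   to the inter-gene dummy state) from each state.
#' @param mark_names character vector of length `E`.
#' @return an object of class `ghmm_model`.
#' @export
ghmm_model <- function(tau, trans, emit, exit, mark_names) {
  tau <- as.matrix(tau)
  M <- nrow(tau); S <- ncol(tau)
  E <- dim(emit)[3]
  model <- structure(
    list(M = M, S = S, E = E, mark_names = as.character(mark_names),
         tau = tau, trans = trans, emit = emit, exit = as.matrix(exit)),
    class = "ghmm_model")
  validate_model(model)
  model
}

#' Validate the probabilistic invariants of a mixture model
#'
#' Checks that initial probabilities sum to one over all states, that each
#' state's within-component transition row plus its exit probability sums to
#' one, and that emissions lie in `[0, 1]`.
#'
#' @param model a `ghmm_model`.
#' @param tol numeric tolerance on the simplex constraints.
#' @return `model`, invisibly; errors on violation.
#' @export
validate_model <- function(model, tol = 1e-9) {
  with(model, {
    if (E < 1L) stop("model must have at least one mark (E >= 1)")
    stopifnot(identical(dim(tau), c(M, S)),
              identical(dim(trans), c(M, S, S)),
              identical(dim(emit), c(M, S, E)),
              identical(dim(exit), c(M, S)),
              length(mark_names) == E)
    if (abs(sum(tau) - 1) > tol)
      stop("initial probabilities must sum to 1 (got ", sum(tau), ")")
    for (m in seq_len(M)) for (s in seq_len(S)) {
      tot <- sum(trans[m, s, ]) + exit[m, s]
      if (abs(tot - 1) > tol)
        stop(sprintf("transition row (%d, %d) sums to %.12f, not 1", m, s, tot))
    }
    if (any(emit < 0 | emit > 1)) stop("emissions must lie in [0, 1]")
    if (any(tau < 0) || any(trans < 0) || any(exit < 0))
      stop("probabilities must be non-negative")
  })
  invisible(model)
}

#' Component prior probabilities
#'
#' The prior that a randomly chosen gene belongs to each component: the sum
#' of the component's initial state probabilities.
#'
#' @param model a `ghmm_model`.
#' @return numeric vector of length `M` summing to 1.
#' @export
component_priors <- function(model) {
  rowSums(model$tau)
}

#' Initialize a mixture model from data
#'
#' Initial state probabilities are drawn from a flat Dirichlet over all
#' `M * S` states.  Emissions are set empirically: each gene is randomly
#' assigned to a component, each of its bins uniformly to one of that
#' component's states, and each state's mark emission probability is the mean
#' observed presence over its assigned bins.  A state that receives no bins
#' falls back to the global mark frequency.  Within-component transition rows
#' are drawn from a flat Dirichlet and rescaled to sum to `1 - exit_prob`,
#' with `exit_prob` (default 0.05) reserved for the transition to the
#' inter-gene dummy state.
#'
#' @param data a `ghmm_dataset` (see [load_dataset()]) or a list of binary
#'   gene observation matrices (bins x marks) sharing column count.
#' @param M,S component and per-component state counts.
#' @param seed integer seed; initialization is deterministic given it.
#' @param exit_prob probability mass reserved for gene-end transitions.
#' @param mark_names optional mark labels; taken from `data` when available.
#' @return a `ghmm_model`.
#' @export
initialize_model <- function(data, M, S, seed, exit_prob = 0.05,
                             mark_names = NULL) {
  stopifnot(is_count(M), is_count(S), exit_prob > 0, exit_prob < 1)
  obs <- gene_observations(data)
  if (length(obs) == 0L) stop("no gene observations supplied")
  E <- ncol(obs[[1L]])
  if (is.null(E) || E == 0L) stop("observations must have at least one mark")
  if (!all(vapply(obs, ncol, 0L) == E))
    stop("all observations must share the same number of marks")
  if (is.null(mark_names)) {
    mark_names <- attr(data, "mark_names")
    if (is.null(mark_names) && !is.null(data$mark_names))
      mark_names <- data$mark_names
    if (is.null(mark_names)) mark_names <- paste0("mark", seq_len(E))
  }

  with_seed(seed, {
    tau <- matrix(rdirichlet1(M * S), M, S, byrow = TRUE)
    trans <- array(0, c(M, S, S))
    for (m in seq_len(M)) for (s in seq_len(S))
      trans[m, s, ] <- rdirichlet1(S) * (1 - exit_prob)
    exit <- matrix(exit_prob, M, S)

    gene_comp <- sample.int(M, length(obs), replace = TRUE)
    num <- array(0, c(M, S, E))
    den <- matrix(0, M, S)
    for (g in seq_along(obs)) {
      m <- gene_comp[g]
      x <- obs[[g]]
      st <- sample.int(S, nrow(x), replace = TRUE)
      for (s in seq_len(S)) {
        rows <- st == s
        if (any(rows)) {
          num[m, s, ] <- num[m, s, ] + colSums(x[rows, , drop = FALSE])
          den[m, s] <- den[m, s] + sum(rows)
        }
      }
    }
    global_freq <- colSums(Reduce(`+`, lapply(obs, colSums)) |> rbind()) /
      sum(vapply(obs, nrow, 0L))
    emit <- array(0, c(M, S, E))
    for (m in seq_len(M)) for (s in seq_len(S)) {
      if (den[m, s] > 0) {
        emit[m, s, ] <- num[m, s, ] / den[m, s]
      } else {
        message(sprintf(
          "state (%d, %d) received no bins at initialization; using global mark frequencies",
          m, s))
        emit[m, s, ] <- global_freq
      }
    }
    ghmm_model(tau, trans, emit, exit, mark_names)
  })
}

# Extract the list of per-gene binary observation matrices (real marks only)
# from a dataset object, or pass a plain list of matrices through.
gene_observations <- function(data) {
  if (inherits(data, "ghmm_dataset")) {
    out <- list()
    for (f in data$files) {
      em <- f$mat[, seq_len(ncol(f$mat) - 1L), drop = FALSE]  # drop dummy mark
      for (i in seq_len(nrow(f$genes)))
        out[[length(out) + 1L]] <-
          em[f$genes$row_start[i]:f$genes$row_end[i], , drop = FALSE]
    }
    return(out)
  }
  if (is.list(data) && all(vapply(data, is.matrix, TRUE))) return(data)
  stop("`data` must be a ghmm_dataset or a list of binary matrices")
}

#' Expand a mixture of HMMs into a single constrained HMM
#'
#' The mixture is equivalent to one HMM with `M * S + 1` states: the extra
#' "dummy" state sits between genes and emits only the "dummy" mark.
#' Cross-component transitions are structural zeros; the dummy row carries
#' the flattened initial probabilities, and the dummy column carries the
#' per-state exit probabilities.  All probability mass of the initial vector
#' is on the dummy state, matching input files that begin with a dummy
#' position.
#'
#' @param model a `ghmm_model`.
#' @return an object of class `ghmm_hmm` with elements `n_states`,
#'   `initial`, `trans_full`, `emit_full`, `state_component`, `state_state`.
#' @export
expand_model <- function(model) {
  validate_model(model)
  M <- model$M; S <- model$S; E <- model$E
  n <- M * S + 1L
  dummy <- n
  trans_full <- matrix(0, n, n)
  emit_full <- matrix(0, n, E + 1L)
  idx <- function(m, s) (m - 1L) * S + s
  for (m in seq_len(M)) {
    rows <- idx(m, seq_len(S))
    trans_full[rows, rows] <- model$trans[m, , ]
    trans_full[rows, dummy] <- model$exit[m, ]
    trans_full[dummy, rows] <- model$tau[m, ]
    emit_full[rows, seq_len(E)] <- model$emit[m, , ]
  }
  emit_full[dummy, E + 1L] <- 1
  initial <- c(rep(0, n - 1L), 1)
  structure(
    list(n_states = n, M = M, S = S, E = E,
         initial = initial, trans_full = trans_full, emit_full = emit_full,
         mark_names = c(model$mark_names, "DUMMY"),
         state_component = c(rep(seq_len(M), each = S), NA_integer_),
         state_state = c(rep(seq_len(S), times = M), NA_integer_)),
    class = "ghmm_hmm")
}

#' Recover the mixture parameters from an expanded HMM
#'
#' Exact inverse of [expand_model()]: the dummy row gives the initial
#' probabilities, the dummy column the exit probabilities, and the block
#' diagonal the within-component transitions.
#'
#' @param hmm a `ghmm_hmm`.
#' @param mark_names optional override for mark labels.
#' @return a `ghmm_model`.
#' @export
contract_model <- function(hmm, mark_names = NULL) {
  M <- hmm$M; S <- hmm$S; E <- hmm$E
  dummy <- hmm$n_states
  idx <- function(m, s) (m - 1L) * S + s
  tau <- matrix(0, M, S)
  trans <- array(0, c(M, S, S))
  emit <- array(0, c(M, S, E))
  exit <- matrix(0, M, S)
  for (m in seq_len(M)) {
    rows <- idx(m, seq_len(S))
    tau[m, ] <- hmm$trans_full[dummy, rows]
    trans[m, , ] <- hmm$trans_full[rows, rows]
    exit[m, ] <- hmm$trans_full[rows, dummy]
    emit[m, , ] <- hmm$emit_full[rows, seq_len(E)]
  }
  if (is.null(mark_names)) mark_names <- hmm$mark_names[seq_len(E)]
  ghmm_model(tau, trans, emit, exit, mark_names)
}

#' Record of hard state/gene usage for collapsing a model
#'
#' @param x integer vector of length `M`: number of bins hard-assigned to
#'   each component's states.
#' @param n integer vector of length `M`: number of genes assigned to each
#'   component.
#' @param state_prior `M x S` matrix; row `m` is the empirical fraction of
#'   component `m`'s bins assigned to each of its states (rows sum to 1).
#' @return an object of class `ghmm_usage`.
#' @export
component_usage <- function(x, n, state_prior) {
  state_prior <- as.matrix(state_prior)
  stopifnot(length(x) == nrow(state_prior), length(n) == length(x),
            all(x >= n), all(n >= 0))
  structure(list(x = x, n = n, state_prior = state_prior),
            class = "ghmm_usage")
}

#' Collapse a multi-state model into a single-state-per-component model
#'
#' Each component's emission vector becomes the mean of its state emissions
#' weighted by the empirical state priors; the collapsed initial probability
#' is the component prior; the self-transition is `(x_m - n_m) / x_m` and the
#' exit probability `n_m / x_m`, where `x_m` counts bins and `n_m` genes
#' hard-assigned to component `m`.  The result is used as-is, without further
#' training.
#'
#' @param model a `ghmm_model`.
#' @param usage a `ghmm_usage` computed from hard assignments under `model`.
#' @return a `ghmm_model` with `S = 1`.
#' @export
collapse_model <- function(model, usage) {
  validate_model(model)
  stopifnot(inherits(usage, "ghmm_usage"),
            length(usage$x) == model$M, ncol(usage$state_prior) == model$S)
  M <- model$M; E <- model$E
  if (any(usage$x == 0))
    stop("no bins assigned to component(s) ",
         paste(which(usage$x == 0), collapse = ", "),
         "; cannot collapse an unused component")
  tau <- matrix(component_priors(model), M, 1L)
  emit <- array(0, c(M, 1L, E))
  for (m in seq_len(M))
    emit[m, 1L, ] <- colSums(usage$state_prior[m, ] * model$emit[m, , , drop = TRUE] |>
                               matrix(model$S, E))
  self <- (usage$x - usage$n) / usage$x
  trans <- array(self, c(M, 1L, 1L))
  exit <- matrix(usage$n / usage$x, M, 1L)
  ghmm_model(tau, trans, emit, exit, model$mark_names)
}

#' Write a model to a plain-text file
#'
#' Single text format with a header (`M`, `S`, `E`, mark names) and
#' tab-separated `INIT`, `TRANSITION`, and `EMISSION` sections at full double
#' precision.  Collapsed and baseline models (`S = 1`) use the identical
#' format.
#'
#' @param model a `ghmm_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  validate_model(model)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  writeLines(sprintf("#model\t%d\t%d\t%d", model$M, model$S, model$E), con)
  writeLines(paste(c("#marks", model$mark_names), collapse = "\t"), con)
  for (m in seq_len(model$M)) for (s in seq_len(model$S))
    writeLines(paste(c("INIT", m, s, fmt(model$tau[m, s])), collapse = "\t"), con)
  for (m in seq_len(model$M)) for (s in seq_len(model$S)) {
    for (s2 in seq_len(model$S))
      writeLines(paste(c("TRANSITION", m, s, s2, fmt(model$trans[m, s, s2])),
                       collapse = "\t"), con)
    writeLines(paste(c("TRANSITION", m, s, 0L, fmt(model$exit[m, s])),
                     collapse = "\t"), con)
  }
  for (m in seq_len(model$M)) for (s in seq_len(model$S))
    for (e in seq_len(model$E))
      writeLines(paste(c("EMISSION", m, s, model$mark_names[e],
                         fmt(model$emit[m, s, e])), collapse = "\t"), con)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path file path.
#' @return a `ghmm_model`.  Rejects files whose records are inconsistent with
#'   the declared dimensions.
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  hd <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (hd[1L] != "#model" || length(hd) != 4L)
    stop("not a model file: bad header in ", path)
  M <- as.integer(hd[2L]); S <- as.integer(hd[3L]); E <- as.integer(hd[4L])
  mk <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  if (mk[1L] != "#marks" || length(mk) != E + 1L)
    stop("mark header inconsistent with declared E = ", E)
  mark_names <- mk[-1L]
  tau <- matrix(NA_real_, M, S)
  trans <- array(NA_real_, c(M, S, S))
  emit <- array(NA_real_, c(M, S, E))
  exit <- matrix(NA_real_, M, S)
  for (ln in lines[-(1:2)]) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    kind <- f[1L]
    m <- as.integer(f[2L]); s <- as.integer(f[3L])
    if (is.na(m) || is.na(s) || m < 1L || m > M || s < 1L || s > S)
      stop("record outside declared dimensions: ", ln)
    if (kind == "INIT") {
      tau[m, s] <- as.numeric(f[4L])
    } else if (kind == "TRANSITION") {
      s2 <- as.integer(f[4L])
      if (s2 == 0L) exit[m, s] <- as.numeric(f[5L])
      else if (s2 >= 1L && s2 <= S) trans[m, s, s2] <- as.numeric(f[5L])
      else stop("transition target outside declared dimensions: ", ln)
    } else if (kind == "EMISSION") {
      e <- match(f[4L], mark_names)
      if (is.na(e)) stop("unknown mark in record: ", ln)
      emit[m, s, e] <- as.numeric(f[5L])
    } else stop("unknown record type: ", kind)
  }
  if (anyNA(tau) || anyNA(trans) || anyNA(emit) || anyNA(exit))
    stop("model file is missing records for the declared dimensions")
  ghmm_model(tau, trans, emit, exit, mark_names)
}

#' @export
print.ghmm_model <- function(x, ...) {
  cat(sprintf(
    "Gene-level mixture-of-HMMs model: %d components x %d states, %d marks\n",
    x$M, x$S, x$E))
  cat("Component priors:",
      paste(sprintf("%.3f", component_priors(x)), collapse = " "), "\n")
  invisible(x)
}
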