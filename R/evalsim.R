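#' Simulation design: three-state Gaussian copy-number-like sequence
#'
#' Default design: `M = 3` Gaussian states with means `(-2, -1, 1)`,
#' standard deviation 0.9, uniform initial distribution and a sticky
#' transition matrix with 0.98 diagonal, sequence length `N = 1000`.
#'
#' @param M Number of states.
#' @param N Sequence length.
#' @param means Per-state Gaussian means.
#' @param sd Shared emission standard deviation.
#' @param A Transition matrix (default the sticky matrix above).
#' @param pi0 Initial distribution (default uniform).
#' @return An object of class `"simulation_design"`: list with `model` (an
#'   [hmm()]) and `N`.
#' @export
simulation_design <- function(M = 3L, N = 1000L,
                              means = c(-2, -1, 1), sd = 0.9,
                              A = NULL, pi0 = NULL) {
  if (is.null(A)) {
    if (M != 3L) stop("provide 'A' explicitly for M != 3")
    A <- matrix(c(0.98, 0.015, 0.005,
                  0.005, 0.98, 0.015,
                  0.015, 0.005, 0.98), 3L, byrow = TRUE)
  }
  if (is.null(pi0)) pi0 <- rep(1 / M, M)
  model <- hmm(pi0, A, emission_gaussian(means, rep(sd^2, M)))
  structure(list(model = model, N = as.integer(N)),
            class = "simulation_design")
}

#' Simulate a hidden path and observations from an HMM
#'
#' @param design An [hmm()] model or a [simulation_design()].
#' @param N Sequence length (taken from the design when omitted).
#' @param seed Integer seed.
#' @return List with `states` (integer vector) and `observations`.
#' @export
simulate_hmm <- function(design, N = NULL, seed) {
  if (inherits(design, "simulation_design")) {
    if (is.null(N)) N <- design$N
    model <- design$model
  } else model <- design
  if (is.null(N)) stop("'N' must be given when 'design' is a bare model")
  if (N < 1L) stop("'N' must be >= 1")
  set.seed(seed)
  M <- model$M
  x <- integer(N)
  x[1L] <- sample.int(M, 1L, prob = model$pi0)
  if (N > 1L) for (n in 2:N)
    x[n] <- sample.int(M, 1L, prob = model$A[x[n - 1L], ])
  em <- model$emission
  y <- if (em$family == "gaussian") {
    stats::rnorm(N, em$mean[x], sqrt(em$var[x]))
  } else {
    vapply(x, function(m) sample.int(em$V, 1L, prob = em$prob[m, ]), integer(1))
  }
  list(states = x, observations = y)
}

#' @export
#' @rdname simulate_hmm
#' @param object,nsim,... For the [stats::simulate()] method: the model, the
#'   number of replicates and unused arguments.
simulate.hmm <- function(object, nsim = 1, seed = NULL, N, ...) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  lapply(seq_len(nsim), function(i) simulate_hmm(object, N, seed = seed + i - 1L))
}

#' Exhaustive path enumeration (test oracle)
#'
#' Enumerates all `M^N` hidden paths, computing the evidence, per-path joint
#' scores, the exact distribution over segment counts and the exact site and
#' pairwise marginals by brute force. Ground truth for validating the
#' dynamic-programming recursions on small instances.
#'
#' @inheritParams kseg_forward
#' @param cap Refuse instances with more than this many paths.
#' @return List with `paths` (`M^N x N` matrix), `log_joint`, `log_evidence`,
#'   `counts` (per-path counts under `spec`), `feasible` (per-path flags,
#'   restricted excursions only), `count_posterior` (named vector over
#'   `k = 0..max`), `site_marginals` and `pair_marginals`.
#' @export
enumerate_posterior <- function(model, y, spec = counting_standard(),
                                cap = 60000) {
  y <- validate_observations(model, y)
  N <- length(y); M <- model$M
  if (M^N > cap)
    stop("enumeration refused: M^N = ", M^N, " exceeds cap ", cap)
  P <- M^N
  idx <- 0:(P - 1L)
  paths <- matrix(0L, P, N)
  for (n in seq_len(N)) {
    paths[, n] <- (idx %% M) + 1L
    idx <- idx %/% M
  }
  logB <- log_emissions(model, y)
  lA <- log_safe(model$A); lpi <- log_safe(model$pi0)
  lj <- lpi[paths[, 1L]] + logB[cbind(1L, paths[, 1L])]
  if (N > 1L) for (n in 2:N)
    lj <- lj + lA[cbind(paths[, n - 1L], paths[, n])] + logB[cbind(n, paths[, n])]
  lZ <- logsumexp(lj)
  post <- exp(lj - lZ)

  if (spec$variant %in% c("excursion", "restricted_excursion")) {
    u <- lapply(seq_len(P), function(i) count_excursions(paths[i, ], spec))
    counts <- vapply(u, `[[`, integer(1), "count")
    feasible <- vapply(u, `[[`, logical(1), "feasible")
  } else {
    counts <- vapply(seq_len(P), function(i) generalized_count(paths[i, ], spec),
                     integer(1))
    feasible <- rep(TRUE, P)
  }
  kmax <- max(counts)
  # restricted-excursion inference conditions on feasible paths (infeasible
  # ones get zero probability in the augmented model), so normalize there too
  pfeas <- sum(post[feasible])
  cp <- vapply(0:kmax, function(k)
    sum(post[counts == k & feasible]) / pfeas, numeric(1))
  names(cp) <- 0:kmax

  site <- matrix(0, N, M)
  for (m in seq_len(M))
    site[, m] <- colSums(post * (paths == m))
  pair <- array(0, c(max(N - 1L, 0L), M, M))
  if (N > 1L) for (n in 2:N)
    for (i in seq_len(M)) for (j in seq_len(M))
      pair[n - 1L, i, j] <- sum(post[paths[, n - 1L] == i & paths[, n] == j])

  list(paths = paths, log_joint = lj, log_evidence = lZ, counts = counts,
       feasible = feasible, count_posterior = cp,
       site_marginals = site, pair_marginals = pair)
}

#' Interval overlap ratio
#'
#' Jaccard overlap (intersection size over union size) between a predicted
#' and a ground-truth segment on integer positions (1-based inclusive
#' endpoints).
#'
#' @param pred,truth Length-2 integer vectors `c(start, end)`.
#' @return Overlap ratio in `[0, 1]`.
#' @examples
#' overlap_ratio(c(1, 10), c(6, 15))  # 1/3
#' @export
overlap_ratio <- function(pred, truth) {
  chk <- function(v, nm) {
    if (length(v) != 2L || any(is.na(v)) || v[1L] > v[2L])
      stop("'", nm, "' must be c(start, end) with start <= end")
    as.integer(v)
  }
  p <- chk(pred, "pred"); g <- chk(truth, "truth")
  inter <- max(0L, min(p[2L], g[2L]) - max(p[1L], g[1L]) + 1L)
  uni <- (p[2L] - p[1L] + 1L) + (g[2L] - g[1L] + 1L) - inter
  inter / uni
}

#' Per-document detection rate for top-k retrieval
#'
#' Counts predictions whose overlap ratio with their matched ground-truth
#' segment exceeds `threshold`, normalized by the requested list size `k`
#' (not by the number of predictions actually made).
#'
#' @param ratios Overlap ratios of the `k_p <= k` predictions.
#' @param k Requested number of retrieved segments.
#' @param threshold Correct-detection threshold (default 0.8).
#' @return Detection rate in `[0, 1]`.
#' @export
detection_rate <- function(ratios, k, threshold = 0.8) {
  if (k < 1L) stop("'k' must be >= 1")
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0, 1)")
  if (length(ratios) > k) stop("more predictions than the list size 'k'")
  sum(ratios > threshold) / k
}

#' Dirichlet-smoothed topic emission estimate
#'
#' The Bayesian mean estimate of a topic's word-emission distribution under a
#' uniform Dirichlet prior: `(n_v + 1) / (n + V)`.
#'
#' @param word_counts Nonnegative counts per vocabulary symbol.
#' @param V Vocabulary size; must equal `length(word_counts)`.
#' @return Probability vector of length `V`.
#' @export
estimate_topic_emissions <- function(word_counts, V) {
  if (length(word_counts) != V)
    stop("'word_counts' must have length V = ", V)
  if (any(word_counts < 0)) stop("counts must be nonnegative")
  (word_counts + 1) / (sum(word_counts) + V)
}

#' Generate labelled synthetic documents
#'
#' Generates symbol sequences from a two-topic (relevant/irrelevant) hidden
#' Markov topic model: a background document drawn from the irrelevant-topic
#' emissions with zero or more contiguous relevant-topic segments inserted at
#' recorded positions. A document is labelled relevant when at least one
#' segment was inserted.
#'
#' @param n_docs Number of documents.
#' @param relevant_prob,irrelevant_prob Emission probability vectors over the
#'   shared vocabulary for the relevant and irrelevant topic.
#' @param doc_length Words per document.
#' @param n_segments Integer vector to sample the number of inserted segments
#'   from (for relevant documents).
#' @param segment_length Integer vector to sample inserted-segment lengths
#'   from.
#' @param prop_relevant Proportion of documents that receive insertions.
#' @param seed Integer seed.
#' @return List of documents, each a list with `symbols`, `label`
#'   (`"relevant"`/`"irrelevant"`) and `segments` (data frame with 1-based
#'   inclusive `start`, `end`).
#' @export
synth_documents <- function(n_docs, relevant_prob, irrelevant_prob,
                            doc_length = 200L, n_segments = 1:2,
                            segment_length = 20:40, prop_relevant = 0.5,
                            seed) {
  V <- length(relevant_prob)
  if (length(irrelevant_prob) != V)
    stop("emission vectors must share one vocabulary")
  if (max(segment_length) * max(n_segments) > doc_length)
    stop("inserted segments cannot exceed the document length")
  set.seed(seed)
  n_rel <- round(n_docs * prop_relevant)
  labels <- rep(c("relevant", "irrelevant"), c(n_rel, n_docs - n_rel))
  lapply(seq_len(n_docs), function(d) {
    sym <- sample.int(V, doc_length, replace = TRUE, prob = irrelevant_prob)
    segs <- data.frame(start = integer(0), end = integer(0))
    if (labels[d] == "relevant") {
      ns <- if (length(n_segments) > 1L) sample(n_segments, 1L) else n_segments
      # split the document into ns blocks and insert one segment per block so
      # that inserted segments never touch (runs stay distinct)
      bounds <- floor(seq(0L, doc_length, length.out = ns + 1L))
      for (b in seq_len(ns)) {
        len <- if (length(segment_length) > 1L) sample(segment_length, 1L)
               else segment_length
        lo <- bounds[b] + 1L + (b > 1L)  # keep a gap between blocks
        hi <- bounds[b + 1L] - len
        if (hi < lo) next
        st <- if (hi > lo) sample(lo:hi, 1L) else lo
        en <- st + len - 1L
        sym[st:en] <- sample.int(V, len, replace = TRUE, prob = relevant_prob)
        segs <- rbind(segs, data.frame(start = st, end = en))
      }
    }
    label <- if (nrow(segs)) "relevant" else "irrelevant"
    list(symbols = sym, label = label, segments = segs)
  })
}

#' Segmental classification error with label matching
#'
#' Fraction of positions where a predicted path disagrees with the
#' ground-truth path, minimized over one-to-one relabelings of the predicted
#' states (estimated state labels are only identified up to permutation).
#'
#' @param pred,truth Integer state paths of equal length.
#' @return Misclassification rate in `[0, 1]`.
#' @export
classification_error <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("paths must have equal length")
  M <- max(pred, truth)
  perms <- permutations_of(M)
  errs <- vapply(perms, function(p) mean(p[pred] != truth), numeric(1))
  min(errs)
}

permutations_of <- function(M) {
  if (M == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(M)) {
    rest <- permutations_of(M - 1L)
    out <- c(out, lapply(rest, function(p) {
      q <- seq_len(M)[-i]
      c(i, q[p])
    }))
  }
  out
}

#' Fit a two-topic hidden Markov topic model to one document
#'
#' EM fit of the document-specific parameters (initial distribution,
#' transition matrix, irrelevant-topic emissions) with the relevant-topic
#' emission row held fixed, using add-one Dirichlet smoothing so that MAP
#' point estimates mirror the supervised topic estimator.
#'
#' @param symbols Integer word sequence.
#' @param relevant_prob Fixed emission distribution of the relevant topic
#'   (state 1).
#' @param smooth Dirichlet pseudo-count for the free emission row.
#' @param ... Passed to [em_fit()]'s engine (`tol`, `max_iter`).
#' @return An `"hmm_em"` object; state 1 is the relevant topic.
#' @export
fit_topic_hmm <- function(symbols, relevant_prob, smooth = 1, ...) {
  V <- length(relevant_prob)
  freq <- (tabulate(symbols, V) + 1) / (length(symbols) + V)
  init <- hmm(c(0.5, 0.5),
              matrix(c(0.95, 0.05, 0.05, 0.95), 2L, byrow = TRUE),
              emission_categorical(rbind(relevant_prob, freq)))
  res <- em_engine(init, symbols, smooth = smooth, fixed_states = 1L, ...)
  structure(c(res, list(event = NULL, spec = NULL)), class = "hmm_em")
}
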