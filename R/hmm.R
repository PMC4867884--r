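#' Construct a hidden Markov model
#'
#' Builds a discrete-state HMM with `M` hidden states, an initial state
#' distribution, a row-stochastic transition matrix and a per-state emission
#' family (Gaussian or categorical).
#'
#' @param pi0 Numeric vector of length `M`; initial state probabilities.
#' @param A Numeric `M x M` row-stochastic transition matrix; `A[i, j]` is the
#'   probability of moving from state `i` to state `j`.
#' @param emission An emission specification from [emission_gaussian()] or
#'   [emission_categorical()].
#' @return An object of class `"hmm"`: a list with elements `M`, `pi0`, `A`
#'   and `emission`.
#' @examples
#' m <- hmm(pi0 = c(0.5, 0.5),
#'          A = matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
#'          emission = emission_gaussian(mean = c(-1, 1), var = c(1, 1)))
#' m
#' @export
hmm <- function(pi0, A, emission) {
  pi0 <- as.numeric(pi0)
  A <- as.matrix(A)
  M <- length(pi0)
  if (M < 1L) stop("model must have at least one state")
  if (!is.numeric(A) || nrow(A) != M || ncol(A) != M)
    stop("'A' must be a numeric ", M, " x ", M, " matrix")
  if (any(pi0 < 0) || any(A < 0))
    stop("probabilities must be nonnegative")
  if (abs(sum(pi0) - 1) > 1e-8)
    stop("'pi0' must sum to 1 (found ", format(sum(pi0)), ")")
  rs <- rowSums(A)
  bad <- which(abs(rs - 1) > 1e-8)
  if (length(bad))
    stop("row ", bad[1L], " of 'A' must sum to 1 (found ", format(rs[bad[1L]]), ")")
  if (!inherits(emission, "hmm_emission"))
    stop("'emission' must be created with emission_gaussian() or emission_categorical()")
  nst <- if (emission$family == "gaussian") length(emission$mean) else nrow(emission$prob)
  if (nst != M)
    stop("emission parameters are for ", nst, " states but the model has ", M)
  structure(list(M = M, pi0 = pi0, A = A, emission = emission), class = "hmm")
}

#' Gaussian emission specification
#'
#' @param mean Numeric vector of per-state means.
#' @param var Numeric vector of per-state variances (> 0).
#' @return An object of class `"hmm_emission"`.
#' @export
emission_gaussian <- function(mean, var) {
  mean <- as.numeric(mean); var <- as.numeric(var)
  if (length(var) == 1L) var <- rep(var, length(mean))
  if (length(mean) != length(var))
    stop("'mean' and 'var' must have the same length")
  if (any(var <= 0)) stop("variances must be > 0")
  structure(list(family = "gaussian", mean = mean, var = var),
            class = "hmm_emission")
}

#' Categorical emission specification
#'
#' @param prob `M x V` matrix; row `m` is the emission distribution of state
#'   `m` over a vocabulary of `V` symbols.
#' @return An object of class `"hmm_emission"`.
#' @export
emission_categorical <- function(prob) {
  prob <- as.matrix(prob)
  if (any(prob < 0)) stop("emission probabilities must be nonnegative")
  rs <- rowSums(prob)
  if (any(abs(rs - 1) > 1e-8))
    stop("each emission row must sum to 1 (row ",
         which(abs(rs - 1) > 1e-8)[1L], " sums to ", format(rs[which.max(abs(rs - 1))]), ")")
  structure(list(family = "categorical", prob = prob, V = ncol(prob)),
            class = "hmm_emission")
}

#' @export
print.hmm <- function(x, ...) {
  cat("Hidden Markov model:", x$M, "states,", x$emission$family, "emissions\n")
  cat("pi0:", format(round(x$pi0, 4)), "\n")
  cat("A:\n")
  print(round(x$A, 4))
  if (x$emission$family == "gaussian") {
    cat("means:", format(round(x$emission$mean, 4)),
        " variances:", format(round(x$emission$var, 4)), "\n")
  } else {
    cat("vocabulary size:", x$emission$V, "\n")
  }
  invisible(x)
}

# N x M matrix of per-site log emission densities; validates observation type.
log_emissions <- function(model, y) {
  y <- validate_observations(model, y)
  N <- length(y); M <- model$M
  em <- model$emission
  if (em$family == "gaussian") {
    out <- vapply(seq_len(M), function(m)
      stats::dnorm(y, em$mean[m], sqrt(em$var[m]), log = TRUE), numeric(N))
  } else {
    lp <- log(em$prob)
    out <- t(lp[, y, drop = FALSE])
  }
  matrix(out, nrow = N, ncol = M)
}

validate_observations <- function(model, y) {
  if (is.list(y) && !is.null(y$values)) y <- y$values
  y <- as.vector(y)
  if (length(y) < 1L) stop("observation sequence must have length >= 1")
  if (model$emission$family == "gaussian") {
    if (!is.numeric(y)) stop("gaussian emissions require numeric observations")
    y <- as.numeric(y)
  } else {
    if (any(y != round(y)))
      stop("categorical emissions require integer symbol indices")
    y <- as.integer(y)
    if (any(y < 1L) || any(y > model$emission$V))
      stop("symbols must lie in 1..V (V = ", model$emission$V, ")")
  }
  y
}

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

log_safe <- function(p) ifelse(p > 0, log(p), -Inf)

# Trivial one-value counting chain: reduces the augmented DP to the plain HMM.
trivial_chain <- function(M) {
  list(variant = 0L, C = matrix(0L, M, M), s_init = integer(M),
       is_null = logical(M), cap = 0L)
}

#' Forward-backward recursion
#'
#' Computes log-domain forward and backward messages and the log-evidence
#' `log p(y)` for an HMM, from which posterior state marginals follow.
#'
#' @param model An [hmm()] object.
#' @param y Observation sequence (numeric vector, or integer symbols for
#'   categorical emissions).
#' @return An object of class `"hmm_fb"` with elements `log_alpha`,
#'   `log_beta` (`N x M` matrices), `log_evidence` and `marginals`
#'   (`N x M` matrix of `p(x_n = m | y)`).
#' @export
forward_backward <- function(model, y) {
  y <- validate_observations(model, y)
  logB <- log_emissions(model, y)
  tc <- trivial_chain(model$M)
  fw <- kseg_forward_cpp(logB, log_safe(model$pi0), log_safe(model$A),
                         tc$s_init, tc$variant, tc$C, tc$is_null, tc$cap, TRUE)
  la <- matrix(fw$alpha, nrow = model$M)  # M x N
  loglik <- logsumexp(la[, ncol(la)])
  if (loglik == -Inf)
    stop("degenerate evidence: the model assigns zero likelihood to 'y'")
  bw <- kseg_backward_cpp(logB, log_safe(model$A), tc$s_init, tc$variant,
                          tc$C, tc$is_null, tc$cap, TRUE)
  lb <- matrix(bw, nrow = model$M)
  marg <- exp(t(la) + t(lb) - loglik)
  marg <- marg / rowSums(marg)
  structure(list(log_alpha = t(la), log_beta = t(lb),
                 log_evidence = loglik, marginals = marg,
                 N = length(y), M = model$M),
            class = "hmm_fb")
}

#' @export
print.hmm_fb <- function(x, ...) {
  cat("Forward-backward messages: N =", x$N, ", M =", x$M, "\n")
  cat("log p(y) =", format(x$log_evidence), "\n")
  invisible(x)
}

#' Viterbi decoding
#'
#' Finds the maximum a posteriori hidden state sequence. Ties are broken
#' deterministically toward smaller state indices during backtracking.
#'
#' @inheritParams forward_backward
#' @return An object of class `"hmm_path"`: list with `path` (integer vector
#'   of states) and `log_score` (`log p(y | x*) p(x*)`).
#' @export
viterbi <- function(model, y) {
  y <- validate_observations(model, y)
  logB <- log_emissions(model, y)
  tc <- trivial_chain(model$M)
  vt <- kseg_viterbi_cpp(logB, log_safe(model$pi0), log_safe(model$A),
                         tc$s_init, tc$variant, tc$C, tc$is_null, tc$cap)
  sc <- vt$scores[1L]
  if (sc == -Inf)
    stop("degenerate evidence: the model assigns zero likelihood to 'y'")
  structure(list(path = as.integer(vt$paths[1L, ]), log_score = sc),
            class = "hmm_path")
}

#' @export
print.hmm_path <- function(x, ...) {
  cat("MAP path:", length(x$path), "positions,",
      count_segments(x$path), "segments, log score", format(x$log_score), "\n")
  invisible(x)
}

#' Posterior path sampling (forward filtering, backward sampling)
#'
#' Draws independent hidden paths from `p(x | y)`. Uniform random draws are
#' consumed in position order `n = N..1` for each sample, so streams are
#' reproducible given the seed.
#'
#' @inheritParams forward_backward
#' @param n_samples Number of independent paths to draw.
#' @param seed Integer seed for the random draws.
#' @return Integer matrix `n_samples x N`; row `i` is the i-th sampled path.
#' @export
ffbs_sample <- function(model, y, n_samples, seed) {
  if (n_samples < 1L) stop("'n_samples' must be >= 1")
  y <- validate_observations(model, y)
  logB <- log_emissions(model, y)
  tc <- trivial_chain(model$M)
  fw <- kseg_forward_cpp(logB, log_safe(model$pi0), log_safe(model$A),
                         tc$s_init, tc$variant, tc$C, tc$is_null, tc$cap, TRUE)
  if (logsumexp(fw$last) == -Inf)
    stop("degenerate evidence: the model assigns zero likelihood to 'y'")
  set.seed(seed)
  U <- matrix(stats::runif(n_samples * length(y)), nrow = n_samples, byrow = TRUE)
  kseg_sample_cpp(fw$alpha, log_safe(model$A), tc$variant, tc$C, tc$is_null,
                  tc$cap, TRUE, U)
}

#' Best-list (top-P) Viterbi decoding
#'
#' Extracts the `P` distinct hidden paths with the largest posterior
#' probability, exactly, by Lawler-style partitioning on the first point of
#' divergence from already-extracted paths.
#'
#' @inheritParams forward_backward
#' @param P Number of paths to extract.
#' @return List with `paths` (integer matrix, one row per path, best first)
#'   and `log_scores` (nonincreasing joint log scores `log p(y | x) p(x)`).
#' @export
best_list_viterbi <- function(model, y, P) {
  if (P < 1L) stop("'P' must be >= 1")
  y <- validate_observations(model, y)
  logB <- log_emissions(model, y)
  M <- model$M; N <- length(y)
  lA <- log_safe(model$A); lpi <- log_safe(model$pi0)

  # bmax[n, m]: best log score of a suffix starting in state m at position n
  # (emissions from n+1 on; emission at n accounted separately)
  bmax <- matrix(-Inf, N, M)
  bmax[N, ] <- 0
  if (N > 1L) for (n in (N - 1L):1L)
    for (m in seq_len(M))
      bmax[n, m] <- max(lA[m, ] + logB[n + 1L, ] + bmax[n + 1L, ])

  complete_from <- function(prefix, j, allowed) {
    # extend prefix (length j) greedily along bmax; position j+1 restricted
    path <- integer(N)
    if (j > 0L) path[seq_len(j)] <- prefix
    for (n in (j + 1L):N) {
      if (n == 1L) {
        sc <- lpi + logB[1L, ] + bmax[1L, ]
      } else {
        sc <- lA[path[n - 1L], ] + logB[n, ] + bmax[n, ]
      }
      if (n == j + 1L) sc[!allowed] <- -Inf
      if (all(sc == -Inf)) return(NULL)
      path[n] <- which.max(sc)  # which.max: smallest index on ties
    }
    path
  }
  path_score <- function(path) {
    s <- lpi[path[1L]] + logB[1L, path[1L]]
    if (N > 1L)
      s <- s + sum(lA[cbind(path[-N], path[-1L])]) + sum(logB[cbind(2:N, path[-1L])])
    s
  }

  queue <- list()
  push <- function(j, allowed, prefix) {
    path <- complete_from(prefix, j, allowed)
    if (is.null(path)) return(invisible(NULL))
    queue[[length(queue) + 1L]] <<- list(path = path, score = path_score(path),
                                         j = j, allowed = allowed)
    invisible(NULL)
  }
  push(0L, rep(TRUE, M), integer(0))

  paths <- matrix(NA_integer_, 0L, N)
  scores <- numeric(0)
  while (nrow(paths) < P && length(queue)) {
    best <- which.max(vapply(queue, `[[`, numeric(1), "score"))
    node <- queue[[best]]
    queue[[best]] <- NULL
    paths <- rbind(paths, node$path)
    scores <- c(scores, node$score)
    # children: fix a longer prefix of this path, exclude its next state
    for (i in (node$j + 1L):N) {
      allowed <- rep(TRUE, M)
      if (i == node$j + 1L) allowed <- node$allowed
      allowed[node$path[i]] <- FALSE
      push(i - 1L, allowed, node$path[seq_len(i - 1L)])
    }
  }
  if (nrow(paths) < P)
    warning("only ", nrow(paths), " distinct paths exist; returning all of them")
  dimnames(paths) <- NULL
  list(paths = paths, log_scores = scores)
}
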