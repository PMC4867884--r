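#' Counting specifications
#'
#' A counting specification says which features of a hidden path are tallied
#' by the auxiliary counting Markov chain:
#'
#' * `counting_standard()`: every segment (maximal run of identical states)
#'   counts; the counter starts at 1 on the initial segment.
#' * `counting_generalized(mu, C)`: segment counting restricted by a binary
#'   initial-state mask `mu` (which initial states open a counted segment)
#'   and a binary transition-coloring matrix `C` with zero diagonal (which
#'   transitions open a counted segment). The count of a path is
#'   `mu[x_1] + sum_n C[x_{n-1}, x_n]`. Standard counting is the special case
#'   `mu = 1`, `C[i, j] = 1(i != j)`.
#' * `counting_excursion(null_states)`: counts completed excursions, i.e.
#'   subpaths that leave the null set into abnormal states and return to the
#'   null set. With `restricted = TRUE` the excursion may not switch between
#'   different abnormal states mid-flight; paths that do are infeasible under
#'   the augmented model.
#'
#' @param mu Binary vector of length `M`.
#' @param C Binary `M x M` matrix with zero diagonal.
#' @param null_states Integer vector: nonempty proper subset of `1..M`.
#' @param restricted Logical; forbid switching abnormal states mid-excursion.
#' @return An object of class `"counting_spec"`.
#' @export
counting_standard <- function() {
  structure(list(variant = "standard"), class = "counting_spec")
}

#' @rdname counting_standard
#' @export
counting_generalized <- function(mu, C) {
  mu <- as.integer(mu); C <- as.matrix(C)
  storage.mode(C) <- "integer"
  if (any(!mu %in% c(0L, 1L))) stop("'mu' must be binary")
  if (any(!C %in% c(0L, 1L))) stop("'C' must be binary")
  if (nrow(C) != ncol(C) || nrow(C) != length(mu))
    stop("'C' must be M x M with M = length(mu)")
  if (any(diag(C) != 0L)) stop("'C' must have a zero diagonal")
  structure(list(variant = "generalized", mu = mu, C = C),
            class = "counting_spec")
}

#' @rdname counting_standard
#' @export
counting_excursion <- function(null_states, restricted = FALSE) {
  null_states <- sort(unique(as.integer(null_states)))
  if (!length(null_states)) stop("'null_states' must be nonempty")
  structure(list(variant = if (restricted) "restricted_excursion" else "excursion",
                 null_states = null_states),
            class = "counting_spec")
}

#' @export
print.counting_spec <- function(x, ...) {
  cat("Counting spec:", x$variant, "\n")
  if (x$variant == "generalized") {
    cat("mu:", x$mu, "\n"); cat("C:\n"); print(x$C)
  } else if (x$variant %in% c("excursion", "restricted_excursion")) {
    cat("null states:", x$null_states, "\n")
  }
  invisible(x)
}

# Validate spec against a state count and return low-level DP arguments.
spec_dp_args <- function(spec, M) {
  v <- spec$variant
  if (v == "standard") {
    list(variant = 0L, C = matrix(1L, M, M) - diag(M),
         s_init = rep(1L, M), is_null = logical(M), k_min = 1L)
  } else if (v == "generalized") {
    if (length(spec$mu) != M)
      stop("counting spec is for ", length(spec$mu), " states but the model has ", M)
    list(variant = 0L, C = spec$C, s_init = spec$mu,
         is_null = logical(M), k_min = 0L)
  } else {
    ns <- spec$null_states
    if (any(ns < 1L) || any(ns > M) || length(ns) >= M)
      stop("'null_states' must be a nonempty proper subset of 1..", M)
    list(variant = if (v == "excursion") 1L else 2L,
         C = matrix(0L, M, M), s_init = integer(M),
         is_null = seq_len(M) %in% ns, k_min = 0L)
  }
}

#' Count segments in a hidden path
#'
#' The number of segments is one plus the number of positions where the state
#' changes, i.e. the number of maximal constant runs.
#'
#' @param x Integer vector of hidden states.
#' @return Integer segment count.
#' @examples
#' count_segments(c(1, 1, 2, 2, 2, 3))  # 3
#' @export
count_segments <- function(x) {
  x <- as.integer(x)
  if (!length(x)) stop("empty path")
  1L + sum(x[-1L] != x[-length(x)])
}

#' Generalized segment count under a (mu, C) specification
#'
#' @param x Integer vector of hidden states.
#' @param spec A [counting_generalized()] (or standard) specification.
#' @return Integer count `mu[x_1] + sum_n C[x_{n-1}, x_n]`.
#' @export
generalized_count <- function(x, spec) {
  x <- as.integer(x)
  if (!length(x)) stop("empty path")
  if (spec$variant == "standard") return(count_segments(x))
  if (spec$variant != "generalized") stop("spec must be standard or generalized")
  if (max(x) > length(spec$mu)) stop("path states exceed spec dimension")
  n <- length(x)
  cnt <- spec$mu[x[1L]]
  if (n > 1L) cnt <- cnt + sum(spec$C[cbind(x[-n], x[-1L])])
  as.integer(cnt)
}

#' Count completed excursions in a hidden path
#'
#' Unrolls the deterministic excursion phase chain and counts its 1 -> 0
#' transitions (completed returns to the null set). An excursion still open at
#' the end of the path is not counted. For restricted excursions, a path that
#' switches between different abnormal states mid-excursion is infeasible.
#'
#' @param x Integer vector of hidden states.
#' @param spec A [counting_excursion()] specification.
#' @return List with `count` (integer) and `feasible` (logical; always `TRUE`
#'   for unrestricted excursions).
#' @export
count_excursions <- function(x, spec) {
  if (!spec$variant %in% c("excursion", "restricted_excursion"))
    stop("spec must be an excursion variant")
  u <- unroll_counter(x, spec)
  list(count = u$s[length(u$s)], feasible = u$feasible)
}

#' Unroll the counting chain along a fixed path
#'
#' Evaluates the deterministic auxiliary chain conditionals step by step,
#' returning the counter trajectory `s` (and excursion phase `e` where
#' applicable). This is the chain-based counterpart of the direct count
#' formulas and is used to cross-check them.
#'
#' @param x Integer vector of hidden states.
#' @param spec A counting specification.
#' @return List with `s` (integer vector), `e` (integer vector or `NULL`) and
#'   `feasible` (logical).
#' @export
unroll_counter <- function(x, spec) {
  x <- as.integer(x)
  if (!length(x)) stop("empty path")
  n <- length(x)
  v <- spec$variant
  if (v %in% c("standard", "generalized")) {
    if (v == "standard") {
      inc <- c(0L, as.integer(x[-1L] != x[-n]))
      s1 <- 1L
    } else {
      inc <- c(0L, spec$C[cbind(x[-n], x[-1L])])
      s1 <- spec$mu[x[1L]]
    }
    s <- s1 + cumsum(inc)
    return(list(s = as.integer(s), e = NULL, feasible = TRUE))
  }
  ns <- spec$null_states
  isnull <- function(state) state %in% ns
  e <- integer(n); s <- integer(n); feasible <- TRUE
  e[1L] <- 0L; s[1L] <- 0L
  if (n > 1L) for (i in 2:n) {
    pn <- isnull(x[i - 1L]); cn <- isnull(x[i])
    if (pn && !cn) {
      e[i] <- 1L
    } else if (!pn && cn) {
      e[i] <- 0L
    } else {
      if (v == "restricted_excursion" && e[i - 1L] == 1L && x[i - 1L] != x[i]) {
        feasible <- FALSE
        e[i] <- 2L  # phase variable leaves {0, 1}
      } else {
        e[i] <- e[i - 1L]
      }
    }
    s[i] <- s[i - 1L] + as.integer(e[i - 1L] == 1L && e[i] == 0L)
  }
  list(s = s, e = e, feasible = feasible)
}

#' Build the augmented counting-chain conditionals
#'
#' Returns the deterministic conditional structure of the counting chain for a
#' model/spec pair: the initial counter value per state and a one-step
#' transition function, with the counter absorbing at `k_max + 1`. Unrolling
#' this structure along any path reproduces the corresponding count function,
#' and marginalizing the auxiliary variables recovers the original chain.
#'
#' @param spec A counting specification.
#' @param M Number of hidden states.
#' @param k_max Absorbing cap: the counter stops at `k_max + 1`.
#' @return List with `s_init` (length-`M` integer vector), `cap`
#'   (`k_max + 1`), `k_min`, and `step(x_prev, x_cur, s_prev, e_prev)`
#'   returning `list(s, e, feasible)`.
#' @export
augmented_chain <- function(spec, M, k_max) {
  if (k_max < 0L) stop("'k_max' must be >= 0")
  args <- spec_dp_args(spec, M)
  cap <- as.integer(k_max) + 1L
  ns <- if (args$variant > 0L) which(args$is_null) else integer(0)
  step <- function(x_prev, x_cur, s_prev, e_prev = 0L) {
    if (args$variant == 0L) {
      inc <- args$C[x_prev, x_cur]; e_new <- 0L; feas <- TRUE
    } else {
      pn <- x_prev %in% ns; cn <- x_cur %in% ns
      if (pn && !cn) {
        e_new <- 1L; inc <- 0L; feas <- TRUE
      } else if (!pn && cn) {
        e_new <- 0L; inc <- as.integer(e_prev == 1L); feas <- TRUE
      } else if (args$variant == 2L && e_prev == 1L && x_prev != x_cur) {
        e_new <- 2L; inc <- 0L; feas <- FALSE
      } else {
        e_new <- e_prev; inc <- 0L; feas <- TRUE
      }
    }
    s <- if (s_prev >= cap) cap else s_prev + inc
    list(s = as.integer(s), e = e_new, feasible = feas)
  }
  list(s_init = pmin(args$s_init, cap), cap = cap, k_min = args$k_min,
       step = step)
}
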