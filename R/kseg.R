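#' @useDynLib ksegment, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Assemble all low-level DP inputs for a model / spec / cap combination.
kseg_dp_inputs <- function(model, y, spec, cap) {
  y <- validate_observations(model, y)
  args <- spec_dp_args(spec, model$M)
  list(y = y, logB = log_emissions(model, y),
       lpi0 = log_safe(model$pi0), lA = log_safe(model$A),
       args = args, cap = as.integer(cap))
}

infeasible_error <- function(event) {
  stop(structure(class = c("ksegment_infeasible", "error", "condition"),
                 list(message = paste0("event {", format(event),
                                       "} has zero posterior probability"),
                      call = sys.call(-1))))
}

#' Exact posterior distribution over segment counts
#'
#' Computes `p(c = k | y)` for `k` up to `k_max` exactly, plus the tail mass
#' `p(c > k_max | y)`, by a single forward pass on the counting-augmented HMM
#' with the counter absorbing at `k_max + 1`. Cost is
#' `O((k_max + 1) M^2 N)`.
#'
#' @inheritParams forward_backward
#' @param spec A counting specification (default: standard segment counting).
#' @param k_max Largest count reported exactly.
#' @return An object of class `"segment_posterior"`: list with `k`
#'   (`k_min..k_max`), `p`, `log_p`, `tail` (`p(c > k_max | y)`),
#'   `log_evidence` and `spec`.
#' @export
kseg_forward <- function(model, y, spec = counting_standard(), k_max) {
  if (k_max < 1L) stop("'k_max' must be >= 1")
  dp <- kseg_dp_inputs(model, y, spec, k_max + 1L)
  fw <- kseg_forward_cpp(dp$logB, dp$lpi0, dp$lA, dp$args$s_init,
                         dp$args$variant, dp$args$C, dp$args$is_null,
                         dp$cap, FALSE)
  last <- fw$last  # M x E x S
  log_joint <- apply(last, 3L, logsumexp)  # log p(s_N = s, y), s = 0..cap
  loglik <- logsumexp(log_joint)
  if (loglik == -Inf)
    stop("degenerate evidence: the model assigns zero likelihood to 'y'")
  k_min <- dp$args$k_min
  ks <- seq.int(k_min, k_max)
  log_p <- log_joint[ks + 1L] - loglik
  structure(list(k = ks, p = exp(log_p), log_p = log_p,
                 tail = exp(log_joint[dp$cap + 1L] - loglik),
                 log_joint = log_joint, log_evidence = loglik, spec = spec,
                 k_max = k_max),
            class = "segment_posterior")
}

#' @export
print.segment_posterior <- function(x, digits = 4, ...) {
  cat("Posterior over segment counts (", x$spec$variant, " counting)\n", sep = "")
  cat("log p(y) =", format(x$log_evidence), "\n")
  df <- data.frame(k = x$k, p = round(x$p, digits), log_p = round(x$log_p, digits))
  print(df, row.names = FALSE)
  cat(sprintf("p(c > %d | y) = %.*f\n", x$k_max, digits, x$tail))
  invisible(x)
}

#' @export
plot.segment_posterior <- function(x, ...) {
  graphics::barplot(c(x$p, x$tail),
                    names.arg = c(x$k, paste0(">", x$k_max)),
                    xlab = "number of segments k", ylab = "p(c = k | y)", ...)
  invisible(x)
}

#' Constrained MAP decoding
#'
#' Finds the hidden path maximizing `p(y | x) p(x)` among paths whose segment
#' count satisfies the event, via the Viterbi recursion on the
#' counting-augmented HMM. Ties are broken lexicographically on the extended
#' state (smaller counter, then smaller state index).
#'
#' @inheritParams kseg_forward
#' @param event A [segment_event][event_exactly] (or a string for
#'   [parse_event()]).
#' @return An object of class `"kseg_path"`: list with `path`, `log_score`
#'   (joint `log p(y | x) p(x)`), `count` and `event`. An infeasible event
#'   raises an error of class `"ksegment_infeasible"`.
#' @export
kseg_viterbi <- function(model, y, spec = counting_standard(), event) {
  if (is.character(event)) event <- parse_event(event)
  dp0 <- spec_dp_args(spec, model$M)
  ed <- event_dp(event, dp0, length(y))
  dp <- kseg_dp_inputs(model, y, spec, ed$cap)
  vt <- kseg_viterbi_cpp(dp$logB, dp$lpi0, dp$lA, dp$args$s_init,
                         dp$args$variant, dp$args$C, dp$args$is_null, dp$cap)
  sc <- vt$scores
  sc[!ed$allowed] <- -Inf
  if (all(sc == -Inf)) infeasible_error(event)
  best_s <- which.max(sc)  # smallest terminal counter on ties
  path <- as.integer(vt$paths[best_s, ])
  structure(list(path = path, log_score = sc[best_s],
                 count = spec_count(path, spec), event = event, spec = spec),
            class = "kseg_path")
}

#' @export
print.kseg_path <- function(x, ...) {
  cat("Constrained MAP path under {", format(x$event), "}: count ",
      x$count, ", log score ", format(x$log_score), "\n", sep = "")
  invisible(x)
}

spec_count <- function(path, spec) {
  if (spec$variant %in% c("excursion", "restricted_excursion"))
    count_excursions(path, spec)$count
  else generalized_count(path, spec)
}

#' k_max + 1 summary of the posterior
#'
#' One constrained Viterbi pass returning the MAP path for every segment
#' count `k = k_min..k_max` together with the MAP path under `c > k_max`
#' (the absorbing entry), in overall `O(k_max M^2 N)` time. The summary is
#' guaranteed to contain the standard Viterbi path: it shows up at the entry
#' whose `k` equals its own count, or at the absorbing entry when that count
#' exceeds `k_max`.
#'
#' @inheritParams kseg_forward
#' @return An object of class `"kseg_summary"`: list with `k`, `paths`
#'   (matrix, one row per `k`; `NA` rows for infeasible counts), `scores`
#'   (`-Inf` for infeasible counts), `absorbing_path`, `absorbing_score` and
#'   `spec`.
#' @export
kseg_summary <- function(model, y, spec = counting_standard(), k_max) {
  if (k_max < 1L) stop("'k_max' must be >= 1")
  dp <- kseg_dp_inputs(model, y, spec, k_max + 1L)
  vt <- kseg_viterbi_cpp(dp$logB, dp$lpi0, dp$lA, dp$args$s_init,
                         dp$args$variant, dp$args$C, dp$args$is_null, dp$cap)
  k_min <- dp$args$k_min
  ks <- seq.int(k_min, k_max)
  structure(list(k = ks,
                 paths = vt$paths[ks + 1L, , drop = FALSE],
                 scores = vt$scores[ks + 1L],
                 absorbing_path = as.integer(vt$paths[dp$cap + 1L, ]),
                 absorbing_score = vt$scores[dp$cap + 1L],
                 k_max = k_max, spec = spec),
            class = "kseg_summary")
}

#' @export
print.kseg_summary <- function(x, ...) {
  cat("k-segment summary (", x$spec$variant, " counting), k = ",
      min(x$k), "..", x$k_max, " plus absorbing entry\n", sep = "")
  df <- data.frame(k = c(x$k, paste0(">", x$k_max)),
                   log_score = c(x$scores, x$absorbing_score),
                   feasible = c(is.finite(x$scores), is.finite(x$absorbing_score)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.kseg_summary <- function(x, y = NULL, ...) {
  feas <- is.finite(x$scores)
  paths <- x$paths[feas, , drop = FALSE]
  N <- ncol(paths)
  graphics::image(seq_len(N), seq_len(nrow(paths)), t(paths),
                  xlab = "position", ylab = "k (feasible entries)",
                  yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nrow(paths)), labels = x$k[feas])
  invisible(x)
}

#' Constrained posterior path sampling
#'
#' Draws independent hidden paths from the event-conditioned posterior
#' `p(x | event, y)` by forward filtering / backward sampling on the
#' counting-augmented HMM. Every returned path satisfies the event.
#'
#' @inheritParams kseg_viterbi
#' @param n_samples Number of independent draws.
#' @param seed Integer seed; draws are consumed in position order `n = N..1`
#'   per sample.
#' @return Integer matrix `n_samples x N` of sampled paths.
#' @export
kseg_sample <- function(model, y, spec = counting_standard(), event,
                        n_samples, seed) {
  if (n_samples < 1L) stop("'n_samples' must be >= 1")
  if (is.character(event)) event <- parse_event(event)
  dp0 <- spec_dp_args(spec, model$M)
  ed <- event_dp(event, dp0, length(y))
  dp <- kseg_dp_inputs(model, y, spec, ed$cap)
  fw <- kseg_forward_cpp(dp$logB, dp$lpi0, dp$lA, dp$args$s_init,
                         dp$args$variant, dp$args$C, dp$args$is_null,
                         dp$cap, TRUE)
  lz <- logsumexp(fw$last[, , which(ed$allowed), drop = FALSE])
  if (lz == -Inf) infeasible_error(event)
  set.seed(seed)
  U <- matrix(stats::runif(n_samples * length(dp$y)), nrow = n_samples,
              byrow = TRUE)
  kseg_sample_cpp(fw$alpha, dp$lA, dp$args$variant, dp$args$C,
                  dp$args$is_null, dp$cap, ed$allowed, U)
}

#' Event-conditioned state marginals
#'
#' Computes the site marginals `p(x_n | event, y)` and pairwise marginals
#' `p(x_{n-1}, x_n | event, y)` by forward-backward on the augmented HMM,
#' summing out the auxiliary counting variables.
#'
#' @inheritParams kseg_viterbi
#' @return List with `site` (`N x M` matrix), `pair` (`(N-1) x M x M` array)
#'   and `log_evidence_event` (`log p(event, y)`).
#' @export
constrained_marginals <- function(model, y, spec = counting_standard(), event) {
  if (is.character(event)) event <- parse_event(event)
  dp0 <- spec_dp_args(spec, model$M)
  ed <- event_dp(event, dp0, length(y))
  dp <- kseg_dp_inputs(model, y, spec, ed$cap)
  fw <- kseg_forward_cpp(dp$logB, dp$lpi0, dp$lA, dp$args$s_init,
                         dp$args$variant, dp$args$C, dp$args$is_null,
                         dp$cap, TRUE)
  lz <- logsumexp(fw$last[, , which(ed$allowed), drop = FALSE])
  if (lz == -Inf) infeasible_error(event)
  bw <- kseg_backward_cpp(dp$logB, dp$lA, dp$args$s_init, dp$args$variant,
                          dp$args$C, dp$args$is_null, dp$cap, ed$allowed)
  mg <- kseg_marginals_cpp(dp$logB, dp$lA, fw$alpha, bw, dp$args$variant,
                           dp$args$C, dp$args$is_null, dp$cap, lz)
  list(site = mg$gamma, pair = mg$pair, log_evidence_event = lz,
       event = event, spec = spec)
}

#' Log probability of a segment-count event
#'
#' Convenience wrapper returning `log p(event, y)` and `log p(event | y)`.
#'
#' @inheritParams kseg_viterbi
#' @return List with `log_joint`, `log_conditional` and `log_evidence`.
#' @export
event_log_prob <- function(model, y, spec = counting_standard(), event) {
  if (is.character(event)) event <- parse_event(event)
  dp0 <- spec_dp_args(spec, model$M)
  ed <- event_dp(event, dp0, length(y))
  dp <- kseg_dp_inputs(model, y, spec, ed$cap)
  fw <- kseg_forward_cpp(dp$logB, dp$lpi0, dp$lA, dp$args$s_init,
                         dp$args$variant, dp$args$C, dp$args$is_null,
                         dp$cap, FALSE)
  lz_all <- logsumexp(fw$last)
  lz <- logsumexp(fw$last[, , which(ed$allowed), drop = FALSE])
  list(log_joint = lz, log_conditional = lz - lz_all, log_evidence = lz_all)
}
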