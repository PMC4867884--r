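# Shared E/M engine for unconstrained and constrained EM.
#
# When `event` is NULL the counting chain is trivial and the objective is the
# ordinary likelihood p(y); otherwise the E-step runs forward-backward on the
# augmented HMM and the objective is p(event, y). The M-step has the same
# form in both cases. Gaussian variances are floored at 1e-8 * var(y);
# `smooth` adds a Dirichlet pseudo-count to categorical emission rows, and
# `fixed_states` (categorical only) keeps the listed emission rows fixed.
em_engine <- function(init, y, spec = NULL, event = NULL, tol = 1e-6,
                      max_iter = 500L, smooth = 0, fixed_states = integer(0)) {
  model <- init
  y <- validate_observations(model, y)
  N <- length(y); M <- model$M
  if (is.null(event)) {
    tc <- trivial_chain(M)
    args <- tc; cap <- 0L; allowed <- TRUE
  } else {
    if (is.character(event)) event <- parse_event(event)
    args <- spec_dp_args(spec, M)
    ed <- event_dp(event, args, N)
    cap <- ed$cap; allowed <- ed$allowed
  }
  amask <- rep_len(allowed, cap + 1L)
  var_floor <- if (model$emission$family == "gaussian") 1e-8 * stats::var(y) else NA

  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    logB <- log_emissions(model, y)
    fw <- kseg_forward_cpp(logB, log_safe(model$pi0), log_safe(model$A),
                           args$s_init, args$variant, args$C, args$is_null,
                           cap, TRUE)
    lz <- logsumexp(fw$last[, , which(amask), drop = FALSE])
    if (lz == -Inf) {
      if (it == 1L)
        stop("event has zero probability under the initial model; ",
             "try a different initialization or a weaker constraint")
      break
    }
    trace <- c(trace, lz)
    if (it > 1L) {
      rel <- abs(trace[it] - trace[it - 1L]) / (abs(trace[it - 1L]) + 1e-12)
      if (rel < tol) { converged <- TRUE; break }
    }
    bw <- kseg_backward_cpp(logB, log_safe(model$A), args$s_init,
                            args$variant, args$C, args$is_null, cap, amask)
    mg <- kseg_marginals_cpp(logB, log_safe(model$A), fw$alpha, bw,
                             args$variant, args$C, args$is_null, cap, lz)
    model <- em_mstep(model, y, mg$gamma, mg$pair, var_floor, smooth,
                      fixed_states)
  }
  list(model = model, trace = trace, iterations = length(trace),
       converged = converged)
}

em_mstep <- function(model, y, gamma, pair, var_floor, smooth, fixed_states) {
  M <- model$M
  pi0 <- gamma[1L, ]
  pi0 <- pi0 / sum(pi0)
  xi <- apply(pair, c(2L, 3L), sum)  # expected transition counts
  A <- matrix(0, M, M)
  for (i in seq_len(M)) {
    tot <- sum(xi[i, ])
    if (tot > 0) {
      A[i, ] <- xi[i, ] / tot
    } else {
      # no posterior mass ever leaves (or occupies) state i: the Q function is
      # flat in this row, so fix the self-transition convention rather than
      # leak the previous iterate's values into the fit
      A[i, i] <- 1
    }
  }
  em <- model$emission
  if (em$family == "gaussian") {
    w <- colSums(gamma)
    dead <- w < 1e-12  # states with no posterior mass keep their parameters
    w[dead] <- 1
    mean_new <- as.numeric(crossprod(gamma, y)) / w
    var_new <- vapply(seq_len(M), function(m)
      sum(gamma[, m] * (y - mean_new[m])^2) / w[m], numeric(1))
    mean_new[dead] <- em$mean[dead]
    var_new[dead] <- em$var[dead]
    floored <- var_new < var_floor
    if (any(floored)) {
      warning("Gaussian variance collapsed for state(s) ",
              paste(which(floored), collapse = ", "), "; floored")
      var_new[floored] <- var_floor
    }
    emission <- emission_gaussian(mean_new, var_new)
  } else {
    V <- em$V
    cnt <- matrix(smooth, M, V)
    for (v in seq_len(V)) {
      idx <- which(y == v)
      if (length(idx)) cnt[, v] <- cnt[, v] + colSums(gamma[idx, , drop = FALSE])
    }
    tot <- rowSums(cnt)
    dead <- tot < 1e-12
    prob <- cnt / ifelse(tot > 0, tot, 1)
    prob[dead, ] <- em$prob[dead, ]
    if (length(fixed_states)) prob[fixed_states, ] <- em$prob[fixed_states, ]
    emission <- emission_categorical(prob)
  }
  hmm(pi0, A, emission)
}

#' Maximum-likelihood fitting by EM (Baum-Welch)
#'
#' @param init Initial [hmm()] model (also fixes `M` and the emission family).
#' @inheritParams forward_backward
#' @param tol Relative log-likelihood change at which to stop.
#' @param max_iter Maximum EM iterations.
#' @return An object of class `"hmm_em"`: list with `model` (fitted [hmm()]),
#'   `trace` (per-iteration log-likelihood, nondecreasing), `iterations` and
#'   `converged`.
#' @export
em_fit <- function(init, y, tol = 1e-6, max_iter = 500L) {
  res <- em_engine(init, y, tol = tol, max_iter = max_iter)
  structure(c(res, list(event = NULL, spec = NULL)), class = "hmm_em")
}

#' EM under a segment-count constraint
#'
#' Fits HMM parameters maximizing `p(event, y)`: the E-step computes
#' event-conditioned marginals on the counting-augmented HMM (summing out the
#' auxiliary counting variables) and the M-step is identical in form to the
#' unconstrained one. Supports all event types; `{c<=k}` and `{c=k}` are the
#' typical uses.
#'
#' @inheritParams em_fit
#' @param spec A counting specification.
#' @param event A [segment_event][event_exactly] or event string.
#' @param smooth Dirichlet pseudo-count added to categorical emission rows.
#' @return An object of class `"hmm_em"` whose `trace` is the nondecreasing
#'   per-iteration `log p(event, y)`.
#' @export
constrained_em <- function(init, y, spec = counting_standard(), event,
                           tol = 1e-6, max_iter = 500L, smooth = 0) {
  if (is.character(event)) event <- parse_event(event)
  res <- em_engine(init, y, spec = spec, event = event, tol = tol,
                   max_iter = max_iter, smooth = smooth)
  structure(c(res, list(event = event, spec = spec)), class = "hmm_em")
}

#' @export
print.hmm_em <- function(x, ...) {
  obj <- if (is.null(x$event)) "log p(y)" else
    paste0("log p(", format(x$event), ", y)")
  cat("EM fit: ", x$iterations, " iterations, ",
      if (x$converged) "converged" else "not converged", "\n", sep = "")
  cat(obj, "=", format(x$trace[length(x$trace)]), "\n")
  print(x$model)
  invisible(x)
}

#' @export
coef.hmm_em <- function(object, ...) {
  m <- object$model
  out <- list(pi0 = m$pi0, A = m$A)
  if (m$emission$family == "gaussian") {
    out$mean <- m$emission$mean; out$var <- m$emission$var
  } else out$prob <- m$emission$prob
  out
}

#' @export
logLik.hmm_em <- function(object, ...) {
  ll <- object$trace[length(object$trace)]
  attr(ll, "df") <- NA
  class(ll) <- "logLik"
  ll
}

#' @export
plot.hmm_em <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "b",
                 xlab = "EM iteration",
                 ylab = if (is.null(x$event)) "log p(y)" else
                   paste0("log p(", format(x$event), ", y)"), ...)
  invisible(x)
}

#' Prospective versus retrospective constraints
#'
#' For each `k` in `k_grid`, compares `log p(c<=k, y)` obtained by (a)
#' constrained EM initialized at the unconstrained EM solution (prospective)
#' and (b) evaluating the unconstrained fit under the constraint
#' (retrospective). By EM monotonicity the prospective value is never below
#' the retrospective one.
#'
#' @inheritParams constrained_em
#' @param k_grid Integer vector of constraint levels.
#' @param unconstrained Optional precomputed [em_fit()] result to start from.
#' @return A data frame with columns `k`, `prospective`, `retrospective` and
#'   `gain`.
#' @export
prospective_vs_retrospective <- function(y, init, spec = counting_standard(),
                                         k_grid, tol = 1e-6, max_iter = 500L,
                                         unconstrained = NULL) {
  if (is.null(unconstrained)) unconstrained <- em_fit(init, y, tol, max_iter)
  base <- unconstrained$model
  pro <- retro <- numeric(length(k_grid))
  for (i in seq_along(k_grid)) {
    ev <- event_at_most(k_grid[i])
    retro[i] <- event_log_prob(base, y, spec, ev)$log_joint
    fit <- constrained_em(base, y, spec, ev, tol = tol, max_iter = max_iter)
    pro[i] <- fit$trace[length(fit$trace)]
  }
  data.frame(k = k_grid, prospective = pro, retrospective = retro,
             gain = pro - retro)
}

#' Conjugate prior specification for Bayesian HMM learning
#'
#' Dirichlet priors on the initial distribution and transition-matrix rows;
#' Normal-Inverse-Gamma priors on Gaussian emissions (mean | var ~
#' `N(m0, var/kappa0)`, var ~ `InvGamma(a0, b0)`); Dirichlet priors on
#' categorical emission rows. Concentration 1 everywhere by default (the
#' add-one / uniform prior).
#'
#' @param dir_pi0,dir_A,dir_emission Dirichlet concentrations (> 0).
#' @param m0,kappa0,a0,b0 Normal-Inverse-Gamma hyperparameters.
#' @return An object of class `"prior_spec"`.
#' @export
prior_spec <- function(dir_pi0 = 1, dir_A = 1, dir_emission = 1,
                       m0 = 0, kappa0 = 0.01, a0 = 1, b0 = 1) {
  stopifnot(dir_pi0 > 0, dir_A > 0, dir_emission > 0, kappa0 > 0,
            a0 > 0, b0 > 0)
  structure(list(dir_pi0 = dir_pi0, dir_A = dir_A,
                 dir_emission = dir_emission,
                 m0 = m0, kappa0 = kappa0, a0 = a0, b0 = b0),
            class = "prior_spec")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Gibbs sampling under a segment-count constraint
#'
#' Alternates (i) constrained path sampling `x ~ p(x | theta, event, y)` by
#' forward filtering / backward sampling on the augmented HMM and (ii) exact
#' conjugate draws `theta ~ p(theta | x, y)`. Every retained path satisfies
#' the event.
#'
#' @inheritParams constrained_em
#' @param prior A [prior_spec()].
#' @param init Initial [hmm()] model (gives `M` and the emission family).
#' @param n_iter Total Gibbs iterations.
#' @param burnin Iterations discarded from the front.
#' @param thin Keep every `thin`-th iteration after burn-in.
#' @param seed Integer seed (one stream for the whole run).
#' @return An object of class `"kseg_gibbs"`: list with `paths` (kept draws,
#'   one row per retained iteration), `theta` (list of retained parameter
#'   draws) and bookkeeping fields.
#' @export
constrained_gibbs <- function(y, prior = prior_spec(), spec = counting_standard(),
                              event, init, n_iter, seed, burnin = 0L,
                              thin = 1L) {
  if (is.character(event)) event <- parse_event(event)
  if (!inherits(prior, "prior_spec")) stop("'prior' must come from prior_spec()")
  model <- init
  y <- validate_observations(model, y)
  N <- length(y); M <- model$M
  fam <- model$emission$family
  if (!fam %in% c("gaussian", "categorical"))
    stop("unsupported configuration: no conjugate prior for this emission family")
  args <- spec_dp_args(spec, M)
  ed <- event_dp(event, args, N)
  set.seed(seed)
  kept_paths <- NULL; theta <- list()
  for (it in seq_len(n_iter)) {
    logB <- log_emissions(model, y)
    fw <- kseg_forward_cpp(logB, log_safe(model$pi0), log_safe(model$A),
                           args$s_init, args$variant, args$C, args$is_null,
                           ed$cap, TRUE)
    if (logsumexp(fw$last[, , which(ed$allowed), drop = FALSE]) == -Inf)
      infeasible_error(event)
    U <- matrix(stats::runif(N), nrow = 1L)
    x <- as.integer(kseg_sample_cpp(fw$alpha, log_safe(model$A),
                                    args$variant, args$C, args$is_null,
                                    ed$cap, ed$allowed, U))
    # theta | x, y: exact conjugate draws (identical to the unconstrained case)
    pi0 <- rdirichlet1(prior$dir_pi0 + as.numeric(tabulate(x[1L], M)))
    A <- matrix(0, M, M)
    trans <- table(factor(x[-N], levels = seq_len(M)),
                   factor(x[-1L], levels = seq_len(M)))
    for (i in seq_len(M)) A[i, ] <- rdirichlet1(prior$dir_A + as.numeric(trans[i, ]))
    if (fam == "gaussian") {
      mean_d <- var_d <- numeric(M)
      for (m in seq_len(M)) {
        ym <- y[x == m]; nm <- length(ym)
        kn <- prior$kappa0 + nm
        mn <- (prior$kappa0 * prior$m0 + sum(ym)) / kn
        an <- prior$a0 + nm / 2
        bn <- prior$b0 +
          (if (nm) sum((ym - mean(ym))^2) / 2 else 0) +
          prior$kappa0 * nm * (if (nm) (mean(ym) - prior$m0)^2 else 0) / (2 * kn)
        var_d[m] <- 1 / stats::rgamma(1L, shape = an, rate = bn)
        mean_d[m] <- stats::rnorm(1L, mn, sqrt(var_d[m] / kn))
      }
      emission <- emission_gaussian(mean_d, var_d)
      draw <- list(pi0 = pi0, A = A, mean = mean_d, var = var_d)
    } else {
      V <- model$emission$V
      prob <- matrix(0, M, V)
      for (m in seq_len(M)) {
        cnt <- tabulate(y[x == m], V)
        prob[m, ] <- rdirichlet1(prior$dir_emission + cnt)
      }
      emission <- emission_categorical(prob)
      draw <- list(pi0 = pi0, A = A, prob = prob)
    }
    model <- hmm(pi0, A, emission)
    if (it > burnin && (it - burnin) %% thin == 0L) {
      kept_paths <- rbind(kept_paths, x)
      theta[[length(theta) + 1L]] <- draw
    }
  }
  rownames(kept_paths) <- NULL
  structure(list(paths = kept_paths, theta = theta, event = event,
                 spec = spec, n_iter = n_iter, burnin = burnin, thin = thin),
            class = "kseg_gibbs")
}

#' @export
print.kseg_gibbs <- function(x, ...) {
  cat("Constrained Gibbs run: ", x$n_iter, " iterations (burnin ", x$burnin,
      ", thin ", x$thin, "), ", nrow(x$paths), " retained draws under {",
      format(x$event), "}\n", sep = "")
  invisible(x)
}
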