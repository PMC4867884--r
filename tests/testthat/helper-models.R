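# Random model / instance generators used across the suite.

rand_stochastic <- function(n, m = n) {
  A <- matrix(stats::rgamma(n * m, 1), n, m)
  A / rowSums(A)
}

rand_hmm <- function(M, family = c("gaussian", "categorical"), V = 4L) {
  family <- match.arg(family)
  pi0 <- as.numeric(rand_stochastic(1L, M))
  A <- rand_stochastic(M)
  em <- if (family == "gaussian") {
    emission_gaussian(stats::rnorm(M, sd = 2), stats::runif(M, 0.3, 2))
  } else {
    emission_categorical(rand_stochastic(M, V))
  }
  hmm(pi0, A, em)
}

rand_instance <- function(M, N, family = "gaussian", V = 4L) {
  model <- rand_hmm(M, family, V)
  y <- if (family == "gaussian") stats::rnorm(N, sd = 2)
       else sample.int(V, N, replace = TRUE)
  list(model = model, y = y)
}

# Conditional posterior over paths satisfying an event, from an enumeration.
enum_event_posterior <- function(en, event) {
  keep <- event_holds(event, en$counts) & en$feasible
  lw <- en$log_joint[keep]
  p <- exp(lw - max(lw)); p <- p / sum(p)
  list(paths = en$paths[keep, , drop = FALSE], prob = p, keep = keep)
}

# MAP path among enumerated paths satisfying an event.
enum_event_map <- function(en, event) {
  keep <- which(event_holds(event, en$counts) & en$feasible)
  if (!length(keep)) return(NULL)
  best <- keep[which.max(en$log_joint[keep])]
  list(path = en$paths[best, ], log_score = en$log_joint[best])
}

path_key <- function(paths) apply(paths, 1L, paste, collapse = ",")
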