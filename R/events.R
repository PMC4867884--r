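#' Segment-count events
#'
#' An event is a condition on the number of counted segments `c` in the
#' hidden path: `c = k`, `c <= k`, `k1 <= c <= k2` or `c > k`. Events select
#' the terminal values of the auxiliary counter that the constrained
#' recursions maximize, marginalize or sample over.
#'
#' @param k,k1,k2 Nonnegative integer bounds.
#' @return An object of class `"segment_event"`.
#' @examples
#' event_exactly(7)
#' parse_event("2<=c<=5")
#' @export
event_exactly <- function(k) new_event("exactly", k = k)

#' @rdname event_exactly
#' @export
event_at_most <- function(k) new_event("at_most", k = k)

#' @rdname event_exactly
#' @export
event_between <- function(k1, k2) new_event("between", k1 = k1, k2 = k2)

#' @rdname event_exactly
#' @export
event_greater_than <- function(k) new_event("greater_than", k = k)

new_event <- function(comparator, k = NULL, k1 = NULL, k2 = NULL) {
  chk <- function(v, nm) {
    if (length(v) != 1L || is.na(v) || v < 0 || v != round(v))
      stop("'", nm, "' must be a single nonnegative integer")
    as.integer(v)
  }
  ev <- list(comparator = comparator)
  if (comparator == "between") {
    ev$k1 <- chk(k1, "k1"); ev$k2 <- chk(k2, "k2")
    if (ev$k1 >= ev$k2) stop("'k1' must be < 'k2'")
  } else {
    ev$k <- chk(k, "k")
  }
  structure(ev, class = "segment_event")
}

#' @export
format.segment_event <- function(x, ...) {
  switch(x$comparator,
         exactly = paste0("c=", x$k),
         at_most = paste0("c<=", x$k),
         greater_than = paste0("c>", x$k),
         between = paste0(x$k1, "<=c<=", x$k2))
}

#' @export
print.segment_event <- function(x, ...) {
  cat("Segment-count event:", format(x), "\n")
  invisible(x)
}

#' Parse an event string
#'
#' Grammar: `"c=K"`, `"c<=K"`, `"c>K"`, `"K1<=c<=K2"`. Whitespace is ignored.
#' Other forms (for instance `"c>=K"`) are rejected; express a lower bound as
#' `"c>K-1"` or via a range.
#'
#' @param text Event string.
#' @return A `"segment_event"` object; `format()` round-trips it.
#' @export
parse_event <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("event must be a nonempty string")
  s <- gsub("[[:space:]]", "", text)
  if (grepl("^c>=", s))
    stop("parse error in \"", text, "\" at position 2: \"c>=K\" is not in the ",
         "grammar; use \"c>K\" with K one lower, or a range \"K1<=c<=K2\"")
  m <- regmatches(s, regexec("^c=([0-9]+)$", s))[[1]]
  if (length(m)) return(event_exactly(as.integer(m[2])))
  m <- regmatches(s, regexec("^c<=([0-9]+)$", s))[[1]]
  if (length(m)) return(event_at_most(as.integer(m[2])))
  m <- regmatches(s, regexec("^c>([0-9]+)$", s))[[1]]
  if (length(m)) return(event_greater_than(as.integer(m[2])))
  m <- regmatches(s, regexec("^([0-9]+)<=c<=([0-9]+)$", s))[[1]]
  if (length(m)) return(event_between(as.integer(m[2]), as.integer(m[3])))
  bad <- regexpr("[^0-9c<=>]", s)
  pos <- if (bad > 0L) bad else nchar(s)
  stop("parse error in \"", text, "\" near position ", pos,
       ": expected \"c=K\", \"c<=K\", \"c>K\" or \"K1<=c<=K2\"")
}

# Map an event + counting spec to DP terminal structure: the absorbing cap
# and the logical mask of allowed terminal counter values (index s = 0..cap).
event_dp <- function(event, spec_args, N) {
  k_min <- spec_args$k_min
  switch(event$comparator,
    exactly = {
      if (event$k < k_min)
        stop("event {c=", event$k, "} is infeasible: this counting variant ",
             "cannot produce counts below ", k_min)
      cap <- event$k + 1L
      allowed <- seq(0L, cap) == event$k
      list(cap = cap, allowed = allowed)
    },
    at_most = {
      if (event$k < k_min)
        stop("event {c<=", event$k, "} is infeasible: counts are at least ", k_min)
      cap <- event$k + 1L
      allowed <- seq(0L, cap) <= event$k
      list(cap = cap, allowed = allowed)
    },
    between = {
      if (event$k2 < k_min)
        stop("event {", format(event), "} is infeasible: counts are at least ", k_min)
      cap <- event$k2 + 1L
      allowed <- seq(0L, cap) >= event$k1 & seq(0L, cap) <= event$k2
      list(cap = cap, allowed = allowed)
    },
    greater_than = {
      cap <- event$k + 1L
      allowed <- seq(0L, cap) == cap
      list(cap = cap, allowed = allowed)
    })
}

#' Does a count satisfy an event?
#'
#' @param event A `"segment_event"`.
#' @param count Integer count(s).
#' @return Logical vector.
#' @export
event_holds <- function(event, count) event_satisfied(event, count)

event_satisfied <- function(event, count) {
  switch(event$comparator,
         exactly = count == event$k,
         at_most = count <= event$k,
         between = count >= event$k1 & count <= event$k2,
         greater_than = count > event$k)
}
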