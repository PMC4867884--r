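#' Read and write HMM model files
#'
#' Models are stored as JSON with fields `M`, `pi0`, `A`, `emission_family`
#' and `emission_params` (gaussian: `mean`, `var`; categorical: `prob`).
#' Numbers are written at full precision so a write/read round trip
#' reproduces the parameters exactly.
#'
#' @param path File path.
#' @param model An [hmm()] object.
#' @return `read_model()` returns an [hmm()]; `write_model()` returns `path`
#'   invisibly.
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  need <- c("M", "pi0", "A", "emission_family", "emission_params")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("model file ", path, " is missing field(s): ",
         paste(miss, collapse = ", "))
  emission <- switch(obj$emission_family,
    gaussian = emission_gaussian(obj$emission_params$mean,
                                 obj$emission_params$var),
    categorical = emission_categorical(as.matrix(obj$emission_params$prob)),
    stop("unknown emission family '", obj$emission_family, "'"))
  hmm(obj$pi0, as.matrix(obj$A), emission)
}

#' @rdname read_model
#' @export
write_model <- function(model, path) {
  em <- model$emission
  params <- if (em$family == "gaussian") {
    list(mean = em$mean, var = em$var)
  } else list(prob = unname(em$prob))
  obj <- list(M = model$M, pi0 = model$pi0, A = unname(model$A),
              emission_family = em$family, emission_params = params)
  # 17 significant digits: lossless text round trip for IEEE doubles
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read an observation sequence
#'
#' Plain text / TSV, one observation per line; lines starting with `#` are
#' skipped.
#'
#' @param path File path.
#' @param type `"numeric"` (default) or `"integer"` symbol indices.
#' @return Numeric or integer vector.
#' @export
read_observations <- function(path, type = c("numeric", "integer")) {
  type <- match.arg(type)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop("cannot parse observation on data line ", bad, ": '", lines[bad], "'")
  }
  if (type == "integer") as.integer(vals) else vals
}

#' @rdname read_observations
#' @param values Observation vector to write.
#' @export
write_observations <- function(values, path) {
  writeLines(format(values, trim = TRUE, digits = 17), path)
  invisible(path)
}

#' Run-length segmentation of a path
#'
#' Converts a hidden state path to its segments (maximal constant runs),
#' 1-based inclusive coordinates; adjacent segments always differ in state
#' and tile `1..N`.
#'
#' @param x Integer state path.
#' @return Data frame with columns `start`, `end`, `state`.
#' @export
path_to_segments <- function(x) {
  x <- as.integer(x)
  if (!length(x)) stop("empty path")
  r <- rle(x)
  end <- cumsum(r$lengths)
  data.frame(start = c(1L, utils::head(end, -1L) + 1L), end = end,
             state = r$values)
}

#' Convert segments to BED-like coordinates
#'
#' Turns a 1-based inclusive segmentation into 0-based half-open rows with a
#' sequence name, the convention of BED-style genome interval files.
#'
#' @param segments Data frame from [path_to_segments()].
#' @param seqname Sequence name for the first column.
#' @return Data frame with columns `seqname`, `start` (0-based), `end`
#'   (exclusive), `state`.
#' @export
segments_to_bed <- function(segments, seqname = "seq") {
  data.frame(seqname = seqname, start = segments$start - 1L,
             end = segments$end, state = segments$state)
}

#' @rdname segments_to_bed
#' @param bed Data frame in BED-like coordinates.
#' @return `bed_to_segments()` returns the 1-based inclusive form.
#' @export
bed_to_segments <- function(bed) {
  data.frame(start = bed$start + 1L, end = bed$end, state = bed$state)
}

#' Write a path or segmentation to TSV
#'
#' `format = "tsv"` writes per-position rows `(index, state)`;
#' `format = "bed"` writes the run-length segmentation in BED-like 0-based
#' half-open coordinates.
#'
#' @param x Integer state path.
#' @param path Output file.
#' @param format `"tsv"` or `"bed"`.
#' @param seqname Sequence name for BED output.
#' @export
write_segments <- function(x, path, format = c("tsv", "bed"),
                           seqname = "seq") {
  format <- match.arg(format)
  df <- if (format == "tsv") {
    data.frame(index = seq_along(x), state = as.integer(x))
  } else segments_to_bed(path_to_segments(x), seqname)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a segment-count posterior table
#'
#' TSV with columns `k`, `p`, `log_p` and `log10_p` (both log scales are
#' written so very small probabilities survive the text round trip), plus a
#' final row for the tail mass.
#'
#' @param posterior A `"segment_posterior"` from [kseg_forward()].
#' @param path Output file.
#' @export
write_probs <- function(posterior, path) {
  df <- data.frame(k = c(posterior$k, paste0(">", posterior$k_max)),
                   p = c(posterior$p, posterior$tail),
                   log_p = c(posterior$log_p, log(posterior$tail)),
                   log10_p = c(posterior$log_p, log(posterior$tail)) / log(10))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counting specification from JSON
#'
#' Schema: `{"variant": ..., "mu": ..., "C": ..., "null_states": ...}` with
#' fields required by the variant.
#'
#' @param path File path.
#' @return A `"counting_spec"` object.
#' @export
read_counting_spec <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$variant)) stop("counting spec file must name a 'variant'")
  switch(obj$variant,
         standard = counting_standard(),
         generalized = counting_generalized(obj$mu, as.matrix(obj$C)),
         excursion = counting_excursion(obj$null_states),
         restricted_excursion = counting_excursion(obj$null_states,
                                                   restricted = TRUE),
         stop("unknown counting variant '", obj$variant, "'"))
}
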