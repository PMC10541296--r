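# small shared helpers

#' Render a 1-based inclusive span as "start-end"
#'
#' Report tables print genomic spans in the `"60001–100000"` style
#' (en dash, 1-based inclusive ends), matching the convention of published
#' candidate-gene tables.
#'
#' @param start,end integer vectors of 1-based inclusive coordinates.
#' @return character vector of rendered spans.
#' @export
format_span <- function(start, end) {
  stopifnot(length(start) == length(end), all(end >= start))
  sprintf("%d–%d", as.integer(start), as.integer(end))
}

#' Parse spans rendered by [format_span()]
#'
#' @param x character vector like `"60001–100000"`; a plain ASCII
#'   hyphen separator is also accepted.
#' @return data.frame with integer columns `start`, `end`.
#' @export
parse_span <- function(x) {
  parts <- strsplit(x, "–|-")
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("malformed span: ", x[bad][1])
  data.frame(
    start = as.integer(vapply(parts, `[`, "", 1L)),
    end = as.integer(vapply(parts, `[`, "", 2L))
  )
}

# derive a stage-specific seed from one global seed, staying inside the
# 32-bit integer range R requires
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
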