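#' Round half away from zero
#'
#' Headline percentages are conventionally rounded half-up (2.5 -> 3), not to
#' even as base `round()` does. Used for every printed percentage in the
#' outcome summaries.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return numeric vector rounded half away from zero
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.345), c(0, 0, 2))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5) / p
}

# Total length of the union of 1-based inclusive intervals.
# starts/ends may overlap or touch; empty input -> 0.
interval_union_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0)
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  total <- 0
  cur_s <- starts[1L]; cur_e <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= cur_e + 1) {
      cur_e <- max(cur_e, ends[i])
    } else {
      total <- total + (cur_e - cur_s + 1)
      cur_s <- starts[i]; cur_e <- ends[i]
    }
  }
  total + (cur_e - cur_s + 1)
}

# shared column check with a readable error
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

REV_COMP <- c(A = "T", C = "G", G = "C", T = "A")

reverse_complement <- function(x) {
  vapply(strsplit(x, ""), function(b) paste(rev(unname(REV_COMP[b])), collapse = ""), character(1))
}
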