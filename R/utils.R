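#' Round half away from zero
#'
#' Commercial rounding used for every reported integer in the assessment
#' tables. `base::round()` rounds half to even, which does not reproduce
#' published accounting (e.g. 5.5 must report as 6, -5.5 as -6).
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @examples
#' round_half_away(c(0.5, 1.5, 2.5, -0.5))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-line abort helper: all user-facing validation errors go through here
# so the CLI can report them as one diagnostic line
smr_stop <- function(...) {
  stop(paste0(...), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) & !is.na(x) & x >= 0 & abs(x - round(x)) < 1e-8
}

# stable content hash for run metadata: serialize to canonical JSON, md5 the
# bytes via a temp file (tools::md5sum is file-based)
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), tf)
  unname(tools::md5sum(tf))
}
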