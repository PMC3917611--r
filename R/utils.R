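# small shared helpers (internal)

#' Round half away from zero
#'
#' Base `round()` rounds half to even; published tables in this field are
#' conventionally rounded half-up, so report rounding goes through this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(0.625, 2) # 0.63, where round(0.625, 2) gives 0.62
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# pipe-separated multi-value cells <-> character vectors
split_multi <- function(x) {
  if (length(x) != 1 || is.na(x) || !nzchar(x)) return(character())
  strsplit(x, "|", fixed = TRUE)[[1]]
}

join_multi <- function(x) {
  if (length(x) == 0) return(NA_character_)
  paste(sort(unique(x)), collapse = "|")
}

# validation / io error conditions used by the CLI exit-code policy
mm_abort <- function(msg, class = "mm_validation_error", ...) {
  abort(msg, class = class, ...)
}

mm_abort_io <- function(msg, ...) {
  abort(msg, class = "mm_io_error", ...)
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    mm_abort(sprintf("%s is missing required column(s): %s",
                     what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
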