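#' Parse a linear chemical formula into element counts
#'
#' Accepts plain element-count strings such as `"C6H12O6"` or `"Fe"`.
#' Unnumbered elements get an implicit count of 1; repeated element tokens
#' (e.g. `"CH3CH3"`) are summed. Deuterium (`D`) is treated as an element
#' symbol distinct from `H`. Parentheses, charge tokens (`+`/`-`), dots and
#' anything else outside `[A-Z][a-z]?[0-9]*` tokens are rejected with an error
#' naming the offending text: reconstruction formulas are linear, and silent
#' mis-parsing is worse than rejection. Charge is never part of a formula; it
#' travels as a separate integer field throughout the package.
#'
#' @param raw a single formula string.
#' @return named integer vector of element counts, sorted by element symbol.
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("Fe")
#' @export
parse_formula <- function(raw) {
  if (length(raw) != 1 || is.na(raw)) mm_abort("formula must be a single non-NA string")
  raw <- trimws(raw)
  if (!nzchar(raw)) mm_abort("formula is empty")
  leftover <- gsub("[A-Z][a-z]?[0-9]*", "", raw)
  if (nzchar(leftover)) {
    mm_abort(sprintf("cannot parse formula '%s': unsupported token '%s'",
                     raw, substr(leftover, 1, 1)))
  }
  m <- str_match_all(raw, "([A-Z][a-z]?)([0-9]*)")[[1]]
  counts <- ifelse(nzchar(m[, 3]), suppressWarnings(as.integer(m[, 3])), 1L)
  if (any(is.na(counts)) || any(counts < 1L)) {
    mm_abort(sprintf("formula '%s' contains a zero or unreadable element count", raw))
  }
  out <- tapply(counts, m[, 2], sum)
  setNames(as.integer(out), names(out))[sort(names(out))]
}

#' Compare two chemical formulas, optionally ignoring hydrogen
#'
#' Protonation-state bookkeeping differs between databases and
#' reconstructions, so identifier review compares formulas with hydrogen
#' counts ignored by default: two formulas match iff their element-count maps
#' are equal after deleting `H` from both. With `ignore_hydrogen = FALSE` the
#' comparison is exact (and an exact match always implies a
#' hydrogen-insensitive one).
#'
#' @param a,b formula strings or parsed count vectors from [parse_formula()];
#'   `a` and `b` are recycled to a common length when given as character
#'   vectors.
#' @param ignore_hydrogen drop `H` before comparing (default `TRUE`).
#' @return logical vector.
#' @examples
#' formulas_match("C6H12O6", "C6H11O6")        # TRUE (H ignored)
#' formulas_match("C6H12O6", "C5H10O5")        # FALSE
#' formulas_match("C3H7NO2", "C3H7NO2", FALSE) # TRUE
#' @export
formulas_match <- function(a, b, ignore_hydrogen = TRUE) {
  if (is.numeric(a) || is.numeric(b)) {
    return(counts_match(as_counts(a), as_counts(b), ignore_hydrogen))
  }
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  vapply(seq_len(n), function(i) {
    counts_match(parse_formula(a[i]), parse_formula(b[i]), ignore_hydrogen)
  }, logical(1))
}

as_counts <- function(x) if (is.numeric(x)) x else parse_formula(x)

counts_match <- function(a, b, ignore_hydrogen) {
  if (ignore_hydrogen) {
    a <- a[names(a) != "H"]
    b <- b[names(b) != "H"]
  }
  identical(a[sort(names(a))], b[sort(names(b))])
}

# canonical hydrogen-free key for a formula string; NA stays NA, unparseable
# strings also become NA (entries with unusable formulas are skipped by
# formula checks rather than crashing the pipeline). Vectorized + memoized
# over unique values since stores repeat formulas heavily.
formula_key <- function(x, ignore_hydrogen = TRUE) {
  ux <- unique(x)
  key1 <- function(f) {
    if (is.na(f) || !nzchar(trimws(f))) return(NA_character_)
    counts <- tryCatch(parse_formula(f), error = function(e) NULL)
    if (is.null(counts)) return(NA_character_)
    if (ignore_hydrogen) counts <- counts[names(counts) != "H"]
    if (length(counts) == 0) return("")
    paste(names(counts), counts, sep = ":", collapse = ",")
  }
  setNames(vapply(ux, key1, character(1)), ux)[match(x, ux)]
}

# single-element formulas (inorganic ions like Cl, Mg) are exempt by default
# from the neutral-form preference rule
is_single_element <- function(x) {
  vapply(x, function(f) {
    if (is.na(f)) return(FALSE)
    counts <- tryCatch(parse_formula(f), error = function(e) NULL)
    !is.null(counts) && length(counts[names(counts) != "H"]) <= 1
  }, logical(1), USE.NAMES = FALSE)
}
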