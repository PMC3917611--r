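#' Identifier types understood by metamapr
#'
#' Metabolites in reconstructions are annotated with chemical names, structure
#' hashes (standard InChIKeys) and primary keys of public compound databases.
#' `id_types()` lists every type the package understands; `db_types()` lists
#' the subset that are database primary keys (the only types eligible as
#' mapping outputs: names and InChIKeys are hard to verify by lookup and are
#' never output types in an evaluation battery).
#'
#' @return character vector of type codes.
#' @export
id_types <- function() {
  c("name", "inchi", "inchikey", "chebi", "hmdb", "kegg", "pubchem", "lipidmaps")
}

#' @rdname id_types
#' @export
db_types <- function() {
  c("chebi", "hmdb", "kegg", "pubchem", "lipidmaps")
}

# input/output types used by the standard evaluation battery
battery_input_types <- function() c("name", "inchikey", "chebi", "hmdb", "kegg", "pubchem")
battery_output_types <- function() c("chebi", "hmdb", "kegg", "pubchem")

#' Normalize a metabolite identifier to its canonical form
#'
#' Deterministic, idempotent canonicalization so that joins between databases
#' and reconstructions are exact string matches:
#'
#' * `name`: lower-cased, trimmed, internal whitespace collapsed to one space.
#' * `inchikey`: upper-cased; must match the 14-10-1 uppercase-letter layout.
#' * `chebi`: any `CHEBI:` prefix stripped; digits only.
#' * `hmdb`: upper-cased; both the legacy 9-character (`HMDB` + 5 digits) and
#'   modern 11-character (`HMDB` + 7 digits) dialects are accepted on input;
#'   the canonical form is the modern 11-character identifier (legacy values
#'   are zero-padded, e.g. `HMDB00186` becomes `HMDB0000186`).
#' * `kegg`: upper-cased; must be `C` followed by exactly 5 digits.
#' * `pubchem`: digit string with leading zeros stripped.
#' * `lipidmaps`: upper-cased; `LM` followed by alphanumerics.
#' * `inchi`: trimmed; must start with `InChI=`.
#'
#' Name matching downstream is case-insensitive *exact* matching; no fuzzy
#' search is performed anywhere in the package.
#'
#' @param id_type one of [id_types()].
#' @param value character vector of raw identifier values.
#' @return character vector of canonical values, same length as `value`.
#'   Malformed values raise an error naming the offending value; use
#'   [valid_identifier()] to pre-screen untrusted input.
#' @examples
#' normalize_identifier("hmdb", "HMDB00186")
#' normalize_identifier("name", "  Lactose ")
#' normalize_identifier("chebi", "CHEBI:17716")
#' @export
normalize_identifier <- function(id_type, value) {
  res <- normalize_quietly(id_type, value)
  bad <- which(is.na(res$value))
  if (length(bad) > 0) {
    mm_abort(sprintf("malformed %s identifier: '%s' (%s)",
                     id_type, value[bad[1]], res$reason[bad[1]]))
  }
  res$value
}

#' @rdname normalize_identifier
#' @return `valid_identifier()` returns a logical vector.
#' @export
valid_identifier <- function(id_type, value) {
  !is.na(normalize_quietly(id_type, value)$value)
}

# normalization that reports failures as NA + reason instead of erroring;
# the ingest path uses this so bad rows become logged rejections.
normalize_quietly <- function(id_type, value) {
  id_type <- match.arg(id_type, id_types())
  value <- as.character(value)
  v <- trimws(value)
  out <- rep(NA_character_, length(v))
  reason <- rep(NA_character_, length(v))
  empty <- is.na(v) | !nzchar(v)
  reason[empty] <- "empty value"
  i <- !empty
  if (any(i)) {
    switch(id_type,
      name = {
        out[i] <- tolower(str_squish(v[i]))
      },
      inchi = {
        ok <- i & str_detect(v, "^InChI=")
        out[ok] <- v[ok]
        reason[i & !ok] <- "InChI must start with 'InChI='"
      },
      inchikey = {
        u <- toupper(v)
        ok <- i & str_detect(u, "^[A-Z]{14}-[A-Z]{10}-[A-Z]$")
        out[ok] <- u[ok]
        reason[i & !ok] <- "not a 14-10-1 uppercase InChIKey"
      },
      chebi = {
        u <- sub("^(?i)CHEBI:", "", v, perl = TRUE)
        ok <- i & str_detect(u, "^[0-9]+$")
        out[ok] <- u[ok]
        reason[i & !ok] <- "ChEBI value must be digits, optionally prefixed 'CHEBI:'"
      },
      hmdb = {
        u <- toupper(v)
        ok <- i & str_detect(u, "^HMDB([0-9]{5}|[0-9]{7})$")
        digits <- str_pad(sub("^HMDB", "", u), 7, pad = "0")
        out[ok] <- paste0("HMDB", digits[ok])
        reason[i & !ok] <- "HMDB value must be HMDB + 5 or 7 digits"
      },
      kegg = {
        u <- toupper(v)
        ok <- i & str_detect(u, "^C[0-9]{5}$")
        out[ok] <- u[ok]
        reason[i & !ok] <- "KEGG Compound value must match C#####"
      },
      pubchem = {
        ok <- i & str_detect(v, "^[0-9]+$") & str_detect(v, "[1-9]")
        out[ok] <- sub("^0+", "", v[ok])
        reason[i & !ok] <- "PubChem CID must be a positive integer"
      },
      lipidmaps = {
        u <- toupper(v)
        ok <- i & str_detect(u, "^LM[A-Z0-9]{6,}$")
        out[ok] <- u[ok]
        reason[i & !ok] <- "LIPID MAPS value must match LM + alphanumerics"
      }
    )
  }
  list(value = out, reason = reason)
}

#' Inspect the syntax and standardness of an InChIKey
#'
#' Purely lexical: never consults a chemistry toolkit. An InChIKey is 27
#' characters: a 14-letter skeleton block, a 10-letter block whose 9th and
#' 10th characters encode the standard flag and InChI version, and a single
#' protonation letter, separated by dashes. A key is *standard* iff those two
#' characters are `S` (standard) then `A` (version 1).
#'
#' @param raw character vector of candidate keys.
#' @return a tibble with one row per input: `key` (upper-cased input),
#'   `valid`, `standard`, `skeleton_block`, `proto_block`, `flag_char`
#'   (the last three are `NA` for invalid keys). Invalid syntax yields an
#'   invalid verdict, never an error.
#' @examples
#' inspect_inchikey(c("AAAAAAAAAAAAAA-BBBBBBBBSA-N", "TOO-SHORT"))
#' @export
inspect_inchikey <- function(raw) {
  key <- toupper(trimws(as.character(raw)))
  valid <- !is.na(key) & str_detect(key, "^[A-Z]{14}-[A-Z]{10}-[A-Z]$")
  skeleton <- ifelse(valid, substr(key, 1, 14), NA_character_)
  proto <- ifelse(valid, substr(key, 16, 25), NA_character_)
  flag <- ifelse(valid, substr(key, 27, 27), NA_character_)
  standard <- valid & substr(proto, 9, 10) == "SA"
  tibble(
    key = key, valid = valid, standard = standard,
    skeleton_block = skeleton, proto_block = proto, flag_char = flag
  )
}

# TRUE for keys that are syntactically valid *standard* InChIKeys
is_standard_key <- function(raw) {
  info <- inspect_inchikey(raw)
  info$valid & info$standard
}
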