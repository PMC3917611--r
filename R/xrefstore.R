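#' Build a cross-reference store from source-database entries
#'
#' An `xref_store` aggregates compound entries from multiple source databases
#' into a single table keyed on the standard InChIKey, the join column for
#' InChIKey-based identifier mapping. Entries pass through ingest-time quality
#' checks (see [ingest_entries()]); the store tracks which database
#' identifiers are *currently* associated with each key and which associations
#' are obsolete (superseded or flagged obsolete at the source), so historical
#' assignments can be queried on request.
#'
#' Two ingest modes are supported, mirroring the two aggregation philosophies
#' found in public cross-reference services:
#'
#' * `strict = TRUE`: entries must carry a database identifier and a standard
#'   InChI; provided InChIKeys are checked against an oracle-derived key when
#'   a `key_oracle` is available, and InChI/InChIKey associations must stay
#'   mutually consistent across the whole store. This emulates a
#'   quality-checked cross-referencing service.
#' * `strict = FALSE` (permissive): entries with a key but no InChI are
#'   accepted and no consistency checks are applied, emphasizing coverage over
#'   specificity. This emulates a coverage-oriented translation service.
#'
#' @param entries optional tibble of source entries in the dump dialect of
#'   [read_source_dump()] to ingest immediately.
#' @param strict apply the full set of quality checks (default `TRUE`).
#' @param key_oracle optional function mapping a standard InChI string to its
#'   standard InChIKey (e.g. [synthetic_key_oracle()] for generated fixtures,
#'   or a wrapper around a chemistry toolkit for real data). Hashing is not
#'   invertible, so without an oracle keys can only be cross-checked
#'   relationally against other accepted entries.
#' @return an object of class `xref_store`.
#' @seealso [ingest_entries()], [assignments_for_key()], [audit_store()],
#'   [map_ids()]
#' @export
xref_store <- function(entries = NULL, strict = TRUE, key_oracle = NULL) {
  store <- structure(
    list(
      entries = tibble(
        source_db = character(), id = character(), inchi = character(),
        inchikey = character(), names = character(), formula = character(),
        charge = integer(), obsolete = logical()
      ),
      assignments = tibble(
        key = character(), source_db = character(), id_type = character(),
        id = character(), current = logical()
      ),
      name_index = tibble(name = character(), key = character()),
      inchi_key_map = tibble(inchi = character(), key = character()),
      rejections = tibble(source_db = character(), id = character(),
                          reason = character()),
      strict = isTRUE(strict),
      n_ingested = 0L
    ),
    class = "xref_store"
  )
  if (!is.null(entries)) {
    store <- ingest_entries(store, entries, key_oracle = key_oracle)
  }
  store
}

#' @export
print.xref_store <- function(x, ...) {
  cat(sprintf(
    "<xref_store: %s mode; %d entries accepted, %d rejected; %d keys, %d names>\n",
    if (x$strict) "strict" else "permissive",
    nrow(x$entries), nrow(x$rejections),
    n_distinct(x$assignments$key), n_distinct(x$name_index$name)
  ))
  invisible(x)
}

#' Ingest source-database entries into a cross-reference store
#'
#' Entries are processed in row order. Each entry is either accepted (updating
#' the key assignments, the name index and the per-(database, id) entry table)
#' or rejected with a reason; rejections are never errors. Reasons:
#'
#' * `missing_id`: no parseable primary identifier for the entry's database.
#' * `missing_inchi`: strict mode requires a standard InChI; in permissive
#'   mode this reason marks entries carrying neither an InChI nor a key.
#' * `invalid_key_syntax`: a provided InChIKey that is not a syntactically
#'   valid *standard* key (only standard keys may index the store).
#' * `key_mismatch`: strict mode with an oracle; the provided key differs from
#'   the key derived from the entry's InChI.
#' * `inconsistent_with_store`: strict mode without needing an oracle; the
#'   entry links an InChI and a key in a way that contradicts an accepted
#'   entry (one InChI must never map to two keys, nor one key to two InChIs).
#' * `unresolvable_key`: the entry has an InChI but no key, and no oracle or
#'   prior store knowledge can supply one (key hashing is not invertible).
#'
#' A re-ingested `(database, id)` pair pointing to a *different* key demotes
#' the old assignment to non-current rather than deleting it, preserving the
#' assignment history. Entries flagged obsolete at source are recorded as
#' non-current assignments and do not contribute names to the name index.
#'
#' @param store an [xref_store()].
#' @param entries tibble with columns `source_db`, `id`, `inchi`, `inchikey`,
#'   `names` (pipe-separated synonyms), `formula`, `charge`, `obsolete`.
#' @param key_oracle see [xref_store()].
#' @return the updated store. The outcome of this batch is in
#'   `store$ingest_report` (columns `source_db`, `id`, `accepted`, `reason`);
#'   cumulative rejections are in `store$rejections`.
#' @export
ingest_entries <- function(store, entries, key_oracle = NULL) {
  stopifnot(inherits(store, "xref_store"))
  stopifnot_cols(entries, c("source_db", "id"), "source entry table")
  n <- nrow(entries)
  get_chr <- function(col) {
    if (col %in% names(entries)) as.character(entries[[col]]) else rep(NA_character_, n)
  }
  source_db <- tolower(trimws(get_chr("source_db")))
  raw_id <- get_chr("id")
  raw_inchi <- get_chr("inchi")
  raw_key <- get_chr("inchikey")
  raw_names <- get_chr("names")
  formula <- get_chr("formula")
  charge <- if ("charge" %in% names(entries)) {
    suppressWarnings(as.integer(entries[["charge"]]))
  } else rep(NA_integer_, n)
  obsolete <- if ("obsolete" %in% names(entries)) {
    as.logical(as.integer(entries[["obsolete"]])) %in% TRUE
  } else rep(FALSE, n)

  # vectorized normalization; failures become per-row rejection reasons
  id_norm <- rep(NA_character_, n)
  for (db in unique(source_db)) {
    sel <- which(source_db == db)
    if (db %in% db_types()) {
      id_norm[sel] <- normalize_quietly(db, raw_id[sel])$value
    }
  }
  inchi_norm <- normalize_quietly("inchi", raw_inchi)$value
  key_norm <- normalize_quietly("inchikey", raw_key)$value
  key_standard <- is_standard_key(key_norm)
  key_provided <- !is.na(raw_key) & nzchar(trimws(raw_key))
  names_norm <- vapply(raw_names, function(x) {
    parts <- normalize_quietly("name", split_multi(x))$value
    join_multi(parts[!is.na(parts)])
  }, character(1), USE.NAMES = FALSE)

  # mutable state, seeded from the existing store
  i2k <- new.env(parent = emptyenv())
  k2i <- new.env(parent = emptyenv())
  amap <- new.env(parent = emptyenv())   # "db\x1fid\x1fkey" -> current?
  cur <- new.env(parent = emptyenv())    # "db\x1fid" -> current key
  for (r in seq_len(nrow(store$inchi_key_map))) {
    assign(store$inchi_key_map$inchi[r], store$inchi_key_map$key[r], envir = i2k)
    assign(store$inchi_key_map$key[r], store$inchi_key_map$inchi[r], envir = k2i)
  }
  for (r in seq_len(nrow(store$assignments))) {
    a <- store$assignments[r, ]
    assign(paste(a$source_db, a$id, a$key, sep = "\x1f"), a$current, envir = amap)
    if (a$current) assign(paste(a$source_db, a$id, sep = "\x1f"), a$key, envir = cur)
  }

  accepted <- logical(n)
  reason <- character(n)
  used_key <- rep(NA_character_, n)
  name_pairs <- vector("list", n)

  for (r in seq_len(n)) {
    db <- source_db[r]
    if (!db %in% db_types() || is.na(id_norm[r])) {
      reason[r] <- "missing_id"
      next
    }
    has_inchi <- !is.na(inchi_norm[r])
    if (store$strict && !has_inchi) {
      reason[r] <- "missing_inchi"
      next
    }
    if (key_provided[r] && (is.na(key_norm[r]) || !key_standard[r])) {
      reason[r] <- "invalid_key_syntax"
      next
    }
    derived <- NA_character_
    if (!is.null(key_oracle) && has_inchi) {
      derived <- as.character(key_oracle(inchi_norm[r]))
    }
    if (store$strict && key_provided[r] && !is.na(derived) &&
        derived != key_norm[r]) {
      reason[r] <- "key_mismatch"
      next
    }
    key <- if (key_provided[r]) key_norm[r] else derived
    if (is.na(key) && has_inchi) {
      key <- get0(inchi_norm[r], envir = i2k, ifnotfound = NA_character_)
    }
    if (is.na(key)) {
      reason[r] <- if (has_inchi) "unresolvable_key" else "missing_inchi"
      next
    }
    if (store$strict && has_inchi) {
      known_key <- get0(inchi_norm[r], envir = i2k, ifnotfound = NA_character_)
      known_inchi <- get0(key, envir = k2i, ifnotfound = NA_character_)
      if ((!is.na(known_key) && known_key != key) ||
          (!is.na(known_inchi) && known_inchi != inchi_norm[r])) {
        reason[r] <- "inconsistent_with_store"
        next
      }
    }

    # accepted
    accepted[r] <- TRUE
    reason[r] <- "ok"
    used_key[r] <- key
    if (has_inchi) {
      if (is.na(get0(inchi_norm[r], envir = i2k, ifnotfound = NA_character_))) {
        assign(inchi_norm[r], key, envir = i2k)
      }
      if (is.na(get0(key, envir = k2i, ifnotfound = NA_character_))) {
        assign(key, inchi_norm[r], envir = k2i)
      }
    }
    dbid <- paste(db, id_norm[r], sep = "\x1f")
    akey <- paste(db, id_norm[r], key, sep = "\x1f")
    if (obsolete[r]) {
      if (is.na(get0(akey, envir = amap, ifnotfound = NA))) {
        assign(akey, FALSE, envir = amap)
      }
    } else {
      prev <- get0(dbid, envir = cur, ifnotfound = NA_character_)
      if (!is.na(prev) && prev != key) {
        assign(paste(db, id_norm[r], prev, sep = "\x1f"), FALSE, envir = amap)
      }
      assign(akey, TRUE, envir = amap)
      assign(dbid, key, envir = cur)
      nm <- split_multi(names_norm[r])
      if (length(nm) > 0) name_pairs[[r]] <- tibble(name = nm, key = key)
    }
  }

  # rebuild tables
  akeys <- ls(amap)
  aparts <- strsplit(akeys, "\x1f", fixed = TRUE)
  store$assignments <- tibble(
    key = map_chr(aparts, 3),
    source_db = map_chr(aparts, 1),
    id_type = map_chr(aparts, 1),
    id = map_chr(aparts, 2),
    current = map_lgl(akeys, function(k) isTRUE(get(k, envir = amap)))
  ) |> arrange(.data$key, .data$source_db, .data$id)

  ikeys <- ls(i2k)
  store$inchi_key_map <- tibble(
    inchi = ikeys,
    key = map_chr(ikeys, function(k) get(k, envir = i2k))
  )

  new_entries <- tibble(
    source_db = source_db, id = id_norm, inchi = inchi_norm,
    inchikey = used_key, names = names_norm, formula = formula,
    charge = charge, obsolete = obsolete
  )[accepted, , drop = FALSE]
  # latest entry per (db, id), but a current (non-obsolete) entry is never
  # shadowed by an obsolete one
  store$entries <- bind_rows(store$entries, new_entries) |>
    mutate(.ord = row_number()) |>
    group_by(.data$source_db, .data$id) |>
    arrange(.data$obsolete, desc(.data$.ord), .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    arrange(.data$.ord) |>
    select(-".ord")

  store$name_index <- bind_rows(store$name_index, name_pairs) |> distinct()

  report <- tibble(
    source_db = source_db,
    id = coalesce(id_norm, raw_id),
    accepted = accepted,
    reason = reason
  )
  store$ingest_report <- report
  store$rejections <- bind_rows(
    store$rejections,
    report |> filter(!.data$accepted) |> select("source_db", "id", "reason")
  )
  store$n_ingested <- store$n_ingested + n
  store
}

#' Ingest a single source entry
#'
#' Single-entry wrapper around [ingest_entries()].
#'
#' @inheritParams ingest_entries
#' @param entry a one-row tibble (or list coercible to one).
#' @return list with elements `store` (updated store) and `outcome` (a one-row
#'   tibble with `accepted` and `reason`).
#' @export
ingest_entry <- function(store, entry, key_oracle = NULL) {
  entry <- as_tibble(entry)
  stopifnot(nrow(entry) == 1)
  store <- ingest_entries(store, entry, key_oracle = key_oracle)
  list(store = store, outcome = store$ingest_report |> select("accepted", "reason"))
}

#' Query identifier assignments for a standard InChIKey
#'
#' @param store an [xref_store()].
#' @param key a single InChIKey (syntactically valid, else an error).
#' @param include_obsolete also return assignments that have been superseded
#'   or were flagged obsolete at source (default `FALSE`: obsolete
#'   associations are only output on request).
#' @return tibble with columns `source_db`, `id_type`, `id`, `current`.
#'   An unknown key yields an empty tibble.
#' @export
assignments_for_key <- function(store, key, include_obsolete = FALSE) {
  stopifnot(inherits(store, "xref_store"))
  info <- inspect_inchikey(key)
  if (nrow(info) != 1 || !info$valid) {
    mm_abort(sprintf("not a syntactically valid InChIKey: '%s'", key))
  }
  out <- store$assignments |> filter(.data$key == info$key)
  if (!include_obsolete) out <- out |> filter(.data$current)
  out |> select("source_db", "id_type", "id", "current")
}

#' Audit a store for InChI/InChIKey consistency violations
#'
#' Scans accepted entries for structural-representation conflicts: a single
#' standard InChI associated with two different standard InChIKeys, or one key
#' associated with two different InChIs. Strictly ingested stores are
#' conflict-free by construction; permissively ingested stores can accumulate
#' such conflicts, which indicate errors in the source databases.
#'
#' @param store an [xref_store()].
#' @return tibble of violations with columns `kind`
#'   (`inchi_multiple_keys` or `key_multiple_inchis`), `value` (the shared
#'   InChI or key) and `entries` (the offending `db:id` pairs, `;`-separated).
#'   Empty when the store is consistent.
#' @export
audit_store <- function(store) {
  stopifnot(inherits(store, "xref_store"))
  pairs <- store$entries |>
    filter(!is.na(.data$inchi), !is.na(.data$inchikey)) |>
    mutate(entry = paste0(.data$source_db, ":", .data$id))
  v1 <- pairs |>
    group_by(value = .data$inchi) |>
    filter(n_distinct(.data$inchikey) > 1) |>
    summarise(entries = paste(sort(.data$entry), collapse = ";"),
              .groups = "drop") |>
    mutate(kind = "inchi_multiple_keys")
  v2 <- pairs |>
    group_by(value = .data$inchikey) |>
    filter(n_distinct(.data$inchi) > 1) |>
    summarise(entries = paste(sort(.data$entry), collapse = ";"),
              .groups = "drop") |>
    mutate(kind = "key_multiple_inchis")
  bind_rows(v1, v2) |> select("kind", "value", "entries")
}

#' Read or write a source-database dump
#'
#' The dump dialect is UTF-8 TSV with a header row and columns `source_db`,
#' `id`, `inchi`, `inchikey`, `names` (pipe-separated synonyms), `formula`,
#' `charge` and `obsolete` (0/1). Lines starting with `#` are provenance
#' comments and are skipped.
#'
#' @param path file path.
#' @return `read_source_dump()` returns the entries tibble.
#' @export
read_source_dump <- function(path) {
  if (!file.exists(path)) mm_abort_io(sprintf("no such file: %s", path))
  df <- readr::read_tsv(path, comment = "#",
                        col_types = readr::cols(.default = readr::col_character()))
  stopifnot_cols(df, c("source_db", "id", "inchi", "inchikey", "names",
                       "formula", "charge", "obsolete"),
                 sprintf("source dump '%s'", path))
  df |>
    mutate(charge = suppressWarnings(as.integer(.data$charge)),
           obsolete = suppressWarnings(as.integer(.data$obsolete)))
}

#' @rdname read_source_dump
#' @param entries entries tibble.
#' @param provenance optional character vector of `#`-prefixed header lines.
#' @export
write_source_dump <- function(entries, path, provenance = NULL) {
  write_tsv_provenance(entries, path, provenance)
  invisible(path)
}

write_tsv_provenance <- function(df, path, provenance = NULL) {
  if (!is.null(provenance) && length(provenance) > 0) {
    readr::write_lines(provenance, path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(df, path)
  }
  invisible(path)
}
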