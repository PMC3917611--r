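#' Read or write a reconstruction metabolite-annotation table
#'
#' The dialect is UTF-8 TSV with a header row: `met_id`, `name`, `formula`,
#' `charge`, plus one column per identifier type (`inchikey`, `chebi`, `hmdb`,
#' `kegg`, `pubchem`, `lipidmaps`), multiple values pipe-separated, empty cells
#' for missing annotations. Lines starting with `#` are provenance comments.
#'
#' @param path file path.
#' @return `read_recon()` returns the reconstruction tibble.
#' @export
read_recon <- function(path) {
  if (!file.exists(path)) mm_abort_io(sprintf("no such file: %s", path))
  df <- readr::read_tsv(path, comment = "#",
                        col_types = readr::cols(.default = readr::col_character()))
  stopifnot_cols(df, c("met_id", "name"), sprintf("reconstruction '%s'", path))
  if ("charge" %in% names(df)) {
    df$charge <- suppressWarnings(as.integer(df$charge))
  }
  df
}

#' @rdname read_recon
#' @param recon reconstruction tibble.
#' @param provenance optional `#`-prefixed header lines.
#' @export
write_recon <- function(recon, path, provenance = NULL) {
  write_tsv_provenance(recon, path, provenance)
  invisible(path)
}

#' Configuration for the annotation-update pipeline
#'
#' @param output_types database identifier types to review and fill
#'   (default: all of [db_types()]).
#' @param auto_threshold confidence needed for automatic addition
#'   (see [confidence_partition()]).
#' @param ignore_hydrogen compare formulas hydrogen-insensitively
#'   (default `TRUE`): databases and reconstructions book protonation
#'   differently, so hydrogen-count differences are not evidence of a wrong
#'   identifier.
#' @param prefer_neutral replace identifiers pointing at charged database
#'   entries with the same database's neutral-form entry when one exists
#'   (default `TRUE`). Neutral-form identifiers maximize comparability across
#'   databases that only register neutral species.
#' @param exempt_single_element exempt metabolites with single-element
#'   formulas (inorganic ions such as chloride or magnesium, which only occur
#'   in a charged state) from the neutral-form rule (default `TRUE`).
#' @param exempt_types identifier types exempt from the neutral-form rule.
#' @return an `update_config` object.
#' @export
update_config <- function(output_types = db_types(), auto_threshold = 1,
                          ignore_hydrogen = TRUE, prefer_neutral = TRUE,
                          exempt_single_element = TRUE,
                          exempt_types = character()) {
  bad <- setdiff(output_types, db_types())
  if (length(bad) > 0) {
    mm_abort(sprintf("output_types must be database identifier types; got: %s",
                     paste(bad, collapse = ", ")))
  }
  structure(list(output_types = output_types, auto_threshold = auto_threshold,
                 ignore_hydrogen = isTRUE(ignore_hydrogen),
                 prefer_neutral = isTRUE(prefer_neutral),
                 exempt_single_element = isTRUE(exempt_single_element),
                 exempt_types = exempt_types),
            class = "update_config")
}

# reconstruction annotations in long form over database identifier columns
recon_db_long <- function(recon, types) {
  present <- intersect(types, names(recon))
  rows <- lapply(present, function(tp) {
    vals <- recon[[tp]]
    keep <- which(!is.na(vals) & nzchar(vals))
    if (length(keep) == 0) return(NULL)
    tibble(met_id = recon$met_id[keep], id_type = tp, value = vals[keep]) |>
      mutate(value = lapply(.data$value, split_multi)) |>
      unnest("value") |>
      mutate(value = normalize_quietly(tp, .data$value)$value) |>
      filter(!is.na(.data$value))
  })
  empty <- tibble(met_id = character(), id_type = character(),
                  value = character())
  bind_rows(empty, rows)
}

empty_change_log <- function() {
  tibble(met_id = character(), id_type = character(), action = character(),
         old_value = character(), new_value = character(), reason = character(),
         confidence = double(), mode = character())
}

#' Review existing reconstruction annotations against a store
#'
#' For every existing database identifier of every metabolite:
#'
#' * if the store entry behind the identifier has a formula that fails the
#'   (by default hydrogen-insensitive) formula check against the metabolite's
#'   formula, the identifier is assumed incorrect and *removed*
#'   (`reason = "formula_mismatch"`);
#' * otherwise, if neutral-form preference applies and the entry carries a
#'   nonzero charge while a neutral (charge 0) entry of the same database
#'   shares its hydrogen-insensitive formula, the identifier is *replaced* by
#'   the neutral entry's identifier (`reason = "neutral_preference"`);
#' * identifiers absent from the store are *flagged for review*, never removed
#'   — absence of evidence is not evidence of incorrectness.
#'
#' Metabolites without a formula skip the formula check and are flagged as
#' such once.
#'
#' @param recon reconstruction tibble.
#' @param store an [xref_store()].
#' @param cfg an [update_config()].
#' @return change-log tibble (`met_id`, `id_type`, `action`, `old_value`,
#'   `new_value`, `reason`, `confidence`, `mode`); `flagged_for_review` rows
#'   are advisory, the rest are material changes.
#' @export
review_existing <- function(recon, store, cfg = update_config()) {
  ann <- recon_db_long(recon, cfg$output_types)
  met_info <- recon |>
    transmute(met_id = .data$met_id,
              met_fkey = formula_key(.data$formula, cfg$ignore_hydrogen),
              met_single = is_single_element(.data$formula))
  entries <- store$entries |>
    transmute(id_type = .data$source_db, value = .data$id,
              entry_fkey = formula_key(.data$formula, cfg$ignore_hydrogen),
              entry_hfree = formula_key(.data$formula, TRUE),
              entry_charge = .data$charge, in_store = TRUE)
  neutral_partners <- store$entries |>
    filter(!is.na(.data$charge), .data$charge == 0L) |>
    transmute(id_type = .data$source_db, neutral_id = .data$id,
              entry_hfree = formula_key(.data$formula, TRUE)) |>
    filter(!is.na(.data$entry_hfree)) |>
    group_by(.data$id_type, .data$entry_hfree) |>
    summarise(neutral_id = min(.data$neutral_id), .groups = "drop")

  df <- ann |>
    left_join(met_info, by = "met_id") |>
    left_join(entries, by = c("id_type", "value")) |>
    mutate(in_store = coalesce(.data$in_store, FALSE))

  flagged <- df |>
    filter(!.data$in_store) |>
    transmute(met_id = .data$met_id, id_type = .data$id_type,
              action = "flagged_for_review", old_value = .data$value,
              new_value = NA_character_, reason = "not_in_store",
              confidence = NA_real_, mode = "manual")

  checked <- df |> filter(.data$in_store)
  removed <- checked |>
    filter(!is.na(.data$met_fkey), !is.na(.data$entry_fkey),
           .data$met_fkey != .data$entry_fkey) |>
    transmute(met_id = .data$met_id, id_type = .data$id_type,
              action = "removed", old_value = .data$value,
              new_value = NA_character_, reason = "formula_mismatch",
              confidence = NA_real_, mode = "automatic")

  replaced <- empty_change_log()
  if (cfg$prefer_neutral) {
    eligible <- checked |>
      anti_join(removed, by = c("met_id", "id_type", value = "old_value")) |>
      filter(!is.na(.data$entry_charge), .data$entry_charge != 0L,
             !.data$id_type %in% cfg$exempt_types)
    if (cfg$exempt_single_element) {
      eligible <- eligible |> filter(!coalesce(.data$met_single, FALSE))
    }
    replaced <- eligible |>
      inner_join(neutral_partners, by = c("id_type", "entry_hfree")) |>
      filter(.data$neutral_id != .data$value) |>
      transmute(met_id = .data$met_id, id_type = .data$id_type,
                action = "replaced", old_value = .data$value,
                new_value = .data$neutral_id, reason = "neutral_preference",
                confidence = NA_real_, mode = "automatic")
  }

  no_formula <- recon |>
    filter(is.na(.data$formula) | !nzchar(coalesce(.data$formula, ""))) |>
    transmute(met_id = .data$met_id, id_type = NA_character_,
              action = "flagged_for_review", old_value = NA_character_,
              new_value = NA_character_, reason = "no_metabolite_formula",
              confidence = NA_real_, mode = "manual")

  bind_rows(removed, replaced, flagged, no_formula) |>
    arrange(.data$met_id, .data$id_type)
}

#' Fill missing annotations via additive mapping
#'
#' For each configured output type a metabolite lacks, runs
#' [additive_map_all()] over the metabolite's existing identifiers, discards
#' candidates whose store-entry formula fails the formula check against the
#' metabolite's formula, re-applies maximal-confidence retention to the
#' survivors, and dispatches them with [confidence_partition()]: unambiguous
#' candidates meeting `cfg$auto_threshold` are *added* automatically, the rest
#' are flagged for manual review.
#'
#' @inheritParams review_existing
#' @param acfg an [additive_config()].
#' @param strategy a [mapping_strategy()].
#' @param masks mask table for the mask strategy.
#' @param blocked optional tibble (`met_id`, `id_type`, `value`) of
#'   identifiers that must not be (re-)added, e.g. those just removed.
#' @return change-log tibble as in [review_existing()] (`added` and
#'   `flagged_for_review` rows).
#' @export
fill_missing <- function(recon, store, cfg = update_config(),
                         acfg = additive_config(), strategy = cts_strategy(),
                         masks = NULL, blocked = NULL) {
  met_fkey <- setNames(formula_key(recon$formula, cfg$ignore_hydrogen),
                       recon$met_id)
  entry_fkey_tbl <- store$entries |>
    transmute(id_type = .data$source_db, candidate = .data$id,
              entry_fkey = formula_key(.data$formula, cfg$ignore_hydrogen))
  out <- vector("list", length(cfg$output_types))
  for (k in seq_along(cfg$output_types)) {
    ot <- cfg$output_types[k]
    vals <- if (ot %in% names(recon)) recon[[ot]] else rep(NA_character_, nrow(recon))
    missing_rows <- which(is.na(vals) | !nzchar(vals))
    if (length(missing_rows) == 0) next
    cs <- additive_map_all(store, recon[missing_rows, , drop = FALSE], ot,
                           acfg, strategy, masks)
    if (nrow(cs) == 0) next
    if (!is.null(blocked) && nrow(blocked) > 0) {
      cs <- cs |>
        anti_join(blocked |> filter(.data$id_type == ot),
                  by = c("met_id", candidate = "value"))
    }
    cs <- cs |>
      left_join(entry_fkey_tbl |> filter(.data$id_type == ot) |>
                  select("candidate", "entry_fkey"),
                by = "candidate") |>
      mutate(met_fk = met_fkey[.data$met_id]) |>
      filter(is.na(.data$met_fk) | is.na(.data$entry_fkey) |
               .data$met_fk == .data$entry_fkey) |>
      select(-"entry_fkey", -"met_fk")
    if (nrow(cs) == 0) next
    cs <- cs |>
      group_by(.data$met_id) |>
      mutate(retained = .data$confidence == max(.data$confidence)) |>
      ungroup()
    parts <- confidence_partition(cs, cfg$auto_threshold)
    out[[k]] <- bind_rows(
      parts$automatic |>
        transmute(met_id = .data$met_id, id_type = ot, action = "added",
                  old_value = NA_character_, new_value = .data$candidate,
                  reason = "additive_confidence",
                  confidence = .data$confidence, mode = "automatic"),
      parts$review |>
        transmute(met_id = .data$met_id, id_type = ot,
                  action = "flagged_for_review", old_value = NA_character_,
                  new_value = .data$candidate, reason = "additive_confidence",
                  confidence = .data$confidence, mode = "manual")
    )
  }
  bind_rows(empty_change_log(), bind_rows(out)) |>
    arrange(.data$met_id, .data$id_type)
}

#' Run the full annotation-update pipeline
#'
#' Review existing identifiers ([review_existing()]), apply the resulting
#' removals and replacements, then fill missing annotations
#' ([fill_missing()]) and apply the automatic additions. Identifiers removed
#' in the review step are blocked from being re-added in the same run. The
#' pipeline is idempotent: a second run over its own output produces an empty
#' change log (advisory review flags may recur; they are reported separately
#' and change nothing).
#'
#' @inheritParams fill_missing
#' @return an `annotation_update` object: `recon` (updated reconstruction),
#'   `log` (material changes: added / removed / replaced) and `review`
#'   (advisory `flagged_for_review` rows). Use [summarize_changes()] or
#'   [glance()] for accounting.
#' @export
update_annotations <- function(recon, store, cfg = update_config(),
                               acfg = additive_config(),
                               strategy = cts_strategy(), masks = NULL) {
  stopifnot_cols(recon, c("met_id", "name"), "reconstruction table")
  rev <- review_existing(recon, store, cfg)
  material <- rev |> filter(.data$action != "flagged_for_review")
  recon2 <- apply_changes(recon, material, cfg$output_types)
  blocked <- material |>
    filter(.data$action %in% c("removed", "replaced")) |>
    select("met_id", "id_type", value = "old_value")
  fill <- fill_missing(recon2, store, cfg, acfg, strategy, masks,
                       blocked = blocked)
  added <- fill |> filter(.data$action == "added")
  recon3 <- apply_changes(recon2, added, cfg$output_types)
  structure(
    list(
      recon = recon3,
      log = bind_rows(material, added) |> arrange(.data$met_id, .data$id_type),
      review = bind_rows(rev, fill) |>
        filter(.data$action == "flagged_for_review") |>
        arrange(.data$met_id, .data$id_type)
    ),
    class = "annotation_update"
  )
}

# apply removed/replaced/added change-log rows to the reconstruction table
apply_changes <- function(recon, log, output_types) {
  if (nrow(log) == 0) return(recon)
  long <- recon_db_long(recon, output_types)
  long <- long |>
    anti_join(log |> filter(.data$action %in% c("removed", "replaced")),
              by = c("met_id", "id_type", value = "old_value"))
  additions <- log |>
    filter(.data$action %in% c("added", "replaced")) |>
    select("met_id", "id_type", value = "new_value")
  long <- bind_rows(long, additions) |> distinct()
  wide <- long |>
    group_by(.data$met_id, .data$id_type) |>
    summarise(value = join_multi(.data$value), .groups = "drop") |>
    pivot_wider(names_from = "id_type", values_from = "value")
  touched <- union(intersect(output_types, names(recon)), names(wide)[-1])
  recon |>
    select(-any_of(touched)) |>
    left_join(wide, by = "met_id")
}

#' @export
print.annotation_update <- function(x, ...) {
  cat(sprintf("<annotation_update: %d material changes, %d review flags>\n",
              nrow(x$log), nrow(x$review)))
  print(summarize_changes(x))
  invisible(x)
}

#' Summarize a change log
#'
#' Per-action, per-type, per-mode accounting of an update run, plus totals.
#' The total number of updated identifiers is the sum of added, removed and
#' replaced actions; review flags are counted separately and change nothing.
#'
#' @param x an `annotation_update` from [update_annotations()], or a
#'   change-log tibble.
#' @param review optional review tibble when `x` is a plain log.
#' @return a `change_summary`: list with `counts` (tibble `action`, `id_type`,
#'   `mode`, `n`) and `totals` (one-row tibble `n_added`, `n_removed`,
#'   `n_replaced`, `n_flagged`, `total_updated`).
#' @export
summarize_changes <- function(x, review = NULL) {
  if (inherits(x, "annotation_update")) {
    log <- x$log
    review <- x$review
  } else {
    log <- x
    review <- review %||% empty_change_log()
  }
  counts <- bind_rows(log, review) |>
    count(.data$action, .data$id_type, .data$mode)
  totals <- tibble(
    n_added = sum(log$action == "added"),
    n_removed = sum(log$action == "removed"),
    n_replaced = sum(log$action == "replaced"),
    n_flagged = nrow(review),
    total_updated = sum(log$action %in% c("added", "removed", "replaced"))
  )
  structure(list(counts = counts, totals = totals), class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  print(x$totals)
  print(x$counts, n = Inf)
  invisible(x)
}

#' @rdname summarize_changes
#' @param ... unused.
#' @export
glance.annotation_update <- function(x, ...) {
  summarize_changes(x)$totals
}

#' @rdname summarize_changes
#' @param object an `annotation_update`.
#' @export
autoplot.annotation_update <- function(object, ...) {
  counts <- summarize_changes(object)$counts |>
    filter(!is.na(.data$id_type))
  ggplot(counts, aes(x = .data$id_type, y = .data$n, fill = .data$action)) +
    geom_col(position = "dodge") +
    labs(x = "identifier type", y = "identifiers",
         title = "Annotation update actions by identifier type")
}
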