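#' Configuration for additive multi-identifier mapping
#'
#' Additive mapping runs one independent query per identifier *type* a
#' metabolite possesses and accumulates a per-candidate confidence score: each
#' input type that returns a candidate contributes its weight once, +0.5 for
#' name-derived hits and +1 for every other input type by default. Names get
#' the lower weight because the number of non-preferred and incorrect
#' identifiers returned for names is consistently higher than for other input
#' types. After all types have been queried, only candidates with the maximal
#' confidence for that metabolite are retained. No normalization by the number
#' of available input types is applied.
#'
#' @param name_weight confidence increment for name-derived hits (default 0.5).
#' @param other_weight increment for every other input type (default 1).
#'   Must satisfy `0 < name_weight <= other_weight`.
#' @param type_order ordered character vector of input identifier types, or
#'   `NULL` to derive it per reconstruction with
#'   [type_order_from_prevalence()].
#' @param auto_threshold minimum confidence for unambiguous candidates to be
#'   dispatched automatically by [confidence_partition()] (default 1: any
#'   unambiguous candidate supported by at least one non-name input type).
#' @return an `additive_config` object.
#' @export
additive_config <- function(name_weight = 0.5, other_weight = 1,
                            type_order = NULL, auto_threshold = 1) {
  if (!(name_weight > 0 && name_weight <= other_weight)) {
    mm_abort("weights must satisfy 0 < name_weight <= other_weight")
  }
  if (auto_threshold <= 0) mm_abort("auto_threshold must be positive")
  structure(list(name_weight = name_weight, other_weight = other_weight,
                 type_order = type_order, auto_threshold = auto_threshold),
            class = "additive_config")
}

#' Order input identifier types by annotation prevalence
#'
#' The order in which input types are added in additive mapping follows how
#' common each annotation already is in the reconstruction: name always comes
#' first (every metabolite has a name), then the remaining types by descending
#' count of metabolites carrying at least one identifier of that type, ties
#' broken alphabetically by type code. Types no metabolite carries are
#' omitted.
#'
#' @param recon reconstruction tibble (see [read_recon()]): one row per
#'   metabolite, identifier types as columns, multiple values pipe-separated.
#' @return ordered character vector of input types, starting with `"name"`.
#' @export
type_order_from_prevalence <- function(recon) {
  candidate_types <- setdiff(id_types(), c("name", "inchi"))
  present <- intersect(candidate_types, names(recon))
  counts <- vapply(present, function(tp) {
    sum(!is.na(recon[[tp]]) & nzchar(recon[[tp]]))
  }, integer(1))
  counts <- counts[counts > 0]
  ord <- names(counts)[order(-counts, names(counts))]
  c("name", ord)
}

#' Additive confidence-weighted mapping
#'
#' For each input type in the configured order that the metabolite possesses
#' (the output type itself excluded — an existing identifier never queries for
#' itself), one independent mapping query is run; returned candidates accrue
#' the type's weight (once per type, however many identifiers of that type the
#' metabolite has). Candidates whose confidence equals the per-metabolite
#' maximum are marked retained.
#'
#' Under the InChIKey strategy the queries are genuinely independent and
#' additive mapping sharpens the candidate set; under the mask strategy every
#' query returns the mask closure, so all candidates tie and the additive step
#' degenerates — the structural reason mask-based tools gain nothing from
#' multi-identifier input.
#'
#' @param store an [xref_store()].
#' @param met a one-row reconstruction tibble (`additive_map()`), or a full
#'   reconstruction (`additive_map_all()`).
#' @param recon reconstruction tibble for `additive_map_all()`.
#' @param output_type identifier type to search for.
#' @param cfg an [additive_config()].
#' @param strategy a [mapping_strategy()].
#' @param masks mask table, for the mask strategy.
#' @return tibble with columns `met_id`, `output_type`, `candidate`,
#'   `confidence`, `supporting_types` (`+`-separated, in query order) and
#'   `retained`. Metabolites with no usable inputs or no hits contribute no
#'   rows.
#' @export
additive_map <- function(store, met, output_type, cfg = additive_config(),
                         strategy = cts_strategy(), masks = NULL) {
  met <- as_tibble(met)
  if (nrow(met) != 1) mm_abort("additive_map() maps one metabolite; see additive_map_all()")
  additive_map_all(store, met, output_type, cfg, strategy, masks)
}

#' @rdname additive_map
#' @export
additive_map_all <- function(store, recon, output_type,
                             cfg = additive_config(),
                             strategy = cts_strategy(), masks = NULL) {
  stopifnot_cols(recon, c("met_id", "name"), "reconstruction table")
  order <- cfg$type_order %||% type_order_from_prevalence(recon)
  order <- setdiff(order, output_type)
  if (!strategy$allow_names && strategy$kind == "inchikey") {
    order <- setdiff(order, "name")
  }
  order <- intersect(order, intersect(names(recon), id_types()))

  per_type <- vector("list", length(order))
  for (k in seq_along(order)) {
    tp <- order[k]
    vals <- recon[[tp]]
    rows <- which(!is.na(vals) & nzchar(vals))
    if (length(rows) == 0) next
    queries <- tibble(met_id = recon$met_id[rows], value = vals[rows]) |>
      mutate(value = lapply(.data$value, split_multi)) |>
      unnest("value") |>
      mutate(value = normalize_quietly(tp, .data$value)$value) |>
      filter(!is.na(.data$value)) |>
      distinct() |>
      mutate(qid = row_number(), input_type = tp)
    if (nrow(queries) == 0) next
    hits <- if (strategy$kind == "mask") {
      map_mask_batch(masks, queries, output_type)
    } else {
      map_ids_batch(store, queries, output_type, strategy)
    }
    if (nrow(hits) == 0) next
    per_type[[k]] <- hits |>
      left_join(queries |> select("qid", "met_id"), by = "qid") |>
      distinct(.data$met_id, .data$candidate) |>
      mutate(input_type = tp,
             weight = if (tp == "name") cfg$name_weight else cfg$other_weight)
  }
  scored <- bind_rows(per_type)
  if (nrow(scored) == 0) {
    return(tibble(met_id = character(), output_type = character(),
                  candidate = character(), confidence = double(),
                  supporting_types = character(), retained = logical()))
  }
  scored |>
    mutate(ord = match(.data$input_type, order)) |>
    arrange(.data$met_id, .data$candidate, .data$ord) |>
    group_by(.data$met_id, .data$candidate) |>
    summarise(confidence = sum(.data$weight),
              supporting_types = paste(.data$input_type, collapse = "+"),
              .groups = "drop_last") |>
    mutate(retained = .data$confidence == max(.data$confidence)) |>
    ungroup() |>
    mutate(output_type = output_type, .after = "met_id") |>
    arrange(.data$met_id, desc(.data$confidence), .data$candidate)
}

# vectorized mask queries, same contract as map_ids_batch
map_mask_batch <- function(masks, queries, output_type) {
  if (is.null(masks)) mm_abort("mask strategy requires a mask table")
  hit <- queries |>
    inner_join(masks, by = c(input_type = "id_type", value = "value"),
               relationship = "many-to-many")
  members <- hit |>
    select("qid", "mask_id") |>
    distinct() |>
    inner_join(masks |> filter(.data$id_type == output_type),
               by = "mask_id", relationship = "many-to-many") |>
    select("qid", candidate = "value") |>
    mutate(via_key = NA_character_)
  members |>
    left_join(queries |> select("qid", "input_type", "value"), by = "qid") |>
    filter(!(.data$input_type == output_type & .data$candidate == .data$value)) |>
    select("qid", "candidate", "via_key") |>
    distinct()
}

#' Split retained candidates into automatic and review queues
#'
#' A metabolite's retained candidate set is dispatched automatically only when
#' it is a *singleton* whose confidence reaches `auto_threshold`; otherwise all
#' retained candidates go to the manual review queue. With the default
#' threshold of 1, a name-only hit (confidence 0.5) always requires review,
#' reflecting that name-derived evidence alone is not trusted for automatic
#' annotation.
#'
#' @param cs candidate tibble from [additive_map()] / [additive_map_all()]
#'   (possibly covering many metabolites).
#' @param auto_threshold positive confidence threshold (default 1).
#' @return list with tibbles `automatic` and `review` (columns as in `cs`,
#'   without `retained`).
#' @export
confidence_partition <- function(cs, auto_threshold = 1) {
  if (auto_threshold <= 0) mm_abort("auto_threshold must be positive")
  retained <- cs |> filter(.data$retained)
  flagged <- retained |>
    group_by(.data$met_id, .data$output_type) |>
    mutate(.auto = n() == 1 & .data$confidence >= auto_threshold) |>
    ungroup()
  list(
    automatic = flagged |> filter(.data$.auto) |> select(-".auto", -"retained"),
    review = flagged |> filter(!.data$.auto) |> select(-".auto", -"retained")
  )
}
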