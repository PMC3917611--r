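#' Mapping strategies
#'
#' A mapping strategy bundles the axes along which the evaluated
#' identifier-mapping approaches differ:
#'
#' * `kind = "inchikey"`: resolve the input identifier to its linked standard
#'   InChIKey(s) and return all identifiers of the requested output type
#'   linked to the same key(s). Queries with different identifiers of the same
#'   compound are *independent* — they can return different sets.
#' * `kind = "mask"`: return all same-mask identifiers of the output type
#'   (see [build_masks()]). Queries with any member of a mask return the same
#'   set, so queries are *not* independent.
#' * `allow_names`: whether chemical names are accepted as inputs (only
#'   meaningful for the InChIKey kind; the mask kind always groups names).
#' * `include_obsolete`: also traverse superseded key assignments.
#' * `skeleton`: match on the 14-character skeleton block instead of the full
#'   27-character key. Off by default and exposed for exploration only —
#'   skeleton matching conflates stereoisomers, defeating the point of
#'   standard-key joins.
#'
#' `cts_strategy()` (permissive aggregation, names allowed) and
#' `unichem_strategy()` (strict quality-checked aggregation, no names) are the
#' two InChIKey-strategy presets contrasted throughout; `mask_strategy()` is
#' the metabolite-mask preset.
#'
#' @param kind `"inchikey"` or `"mask"`.
#' @param allow_names accept name inputs (default `TRUE`).
#' @param include_obsolete traverse obsolete assignments (default `FALSE`).
#' @param skeleton match on skeleton blocks (default `FALSE`).
#' @return a `mapping_strategy` object.
#' @export
mapping_strategy <- function(kind = c("inchikey", "mask"), allow_names = TRUE,
                             include_obsolete = FALSE, skeleton = FALSE) {
  structure(
    list(kind = match.arg(kind), allow_names = isTRUE(allow_names),
         include_obsolete = isTRUE(include_obsolete),
         skeleton = isTRUE(skeleton)),
    class = "mapping_strategy"
  )
}

#' @rdname mapping_strategy
#' @export
cts_strategy <- function(include_obsolete = FALSE) {
  mapping_strategy("inchikey", allow_names = TRUE,
                   include_obsolete = include_obsolete)
}

#' @rdname mapping_strategy
#' @export
unichem_strategy <- function(include_obsolete = FALSE) {
  mapping_strategy("inchikey", allow_names = FALSE,
                   include_obsolete = include_obsolete)
}

#' @rdname mapping_strategy
#' @export
mask_strategy <- function() {
  mapping_strategy("mask", allow_names = TRUE)
}

#' Map one identifier to identifiers of another type
#'
#' Under the InChIKey strategy, the input is resolved to its linked standard
#' InChIKeys (identity for key inputs, the name index for names, current key
#' assignments for database identifiers) and all current assignments of the
#' output type over those keys are returned. An empty result is a valid
#' outcome: it signals that no identifier of the requested output type is
#' associated with the exact same standard InChI — e.g. when two databases
#' store different stereoisomers of the same compound under different keys.
#'
#' Under the mask strategy, all output-type members of the mask containing the
#' input are returned (the input itself excluded).
#'
#' @param store an [xref_store()] (InChIKey strategy).
#' @param input_type,value the query identifier (one of [id_types()]).
#' @param output_type requested output identifier type.
#' @param strategy a [mapping_strategy()].
#' @param masks mask table from [build_masks()] (mask strategy only).
#' @return tibble with columns `input_type`, `input_value`, `output_type`,
#'   `candidate`, `via_key` (`NA` for the mask strategy), sorted by candidate
#'   for deterministic output. Zero rows when nothing maps.
#' @examples
#' fx <- fixture_sugars()
#' store <- xref_store(fx$entries, strict = FALSE)
#' map_ids(store, "name", "dextrose", "pubchem")
#' map_ids(store, "kegg", "C00243", "hmdb") # empty: stereoisomer split
#' @export
map_ids <- function(store = NULL, input_type, value, output_type,
                    strategy = cts_strategy(), masks = NULL) {
  input_type <- match.arg(input_type, id_types())
  output_type <- match.arg(output_type, id_types())
  if (strategy$kind == "mask") {
    if (is.null(masks)) mm_abort("mask strategy requires a mask table")
    return(map_mask(masks, input_type, value, output_type))
  }
  if (input_type == "name" && !strategy$allow_names) {
    mm_abort("name inputs are not supported by this mapping strategy")
  }
  value <- normalize_identifier(input_type, value)
  res <- map_ids_batch(store,
                       tibble(qid = 1L, input_type = input_type, value = value),
                       output_type, strategy)
  res |>
    transmute(input_type = input_type, input_value = value,
              output_type = output_type,
              candidate = .data$candidate, via_key = .data$via_key) |>
    arrange(.data$candidate)
}

# vectorized mapping over many queries at once; the battery, additive mapping
# and the update pipeline all route through this join-based core.
# queries: tibble(qid, input_type, value) with values already normalized.
map_ids_batch <- function(store, queries, output_type, strategy) {
  stopifnot(inherits(store, "xref_store"))
  asg <- store$assignments
  if (!strategy$include_obsolete) asg <- asg |> filter(.data$current)

  resolve_one_type <- function(tp, q) {
    if (nrow(q) == 0) return(tibble(qid = integer(), key = character()))
    if (tp == "inchikey") {
      q |> transmute(.data$qid, key = .data$value)
    } else if (tp == "name") {
      q |> inner_join(store$name_index, by = c(value = "name"),
                      relationship = "many-to-many") |>
        select("qid", "key")
    } else if (tp %in% db_types()) {
      q |> inner_join(asg |> filter(.data$id_type == tp),
                      by = c(value = "id"), relationship = "many-to-many") |>
        select("qid", "key")
    } else {
      mm_abort(sprintf("unsupported input type for InChIKey mapping: %s", tp))
    }
  }
  keys <- queries |>
    group_by(.data$input_type) |>
    group_map(~ resolve_one_type(.y$input_type, .x |>
                                   mutate(input_type = .y$input_type))) |>
    bind_rows() |>
    distinct()

  out_asg <- asg |> filter(.data$id_type == output_type)
  if (strategy$skeleton) {
    keys <- keys |> mutate(skel = substr(.data$key, 1, 14))
    out_asg <- out_asg |> mutate(skel = substr(.data$key, 1, 14))
    hits <- keys |>
      inner_join(out_asg, by = "skel", suffix = c("_in", ""),
                 relationship = "many-to-many") |>
      select("qid", candidate = "id", via_key = "key")
  } else {
    hits <- keys |>
      inner_join(out_asg, by = "key", relationship = "many-to-many") |>
      select("qid", candidate = "id", via_key = "key")
  }
  # a query never returns itself as its own candidate
  hits <- hits |>
    left_join(queries |> select("qid", "input_type", "value"), by = "qid") |>
    filter(!(.data$input_type == output_type & .data$candidate == .data$value)) |>
    select("qid", "candidate", "via_key") |>
    distinct()
  hits
}

#' Merge identifier groups into metabolite masks
#'
#' A metabolite mask is a merged identifier group treated as referring to one
#' compound. Groups (e.g. one per reconstruction metabolite plus one per
#' source-database entry) are merged by transitive closure: two groups belong
#' to the same mask iff they are connected through groups sharing at least one
#' identifier whose type is in `merge_on_types`. The published merge
#' heuristics of mask-based tools are not specified, so the rule here is the
#' simplest one that reproduces the documented mask behaviors (shared output
#' sets for all members, over-merging across stereoisomer splits); the
#' identifier-type set it merges on is configurable, with names excluded by
#' default since name collisions are the least trustworthy evidence.
#'
#' @param groups tibble with columns `group` (group label), `id_type`,
#'   `value` (normalized identifier).
#' @param merge_on_types identifier types whose sharing merges groups
#'   (default: all types except `name` and `inchi`).
#' @return tibble of mask members: `mask_id` (integer), `id_type`, `value`.
#'   Masks partition the groups; every identifier of a group (including
#'   non-merge types such as names) is a member of that group's mask.
#' @export
build_masks <- function(groups,
                        merge_on_types = setdiff(id_types(), c("name", "inchi"))) {
  stopifnot_cols(groups, c("group", "id_type", "value"), "group table")
  if (nrow(groups) == 0) {
    return(tibble(mask_id = integer(), id_type = character(), value = character()))
  }
  groups <- groups |> mutate(group = as.character(.data$group))
  gids <- unique(groups$group)
  shared <- groups |>
    filter(.data$id_type %in% merge_on_types) |>
    mutate(token = paste(.data$id_type, .data$value, sep = ":"))
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c(paste0("g\x1f", gids),
                       unique(paste0("t\x1f", shared$token))))
  if (nrow(shared) > 0) {
    g <- igraph::add_edges(g, c(rbind(paste0("g\x1f", shared$group),
                                      paste0("t\x1f", shared$token))))
  }
  comp <- igraph::components(g)$membership
  gcomp <- comp[paste0("g\x1f", gids)]
  mask_of_group <- setNames(as.integer(factor(gcomp, levels = unique(gcomp))), gids)
  groups |>
    mutate(mask_id = mask_of_group[.data$group]) |>
    distinct(.data$mask_id, .data$id_type, .data$value) |>
    arrange(.data$mask_id, .data$id_type, .data$value)
}

#' Query a mask table
#'
#' Returns every output-type identifier sharing a mask with the input. By
#' construction the result is identical whichever member of the mask is used
#' as the query — mask queries are not independent.
#'
#' @param masks mask table from [build_masks()].
#' @inheritParams map_ids
#' @return tibble in the same shape as [map_ids()] (with `via_key = NA`).
#'   Empty when the input belongs to no mask.
#' @export
map_mask <- function(masks, input_type, value, output_type) {
  stopifnot_cols(masks, c("mask_id", "id_type", "value"), "mask table")
  value <- normalize_identifier(input_type, value)
  hit <- masks |> filter(.data$id_type == input_type, .data$value == !!value)
  members <- masks |>
    filter(.data$mask_id %in% hit$mask_id, .data$id_type == output_type) |>
    filter(!(.data$id_type == input_type & .data$value == !!value))
  tibble(
    input_type = input_type, input_value = value, output_type = output_type,
    candidate = sort(unique(members$value)), via_key = NA_character_
  )
}
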