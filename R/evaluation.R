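#' Identifier-mapping evaluation score
#'
#' For a mapping test with `n_in` input identifiers, of which `n_hits`
#' returned at least one output identifier, `n_out` output identifiers
#' returned in total and `n_matches` of them preferred, the score is
#'
#' \deqn{Score = (Hits \times Matches) / (In \times Out)}
#'
#' It ranges over \[0, 1\]: maximal when every input returns exactly its
#' preferred output and nothing else, lower when non-preferred identifiers are
#' returned (inflating `Out`) or inputs return nothing (reducing `Hits`),
#' since both cost manual sorting or gap-filling effort. Defined as 0 when
#' `n_out = 0`. The score is scale-invariant: multiplying all four counts by a
#' constant leaves it unchanged.
#'
#' @param n_in number of input identifiers (> 0).
#' @param n_hits inputs with at least one returned output (`0 <= n_hits <= n_in`).
#' @param n_out total returned output identifiers.
#' @param n_matches preferred outputs returned (`0 <= n_matches <= n_out`).
#' @return numeric score in \[0, 1\]; vectorized over the four counts.
#' @examples
#' mapping_score(99, 98, 146, 93)   # 0.63 at 2-decimal rounding
#' mapping_score(100, 67, 141, 63)  # 0.30
#' @export
mapping_score <- function(n_in, n_hits, n_out, n_matches) {
  if (any(n_in <= 0)) mm_abort("n_in must be positive")
  if (any(n_hits < 0 | n_hits > n_in)) mm_abort("need 0 <= n_hits <= n_in")
  if (any(n_out < 0 | n_matches < 0 | n_matches > n_out)) {
    mm_abort("need 0 <= n_matches <= n_out")
  }
  ifelse(n_out == 0, 0, (n_hits * n_matches) / (n_in * n_out))
}

label_priority <- function() {
  c("preferred", "valid", "invalid", "incorrect", "nonexistent")
}

#' Label returned output identifiers against a truth table
#'
#' Each returned candidate is annotated with one of five labels: *preferred*
#' (the preferred stereoisomer, generally the input stereoisomer; exactly one
#' per input/output-type pair), *valid* (a valid but non-preferred
#' stereoisomer), *invalid* (an invalid stereoisomer or mixture), *incorrect*
#' (a different compound) or *nonexistent* (points to nothing). Candidates
#' absent from the truth table are labeled `incorrect` when the identifier
#' exists in `known_ids` (it is a real entry, just the wrong compound) and
#' `nonexistent` otherwise (a dangling identifier).
#'
#' @param results mapping results: tibble with columns `input_type`,
#'   `input_value`, `output_type`, `candidate` (e.g. from [map_ids()]).
#' @param truth truth table: tibble with columns `input_type`, `input_value`,
#'   `output_type`, `candidate`, `label`.
#' @param known_ids optional tibble of existing identifiers (`id_type`,
#'   `value`) used for the unknown-candidate policy.
#' @return `results` with a `label` column, one row per distinct
#'   (input, candidate).
#' @export
label_outputs <- function(results, truth, known_ids = NULL) {
  stopifnot_cols(results, c("input_type", "input_value", "output_type", "candidate"),
                 "results table")
  stopifnot_cols(truth, c("input_type", "input_value", "output_type",
                          "candidate", "label"), "truth table")
  labeled <- results |>
    distinct(.data$input_type, .data$input_value, .data$output_type,
             .data$candidate) |>
    left_join(truth |> distinct(.data$input_type, .data$input_value,
                                .data$output_type, .data$candidate, .data$label),
              by = c("input_type", "input_value", "output_type", "candidate"))
  if (!is.null(known_ids)) {
    labeled <- labeled |>
      left_join(known_ids |> distinct(.data$id_type, .data$value) |>
                  mutate(.known = TRUE),
                by = c(output_type = "id_type", candidate = "value")) |>
      mutate(label = coalesce(.data$label,
                              ifelse(coalesce(.data$.known, FALSE),
                                     "incorrect", "nonexistent"))) |>
      select(-".known")
  } else {
    labeled <- labeled |> mutate(label = coalesce(.data$label, "nonexistent"))
  }
  labeled
}

# In/Hits/Out/Matches for one test from the supplied inputs and the labeled
# candidates they returned
score_counts <- function(inputs, labeled) {
  tibble(
    n_in = n_distinct(inputs$input_value),
    n_hits = n_distinct(labeled$input_value),
    n_out = nrow(labeled),
    n_matches = sum(labeled$label == "preferred")
  )
}

#' Run an identifier-mapping test battery
#'
#' Executes one mapping test per (input type, output type) pair, skipping
#' pairs where input and output types coincide, and — for InChIKey strategies
#' without name support — pairs with name inputs. With the default six input
#' types and four output types this yields 20 pairs; restricted to the
#' coverage of a strict no-names service (no names, no PubChem), 9 pairs.
#'
#' For each pair, the inputs are the test-set metabolites possessing that
#' input type (so `In` varies by type); every input is queried independently,
#' candidates are labeled against the truth table, and the In/Hits/Out/Matches
#' counts and [mapping_score()] are recorded. The report also pools unique
#' output identifiers across all pairs (an identifier returned in several
#' tests is counted once, under its best label).
#'
#' @param store an [xref_store()] (InChIKey strategies).
#' @param test_set reconstruction-style tibble of test metabolites.
#' @param truth truth table (see [label_outputs()]).
#' @param strategy a [mapping_strategy()].
#' @param masks mask table for the mask strategy.
#' @param input_types,output_types identifier types to cross.
#' @param known_ids unknown-candidate policy table (see [label_outputs()]).
#' @return a `battery_report`: use [tidy()] for per-pair counts and scores,
#'   [glance()] for the mean counts, the mean of per-pair scores and the
#'   score recomputed from mean counts, and [autoplot()] for the pooled
#'   label tallies.
#' @export
run_battery <- function(store = NULL, test_set, truth,
                        strategy = cts_strategy(), masks = NULL,
                        input_types = battery_input_types(),
                        output_types = battery_output_types(),
                        known_ids = NULL) {
  if (is.null(test_set) || nrow(test_set) == 0) mm_abort("empty test set")
  if (strategy$kind == "inchikey" && !strategy$allow_names) {
    input_types <- setdiff(input_types, "name")
  }
  pairs <- expand.grid(input_type = input_types, output_type = output_types,
                       stringsAsFactors = FALSE) |>
    filter(.data$input_type != .data$output_type)

  all_labeled <- vector("list", nrow(pairs))
  counts <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    tp <- pairs$input_type[p]
    ot <- pairs$output_type[p]
    vals <- test_set[[tp]]
    rows <- which(!is.na(vals) & nzchar(vals))
    inputs <- tibble(
      input_value = map_chr(vals[rows], function(v) split_multi(v)[1])
    ) |>
      mutate(input_value = normalize_quietly(tp, .data$input_value)$value) |>
      filter(!is.na(.data$input_value)) |>
      distinct()
    queries <- inputs |>
      mutate(qid = row_number(), input_type = tp, value = .data$input_value)
    hits <- if (strategy$kind == "mask") {
      map_mask_batch(masks, queries, ot)
    } else {
      map_ids_batch(store, queries, ot, strategy)
    }
    results <- hits |>
      left_join(queries |> select("qid", "input_value"), by = "qid") |>
      transmute(input_type = tp, input_value = .data$input_value,
                output_type = ot, candidate = .data$candidate)
    labeled <- label_outputs(results, truth, known_ids)
    all_labeled[[p]] <- labeled
    counts[[p]] <- score_counts(inputs, labeled) |>
      mutate(input_type = tp, output_type = ot, .before = 1)
  }
  per_pair <- bind_rows(counts) |>
    mutate(score = mapping_score(.data$n_in, .data$n_hits, .data$n_out,
                                 .data$n_matches))
  pooled <- bind_rows(all_labeled) |>
    mutate(label = factor(.data$label, levels = label_priority())) |>
    group_by(.data$output_type, .data$candidate) |>
    summarise(label = label_priority()[min(as.integer(.data$label))],
              .groups = "drop") |>
    count(label = factor(.data$label, levels = label_priority()),
          .drop = FALSE, name = "n_unique")
  mean_counts <- per_pair |>
    summarise(across(c("n_in", "n_hits", "n_out", "n_matches"), mean))
  structure(
    list(
      pairs = per_pair,
      pooled = pooled,
      mean_counts = mean_counts,
      mean_score = mean(per_pair$score),
      score_from_mean_counts = mapping_score(
        mean_counts$n_in, mean_counts$n_hits,
        mean_counts$n_out, mean_counts$n_matches
      )
    ),
    class = "battery_report"
  )
}

#' @export
print.battery_report <- function(x, ...) {
  cat(sprintf("<battery_report: %d input-output pairs>\n", nrow(x$pairs)))
  print(x$pairs, n = Inf)
  cat(sprintf("mean score (per-pair mean): %.2f; score of mean counts: %.2f\n",
              round_half_up(x$mean_score, 2),
              round_half_up(x$score_from_mean_counts, 2)))
  invisible(x)
}

#' @rdname run_battery
#' @param x a `battery_report`.
#' @param ... unused.
#' @export
tidy.battery_report <- function(x, ...) x$pairs

#' @rdname run_battery
#' @export
glance.battery_report <- function(x, ...) {
  x$mean_counts |>
    mutate(n_pairs = nrow(x$pairs),
           mean_score = x$mean_score,
           score_from_mean_counts = x$score_from_mean_counts)
}

#' @rdname run_battery
#' @param object a `battery_report`.
#' @export
autoplot.battery_report <- function(object, ...) {
  ggplot(object$pooled, aes(x = .data$label, y = .data$n_unique)) +
    geom_col() +
    labs(x = NULL, y = "unique output identifiers",
         title = "Pooled output identifiers by annotation label")
}

#' Run the additive mapping test battery
#'
#' One battery per prefix of the input-type order: the first iteration uses
#' names only, each subsequent iteration adds the next most prevalent input
#' type, and only *retained* (maximal-confidence) candidates are counted. `In`
#' equals the full test-set size for every iteration, since every metabolite
#' has a name. For strategies without name support the order starts at the
#' first non-name type instead.
#'
#' Candidates are labeled against a metabolite-level truth table (additive
#' queries combine several inputs, so labels attach to the metabolite rather
#' than to a single input identifier).
#'
#' @inheritParams run_battery
#' @param met_truth tibble `met_id`, `output_type`, `candidate`, `label`.
#' @param cfg an [additive_config()].
#' @return an `additive_battery_report`; [tidy()] gives per-iteration,
#'   per-output-type counts and scores, [glance()] one row per iteration with
#'   mean counts and mean score.
#' @export
run_additive_battery <- function(store, test_set, met_truth,
                                 cfg = additive_config(),
                                 strategy = cts_strategy(),
                                 output_types = battery_output_types(),
                                 masks = NULL, known_ids = NULL) {
  if (is.null(test_set) || nrow(test_set) == 0) mm_abort("empty test set")
  stopifnot_cols(met_truth, c("met_id", "output_type", "candidate", "label"),
                 "metabolite truth table")
  order <- cfg$type_order %||% type_order_from_prevalence(test_set)
  if (strategy$kind == "inchikey" && !strategy$allow_names) {
    order <- setdiff(order, "name")
  }
  n_in <- nrow(test_set)
  iters <- vector("list", length(order))
  for (k in seq_along(order)) {
    cfg_k <- cfg
    cfg_k$type_order <- order[seq_len(k)]
    per_out <- vector("list", length(output_types))
    for (j in seq_along(output_types)) {
      ot <- output_types[j]
      cs <- additive_map_all(store, test_set, ot, cfg_k, strategy, masks) |>
        filter(.data$retained)
      labeled <- cs |>
        left_join(met_truth |> filter(.data$output_type == ot) |>
                    select("met_id", "candidate", "label"),
                  by = c("met_id", "candidate"))
      if (!is.null(known_ids)) {
        labeled <- labeled |>
          left_join(known_ids |> distinct(.data$id_type, .data$value) |>
                      mutate(.known = TRUE),
                    by = c(output_type = "id_type", candidate = "value")) |>
          mutate(label = coalesce(.data$label,
                                  ifelse(coalesce(.data$.known, FALSE),
                                         "incorrect", "nonexistent")))
      } else {
        labeled <- labeled |> mutate(label = coalesce(.data$label, "nonexistent"))
      }
      per_out[[j]] <- tibble(
        iteration = k,
        added_type = order[k],
        output_type = ot,
        n_in = n_in,
        n_hits = n_distinct(labeled$met_id),
        n_out = nrow(labeled),
        n_matches = sum(labeled$label == "preferred")
      )
    }
    iters[[k]] <- bind_rows(per_out)
  }
  detail <- bind_rows(iters) |>
    mutate(score = mapping_score(.data$n_in, .data$n_hits, .data$n_out,
                                 .data$n_matches))
  summary <- detail |>
    group_by(.data$iteration, .data$added_type) |>
    summarise(across(c("n_in", "n_hits", "n_out", "n_matches"), mean),
              mean_score = mean(.data$score), .groups = "drop")
  structure(list(detail = detail, summary = summary),
            class = "additive_battery_report")
}

#' @export
print.additive_battery_report <- function(x, ...) {
  cat("<additive_battery_report>\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' @rdname run_additive_battery
#' @param x,object an `additive_battery_report`.
#' @param ... unused.
#' @export
tidy.additive_battery_report <- function(x, ...) x$detail

#' @rdname run_additive_battery
#' @export
glance.additive_battery_report <- function(x, ...) x$summary

#' @rdname run_additive_battery
#' @export
autoplot.additive_battery_report <- function(object, ...) {
  ggplot(object$summary,
         aes(x = factor(.data$iteration), y = .data$mean_score)) +
    geom_col() +
    labs(x = "iteration (input types added in prevalence order)",
         y = "mean score",
         title = "Additive mapping: score by number of input types")
}
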