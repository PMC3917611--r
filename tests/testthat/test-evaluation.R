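test_that("the score formula reproduces published worked examples", {
  expect_identical(round_half_up(mapping_score(99, 98, 146, 93), 2), 0.63)
  expect_identical(round_half_up(mapping_score(100, 67, 141, 63), 2), 0.30)
  expect_identical(mapping_score(50, 50, 50, 50), 1)
  expect_identical(mapping_score(10, 0, 0, 0), 0)
  expect_error(mapping_score(0, 0, 0, 0), "positive")
  expect_error(mapping_score(10, 11, 12, 12), "n_hits")
  expect_error(mapping_score(10, 9, 8, 9), "n_matches")
})

test_that("the score is scale-invariant and monotone in the right directions", {
  withr::local_seed(12)
  for (rep in 1:25) {
    n_in <- sample(50:150, 1)
    n_hits <- sample(0:n_in, 1)
    n_out <- sample(n_hits:200, 1)
    n_matches <- sample(0:min(n_out, n_in), 1)
    s <- mapping_score(n_in, n_hits, n_out, n_matches)
    expect_true(s >= 0 && s <= 1)
    expect_equal(mapping_score(3 * n_in, 3 * n_hits, 3 * n_out, 3 * n_matches), s)
    if (n_out > 0) {
      expect_gte(mapping_score(n_in, n_hits, n_out, min(n_matches + 1, n_out)), s)
      expect_lte(mapping_score(n_in, n_hits, n_out + 5, n_matches), s)
      if (n_hits < n_in && n_hits + 1 <= n_out) {
        expect_gte(mapping_score(n_in, n_hits + 1, n_out, n_matches), s)
      }
    }
  }
})

test_that("the D-glucose output quartet is labeled across all five categories", {
  sugars <- fixture_sugars()
  results <- tibble(
    input_type = "kegg", input_value = "C00031", output_type = "pubchem",
    candidate = c("5793", "79025", "206", "440147", "424242")
  )
  labeled <- label_outputs(results, sugars$truth, sugars$known_ids)
  got <- setNames(labeled$label, labeled$candidate)
  expect_identical(got[["5793"]], "preferred")    # same stereoisomer
  expect_identical(got[["79025"]], "valid")       # more specific epimer
  expect_identical(got[["206"]], "invalid")       # generic hexose
  expect_identical(got[["440147"]], "incorrect")  # different compound
  expect_identical(got[["424242"]], "nonexistent")# dangling identifier
})

test_that("counts follow their definitions at the edges", {
  inputs <- tibble(input_value = c("a", "b", "c"))
  labeled <- tibble(input_value = c("a", "a", "b"),
                    label = c("preferred", "valid", "preferred"))
  counts <- metamapr:::score_counts(inputs, labeled)
  expect_identical(counts$n_in, 3L)      # every input counts toward In
  expect_identical(counts$n_hits, 2L)    # c returned nothing
  expect_identical(counts$n_out, 3L)
  expect_identical(counts$n_matches, 2L)
  # a perfect mapping has Matches = Out = Hits
  perfect <- tibble(input_value = c("a", "b", "c"), label = "preferred")
  pc <- metamapr:::score_counts(inputs, perfect)
  expect_identical(pc$n_matches, pc$n_out)
  expect_identical(pc$n_out, pc$n_hits)
})

fx_clean <- generate_fixture(fixture_spec(
  n_compounds = 60, stereo_split_rate = 0, name_ambiguity_rate = 0,
  bad_entry_rate = 0, charged_duplicate_rate = 0, obsolete_rate = 0,
  planted_error_rate = 0, seed = 14
))

test_that("the battery crosses input and output types, skipping same-type pairs", {
  store <- xref_store(fx_clean$entries, strict = FALSE)
  rep20 <- run_battery(store, fx_clean$recon, fx_clean$truth, cts_strategy(),
                       known_ids = fx_clean$manifest$real_ids)
  expect_identical(nrow(tidy(rep20)), 20L)
  expect_identical(anyDuplicated(tidy(rep20)[c("input_type", "output_type")]), 0L)
  expect_false(any(tidy(rep20)$input_type == tidy(rep20)$output_type))
  rep9 <- run_battery(store, fx_clean$recon, fx_clean$truth, unichem_strategy(),
                      input_types = c("inchikey", "chebi", "hmdb", "kegg"),
                      output_types = c("chebi", "hmdb", "kegg"),
                      known_ids = fx_clean$manifest$real_ids)
  expect_identical(nrow(tidy(rep9)), 9L)
  expect_error(run_battery(store, fx_clean$recon[0, ], fx_clean$truth),
               "empty test set")
})

test_that("In varies with how many test metabolites carry each input type", {
  store <- xref_store(fx_clean$entries, strict = FALSE)
  rep <- run_battery(store, fx_clean$recon, fx_clean$truth, cts_strategy())
  pairs <- tidy(rep)
  have <- function(tp) sum(!is.na(fx_clean$recon[[tp]]))
  for (tp in unique(pairs$input_type)) {
    expected <- if (tp == "name") nrow(fx_clean$recon) else have(tp)
    expect_identical(unique(pairs$n_in[pairs$input_type == tp]), expected)
  }
})

test_that("a perfect store scores 1.0 on every pair", {
  store <- xref_store(fx_clean$entries, strict = TRUE)
  rep <- run_battery(store, fx_clean$recon, fx_clean$truth, cts_strategy(),
                     known_ids = fx_clean$manifest$real_ids)
  expect_true(all(tidy(rep)$score == 1))
  expect_identical(rep$mean_score, 1)
  expect_identical(glance(rep)$score_from_mean_counts, 1)
})

test_that("pooled unique-output tallies ignore pair execution order", {
  store <- xref_store(fx_clean$entries, strict = FALSE)
  a <- run_battery(store, fx_clean$recon, fx_clean$truth, cts_strategy(),
                   input_types = c("name", "kegg", "chebi"),
                   output_types = c("chebi", "hmdb"))
  b <- run_battery(store, fx_clean$recon, fx_clean$truth, cts_strategy(),
                   input_types = c("chebi", "name", "kegg"),
                   output_types = c("hmdb", "chebi"))
  expect_identical(a$pooled, b$pooled)
})

test_that("the additive battery iterates over input-type prefixes", {
  fx <- generate_fixture(fixture_spec(n_compounds = 50, seed = 15,
                                      planted_error_rate = 0))
  store <- xref_store(fx$entries, strict = FALSE)
  rep <- run_additive_battery(store, fx$recon, fx$met_truth,
                              known_ids = fx$manifest$real_ids)
  s <- glance(rep)
  expect_identical(s$added_type[1], "name")
  expect_identical(s$iteration, seq_len(nrow(s)))
  # In is the full test-set size in every iteration: every metabolite has a name
  expect_true(all(tidy(rep)$n_in == nrow(fx$recon)))
})

test_that("raising the name weight to parity changes retention where it should", {
  # candidate 1 is name-supported only, candidate 2 kegg-supported only:
  # downweighted names lose the tie, equal weights keep both
  inst <- additive_instance(list(name = 1, kegg = 2))
  half <- additive_map(inst$store, inst$met, "lipidmaps",
                       additive_config(type_order = c("name", "kegg")))
  expect_identical(half$candidate[half$retained], inst$cand_id(2))
  even <- additive_map(inst$store, inst$met, "lipidmaps",
                       additive_config(name_weight = 1, other_weight = 1,
                                       type_order = c("name", "kegg")))
  expect_setequal(even$candidate[even$retained], inst$cand_id(1:2))
  expect_error(additive_config(name_weight = 2, other_weight = 1), "weights")
})

test_that("report accessors expose tidy frames and plots", {
  store <- xref_store(fx_clean$entries, strict = TRUE)
  rep <- run_battery(store, fx_clean$recon, fx_clean$truth, cts_strategy())
  expect_s3_class(tidy(rep), "tbl_df")
  expect_identical(nrow(glance(rep)), 1L)
  expect_s3_class(autoplot(rep), "ggplot")
})
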