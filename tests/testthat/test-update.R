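# a small hand-built universe for the review rules: one well-annotated
# metabolite, one formula conflict, one charged/neutral chebi duplicate,
# one identifier the store has never seen, and one chloride ion
review_store <- xref_store(bind_rows(
  entry_row("chebi", "200", inchi = "InChI=1S/C3H6O3/lact",
            key = skey("C3H6O3/lact"), names = "lactate",
            formula = "C3H5O3"),                      # one H off: fine
  entry_row("chebi", "201", inchi = "InChI=1S/C2H4O2/acet",
            key = skey("C2H4O2/acet"), names = "acetate", formula = "C2H4O2"),
  entry_row("chebi", "300", inchi = "InChI=1S/C3H5O3/lactq",
            key = skey("C3H5O3/lactq"), names = "lactate(1-)",
            formula = "C3H5O3", charge = -1L),        # charged form of 200
  entry_row("chebi", "400", inchi = "InChI=1S/ClH/hcl", key = skey("ClH/hcl"),
            names = "chloride", formula = "ClH", charge = -1L),
  entry_row("chebi", "401", inchi = "InChI=1S/ClH/hcl0", key = skey("ClH/hcl0"),
            names = "hydrogen chloride", formula = "ClH", charge = 0L)
), strict = TRUE)

test_that("review keeps, removes, replaces and flags by the stated rules", {
  recon <- tibble(
    met_id = c("m_ok", "m_bad", "m_chg", "m_gone", "m_cl"),
    name = c("lactate", "pyruvate", "lactate", "mystery", "chloride"),
    formula = c("C3H6O3", "C3H4O3", "C3H6O3", "C5H5N5", "Cl"),
    charge = 0L,
    chebi = c("200", "201", "300", "999", "400")
  )
  log <- review_existing(recon, review_store)
  by_met <- split(log, log$met_id)
  # hydrogen-insensitive match: kept, no log entry
  expect_false("m_ok" %in% names(by_met))
  # carbon-count conflict: removed automatically
  expect_identical(by_met$m_bad$action, "removed")
  expect_identical(by_met$m_bad$reason, "formula_mismatch")
  expect_identical(by_met$m_bad$old_value, "201")
  # charged entry with a neutral same-formula partner: replaced
  expect_identical(by_met$m_chg$action, "replaced")
  expect_identical(by_met$m_chg$reason, "neutral_preference")
  expect_identical(by_met$m_chg$old_value, "300")
  expect_identical(by_met$m_chg$new_value, "200")
  # absent from the store: flagged, never removed
  expect_identical(by_met$m_gone$action, "flagged_for_review")
  expect_identical(by_met$m_gone$reason, "not_in_store")
  # single-element formula (inorganic ion): exempt from the neutral-form rule
  expect_false("m_cl" %in% names(by_met))
  # ... but replaced by the neutral entry once the exemption is switched off
  log2 <- review_existing(recon, review_store,
                          update_config(exempt_single_element = FALSE))
  cl <- log2[log2$met_id == "m_cl", ]
  expect_identical(cl$action, "replaced")
  expect_identical(cl$new_value, "401")
})

test_that("metabolites without a formula skip checks and are flagged as such", {
  recon <- tibble(met_id = "m_nf", name = "polymer", formula = NA_character_,
                  charge = NA_integer_, chebi = "201")
  log <- review_existing(recon, review_store)
  expect_false(any(log$action == "removed"))
  expect_true(any(log$reason == "no_metabolite_formula"))
})

test_that("fill_missing adds unambiguous formula-checked candidates automatically", {
  entries <- bind_rows(
    entry_row("chebi", "500", inchi = "InChI=1S/C6H12O6/glc",
              key = skey("C6H12O6/glc"), names = "d-glucose",
              formula = "C6H12O6"),
    entry_row("kegg", "C00031", inchi = "InChI=1S/C6H12O6/glc",
              key = skey("C6H12O6/glc"), names = "d-glucose",
              formula = "C6H12O6")
  )
  store <- xref_store(entries, strict = TRUE)
  recon <- tibble(met_id = "m1", name = "D-glucose", formula = "C6H12O6",
                  charge = 0L, inchikey = skey("C6H12O6/glc"))
  log <- fill_missing(recon, store, update_config(output_types = "chebi"))
  added <- log[log$action == "added", ]
  expect_identical(added$new_value, "500")
  expect_identical(added$confidence, 1.5)  # name (0.5) + inchikey (1)
  expect_identical(added$mode, "automatic")
})

test_that("ambiguous stereoisomer annotations surface both epimers for review", {
  sugars <- fixture_sugars()
  store <- xref_store(sugars$entries, strict = FALSE)
  lcts <- sugars$recon[sugars$recon$met_id == "M_lcts", ]
  log <- fill_missing(lcts, store, update_config(output_types = "pubchem"))
  flagged <- log[log$action == "flagged_for_review", ]
  expect_setequal(flagged$new_value, c("6134", "84571"))
  expect_false(any(log$action == "added"))
})

test_that("candidates failing the formula check are rejected before addition", {
  entries <- bind_rows(
    entry_row("chebi", "600", inchi = "InChI=1S/C2H4O2/acet",
              key = skey("C2H4O2/acet"), names = "shared name",
              formula = "C2H4O2"),
    entry_row("kegg", "C00600", inchi = "InChI=1S/C2H4O2/acet",
              key = skey("C2H4O2/acet"), names = "shared name",
              formula = "C2H4O2")
  )
  store <- xref_store(entries, strict = TRUE)
  recon <- tibble(met_id = "m1", name = "shared name", formula = "C5H5N5",
                  charge = 0L, kegg = "C00600")
  log <- fill_missing(recon, store, update_config(output_types = "chebi"))
  expect_identical(nrow(log), 0L)
})

test_that("a metabolite with no store hits is left unchanged but reported", {
  store <- review_store
  recon <- tibble(met_id = "m_R", name = "a generic r-group polymer",
                  formula = NA_character_, charge = NA_integer_)
  upd <- update_annotations(recon, store)
  expect_identical(nrow(upd$log), 0L)
  expect_identical(upd$recon$met_id, "m_R")
  expect_true(any(upd$review$reason == "no_metabolite_formula"))
})

test_that("the pipeline recovers exactly the planted errors and is idempotent", {
  fx <- generate_fixture(fixture_spec(n_compounds = 400, seed = 23))
  store <- xref_store(fx$entries, strict = FALSE)
  upd <- update_annotations(fx$recon, store)
  tot <- glance(upd)
  expect_identical(tot$n_removed, nrow(fx$manifest$mismatch))
  expect_identical(tot$n_replaced, nrow(fx$manifest$charged))
  removed <- upd$log |> filter(.data$action == "removed")
  expect_setequal(paste(removed$met_id, removed$id_type, removed$old_value),
                  paste(fx$manifest$mismatch$met_id, fx$manifest$mismatch$id_type,
                        fx$manifest$mismatch$bad_value))
  replaced <- upd$log |> filter(.data$action == "replaced")
  expect_setequal(paste(replaced$met_id, replaced$old_value, replaced$new_value),
                  paste(fx$manifest$charged$met_id, fx$manifest$charged$old_value,
                        fx$manifest$charged$new_value))
  # additions never leave the manifest's recoverable set
  added <- upd$log |> filter(.data$action == "added")
  expect_identical(
    nrow(anti_join(
      added |> transmute(.data$met_id, .data$id_type, value = .data$new_value),
      fx$manifest$recoverable, by = c("met_id", "id_type", "value"))),
    0L
  )
  # nothing removed is re-added for the same metabolite and type
  expect_identical(
    nrow(inner_join(
      removed |> select("met_id", "id_type", v = "old_value"),
      added |> select("met_id", "id_type", v = "new_value"),
      by = c("met_id", "id_type", "v"))),
    0L
  )
  # post-hoc formula soundness of every automatic addition
  entry_formula <- store$entries |>
    select(id_type = "source_db", value = "id", ef = "formula")
  sound <- added |>
    transmute(.data$met_id, .data$id_type, value = .data$new_value) |>
    left_join(entry_formula, by = c("id_type", "value")) |>
    left_join(fx$recon |> select("met_id", "formula"), by = "met_id")
  expect_true(all(formulas_match(sound$ef, sound$formula, TRUE)))
  # a second run changes nothing
  upd2 <- update_annotations(upd$recon, store)
  expect_identical(nrow(upd2$log), 0L)
})

test_that("summarize_changes accounts per action, type and mode", {
  log <- tibble(
    met_id = c("a", "a", "b", "c"), id_type = c("chebi", "kegg", "chebi", "hmdb"),
    action = c("added", "added", "removed", "replaced"),
    old_value = c(NA, NA, "1", "2"), new_value = c("3", "C00001", NA, "HMDB0000001"),
    reason = "r", confidence = NA_real_, mode = "automatic"
  )
  s <- summarize_changes(log)
  expect_identical(s$totals$total_updated, 4L)
  expect_identical(s$totals$n_added, 2L)
  expect_identical(s$totals$n_removed, 1L)
  expect_identical(s$totals$n_replaced, 1L)
  empty <- summarize_changes(log[0, ])
  expect_identical(empty$totals$total_updated, 0L)
})
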