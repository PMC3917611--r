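sugars <- fixture_sugars()
sugar_store <- xref_store(sugars$entries, strict = FALSE)

test_that("a name query returns every structure the name is attached to", {
  res <- map_ids(sugar_store, "name", "dextrose", "pubchem")
  expect_setequal(res$candidate, c("5793", "79025", "64689", "206"))
  res2 <- map_ids(sugar_store, "name", "lactose", "pubchem")
  expect_setequal(res2$candidate, c("6134", "84571", "440995", "294"))
})

test_that("key joins cannot bridge a stereoisomer split between databases", {
  # the generic stereoisomer (KEGG) and the alpha epimer (HMDB) have
  # different standard keys, so neither direction maps
  expect_identical(nrow(map_ids(sugar_store, "kegg", "C00243", "hmdb")), 0L)
  expect_identical(nrow(map_ids(sugar_store, "hmdb", "HMDB0000186", "kegg")), 0L)
  # but each maps fine to a database holding its own stereoisomer
  expect_identical(map_ids(sugar_store, "kegg", "C00243", "chebi")$candidate,
                   "17716")
  expect_identical(map_ids(sugar_store, "hmdb", "HMDB0000186", "chebi")$candidate,
                   "36219")
})

test_that("name inputs are refused by strategies without name support", {
  expect_error(
    map_ids(sugar_store, "name", "lactose", "chebi", unichem_strategy()),
    "not supported"
  )
  # non-name queries are unaffected by the name switch
  expect_identical(
    map_ids(sugar_store, "kegg", "C00243", "chebi", unichem_strategy())$candidate,
    map_ids(sugar_store, "kegg", "C00243", "chebi", cts_strategy())$candidate
  )
})

test_that("identifiers absent from the store map to empty sets", {
  expect_identical(nrow(map_ids(sugar_store, "kegg", "C99999", "chebi")), 0L)
  expect_identical(nrow(map_ids(sugar_store, "name", "nonesuch", "chebi")), 0L)
})

test_that("candidate sets come back lexicographically sorted", {
  res <- map_ids(sugar_store, "name", "lactose", "pubchem")
  expect_identical(res$candidate, sort(res$candidate))
})

test_that("groups sharing only a name merge iff names are a merge type", {
  groups <- tribble(
    ~group, ~id_type, ~value,
    "g1", "kegg", "C00243",
    "g1", "name", "lactose",
    "g2", "hmdb", "HMDB0000186",
    "g2", "name", "lactose"
  )
  two <- build_masks(groups)  # default merge types exclude names
  expect_identical(max(two$mask_id), 2L)
  one <- build_masks(groups, merge_on_types = id_types())
  expect_identical(max(one$mask_id), 1L)
  # disjoint groups stay apart
  disjoint <- tribble(
    ~group, ~id_type, ~value,
    "a", "kegg", "C00001",
    "b", "kegg", "C00002"
  )
  expect_identical(max(build_masks(disjoint)$mask_id), 2L)
})

test_that("any member of a mask retrieves the same output set", {
  groups <- bind_rows(recon_groups(sugars$recon), store_groups(sugar_store))
  masks <- build_masks(groups)
  by_kegg <- map_mask(masks, "kegg", "C00243", "chebi")
  by_hmdb <- map_mask(masks, "hmdb", "HMDB0000186", "chebi")
  expect_identical(by_kegg$candidate, by_hmdb$candidate)
  # both lactose stereoisomers' ChEBI ids are in the shared mask
  expect_setequal(by_kegg$candidate, c("17716", "36219"))
  # exhaustive closure check over every mask and output type. names are
  # merged here too so that masks partition all identifiers: with names
  # outside the merge set, one ambiguous name may sit in several masks and
  # closure is only guaranteed within each mask's merge-type identifiers.
  masks_named <- build_masks(groups, merge_on_types = setdiff(id_types(), "inchi"))
  for (m in unique(masks_named$mask_id)) {
    members <- masks_named[masks_named$mask_id == m, ]
    for (ot in intersect(unique(members$id_type), db_types())) {
      results <- lapply(seq_len(nrow(members)), function(r) {
        sort(union(
          map_mask(masks_named, members$id_type[r], members$value[r], ot)$candidate,
          if (members$id_type[r] == ot) members$value[r] else character()
        ))
      })
      expect_identical(length(unique(results)), 1L)
    }
  }
  # an identifier outside every mask maps to nothing
  expect_identical(nrow(map_mask(masks, "kegg", "C99998", "chebi")), 0L)
})

test_that("build_masks agrees with a brute-force connected-components oracle", {
  withr::local_seed(808)
  for (rep in 1:5) {
    n_groups <- sample(20:50, 1)
    groups <- bind_rows(lapply(seq_len(n_groups), function(g) {
      k <- sample(1:4, 1)
      tibble(
        group = paste0("g", g),
        id_type = sample(c("kegg", "chebi", "name"), k, TRUE),
        value = as.character(sample(1:25, k, TRUE))
      )
    })) |> distinct()
    merge_types <- c("kegg", "chebi")
    expect_identical(
      masks_to_sets(build_masks(groups, merge_types)),
      brute_masks(groups, merge_types)
    )
  }
})

test_that("a conflict-free store reproduces its own cross-references", {
  fx <- generate_fixture(fixture_spec(
    n_compounds = 25, stereo_split_rate = 0, name_ambiguity_rate = 0,
    bad_entry_rate = 0, charged_duplicate_rate = 0, obsolete_rate = 0,
    seed = 21
  ))
  store <- xref_store(fx$entries, strict = TRUE)
  expect_identical(nrow(store$rejections), 0L)
  for (i in c(1, 7, 25)) {
    expect_identical(
      map_ids(store, "kegg", sprintf("C%05d", i), "chebi")$candidate,
      as.character(10000 + i)
    )
    expect_identical(
      map_ids(store, "chebi", as.character(10000 + i), "hmdb")$candidate,
      sprintf("HMDB%07d", i)
    )
  }
})

test_that("obsolete assignments are only traversed on request", {
  entries <- bind_rows(
    entry_row("kegg", "C00010", inchi = "InChI=1S/C5H10O5/rib",
              key = skey("C5H10O5/rib"), formula = "C5H10O5"),
    entry_row("chebi", "555", inchi = "InChI=1S/C5H10O5/old",
              key = skey("C5H10O5/old"), formula = "C5H10O5"),
    entry_row("chebi", "555", inchi = "InChI=1S/C5H10O5/rib",
              key = skey("C5H10O5/rib"), formula = "C5H10O5")
  )
  store <- xref_store(entries, strict = TRUE)
  # chebi:555 was re-assigned to the ribose key; its old key is history
  cur <- map_ids(store, "kegg", "C00010", "chebi")
  expect_identical(cur$candidate, "555")
  old_default <- map_ids(store, "inchikey", skey("C5H10O5/old"), "chebi")
  expect_identical(nrow(old_default), 0L)
  old_incl <- map_ids(store, "inchikey", skey("C5H10O5/old"), "chebi",
                      cts_strategy(include_obsolete = TRUE))
  expect_identical(old_incl$candidate, "555")
})
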