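# ---- deterministic synthetic InChIKeys ------------------------------------

# fold a string into a positive integer below the Mersenne prime 2^31-1,
# then draw letters from a Lehmer multiplicative congruential generator.
# all arithmetic stays below 2^53, so results are identical on any platform.
str_fold <- function(s) {
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483629
  h + 1
}

lehmer_letters <- function(seed, n) {
  state <- seed
  out <- character(n)
  for (j in seq_len(n)) {
    state <- (state * 48271) %% 2147483647
    out[j] <- LETTERS[(state %% 26) + 1]
  }
  paste(out, collapse = "")
}

#' Deterministic synthetic standard InChIKeys
#'
#' Renders a synthetic InChI string into a syntactically valid *standard*
#' InChIKey (14-letter skeleton block, 10-letter block ending in the `SA`
#' standard/version flag, protonation letter `N`) using a deterministic string
#' hash — no chemistry toolkit involved. Mapping logic only needs key
#' *equality* semantics, not chemical validity, so hash-derived keys suffice
#' for fixtures. Stereo layers (everything from `/t` on) are excluded from the
#' skeleton hash, so stereo variants of one synthetic compound share a
#' skeleton block and differ in the second block.
#'
#' `synthetic_key_oracle()` returns this function for use as the
#' `key_oracle` of [ingest_entries()] on generated fixtures.
#'
#' @param inchi character vector of (synthetic) InChI strings.
#' @return character vector of standard InChIKeys.
#' @export
synthetic_inchikey <- function(inchi) {
  vapply(inchi, function(x) {
    base <- sub("/t.*$", "", x)
    paste0(lehmer_letters(str_fold(base), 14), "-",
           lehmer_letters(str_fold(x), 8), "SA-N")
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname synthetic_inchikey
#' @export
synthetic_key_oracle <- function() {
  function(inchi) synthetic_inchikey(inchi)
}

# ---- fixture specification --------------------------------------------------

#' Specification for a synthetic identifier-mapping fixture
#'
#' The generator emulates, in a fully controlled miniature universe, the
#' phenomena that make real metabolite identifier mapping hard:
#' stereoisomer splits across databases (some databases register the generic
#' stereoisomer, others a specific epimer, under different standard keys with
#' a shared skeleton), ambiguous names attached to more than one structure,
#' entries that fail ingest quality checks (missing InChI, or an
#' InChI/InChIKey pair contradicting another entry) and carry dangling
#' identifiers, parallel charged-form database entries, obsolete key
#' assignments, partial annotation coverage in the reconstruction, and planted
#' wrong annotations detectable by the formula check.
#'
#' All rates are converted to exact counts (`round(rate * n)`), so realized
#' fractions match the specification to within rounding at any size. The
#' default annotation coverages mirror the identifier prevalences of a large
#' published human reconstruction (names 100%, InChIKeys ~64%, ChEBI ~43%,
#' HMDB ~40%, KEGG ~15%, PubChem ~6%).
#'
#' @param n_compounds number of synthetic compounds (default 100).
#' @param n_databases how many of kegg, chebi, hmdb, pubchem to emulate
#'   (2 to 4; default 4).
#' @param stereo_split_rate fraction of compounds stored as the generic
#'   stereoisomer in kegg/chebi but as an alpha epimer in hmdb/pubchem.
#' @param name_ambiguity_rate fraction of compound names also attached to a
#'   different compound's entry.
#' @param bad_entry_rate fraction of entries (relative to the good-entry
#'   count) violating exactly one ingest check each.
#' @param charged_duplicate_rate fraction of compounds with a parallel
#'   charged-form ChEBI entry; the reconstruction is annotated with the
#'   charged identifier for these, to be replaced by the neutral one.
#' @param obsolete_rate fraction of compounds whose KEGG identifier carries an
#'   additional obsolete key assignment.
#' @param annotation_coverage named fractions of reconstruction metabolites
#'   annotated with each identifier type (names are always 100%).
#' @param planted_error_rate fraction of reconstruction database annotations
#'   replaced by another compound's identifier (a formula-detectable error).
#' @param seed integer seed; identical (spec, seed) gives identical output.
#' @return a `fixture_spec` object for [generate_fixture()].
#' @export
fixture_spec <- function(n_compounds = 100, n_databases = 4,
                         stereo_split_rate = 0.1, name_ambiguity_rate = 0.1,
                         bad_entry_rate = 0.05, charged_duplicate_rate = 0.2,
                         obsolete_rate = 0.05,
                         annotation_coverage = c(inchikey = 0.64, chebi = 0.43,
                                                 hmdb = 0.40, kegg = 0.15,
                                                 pubchem = 0.06),
                         planted_error_rate = 0.05, seed = 1L) {
  rates <- c(stereo_split_rate, name_ambiguity_rate, bad_entry_rate,
             charged_duplicate_rate, obsolete_rate, planted_error_rate,
             annotation_coverage)
  if (any(rates < 0 | rates > 1)) mm_abort("all rates must be in [0, 1]")
  if (n_compounds < 2) mm_abort("need at least 2 compounds")
  if (n_databases < 2 || n_databases > 4) mm_abort("n_databases must be 2..4")
  structure(
    list(n_compounds = as.integer(n_compounds),
         n_databases = as.integer(n_databases),
         stereo_split_rate = stereo_split_rate,
         name_ambiguity_rate = name_ambiguity_rate,
         bad_entry_rate = bad_entry_rate,
         charged_duplicate_rate = charged_duplicate_rate,
         obsolete_rate = obsolete_rate,
         annotation_coverage = annotation_coverage,
         planted_error_rate = planted_error_rate,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# compound-level deterministic building blocks
fixture_formula <- function(i) {
  c <- 2 + (i - 1) %% 40
  o <- 1 + ((i - 1) %/% 40) %% 30
  nn <- (i - 1) %/% 1200
  paste0("C", c, "H", 2 * c + 2, "O", o, if (nn > 0) paste0("N", nn) else "")
}

fixture_id <- function(db, i) {
  switch(db,
    kegg = sprintf("C%05d", i),
    chebi = as.character(10000 + i),
    hmdb = sprintf("HMDB%07d", i),
    pubchem = as.character(100000 + i)
  )
}

fixture_inchi <- function(i, variant) {
  base <- sprintf("InChI=1S/%s/c%d", fixture_formula(i), i)
  if (variant == "a") paste0(base, "/t1a") else base
}

#' Generate a synthetic identifier-mapping fixture
#'
#' Produces source-database dumps, a reconstruction annotation table, truth
#' tables (per input identifier and per metabolite) and a planted-error
#' manifest, all deterministic in `(spec, seed)`. See [fixture_spec()] for
#' what is emulated. A self-audit pass asserts that the manifest is consistent
#' with the emitted tables (every planted error refers to identifiers that
#' exist, under the detection rule intended for it).
#'
#' @param spec a [fixture_spec()].
#' @return a list of class `metamapr_fixture` with elements `entries` (all
#'   database dump rows, including the deliberately bad ones), `recon`
#'   (reconstruction with planted errors), `truth` (input-level labels),
#'   `met_truth` (metabolite-level labels for additive mapping), `manifest`
#'   (ground truth: `real_ids`, `dangling`, `mismatch`, `charged`,
#'   `recoverable`, `stereo`) and `spec`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::local_seed(spec$seed)
  n <- spec$n_compounds
  dbs <- head(c("kegg", "chebi", "hmdb", "pubchem"), spec$n_databases)

  pick <- function(rate, from = seq_len(n)) {
    k <- min(round(rate * length(from)), length(from))
    sort(sample(from, k))
  }
  stereo_idx <- pick(spec$stereo_split_rate)
  amb_idx <- pick(spec$name_ambiguity_rate)
  charged_idx <- if ("chebi" %in% dbs) pick(spec$charged_duplicate_rate) else integer()
  obs_idx <- if ("kegg" %in% dbs) pick(spec$obsolete_rate) else integer()

  cmp <- tibble(
    i = seq_len(n),
    name = sprintf("compound%04d", seq_len(n)),
    formula = vapply(seq_len(n), fixture_formula, character(1)),
    stereo = seq_len(n) %in% stereo_idx
  )
  variant_in <- function(i, db) {
    ifelse(cmp$stereo[i] & db %in% c("hmdb", "pubchem"), "a", "g")
  }

  # good entries: one per compound per database
  good <- bind_rows(lapply(dbs, function(db) {
    v <- variant_in(cmp$i, db)
    inchi <- vapply(seq_len(n), function(i) fixture_inchi(i, v[i]), character(1))
    tibble(
      source_db = db,
      id = vapply(cmp$i, function(i) fixture_id(db, i), character(1)),
      inchi = inchi,
      inchikey = synthetic_inchikey(inchi),
      names = cmp$name,
      formula = cmp$formula,
      charge = 0L,
      obsolete = 0L
    )
  }))
  # ambiguous names: compound i's name also attached to its partner's entry
  # in the last database (a wrong name-structure association)
  amb_db <- dbs[length(dbs)]
  amb_partner <- (amb_idx %% n) + 1L
  keep <- amb_partner != amb_idx
  amb_idx <- amb_idx[keep]
  amb_partner <- amb_partner[keep]
  for (k in seq_along(amb_idx)) {
    sel <- which(good$source_db == amb_db &
                   good$id == fixture_id(amb_db, amb_partner[k]))
    good$names[sel] <- paste(good$names[sel], cmp$name[amb_idx[k]], sep = "|")
  }

  # parallel charged-form chebi entries (one H fewer, charge -1, own key)
  charged <- NULL
  if (length(charged_idx) > 0) {
    inchi <- vapply(charged_idx, function(i) {
      paste0(fixture_inchi(i, "g"), "/q-1")
    }, character(1))
    fml <- vapply(charged_idx, function(i) {
      f <- parse_formula(cmp$formula[i])
      f["H"] <- f["H"] - 1L
      paste0(names(f), ifelse(f > 1, f, ""), collapse = "")
    }, character(1))
    charged <- tibble(
      source_db = "chebi",
      id = as.character(50000 + charged_idx),
      inchi = inchi, inchikey = synthetic_inchikey(inchi),
      names = cmp$name[charged_idx], formula = fml,
      charge = -1L, obsolete = 0L
    )
  }

  # obsolete key assignments: an extra kegg row under a superseded key
  obsolete <- NULL
  if (length(obs_idx) > 0) {
    inchi <- vapply(obs_idx, function(i) {
      paste0(fixture_inchi(i, "g"), "/v0")
    }, character(1))
    obsolete <- tibble(
      source_db = "kegg",
      id = vapply(obs_idx, function(i) fixture_id("kegg", i), character(1)),
      inchi = inchi, inchikey = synthetic_inchikey(inchi),
      names = cmp$name[obs_idx], formula = cmp$formula[obs_idx],
      charge = 0L, obsolete = 1L
    )
  }

  # bad entries: each violates exactly one ingest check and carries a
  # dangling identifier. flavor A has a key but no InChI (rejected strictly,
  # accepted permissively); flavor B pairs one compound's InChI with
  # another's key (rejected strictly as inconsistent/mismatched).
  n_bad <- round(spec$bad_entry_rate * nrow(good))
  bad <- NULL
  if (n_bad > 0) {
    k <- seq_len(n_bad)
    host <- ((k - 1) %% n) + 1L
    flavor_a <- k %% 2 == 1
    bad_inchi <- ifelse(flavor_a, NA_character_,
                        vapply(host, function(i) fixture_inchi(i, "g"), character(1)))
    bad_key_host <- ifelse(flavor_a, host, (host %% n) + 1L)
    bad_key <- synthetic_inchikey(
      vapply(bad_key_host, function(i) fixture_inchi(i, "g"), character(1)))
    bad <- tibble(
      source_db = "chebi",
      id = as.character(ifelse(flavor_a, 90000 + k, 95000 + k)),
      inchi = bad_inchi, inchikey = bad_key,
      names = NA_character_, formula = NA_character_,
      charge = NA_integer_, obsolete = 0L
    )
  }

  entries <- bind_rows(good, charged, obsolete, bad)

  # reconstruction: exact-count annotation coverage per type
  recon <- tibble(met_id = sprintf("M%04d", cmp$i), name = cmp$name,
                  formula = cmp$formula, charge = 0L)
  cov <- spec$annotation_coverage
  type_cols <- intersect(names(cov), c("inchikey", dbs))
  for (tp in type_cols) {
    idx <- pick(cov[[tp]])
    vals <- rep(NA_character_, n)
    if (tp == "inchikey") {
      vals[idx] <- synthetic_inchikey(
        vapply(idx, function(i) fixture_inchi(i, "g"), character(1)))
    } else {
      vals[idx] <- vapply(idx, function(i) fixture_id(tp, i), character(1))
    }
    recon[[tp]] <- vals
  }

  # plant charged-form annotations (chebi slot points at the charged entry)
  charged_manifest <- tibble(met_id = character(), id_type = character(),
                             old_value = character(), new_value = character())
  if (length(charged_idx) > 0 && "chebi" %in% names(recon)) {
    sel <- charged_idx[!is.na(recon$chebi[charged_idx])]
    recon$chebi[sel] <- as.character(50000 + sel)
    charged_manifest <- tibble(
      met_id = recon$met_id[sel], id_type = "chebi",
      old_value = as.character(50000 + sel),
      new_value = vapply(sel, function(i) fixture_id("chebi", i), character(1))
    )
  }

  # plant formula-detectable wrong annotations (another compound's id)
  slots <- bind_rows(lapply(intersect(dbs, names(recon)), function(tp) {
    tibble(row = which(!is.na(recon[[tp]])), id_type = tp)
  })) |>
    anti_join(charged_manifest |>
                mutate(row = match(.data$met_id, recon$met_id)) |>
                select("row", "id_type"),
              by = c("row", "id_type"))
  n_plant <- round(spec$planted_error_rate * nrow(slots))
  mismatch_manifest <- tibble(met_id = character(), id_type = character(),
                              bad_value = character(), true_value = character())
  if (n_plant > 0) {
    planted <- slots[sort(sample(nrow(slots), n_plant)), ]
    partner <- ((planted$row + 5L) %% n) + 1L
    bad_vals <- vapply(seq_len(n_plant), function(k) {
      fixture_id(planted$id_type[k], partner[k])
    }, character(1))
    true_vals <- vapply(seq_len(n_plant), function(k) {
      fixture_id(planted$id_type[k], planted$row[k])
    }, character(1))
    for (k in seq_len(n_plant)) {
      recon[[planted$id_type[k]]][planted$row[k]] <- bad_vals[k]
    }
    mismatch_manifest <- tibble(
      met_id = recon$met_id[planted$row], id_type = planted$id_type,
      bad_value = bad_vals, true_value = true_vals
    )
  }

  # truth tables -------------------------------------------------------------
  # per-input labels for same-compound candidates; cross-compound and dangling
  # candidates are covered by the unknown-candidate policy via manifest ids
  out_types <- dbs
  truth <- bind_rows(lapply(seq_len(n), function(i) {
    ins <- bind_rows(
      tibble(input_type = "name", input_value = cmp$name[i], v = "any"),
      tibble(input_type = "inchikey",
             input_value = synthetic_inchikey(fixture_inchi(i, "g")), v = "g"),
      bind_rows(lapply(dbs, function(db) {
        tibble(input_type = db, input_value = fixture_id(db, i),
               v = variant_in(i, db))
      }))
    )
    cands <- bind_rows(lapply(out_types, function(db) {
      tibble(output_type = db, candidate = fixture_id(db, i),
             w = variant_in(i, db))
    }))
    tidyr::crossing(ins, cands) |>
      filter(.data$input_type != .data$output_type) |>
      mutate(label = case_when(
        .data$v == "any" ~ "preferred",
        .data$v == .data$w ~ "preferred",
        .data$v == "g" & .data$w == "a" ~ "valid",
        TRUE ~ "invalid"
      )) |>
      select("input_type", "input_value", "output_type", "candidate", "label")
  }))
  met_truth <- bind_rows(lapply(out_types, function(db) {
    tibble(met_id = recon$met_id, output_type = db,
           candidate = vapply(cmp$i, function(i) fixture_id(db, i), character(1)),
           label = "preferred")
  }))

  # manifest -----------------------------------------------------------------
  real_ids <- bind_rows(
    good |> transmute(id_type = .data$source_db, value = .data$id),
    if (!is.null(charged)) charged |>
      transmute(id_type = .data$source_db, value = .data$id)
  ) |> distinct()
  dangling <- if (is.null(bad)) {
    tibble(id_type = character(), value = character())
  } else {
    bad |> transmute(id_type = .data$source_db, value = .data$id)
  }
  recoverable <- bind_rows(lapply(intersect(dbs, names(recon)), function(tp) {
    correct <- vapply(cmp$i, function(i) fixture_id(tp, i), character(1))
    lacks <- is.na(recon[[tp]]) | recon[[tp]] != correct
    tibble(met_id = recon$met_id[lacks], id_type = tp, value = correct[lacks])
  }))

  manifest <- list(
    real_ids = real_ids, dangling = dangling,
    mismatch = mismatch_manifest, charged = charged_manifest,
    recoverable = recoverable,
    stereo = tibble(i = stereo_idx, met_id = sprintf("M%04d", stereo_idx))
  )

  fx <- structure(
    list(entries = entries, recon = recon, truth = truth,
         met_truth = met_truth, manifest = manifest, spec = spec),
    class = "metamapr_fixture"
  )
  audit_fixture(fx)
  fx
}

# self-audit: the manifest must be consistent with the emitted tables
audit_fixture <- function(fx) {
  ids <- paste(fx$entries$source_db, fx$entries$id)
  m <- fx$manifest
  stopifnot(
    all(paste(m$mismatch$id_type, m$mismatch$bad_value) %in% ids),
    all(paste(m$charged$id_type, m$charged$old_value) %in% ids),
    all(paste(m$charged$id_type, m$charged$new_value) %in% ids),
    all(paste(m$recoverable$id_type, m$recoverable$value) %in% ids),
    !any(paste(m$dangling$id_type, m$dangling$value) %in%
           paste(m$real_ids$id_type, m$real_ids$value)),
    all(is_standard_key(fx$entries$inchikey[!is.na(fx$entries$inchikey)]))
  )
  invisible(fx)
}

#' @export
print.metamapr_fixture <- function(x, ...) {
  cat(sprintf(
    "<metamapr_fixture: %d compounds, %d databases, %d entries, %d metabolites>\n",
    x$spec$n_compounds, x$spec$n_databases, nrow(x$entries), nrow(x$recon)))
  invisible(x)
}

#' Identifier groups for mask building
#'
#' Convenience constructors for [build_masks()] group tables: one group per
#' reconstruction metabolite (its name plus all annotations) and one group per
#' accepted database entry (its identifier, key and names).
#'
#' @param recon reconstruction tibble.
#' @return tibble with columns `group`, `id_type`, `value`.
#' @export
recon_groups <- function(recon) {
  ann <- recon_db_long(recon, setdiff(id_types(), c("name", "inchi"))) |>
    rename(group = "met_id")
  names <- tibble(group = recon$met_id, id_type = "name",
                  value = normalize_quietly("name", recon$name)$value)
  bind_rows(names, ann) |> filter(!is.na(.data$value))
}

#' @rdname recon_groups
#' @param store an [xref_store()].
#' @export
store_groups <- function(store) {
  e <- store$entries |>
    mutate(group = paste0(.data$source_db, ":", .data$id))
  ids <- e |> transmute(.data$group, id_type = .data$source_db, value = .data$id)
  keys <- e |>
    filter(!is.na(.data$inchikey)) |>
    transmute(.data$group, id_type = "inchikey", value = .data$inchikey)
  names <- e |>
    filter(!is.na(.data$names), nzchar(.data$names)) |>
    mutate(value = lapply(.data$names, split_multi)) |>
    select("group", "value") |>
    unnest("value") |>
    mutate(id_type = "name")
  bind_rows(ids, keys, names) |> select("group", "id_type", "value")
}

#' Curated miniature database of classic sugar-identifier ambiguities
#'
#' A hand-built fixture encoding well-documented cross-database pathologies
#' around glucose and lactose:
#'
#' * the name *dextrose* attached to four different PubChem structures
#'   (D-glucose 5793, the alpha and beta epimers 79025 / 64689, and a generic
#'   hexopyranose 206 — an incorrect name-structure association);
#' * the lactose stereoisomer split: KEGG registers the generic stereoisomer
#'   (C00243), HMDB only the alpha epimer (HMDB0000186); the two entries carry
#'   different standard keys, so key-based mapping cannot link them;
#' * the name *lactose* returning four PubChem candidates of which CID 294, a
#'   generic disaccharide, is invalid (the other lactose CIDs here are
#'   synthetic stand-ins, as is the phospholactic-acid CID);
#' * a D-glucose labeling quartet for one KEGG input: a preferred, a valid,
#'   an invalid and an incorrect PubChem candidate.
#'
#' InChIs and keys are synthetic ([synthetic_inchikey()]); identifier values
#' are the published ones where the sources state them.
#'
#' @return list with `entries` (source dump tibble), `recon` (two-metabolite
#'   reconstruction: lactose with the ambiguous generic-KEGG + alpha-HMDB
#'   annotation pair, and D-glucose), `truth`, `met_truth` and `known_ids`.
#' @export
fixture_sugars <- function() {
  mk <- function(tag, stereo = NULL) {
    inchi <- paste0("InChI=1S/", tag, if (!is.null(stereo)) paste0("/t", stereo))
    list(inchi = inchi, key = synthetic_inchikey(inchi))
  }
  glc <- mk("C6H12O6/glc")          # D-glucose
  glc_a <- mk("C6H12O6/glc", "1a")  # alpha-D-glucose
  glc_b <- mk("C6H12O6/glc", "1b")  # beta-D-glucose
  hexp <- mk("C6H12O6/hexopyranose")
  lac <- mk("C12H22O11/lac")        # generic lactose
  lac_a <- mk("C12H22O11/lac", "2a")
  lac_b <- mk("C12H22O11/lac", "2b")
  disac <- mk("C12H22O11/disaccharide")
  pla <- mk("C3H7O6P/phospholactate")

  row <- function(db, id, cpd, names, formula) {
    tibble(source_db = db, id = id, inchi = cpd$inchi, inchikey = cpd$key,
           names = names, formula = formula, charge = 0L, obsolete = 0L)
  }
  entries <- bind_rows(
    row("pubchem", "5793", glc, "D-glucose|dextrose", "C6H12O6"),
    row("pubchem", "79025", glc_a, "alpha-D-glucose|dextrose", "C6H12O6"),
    row("pubchem", "64689", glc_b, "beta-D-glucose|dextrose", "C6H12O6"),
    row("pubchem", "206", hexp, "hexopyranose|dextrose", "C6H12O6"),
    row("kegg", "C00031", glc, "D-glucose|grape sugar", "C6H12O6"),
    row("pubchem", "440147", pla, "phospholactic acid", "C3H7O6P"),
    row("kegg", "C00243", lac, "lactose|milk sugar", "C12H22O11"),
    row("hmdb", "HMDB0000186", lac_a, "lactose|milk sugar|alpha-lactose",
        "C12H22O11"),
    row("chebi", "17716", lac, "lactose", "C12H22O11"),
    row("chebi", "36219", lac_a, "alpha-lactose|lactose", "C12H22O11"),
    row("pubchem", "6134", lac, "lactose", "C12H22O11"),
    row("pubchem", "84571", lac_a, "alpha-lactose|lactose", "C12H22O11"),
    row("pubchem", "440995", lac_b, "beta-lactose|lactose", "C12H22O11"),
    row("pubchem", "294", disac, "generic disaccharide|lactose", "C12H22O11")
  )

  recon <- tibble(
    met_id = c("M_lcts", "M_glc"),
    name = c("lactose", "D-glucose"),
    formula = c("C12H22O11", "C6H12O6"),
    charge = 0L,
    inchikey = c(NA_character_, NA_character_),
    chebi = c(NA_character_, NA_character_),
    hmdb = c("HMDB0000186", NA),
    kegg = c("C00243", "C00031"),
    pubchem = c(NA_character_, NA_character_)
  )

  tr <- function(it, iv, ot, cand, label) {
    tibble(input_type = it, input_value = iv, output_type = ot,
           candidate = cand, label = label)
  }
  truth <- bind_rows(
    tr("name", "dextrose", "pubchem",
       c("5793", "79025", "64689", "206"),
       c("preferred", "valid", "valid", "invalid")),
    tr("name", "d-glucose", "pubchem",
       c("5793", "79025", "64689", "206"),
       c("preferred", "valid", "valid", "invalid")),
    tr("kegg", "C00031", "pubchem",
       c("5793", "79025", "64689", "206", "440147"),
       c("preferred", "valid", "valid", "invalid", "incorrect")),
    tr("name", "lactose", "pubchem",
       c("6134", "84571", "440995", "294"),
       c("preferred", "valid", "valid", "invalid")),
    tr("name", "lactose", "hmdb", "HMDB0000186", "preferred"),
    tr("name", "lactose", "kegg", "C00243", "preferred"),
    tr("name", "lactose", "chebi", c("17716", "36219"),
       c("preferred", "valid")),
    tr("kegg", "C00243", "hmdb", "HMDB0000186", "valid"),
    tr("kegg", "C00243", "chebi", c("17716", "36219"),
       c("preferred", "valid")),
    tr("kegg", "C00243", "pubchem", c("6134", "84571", "440995", "294"),
       c("preferred", "valid", "valid", "invalid")),
    tr("hmdb", "HMDB0000186", "chebi", c("36219", "17716"),
       c("preferred", "invalid")),
    tr("hmdb", "HMDB0000186", "kegg", "C00243", "invalid"),
    tr("hmdb", "HMDB0000186", "pubchem", c("84571", "6134", "440995", "294"),
       c("preferred", "invalid", "invalid", "invalid"))
  )
  met_truth <- bind_rows(
    tibble(met_id = "M_lcts", output_type = "pubchem",
           candidate = c("6134", "84571", "440995", "294"),
           label = c("preferred", "valid", "valid", "invalid")),
    tibble(met_id = "M_lcts", output_type = "chebi",
           candidate = c("17716", "36219"), label = c("preferred", "valid")),
    tibble(met_id = "M_glc", output_type = "pubchem",
           candidate = c("5793", "79025", "64689", "206"),
           label = c("preferred", "valid", "valid", "invalid"))
  )
  known_ids <- entries |> transmute(id_type = .data$source_db, value = .data$id)
  list(entries = entries, recon = recon, truth = truth,
       met_truth = met_truth, known_ids = known_ids)
}
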