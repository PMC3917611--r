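# independent oracles and small builders shared across tests

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# naive fixpoint merger: the oracle for build_masks(). groups is a tibble
# (group, id_type, value); returns a canonical set-of-sets representation.
brute_masks <- function(groups, merge_on_types) {
  gs <- split(groups, groups$group)
  sets <- lapply(gs, function(g) paste(g$id_type, g$value, sep = ":"))
  alive <- rep(TRUE, length(sets))
  merge_tokens <- function(s) {
    s[sub(":.*$", "", s) %in% merge_on_types]
  }
  repeat {
    merged <- FALSE
    for (a in seq_along(sets)) {
      if (!alive[a]) next
      for (b in seq_along(sets)) {
        if (b <= a || !alive[b]) next
        if (length(intersect(merge_tokens(sets[[a]]),
                             merge_tokens(sets[[b]]))) > 0) {
          sets[[a]] <- union(sets[[a]], sets[[b]])
          alive[b] <- FALSE
          merged <- TRUE
        }
      }
    }
    if (!merged) break
  }
  unname(sort(vapply(sets[alive],
                     function(s) paste(sort(unique(s)), collapse = "|"),
                     character(1))))
}

masks_to_sets <- function(masks) {
  sets <- split(paste(masks$id_type, masks$value, sep = ":"), masks$mask_id)
  unname(sort(vapply(sets, function(s) paste(sort(unique(s)), collapse = "|"),
                     character(1))))
}

# build a store + one-metabolite reconstruction realizing arbitrary per-type
# candidate sets for additive mapping: input type t returns candidate set
# sets[[t]] (lipidmaps ids) through one key per candidate.
additive_instance <- function(sets) {
  cand_key <- function(c) synthetic_inchikey(sprintf("InChI=1S/C2H6O/c%d", c))
  all_cands <- sort(unique(unlist(sets)))
  rows <- list()
  for (c in all_cands) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      source_db = "lipidmaps", id = sprintf("LMFA%08d", c),
      inchi = sprintf("InChI=1S/C2H6O/c%d", c), inchikey = cand_key(c),
      names = if ("name" %in% names(sets) && c %in% sets$name) "met one" else NA,
      formula = "C2H6O", charge = 0L, obsolete = 0L
    )
  }
  met <- tibble::tibble(met_id = "m1", name = "met one", formula = "C2H6O")
  for (tp in setdiff(names(sets), "name")) {
    vals <- character(0)
    for (c in sets[[tp]]) {
      v <- switch(tp, kegg = sprintf("C%05d", 900 + c),
                  chebi = as.character(7000 + c),
                  hmdb = sprintf("HMDB%07d", 900 + c),
                  pubchem = as.character(88000 + c))
      vals <- c(vals, v)
      rows[[length(rows) + 1]] <- tibble::tibble(
        source_db = tp, id = v,
        inchi = sprintf("InChI=1S/C2H6O/c%d", c), inchikey = cand_key(c),
        names = NA, formula = "C2H6O", charge = 0L, obsolete = 0L
      )
    }
    met[[tp]] <- paste(vals, collapse = "|")
  }
  list(store = xref_store(dplyr::bind_rows(rows), strict = FALSE), met = met,
       cands = all_cands, cand_id = function(c) sprintf("LMFA%08d", c))
}

# exhaustive-enumeration oracle for additive mapping
brute_additive <- function(sets, name_weight = 0.5, other_weight = 1) {
  all_cands <- sort(unique(unlist(sets)))
  conf <- setNames(numeric(length(all_cands)), all_cands)
  for (tp in names(sets)) {
    w <- if (tp == "name") name_weight else other_weight
    for (c in sets[[tp]]) conf[as.character(c)] <- conf[as.character(c)] + w
  }
  conf <- conf[conf > 0]
  list(confidence = conf, retained = names(conf)[conf == max(conf)])
}

# one-line source entry builder
entry_row <- function(db, id, inchi = NA, key = NA, names = NA, formula = NA,
                      charge = 0L, obsolete = 0L) {
  tibble::tibble(source_db = db, id = id, inchi = inchi, inchikey = key,
                 names = names, formula = formula, charge = as.integer(charge),
                 obsolete = as.integer(obsolete))
}

skey <- function(tag) synthetic_inchikey(paste0("InChI=1S/", tag))
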