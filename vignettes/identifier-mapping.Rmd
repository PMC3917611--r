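---
title: "Mapping between metabolite identifiers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping between metabolite identifiers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamapr)
library(dplyr)
```

## The problem

Genome-scale metabolic reconstructions annotate each metabolite with a name
and, ideally, identifiers in several public compound databases (ChEBI, HMDB,
KEGG Compound, PubChem Compound, LIPID MAPS) plus a structure hash, the
standard InChIKey. These annotations are routinely incomplete or wrong, and a
reconstruction has thousands of metabolites, so updating them by hand does not
scale. metamapr implements, offline and reproducibly, the machinery needed to
map between identifier types, to quantify how well a mapping strategy works,
and to update a reconstruction's annotations with an audit trail.

Two mapping philosophies are implemented side by side:

* **InChIKey joins** (`mapping_strategy("inchikey")`): every database entry is
  keyed by its standard InChIKey; a query resolves the input identifier to its
  key(s) and returns all identifiers of the requested type under the same
  key(s). Queries with different identifiers of the same compound are
  *independent* — each sees only its own key. Two presets mirror the two
  aggregation philosophies found in public services: `cts_strategy()`
  (permissive ingest, names allowed, coverage-oriented) and
  `unichem_strategy()` (strict quality-checked ingest, no names,
  specificity-oriented).
* **Metabolite masks** (`mask_strategy()` over `build_masks()`): identifier
  groups are merged by transitive closure into masks; querying any member of a
  mask returns all same-type members. Queries are deliberately *not*
  independent — that is the point of masking, and also its weakness, since
  over-merged masks (e.g. across a stereoisomer split) contaminate every
  query.

## Why stereochemistry makes this hard

A single compound can have several equally valid structures — usually
stereoisomers — each with its own standard InChI and hence its own key.
Databases disagree about which one to register: one may hold a generic
stereoisomer (configuration unspecified at a stereocenter) while another holds
only the alpha epimer. Lactose is the canonical example: the generic
stereoisomer in KEGG (C00243) and the alpha epimer in HMDB (HMDB0000186)
carry different keys, so no key join can bridge them, in either direction.
`fixture_sugars()` encodes this and the related name pathologies (the name
*dextrose* attached to four PubChem structures, one of them wrong) as a
curated miniature database used throughout the tests.

## Quality-checked aggregation

`xref_store()` ingests source-database dumps. In strict mode an entry must
carry a database identifier and a standard InChI; a provided InChIKey is
checked against the key derived by a pluggable oracle function when one is
supplied, and — because key hashing is not invertible — in the absence of an
oracle the store enforces the same property relationally: no InChI may be
associated with two keys across accepted entries, nor one key with two InChIs.
Permissive mode accepts entries with a key but no InChI and skips the
consistency checks; `audit_store()` can then report the conflicts that
accumulated. Re-assigning a database identifier to a new key *demotes* the old
association instead of deleting it, so obsolete assignments remain queryable
on request (`include_obsolete`).

One design point needed a decision the ingest contract leaves open: an entry
carrying an InChI but no key, with no oracle and no prior knowledge of that
InChI, cannot be indexed at all; it is rejected with its own reason
(`unresolvable_key`) rather than being silently dropped or misfiled under a
generic reason.

Matching granularity is the full 27-character standard key. A
skeleton-block-only mode exists behind `mapping_strategy(skeleton = TRUE)` for
exploration, but it deliberately conflates stereoisomers and is off by
default.

## Additive confidence-weighted mapping

Metabolites usually carry several identifier types, and under the key-join
strategy each type gives an independent query. `additive_map()` runs one query
per type the metabolite possesses (the output type never queries for itself),
in the order given by `type_order_from_prevalence()` — names first, since
every metabolite has one, then types by how common they already are in the
reconstruction. Every candidate accrues the weight of each input type that
returned it: 0.5 for names, 1 for everything else, each type counted once no
matter how many identifiers of that type the metabolite has. Only candidates
at the per-metabolite maximum confidence are retained. Names get half weight
because name-derived hits are systematically noisier — the same name is often
attached to several structures, sometimes incorrect ones. No normalization by
the number of available types is applied; the retention step only compares
candidates of the same metabolite, so the absolute scale is immaterial.

`confidence_partition()` turns retained candidates into dispositions: a
*singleton* candidate with confidence at or above `auto_threshold` (default 1)
is applied automatically; ties and name-only hits (0.5) go to a manual review
queue. The threshold default encodes exactly "any unambiguous hit supported by
at least one non-name input type".

## Evaluation: labels, counts and the score

Returned candidates are labeled *preferred* (the input's stereoisomer; exactly
one per input and output type), *valid* (a valid but non-preferred
stereoisomer), *invalid* (an invalid stereoisomer or mixture), *incorrect* (a
different compound) or *nonexistent* (dangling). Candidates missing from the
truth table are labeled by a fixed policy: *incorrect* if the identifier
exists in the known-identifier table, *nonexistent* otherwise. For a test with
`In` inputs, `Hits` of which returned anything, `Out` returned candidates and
`Matches` preferred ones,

$$\mathrm{Score} = \frac{\mathrm{Hits} \times \mathrm{Matches}}{\mathrm{In} \times \mathrm{Out}} \in [0, 1],$$

defined as 0 when `Out = 0`. The score rewards returning exactly the preferred
identifier and penalizes both silence (low `Hits`) and noise (high `Out`).
`run_battery()` crosses input and output types (same-type pairs skipped; name
pairs skipped for strategies without name support: 6 x 4 types give 20 pairs,
the restricted no-names/no-PubChem coverage gives 9), and reports per-pair
counts, two aggregate scores — the mean of per-pair scores and the score
recomputed from mean counts, which differ slightly and are both reported
because published tables are ambiguous about which was used — and pooled
unique-output label tallies, each unique identifier counted once under its
best label. Report rounding is half-up to 2 decimals, matching the precision
convention of published tables (`round_half_up()`).

`run_additive_battery()` repeats the battery over prefixes of the input-type
order (names only, then +InChIKey, and so on), counting retained candidates
only, with `In` equal to the full test-set size since every metabolite has a
name. Labels come from a metabolite-level truth table, because additive
queries combine inputs and the label belongs to the metabolite rather than to
one input identifier.

## The annotation-update pipeline

`update_annotations()` composes three steps, in an order chosen so that
evidence-destroying actions happen before gap filling:

1. **Review** (`review_existing()`): an existing identifier whose store entry
   has a formula incompatible with the metabolite's formula is removed
   (`formula_mismatch`); hydrogen differences are ignored by default because
   protonation bookkeeping differs between databases and reconstructions. An
   identifier pointing at a charged entry is replaced by the same database's
   neutral entry sharing its hydrogen-free formula (`neutral_preference`),
   with the lexicographically smallest neutral identifier chosen when several
   qualify, for determinism. Metabolites with single-element formulas
   (inorganic ions, which only occur charged) are exempt by default, as is any
   type listed in `exempt_types`. Identifiers absent from the store are
   flagged, never removed: absence of evidence is not evidence of error.
2. **Fill** (`fill_missing()`): for each missing output type, additive mapping
   proposes candidates; those whose entry formula contradicts the metabolite
   formula are rejected *before* retention and disposition, so a wrong
   candidate can never shadow a right one, and identifiers removed in step 1
   are blocked from immediate re-addition.
3. **Accounting** (`summarize_changes()`): per-action, per-type, per-mode
   counts plus totals.

Review flags (`flagged_for_review`) are reported on a separate table rather
than in the change log. The log records what changed; flags record what a
curator should look at, and they recur on every run by construction (an
identifier the store has never seen stays unseen). Keeping them out of the log
is what makes the pipeline idempotent: running it twice over its own output
yields an empty second change log, which the tests assert.

## The synthetic fixture generator

`generate_fixture()` builds a deterministic miniature universe — database
dumps, a reconstruction, truth tables and a ground-truth manifest — from a
`fixture_spec()`. It emulates: stereoisomer splits (kegg/chebi hold the
generic form, hmdb/pubchem an alpha epimer, with distinct keys sharing a
skeleton block); ambiguous names attached to a second compound's entry;
entries violating exactly one ingest check each, carrying dangling
identifiers; parallel charged-form ChEBI entries one hydrogen short; obsolete
key assignments; partial annotation coverage; and planted wrong annotations
(another compound's identifier, guaranteed formula-detectable because the
synthetic formula map is injective over compounds). Synthetic InChIKeys are
hash-derived (`synthetic_inchikey()`), syntactically valid standard keys;
`synthetic_key_oracle()` plays the role of an InChI-to-key converter for
ingest checking. All rates are realized as exact counts, so realized fractions
match the specification to within rounding at any size.

Default parameters are fixed study conditions, not tuning knobs. Annotation
coverage defaults (InChIKey 0.64, ChEBI 0.43, HMDB 0.40, KEGG 0.15, PubChem
0.06, names 1.0) mirror the identifier prevalences reported for a large
published human reconstruction (2,626 metabolites of which 1,690 / 1,125 /
1,040 / 396 / 150 carried each type); the planted-error rate 0.05 and the
charged-duplicate rate 0.2 are in the proportion of that reconstruction's
reported removed (124) and replaced (569) identifier counts. Rates that no
published figure constrains — stereo splits 0.1, name ambiguity 0.1, bad
entries 0.05, obsolete assignments 0.05 — were chosen once as plausible
magnitudes for public compound databases and left alone.

What the generator does *not* emulate: real chemical nomenclature and synonym
distributions (names are `compoundNNNN` strings with controlled collisions),
real structures (keys are hashes, not derived from structures), database-size
asymmetries, and tautomer or protonation families beyond the single
charged-duplicate pattern. Passing tests on fixtures therefore demonstrate the
correctness of the mapping, scoring and update *logic* under the documented
pathologies — not performance on any real database snapshot, which depends on
data quality beyond this package's control.

## Numerical and degenerate-input choices

* Candidate sets are returned sorted lexicographically; ties in the neutral
  partner choice break to the smallest identifier — all outputs are
  deterministic for identical inputs.
* `Score` is 0 when nothing is returned; `In = 0` is an error, not a 0.
* Formula parsing rejects parentheses, charge tokens and unreadable counts
  outright (reconstruction formulas are linear; silent mis-parsing is worse
  than rejection); repeated element tokens are summed and deuterium is a
  distinct element. Charge never lives in the formula.
* Empty candidate sets, metabolites without formulas (checks skipped, one
  flag logged) and unknown identifiers (empty results, not errors) are all
  legal inputs everywhere past ingest.
* Test and battery problem sizes: unit fixtures use 25–150 compounds; the
  planted-error recovery check runs at 400 compounds in the unit suite and
  1,000 in the acceptance suite. These sizes already realize every planted
  phenomenon several times over while keeping the whole suite fast.

## A worked example

```{r example, eval = FALSE}
fx <- fixture_sugars()
store <- xref_store(fx$entries, strict = FALSE)

# the stereoisomer split: no key join from generic KEGG to alpha-only HMDB
map_ids(store, "kegg", "C00243", "hmdb")

# additive mapping for lactose, which is annotated with the generic KEGG id
# and the alpha HMDB id: both epimers' PubChem ids surface, tied, for review
met <- fx$recon[fx$recon$met_id == "M_lcts", ]
additive_map(store, met, "pubchem")

# published worked example of the evaluation score
round_half_up(mapping_score(99, 98, 146, 93), 2)
```

## Limitations

* Name matching is exact (case-insensitive, whitespace-collapsed); no fuzzy
  or synonym-expansion search. A metabolite registered under a different
  synonym is simply not found, which mirrors the behavior of the emulated
  services.
* Without a key oracle, InChI-to-key derivation is impossible; strict-mode
  consistency is relational and therefore order-sensitive in the presence of
  conflicts (the first accepted association wins).
* Generic metabolites with R-groups or variable structure cannot carry an
  InChI and are invisible to the key strategy; they surface only in the
  no-hit report.
* The mask merge rule (share one identifier of a configurable type set,
  transitive closure) is one defensible reconstruction of masking semantics;
  published mask-based tools do not document theirs.
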