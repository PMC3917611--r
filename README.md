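# metamapr

Offline mapping between metabolite identifiers in genome-scale metabolic
network reconstructions.

## The problem

Reconstructions annotate each metabolite with a name and, ideally,
identifiers in public compound databases (ChEBI, HMDB, KEGG Compound, PubChem
Compound, LIPID MAPS) plus a standard InChIKey. These annotations are often
incomplete or wrong, and with thousands of metabolites per reconstruction
they cannot be curated by hand. Two mapping philosophies exist among the
open-source tools built for this task: **standard-InChIKey joins** over an
aggregated cross-reference database (queries with different identifiers of
one compound are independent), and **metabolite masks** — merged identifier
groups where querying any member returns all same-type members (queries are
deliberately not independent). metamapr implements both, the quality checks
that separate a strict aggregation service from a permissive one, an
**additive confidence-weighted** multi-identifier mapping on top of the key
strategy, an evaluation framework, and an annotation-update pipeline — all
testable offline against a seeded synthetic fixture generator.

## The core statistic

A mapping test with *In* input identifiers, *Hits* of them returning at least
one candidate, *Out* returned candidates in total, and *Matches* preferred
candidates, is scored

```
Score = (Hits × Matches) / (In × Out)   ∈ [0, 1]
```

maximal when every input returns exactly its preferred identifier and nothing
else; silence lowers *Hits*, noise raises *Out*, and both cost manual effort.
Additive mapping accumulates per-candidate confidence across independent
per-type queries (+0.5 for name-derived hits, +1 otherwise) and retains only
maximal-confidence candidates per metabolite.

## A worked example

The curated sugar fixture encodes classic cross-database pathologies.

```r
library(metamapr)
fx <- fixture_sugars()
store <- xref_store(fx$entries, strict = FALSE)

map_ids(store, "name", "dextrose", "pubchem")
#> # A tibble: 4 × 5
#>   input_type input_value output_type candidate via_key
#>   <chr>      <chr>       <chr>       <chr>     <chr>
#> 1 name       dextrose    pubchem     206       BMRMZDHSBHDXDD-BMRMZDHSSA-N
#> 2 name       dextrose    pubchem     5793      KBRSVWGQKSQVFW-KBRSVWGQSA-N
#> 3 name       dextrose    pubchem     64689     KBRSVWGQKSQVFW-JWAESONPSA-N
#> 4 name       dextrose    pubchem     79025     KBRSVWGQKSQVFW-UCYQIEXWSA-N
```

The name *dextrose* is attached to four PubChem structures — D-glucose
(5793), its two epimers, and a generic hexopyranose (206) that is an
incorrect name-structure association. Name queries are noisy by nature, which
is why additive mapping down-weights them.

```r
map_ids(store, "kegg", "C00243", "hmdb")
#> # A tibble: 0 × 5
```

Lactose is registered as the generic stereoisomer in KEGG (C00243) but only
as the alpha epimer in HMDB (HMDB0000186); their standard keys differ, so a
key join returns nothing in either direction. Combining the metabolite's
identifiers narrows things down:

```r
met <- fx$recon[fx$recon$met_id == "M_lcts", ]
additive_map(store, met, "pubchem")
#> # A tibble: 4 × 6
#>   met_id output_type candidate confidence supporting_types retained
#>   <chr>  <chr>       <chr>          <dbl> <chr>            <lgl>
#> 1 M_lcts pubchem     6134             1.5 name+kegg        TRUE
#> 2 M_lcts pubchem     84571            1.5 name+hmdb        TRUE
#> 3 M_lcts pubchem     294              0.5 name             FALSE
#> 4 M_lcts pubchem     440995           0.5 name             FALSE
```

The two name-only candidates (including 294, an invalid generic disaccharide)
are dropped by maximal-confidence retention; the surviving tie between the
generic and alpha PubChem entries reflects the metabolite's own ambiguous
annotation pair and goes to manual review, not automatic addition.

The evaluation score on a published worked example:

```r
round_half_up(mapping_score(99, 98, 146, 93), 2)
#> [1] 0.63
```

And the update pipeline on a generated fixture with planted errors:

```r
sim <- generate_fixture(fixture_spec(n_compounds = 300, seed = 42))
upd <- update_annotations(sim$recon, xref_store(sim$entries, strict = FALSE))
glance(upd)
#> # A tibble: 1 × 5
#>   n_added n_removed n_replaced n_flagged total_updated
#> 1     738        14         27       204           779
```

The 14 removals and 27 replacements are exactly the fixture's planted
formula-mismatch and charged-form annotations
(`nrow(sim$manifest$mismatch)`, `nrow(sim$manifest$charged)`); a second run
over `upd$recon` produces an empty change log.

A thin command-line wrapper is installed with the package
(`system.file("cli/metamapper", package = "metamapr")`) with subcommands
`simulate`, `ingest`, `map`, `additive-map`, `evaluate` and `update`.

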