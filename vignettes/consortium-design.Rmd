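---
title: "Rational design of live biotherapeutic consortia: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rational design of live biotherapeutic consortia: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consortia)
```

## The design problem

A live biotherapeutic product (LBP) for inflammatory bowel disease is a
defined set of commensal gut strains intended to replace functions that are
missing or under-represented in a dysbiotic microbiome: short-chain fatty
acid synthesis (butyrate, propionate), GABA and indole synthesis from
tryptophan, bile-salt deconjugation and conversion to the secondary bile
acids DCA and LCA, and pathobiont control through antimicrobials and
siderophore competition for iron. `consortia` implements the computational
side of a bottom-up design workflow for such products:

1. **Function profiling** — call each therapeutic function present or
   absent per strain from genome annotations (`profile_functions()`), and
   screen strains for disqualifying features — transferable antibiotic
   resistance, virulence factors (`screen_exclusions()`).
2. **Species delimitation** — fragment-based average nucleotide identity
   (`compute_ani()`), with strains split into distinct species at more
   than 10% whole-genome difference (`classify_species_pair()`).
3. **Metabolic modelling** — flux balance analysis (`fba()`), exact
   minimum-penalty gapfilling (`gapfill()`), and single-omission
   auxotrophy detection (`detect_auxotrophies()`) on small
   constraint-based strain models.
4. **Community analysis** — a compartmentalized merge around a shared
   extracellular pool (`merge_models()`), community FBA under max-min or
   max-total objectives (`community_fba()`), cross-feeding dependency
   tables (`strain_interaction_table()`) and dropout robustness
   (`dropout_analysis()`).
5. **Selection** — a greedy set-multicover selector with repair and prune
   stages (`select_consortium()`) under redundancy, complementarity,
   exclusion and viability constraints, with an exhaustive oracle
   (`exhaustive_select()`) for small pools.

Two design principles drive the constraint system. *Functional redundancy*
(each key function carried by at least $r_f$ strains, default 2) ensures
the loss of one strain does not remove a therapeutic function.
*Complementary auxotrophy* (each member's required compounds secretable by
at least $k$ co-members, default 1) creates a network of metabolically
interdependent strains in which no member can outcompete the rest —
engraftment of the consortium is engraftment of the network.

## Function calling from annotations

A `function_catalog()` defines each function as marker groups: OR within a
group, AND across groups (`min_groups` relaxes this), with
case-insensitive substring matching on product text and exact matching on
controlled-vocabulary term ids. The AND-over-groups default reflects that
a multi-step pathway needs all of its steps; the substring convention
matches how consistently annotated genomes name enzymes. These are
deliberately simple, auditable rules — every presence call records the
matching terms as evidence, and the package re-checks evidence against
annotations in its test suite. The shipped default catalog encodes the
enzyme names behind the therapeutic functions (e.g. butyrate kinase,
tryptophanase, choloylglycine hydrolase, 7α-dehydratase); it does not
attempt HMM-level protein family detection, which is out of scope.

## Average nucleotide identity

`compute_ani()` follows the fragment-based (ANIb-style) convention: the
query is cut into non-overlapping 1020 bp fragments; each fragment is
placed in the subject by 15-mer seeds (at least two seeds must agree on a
diagonal within the 60 bp band — isolated seed hits on unrelated sequence
are chance matches, and forcing an alignment onto them would fabricate
homology); placed fragments are aligned global-locally within the banded
window; fragments with at least 30% identity and 70% coverage contribute
their identity; directional ANI is the mean over passing fragments and
the symmetric value is the mean of the two directions. When no fragment
passes in either direction the result is flagged and ANI is undefined
rather than reported as a number.

The parameters (1020/60/0.30/0.70) are declared package defaults in the
ANIb tradition, not a reconstruction of any particular external tool. On
substitution-only synthetic pairs the positional mismatch count is an
exact oracle, and the test suite requires recovered divergence within
±0.01 of the planted rate across 2–15% divergence.

## Constraint-based models and FBA

Strain models use the standard constraint-based conventions: a
stoichiometric matrix over cytosolic and extracellular metabolites,
exchange reactions touching exactly one extracellular metabolite, uptake
as a negative lower bound on exchange flux, and a single biomass
objective. Bounds are clamped to ±1000 mmol/gDW/h so every linear program
is bounded; growth is declared at biomass flux ≥ 1e−6, and feasibility is
checked to a steady-state residual of 1e−6.

The linear programs are solved by a bounded-variable two-phase primal
simplex with Bland's anti-cycling rule implemented in the package. It is
deliberately dense and simple: design-scale models have tens to a few
hundred reactions, and the implementation is cross-validated in the test
suite against an exhaustive vertex-enumeration oracle on every toy
network as well as on randomized LPs. Degenerate alternate optima are
resolved arbitrarily; only the objective value and status are
contract-bound.

`gapfill()` is exact rather than heuristic: subsets of the universal
database are enumerated in order of total penalty (ties by lexicographic
reaction id) and the first growing subset is returned, so the repair is a
certified minimum. This is practical because curated design-time
databases are small (the implementation accepts up to 16 reactions); the
trade of scalability for testability is intentional, and minimality is
re-verified by brute force in the tests.

`detect_auxotrophies()` mirrors how auxotrophy tables are read in
practice: a strain is auxotrophic for a compound when it grows on the
complete medium but not when that single compound is withheld.
Producibility is probed separately via a temporary demand (sink) reaction
rather than through biomass coupling, so "the compound is produced" is
tested directly. Probe the biosynthetic targets of interest; probing the
sole carbon source trivially reports it as required.

## Community models and objectives

`merge_models()` namespaces each member's metabolites and reactions with
a `<strain_id>__` prefix, turns each member's former exchanges into
member↔pool transfer reactions (±1000), and gives the shared pool its own
environment exchanges carrying the medium. Members therefore interact
*only* through the pool, and the pool is the only system boundary.

Two community objectives are provided because the field has no single
convention. `max_total` maximizes summed growth and can starve members;
`max_min` maximizes the worst member's growth and is the default here
because the design claim being tested is that *all* strains of a
consortium grow together. Members are weighted equally — no
biomass-ratio coupling — since no abundances exist at design time.

The central in-silico property the package makes testable is *consortium
synergy*: in a universe of cyclically complementary auxotrophs, every
strain alone has growth < 1e−6 while the community's max-min growth is
positive. Dependency edges in `strain_interaction_table()` are
established by member removal (consumer fails without producer, and the
metabolite is secreted by the producer and consumed by the consumer at
the optimum) rather than by flux-coupling analysis, because removal is
directly testable.

## The selector

The published design workflows state their constraints but not a
selection algorithm, so the selector here is a declared implementation: a
viability pre-filter excluding strains whose auxotrophies cannot be
complemented by k secretors anywhere in the pool (no feasible selection
can contain such a strain, so the exclusion — iterated to a fixpoint — is
exact, and it is what makes the greedy stage complete: any dead-end in
repair would have to involve a strain the filter already removed);
greedy set-multicover on the unmet (function, redundancy) demand, ties
broken by fewer own auxotrophies then lexicographic id; a repair stage
adding secreting strains until complementarity holds; a reverse-order
prune; and an optional community-viability check. "Complemented" means
the co-member's model can *secrete* the compound on the working medium
(maximal secretion flux > 1e−6), not merely produce it intracellularly —
cross-feeding requires export. Candidates are sorted by strain id before
selection so results are platform-stable, and the whole procedure is
deterministic. For pools of up to 15 strains `exhaustive_select()`
returns the certified minimum-cardinality design, and the test suite
requires the greedy selector to be feasible whenever the oracle is.

## The packaged consortium tables

`load_fixture("gut103")` and `load_fixture("gut108")` encode the
published 17-strain and 11-strain gut consortium overview tables as
candidate sets: strain and family names verbatim, SCFA/GABA/indole flags,
siderophore synthesis and uptake, antimicrobials, and the bile-acid
enzyme codes expanded to per-enzyme function ids. The extracted table
text does not always disambiguate which SCFA column an individual "+"
mark occupies; those few cells were assigned from the strains' published
physiology, which leaves headline-function coverage — the property the
package verifies — unchanged. The marker genes behind each table entry
are not printed in the source tables, so the fixtures carry function
profiles only: model-dependent checks (complementarity, community
viability) are disabled when verifying fixtures, and verification reports
state which checks ran.

## The synthetic universe generator

Real strain collections cannot ship with a package, so validation runs on
generated universes with planted ground truth. Each strain shares a core
metabolism (substrate uptake S\_e → S, precursor S → P) and one
two-reaction biosynthesis chain per essential compound; biomass consumes
the precursor plus every compound. An auxotrophy is planted by deleting a
chain; every strain carries a reversible transporter and exchange per
compound, so producers can export and auxotrophs can import. Under the
cyclic plan strain *i* is auxotrophic exactly for compound *i*, which its
neighbours produce — singletons fail and the full cycle grows, the
sharpest version of the interdependence the designer aims for. Under the
random plan deletions are independent at the specified rate with a
repair guaranteeing every auxotrophy has at least one producer.
Annotation tables carry one marker term per group of each planted
function plus hypothetical-protein distractors; genomes are uniform
random DNA, mutated by substitution only so the mismatch count is an
exact divergence oracle (an indel-free default keeps the oracle exact).
Generated universes re-derive their own truth labels through the
detection code before being returned and error on any mismatch.

Default study conditions: 20 strains, 6 compounds, auxotrophy rate 0.15,
function planting rate 0.5, 20 kb genomes. What the generator does *not*
emulate — annotation noise and synonymy, incomplete or wrong gene calls,
genome-scale model reconstruction error, realistic sequence structure —
bounds what green tests mean: they certify the algorithms against their
stated contracts on noise-free inputs, not annotation-pipeline robustness
on real genomes.

## qPCR quantification

Community composition uses the comparative-Ct method with
efficiency fixed at 2 (the printed formulas' assumption; configurable):
weights $2^{-Ct}$ normalized within sample, missing Ct (below the
detection limit) mapped to abundance 0 — no floor imputation, since the
assay reports a detection limit but no imputation rule. Expression fold
change uses $2^{-\Delta\Delta Ct}$. The forward simulator
(`simulate_ct()`) inverts exactly at zero noise, giving a round-trip
identity the tests assert to 1e−9.

## Worked example

```{r example, eval = FALSE}
u <- generate_universe(universe_spec(n_strains = 5, plan = "cyclic", seed = 42))

# singletons fail on the minimal medium ...
vapply(u$models, function(m) fba(m, u$minimal_medium)$objective_value, numeric(1))

# ... the five-member community grows (max-min growth 1/3 each)
com <- merge_models(unname(u$models), u$minimal_medium)
sol <- community_fba(com, scheme = "max_min")
tidy(sol)

# who feeds whom at the optimum
tab <- strain_interaction_table(com, sol, unname(u$models), u$minimal_medium)
tab$exchanges
```

Note that in the five-member cycle every compound has four producers, so
the pairwise-removal *dependency* edge set is empty — dependencies appear
when a producer is sole, as in a two-strain obligate pair, where the
table reports the two reciprocal edges.

## Numerical choices and limitations

* Growth threshold 1e−6; LP pivot tolerance 1e−9; steady-state residual
  checked to 1e−6; ties in the selector and gapfiller broken
  lexicographically so all results are reproducible.
* Problem sizes used in the shipped tests: 10–20 kb genomes for ANI,
  universes of 3–20 strains, gapfill databases of 12 reactions, selector
  pools of 6–12 candidates. These match the scale at which the exhaustive
  oracles remain exact.
* Not implemented (out of scope): genome-scale reconstruction from
  annotations, flux variability or thermodynamic analysis, dynamic or
  abundance-coupled community FBA, HMM-based function detection, and all
  wet-lab readouts (histology, cytometry, metabolomics chemistry).
* The exact gapfiller and the exhaustive selector trade scalability for
  certified optimality; both refuse inputs beyond their stated limits
  rather than silently switching to a heuristic.
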