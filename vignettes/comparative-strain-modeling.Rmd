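---
title: "Comparative constraint-based modeling of strain families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative constraint-based modeling of strain families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainflux)
```

## The model

`strainflux` treats a bacterial strain as a constraint-based metabolic
network: metabolites, reactions with stoichiometry and flux bounds
(mmol per gram ash-free dry weight per hour), and boolean
gene–protein–reaction (GPR) associations. Growth is the flux through a
biomass pseudo-reaction that consumes precursor metabolites in fixed
ratios, predicted by flux balance analysis (FBA): maximize the biomass
flux subject to steady-state mass balance $Sv = 0$ and the bounds
$lb \le v \le ub$.

FBA's assumptions matter for how the results should be read. The cell
is assumed to be at steady state and to maximize growth; regulation,
kinetics and expression cost are ignored. Growth predictions are
therefore *capability* statements — a predicted "growth" means the
network can route flux to biomass, not that the strain would express
that route. Comparative conclusions (strain A can, strain B cannot)
are more robust than absolute growth rates, which is why the pipeline
asserts growth/no-growth patterns and flux differences rather than
rate values.

## Medium conventions and their parameters

`set_medium()` implements a deliberately uniform simulation medium so
that every model in a comparison sees identical constraints:

* carbon source and electron acceptor: uptake capped at
  10 mmol/gAFDW/h (`uptake_bound`);
* phosphate, sulfate, water, protons — and ammonia when it is the
  nitrogen source — freely available at 1000 (`free_bound`);
* every exchange open for secretion at 1000 (`secretion_bound`);
* all other uptake closed;
* growth- and non-growth-associated ATP maintenance set to zero,
  because maintenance coefficients fitted for one strain do not
  transfer to relatives and would bias cross-strain comparisons.

The maintenance rule is applied to reactions matched by a configurable
pattern (`atpm_pattern`, default matching ids/names like `ATPM` or
"ATP maintenance"); compound-to-exchange mapping is by metabolite id
(with or without compartment suffix), metabolite name, or `EX_`-stripped
reaction id, case-insensitively, and is configurable rather than
hard-coded because supplementary SBML dialects disagree on identifiers.
A compound with no matching exchange makes the condition
*not representable* for that model; grid-style phenotype prediction
records the event and scores the cell 0 (no growth), because a
comparison over union condition sets must keep every cell defined.

The growth threshold is 1e−6 on the biomass flux. The qualitative rule
is "growth iff the optimum is positive"; the threshold guards against
solver round-off around zero and is far below any meaningful growth
flux at these bounds.

## Strain derivation and the core model

`derive_strain_model()` translates each template GPR leaf into the OR
of its co-orthologs in the target strain (co-orthologs are isozyme
alternatives); a reaction is removed only when its translated GPR is
unsatisfiable, i.e. every way of catalyzing it needs a gene with no
ortholog. Reactions with no gene association, exchanges and the
biomass reaction are carried over unchanged — curated biomass or
lipopolysaccharide edits are user-supplied overrides, not computed.
Pseudogene-flagged table entries (gene fragments) count as absent
everywhere.

`build_core_model()` restricts the template to ortholog groups
conserved in *all* strains, then prunes in two deterministic
fixed-point passes: first the reactions whose GPRs lost all conserved
support (survivors are retained with their original GPRs and flagged
as *isozyme exceptions* — reactions the group cannot do without even
though no single gene for them is conserved), then the reactions with
no gene association, keeping only those whose removal abolishes growth
on the reference condition (aerobic pyruvate by default). Each pass
repeatedly removes the lexicographically first candidate whose removal
keeps the model growing, until every remaining candidate is essential.
This order is fixed by reaction id, so the result is independent of
strain order and reproducible; because pruning starts from the full
candidate set and only ever removes reactions that are individually
dispensable *in the current context*, the core is guaranteed to grow.
A single-pass test against the template instead of the shrinking core
would miss collectively essential sets (e.g. a two-step bypass whose
steps are individually dispensable), which is why the fixed point is
evaluated in context.

## Phenotyping and clustering

Phenotype matrices are binary growth layers over carbon ×
electron-acceptor grids, one layer per strain, with per-cell counts of
growing strains. Clustering of models — by gene-content profiles or by
phenotype profiles — uses euclidean distance on the binary columns, the
conventional metric for such presence/absence dendrograms. The linkage
is *average* by default and exposed as a parameter: only the distance
metric is pinned by convention, and with few models the topology can be
sensitive to the linkage, so it is recorded rather than hidden. Rows
identical across all models may be dropped for display; identical
coordinates contribute nothing to euclidean distances, so the
clustering is unaffected. Merge-order ties are broken deterministically
by sorting model columns lexicographically before clustering.

## Deletion-set comparison and difference classes

`find_deletion_sets()` aligns two models at the gene level through the
ortholog table and enumerates deletion sets over *shared* ortholog
groups (sizes 1, then 2) after which exactly one model grows — the
deletions that maximize the biomass-flux difference all the way to
lethality in one network. Genes unique to one model are reported
separately by `align_genes()`: deleting them is a no-op in the other
model and would create differences trivially. Reported sets are
minimal (no pair containing a reported or both-lethal single), and FBA
calls are memoized by the set of reactions a deletion actually closes,
which collapses the many deletions that close nothing.

Exhaustive enumeration is the engine and the ground truth; set sizes
beyond 2 are rejected. Classification of a result, with dying model N
and surviving model G, applies three checks in order:

1. **genetic** — some reaction closed in N is present and still active
   in G under the same group deletion (G has an extra isozyme or
   subunit arrangement);
2. **biomass** — the biomass components of N that the deletion makes
   unproducible are all absent from G's biomass equation.
   Unproducibility is operationalized as per-component sink FBA:
   maximize a demand for the component under the deletion;
3. **metabolic** — otherwise: the same reactions close in both, and G
   reroutes through an alternative pathway.

Genetic and biomass can co-occur; metabolic is the fallback, so every
result carries at least one label. Summaries across a model set union
all ordered pair results, group them by the dying model and
de-duplicate by ortholog group; by default counts are per ortholog
group, since every subunit of an AND complex yields the same lethal
set.

## Fitness evaluation

Transposon-mutant fitness z-scores are converted to growth calls per
(mutant, simulatable condition): replicates vote, a majority above the
cutoff (default −3.5) calls growth, a majority below calls no growth,
and an exact tie is *undetermined* and excluded from scoring. The
stated rule is strict on both sides of the cutoff, so a score exactly
at the cutoff must be assigned somewhere; it counts as growth here (the
boundary stays with the viable class) and the choice is visible in
`call_growth()`'s documentation. Model predictions are scored as a
confusion summary — accuracy, false positives (model growth, data no
growth) and false negatives (the reverse) — whose percentages sum to
100 over the compared calls. In the cutoff sweep the limits follow
from the definitions: a cutoff below every score calls all mutants
growth, making false positives impossible; a cutoff above every score
makes false negatives impossible.

Growth rates from OD curves are the least-squares slope of ln(OD)
versus time on a maximal-slope sliding window (default one third of the
curve), and biomass yields are the plateau OD minus starting OD over
substrate amount, with the plateau detected as a terminal window of
relative spread below 2%.

## The synthetic generators

`generate_template()` builds a toy strain whose backbone is fixed —
pyruvate uptake, oxidation to acetate with NADH formation, respiration
on oxygen/nitrate/fumarate with different ATP yields, precursor
biosynthesis drawing on ammonia, phosphate and sulfate, an
ATP-maintenance demand, and a biomass reaction over the precursors —
and whose redundancy is seeded: extra two-step routes to precursors
with singleton, isozyme-pair (OR) and complex-pair (AND) GPRs. The
pyruvate transporter and the first precursor's sole synthesis route are
reserved (never bypassed) so that planted differences have guaranteed
targets. Defaults (about 45 reactions, 35–40 genes, 4 strains) are
large enough to contain isozymes, complexes and bypasses yet small
enough that exhaustive double-deletion enumeration and the LP
cross-checks stay fast; these are also the problem sizes the test suite
and the acceptance script run at.

`generate_family()` founds one ortholog group per template gene and
loses non-essential genes per strain at the spec's loss probability
(15% by default, a realistic divergence for close relatives; a
configurable fraction of losses are recorded as pseudogene fragments).
Genes essential on the designated condition are conserved in every
strain — essential genes are what conservation selects for — and any
strain still left unable to grow has lost groups restored in
deterministic order until it grows. Strain models are produced by
`derive_strain_model()` itself, so generator and deriver agree by
construction. `plant_difference()` injects one archetype of each
difference class with a known expected deletion set and label, and
`simulate_fitness()` draws replicate z-scores from Normal(0, sd) for
growing mutants and Normal(−6, sd) for non-growing ones — means chosen
so the conventional −3.5 cutoff sits between the modes, mirroring the
cutoff's semantics rather than any empirical score distribution.

What the generators do *not* emulate: realistic stoichiometry or
genome scale, transcriptional regulation, condition-dependent biomass
composition, horizontal gene gain (strains only lose template content),
or correlated noise across fitness experiments. Green synthetic tests
therefore demonstrate correctness of the algorithms, not calibration
against any organism's data.

```{r example}
spec <- family_spec(seed = 7)
template <- generate_template(spec)
family <- generate_family(template, spec)
template
sapply(family$models, function(m) length(m$genes))
```

## Numerical choices

The FBA linear programs are solved by an internal two-phase dense
simplex on shifted variables $x = v - lb \ge 0$ (all bounds are
finite), with Bland's smallest-index rule for entering and leaving
variables. These systems are small (tens of reactions here; hundreds
for curated strain models) but highly degenerate — most equality rows
have zero right-hand sides — and the general-purpose simplex routines
available in R's package ecosystem fail on exactly that degeneracy,
which is why the solver is in-package. Bland's rule guarantees
termination; pivot tolerance is 1e−9, phase-1 feasibility tolerance
1e−7, and redundant constraints surviving phase 1 are dropped. Only
objective values are asserted anywhere: optimal flux vectors are
degenerate, the optimum is not.

SBML input accepts both Level 3 with the `fbc` package (bounds as
parameters, gene associations as `fbc` trees) and the legacy Level 2
COBRA dialect (bounds in kinetic-law parameters, GPR strings and
subsystems in notes, boundary species marking exchanges); output is
always Level 3 + fbc v2 and byte-deterministic for a given model. The
biomass reaction is taken from the fbc objective when present,
otherwise from a configurable id/name pattern (default "biomass") that
fails loudly when ambiguous or absent.

## Limitations

* No flux variability, parsimonious FBA, or minimization-of-adjustment
  analyses; only growth objectives.
* No automated gap-filling: derivation only removes content, and
  conflicts with observed phenotypes are flagged for manual curation
  rather than repaired.
* Deletion-set search is exhaustive enumeration, suitable for set
  sizes up to 2; a bilevel optimization engine for larger sets is out
  of scope.
* Thermodynamic constraints, formula/charge balancing and model repair
  are out of scope; reversibility is taken from bounds as given.
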