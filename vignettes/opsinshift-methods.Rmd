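---
title: "Methods: genotype-based inference of avian UV/violet vision and parsimony reconstruction of spectral shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-based inference of avian UV/violet vision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opsinshift)
```

## The biological model

Diurnal birds carry one of two classes of short-wavelength colour vision,
defined by the spectral position of the SWS1 cone opsin: ultraviolet-sensitive
(UVS, wavelength of maximum absorbance 355--380 nm) and violet-sensitive
(VS, 402--426 nm). Uniquely among the avian cone classes, SWS1 tuning is
governed entirely by the opsin protein, and in practice by a handful of
residues lining the retinal binding pocket near the Schiff-base linkage --
principally sites 86 and 90 in bovine rhodopsin numbering, with site 93
implicated but unconfirmed. Site-directed mutagenesis has shown that the
single substitutions C90S and S90C move a pigment across the whole
UVS/VS divide, and S86F shifts VS pigments into the ultraviolet. The
spectral class of a bird can therefore be read from a genomic fragment of
roughly 50--160 bp spanning those sites.

This package implements that inference and everything needed to interpret
it comparatively: translation and site-anchoring of short fragments, the
genotype classification rules, codon-level substitution-path arithmetic,
and exact parsimony reconstruction of UVS/VS shifts on a reference
phylogeny.

## Classification rules

`classify_genotype()` applies a small, fixed dichotomy to the residues at
sites 86/90/93:

* **UVS** if residue 90 is cysteine (C90) *or* residue 86 is phenylalanine
  (F86). The C90 check comes first; both conditions reflect destabilized
  Schiff-base protonation.
* **VS** if residue 90 is serine and residue 86 is one of S, A, I, C, T or
  M -- exactly the residues that have been observed together with S90 in
  violet-type pigments. Any other residue paired with S90 yields
  `INDETERMINATE` rather than a guess.
* **INDETERMINATE** whenever a deciding site is unknown (`X`) or the
  combination is unlisted.

Site 93 never changes the class. Nonpolar residues at site 93 (M, L, I)
co-occurring with C90 may stabilize Schiff-base protonation and hence mask
a UVS genotype -- the palaeognath situation -- but the mutagenesis evidence
for a strong site-93 effect is weak (a measured T93V shift is only 3 nm),
so the package only attaches an evidence note in that case.

**Phenotype overrides.** Direct measurements outrank sequence-based
inference. The override registry (`default_overrides()`) maps taxon labels
to forced phenotype classes; the packaged registry contains one entry,
`Palaeognathae -> VS`, because microspectrophotometry of the ostrich
retina shows violet-type SWS1 single cones even though all palaeognaths
carry the canonically UVS-conferring F86+C90+M93 genotype. Overrides never
alter the genotype class, only the phenotype call, and every application
is recorded in the evidence notes.

**Lambda-max estimation.** `estimate_lambda_max()` consults an ordered
pattern table (`default_lambda_rules()`, shipped as a plain-text TSV with
a provenance note per rule). Patterns are literal residues or wildcards at
the three sites; the first match wins and a catch-all guarantees totality.
Point estimates are configuration values drawn from the mutagenesis
literature (370--372 nm for the C90 routes, 369 nm for F86, 406 nm for
violet-type genotypes); only the class intervals (355--380 / 402--426 nm)
and the 31--47 nm magnitude of a single-substitution shift are treated as
assertable facts in the test suite, because the point values are
calibration choices, not measurements made by this package.

**Non-conservative substitutions.** The classical definition used in this
field -- a change of formal charge or the gain/loss of a hydroxyl group
(S, T, Y) -- does not cover the C-to-M replacement observed at site 86 in
Passerida songbirds, although the field treats all observed site-86/90
changes as non-conservative. `is_nonconservative()` therefore also scores
a change of polar/nonpolar class (cysteine's thiol counts as polar,
methionine's thioether does not). Under this definition every substitution
pair observed at the tuning sites (S/C, S/F, S/A, A/T, T/I, C/M) is
non-conservative, S-to-C remains non-conservative via hydroxyl loss, and
neutral swaps such as I/L remain conservative. Histidine is counted as
charged; no observed case depends on it.

## Fragment handling

Anchoring is **ungapped**: the amplicon is a short exon fragment and no
indels have been reported in this region, so `select_frame()` slides the
translated fragment against a reference window (default: the modal
residue per site over the neognath survey rows, `FISCIFSVFTV`, sites
84--94) in all six frame/strand combinations. The winning frame must reach
a minimum identity (default 5 of 11 anchor sites -- half the window,
conservative enough that random sequence essentially never anchors) and
must not contain a stop codon inside the anchored region; ties between
frames are reported as errors listing the candidates, never resolved
silently. Codons containing IUPAC ambiguity codes translate to their
residue only when all disambiguations agree, otherwise to `X`; the
classifier treats `X` at a deciding site as indeterminate rather than
guessing. `window_hamming()` excludes `X` positions by default and reports
how many sites were compared.

## Parsimony engine

`fitch_count()` computes the exact minimum number of unordered state
changes with the unit-cost dynamic programme (the Sankoff recursion with a
0/1 cost matrix). On binary trees this is Fitch parsimony; on
multifurcating trees it is the exact generalization, so polytomies are
handled natively and never resolved. The root state set is the set of
states attainable at the root across all most-parsimonious
reconstructions (MPRs).

Counting *events* is more delicate than counting changes, because MPRs
differ in where they place changes and in which direction. Two devices
are used:

* **Per-type ranges.** For each labelled event type (e.g. `S90C`,
  `C90S`), `reconstruct_shifts()` runs a second dynamic programme over the
  MPR space that yields the exact minimum and maximum count of that type
  over *all* MPRs. An independent path (`method = "enumerate"`) lists
  every MPR explicitly (refusing beyond a candidate-space cap, default
  50000) and recounts; the two paths are cross-validated in the test
  suite. Direction totals (UV gains vs losses) are recomputed by a
  direction-level DP rather than by summing per-label bounds, so the
  reported bounds are jointly attainable.
* **A representative MPR** is produced by deterministic backtracking: the
  root takes the alphabetically first optimal state and each child keeps
  its parent's state whenever that is optimal (otherwise the
  alphabetically first optimal state). This favours placing changes as
  close to the tips as the optimum allows and makes reports reproducible.

Fitch counts are root-invariant, but event *direction* (gain vs reversal)
is meaningful only on a rooted tree, so direction labels are computed on
the rooted input as drawn.

`brute_force_min_changes()` is an intentionally naive exhaustive oracle
(every assignment of internal states, at most 12 internal nodes) kept
separate from the DP; the test suite checks the two agree on every rooted
shape with up to 6 tips over 2- and 3-state assignments, and checks the DP
against an independent parsimony implementation (phangorn) on random
trees.

## Character codings and the route coding

Four codings of the reference data are shipped:

* `phenotype`: binary UVS/VS after overrides. This is the coding behind
  the headline count -- a minimum of **14** VS/UVS shifts on the reference
  tree.
* `site86`, `site90`: raw residue characters (palaeognaths carry F86/C90
  here, because these are genotype characters). They drive the
  root-ambiguity result: the root state set is {F, S} at site 86 and
  {C, S} at site 90 -- the ancestral tuning-site residues cannot be
  resolved, because palaeognaths are fixed for F86/C90 while neognaths are
  ancestrally S86/S90.
* `route`: phenotype with the causal route resolved,
  {VS, UVS_C90, UVS_F86}. This is the coding used for substitution-route
  event counts (S90C gains 5--6, C90S reversals 5--6, S86F gains 3, UV
  gains 8--9, UV losses 5--6, always summing to 14).

The route coding applies the palaeognath override deliberately. On the raw
site-90 genotype coding the unresolved root forces one extra basal event
into every MPR -- either an S90C gain on the palaeognath stem or a C90S
reversal on the neognath stem, depending on the (unknowable) root state --
which would smear the gain count to 5--7. The published counts are
phenotype-shift counts that exclude that unpolarizable basal branch, and
the route coding reproduces them exactly while the residue codings retain
the honest root ambiguity.

## The reference tree fixture

The packaged tree follows the order-level topology of the molecular
phylogeny used in the source figure, with states from the packaged
40-species survey plus prior-study states for taxa outside it. Two clades
are collapsed in the source figure and are expanded here into *minimal
subtrees that realize the reported shift placements*:

* **Charadriiformes**: one S90C gain in the ancestor of the
  gull/tern/skimmer clade and one C90S reversal nested inside it
  (*Sterna*). The expansion is pectinate with UVS lineages above and below
  the reversal, which makes both events forced in every MPR.
* **Passeriformes**: a gain in the common ancestor of parrots and
  passerines, a reversal at the base of the passerine radiation
  (suboscines), and an oscine core that is strictly UVS-rooted with
  reversals nested inside, arranged so that exactly one motif is
  ambiguous: three-or-four gains with, correspondingly, five-or-four
  reversals. This is the only MPR ambiguity in the whole fixture (the
  route character has exactly 2 MPRs).

The expansion is the largest reconstruction gap in the packaged data: the
source states *where* events occurred but not the full subtree topologies,
so representative tips for the expanded clades are **stylized** -- chosen
to be plausible members of the groups involved, but their individual
states should not be cited as data. They are marked `prior` in the
tip-state table; every tip also present in the 40-species survey carries
its surveyed states, and a consistency test enforces that. The whole
fixture is validated computationally: the test suite asserts the headline
14, every event range, both root-state sets, and agreement between the
DP and exhaustive MPR enumeration on the fixture itself.

## The simulator

`simulate_fragments()` evolves the site 81--94 codon region down a tree:
a root codon configuration (default TCC/AGC/ACC at 86/90/93 -- the
violet-type ancestral neognath genotype with the modal threonine at 93),
planted codon substitutions on named branches, seeded random flanks, and
optional per-base substitution noise and `N`-masking. It emulates what
the pipeline actually consumes -- short, directionally arbitrary fragments
with the tuning sites inside -- and it is deterministic under its seed.

It does *not* emulate several features of real amplicon data: indels and
alignment error (excluded by design, matching the ungapped anchoring),
chromatogram-level base-calling error structure (noise is i.i.d.),
heterogeneous substitution processes along the tree (only planted events
change the coding region), or primer footprints (flanks are random and
trimming is anchor-based). Passing the simulator round-trip therefore
demonstrates the internal consistency of the pipeline -- translation,
anchoring, classification and reconstruction invert the generative
process -- not robustness to artefacts absent from the generator.

`plant_random_events()` guarantees recoverability by construction:
planted clades are pairwise disjoint, never two children of the same
node, and a placement whose implied tip coloring could be explained by
fewer than *k* changes (for instance by flipping the root side when the
unaffected tips happen to form a single clade) is rejected and resampled.
Under those conditions the planted event count equals the parsimony
minimum exactly, and the test suite verifies 100 of 100 seeded runs on
16-tip trees with up to 3 events.

## Numerical and design choices

* Site numbering is absolute (bovine rhodopsin) everywhere; windows carry
  their own `start_site` and there are no fragment-relative offsets in
  any interface.
* Codon-path distances are unweighted base differences; no
  transition/transversion weighting, because the inferences the package
  supports reason in raw substitution counts. Stop-codon filtering of
  path intermediates exists but is off by default.
* Tips without states are dropped per character with a warning, never
  imputed (the kiwi situation: amplification can simply fail).
* The representative-MPR tie-break (keep the parent's state when optimal,
  else first alphabetically) and the first-match-wins rule table are the
  only tie-breaking rules; both are deterministic and documented.
* Problem sizes in the shipped tests: the 70-tip reference tree for the
  end-to-end checks; exhaustive oracle comparisons on all rooted shapes
  with 4--5 tips and sampled shapes with 6; 100 seeded 16-tip simulations
  for the recovery property. These sizes were chosen so the whole suite
  exercises every exact algorithm exhaustively at small scale while
  staying comfortably interactive.

## Known limitations

* The classifier is a rule engine for the avian SWS1 system; it does not
  model absorbance curves quantitatively and deliberately refuses
  (returns `INDETERMINATE`) outside the observed residue combinations.
* Phenotype overrides are coarse taxon-label matches; they implement the
  direct-evidence-wins policy but carry no probabilistic weighting.
* The reference tree is a fixture for reproducing the reconstruction, not
  a phylogenetic estimate; alternative topologies (e.g. different
  placements of the parrot/passerine clade) change the counts and can be
  supplied by the user as Newick plus tip-state TSVs.
* Parsimony gives minimum-change reconstructions; likelihood or Bayesian
  ancestral-state methods are out of scope.
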