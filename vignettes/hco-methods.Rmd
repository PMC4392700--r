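---
title: "Methods: semantic annotation and DL querying of tractography connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic annotation and DL querying of tractography connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hco)
```

## The problem

Diffusion tractography yields, per subject, a stack of region-to-region
connectivity matrices: one matrix per white-matter seed mask, rows indexed
by the parcels of a target region of interest, columns by every other
parcel or subcortical structure. Interpreting such matrices across levels
of granularity — parcel, gyrus, lobe, fiber bundle — requires part-whole
knowledge that the matrices themselves do not carry. This package couples
the matrices to a gross-anatomy ontology so that multi-granularity
questions become class-expression queries answered by a reasoner.

The driving use case is the right medial premotor cortex (medial Brodmann
area 6), which long-range connectivity separates into an SMA-like portion
(connected through the corticospinal tract or to precentral gray matter)
and a pre-SMA-like portion (connected to medial parietal and inferior
frontal cortex). The four shipped competency queries
(`competency_query(1:4)`) express exactly these contrasts.

## The knowledge model

The TBox built by `build_hco_schema()` contains four classes and eleven
object properties. `Gray_matter_part` / `White_matter_part` are defined as
gray/white matter of the neuraxis that is a regional or constitutional part
of some anatomical structure. `MR_Node` and `MR_Route` are the
tractography-specific refinements:

* `MR_Node ≡ Gray_matter_part ⊓ ∃is_tracto_connected.MR_Route`
* `MR_Route ≡ White_matter_part ⊓ ∃tracto_connects.MR_Node`

`is_tracto_connected`/`tracto_connects` are mutually inverse;
`mr_connection` and `continuous_with` are symmetric; `part_of` and `part`
are transitive umbrella properties above the regional/constitutional part
properties of the source anatomy ontology. The role chain
`is_tracto_connected ∘ tracto_connects ⊑ mr_connection` converts
node–route–node paths into node-level connections.

Two schema-level choices deserve a note. First, `part_of` and `part` are
*not* declared inverses of each other: the property table that defines them
lists super-property and transitivity characteristics only, and declaring
the inverse would derive strictly more than the declared schema warrants;
the reasoner still derives both directions wherever the underlying
regional/constitutional assertions exist, because those properties do have
inverses. Second, `attributed_continuous_with` (the source ontology's
reified adjacency) is kept as a plain property with no inverse or symmetry
flag, since its characteristics are not specified by the source; the
instance level uses the explicitly symmetric `continuous_with` instead.

## View extraction and translation

`extract_view()` reproduces the recursive partonomy extraction: seeds (the
most specific mapped terms) are closed upward along `regional_part_of` and
`constitutional_part_of` (entity → whole, never downward: seeding with
specific terms and pulling in their parts would re-import most of the
source ontology), then adjacency partners are admitted, then subsumers.
Design points that were genuinely open:

* **Lateral policy.** Partners related by `attributed_continuous_with` may
  either join the view once and be closed upward (`one_step`, the default,
  since adjacency knowledge is only useful if the partner is present) or
  be kept only when both ends are already in the view (`closed`).
* **Order of closures.** The subsumption closure runs *after* the lateral
  expansion, so newly admitted partners also contribute their subsumers.
* **Exclusions after closure.** Excluded hubs (e.g. the whole-body term)
  are removed after the traversal, not before, so they cannot truncate it.

`translate_frame_to_dl()` removes the class/individual punning: every
entity becomes a named class, every kept entity-level triple `(A, p, B)`
becomes `A ⊑ ∃p.B`. One stored triple yields one axiom — inverse axioms
are not synthesized; inverse consequences are the reasoner's job. Triples
over discarded relation types are counted in a report rather than being
fatal, since discarding them is part of the procedure.

## Matrix post-processing

`binarize_matrix()` applies, in order: natural `log1p` element-wise,
division of each row by its row maximum (all-zero rows stay zero), and a
threshold of τ = 0.7 with `≥` comparison. Choices, where the procedure
description left room:

* **`log1p` rather than `log`** handles zero connectivity without a
  pseudo-count parameter.
* **Row maximum** as the normalizer makes the threshold directly
  interpretable — "at least 70 % of the strongest log-connectivity in the
  row" — and guarantees every non-empty row keeps at least one connection
  (its maximum normalizes to exactly 1). Sum or min-max normalization
  would make the threshold depend on row density.
* **`≥` with ties kept** so that the row maximum always survives under
  exact arithmetic.

The procedure is deliberately scale-*detecting*, not scale-invariant:
rescaling a row changes log-ratios and therefore may change which cells
survive. The log is part of the connectivity model, not cosmetics.

`aggregate_voxelwise()` reduces voxel-level matrices by the arithmetic
mean over all voxel pairs of the two regions, which is exact for the
region-level quantity it estimates and linear in the input.

## Annotation conventions

Each parcel individual (`s1_gray_matter_of_right_superior_frontal_gyrus_17`)
is `regional_part_of` a per-subject gray-matter-of-region individual,
which is `constitutional_part_of` the region individual, which carries the
configured partonomy-hint chain (lobe, segment, hemisphere). Anatomical
individuals are created lazily and shared within a subject, never across
subjects. Routes are numbered over matrices in input order and cells in
row-major order, so names are reproducible byte-for-byte. One route is
created per surviving matrix cell — per matrix, not per global pair — so
the same anatomical pair seen from two seed masks yields two routes; a
collapse to one-per-pair would lose the bundle attribution that
distinguishes the seeds. `mr_connection` is also asserted directly at
annotation time (the chain rule would re-derive it); endpoints are distinct
by construction and a self-connection is an error.

## The saturation engine

`saturate()` materializes a least fixpoint over TBox rules (reflexivity,
subsumption transitivity, definitional introduction for conjunctions and
disjunctions, propagation of class-level existentials along the role
hierarchy, transitive roles, filler subsumption) and ABox rules (type
inheritance, role hierarchy, inverses/symmetry, transitivity, the role
chain, and realization of defined classes). Facts are stored as
deduplicated tables and rules are applied as joins until nothing new
appears; termination follows from the finite fact space and the result is
independent of rule-application order (the optional trace is not).

The chain rule suppresses conclusions with identical endpoints: a node
trivially reaches itself through its own route, but a connection links
*two different* nodes. This is a documented divergence from a literal OWL
property chain, which would entail the reflexive pair.

The engine is *sound but incomplete* relative to full OWL DL: disjunction
is handled only definitionally (no tableau branching), there is no
negation, disjointness or cardinality, and anonymous-filler entailment in
query evaluation applies only when the filler reduces to a named class or
a disjunction of named classes. In this fragment every knowledge base is
satisfiable, so consistency checking reduces to referential integrity.
Completeness against a tableau reasoner is not claimed and not required by
any shipped result; the test suite instead proves equivalence with an
independently written naive fixpoint oracle on hundreds of random
knowledge bases.

## Query language

The grammar is a small Manchester fragment: `and`, `or`, `some`,
parentheses; precedence `some > and > or`; `some` right-associative over
atoms. Unprefixed identifiers resolve against the vocabulary `hco:` first,
then `fma:`; a name present in both namespaces is an ambiguity error
rather than a silent pick. The printed form of the second competency query
groups the medial-parietal conjunction under the connection restriction,
with both disjuncts inside the outer conjunction — the reading that
matches the query's prose ("medial parietal cortex or inferior frontal
cortex").

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` reproduces the *data shapes* of the emulated study:
five subjects, 1000 cortical parcels plus 15 non-cortical regions, an
11-parcel target mask with the published parcel numbers (20, 12, 32, 9,
17, 13, 42, 18, 24, 25, 38), and 22 seed masks — 20 anatomically labeled
tracts and one rest-of-white-matter mask per hemisphere — each yielding an
11 × 1004 matrix. The 20-tract list doubles the bilateral tract stems per
hemisphere and keeps the two corpus-callosum forceps unpaired; the exact
enumeration used originally cannot be reconstructed from the nine listed
stems, so this JHU-style list is a documented stand-in.

Planted connectivity is designed for *provable* recovery: planted cells
carry the row maximum (raw value 1000), and noise values are drawn
uniformly from [1, 100], strictly below the level that survives
binarization in a row holding a planted entry
(ln(101)/ln(1001) ≈ 0.67 < 0.7). Hence at zero noise the queries return
exactly the planted parcels, and at positive noise answers can only grow.
Noise placement is the only randomness, drawn in a fixed order, so a fixed
seed reproduces the cohort bitwise. The default noise rate of 0.01 models
a small spurious-streamline background.

What is *not* emulated: parcel geometry (adjacency is a ring within each
gyrus plus planted cross-gyrus edges — contiguity queries need topology,
not coordinates), diffusion signal, streamline counts and lengths,
registration error, and inter-subject anatomical variability (all subjects
share the parcel-to-gyrus assignment). Passing tests therefore demonstrate
the correctness of the representation, reasoning and recovery machinery —
not robustness to real tractography artifacts.

The mini anatomy fixture is likewise synthetic: it follows the source
ontology's naming conventions (gyri, lobes, hemispheres, tracts,
metaclass templates, a whole-body hub for exclusion tests) but copies no
content; real anatomy ontologies are orders of magnitude larger, which is
why published class counts over the full ontology are replaced here by
fixture-manifest equality checks.

## Overlap statistics

`overlap_fractions()` computes, at full precision, the percentage of the
term union present in at least k subjects, displaying values rounded half
up to one decimal. Term comparison is exact string equality on trimmed
strings. The shipped five-subject transcription keeps truncated variants
(e.g. a term printed once without its final noun) distinct; this verbatim
policy is the one whose k = 5, 4, 3 fractions (23.73, 38.98, 69.49)
reproduce all three published percentages within 0.1 point — note 38.98
matches the published 38.9 by truncation, not rounding, so comparisons use
a ±0.1-point band rather than a fixed rounding convention.

## Problem sizes and runtime

Full-scale runs (five subjects, 22 × 11 × 1004 matrices, saturation and
all four queries) complete in well under a minute. The test suite uses the
full shapes where the claim is about shape, and reduced cohorts (60–120
parcels, 1–2 subjects) where the claim is about logic, keeping the whole
suite under a minute; property-style tests draw 100 random frame graphs
and 200+ random knowledge bases under fixed seeds.

## Known limitations

* No SPARQL endpoint or full Manchester syntax (no negation,
  cardinalities, `value`).
* The reasoner's incompleteness boundary above; cross-validation against a
  tableau reasoner is possible through the Turtle export but is not part
  of the shipped checks.
* Turtle support is a subset: labeled blank nodes and explicit list
  triples, two fixed domain namespaces.
* Tractography itself (streamline filtering, distance correction,
  exclusion masks, registrations) is upstream of the input contract.
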