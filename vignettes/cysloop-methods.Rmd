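---
title: "Methods: variant interpretation in Cys-loop receptors"
author: "cysloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant interpretation in Cys-loop receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cysloop)
```

# The problem

Cys-loop receptors are pentameric ligand-gated ion channels whose five
subunits each contribute four transmembrane helices (M1–M4), with the five
M2 helices lining the ion pore. The family shares a single structural
topology, so a residue in one subunit has an equivalent position in every
paralog, and pore-facing M2 positions carry a family-wide prime index:
the −2′ ring is the narrowest intracellular constriction (desensitization
gate) of the anion-selective members, and the 9′ leucine ring is the
activation gate. When a new missense variant appears in one receptor gene,
three coordinated analyses place it in context: coordinate mapping (helix,
depth, prime index), a search for previously reported pathogenic variants
at the equivalent position in other family members, and the geometric
effect on the pore. This vignette describes how `cysloop` implements each
step, which choices were open, and what the tests do and do not establish.

# Cross-paralog residue mapping

Equivalence between paralogs is computed by optimal pairwise alignment to
a single reference subunit (GABA-A α2), not by a multiple sequence
alignment. Every published equivalence we reproduce is a single
source-to-reference relation, and pairwise alignments make each relation
independent of which other sequences happen to be in the set; the cost is
that transitivity across three or more paralogs is not guaranteed, which
the package never relies on.

Alignments use BLOSUM62 with affine gap penalties, open 10 and extend 0.5
per residue (a gap run of length $L$ costs $10 + 0.5L$). These are the
long-standing defaults of the EMBOSS tools for protein alignment; within
the strongly conserved transmembrane region the mapping is insensitive to
moderate changes of these parameters. The dynamic programming is
delegated to `Biostrings::pairwiseAlignment`, which returns one
deterministic optimal alignment; its scores are validated in the test
suite against exhaustive enumeration of all alignments (lengths ≤ 5) and
against an independent plain-R three-state Gotoh implementation (lengths
≤ 8, 20-letter alphabet).

A source position whose alignment column is a gap in the target is
reported *unaligned* together with the nearest mapped flanking positions
— never silently replaced by a nearest guess. All indices are 1-based,
matching UniProt and HGVS conventions.

# Topology and prime numbering

Helix spans are configuration data, not computation: the packaged YAML
registry snapshots SwissProt-style TRANSMEM annotations (GABRA2: M1
252–273, M2 278–299, M3 312–333, M4 424–445, flank 5). Annotation
releases drift by one or two residues at helix termini; pinning the spans
in a versioned config makes every downstream number reproducible. For the
same reason, prime numbering is defined by anchor arithmetic from the
conserved 9′ leucine (`prime(p) = p − 291 + 9` for GABRA2) rather than by
counting from the annotated M2 start, so it is immune to boundary drift.
The numbering is only defined within M2 ± flank; outside, the package
raises an error rather than extrapolating.

Orientation alternates out–in–out–in (N-terminal side of M1/M3
extracellular, of M2/M4 cytoplasmic), which fixes the sign of the
center-relative coordinate: negative offsets always point toward the
extracellular space. The center of an even-length helix is
`floor((start + end) / 2)` — a deterministic choice; the alternative
(rounding up) shifts every histogram by at most one position and is never
mixed in. When the flank windows of adjacent helices overlap, a position
is assigned to the nearer helix, an exact tie going to the N-terminal
helix; ties are rare (they require an inter-helix gap of exactly twice
the flank) and no packaged topology produces one.

# Variant tables, merging and equivalence reports

Variant input is protein-level: HGVS p. strings in three-letter code
(with or without the `p.` prefix) or explicit (protein, position,
reference, alternate) tuples. Genomic-to-protein lifting is out of scope
by design — the analysis operates entirely in protein coordinates. The
only coding-level arithmetic retained is `codon_index(c) = ceiling(c/3)`.

The two supported dialects are minimal column subsets of ClinVar and
Humsavar exports (documented in the README) rather than full XML/VCF
parsing; a column-rename is all that is needed to adapt a real export.
Only missense records are kept. Significance labels normalize onto a
closed vocabulary; the pathogenic class is {pathogenic,
likely_pathogenic, disease}. Merging treats "same amino-acid change at
the same position in the same protein" as the duplicate key; duplicates
across sources count once (provenance `both`), and a key that is
pathogenic-class in one source but benign/uncertain-class in the other is
a conflicting interpretation and is dropped entirely — from both sources.
"Conflicting" had to be operationalized; we chose the strictest reading
(any cross-source disagreement about the pathogenic class removes the
key), which can only deflate enrichment counts, never inflate them.

The equivalence report lists, for each query variant, pathogenic variants
of other receptors whose mapped reference position lies within ±1. The
±1 window reflects how flanking positions are reported in the published
cross-receptor comparisons this reproduces. Each other-receptor variant
is reported once, under its nearest query — an exact match beats an
adjacent one, a remaining tie goes to the lower query position. Without
this rule a variant exactly at one query and adjacent to a neighboring
query (the 9′/10′ pair, one residue apart, is the concrete case) would be
double-counted. Replaying the packaged 23-row published table through
this rule reproduces its grouping exactly: 6 of the 7 GABRA2 study
variants have equivalents, in groups of 6/2/3/5/2/5.

# Per-helix enrichment statistics

`count_by_helix` assigns each merged disease variant to at most one helix
(core only, or core + flank behind a flag) and `chisquare_uniform` tests
the M1–M4 counts against equal expected frequencies with df = 3 — the
default null of the standard goodness-of-fit routine. Equal expectation,
not length-proportional, is the primary null because the four helices
have near-identical lengths in these receptors and the published analysis
used the plain test; a length-proportional expectation is available via
`expected = "length"`. P-values come from the exact χ² survival function
(`pchisq(..., lower.tail = FALSE)`), never Monte Carlo; the suite checks
agreement with the closed form
$S(x) = \mathrm{erfc}(\sqrt{x/2}) + \sqrt{2x/\pi}\,e^{-x/2}$ to 1e-10.

For the two published count vectors the statistics recompute as
χ²(27, 39, 16, 4) = 31.30 and χ²(39, 47, 31, 5) = 32.62, with survival
p-values 7.3e-7 and 3.9e-7 respectively. The source publication prints
the p-values 3.8e-7 (helix-only) and 7.3e-7 (with flanks) — the opposite
pairing of what recomputation from its own printed counts yields under
equal expectation. The package reports the computed values and takes no
position on the printed pairing; both are far beyond any conventional
threshold and the scientific conclusion (M2 is over-populated) is
unaffected.

Calibration is tested empirically: on 2,000 simulated uniform tables of
n = 86 the rejection rate at α = 0.05 must fall in 0.05 ± 0.02, and with
a 3× M2 enrichment at n = 200 the test must reject at α = 10⁻³ in ≥ 95%
of 200 simulations.

# Pore geometry

The pore axis is the dominant principal direction through the centroid of
the transmembrane Cα atoms, oriented extracellular → cytoplasmic (via a
reference point, or a deterministic sign rule when none is given). This
assumes an elongated, roughly symmetric bundle — true of intact
pentamers; a degenerate (rank < 3) point cloud is an error.

At each step (default 3 Å, matching the published profiles) the profile
records the radius of the largest sphere centered in the step plane that
avoids van der Waals overlap with any atom:
$r(s) = \max_c \min_a (\lVert c - a\rVert - \mathrm{vdW}_a)$. Radii are
Bondi (C 1.70, N 1.55, O 1.52, S 1.80 Å); hydrogens are ignored, the
standard resolution-appropriate convention for cryo-EM structures. The
in-plane center is refined from the axis point by greedy hill-climbing
(0.5 Å moves within a 1.5 Å neighborhood, then Nelder–Mead polish at
reltol 1e-10), with total displacement capped at 8 Å. A *local* search is
essential, not a convenience: the maximal-sphere objective grows without
bound outside the channel wall, so a global search would tunnel through
inter-subunit gaps and report the exterior. The local search follows the
connected pore the way established channel-profiling tools do. A pure
fixed-axis measurement is available with `refine = FALSE`. Negative
clearances clamp to zero and flag the step blocked; steps with no atoms
within 15 Å are undefined. Each radius is classified against the Pauling
radius of Cl⁻ (1.81 Å) and the hydrated Cl⁻ radius (3.2 Å), with
boundary values assigned to the wider class.

Two conventions are implemented for inter-residue distances (Cα–Cα and
minimum heavy-atom) because published gate distances rarely state their
convention; with no experimental pentamer structure distributable in this
package, which convention reproduces specific published distances remains
undetermined and both are exposed. Superposition RMSD uses the Kabsch SVD
construction constrained to proper rotations, validated against the Horn
quaternion closed form to 1e-9; collinear inputs are an error because the
rotation is not unique.

Mutant structures are consumed as external coordinate files; building
them (side-chain repacking, stability estimation) is out of scope.

# What the synthetic data emulates — and what it does not

`gen_toy_pentamer` builds exactly C5-symmetric rings of atoms, so the
on-axis clearance is closed-form: at ring $i$,
$\min_j \sqrt{r_j^2 + (z_i - z_j)^2} - \mathrm{vdW}_j$, reducing to
$r_i - \mathrm{vdW}_i$ for well-separated rings. This gives the profiler
an analytic oracle and, with rigid rotation/translation applied, an
invariance test. It deliberately sacrifices realism: no backbone, five
atoms per ring, perfect symmetry. Passing these tests shows the geometry
engine is correct, not that it reproduces any particular experimental
structure; agreement with other profiling tools on real pores is expected
at the 0.1–0.2 Å level, not bit-exact, because center-refinement
strategies differ in detail.

`gen_family` evolves descendants from a random ancestor with recorded
substitutions and single-residue indels (indels avoid the three terminal
columns to keep end-gap placement stable); the recorded
descendant-to-ancestor map is the ground truth for the mapper, so no test
infers truth from an alignment. Uniform random ancestors are *harder*
for alignment than real proteins (no conserved blocks), making the ≥ 99%
mapping-accuracy requirement at 5% substitution / 2% indel conservative;
but the generator does not model rate heterogeneity or domain structure,
so these tests do not certify mapping accuracy on highly divergent real
paralog pairs. The packaged equivalence fixture carries published
positions as data for exactly that reason.

`gen_variant_table` draws variant positions multinomially over placement
categories (helix cores, flanks, outside) with the truth recorded,
emulating the structure of the enrichment input; it does not emulate
mutational hotspots within a helix.

All generators are deterministic under a seed (byte-identical output,
global RNG state restored).

# Problem sizes and numerical tolerances

The default test suite uses: alignment oracles at lengths ≤ 5
(enumeration) and ≤ 8 (independent DP); families of 150–300 residues and
3–6 descendants; 2,000 + 200 + 500 multinomial simulations for the χ²
calibration, power and enrichment-recovery checks; toy channels of 3–9
rings. These sizes make every property statistically meaningful while the
whole suite completes in well under a minute. Numerical tolerances:
pore radii within 0.05 Å absolute of the closed form; χ² p-values within
1e-10 of the analytic survival function; Kabsch RMSD within 1e-9 of the
quaternion oracle; alignment scores exactly equal to the oracles.

# Known limitations

* Real canonical sequences and experimental structures are not packaged;
  analyses against them require the user to supply files (a `uniprot_fetch`
  helper exists for convenience). The packaged topology spans may differ
  by 1–2 residues from any particular annotation release.
* Pairwise mapping to one reference does not guarantee transitive
  consistency across paralogs.
* The pore profiler assumes a single, connected, roughly axial pore; it
  does not handle side tunnels or branched vestibules.
* Contact detection uses fixed distance thresholds (vdW sum + 0.5 Å;
  N/O pairs ≤ 3.5 Å) without angular terms, so reported hydrogen bonds
  are distance-plausible pairs, not geometry-validated bonds.
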