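---
title: "Methods and design notes for ringscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for ringscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringscape)
```

`ringscape` analyses C4C4 RING-finger domains at three levels — sequence,
structure, and transgenic-rescue genetics. This vignette records the models
behind each level, the tunable parameters and why their defaults are what
they are, the numerical conventions, and the limits of what the synthetic
benchmarks demonstrate.

## The zinc-ligand assignment model

A RING finger coordinates two Zn²⁺ ions through eight ligand residues. We
model a candidate domain as a `spacing_model`: one allowed residue set per
ligand slot (all-cysteine for the C4C4 family; `mode = "c3hc4"` admits
histidine at slot 4, and `allow_aspartate = TRUE` admits aspartate
everywhere, since aspartate side chains are occasional zinc donors), plus
seven inter-ligand gap ranges counting residues *strictly between*
consecutive ligands. The default ranges,

```{r}
spacing_model()$gap_ranges
```

are the classic RING consensus spacing
(`C-x2-C-x(9-39)-C-x(1-3)-C-x(2-3)-C-x2-C-x(4-48)-C-x2-C`) with the fourth
gap widened from 3 to 4 so that C4C4 domains of the SPE-42 family, whose
fourth gap is 4 residues, validate. All ranges are config-overridable.

`scan_ring_ligands` performs a depth-first constraint search over candidate
positions. It is *complete* — the test suite checks it against exhaustive
enumeration of all 8-subsets of candidates — and deterministic, ordering
results by first-ligand position and then lexicographically. Every returned
assignment carries the canonical cross-brace zinc partition (ligands 1,2,5,6
to Zn-1 and 3,4,7,8 to Zn-2). The partition is an assumption, not an
inference: nothing in a sequence scan can distinguish cross-brace from
sequential pairing, and the cross-brace arrangement is simply what RING
structures show.

**Ambiguity on the SPE-42 C-terminus.** With nine cysteines at positions
678, 681, 684, 700, 703, 708, 711, 718 and 721, the consensus spacing
admits *two* assignments: the experimentally supported one (681–721,
excluding C678, gaps 2-15-2-4-2-6-2) and a second in which C678 and C681
occupy slots 1–2 and gap 2 absorbs C684 (gaps 2-18-2-4-2-6-2; 18 sits
comfortably inside the 9–39 consensus range). Spacing constraints alone
therefore cannot single out the biological assignment; in the original
analysis the exclusion of C678 came from structural alignment to solved
RING domains. We deliberately keep the scanner complete rather than
narrowing gap 2 ad hoc to suppress the second solution: a range like 9–17
would have no basis in the RING consensus and would silently discard valid
motifs elsewhere. `assign_unique` stays strict (it errors with the candidate
count on ambiguity), and downstream code selects among assignments
explicitly.

## Alignment and divergence statistics

`pairwise_global_align` wraps Needleman–Wunsch global alignment with affine
gaps (a gap of length $L$ costs $10 + 0.5L$) and BLOSUM62 scores.
Divergence statistics are column-wise: identity is identical columns divided
by *all* alignment columns, gap columns included in the denominator;
similarity additionally counts residue pairs with a positive substitution
score. The gap-inclusive denominator is a decision — the alternative
(aligned-pairs-only) inflates identity for gappy alignments of unequal-length
sequences; both conventions coincide on gapless alignments, which is the
regime of the close ortholog comparisons the statistics are meant for.
`cterminal_divergence` recomputes both statistics over the columns touched
by the last `tail_a`/`tail_b` residues of either sequence, the window used
to contrast a divergent C-terminal exon with the rest of a protein.

These parameter choices (matrix, penalties, denominators) are stated rather
than inherited: published percent-identity figures rarely name their method,
so exact reproduction of a printed figure depends on the original tool's
conventions. The machinery is pinned instead on constructed pairs with
known column identity and on an exhaustive-path oracle at small length
(all monotone alignment paths of length-5 strings; the path count grows
as the Delannoy numbers, so exhaustive checking at length 8 would already
enumerate ~265k paths for no additional coverage).

## Structure-level analysis

**Containers and I/O.** Structures are flat atom tables (chain, residue,
atom name, coordinates in Å) with metals held separately; PDB reading and
writing go through `bio3d`. Alternate locations resolve per atom name by
highest occupancy, then file order; insertion codes are rejected rather than
silently renumbered; zinc HETATMs populate the metal table and other
heteroatoms are dropped.

**Superposition.** `kabsch_superpose` computes the least-squares optimal
rigid transform by SVD of the cross-covariance of centred coordinates, with
the determinant correction that excludes reflections. Inputs with fewer
than three points or with collinear geometry (second singular value below
$10^{-8}$ of the first) are rejected as degenerate — a rotation about the
line would be arbitrary. Optimality is tested against a multi-start BFGS
minimisation over axis-angle rotations (agreement to $10^{-6}$ Å on random
clouds) and against sampled random rigid motions.

**Template ranking.** The three ranking criteria are those used when
selecting RING templates for homology modelling: overall percent identity,
the longest contiguous block of identical-or-similar aligned columns, and
inter-ligand spacing compatibility, defined as
$1 - \sum_i |g^q_i - g^t_i| / \sum_i (g^q_i + g^t_i)$, floored at 0.
Because the criteria come without published weights, the combined score is
an equal-weight mean after min-max scaling across the template set
(weights are an argument); ties break by template id, and the ranking is
invariant to input order.

**Threading.** `thread_model` is deliberately *not* homology modelling: each
query residue aligned to a template residue inherits that residue's CA
coordinate, gap-aligned query residues are flagged unmodeled, and template
metals are copied through. Restraint-based all-atom modelling is out of
scope; every downstream analysis (interface, exposure, zinc geometry)
consumes CA/pseudo-atom geometry and operates identically on threaded or
user-supplied models.

**Interface calling.** A residue is at the interface iff the minimum
distance from any of its heavy atoms to any partner heavy atom is ≤ the
cutoff (default 5.0 Å, boundary inclusive). Any-heavy-atom distance is the
decision — interface figures of RING–E2 complexes show side chains, not
backbones. The implementation is vectorised but must (and is tested to)
equal the brute-force all-pairs scan exactly.

**Exposure proxy.** Solvent accessibility is approximated by neighbor
counting: `1 - min(n, cap)/cap` with `n` the CA atoms within 10 Å and
`cap = 20`. This is a monotone burial proxy good for ranking
(polar-exposed vs apolar-buried sanity checks), not an accessibility area.

**Zinc-site geometry.** `zinc_geometry_check` reports each assigned
ligand's sulfur-to-zinc distance (falling back to CA when no sulfur atom is
present) and flags distances outside 1.8–3.0 Å, bracketing the canonical
~2.3 Å Zn–S bond. Partition halves are matched to the two zincs by total
distance.

## Rescue quantification

Brood data arrive as per-worm counts or as printed line summaries
(mean ± SEM, n). Conventions:

- `line_summary` uses the sample SD (n−1) over √n; for n = 1 the SEM is
  reported as 0 with an explicit flag rather than NA.
- Printed `"<1"` cells are ingested as 0.5 (the midpoint of the censoring
  interval (0, 1)) with a `censored_lt1` flag. The choice only matters for
  genotypes that are null-like anyway.
- The genotype grand mean defaults to the *unweighted* mean of line means:
  each independently derived extrachromosomal array is one biological
  replicate, and weighting by worm count would let a single well-sampled
  array dominate. On the shipped fixture the two modes give 46.4%
  (unweighted) vs 44.0% (n-weighted) for C681A; the unweighted figure
  matches the ~46% quoted from these data, while a printed 45% plausibly
  reflects different rounding or the unprinted per-worm counts — both modes
  are therefore provided.
- `classify_rescue` thresholds — below 0.10 null-like, 0.10–0.80 partial,
  above 0.80 full, boundaries inclusive upward — are configuration values
  mapping onto qualitative descriptions ("severely reduced", intermediate,
  "same level as wild type"), not measured quantities.
- `compensation_test` returns *compensatory* when single A is full, the
  double is null-like, and single B is partial (or at least better than the
  double); *independent* when the double matches the product of the singles
  within a relative tolerance (default 25%, absolute floor 0.02, the
  multiplicative null for residues acting independently); otherwise
  *inconclusive*.
- `recombinant_filter` drops lines whose non-transgenic homozygote siblings
  produce any progeny — in a background that is fully sterile without the
  transgene, fertile controls indicate recombination.
- `bootstrap_ci` is a percentile bootstrap resampling *line means* within
  each group. It is descriptive. With the assay-scale 3 lines per genotype
  a percentile bootstrap cannot attain nominal coverage (resampling 3
  units); the coverage property is therefore verified at 30 lines per
  group, where the asymptotics apply, and intervals on 3-line data should
  be read as variability summaries, not calibrated 95% statements. No
  hypothesis tests are attached to genotype contrasts: the underlying assay
  reports descriptive summaries only.

## Synthetic data: what it emulates and what it does not

`simulation_config` fixes all generator parameters; every generator is a
pure function of the config (fixed seed ⇒ byte-identical output) and emits
its ground truth.

- **Sequences**: an 8-cysteine motif with the SPE-42 gap vector
  (2, 15, 2, 4, 2, 6, 2) planted at position 681 of a 60-residue,
  cysteine-free random background (offset 670, mirroring the published
  residue numbering). A cysteine-free background makes planted-motif
  recovery a closed loop; real flanking sequence can of course contain
  extra cysteines, which is exactly the C678 situation above.
- **Structures**: two idealized tetrahedral zinc sites 20 Å apart, Zn–S
  2.3 Å, CA shell 4.5 Å, partner-chain pseudo-atom adjacent to site 1 so
  the planted interface is the four site-1 ligands; Gaussian jitter
  (default σ = 0.05 Å) applied last, with generation refusing any
  configuration whose pre-jitter contact distances fall within
  cutoff ± 2σ (the ground truth would be ambiguous). These are geometric
  toys: no fold, no secondary structure, no steric realism — sufficient for
  the distance-based operations implemented, and nothing else.
- **Broods**: per-worm counts are negative binomial (default size 5) around
  wild-type mean 110 × genotype fraction × a log-normal line effect
  (σ_log = 0.2), 3 lines per genotype × 10 worms per line — the scale and
  spread of the published tables (wild-type transgene lines 92–123;
  line-to-line ranges like 0–6 for null-like genotypes motivate the
  overdispersion). `nb_size = Inf` gives the Poisson limit; optional zero
  inflation mimics fully penetrant sterile worms. Not emulated: daily
  brood-count time courses, temperature effects, germline silencing of
  arrays — fractions are planted directly, so recovery tests validate the
  estimator, not the biology.

## Problem sizes and determinism in the test suite

All stochastic tests run under fixed seeds. The property suite checks:
superposition against the optimizer oracle on 100 random 10-point clouds;
the interface caller against brute force on 50-residue chain pairs;
scanner completeness against exhaustive enumeration on random sequences up
to 80 residues with up to 12 cysteines; rescue-fraction recovery for
planted fractions {0, 0.05, 0.5, 1} over 200 replicate datasets each
(estimates within 3 Monte-Carlo SEs — note the ratio-of-means estimator
carries an O(CV²) positive bias, ~2% of the fraction at assay scale, well
inside that band); and bootstrap coverage over 500 replicates at 30 lines
per group against a 0.95 ± 0.04 band covering small-sample undercoverage
plus Monte-Carlo error.

## Known limitations

- The scanner assigns ligands from spacing and composition only; where
  several assignments satisfy the consensus (as on SPE-42 itself),
  disambiguation needs structural evidence that sequence-level scanning
  cannot supply.
- Threading preserves template geometry exactly; it cannot model insertions
  (left unmodeled) or any conformational change, and interface calls on
  threaded models inherit the template's backbone.
- The exposure score is a burial ranking, not solvent-accessible area.
- Printed-summary ingestion cannot recover per-worm distributions; bootstrap
  intervals from 3-line groups are descriptive only.
- Alignment-derived percent identities depend on the stated scoring
  conventions; other tools' printed figures may differ by a point or two
  purely from denominator and parameter choices.
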