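---
title: "Scoring giant virus signatures: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring giant virus signatures: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvscan)
```

# The model

`gvscan` decides whether assembled sequence is derived from a
nucleo-cytoplasmic large DNA virus (NCLDV) by combining, for every
predicted ORF, evidence for and against NCLDV origin:

* a **reward** from the ORF's best match against a library of giant virus
  orthologous groups (GVOGs) — protein families built from NCLDV genomes;
* a **penalty** from its best match against Pfam domains, which stand in
  for generically cellular content.

Raw profile-HMM bit scores cannot be used directly, because many GVOGs are
shared with *Caudovirales* bacteriophages (above all jumbo phages, the
dominant source of false positives) and many Pfam domains are perfectly
normal NCLDV content. Both components are therefore normalized by the
family's occurrence in two reference surveys: the fraction of NCLDV
genomes, $P_\mathrm{NCLDV}$, and the fraction of *Caudovirales* genomes,
$P_\mathrm{Caudo}$, that carry at least one hit to the family (presence,
not hit counts). With $B$ the bit score clamped below at zero:

$$S_\mathrm{gvog} = B \cdot
  \frac{P_\mathrm{NCLDV}}{P_\mathrm{NCLDV} + P_\mathrm{Caudo}}, \qquad
S_\mathrm{pfam} = B (1 - P_\mathrm{NCLDV}) +
  \frac{P_\mathrm{Caudo}}{\max(P_\mathrm{NCLDV}, 0.01)},$$

$$S_\mathrm{final} = \sqrt{S_\mathrm{gvog}} - \sqrt{S_\mathrm{pfam}}.$$

The reward keeps the full bit score for NCLDV-exclusive families, halves
it for families equally common in phages, and vanishes for families absent
from both surveys. The penalty vanishes for NCLDV-universal domains,
passes the raw score through for domains rare in both surveys (only
domains present in at least 1% of either survey are normalized — the
inclusive `>= 0.01` threshold), and grows with phage occurrence. The
square root in the combination keeps the domain-level Pfam scores, which
are systematically smaller than full-protein GVOG scores, on a comparable
scale, and stops a single outlier match from dominating a contig.

Contigs are summarized by the **mean** of raw per-ORF scores and called
NCLDV when that mean strictly exceeds the cutoff (default 0); a rolling
average localizes the signal within long sequences, and maximal runs of
ORFs with positive windowed scores are reported as putative endogenous
viral regions, annotated with hits to the ten conserved NCLDV marker
families (`GV_MARKERS`).

## The GVOG reward variant

The additive form $S_\mathrm{gvog} = B\,(P_\mathrm{NCLDV} +
P_\mathrm{Caudo}/P_\mathrm{NCLDV})$ is retained behind
`score_params(eq1_variant = "literal")`. It is *increasing* in
$P_\mathrm{Caudo}$: a GVOG found in every phage surveyed would score
higher than an NCLDV-exclusive one, which contradicts the scoring model's
purpose — phage-shared families must not produce high scores. The default
`"ratio"` variant has the intended monotonicity (non-increasing in
$P_\mathrm{Caudo}$, non-decreasing in $P_\mathrm{NCLDV}$, bounded by $B$),
which the test suite enforces by grid sweep. Users can switch variants to
compare; all downstream machinery is variant-agnostic.

The penalty is implemented exactly as written above. Its second term is
unitless while the first carries bits; an alternative reading would
multiply both by $B$. We keep the literal form: it already satisfies the
required monotonicities, and at the default e-value threshold the additive
term (at most $P_\mathrm{Caudo}/0.01 = 100$) only matters for domains that
are genuinely phage-typical, where a strong penalty is the desired
behavior.

# Tunable parameters

| Parameter | Default | Where | Meaning |
|---|---|---|---|
| `evalue_max` | 1e-5 | `score_params()`, `best_hit_per_orf()` | hit acceptance threshold; 1e-5 is the value used for the occurrence surveys, adopted as the default since no other threshold is attested |
| `pncldv_floor` | 0.01 | `score_params()` | denominator floor for $P_\mathrm{NCLDV}$; reuses the 1% eligibility threshold rather than introducing a second constant |
| `eq1_variant` | `"ratio"` | `score_params()` | GVOG reward algebra (above) |
| `window` | 15 ORFs | `region_params()` | rolling-average window; even values are widened to the next odd so the window can be centered |
| `cutoff` | 0 | `region_params()` | classification and region threshold; strictly-greater, so a hit-free contig (mean exactly 0) is non-NCLDV |
| `min_region_orfs` | 4 | `region_params()` | minimum region size, suppressing one-ORF noise |
| `require_gvog_hit` | TRUE | `region_params()` | regions must contain at least one ORF whose best GVOG hit exists |

Exactly one GVOG hit and one Pfam hit — the best-scoring per database,
ties broken by lexicographically smallest profile id — feed each ORF's
score: per-protein scoring implies a single $B$ per database.

# Numerical and procedural choices

* **Negative bit scores** are clamped to zero before use so the square
  roots are always defined; hits passing the default e-value threshold
  have positive scores in practice, making the clamp the least surprising
  total extension.
* **Rolling window**: centered with half-width $\lfloor w/2 \rfloor$ and
  truncated at contig edges (the mean is over the neighbors that exist),
  so the track has one value per ORF. A trailing window would shift region
  boundaries by half a window systematically; centered smoothing keeps
  boundary error symmetric.
* **Contig mean** is taken over raw scores, not the rolling track — the
  two differ at contig edges where the truncated windows re-weight
  interior ORFs.
* **Degenerate inputs**: empty score vectors roll to empty tracks; a
  sequence shorter than the minimum fragment length shreds to nothing
  (with a notice); surveys missing a genome class, empty member lists and
  empty clusters are errors naming the problem.
* **Strictness conventions**: classification uses mean > cutoff;
  dereplication links genomes at distance strictly below 0.05; duplicated
  markers fail quality control only strictly below 90% identity; majority
  annotation requires strictly more than half of *all* members (absentees
  count in the denominator).
* **Reported percentages** (sensitivity, specificity) round half away
  from zero to one decimal; the false-positive rate is defined as
  $100 - \mathrm{specificity}$ so the pair always sums to exactly 100.
* **Pseudocontig shredding** draws fragment lengths i.i.d. uniformly on
  `[min_len, max_len]` (defaults 5–100 kbp), tiling the parent from its
  start and discarding a sub-minimum tail; only non-overlap and the length
  range are load-bearing for the benchmark, so no attempt is made to mimic
  any particular external shredder's length distribution.

# What the fixture generator emulates — and what it does not

`fixture_spec()` / `make_profile_db()` / `make_genome()` /
`make_endogenized_genome()` fabricate everything the pipeline consumes:
profile metadata with a matching genome-by-profile occurrence survey,
contigs with non-overlapping strand-alternating ORF layouts,
gene-caller-style protein FASTA, and profile-search tables in the standard
per-domain tabular format. Crucially, they plant search *results* (bit
scores), not sequences that genuinely match profiles — running a real
profile search is an optional integration path, never a test dependency.

The occurrence survey uses 20 NCLDV + 20 *Caudovirales* genomes so every
planted proportion is an exact multiple of 1/20 and the metadata equals
the proportions recomputed from the survey, bit for bit. Profiles fall
into strata: GVOGs that are NCLDV-specific (including the ten markers),
shared with phages (with $P_\mathrm{NCLDV} \le P_\mathrm{Caudo}$), or
rare; Pfam domains that are NCLDV-common, phage-common, or absent from
both surveys (hence normalization-ineligible, i.e. cellular).

The planted bit-score bands make every scored ORF's *sign* certain rather
than merely likely: NCLDV ORFs hit specific GVOGs at 80–200 bits with at
most a weak NCLDV-common Pfam hit (net $\ge +3.4$); phage ORFs carrying a
shared-GVOG hit always also carry a phage-common Pfam hit on the same ORF,
so every phage ORF is net negative yet less negative than cellular ORFs
(echoing how jumbo phages produce the highest non-NCLDV scores); cellular
ORFs receive only raw-bit-score penalties. ORFs without hits score exactly
0, and the NCLDV call needs a strictly positive mean, so the separation
survives shredding into pseudocontigs. Consequently the synthetic
benchmark's 100% specificity and sensitivity, and the deterministic
recovery of planted endogenous regions to within half a window of truth,
are *pipeline-correctness* checks: a miss indicates a bug, not an unlucky
draw. By the same token, passing them says nothing about accuracy on real
data, where bit-score distributions overlap, occurrence estimates are
noisy, gene callers err, and composition varies — none of which the
fixtures model (no realistic nucleotide composition, codon usage, or
HMM-matchable sequences).

Problem sizes used by the test suite and the acceptance script — fixture
genomes of 50–150 ORFs, 200-ORF hosts with 20–60-ORF inserts, 20 region
replicates, 10 benchmark seeds, 5–25 kbp pseudocontigs — were chosen as
the smallest sizes at which every window, shredding and smoothing effect
is still exercised (several windows per contig, several fragments per
genome).

# Benchmarking and curation utilities

`specificity()` / `sensitivity()` reproduce confusion-metric arithmetic at
the score cutoff; `shred()` + `assign_orfs_to_fragments()` build the
fragmented-assembly benchmark; `compute_n50()`,
`single_linkage_clusters()` (union-find connected components under a
strict distance threshold), `select_representative()` (highest N50,
lexicographic ties) and `dereplicate_genomes()` support genome-set
dereplication; `quality_filter()` applies the four genome-inclusion
criteria (all four single-copy markers present; no duplicated marker below
90% identity; fewer than 30 contigs; not externally flagged low quality)
and enumerates failures. Pairwise distances and marker-copy identities are
*inputs* — computing k-mer sketch distances or protein alignments is out
of scope.

# Known limitations

* The occurrence-normalization constants live in the profile metadata; the
  package ships no real GVOG/Pfam metadata, so analyses of real data
  require a user-supplied metadata TSV plus search tables (or the optional
  `prodigal`/`hmmsearch` adapters with real profile flatfiles).
* Short contigs with few ORFs may simply lack profile matches; a hit-free
  contig scores exactly 0 and is conservatively called non-NCLDV.
* Virophages and other NCLDV-adjacent elements that exchange genes with
  giant viruses can score positive; the marker report exists precisely to
  support manual inspection in such cases.
* Region boundaries inherit half-window uncertainty from smoothing; callers
  needing exact breakpoints should inspect the raw per-ORF track.
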