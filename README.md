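# gvscan

Detection of giant virus (NCLDV) signatures in assembled sequence data.

Nucleo-cytoplasmic large DNA viruses (NCLDVs, phylum *Nucleocytoviricota*)
carry the largest and most gene-rich viral genomes known. They turn up
abundantly in metagenomes and as endogenous viral elements inside eukaryotic
genomes, but recognizing their sequences is hard: NCLDV families are highly
diverged from one another, and their genomes are full of genes otherwise
typical of cellular life. `gvscan` is for researchers who need to (a) decide
whether a contig or metagenome-assembled genome (MAG) is NCLDV-derived,
(b) strip non-NCLDV contamination (jumbo bacteriophage, bacteria) out of
putative giant-virus MAGs, or (c) locate NCLDV-derived regions inside
eukaryotic assemblies.

## The score

Every predicted ORF is searched against two profile-HMM libraries: giant
virus orthologous groups (GVOGs), which reward NCLDV-like content, and Pfam
domains, which penalize generically cellular content. Raw bit scores *B*
are normalized by each family's occurrence among NCLDV genomes
(*P*<sub>NCLDV</sub>) versus *Caudovirales* genomes (*P*<sub>Caudo</sub>),
the main source of false positives:

- GVOG reward:
  *S*<sub>gvog</sub> = *B* · *P*<sub>NCLDV</sub> / (*P*<sub>NCLDV</sub> + *P*<sub>Caudo</sub>)
  — a family as common in phages as in NCLDVs keeps only half its score
  (an alternative additive variant is available via `eq1_variant`; see the
  methods vignette for the algebra and the reasons behind the default).
- Pfam penalty:
  *S*<sub>pfam</sub> = *B* · (1 − *P*<sub>NCLDV</sub>) + *P*<sub>Caudo</sub> / max(*P*<sub>NCLDV</sub>, 0.01)
  for domains present in ≥ 1% of either survey; rarer (typically cellular)
  domains are penalized at their raw bit score.
- Per-ORF score:
  *S*<sub>final</sub> = √*S*<sub>gvog</sub> − √*S*<sub>pfam</sub>,
  the square root keeping domain-level Pfam scores commensurate with
  full-protein GVOG scores.

Scores are reported as contig means (a contig is called NCLDV when its mean
is strictly positive) and as a centered rolling average over a window of 15
ORFs, whose maximal positive runs are reported as putative endogenous viral
regions. Hits to ten conserved NCLDV marker families (PolB, A32, VLTF3,
SFII, MCP, RNAPL, RNAPS, mRNAc, RNR, D5) are tabulated to support manual
verification. Benchmarking utilities (pseudocontig shredding, sensitivity
and specificity at the cutoff, N50-based dereplication, genome quality
filters) and a synthetic-fixture generator round out the package; the
entire pipeline runs from parsed search tables, so no external binaries are
required.

## Worked example

The fixture generator fabricates a profile database (with its occurrence
survey) and a genome with planted search results, so the example is fully
self-contained:

```r
library(gvscan)

spec <- fixture_spec(seed = 42)
made <- make_profile_db(spec)               # metadata + occurrence survey
gen  <- make_genome("NCLDV", n_orfs = 60, spec, made$db)

best   <- best_hit_per_orf(gen$hits, evalue_max = 1e-5)
scores <- score_all_orfs(gen$orfs, best, made$db)
contig_summary(scores, made$db)
```

```
   contig_id length_bp n_orfs mean_score  call n_regions
1 ncldv_ctg1     62833     60   8.717804 NCLDV         1
                                                               markers
1 PolB:2,A32:1,VLTF3:3,SFII:1,MCP:2,RNAPL:2,RNAPS:1,mRNAc:2,RNR:1,D5:2
```

The contig's mean per-ORF score is 8.7, well above the cutoff of 0, so it
is called NCLDV; the whole contig forms one positive-scoring region, and
all ten marker families are hit at least once. The first rows of the
per-ORF table show the components: `ncldv_ctg1_1` matches `GVOG0003` at a
normalized reward of 188.4 bits with no Pfam penalty, giving
*S*<sub>final</sub> = √188.4 ≈ 13.7.

File-based runs work the same way through `run_detect()`, which reads the
gene-caller protein FASTA and the two search tables and writes per-ORF
scores, contig summaries, regions (TSV and BED), a marker report and a run
log. A thin command-line wrapper with `detect`, `benchmark` and `fixtures`
subcommands is installed at `inst/scripts/gvscan.R`.

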