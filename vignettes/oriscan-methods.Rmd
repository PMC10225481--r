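---
title: "How oriscan predicts bacterial replication origins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How oriscan predicts bacterial replication origins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriscan)
```

## The problem

Bacterial chromosome replication initiates at a defined locus, *oriC*,
which is almost always an intergenic sequence (IGS) carrying a
recognisable architecture: a cluster of DnaA-protein binding sites
(DnaA boxes, canonically the 9-mer `TTATCCACA` in *E. coli*), a
DnaA-trio repeat that stabilises DnaA filaments on single-stranded DNA,
an AT-rich DNA unwinding element (DUE) where the duplex first melts,
and regulatory sites such as Dam-methylated `GATC` clusters or, in some
alphaproteobacteria, CtrA boxes (`TTAA`-N7-`TTAA`). The locus also
tends to sit where the genome-wide strand asymmetry switches sign and
next to the *dnaA* gene. `oriscan` turns each of these observations
into a quantitative score per IGS and reports the best-scoring IGS as
the predicted origin.

## The scoring model

For every IGS $i$ of a replicon of length $L$, three components are
computed, each bounded in $[0, 1]$:

* **Base composition.** The cumulative GC disparity is computed by the
  Z-curve method: a walk that rises by 1 at `G` and falls by 1 at `C`
  (together with AT, RY = AT + GC and MK = AT − GC walks). Its global
  minimum $m$ is the expected neighbourhood of the origin, so
  $s_\mathrm{dist} = \max(0,\; 1 - d_i / (L/2))$, where $d_i$ is the
  topology-aware distance from the IGS midpoint to $m$.

* **Indicator genes.** $s_\mathrm{gene}$ is 1 when a principal
  indicator gene (*dnaA* by default) is an immediate flank of the IGS,
  0.75 when a secondary indicator (*dnaN*, *repA*, *rctB*) flanks it,
  0.5 when any indicator gene midpoint lies within 5 kb, and 0
  otherwise. For secondary chromosomes (`chromosome_type =
  "secondary"`), the secondary list is promoted to principal, since
  initiators such as RctB replace DnaA there.

* **DnaA boxes.** Boxes are scanned on both strands with up to
  $k$ mismatches ($k = 1$ by default) and scored
  $s_\mathrm{box} = \min\!\Big(\tfrac{1}{3}\sum_h \tfrac{k + 1 - m_h}{k + 1},\; 1\Big)$,
  where $m_h$ is the mismatch count of hit $h$. A perfect box is worth
  one third; the component saturates at three box-equivalents, which
  encodes "a DnaA box cluster" without rewarding arbitrarily many weak
  matches.

The total is the weighted sum (default weights 1, 1, 1, hence total in
$[0, 3]$). Exact ties are screened by functional elements, in order:
more DnaA-trio arrays, more GATC sites, higher AT fraction, then the
smaller start coordinate for determinism. Candidates tying with the
best total (within a configurable margin, default exact ties) are all
reported, since chromosomes with multiple origins exist; candidates
with total 0 are never reported.

The additive form and its constants are this package's normative
definition of the scoring criterion; all worked values in the tests
derive from these formulas.

## Functional-element annotation

Independently of scoring, each candidate is annotated with: DnaA-trio
arrays (maximal tandem runs of ≥ 3 `GAT` units on either strand, linked
to the nearest same-strand box ending within 50 bp upstream — the basal
unwinding system); DnaA boxes at up to 4 mismatches when adjacent to a
trio (labelled, never scored); exact ATP-DnaA boxes (`AGATCT`) and Dam
`GATC` sites (palindromes counted once per position); CtrA sites with a
1-mismatch budget over the two `TTAA` half-sites (the N7 spacer is
free); any user-supplied motifs (e.g. Fis or IHF sites — none are
shipped because no consensus is bundled); and the AT-richest window
(default 30 bp) as a DUE proxy. The AT-richness profile is a windowed
mean, a deliberately simple surrogate for stress-induced
duplex-destabilisation calculations; it marks AT-rich islands, not
actual melting energetics.

## Terminus, draft genomes, strand bias

The terminus of a complete genome is the midpoint of the best *dif*
site (fewest mismatches, then nearest to the GC-disparity maximum) when
a *dif* motif is configured and found, otherwise the position of the
GC-disparity maximum. Multi-contig drafts have no defined terminus and
are rejected.

Draft genomes are handled per contig: each contig is treated as a
linear fragment and scored against its *own* GC-disparity minimum and
its own length (a pooled minimum is meaningless when contig order is
unknown); candidates from all contigs are then ranked together.
Contigs without annotation are first annotated with a six-frame ORF
fallback (ATG/GTG/TTG to the next in-frame stop, ≥ 300 nt, longest ORF
per stop codon). This fallback is a crude delimiter of intergenic
space, not a gene finder of record; with annotated input it is never
used.

For strand-bias analysis the chromosome is partitioned at oriC and
terminus into two replichores; a gene is *leading* when transcribed
co-directionally with its fork (plus strand on the oriC→ter arc, minus
strand on the other), genes straddling a boundary are classified by
midpoint, and the leading-strand base composition concatenates the
forward bases of one arc with the reverse complement of the other. The
reported "strand lengths" are the replichore arc lengths — the quantity
that can deviate from 50/50 — and the output says so explicitly.

## Defaults and why

| parameter | default | rationale |
|---|---|---|
| minimum IGS length | 80 bp | admits compact origins (a few hundred bp is typical) while suppressing micro-gaps between adjacent genes |
| DnaA box / scoring mismatches | `TTATCCACA` / 1 | the broadly conserved box; 1 mismatch tolerates species drift without flooding the scan |
| box-cluster saturation | 3 box-equivalents | typical oriC clusters hold several boxes; more adds no evidence |
| indicator radius | 5 kb | "adjacent to dnaA" on the scale of a few genes |
| trio unit / minimum units / box gap | `GAT` / 3 / 50 bp | the *B. subtilis* DnaA-trio description; unit and counts are configurable because the element varies |
| DUE window | 30 bp | the scale of unwinding elements |
| ORF fallback minimum | 300 nt | short enough to delimit IGSs, long enough to avoid spurious micro-ORFs |
| dif mismatches | 2 | *dif* sites are long (28 bp) and diverge mildly |

Ties at curve extrema are broken by the smallest index; curves are
never smoothed for prediction (smoothing is available for display
only); circular genomes are analysed on the given linearization with
circular distances, with no rotation search — rotating the curve is a
display transform that does not move the extrema.

## The simulator, and what passing tests mean

`simulate_genome()` generates the benchmark conditions used throughout
the tests: a circular chromosome (200 kb by default) whose two
replichores carry opposite composition skews (leading-strand G−C
probability excess 0.04 and T−A excess 0.02, applied as ±skew/2 shifts
around a uniform 25% background), placeholder genes of 900 bp tiled
with 150 bp gaps, and a planted origin IGS at coordinate 0 carrying
three exact DnaA boxes, a 4-unit GAT trio within box-linkage range, a
30 bp island of 90% AT, and an immediately flanking *dnaA* gene; the
terminus sits at L/2, optionally marked with the *E. coli* *dif* site.
Genomes are fully seed-deterministic and the background is resampled in
the rare event that it creates a spurious exact box inside the planted
IGS, so the truth interval carries exactly the configured architecture.

The simulator emulates the *signals* the predictor uses, not real
genomes: genes are random sequence without codon structure, skew is
homogeneous within each replichore, there are no rearrangements,
repeats, horizontally transferred islands, multiple replicons, or
weak/atypical origins. Passing the recovery benchmarks therefore shows
that the pipeline correctly integrates the evidence it models under
clean conditions; it does not certify accuracy on genomes whose origin
lacks these signals (e.g. skew-less Cyanobacteria, or species whose
origin is far from *dnaA*), where users should supply lineage-specific
motifs and inspect the full candidate table.

Problem sizes used by the shipped checks, chosen to exercise the study
conditions at desk scale: 1000 random sequences for the curve
identities, 200 random cases for scanner-oracle equivalence, 100
simulated 200-kb chromosomes for origin/terminus recovery, and the same
100 chromosomes split into 3 contigs for draft-mode consistency.

## Degenerate and edge inputs

Sequences are restricted to `{A,C,G,T,N}`; other IUPAC codes in input
are demoted to `N` with a warning, and `N` contributes nothing to the
disparity curves, matches any pattern `N`, and mismatches every
concrete pattern symbol. A record without features becomes a single
whole-sequence IGS; an all-coding record yields an empty prediction
with a warning rather than an error. Features wrapping the coordinate
origin of a circular record are split at read time; the IGS spanning
the origin is reported as one wrap-around interval. GenBank `join()`
locations are split into their segments; features whose coordinates
exceed the sequence are dropped with a warning.

## Known limitations

* The scoring constants (tier values 1/0.75/0.5, saturation at 3
  boxes, equal weights) are normative choices of this package, not
  fitted quantities; alternative weightings are exposed as parameters.
* No merging of adjacent high-scoring IGSs is attempted, so bipartite
  origins (as discussed for *H. pylori*) appear as two candidates.
* The terminus falls back on a single global GC-disparity maximum;
  heavily rearranged chromosomes with fluctuating curves can place it
  poorly when no *dif* motif is supplied.
* Homology-based confirmation against origin databases and de novo
  repeat discovery are outside the package's scope.
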