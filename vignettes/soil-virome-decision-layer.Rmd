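---
title: "The soil-virome decision layer: rules, statistics, and how they are tested"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The soil-virome decision layer: rules, statistics, and how they are tested}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilvirome)
```

# What this package computes

Soil-virome studies assemble metagenomic contigs, call a subset of them
viral, classify their replication lifestyle, attach them to bacterial
hosts, mine their cargo genes, and relate the resulting community structure
to soil chemistry. Each of those steps is a *decision layer*: a set of
numeric thresholds and test procedures applied to the outputs of external
detectors and annotators. This package implements that layer as plain,
testable functions, and pairs it with a synthetic-community generator that
plants every decision's ground truth, so that the whole chain can be
validated without any sequencing data.

The package deliberately does *not* run the upstream tools (viral
detection, quality estimation, HMM searches, CRISPR array detection, tRNA
prediction, homology search engines). Their outputs are consumed as flat
tables; the decisions made on those tables are what is implemented and
tested here.

# The triage rules

A candidate contig with feature vector (detector score $s$, completeness
$c$, contamination $k$, gene counts $n$, $n_\mathrm{VPF}$,
$n_\mathrm{KEGG}$, $n_\mathrm{Pfam}$, length $\ell$) is retained when all
of the following hold:

* **Primary screen.** $s \ge 0.5$, and the contig is not removed by the
  quality rules: removal requires $c < 50\%$ or $k > 10\%$. The removal
  inequalities are strict as printed, so the boundary values ($c = 50$,
  $k = 10$) survive.
* **Criterion 1.** $n_\mathrm{VPF} \ge 5$, $n_\mathrm{KEGG}/n < 0.20$, and
  $n_\mathrm{Pfam}/n \le 0.40$.
* **Criterion 2.** $n_\mathrm{VPF} \ge n_\mathrm{Pfam}$ and
  $n_\mathrm{VPF}/n \ge 0.60$.
* **Length.** $\ell > 5\,000$ bp, strictly: a 5,000 bp contig drops.

Counts are genes, one vote per gene, regardless of how many domain hits a
gene accumulates. Contigs with $n = 0$ fail the criteria with reason
`"no genes"` rather than raising an error, because fragmentary contigs
must not abort a pipeline run.

Criteria 1 and 2 are combined **conjunctively** by default: protocols of
this kind list them as numbered items of a single strategy whose
conditions must all hold, rather than as alternative admission routes. An
`admission = "any"` switch exposes the alternative reading in
`run_triage()`.

Retained contigs are then clustered greedily at 95% identity, sorted by
length descending (ties broken lexicographically by id for determinism);
each contig joins the first cluster whose representative it matches, else
founds a new cluster, and the longest member (the founder) is the
representative. The length cut is applied *before* clustering, because the
protocol sentence binds the two operations together.

**Identity definition.** Clustering protocols name a tool, not a formula.
Here identity is defined as matches divided by alignment columns when the
shorter sequence is aligned end-to-end onto the best-matching window of
the longer one (global–local dynamic programming, match +1, mismatch −1,
gap open 4, gap extend 1), with the threshold compared inclusively
($\ge 0.95$). Two shortcuts never change a decision but keep the greedy
loop fast: a 12-mer containment prefilter skips pairs that share almost no
k-mers (at 95% identity the expected exact 12-mer survival is
$0.95^{12} \approx 0.54$, while unrelated sequences share essentially
none), and a gap-free end-to-end placement that already reaches the
threshold is accepted without running the dynamic program, since the
program can only add matches.

# Lifestyle classification

A retained contig is **lysogenic** when it carries at least one
marker-protein annotation from the lexicon {integrase, transposase,
invertase, recombinase, excisionase}, or when an external lifestyle
predictor labels it lysogenic; everything else is a **potential lytic**
virus. The external predictor is merged as a union because it is a
supplementary detector: it can add lysogeny calls, never remove them.
`merge = "markers-only"` and `"external-only"` are available. The calls
partition the community — every contig is exactly one of the two classes —
and evidence is monotone: adding annotations can only move a contig from
lytic to lysogenic.

Per-sample lifestyle proportions are abundance-weighted (each contig
contributes its RPKM share) by default, since published treatment-level
proportions are relative abundances; a count-weighted mode (each present
contig weighs equally) is provided, and it is the mode under which a
planted lysogenic fraction is recovered *exactly* on equal-abundance
communities. Whether published figures used abundance or count weighting
is usually not stated; both modes are first-class here.

# Virus–host linking

Three independent evidence channels produce links, which are then merged
into unique (virus, host) pairs with their supporting channel sets.

**CRISPR spacers.** Each spacer is scanned against every viral contig on
both strands for ungapped windows of spacer length. The printed rule —
identity $\ge 95\%$ *and* at most two mismatches — is internally tense:
two mismatches in a spacer shorter than 40 nt already violate 95%
identity. The default applies both constraints conjunctively, an
effective budget of $\min(2, \lfloor 0.05 L \rfloor)$ mismatches for a
spacer of length $L$; `rule = "union"` applies either alone. Matching is
substitutions-only (Hamming), since the protocol counts "single nucleotide
polymorphisms"; alignment-score e-values are not reproduced for these
short queries because at 20–50 nt the identity/mismatch rule is the
binding constraint. The scanner is exact: a pigeonhole seed-and-verify
(a window with $\le d$ mismatches must contain one of $d+1$ pattern
chunks exactly; candidate positions come from exhaustive, overlap-safe
substring search and only those windows are verified), and the test suite
holds it equal to a literal all-windows Hamming oracle.

**tRNAs.** Full-length ungapped windows on either strand at identity
$\ge 95\%$; a 75-nt tRNA therefore tolerates 3 mismatches (96.0%) but not
4 (94.7%).

**Genomic homology.** Tabular hits (the standard 12-column tabular
homology format) are filtered on five inclusive thresholds: identity
$\ge 70\%$, query coverage $\ge 75\%$, e-value $\le 10^{-3}$, bit score
$\ge 50$, alignment length $\ge 2{,}500$ bp. Query coverage is derived
from hit coordinates and the viral contig length. The package does not
embed an alignment engine for this channel: the decision under test is
the filter, and the generator plants real homologous blocks whose
statistics are known exactly at planting time, which removes the need for
a toy aligner in the tests.

Merging is idempotent and deduplicates by pair; host range per virus is
**specialist** (one host taxon at the chosen rank, or one host contig when
no taxonomy is supplied) versus **generalist**.

# AMG retention

An auxiliary metabolic gene candidate is retained when its auxiliary
score is in {1, 2, 3} *and* its flag set contains M or F *and* contains
none of {V, A, P, T, B}. The source protocol states the score range and
the M/F requirement but not the exclusions; the disqualifying set follows
the cited annotator's documented convention, and both sets are arguments
of `filter_amgs()` so the rule is always explicit. Retained genes are
categorized by KEGG level-2 label and by CAZyme class parsed from the
leading letters of the family label (GH/GT/PL/CE/AA/CBM); genes with
neither label count as unclassified.

Abundances are Z-scored per gene across treatments with the sample
standard deviation ($n-1$); constant rows map to zero by convention, and
normalized non-constant rows have mean 0 and SD 1 to $10^{-12}$.

# Community and microcosm statistics

* **RPKM**: $\mathrm{rpkm}_{is} = c_{is} / (\ell_i/10^3) / (N_s/10^6)$,
  which obeys the conservation identity
  $\sum_i \mathrm{rpkm}_{is}\,\ell_i/10^3 = 10^6 \sum_i c_{is}/N_s$
  (checked numerically on random tables).
* **Shannon diversity** with natural logarithm over nonzero proportions
  (the alpha-diversity metric is usually unnamed in protocols; Shannon is
  the standard default of the ecology toolkit, and richness is emitted
  alongside). All-zero samples yield missing values, with distances to
  them set to 1 by convention.
* **Bray–Curtis** $d(u,v) = 1 - 2\sum_i \min(u_i,v_i) / \sum_i (u_i+v_i)$.
* **ANOSIM**: $R = (\bar r_B - \bar r_W)/(M/2)$ with ranks over all
  pairwise distances, $M = n(n-1)/2$; being rank-based it is invariant
  under strictly monotone distance transforms, and $R \in [-1, 1]$.
* **Mantel**: Spearman correlation of the two distance triangles, p by
  permuting one matrix's sample order.
* Both permutation tests use the add-one estimator
  $p = (1 + \#\{T^* \ge T\})/(1 + n_\mathrm{perm})$, so $p$ is never 0 and
  never below $1/(n_\mathrm{perm}+1)$; permutation streams are seeded
  explicitly, so results are reproducible.
* **Correlation networks**: all pairwise Spearman correlations, p-values
  from the $t$ approximation on $\rho$ (the convention of the standard
  correlation-matrix tools), Benjamini–Hochberg adjusted across the full
  pairwise family of one network (the family is not specified more finely
  in the protocols); an edge needs $|r| > 0.7$ *and* adjusted $p < 0.01$,
  both strict as printed, so $|r| = 0.7$ exactly is excluded.
* **Cumulative CO₂** is the prefix sum of interval trap amounts — alkali
  traps integrate respiration over the interval, so no trapezoidal
  interpolation is applied — and
  $q\mathrm{CO}_2 = \mathrm{CO_2\text{-}C_{cum}} / (\mathrm{MBC} \times
  \mathrm{days})$ in mg CO₂-C mg⁻¹ MBC d⁻¹.
* **Group comparisons**: one-way ANOVA with Duncan's multiple range test.
  Duncan's critical values come from the studentized-range distribution at
  the stepwise protection levels $1-(1-\alpha)^{p-1}$ for a span of $p$
  ordered means, with the harmonic mean of group sizes; a range contained
  in a non-significant wider range is never declared significant, and
  groups sharing a letter are not separated. Tukey's HSD is available as
  the conservative alternative. Pairwise contrasts use Welch's t-test by
  default (whether published pairwise tests pooled variances is typically
  unstated; pooled is available via `var_equal = TRUE`).

# The synthetic-data generator

`generate_community()` plants every decision's ground truth:

* Feature profiles spanning **every decision boundary** (score 0.49/0.50,
  completeness 49.9/50, KEGG 19.9/20%, Pfam 40/40.1%, VPF 4/5, VPF
  fraction 59/60%, length 5,000/5,001 bp), plus randomized passing and
  failing profiles to reach a planted pass fraction (0.4 by default).
* A planted lysogenic fraction, 0.21 by default — the low end of temperate
  prevalence in arable-soil viromes — realized exactly
  (`round(frac * n)` contigs carry markers).
* Protospacers extracted from the target contig and mutated at exactly
  0–3 interior positions (never the first or last, which keeps the match
  length unambiguous under any alignment convention), planted on a random
  strand with probability ½ to force both-strand search correctness.
  tRNA plants likewise, spanning the 95% identity boundary at 75 nt.
* Real homologous blocks copied from host to virus contigs with an exact
  planted mismatch count, together with the tabular hit rows describing
  them; the plan spans all five filter thresholds. Because query coverage
  is relative to the virus contig, the homology targets are dedicated
  short (~3–3.3 kb) contigs so that block lengths stay near the nominal
  3 kb maximum while the coverage plan crosses the 75% boundary.
* Near-duplicate contig pairs at ~98% identity (truncated mutated copies)
  to exercise clustering; spacer/tRNA/homology plants avoid duplicated
  contigs so that planted link truth stays exact.
* An AMG candidate grid cycling scores 1–5 against flag sets
  {M}, {F}, {M,V}, {}, {V}.
* Per-sample relative abundances with a log-normal backbone and
  treatment-specific log-scale shifts on a responsive subset
  (`group_effect = 0` gives exchangeable null communities for
  permutation-test calibration); read counts are multinomial draws, so
  column sums equal the requested depth exactly.
* A microcosm incubation (alkali-trap intervals on days 1, 3, 5, 7, 14,
  21, 28, 35; 24 microcosms: virus-addition × four straw/N treatments ×
  three replicates) with virus addition planted to raise MBC — and hence
  lower qCO₂ — in the straw-removal treatments, and to raise DOC, SUVA₂₅₄
  and the BG/NAG enzyme activities throughout. Magnitudes (basal
  respiration ~0.012 mg CO₂-C g⁻¹ d⁻¹, MBC ~0.25 mg g⁻¹, DOC
  ~0.15 mg g⁻¹) are ordinary arable-topsoil values.

All randomness derives from one integer seed through fixed sub-stream
labels, so identical configurations are byte-identical and adding one
planted table never shifts another's draws.

**What the generator does not emulate** — and therefore what passing tests
do and do not show: sequences are uniform random nucleotides, without the
composition, repeat structure, or shared gene content of real genomes, so
the tests certify the *decision rules*, not detector performance on real
data; annotation counts are planted, not produced by profile searches, so
nothing is claimed about HMM score distributions; amplification bias and
assembly artifacts are out of scope. Accidental extra protospacer matches
in random sequence are astronomically unlikely at the planted lengths
(probability on the order of $10^{-12}$ per window), which is what makes
exact-recall assertions meaningful.

# Problem sizes and numerical choices

The test suite and the acceptance script run communities of 100–200
contigs, 12 samples at depths of 10⁴–10⁵ reads (10⁶ for the
binomial-convergence check), and calibrate the permutation tests on 500
null datasets with 199 permutations each at α = 0.05 — sizes chosen so
the full suite completes in a few minutes on a single core while keeping
the binomial 95% interval around the nominal error rate informative
([0.032, 0.071] at 500 replicates). Production analyses should use 999
permutations (the default). Closed-form quantities are asserted to 10⁻⁹
relative tolerance; Z-score and truth round-trip identities to 10⁻¹²;
threshold comparisons use an epsilon of 10⁻⁹ inside
`floor((1 - identity) * L)` so that exact decimal boundaries (e.g.
0.05 × 40) are not lost to floating-point representation.

# Known limitations

* The clustering identity convention approximates a named tool's behavior,
  not its implementation; on real data the cluster boundaries can differ
  near the threshold.
* The homology channel trusts its input table; it does not re-align.
* Duncan's test is implemented from the studentized-range definition with
  stepwise protection levels; software packages differ in their handling
  of unbalanced designs (the harmonic mean is used here).
* The external lifestyle predictor is consumed as a table; its internal
  model is out of scope.
* Microcosm chemistry values are consumed, not derived from measurement
  models; necromass components have no published closed form and are not
  computed.

```{r example, eval = FALSE}
cfg <- synth_config(seed = 1)
res <- run_pipeline(cfg, nperm = 999)
length(res$retained_ids)        # retained representatives
mean(res$lifestyle$call == "lysogenic")
res$anosim$statistic            # ANOSIM R over treatments
head(res$microcosm_summary)
```
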