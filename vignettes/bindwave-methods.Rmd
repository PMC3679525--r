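---
title: "Models and methods behind bindwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bindwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

bindwave reconstructs a master transcription factor's temporal regulatory
program from timecourse ChIP-seq and mRNA-seq, modelled on the ethylene
response of dark-grown Arabidopsis seedlings, where EIN3 binding rises to
a maximum around 4 hr of hormone treatment while transcription unfolds in
successive waves. This vignette explains each model, the tunable
parameters and their defaults, the numerical choices made where the
design was genuinely open, and what the synthetic-data generator does and
does not emulate.

## Consensus binding regions

Peak calls arrive per caller, biological replicate and timepoint. Within
a replicate-timepoint, each caller's calls are first merged with the gap
rule — two intervals merge when the gap between them is strictly less
than `max_gap` (default 200 bp) — then genomic stretches covered by more
than one caller (any overlap of at least 1 bp) are retained and merged
again. With two callers this means both must call; with *k* callers, at
least two. The per-condition consensus sets are pooled across all
replicates and timepoints and unified with the same merge rule, so a
region supported in any single condition enters the final set, with the
number of supporting conditions recorded.

Three choices here were open and are worth stating. First, the order of
operations (merge per caller, vote, merge again) matters in edge cases;
we merge per caller first because callers fragment peaks differently.
Second, the vote retains the *covered intersection* rather than whole
peaks; at matched calls the two coincide, and the intersection is the
conservative choice under caller jitter. Third, the overlap needed to
count two callers as agreeing is 1 bp, exposed as `min_callers` plus the
merge gap rather than a fraction-of-overlap rule.

Binding signal is quantified as RPKM (reads per kb of region per million
library reads) from per-region read counts. Replicates are rescaled
multiplicatively so each replicate's median equals the grand median of
replicate medians — the reference had to be fixed somewhere, and the
grand median keeps the overall scale of the data. A replicate whose
median is zero has no defined scale and is an error. Temporal profiles
are log2 ratios of replicate-averaged RPKM against the 0 hr value, with
a pseudocount (default 0.5 RPKM) so silent regions stay finite. The
`ddct_fold_change()` helper implements the qPCR delta-delta-Ct fold
change used for validation tables, normalising to a reference amplicon
such as Actin.

## Target assignment

A region is associated with a gene when the region center lies within
5 kb of it. Distance runs to the nearest bp of the gene body (zero
inside the gene) rather than to the TSS, because a region inside a gene
should count as distance zero; `distance_to = "tss"` restores the
alternative. With several candidates the nearest *expressed* gene (max
RPKM > 1 anywhere in the timecourse) wins; if none is expressed, the
nearest gene wins. The rule as stated contemplates two candidates; we
generalise "both unexpressed" to "all unexpressed". Ties break to the
lower gene coordinate and then the gene identifier, making assignment
independent of annotation row order. Promoters are the 1000 bp
immediately upstream of the TSS, strand-aware and clipped at chromosome
bounds.

## Expression calling and classification

A gene is expressed if any replicate at any timepoint exceeds 1 RPKM
(strictly). Differential expression is tested between consecutive
timepoints with a two-sample t test on replicates plus a 50% change
filter on the un-logged means. The t test runs on log2(RPKM + 0.5) —
the scale on which multiplicative replicate noise is closest to Gaussian
and on which the test holds its nominal level; the percent filter stays
on the raw means so the 50% rule keeps its plain meaning. The
pooled-variance Student form is the default with Welch as an option,
and no multiple-testing correction is applied by default, reproducing a
per-test p = 0.05 workflow faithfully; `adjust = "BH"` enables step-up
control. When the prior mean is zero the percent change is undefined and
a call requires only a positive current mean and a passing test.

Candidate targets are then partitioned: regulated (EIN3-R, at least one
DE call), expressed but never called (EIN3-NR), never expressed
(EIN3-ND), everything else nontarget. Binding-versus-expression coupling
is summarised by an ordinary least-squares fit of the per-gene
expression log2 change at 4 hr on the assigned region's binding log2
change; on heterogeneous response programs the R² stays far below 0.5.
`rank_timecourses()` orders binding profiles by a moderated score — the
sum of squared replicate-mean log2 changes scaled by the region's
replicate variance shrunk halfway toward the global mean variance. This
stands in for published replicated-timecourse ranking statistics whose
exact moderation parameters are not restated here; it shares their
behaviour (flat profiles near zero, coherent change first) and is
deterministic.

## The split-tree wave model

Transcriptional waves are mined with a transparent variant of dynamic
regulatory-events mining. Genes are first filtered to those changing at
least twofold at some timepoint (max |log2fc| ≥ 1). Starting from one
root state, at every subsequent timepoint each group of genes is tested
for divergence by fitting univariate Gaussian mixtures with 1 to 3
components (up to 3-way splits) to the group's values at that
timepoint; the BIC-best model is accepted and genes are hard-assigned by
maximum posterior. Full DREM is an input-output HMM with logistic split
classifiers; we deliberately implement this lighter model because every
element the analysis depends on — 3-way splits, the twofold filter, the
10⁻¹⁰/15% annotation rule, time-varying target sets — is preserved,
while the fit stays auditable.

Numerical choices: EM is run through mclust's univariate
unequal-variance model, started from both a kmeans partition (10 random
starts) and an equal-count partition of the sorted values, keeping the
best likelihood per component count — the default model-based
hierarchical initialisation proved prone to poor local optima on
well-separated trimodal nodes. Fitting on sorted values makes the result
depend only on the value multiset, so gene order cannot change the tree.
Groups smaller than 9 genes (3 × max components) never split; candidate
solutions containing a component of fewer than 5 genes are treated as
degenerate outlier captures and skipped in BIC order. BIC uses 3G − 1
parameters per G-component model. The root timepoint is constant zero by
construction (log2 versus itself), and any node with essentially zero
variance is left unsplit.

Paths (root-to-leaf gene sets) are annotated per TF by the exact
hypergeometric upper tail of the overlap between path genes and the TF's
targets within the analysed universe; a path is a TF-modulated wave when
p < 10⁻¹⁰ and more than 15% of its genes are targets. The ">15%" is
read as a fraction of the path's genes. For time-varying binding, a
region counts as bound at a timepoint when its RPKM strictly exceeds the
mean of its two input-control values (0 and 4 hr), a gene is bound when
any assigned region is, and a path is scored against the targets bound
at the timepoint where the path last diverged from a sibling (root-only
paths use the first timepoint) — the natural reading of annotating the
divergence event itself. Wave onset is reported as the first timepoint
at which the wave's mean trajectory reaches twofold, which also covers
waves that become distinct by *not* moving when their siblings do. Wave
noise is the pooled standard deviation of member trajectories around the
wave mean; temporal distinctness is tested pairwise by Mann-Whitney on
members' first-DE timepoints at p < 0.001.

## PBM motifs

Protein-binding microarray intensities are summarised per 8-mer as an
E-score: the area under the ROC curve of probes containing the 8-mer (in
either orientation) against all remaining probes, minus 0.5. This is a
rank statistic in [−0.5, 0.5], symmetric under reverse complement and
invariant under monotone transforms of intensity — the defining
properties of the published E-score, whose exact split-half form is not
restated here; the plain AUC is the simplest statistic with those
properties. 8-mers absent from every probe are reported missing, never
zero.

`pwm_align()` builds a PFM from all 8-mers with E-score strictly above
0.45: the top scorer seeds an ungapped alignment and each further 8-mer
joins at the offset and orientation maximising matches to the running
consensus (gapless 8-mers make a gapped multiple alignment unnecessary).
Column counts are E-score-weighted by default (uniform by flag), and
columns covered by fewer than half the aligned 8-mers are trimmed —
exactly half is kept (the at-least-half reading). Cross-array
evaluation predicts each probe of the *opposite* design as the maximum
log-odds window score over both strands and reports the Pearson
correlation with measured intensities; `select_best_pfm()` picks the
candidate with the highest cross-design r, breaking ties toward wider
matrices.

Scanning uses the log-odds form
score(b, i) = log2((f_i(b) + pc·bg(b)) / ((1 + pc)·bg(b))) with
pseudocount 0.01 and a user threshold in bits, defaulting to 60% of the
maximum achievable score — a practical stand-in for exact score p-value
machinery. Promoter over-representation counts a gene as carrying a
motif when its promoter has at least one hit, and scores regulated
versus universe gene sets with the exact hypergeometric tail, flagged
below 10⁻⁵. For enrichment in binding regions the background is a
length- and chromosome-preserving shuffle of the regions.

## Co-regulation network

PPI (undirected) and PDI (directed TF→gene) edge lists merge into one
deduplicated network; an edge present in several sources keeps all
source labels. Gene and protein identifiers are assumed to share one
locus-id namespace; no alias resolution is attempted. Hormone labels
come from an eight-hormone vocabulary (ABA, BR, CK, ETH, GA, IAA, MJ,
SA); the ">1" multi-hormone label is derived at export time, never
stored, to avoid double counting. `hormone_fraction()` reports the
percentage of a gene set carrying any hormone label against supplied
genome totals (e.g. 5729 of 27,416, which prints as 21%) with an exact
hypergeometric enrichment p. Genome totals are inputs because they
depend on the annotation release.

## The synthetic study

The generator exists so every stage is testable without sequencing data;
its defaults are the study conditions, not tuning knobs. Timepoints are
0, 0.25, 0.5, 1, 4, 12 and 24 hr with three replicates. 2000 genes are
placed on two 10 Mb chromosomes, non-overlapping and at least 6 kb
apart, so each planted binding region (placed within 800 bp of its
target's TSS) has an unambiguous gene within the 5 kb window. Four
induction waves (onsets 0.25, 1, 4 and 12 hr; amplitudes 3.5, 3, 2.5
and 2 log2; replicate sds 0.8, 0.6, 0.45 and 0.3, strictly decreasing
to emulate the observed reduction of transcriptional noise across
successive waves) each contain 120 genes of which half are TF targets.
Two repressed groups (800 genes, onsets 0.5 and 4 hr, amplitudes −2.5
and −2) populate the non-TF paths of the tree and carry the minority of
down-regulated targets, so that ~85% of regulated targets are induced.
Of 2000 genes, 20% are expressed but flat and 10% sit below 1 RPKM
throughout (flat low expression censored at 0.95). The 400 target genes
split into 282 regulated, with the rest divided 70/30 between
non-responsive and not-detected genes. Wave amplitudes are step
functions — zero before onset, the amplitude after — with log2-normal
replicate noise.

Binding occupancy follows a smooth log-logistic rise peaking at 4 hr
with a mild decline after (any shape with that argmax would satisfy the
design; this one is parameter-light), scaled to a 6-fold maximum over a
per-region baseline. Two emulated callers perturb the true intervals
with Gaussian coordinate jitter (30 and 50 bp), drop calls at 5–8% and
add a proportional number of spurious intervals; peaks are only emitted
where occupancy is detectably above baseline, so 0 hr has no calls.
Read counts are derived from RPKM with a replicate-level ChIP-efficiency
factor (log2 sd 0.15) that median normalization removes. Reads are not
simulated at base resolution — per-region counts suffice for the RPKM
arithmetic, and alignment is out of scope.

PBM probes tile de Bruijn order-8 cycles (a different alphabet rotation
per design, labelled ME and HK) into 36-mers overlapping by 7 bp, so
every 8-mer occurs at least once per design; real universal-array
layouts are proprietary and are not reproduced. Probe intensity is the
planted PFM's best window score plus Gaussian noise (sd 0.25). The
planted motif is an 8 bp EIN3/TEIL-like consensus (ATGTATCT at 0.85 per
column, ~1.15 bits per column).

What the generator does *not* emulate: sequencing-error models, mapping
artefacts, copy-number or GC biases, correlated replicate structure,
isoform-level expression, enhancer-promoter looping, or realistic array
spatial effects. Passing tests therefore demonstrate that the
implementations are faithful to their rules and recover planted
structure under controlled noise — not that the pipeline is robust to
every artefact of real sequencing data.

## Problem sizes and determinism

The shipped tests and the acceptance script run the default study (2000
genes, 400 regions, 7 × 3 conditions), a 10,000-gene null calibration
for the DE test, 1000 random instances against the interval-merging
oracle, exhaustive hypergeometric checks for universes up to 30, and the
full two-design PBM (2 × 2260 probes, all 32,896 reverse-complement
8-mer classes). These sizes give stable statistics while keeping a full
run in minutes on one core. Every stochastic step draws from a seed
carried in the configuration (each generator consumes a distinct offset,
so stages are independently reproducible), and the split-tree fit is
deterministic given its seed and invariant to gene order.

## Known limitations

The split tree hard-assigns genes, so genes near a split boundary
contribute to exactly one wave; DREM's soft assignments would share
them. The vote's covered-intersection semantics can shorten regions
relative to union-style merging under heavy caller jitter. The E-score
here is a plain AUC rather than the published split-half median rank;
values are comparable but not numerically identical on real arrays. The
moderated timecourse ranking is a simplification with the same ordering
behaviour as published moderated statistics, not a reimplementation.
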