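---
title: "Methods: 3D genome analysis across the EMT spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D genome analysis across the EMT spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicemt)
```

# Scope and model

`hicemt` implements an integrative analysis of three-dimensional genome
organization along the epithelial-mesenchymal transition (EMT) spectrum:
contact-matrix normalization, A/B compartment calling and switch
classification, insulation-based TAD calling with a boundary-change taxonomy,
integration of EMT gene signatures with histone signal, aggregate contact
analysis, and single-cell Hi-C structure comparison. Every stage is driven
and validated by a synthetic-data generator that plants the structures the
analysis is designed to recover, so each claim the package makes about its
own correctness is a recovery statement against a known truth, not a
comparison with an external data set.

## Contact matrices, balancing and O/E

Binned contacts are stored as upper-triangle sparse triplets over a
`binned_genome` (0-based half-open coordinates; bin index =
`floor(position / resolution)`, as in BED and cooler). `ice_balance()`
removes multiplicative per-bin biases by Imakaev-style iterative correction:
bins with marginal below `coverage_floor` (default 0.1) times the median
marginal are masked, then marginals are iteratively equalized until their
coefficient of variation drops below `tol` (default 1e-5, `max_iter` 200).
The returned `bias` uses the cooler weight convention
(`balanced = raw * bias_i * bias_j`), so `1/bias` estimates the bias planted
in the raw counts. Iterative correction was chosen over sequencing-depth
normalization because every downstream stage consumes observed/expected
(O/E) values, which absorb the difference.

`observed_over_expected()` divides each intra-chromosomal pixel by the mean
of its diagonal (zeros included over unmasked positions), which makes every
unmasked diagonal average exactly 1 — a contract asserted in the tests to
1e-6. Inter-chromosomal pixels share a single genome-wide expectation; they
feed no downstream statistic here, so no distance model is fitted for them.

## Compartments

Per chromosome, `correlation_matrix()` correlates O/E rows (the diagonal
entries of the two rows being compared are excluded, as self-contact pixels
would otherwise dominate), and `compute_pc1()` takes the leading eigenvector
of that correlation matrix. The eigenvector sign is arbitrary, so it is
oriented against an activity track — smoothed gene density
(`gene_density_track()`) or the coverage of an active chromatin mark. On
the synthetic panel the end-to-end runs orient with each sample's H3K4me1
(enhancer-mark) track: on a 40-Mb toy genome the gene-density signal is
weak enough per chromosome for its sign to be unreliable, and the planted
H3K27ac is a poor orientation carrier precisely because of the biology the
panel plants (eTADs, a large share of the toy A compartment, lose H3K27ac
in mesenchymal lines). On a real genome any of the three works. A/B labels follow the sign of PC1, with the tie at
exactly zero broken toward B (the inactive compartment) — a documented,
testable rule. Genes take the label of the bin containing their TSS
(strand-aware); assigning by TSS bin rather than by majority vote over the
gene body is a deliberate choice — the TSS is where compartment status acts
on transcription — and is localized in `gene_compartment()` should a user
prefer otherwise.

Switch classes between two samples are the ordered label pairs AA/BB/AB/BA;
`expression_concordance()` calls an AB gene concordant when its expression
falls (log2 fold change below `-threshold`) and a BA gene concordant when it
rises. The threshold defaults to 0 — any directional change counts — and is
exposed because no canonical cut-off exists.

Sub-compartments use a deliberately simplified nested rank-split: each bin's
compartment score is its mean correlation with the 10% most A-like bins;
within A and B separately, bins are split at the median score and each half
split again at its own median, yielding eight classes (A.1.1 ... B.2.2) that
exactly refine the A/B labels. This keeps the nested 8-class semantics
testable without reproducing a full nested-clustering tool; the class labels
carry ranking information only.

## TADs and boundary changes

`insulation_profile()` computes, for each bin and window size, the mean
contact level in the square window upstream x downstream of the bin, log2
transforms it and z-scores per window along the chromosome; the score is the
mean z across windows. Default windows are {1, 3, 5} bins (50-250 kb at
50 kb): the window set must sit below the expected domain size — windows
that span whole domains average away the boundary dip — and the single-pixel
window sharpens localization. Boundaries are score minima with topographic
prominence at least 0.2 and negative score. One numerical subtlety: a
boundary between bins b-1 and b produces a two-bin minimum plateau, because
both flanking bins see windows of purely cross-domain pixels. `call_tads()`
resolves the plateau deterministically to its right element, so the called
edge is the first bin of the downstream domain; this took boundary calls
from roughly half exact to nearly all exact on planted panels.

`classify_tad_change()` matches each reference TAD to the query TAD with
maximal base-pair overlap (ties broken by midpoint distance; no overlap is
`Absent`) and classifies the matched pair with tolerance
`tol_bins` x resolution (default one bin): Stable if both boundaries moved
within tolerance; Expand if the query covers the reference with at least one
boundary beyond tolerance outward; Shrink for the mirror case; Shift
otherwise. These rules are one consistent formalization of the
Stable/Expand/Shrink/Shift taxonomy — tolerance and matching rule are not
canonical anywhere — and the classifier is tested against an independent
rule-table enumeration over all offset pairs in [-5, 5] bins. eTAD/mTAD
flags follow TSS containment under the half-open rule; a TAD containing
both an epithelial and a mesenchymal gene is both.

## EMT signature, scoring and signal integration

`refine_signature()` keeps a gene in a class if it appears in at least 2 of
3 sources (tumor list, cell-line list, hallmark list); genes qualifying for
both classes are dropped with a warning. The published counts that motivate
this step arise from specific external source lists; the rule itself is the
reusable part.

The per-sample EMT score is half the difference between the mean expression
z-score of mesenchymal and epithelial signature genes, clipped to [-1, 1].
This is a transparent stand-in for published two-sample scoring schemes
(which live outside this package's scope); it is antisymmetric in the E/M
sets, monotone in the planted latent score on synthetic panels, and should
be read as an ordering device, not a calibrated quantity. When published
scores exist for real samples they should be passed in as data.

Histone signal over TADs is the base-pair-weighted mean of bedGraph values
with uncovered bases contributing zero (`mean_signal_in_intervals()`, built
on GenomicRanges overlap arithmetic). Correlations of per-sample signal with
the EMT score use Pearson r with the two-sided t-test on n-2 degrees of
freedom; group comparisons expose the rank-sum (normal approximation with
tie correction) and Welch t tests.

## Aggregate contacts and 3C

`aggregate_tads()` rescales each TAD's O/E sub-matrix (plus 10% flanks) to a
common odd side length by area-weighted averaging — which conserves the
matrix mean exactly — and averages across TADs; per-TAD interior means
exclude the first two diagonals, where self-ligation artifacts dominate in
real data. `aggregate_pairs()` stacks fixed-size windows centered on locus
pairs and z-scores the pooled pixel distribution (one global mean/sd across
all windows; a per-window variant is available via `per_window = TRUE`).
Pooled z-scoring was chosen so the center-pixel z of different pairs are on
one scale within a sample; cross-sample comparisons are made per sample so
that each cell line provides its own background. 3C-qPCR frequencies use the
ideal doubling model `2^(Ct_loading - Ct_target)` with efficiency fixed at
2, averaged over replicates; no efficiency calibration is attempted.

## Single-cell structures

Contacts are filtered per cell (`filter_sc_contacts()`): self-pairs,
pairs closer than 2 bins, duplicates, and all contacts of bins whose count
exceeds 8x the per-bin median (promiscuous bins, typically mapping
artifacts). `embed_structure()` reconstructs one chromosome per cell by
distance geometry: backbone edges (length 1) and contact edges (length 1)
define a graph; shortest-path lengths complete the distance matrix;
classical MDS initializes coordinates; and gradient descent with a
backtracking line search refines them under a flat-bottom loss (backbone
distances to 1, contacts at most 1.5, all pairs at least 0.5). The best of
several restarts by final loss is kept (default 5; the first restart is the
unperturbed MDS solution), and coordinates are normalized to unit radius of
gyration because contact data carry no absolute scale. This embedder
replaces annealed particle dynamics with something deterministic at fixed
seeds, desk-scale, and directly testable against planted conformations.

Contacts cannot determine chirality, so `align_structures()` evaluates the
Kabsch superposition and, by default, its mirror image, returning the
smaller r.m.s.d; structures are centered and Rg-normalized on their common
unmasked bins first. The resulting cell-cell dissimilarity is clustered by
average-linkage hierarchical clustering. Because each pair is normalized on
its own common bin set, the r.m.s.d matrix is symmetric and non-negative but
the triangle inequality is not guaranteed — hierarchical clustering does not
require it.

# The synthetic panel

`panel_spec()` defaults define the study conditions: five cell lines with
latent EMT scores (-0.6, -0.328, 0.05, 0.4, 0.643) — endpoints matching the
characteristic scores of an epithelial and a mesenchymal ovarian line, the
rest spread across the spectrum — over 2 chromosomes x 400 bins at 50 kb,
with 2e5 expected counts per chromosome, and 30 E / 20 M / 60 other genes.
The gene counts are scaled to the toy genome (about 150 genes would not fit
at the enforced 5-bin TSS spacing); published signature sizes apply to a
full genome.

Planted structure, per sample:

* **Compartments.** Reference TADs of 10-15 bins tile each chromosome;
  compartment blocks are runs of 1-2 TADs with alternating sign. Block
  transitions follow the sample's (possibly edited) TAD boundaries — in real
  genomes compartment transitions track domain boundaries, and an earlier
  generator draft that left block edges at reference positions produced
  spurious-looking insulation dips at the old positions in edited samples.
  A seeded subset of M-gene-bearing B blocks (40% of M genes) flips to A in
  samples with positive EMT score.
* **TAD edits.** Non-reference samples move scripted interior boundaries by
  ±3 bins in patterns generating Expand, Shrink and both Shift directions
  (each pattern also determines the classes of the two adjacent TADs, via
  the same offset arithmetic); every class occurs at least 5 times per
  panel. Offsets of 3 bins against a 1-bin tolerance make the planted
  classes unambiguous.
* **Counts.** Expected counts follow
  `depth * Z^-1 * (1+d)^-1 * exp(kappa v_i v_j) * (1 + lambda [same TAD]) *
  (1 + rho [loop]) * b_i b_j` with kappa 0.6, lambda 1.0, rho 3.0 and
  log-normal(0, 0.3) biases; counts are Poisson (no over-dispersion in this
  version — sufficient for recovery testing, simpler variance arithmetic).
  Loops join each M-gene TSS to an intra-TAD partner 4 bins away and are
  active only in positive-score samples.
* **Tracks and expression.** eTAD H3K27me3 rises and H3K27ac falls linearly
  with the EMT score (slope 0.5 on a baseline of 1, bin noise sd 0.1);
  H3K27ac additionally carries a +0.15 A-compartment enrichment and a
  dedicated H3K4me1 track a +0.3 A-enrichment with no EMT dependence, the
  activity signals real genomes offer for orienting PC1. mTAD
  H3K27me3/H3K27ac carry no score dependence; their across-line variation is a
  line-specific nuisance component constructed orthogonal to the score
  vector. With five samples, a *random* independent baseline would still
  show |r| up to ~0.5 against the score by chance alone, which would make
  the planted null a coin flip; orthogonalizing the nuisance makes "no
  dependence" exact while keeping realistic line-to-line variation.
  E-gene expression decreases and M-gene expression increases in the score
  (slopes ∓2 on log2 FPKM, noise sd 0.15); flip-set M genes are instead
  tied to their planted compartment sign (+3 log2 units when in A), so
  their B-to-A switches come with concordant expression gains.
* **Single cells.** Base conformations are smoothed random walks with unit
  mean bond length; the shared chromosome ("chr2like") uses one conformation
  for all states, the state-specific one ("chr10like") a distinct
  conformation per state. Cells perturb their state's conformation with
  isotropic Gaussian noise (sd 0.3) and report 1000 subsampled contacts
  within radius 4 (radius chosen so a 200-bin walk yields a few thousand
  candidate pairs, comfortably above the subsampling target).

What the generator does **not** emulate: read-level noise and mapping
artifacts, restriction-fragment geometry, copy-number aberrations,
over-dispersed counts, trans-chromosomal structure, and cell-cycle
variation. Recovery on this panel therefore demonstrates the correctness of
the algorithms under their stated model, not performance on real libraries.

# Numerical choices and degenerate inputs

* PC1 orientation failing (exactly zero correlation with the track) is an
  error instructing the caller to supply a different track, rather than a
  silent sign guess.
* `pc1 = 0` labels B; sub-compartment median splits send values equal to
  the median to the lower half — both deterministic tie rules.
* Balancing masks zero-marginal bins unconditionally; an all-masked matrix
  is an error ("matrix too sparse").
* O/E diagonals with zero expectation are masked, not set to 0 or 1.
* Chromosomes need at least 8 unmasked bins for a correlation matrix and 16
  for sub-compartments.
* The embedder requires 0.5 contacts per bin (beyond toy sizes), embeds the
  largest component of a disconnected contact graph and masks the rest, and
  its line search guarantees the loss never increases.
* Problem sizes used throughout the tests and the acceptance script — the
  400-bin panel, 200-bin single-cell chromosomes, 20 cells, 5 simulation
  seeds, 2 embedding restarts — are the package's chosen desk-scale study
  conditions; they keep every planted structure comfortably recoverable.

# Known limitations

* The insulation caller reports each boundary once; two true boundaries
  closer than about 4 bins can merge into one valley (such TADs arise in
  the edited samples as 4-bin Shrink products and are the main source of
  residual classification error, about 10% from called sets).
* The EMT score stand-in is uncalibrated across data sets.
* Sub-compartment classes are ranked labels, not biochemical annotations.
* r.m.s.d-based clustering compares single chromosomes; whole-nucleus
  comparisons are out of scope.

```{r example, eval = FALSE}
# A minimal end-to-end run on the default panel
spec <- panel_spec(seed = 1)
panel <- simulate_panel(spec)
bal <- ice_balance(panel$sims[[1]]$cm)
oe <- observed_over_expected(bal)
dens <- gene_density_track(panel$gen$genome, panel$gen$genes)
pc1 <- compute_pc1(correlation_matrix(oe, "chr1"),
                   dens[chrom_bins(panel$gen$genome, "chr1") + 1])
table(label_compartments(pc1))
```
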