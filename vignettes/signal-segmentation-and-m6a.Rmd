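---
title: "Raw-signal segmentation and m6A calling: models and methods"
author: "poreseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Raw-signal segmentation and m6A calling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreseg)
```

## The problem

Direct RNA sequencing reads out an ionic current while a motor protein
ratchets an RNA strand through a nanopore. At any instant about five
nucleotides (a 5-mer) sit in the pore and set the current baseline, so the
trace is, ideally, a staircase: one quasi-flat *base block* per k-mer,
joined by short steep *transition blocks*. Calling base modifications such
as N6-methyladenosine (m6A) from this trace requires knowing which signal
stretch belongs to which reference k-mer — the segmentation-and-alignment
(eventalign) task — because an m6A shifts the k-mer's baseline by a few
picoamperes.

The difficulty is that translocation is not monotone. The motor protein
transiently pulls the strand backward and pushes it forward by roughly one
nucleotide, so samples inside one base block intermittently match the
*previous* or *next* k-mer's baseline ("jiggling"). Methods that assume a
flat level per k-mer absorb these excursions into the event statistics as
structured noise, which blurs exactly the small baseline shifts that
modification calling depends on.

## The model

### Hierarchical hidden Markov segmentation

The raw signal $y$ of a read is modelled as $2K+1$ alternating blocks
$c = (c_1, \dots, c_{2K+1})$, $c_k \in \{B, T\}$, odd blocks base and even
blocks transition. The joint likelihood factorizes into per-block emission
terms and an outer two-state Markov chain over per-sample labels, with
transition matrix $T^{outer}$ and initial distribution $\pi^{outer}$:
long blocks pay $(n-1)\log T^{outer}_{cc}$ in self-transitions and each
block change pays a cross-transition, so the outer chain acts as a
complexity penalty on the number of blocks.

Within a base block, samples are emitted by an inner four-state HMM:
`curr`, `prev` and `next` are Gaussians with means at the current,
previous and next k-mer baselines and a shared std `sigma_inner`; `noise`
is uniform on a wide interval. The block emission term is the inner HMM's
*marginal* likelihood (forward algorithm, scaled, exact in log space).
Transition blocks are scored by an ordinary least-squares line whose
residuals are Gaussian; a fitted absolute slope below `min_abs_slope`
makes the stretch inadmissible as a transition, because the model requires
a sharp ramp between consecutive baselines.

Maximizing the joint over all segmentations is exponential, so
`segment_signal()` is exact over a *candidate lattice*: a multiscale
changepoint detector (`propose_changepoints()`) standardizes mean shifts
at windows of 4, 6 and 10 samples by a robust noise estimate and emits a
dense cluster of candidates around every local peak of the |z| profile,
and a dynamic program then chooses the maximum-objective alternating
segmentation with boundaries on the lattice. The detector is
deliberately recall-oriented: a false candidate costs only compute (the DP
rejects it), a missed candidate is unrecoverable.

During segmentation no reference is available, so the `prev`/`next` means
of a candidate block are the 10% trimmed means of the nearest elementary
lattice segment of at least base length on each side; at the read ends the
corresponding state is disabled by zeroing its transition and initial
mass. Ties in the DP are broken toward fewer blocks (the longest
admissible final block found first), then earlier boundaries, making the
output deterministic.

Per-block statistics mask structured noise: a base block's mean and std
are computed from samples whose inner-HMM posterior attributes them to
`curr`, and the mean additionally trims 15% per tail. The trim matters
when a neighbouring baseline sits within about two `sigma_inner` of the
current level — such excursions evade per-sample attribution, and without
the trim they bias block means by several tenths of a pA toward the
neighbour.

### Many-to-one alignment

Base-block means $\mu_1, \dots, \mu_m$ (pore time order) are aligned to
the reference k-mer list $s_1, \dots, s_n$ with an $(m+1)\times(n+1)$
score matrix whose recursion has four moves: diagonal match, k-mer skip
(deletion), mean skip (insertion), and a vertical *stay* that aligns a
further mean to the same k-mer. The stay move is the point of the design:
a k-mer often emits several base blocks (sub-states), and the aligner
merges them rather than forcing them onto distinct k-mers. Direct RNA is
sequenced 3'→5', so the k-mer list is traversed in pore order and events
are reported back in reference coordinates.

Match scores are log-densities of the mean under the k-mer's Gaussian
baseline; for k-mers with modification parameters the larger of the
unmodified and modified log-densities is used, so a modified block is not
penalized. Insertions and deletions score as a fixed uniform log-density
whose range defaults to the table's level spread plus three times the
largest std on each side — wide enough that a gap never beats a plausible
match. The *full* variant consumes both lists entirely (traceback from
$(m+1, n+1)$); the *partial* variant allows only match and stay moves,
anchors the path at the first k-mer, and tracebacks from the maximum of
the last row, aligning all means to the best prefix of the k-mer list.
Traceback ties prefer stay, then match, then deletion, then insertion.

Blocks aligned to one k-mer merge into an *event*: the mean is the
length-weighted mean of member blocks, the std pools member blocks by the
combined-moments identity (identical to the std of the concatenated
member samples), dwell is the total contributing sample count, and
samples inside intervening transition blocks are excluded. K-mers hit
only by deletions produce no event row.

### Modification calling and table re-estimation

Event means pooled for one k-mer across reads and positions are fit with
a two-component Gaussian mixture whose first mean is *pinned* to the
k-mer's unmodified baseline at every M step (`fit_gmm_fixed_mean()`);
only its std and weight are re-estimated, which removes label switching
and anchors the mixture. EM stops when the log-likelihood improves by
less than `tol` (default 1e-6) or after `max_iter` (500). Initialization:
component 1 at the pinned mean with the sample std, component 2 at the
mean of the points beyond one sample-std on the heavier side, weights
(0.7, 0.3), three restarts with seed-derived jitter.

A k-mer becomes callable (`mod_enabled`) only when the fitted component
separation exceeds `min_sep` (default 5 pA), the modified weight is at
least 0.05, and the modified std lies in a plausible 0.5–10 pA band; the
pooled-coverage gate defaults to 1500 events (simulation studies lower it
through configuration). Per read, the hard state call compares the
unweighted Gaussian densities of the event mean under the two baselines,
while the reported probability is the weight-aware posterior
$\omega_{mod}\phi_{mod} / (\omega_{un}\phi_{un} + \omega_{mod}\phi_{mod})$
— the simple density-comparison rule and the calibrated quantity, side by
side. A
site's modification rate is the modified fraction of reads covering it,
reported only at coverage ≥ 20.

`iterate_workflow()` loops alignment → event assembly → re-estimation
(segmentation does not depend on the table and is computed once) until
the mean absolute change of the table's mean values falls below 5e-3 pA
or five rounds, and reports the per-round change metric.

## The simulator and what it does (not) show

`simulate_read()` generates ground truth for every stage under the
jiggling model: per k-mer (pore order) a base block of
$3 + \text{Poisson}(\text{dwell\_mean} - 3)$ samples, each sample
independently from the current k-mer's Gaussian (probability
$1 - p_{prev} - p_{next} - p_{noise}$), the previous or next k-mer's
Gaussian ($p_{prev}, p_{next}$), or a uniform noise floor; linear ramps
with Gaussian residuals join consecutive blocks; a poly(A) segment
precedes the transcript region; DRACH-centre sites are modified per read
with probability `mod_rate`, switching that k-mer's emissions to its
modified Gaussian.

Defaults are chosen once as realistic desk-scale conditions:
`dwell_mean = 30` samples per base (RNA002 chemistry translocates at
~70 nt/s against a ~3 kHz sampling rate, i.e. ~43 samples per base;
30 keeps runs fast without changing the regime), `p_prev = p_next = 0.05`
and `p_noise = 0.01`, transition lengths 4–8 samples (events carry about
six transition-state points on average), a 2000-sample poly(A) tail
(real tails are thousands of samples; much shorter tails make the
per-read standardization scale estimate the dominant event-mean error),
and a per-read affine pore drift (gain $N(1, 0.02)$, offset $N(0, 2)$ pA)
— precisely the variability that poly(A) standardization removes. One
base block per k-mer is the default: the generator gives all sub-blocks
of a k-mer a common baseline, so their shared boundaries would be
unidentifiable in principle; multi-block emission
(`n_blocks_per_kmer_max > 1`) is available and is exercised where the
many-to-one aligner is the subject.

Test references come from `random_reference()`, which enforces the
model's identifiability assumption — a sharp current step between
consecutive k-mers — as a minimum 5 pA separation between consecutive
k-mer baselines *under every modification state the table defines*. The 5 pA
floor mirrors the separation significance gate used for calling.

What passing these simulations does **not** show: performance on real
reads with adapter artefacts, within-read drift, basecalling and mapping
errors, neighbouring k-mers with near-identical baselines (the model's
known hard case), modifications other than a single-centre two-state
m6A model, or RNA004 chemistry. The simulator emulates the generative
assumptions of the model, so simulation results validate the inference
machinery, not the biology.

## Numerical choices and degenerate inputs

- All HMM passes are scaled (forward) or log-space (scores); blocks of
  10^4 samples are routine.
- Zero-probability data (e.g. samples outside the noise bounds with all
  Gaussian states suppressed) yield `-Inf` log-likelihoods, not errors.
- Constant signals segment into a single base block; signals shorter than
  `min_base_len` return a flagged single-block segmentation with a
  warning.
- The DP considers base blocks longer than 150 samples only between
  adjacent lattice candidates — a compute cap that leaves degenerate flat
  signals exact.
- GMM stds are clamped at a 0.05 pA floor (flagged); re-estimated
  modified stds are clamped into [0.5, 10] pA.
- Every source of randomness flows through `derive_seed(master, index)`,
  so any run is reproducible from one master seed; identical
  configuration and seed give byte-identical eventalign output.

## Study sizes used by the shipped tests

Oracle checks use 200 random instances (hidden-path enumeration up to
n = 8; alignment enumeration up to 6×6). Boundary recovery uses 50 reads
on 30-nt references; single-molecule calling uses 200 reads over one
DRACH site at +8 pA separation and a 0.3 site rate; table re-estimation
uses 300 reads pooling one motif across four sequence contexts — pooling
across contexts matters, because each context leaves a small
boundary-leakage bias toward its own neighbours that only averages out
across contexts, which is also why the re-estimation procedure pools
k-mers across genomic locations in the first place.

## Known limitations

- Boundaries between k-mers whose baselines differ by less than ~4 pA are
  not identifiable at realistic noise; recovery there fails gracefully
  (blocks merge and the aligner's stay/deletion moves absorb the loss).
- The changepoint detector, not the DP, bounds recall: its candidates are
  a superset of the truth only down to steps of roughly twice the
  per-sample noise.
- Modification calling is limited to k-mers whose two states separate by
  more than the significance gate; others are reported as not callable
  rather than guessed.
- The single-molecule probability is the two-component posterior; with
  modifications at multiple positions of one k-mer ($2^5 = 32$ states in
  principle) it is mis-specified by construction.

## A minimal end-to-end run

```{r example, eval = FALSE}
table <- synthetic_kmer_table()
table <- enable_modification(table, "GGACT", delta = 8)
ref <- random_reference(table, 25, min_step = 5, include = "GGACT", seed = 1)
cfg <- sim_config(table, mod_rate = 0.3, seed = 1)
ds <- simulate_dataset(c(tx = ref), 100, cfg)
pe <- pipeline_events(ds$reads, c(tx = ref), table)
calls <- call_modifications(pe$events, table)
calls$site_calls
```
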