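---
title: "Calling nucleosome dyads from ultra-high-resolution contact maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling nucleosome dyads from ultra-high-resolution contact maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Nucleosomes — ~147 bp of DNA wrapped around a histone octamer — are
regularly spaced along the chromatin fiber, but how consistently a given
nucleosome occupies the same coordinate across a cell population (its
*positioning level*) varies enormously. MNase-seq-style peak callers work
well where nucleosomes are well positioned and peaks are sharp; in poorly
positioned regions neighboring peaks blur into each other and the callers
lose the array structure. Nucleosome-resolution chromatin conformation
assays (Micro-C, DNase Hi-C, Hi-CO) offer a way out: each ligation contact
joins reads from *two different* nucleosomes, so the data carry both
per-nucleosome read density and inter-nucleosome spacing. `dyadmap`
exploits both signals, plus the sequence preference of nucleosomal DNA, to
place dyads even where positioning is fuzzy.

## The model

Within 1 kb windows, read centers `x_i` are treated as draws from an
unknown number of Gaussians with a common, vanishing variance — a
Dirichlet-process mixture whose hard-assignment (small-variance) limit is a
DP-means problem:

$$\min_{\{\ell_c\}} \sum_c \sum_{x \in \ell_c} \tilde d_c(x)^2 +
  \lambda^2 k,$$

where `k` is the number of clusters (nucleosomes) and a new cluster is
opened whenever a read sits farther than `lambda_bp` from every existing
center. The adjusted distance

$$\tilde d_c(x) = \max\!\big(0,\; |x - \mu_c|
  + \gamma_1\,[\text{partner of } x \in \ell_c]
  + \gamma_2\,B(\mu_c)\big)$$

adds two penalties: a *cannot-link* term (`gamma1`, bp) discouraging the
two ends of one contact from sharing a cluster — the two reads of a
ligation event come from different nucleosomes by construction — and a
binding-score term (`gamma2`, bp per z-unit) that, when negative, attracts
centers to sequence positions that look like nucleosomal DNA.

### Parameters that matter

| parameter | unit | default | role |
|---|---|---|---|
| `lambda_bp` | bp | 75 | new-cluster threshold; ~half a repeat length. The internal cluster penalty is `lambda_bp^2`. |
| `gamma1` | bp | 80 | cannot-link penalty between a read and the cluster holding its contact partner. |
| `gamma2` | bp/z | -2 | signed binding-score weight; negative = attraction. |
| `window`/`overlap` | bp | 1000 / 200 | tiling of each chromosome; calls in overlap zones are deduplicated at 74 bp keeping the call with more member reads. |
| `b_clip` | z | 3 | binding scores are clipped to `[-3, 3]` inside the objective. |
| `min_dist` | bp | 160 | contacts closer than this after center shifting are discarded entirely. |
| `w` (occupancy) | bp | 30 | kernel aggregation window. |

`gamma2` deserves a note. The `max(0, ...)` clamp means a large negative
`gamma2` creates flat zero-cost plateaus around binding-score maxima:
every center position within `|gamma2 * B|` bp of a tight read stack costs
nothing, and centers drift to wherever the score comb happens to peak. We
calibrated `gamma2` on the synthetic recovery suite: at `-15` bp/z the
drift reaches ~28 bp on perfectly positioned arrays (median recovery error
15 bp), while `-2` bp/z keeps the attraction and recovers planted dyads
with 2 bp median error at jitter sd 0 and 20 alike. `-2` is the default;
the flag remains exposed.

### Optimization

Reads are scanned left to right once to seed clusters, then the engine
alternates a sequential reassignment sweep with a guarded recentering step
until no move improves the objective (or `max_iter = 50`). Reassignment
evaluates the exact objective delta of each candidate move, including the
partner's penalty change and the `lambda^2` bookkeeping for emptied or
fresh clusters, so the objective cannot increase. Recentering is where the
binding term acts: with penalties active the member mean no longer
minimizes the cluster cost, so the step evaluates the current center, the
member mean, and an integer grid of +/-30 bp around the mean, keeping the
argmin. Because the current center is always a candidate, the objective is
non-increasing at every iteration — an invariant the test suite asserts on
seeded random windows. Initialization is deterministic (no random
restarts), so results are reproducible without a seed.

## Read centers and the read-size estimate

Only ~50 bp at the two ends of each contact are sequenced, so read centers
are estimated by shifting every 5' coordinate half an average read size in
the 3' direction (`floor(read_size/2)` on both strands, keeping them
symmetric). The read size itself is estimated from the data: for the same
nucleosome pair, `+-` contacts span both cores while `++` contacts span
one, so the difference between the first peaks of their contact-distance
histograms is one average read size. Peaks are located on 1 bp histograms
smoothed with an 11 bp moving average; the first local maximum with
*topographic prominence* at least 10% of the global maximum is taken
(plain height thresholds latch onto noise bumps on the rising flank).
Estimates outside a 20-120 bp plausibility band raise an error asking for
an explicit `--read-size`. On perfectly positioned simulations the
estimator is exact; at jitter sd 20 it is unbiased to about +/-12 bp,
which only redistributes centers symmetrically around the dyad and leaves
the cluster means in place. After shifting, contacts whose center distance
is below 160 bp are dropped ("both reads excluded"); the boundary value
160 is kept.

## The binding score

The sequence model is fixed to the AA/AT/TA/TT dinucleotide class, whose
~10 bp periodicity along nucleosomal DNA is the classic positioning
signal; the class is its own reverse complement, so only the forward
strand is scanned. A 2 x 160 position frequency matrix counts the class at
offsets -80..+79 from each read center (centers too close to a chromosome
end are skipped and reported), a pseudocount of `1e-4` guards the log2
odds against zero counts, and the genome-wide dinucleotide composition
supplies the background. The raw score `D(i)` cross-correlates the weight
matrix with the genome, anchored so `D(i)` scores position `i` as a
putative dyad; `N`-containing dinucleotides score as the non-class row.

Normalization is two-step: divide by the score sum over +/-50 bp, then
z-standardize over all scored positions. The ratio step presumes
non-negative scores, but log-odds sums are negative wherever the sequence
looks like background — and on a strongly periodic genome the
negative-valued ratio *inverts* the 10 bp comb, because the 101 bp window
resonates with the period while the negative denominator flips the
ordering. `D` is therefore floored at 0 before the ratio ("no detectable
affinity"); neighborhoods flooring to zero entirely get `Btilde = 0` and a
flag rather than a division by zero. With the floor in place the score
peaks at planted dyads, as it should. Inside the caller, `B` lookups are
additionally clipped to +/-3 z-units so that a handful of extreme
normalization outliers cannot dominate a squared objective.

## Occupancy and positioning level

Coverage is convolved with the smooth bump kernel
`K(i, w) = (1 - (i/w)^2)^3` on the open support `|i| < w` (`w = 30` bp),
then locally normalized:

$$S(i) = \frac{D(i)}{\frac{1}{c\,w} \sum_{|j-i| \le 4w} D(j)},
  \qquad c = \Big(\int_{-1}^{1} (1-u^2)^3\,du\Big)^{-1} = \tfrac{35}{32}
  = 1.09375,$$

so a flat track normalizes to the kernel's own mass (the constant prints
as 1.09 at two decimals). The +/-4w neighborhood slightly exceeds one
nucleosome footprint, which is what makes the statistic sensitive to
poorly positioned nucleosomes. Edge windows are clipped and flagged rather
than dropped; zero denominators yield `S = 0` with a flag. A call's
positioning level is the maximum `S` within +/-30 bp of its dyad. The
statistic is invariant to global coverage scaling, and on synthetic data
low-jitter arrays score visibly higher levels than high-jitter ones.

## Nucleosome contact maps and OE normalization

Each end of every retained contact is assigned to its nearest called dyad
(ties to the lower coordinate), turning contacts into edges between
nucleosome nodes. On perfectly positioned simulations the self-contact
fraction is exactly zero — both ends of a contact always have distinct
nearest dyads — and the recovered inter-dyad distance histogram peaks at
repeat-length multiples, reproducing the raw contact-distance profile.
The per-contact distance error (recovered minus center distance) is
symmetric around zero beyond the first repeat length; within it, the
160 bp filter censors short distances from below and skews the adjacent
class slightly.

Expected contact counts are modeled per genomic distance. Treating
nucleosome occurrences as a homogeneous process with rate
`N_nuc / L_chrom` per bp, the distance between the i-th and (i+k)-th
nucleosome is Erlang(k, rate), and the expected number of pairs in a
distance bin `[d1, d2)` is

$$NP(d_1, d_2) = \sum_k (N_{nuc} - k)\,
  \big[F_{k}(d_2) - F_{k}(d_1)\big],$$

with `F_k` the Erlang CDF (`pgamma`) and the k-sum truncated to
`max(1, d1/150 - 20) .. min(N_nuc, d2/150 + 20)`; the truncation loses
under 0.1% of the mass on realistic configurations while avoiding the
O(n^2) pair enumeration, and the model matches exhaustive pair counting
within 5% on 2,000 uniform dyads over 400 kb. Distance bins are 50 bp up
to 2 kb and multiplicative (x1.2) beyond — the binning itself is a
package choice. `C_exp(bin) = N_c(bin) / NP(bin)`, and each edge's OE
value is its count over its bin's `C_exp`; bins with no pairs or no
contacts are flagged and skipped. Pileups extract the
`(2*flank_n + 1)`-node OE submatrix centered at the node nearest each
anchor midpoint and average element-wise, skipping (and counting) anchors
whose window leaves the node range.

## Tetra-nucleosome folding motifs

Four consecutive nucleosomes fold predominantly as either an
alpha-tetrahedron (contact-dense neighborhood) or a beta-rhombus
(sparse). Per nucleosome `i`, the feature is the row-major upper triangle
(diagonal included — 4 diagonal + 6 off-diagonal = 10 values) of the 4x4
contact submatrix over nucleosomes `i-1..i+2`; boundary nucleosomes are
skipped. Features are grouped by their contact sum with left-inclusive
bins at 200/400/600, and a binary classifier is selected per group (2-4)
by F1 on a held-out 25% split; group 1 neighborhoods are too sparse and
stay `unpredicted`. The classifier set is pluggable; the default set holds
ten standard families (kNN, linear/RBF SVM, Gaussian process, decision
tree, random forest, MLP, boosted trees, naive Bayes, QDA) behind a
two-function `fit`/`predict` interface, with failures scored `NA` and
ignored. The contribution here is the harness — split, scoring, per-group
routing — not the classifiers.

Regional motif preference is the odds ratio
`n_local(alpha) * n_genome(beta) / (n_local(beta) * n_genome(alpha))`;
it is scale-free and antisymmetric under label swap. Because the source
of replication behind its significance test is genuinely unspecified, the
package uses an explicit resampling construction: draw genome subsets of
the region's size, compute each subset's log odds ratio, and score the
observed log ratio as a new observation from that null —
`t = (obs - mean)/sd` with `n_resamples - 1` degrees of freedom,
two-sided. Under the null (region drawn from the genome itself) the
p-values are approximately uniform; a fully enriched region of 500
nucleosomes reaches `p < 1e-6`. This construction is this package's
documented choice, not a published recipe.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the study
conditions every downstream module is validated against:

* **Arrays**: dyads spaced exactly `nrl` bp apart (default 190, a typical
  repeat length), jittered per cell by `positioning_sd` — 0 models
  yeast-like well-positioned chromatin, 20 the poorly positioned regime.
* **Contacts**: partner separation `k` follows `k^-1.5` truncated at 50
  nucleosomes (steep local decay; the caller and map tests only need
  local structure), strands drawn uniformly from the four types, and 5'
  coordinates placed at `dyad -/+ read_size/2` for `+`/`-` ends — which
  reproduces the strand-type distance offsets exactly at sd 0.
* **Sequence**: within +/-73 bp of each dyad, dinucleotides at 10 bp
  phase get AA/AT/TA/TT probability `background + motif_strength`
  (default 0.3, a strong but not saturating planted signal).
* **Coverage**: 147 bp pseudo-reads around jittered dyads.
* **Labels**: P(alpha) increasing linearly in the tetra feature sum.

It does **not** model MNase digestion bias, GC bias, trans contacts,
duplicate reads, variable repeat lengths, or empirical strand-type
ratios. Passing tests therefore demonstrate correctness of the
algorithms under the stated geometry and decay model, not robustness to
every artifact of real libraries.

The bundled validation problems are sized for interactive runs: 60-200 kb
chromosomes, 8,000-26,000 contacts (50 reads per nucleosome at the
largest), 2,000 dyads for the Erlang oracle. These sizes give the
recovery statistics comfortable margins while keeping the whole suite in
the low minutes.

## Coordinates and file formats

Internally everything is 1-based inclusive, the R/Bioconductor convention
(Biostrings, IRanges, GenomicRanges); BED-family files convert to and
from 0-based half-open at the file boundary. Pair files follow the 4DN
`.pairs` dialect (`readID chrom1 pos1 chrom2 pos2 strand1 strand2`, `#`
headers) or a 7-column BEDPE-like TSV; intra-chromosomal records are
normalized to `pos1 <= pos2` with strands traveling along. Calls are
BED6+2 (score = member reads, then fuzziness and binding); tracks are
bedGraph; contact maps are sparse triplet TSVs plus a node BED.

## Known limitations

* The caller is a local optimizer: sequential reassignment plus guarded
  recentering converges to a single-move-optimal state, not a global
  optimum; the deterministic scan makes that state reproducible.
* The read-size estimator needs visible first peaks; with fewer than ~500
  short-range contacts per strand type, or heavily smeared histograms, it
  refuses and asks for an explicit value.
* The Erlang expected model assumes homogeneous nucleosome density per
  chromosome; strong large-scale density gradients would bias `C_exp`.
* Occupancy uses only the `w = 30` kernel variant (plus the exposed `w`
  flag); no other kernel families are implemented.
* Trans contacts are parsed and carried through, but the OE model and the
  motif features are cis-only.
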