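# dyadmap

Nucleosome dyad calling and nucleosome-resolution contact maps from
Micro-C-style pair data.

Nucleosome-level chromatin conformation assays (Micro-C, DNase Hi-C,
Hi-CO) capture two things at once: where mono-nucleosomes sit (read
density) and how far apart neighboring nucleosomes are (contact
distances, since each ligation joins reads from two different
nucleosomes). Peak callers built for MNase-seq use only the first signal
and struggle wherever nucleosomes are poorly positioned and neighboring
peaks blur together. `dyadmap` uses both, plus the ~10 bp periodic
AA/AT/TA/TT dinucleotide preference of nucleosomal DNA, to place dyads in
well- and poorly-positioned chromatin alike.

## The model

Read centers within 1 kb windows are clustered by the hard-assignment
(small-variance) limit of a Dirichlet-process Gaussian mixture — a
DP-means problem with a penalty-adjusted distance:

    min over assignments:  sum_c sum_{x in c} d~_c(x)^2  +  lambda^2 k

    d~_c(x) = max(0, |x - mu_c| + gamma1 * [partner of x in c]
                     + gamma2 * B(mu_c))

A new nucleosome is opened whenever a read lies farther than `lambda`
(75 bp) from every existing center; `gamma1` (80 bp) is a cannot-link
penalty keeping the two ends of one contact in different clusters;
`gamma2` (-2 bp per z-unit) attracts centers to high sequence-affinity
positions `B(mu)`. Downstream, called dyads become nodes of a nucleosome
contact map whose observed/expected normalization uses an Erlang model of
inter-nucleosome distances, and 4x4 diagonal submatrices feed a
classifier harness that labels tetra-nucleosome folding motifs
(alpha-tetrahedron vs beta-rhombus), summarized per region by the odds
ratio `n_local(a) n_genome(b) / (n_local(b) n_genome(a))`.

A synthetic-data module generates genomes, contacts, coverage, and motif
labels with known ground truth; every stage is validated against it.

## Worked example

Simulate a poorly positioned 60 kb array (repeat length 190 bp, per-cell
jitter sd 20 bp), run the full calling path, and compare against the
planted truth:

```r
library(dyadmap)

tr     <- truth_set(60000, nrl = 190, positioning_sd = 20,
                    read_size = 70, seed = 1)
genome <- make_genome(tr, motif_strength = 0.3)
rec    <- simulate_contacts(tr, 8000)

rs      <- estimate_read_size(rec)        # 73 bp (true: 70)
shifted <- filter_short(shift_to_centers(rec, rs))
centers <- read_center_set(shifted)
B       <- binding_score_track(centers, genome)
calls   <- call_genome(centers, B, caller_params())

err <- vapply(tr$dyads, function(d) min(abs(calls$dyad - d)), numeric(1))
median(err)          # 4 bp
mean(err <= 50)      # 1.0

map <- assign_contacts(shifted, calls)
map
#> nuc_contact_map: 315 nodes, 2945 edges, 7457 contacts (0 self, 0 skipped)
```

315 calls recover the 314 planted dyads with a 4 bp median error, every
true dyad matched within 50 bp. The map has zero self contacts — both
ends of a ligation always land on different nucleosomes — and its
recovered contact profile peaks at the repeat length (first peak at the
192.5 bp histogram bin). Regional folding-motif preference works directly
on label vectors:

```r
lab <- function(a, b) factor(c(rep("alpha", a), rep("beta", b)),
                             levels = c("alpha", "beta"))
folding_ratio(lab(692, 308), lab(514, 486))
#> folding ratio 2.124 (local 692/308 alpha/beta vs genome 514/486)
```

A local region that is 69.2% alpha against a 51.4%-alpha genome has a
folding ratio of 2.12 — a strong alpha-tetrahedron preference.

There is also a thin CLI over the same functions
(`exec/dyadmap simulate|prep|call|occupancy|cmap|run`) and a pipeline
driver, `run_pipeline()`, that executes the stages
prep -> binding -> call -> occupancy -> cmap -> motifs and writes each
artifact plus the hashed run configuration to an output directory.

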