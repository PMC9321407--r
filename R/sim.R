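#' Ground-truth description of a synthetic nucleosome array
#'
#' A `truth_set` describes one synthetic chromosome: planted dyad positions
#' with a fixed repeat length, the per-cell positioning jitter, the core-DNA
#' read size, and the contact distance-decay exponent. It is the ground truth
#' against which every downstream module can be validated.
#'
#' @param chrom_length Chromosome length in bp.
#' @param nrl Nucleosome repeat length (mean dyad spacing) in bp; must exceed
#'   the 147 bp nucleosome footprint.
#' @param positioning_sd Per-cell dyad jitter (bp standard deviation); 0 gives
#'   perfectly positioned arrays.
#' @param read_size Core-DNA read size in bp (the paper's anchor reads are
#'   ~120-170 bp; the simulator uses a single fixed size).
#' @param decay_exponent Power-law exponent gamma > 0 of the contact
#'   distance-decay P(|i - j| = k) proportional to k^(-gamma).
#' @param seed Integer seed stored with the truth set.
#' @param dyads Optional explicit dyad positions (1-based, strictly
#'   increasing); default is a regular array spaced by `nrl`.
#' @param chrom Chromosome name used in all emitted files.
#' @return An object of class `truth_set`.
#' @export
truth_set <- function(chrom_length, nrl = 190L, positioning_sd = 20,
                      read_size = 70L, decay_exponent = 1.5, seed = 1L,
                      dyads = NULL, chrom = "chrS") {
  stopifnot(chrom_length > 147, nrl > 146, positioning_sd >= 0,
            read_size > 0, decay_exponent > 0)
  if (is.null(dyads)) {
    dyads <- seq.int(from = nrl, to = chrom_length - nrl, by = nrl)
  }
  dyads <- as.integer(dyads)
  if (length(dyads) < 1L || any(diff(dyads) <= 0L) ||
      dyads[1L] < 1L || dyads[length(dyads)] > chrom_length) {
    stop("dyads must be strictly increasing and lie within [1, chrom_length]")
  }
  structure(list(chrom = chrom, chrom_length = as.integer(chrom_length),
                 dyads = dyads, nrl = as.integer(nrl),
                 positioning_sd = positioning_sd,
                 read_size = as.integer(read_size),
                 decay_exponent = decay_exponent, seed = as.integer(seed)),
            class = "truth_set")
}

#' @method print truth_set
#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf(
    "truth_set: %s (%d bp), %d dyads, NRL %d, jitter sd %.1f, read size %d\n",
    x$chrom, x$chrom_length, length(x$dyads), x$nrl, x$positioning_sd,
    x$read_size))
  invisible(x)
}

.WW_DINUCS <- c("AA", "AT", "TA", "TT")

#' Simulate a genome with 10 bp-phased AA/AT/TA/TT dinucleotide bias
#'
#' Draws an i.i.d. uniform background sequence and, within +/-73 bp of each
#' planted dyad, rewrites dinucleotides at 10 bp phase relative to the dyad so
#' that the probability of an AA/AT/TA/TT dinucleotide at those phase
#' positions is `background + motif_strength` (background is 0.25 for a
#' uniform genome). This emulates the ~10 bp periodic AA/AT/TA/TT preference
#' of nucleosomal DNA.
#'
#' @param truth A [truth_set()].
#' @param motif_strength Added AA/AT/TA/TT probability at phase positions, in
#'   [0, 0.5].
#' @param seed Integer seed (defaults to the truth set's seed).
#' @return A [Biostrings::DNAStringSet] of length one named after the
#'   chromosome, with the `truth_set` attached as attribute `"truth"`.
#' @export
make_genome <- function(truth, motif_strength = 0.3, seed = truth$seed) {
  stopifnot(inherits(truth, "truth_set"),
            motif_strength >= 0, motif_strength <= 0.5)
  L <- truth$chrom_length
  if (L < 147L) stop("chromosome too small to hold one nucleosome footprint")
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  if (motif_strength > 0) {
    # phase positions: dyad + 10k for |10k| <= 73 -> offsets -70..70 step 10
    off <- seq.int(-70L, 70L, by = 10L)
    pos <- as.vector(outer(truth$dyads, off, `+`))
    pos <- pos[pos >= 1L & pos <= L - 1L]
    # overwrite with prob q so that q + (1-q)*0.25 = 0.25 + motif_strength
    q <- motif_strength / 0.75
    hit <- pos[stats::runif(length(pos)) < q]
    if (length(hit)) {
      dn <- .WW_DINUCS[sample.int(4L, length(hit), replace = TRUE)]
      base[hit] <- substr(dn, 1L, 1L)
      base[hit + 1L] <- substr(dn, 2L, 2L)
    }
  }
  g <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(g) <- truth$chrom
  attr(g, "truth") <- truth
  g
}

#' Simulate Micro-C-like contact pairs around planted dyads
#'
#' Each contact picks a nucleosome i uniformly and a partner j != i with
#' probability proportional to `|i-j|^-gamma` (truncated at `max_sep`
#' nucleosomes), jitters both dyads independently by the per-cell positioning
#' sd, draws each end's strand uniformly, and places the 5' mapped coordinate
#' of a `+` end at (jittered dyad - read_size/2) and of a `-` end at
#' (jittered dyad + read_size/2). With that geometry the four strand types
#' (++, +-, -+, --) differ systematically in contact distance: for the same
#' nucleosome pair, +- spans both cores (distance + read_size), -+ spans only
#' the linker (distance - read_size), and ++/-- sit in between.
#'
#' @param truth A [truth_set()] with at least 2 dyads.
#' @param n_contacts Number of contacts to draw (>= 1).
#' @param seed Integer seed.
#' @param max_sep Maximum nucleosome-index separation sampled.
#' @return A `data.table` of contact records (see [parse_pairs()] for the
#'   column contract), normalized so `pos1 <= pos2`.
#' @export
simulate_contacts <- function(truth, n_contacts, seed = truth$seed,
                              max_sep = 50L) {
  stopifnot(inherits(truth, "truth_set"))
  if (length(truth$dyads) < 2L) stop("need at least 2 dyads to form contacts")
  if (n_contacts < 1L) stop("n_contacts must be >= 1")
  set.seed(seed)
  N <- length(truth$dyads)
  kmax <- min(max_sep, N - 1L)
  pk <- (seq_len(kmax))^(-truth$decay_exponent)
  pk <- pk / sum(pk)
  i <- sample.int(N, n_contacts, replace = TRUE)
  k <- sample.int(kmax, n_contacts, replace = TRUE, prob = pk)
  dir <- sample(c(-1L, 1L), n_contacts, replace = TRUE)
  j <- i + dir * k
  bad <- which(j < 1L | j > N)
  while (length(bad)) {              # redraw direction/offset near the edges
    dir[bad] <- sample(c(-1L, 1L), length(bad), replace = TRUE)
    k[bad] <- sample.int(kmax, length(bad), replace = TRUE, prob = pk)
    j[bad] <- i[bad] + dir[bad] * k[bad]
    bad <- bad[j[bad] < 1L | j[bad] > N]
  }
  jit <- function(idx) truth$dyads[idx] +
    if (truth$positioning_sd > 0)
      stats::rnorm(n_contacts, 0, truth$positioning_sd) else 0
  p1 <- jit(i); p2 <- jit(j)
  s1 <- sample(c("+", "-"), n_contacts, replace = TRUE)
  s2 <- sample(c("+", "-"), n_contacts, replace = TRUE)
  half <- truth$read_size / 2
  end5 <- function(p, s) as.integer(round(ifelse(s == "+", p - half, p + half)))
  x1 <- pmin(pmax(end5(p1, s1), 1L), truth$chrom_length)
  x2 <- pmin(pmax(end5(p2, s2), 1L), truth$chrom_length)
  rec <- data.table::data.table(
    readID = sprintf("sim%07d", seq_len(n_contacts)),
    chrom1 = truth$chrom, pos1 = x1, strand1 = s1,
    chrom2 = truth$chrom, pos2 = x2, strand2 = s2)
  normalize_records(rec)
}

#' Simulate a per-base coverage track from planted dyads
#'
#' For each dyad, `depth` pseudo-reads of 147 bp are centered at
#' Normal(dyad, sd) and added to a per-base coverage vector (clipped at the
#' chromosome ends).
#'
#' @param truth A [truth_set()].
#' @param depth Pseudo-reads per nucleosome (>= 1).
#' @param sd Center jitter in bp.
#' @param seed Integer seed.
#' @return Integer vector of per-base coverage (length `chrom_length`).
#' @export
make_coverage <- function(truth, depth = 20L, sd = truth$positioning_sd,
                          seed = truth$seed) {
  stopifnot(inherits(truth, "truth_set"), depth >= 1)
  set.seed(seed)
  n <- length(truth$dyads) * depth
  ctr <- rep(truth$dyads, each = depth)
  if (sd > 0) ctr <- as.integer(round(ctr + stats::rnorm(n, 0, sd)))
  L <- truth$chrom_length
  s <- pmax(ctr - 73L, 1L)
  e <- pmin(ctr + 73L, L)
  # difference-array accumulation of [s, e] increments
  d <- integer(L + 1L)
  ts <- tabulate(s, nbins = L)
  te <- tabulate(e + 1L, nbins = L + 1L)
  d[seq_len(L)] <- ts
  d <- d - te
  cumsum(d[seq_len(L)])
}

#' Sample alpha/beta folding-motif labels from local contact intensity
#'
#' Labels are drawn independently with P(alpha) increasing linearly in the
#' tetra-nucleosome feature sum: `P(alpha) = 0.5 + slope * (sum - mean(sum))`.
#' This emulates the observed trend that contact-dense neighborhoods form
#' more alpha-tetrahedra.
#'
#' @param contact_sums Numeric vector of per-nucleosome feature sums (or a
#'   tetra-feature table containing a `contact_sum` column).
#' @param slope Probability increment per contact.
#' @param seed Integer seed.
#' @return Factor with levels `alpha`, `beta`.
#' @export
make_tetra_labels <- function(contact_sums, slope = 0, seed = 1L) {
  if (is.data.frame(contact_sums)) contact_sums <- contact_sums$contact_sum
  stopifnot(is.numeric(contact_sums), length(contact_sums) >= 1L)
  p <- 0.5 + slope * (contact_sums - mean(contact_sums))
  if (any(p < 0 | p > 1)) {
    stop("slope too large: resulting probabilities fall outside [0, 1]")
  }
  set.seed(seed)
  factor(ifelse(stats::runif(length(p)) < p, "alpha", "beta"),
         levels = c("alpha", "beta"))
}

#' Write a truth set's dyads as a BED file of 1 bp intervals
#' @param truth A [truth_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  dt <- data.table::data.table(chrom = truth$chrom,
                               start = truth$dyads - 1L, end = truth$dyads,
                               name = sprintf("dyad_%d", seq_along(truth$dyads)))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a per-base coverage track as a samtools-depth-style TSV
#' @param coverage Integer coverage vector.
#' @param chrom Chromosome name.
#' @param path Output path.
#' @param keep_zero Write zero-coverage positions too (default TRUE, matching
#'   `samtools depth -a`).
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(coverage, chrom, path, keep_zero = TRUE) {
  dt <- data.table::data.table(chrom = chrom, pos = seq_along(coverage),
                               depth = coverage)
  if (!keep_zero) dt <- dt[dt$depth > 0L, ]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
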