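# Nucleosome-node contact maps: contact-to-dyad assignment, recovered
# contact profiles, distance errors, the Erlang expected-pair model and
# observed/expected normalization, and anchor pileups.

# nearest called dyad for positions on one chromosome; ties -> lower dyad
.nearest_node <- function(pos, dyads) {
  k <- findInterval(pos, dyads)
  left <- pmax(k, 1L)
  right <- pmin(k + 1L, length(dyads))
  d_left <- abs(pos - dyads[left])
  d_right <- abs(dyads[right] - pos)
  ifelse(k == 0L, right,
         ifelse(k >= length(dyads), left,
                ifelse(d_left <= d_right, left, right)))
}

#' Assign contact ends to their nearest called nucleosomes
#'
#' Each end of every intra-chromosomal (center-shifted) contact is assigned
#' to the nearest called dyad (ties to the lower-coordinate dyad), producing
#' a nucleosome-node contact map. Contacts on chromosomes without calls are
#' skipped and counted. Self pairs (both ends assigned to the same node) are
#' retained in the edge list and reported via `self_count`.
#'
#' @param rec Center-shifted, filtered contact record `data.table`.
#' @param calls Nucleosome call table, sorted.
#' @return An object of class `nuc_contact_map`: `nodes` (data.table chrom,
#'   dyad, node), `edges` (node_i <= node_j with `count` and `dist`),
#'   `assignments` (one row per assigned contact: node_i, node_j, pos1,
#'   pos2), `self_count`, `skipped`.
#' @export
assign_contacts <- function(rec, calls) {
  rec <- data.table::as.data.table(rec)
  intra <- rec[rec$chrom1 == rec$chrom2, ]
  nodes <- data.table::data.table(chrom = calls$chrom, dyad = calls$dyad)
  data.table::setorderv(nodes, c("chrom", "dyad"))
  data.table::set(nodes, NULL, "node", seq_len(nrow(nodes)))
  asn <- list()
  skipped <- 0L
  for (ch in unique(intra$chrom1)) {
    sub <- intra[intra$chrom1 == ch, ]
    nd <- nodes[nodes$chrom == ch, ]
    if (nrow(nd) == 0L) { skipped <- skipped + nrow(sub); next }
    i1 <- .nearest_node(sub$pos1, nd$dyad)
    i2 <- .nearest_node(sub$pos2, nd$dyad)
    asn[[ch]] <- data.table::data.table(
      chrom = ch,
      node_i = nd$node[pmin(i1, i2)], node_j = nd$node[pmax(i1, i2)],
      pos1 = sub$pos1, pos2 = sub$pos2)
  }
  assignments <- if (length(asn)) data.table::rbindlist(asn) else
    data.table::data.table(chrom = character(), node_i = integer(),
                           node_j = integer(), pos1 = integer(),
                           pos2 = integer())
  edges <- assignments[, list(count = .N), by = c("chrom", "node_i", "node_j")]
  data.table::set(edges, NULL, "dist",
                  abs(nodes$dyad[edges$node_j] - nodes$dyad[edges$node_i]))
  data.table::setorderv(edges, c("chrom", "node_i", "node_j"))
  structure(list(nodes = nodes, edges = edges, assignments = assignments,
                 self_count = sum(assignments$node_i == assignments$node_j),
                 skipped = skipped),
            class = "nuc_contact_map")
}

#' @method print nuc_contact_map
#' @export
print.nuc_contact_map <- function(x, ...) {
  cat(sprintf(
    "nuc_contact_map: %d nodes, %d edges, %d contacts (%d self, %d skipped)\n",
    nrow(x$nodes), nrow(x$edges), nrow(x$assignments), x$self_count,
    x$skipped))
  invisible(x)
}

#' Recovered contact profile
#'
#' Histogram of inter-dyad genomic distances over all assigned contacts.
#' When the calls are accurate this reproduces the repeat-length peak
#' structure of the raw contact-distance profile.
#'
#' @param map A `nuc_contact_map`.
#' @param binwidth Bin width, bp.
#' @param max_d Largest distance tabulated, bp.
#' @return `data.table` with `mid` (bin midpoint) and `count`.
#' @export
recovered_profile <- function(map, binwidth = 5L, max_d = 2000L) {
  if (nrow(map$assignments) == 0L) stop("no assigned contacts")
  d <- abs(map$nodes$dyad[map$assignments$node_j] -
             map$nodes$dyad[map$assignments$node_i])
  d <- d[d <= max_d]
  bin <- d %/% binwidth
  tab <- tabulate(bin + 1L, nbins = max_d %/% binwidth + 1L)
  data.table::data.table(
    mid = (seq_along(tab) - 1L) * binwidth + binwidth / 2,
    count = tab)
}

#' Per-contact distance error after node assignment
#'
#' For every assigned contact, the recovered inter-dyad distance minus the
#' original center distance. Symmetric, zero-centered errors indicate that
#' the called nodes faithfully represent the read distribution.
#'
#' @param map A `nuc_contact_map`.
#' @return Numeric vector of errors (bp), one per assigned contact.
#' @export
distance_error <- function(map) {
  a <- map$assignments
  if (nrow(a) == 0L) stop("no assigned contacts")
  (map$nodes$dyad[a$node_j] - map$nodes$dyad[a$node_i]) - (a$pos2 - a$pos1)
}

#' Expected number of nucleosome pairs in a genomic-distance interval
#'
#' Under a homogeneous model in which nucleosomes occur at rate
#' `N_nuc / L` per bp, the distance between the i-th and (i+k)-th
#' nucleosome is Erlang(k, rate) distributed, so the expected number of
#' pairs with distance in `[d1, d2)` is
#' `sum_k (N_nuc - k) * [ErlangCDF(d2; k) - ErlangCDF(d1; k)]`. The k-sum
#' is truncated to `max(1, d1/150 - 20) <= k <= min(N_nuc, d2/150 + 20)`,
#' which keeps essentially all the mass while avoiding the O(n^2) pair
#' enumeration.
#'
#' @param d1,d2 Interval bounds, bp (`0 <= d1 <= d2`).
#' @param n_nuc Number of nucleosomes (>= 2).
#' @param chrom_length Chromosome length, bp.
#' @param truncate Use the k-range truncation (default) or the full sum.
#' @param k_range Optional explicit integer vector of neighbor lags k,
#'   overriding the truncation rule.
#' @return Expected pair count.
#' @export
expected_pairs <- function(d1, d2, n_nuc, chrom_length, truncate = TRUE,
                           k_range = NULL) {
  if (d1 > d2) stop("d1 must not exceed d2")
  stopifnot(d1 >= 0, n_nuc >= 2, chrom_length > 0)
  rate <- n_nuc / chrom_length
  if (!is.null(k_range)) {
    k <- k_range
    return(sum((n_nuc - k) *
                 (stats::pgamma(d2, shape = k, rate = rate) -
                    stats::pgamma(d1, shape = k, rate = rate))))
  }
  k_lo <- if (truncate) max(1, floor(d1 / 150) - 20) else 1
  k_hi <- if (truncate) min(n_nuc - 1, ceiling(d2 / 150) + 20) else n_nuc - 1
  if (k_hi < k_lo) return(0)
  k <- seq.int(k_lo, k_hi)
  sum((n_nuc - k) *
        (stats::pgamma(d2, shape = k, rate = rate) -
           stats::pgamma(d1, shape = k, rate = rate)))
}

#' Fit the Erlang expected-contact model on a contact map
#'
#' Bins genomic distance (50 bp bins up to `linear_max`, then multiplicative
#' 1.2x bins), computes the expected pair count `NP` per bin with
#' [expected_pairs()] and the observed contact total `N_c` per bin, and
#' derives the per-bin expected contact count `C_exp = N_c / NP`. Bins with
#' `NP = 0` or `N_c = 0` are flagged.
#'
#' @param map A `nuc_contact_map` (single chromosome).
#' @param chrom_length Chromosome length, bp.
#' @param linear_max Upper end of the 50 bp linear bins.
#' @return Object of class `expected_model`: `breaks`, `np`, `nc`, `c_exp`,
#'   `flagged`, `n_nuc`, `chrom_length`.
#' @export
expected_model <- function(map, chrom_length, linear_max = 2000L) {
  ch <- unique(map$nodes$chrom)
  if (length(ch) != 1L) stop("expected model is fitted per chromosome")
  n_nuc <- nrow(map$nodes)
  max_d <- max(map$edges$dist, linear_max) + 1
  breaks <- seq.int(0L, linear_max, by = 50L)
  b <- linear_max
  while (b < max_d) { b <- b * 1.2; breaks <- c(breaks, b) }
  np <- vapply(seq_len(length(breaks) - 1L), function(i) {
    expected_pairs(breaks[i], breaks[i + 1L], n_nuc, chrom_length)
  }, numeric(1))
  bin <- findInterval(map$edges$dist, breaks, rightmost.closed = FALSE)
  bin[bin < 1L] <- 1L
  nc <- vapply(seq_len(length(breaks) - 1L), function(i) {
    sum(map$edges$count[bin == i])
  }, numeric(1))
  c_exp <- ifelse(np > 0 & nc > 0, nc / np, NA_real_)
  structure(list(breaks = breaks, np = np, nc = nc, c_exp = c_exp,
                 flagged = np == 0 | nc == 0, n_nuc = n_nuc,
                 chrom_length = chrom_length),
            class = "expected_model")
}

#' Observed/expected normalization of a nucleosome contact map
#'
#' Divides each edge's observed contact count by the expected contact count
#' of its distance bin (`C_OE = C_obs / C_exp(d)`). Edges in flagged bins
#' get `NA`.
#'
#' @param map A `nuc_contact_map`.
#' @param model An [expected_model()] fitted on the same chromosome.
#' @return The map with an `oe` column added to `edges`.
#' @export
oe_normalize <- function(map, model) {
  bin <- findInterval(map$edges$dist, model$breaks)
  bin[bin < 1L] <- 1L
  bin[bin > length(model$c_exp)] <- length(model$c_exp)
  oe <- map$edges$count / model$c_exp[bin]
  data.table::set(map$edges, NULL, "oe", oe)
  map$model <- model
  map
}

# dense symmetric OE (or count) submatrix for node range lo..hi
.submatrix <- function(map, lo, hi, value = "oe") {
  n <- hi - lo + 1L
  M <- matrix(0, n, n)
  e <- map$edges[map$edges$node_i >= lo & map$edges$node_i <= hi &
                   map$edges$node_j >= lo & map$edges$node_j <= hi, ]
  if (nrow(e)) {
    v <- e[[value]]
    M[cbind(e$node_i - lo + 1L, e$node_j - lo + 1L)] <- v
    M[cbind(e$node_j - lo + 1L, e$node_i - lo + 1L)] <- v
  }
  M
}

#' Pileup of OE submatrices at anchor features
#'
#' For each anchor interval, the node nearest to the anchor midpoint becomes
#' the center of a `(2*flank_n+1)`-node square OE submatrix; anchors whose
#' window exceeds the node range of their chromosome are skipped and
#' counted. Returns the element-wise mean matrix.
#'
#' @param map An OE-normalized `nuc_contact_map`.
#' @param anchors `data.table`/data.frame with `chrom`, `start`, `end`
#'   (0-based half-open, as in BED).
#' @param flank_n Number of flanking nodes on each side.
#' @param value Edge column to aggregate (`"oe"` or `"count"`).
#' @return Mean matrix with attributes `n_used` and `n_skipped`.
#' @export
pileup <- function(map, anchors, flank_n = 10L, value = "oe") {
  if (value == "oe" && is.null(map$edges$oe)) {
    stop("run oe_normalize() first")
  }
  anchors <- data.table::as.data.table(anchors)
  size <- 2L * flank_n + 1L
  acc <- matrix(0, size, size)
  n_used <- 0L; n_skipped <- 0L
  for (r in seq_len(nrow(anchors))) {
    nd <- map$nodes[map$nodes$chrom == anchors$chrom[r], ]
    if (nrow(nd) == 0L) { n_skipped <- n_skipped + 1L; next }
    mid <- (anchors$start[r] + anchors$end[r]) / 2
    ctr <- nd$node[.nearest_node(mid, nd$dyad)]
    lo <- ctr - flank_n; hi <- ctr + flank_n
    if (lo < min(nd$node) || hi > max(nd$node)) {
      n_skipped <- n_skipped + 1L
      next
    }
    M <- .submatrix(map, lo, hi, value)
    M[is.na(M)] <- 0
    acc <- acc + M
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no usable anchors")
  out <- acc / n_used
  attr(out, "n_used") <- n_used
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a nucleosome contact map as sparse triplets plus a node BED
#' @param map A `nuc_contact_map`.
#' @param path Output TSV path (`node_i`, `node_j`, `count`, `oe`); the node
#'   table goes to `paste0(path, ".nodes.bed")`.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path) {
  e <- data.table::copy(map$edges)
  if (is.null(e$oe)) data.table::set(e, NULL, "oe", NA_real_)
  data.table::fwrite(
    e[, c("node_i", "node_j", "count", "oe"), with = FALSE], path,
    sep = "\t", na = "NA")
  nb <- data.table::data.table(chrom = map$nodes$chrom,
                               start = map$nodes$dyad - 1L,
                               end = map$nodes$dyad,
                               name = sprintf("node_%d", map$nodes$node))
  data.table::fwrite(nb, paste0(path, ".nodes.bed"), sep = "\t",
                     col.names = FALSE)
  invisible(path)
}
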