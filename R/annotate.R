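# Mapping genomic features to mono-nucleosomes. Three assignment modes:
# peaks go to the single nearest dyad, regulatory elements / TAD boundaries
# / loop anchors flag every dyad within +/-500bp, and compartments / SPIN
# states / stripes flag dyads inside their span.

#' Read a BED or narrowPeak file into a feature table
#'
#' Keeps 0-based half-open `start`/`end` as in the file. For narrowPeak
#' (10 columns) a `center` column is derived from the summit offset when it
#' is non-negative, otherwise from the interval midpoint; for plain BED the
#' midpoint is used. Centers are 1-based positions.
#'
#' @param path BED/narrowPeak path.
#' @return `data.table` with `chrom`, `start`, `end`, `center`.
#' @export
read_features_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  data.table::setnames(dt, 1:3, c("chrom", "start", "end"))
  center <- (dt$start + dt$end) / 2 + 0.5       # 1-based midpoint
  if (ncol(dt) >= 10L) {
    summit <- dt[[10L]]
    has <- !is.na(summit) & summit >= 0
    center[has] <- dt$start[has] + summit[has] + 1L   # 1-based summit
  }
  data.table::data.table(chrom = dt$chrom, start = dt$start, end = dt$end,
                         center = center)
}

.calls_gr <- function(calls) {
  GenomicRanges::GRanges(calls$chrom,
                         IRanges::IRanges(calls$dyad, width = 1L))
}

#' Flag the nucleosome nearest to each peak center
#'
#' Each feature's center is assigned to the single nearest dyad on its
#' chromosome (ties to the lower-coordinate dyad); peak strengths are
#' ignored. Returns one logical per call.
#'
#' @param calls Nucleosome call table.
#' @param features Feature table ([read_features_bed()]) or anything with
#'   `chrom` and `center` columns.
#' @return Logical vector along `calls`.
#' @export
assign_nearest <- function(calls, features) {
  flags <- logical(nrow(calls))
  for (ch in unique(features$chrom)) {
    rows <- which(calls$chrom == ch)
    if (!length(rows)) next
    dy <- calls$dyad[rows]
    ctr <- features$center[features$chrom == ch]
    hit <- .nearest_node(ctr, dy)
    flags[rows[unique(hit)]] <- TRUE
  }
  flags
}

#' Flag nucleosomes within a +/- flank of feature intervals
#'
#' A dyad is flagged when its distance to the nearest point of any interval
#' (half-open, BED convention) is at most `flank` bp. Dyads inside an
#' interval have distance 0.
#'
#' @param calls Nucleosome call table.
#' @param features Feature table with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param flank Neighborhood half width, bp.
#' @return Logical vector along `calls`.
#' @export
assign_window <- function(calls, features, flank = 500L) {
  gr_n <- .calls_gr(calls)
  gr_f <- GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(features$start + 1L, features$end))   # to 1-based
  hits <- GenomicRanges::findOverlaps(gr_n, gr_f + flank)
  flags <- logical(nrow(calls))
  flags[unique(S4Vectors::queryHits(hits))] <- TRUE
  flags
}

#' Flag nucleosomes inside the span of feature intervals
#'
#' A dyad is flagged when it falls inside a half-open interval
#' `[start, end)`; a dyad exactly at `end` is outside.
#'
#' @inheritParams assign_window
#' @return Logical vector along `calls`.
#' @export
assign_span <- function(calls, features) {
  assign_window(calls, features, flank = 0L)
}

#' Average genomic distance of local contacts at flagged nucleosomes
#'
#' The count-weighted mean inter-dyad distance over contact-map edges with
#' distance at most `max_d` and at least one flagged endpoint. Longer
#' averages indicate more compact local nucleosome packing (more distal
#' neighbors in contact); shorter averages a more relaxed fiber.
#'
#' @param map A `nuc_contact_map`.
#' @param flags Logical vector along `map$nodes` (i.e. along the calls the
#'   map was built from).
#' @param max_d Maximum contact distance considered "local", bp.
#' @return Weighted mean distance in bp (NA when no qualifying contacts).
#' @export
avg_local_contact_distance <- function(map, flags, max_d = 1000L) {
  stopifnot(length(flags) == nrow(map$nodes))
  e <- map$edges
  use <- e$dist <= max_d & (flags[e$node_i] | flags[e$node_j])
  if (!any(use)) return(NA_real_)
  stats::weighted.mean(e$dist[use], e$count[use])
}

#' Annotate nucleosome calls with multiple feature classes
#'
#' Applies the per-class assignment rule (`nearest`, `window`, or `span`)
#' and returns the binary annotation matrix.
#'
#' @param calls Nucleosome call table.
#' @param feature_sets Named list; each element a list with `features` (a
#'   feature table) and `mode` (one of `"nearest"`, `"window"`, `"span"`),
#'   plus optional `flank`.
#' @return `data.table`: calls columns plus one logical column per set.
#' @export
annotate_calls <- function(calls, feature_sets) {
  out <- data.table::as.data.table(calls)
  for (nm in names(feature_sets)) {
    fs <- feature_sets[[nm]]
    flags <- switch(fs$mode,
      nearest = assign_nearest(calls, fs$features),
      window = assign_window(calls, fs$features,
                             flank = if (is.null(fs$flank)) 500L else
                               fs$flank),
      span = assign_span(calls, fs$features),
      stop("unknown annotation mode: ", fs$mode))
    data.table::set(out, NULL, nm, flags)
  }
  out
}
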