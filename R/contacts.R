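# Contact-pair parsing, type classification, read-size estimation, center
# shifting and the short-distance filter.
#
# A contact record table has columns:
#   readID, chrom1, pos1, strand1, chrom2, pos2, strand2, type
# pos* are 1-based 5' mapped coordinates. Intra-chromosomal records are stored
# with pos1 <= pos2 (ends swapped consistently); `type` is the strand pair in
# genomic order ("++", "+-", "-+", "--").

#' Normalize contact records to genomic order and derive contact types
#'
#' Swaps the two ends of intra-chromosomal records so that `pos1 <= pos2`
#' (strands travel with their ends) and recomputes the contact `type`.
#'
#' @param rec A contact record `data.table`.
#' @return The normalized `data.table` (a copy).
#' @export
normalize_records <- function(rec) {
  rec <- data.table::as.data.table(rec)
  swap <- rec$chrom1 == rec$chrom2 & rec$pos1 > rec$pos2
  if (any(swap)) {
    tmp_p <- rec$pos1[swap]; tmp_s <- rec$strand1[swap]
    data.table::set(rec, which(swap), "pos1", rec$pos2[swap])
    data.table::set(rec, which(swap), "strand1", rec$strand2[swap])
    data.table::set(rec, which(swap), "pos2", tmp_p)
    data.table::set(rec, which(swap), "strand2", tmp_s)
  }
  data.table::set(rec, NULL, "type", paste0(rec$strand1, rec$strand2))
  rec
}

#' Parse a contact pair file
#'
#' Reads either the 4DN `.pairs` dialect (columns `readID chrom1 pos1 chrom2
#' pos2 strand1 strand2`, `#`-prefixed header lines skipped) or a 7-column
#' BEDPE-like TSV (`chrom1 pos1 strand1 chrom2 pos2 strand2 name`). Records
#' are normalized to genomic order (`pos1 <= pos2` for intra-chromosomal
#' contacts) and annotated with their strand type.
#'
#' @param path Path to the pair file.
#' @param dialect `"pairs"` (default) or `"bedpe"`.
#' @return A contact record `data.table` with an `inter` logical column
#'   flagging inter-chromosomal records.
#' @export
parse_pairs <- function(path, dialect = c("pairs", "bedpe")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pair file not found: ", path)
  first <- readLines(path, n = 1000L)
  n_header <- match(FALSE, startsWith(first, "#"), nomatch = NA_integer_) - 1L
  if (is.na(n_header)) {
    n_header <- if (length(first) == 1000L)
      stop("more than 1000 header lines; not a pair file?") else length(first)
  }
  dt <- data.table::fread(path, skip = n_header, header = FALSE, sep = "\t",
                          fill = TRUE)
  if (nrow(dt) == 0L) {
    return(normalize_records(data.table::data.table(
      readID = character(), chrom1 = character(), pos1 = integer(),
      strand1 = character(), chrom2 = character(), pos2 = integer(),
      strand2 = character()))[, `:=`(inter = logical())][])
  }
  cols <- switch(dialect,
    pairs = c(readID = 1L, chrom1 = 2L, pos1 = 3L, chrom2 = 4L, pos2 = 5L,
              strand1 = 6L, strand2 = 7L),
    bedpe = c(chrom1 = 1L, pos1 = 2L, strand1 = 3L, chrom2 = 4L, pos2 = 5L,
              strand2 = 6L, readID = 7L))
  if (ncol(dt) < max(cols)) {
    stop(sprintf("expected >= %d columns for dialect '%s', found %d",
                 max(cols), dialect, ncol(dt)))
  }
  rec <- data.table::data.table(
    readID = as.character(dt[[cols["readID"]]]),
    chrom1 = as.character(dt[[cols["chrom1"]]]),
    pos1 = as.integer(dt[[cols["pos1"]]]),
    strand1 = as.character(dt[[cols["strand1"]]]),
    chrom2 = as.character(dt[[cols["chrom2"]]]),
    pos2 = as.integer(dt[[cols["pos2"]]]),
    strand2 = as.character(dt[[cols["strand2"]]]))
  ok <- rec$strand1 %in% c("+", "-") & rec$strand2 %in% c("+", "-")
  if (!all(ok)) {
    stop(sprintf("unknown strand symbol at line %d of %s",
                 n_header + which(!ok)[1L], path))
  }
  rec <- normalize_records(rec)
  data.table::set(rec, NULL, "inter", rec$chrom1 != rec$chrom2)
  rec
}

#' Write contact records as a 4DN-style `.pairs` file
#' @param rec Contact record `data.table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(rec, path) {
  writeLines(c("## pairs format v1.0",
               "#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2"),
             path)
  if (nrow(rec)) {
    data.table::fwrite(
      rec[, c("readID", "chrom1", "pos1", "chrom2", "pos2",
              "strand1", "strand2"), with = FALSE],
      path, sep = "\t", col.names = FALSE, append = TRUE)
  }
  invisible(path)
}

# first local maximum of the smoothed histogram with topographic prominence
# >= `prominence` of the global maximum (prominence = height above the
# deepest valley separating the peak from any higher point, so noise bumps
# on a rising flank are rejected)
.first_peak <- function(counts, smooth_window = 11L, prominence = 0.1) {
  sm <- stats::filter(counts, rep(1 / smooth_window, smooth_window),
                      sides = 2L)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)
  n <- length(sm)
  if (n < 3L) return(NA_integer_)
  is_pk <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] &
                    sm[2:(n - 1)] >= sm[3:n], FALSE)
  thr <- prominence * max(sm)
  for (p in which(is_pk)) {
    h <- sm[p]
    left <- sm[seq_len(p - 1L)]
    hi_l <- which(left > h)
    vl <- if (length(hi_l)) min(left[(max(hi_l) + 1L):(p - 1L)]) else
      min(c(left, h))
    right <- sm[(p + 1L):n]
    hi_r <- which(right > h)
    vr <- if (length(hi_r)) min(right[seq_len(min(hi_r) - 1L)]) else
      min(c(right, h))
    if (h - max(vl, vr) >= thr) return(p)
  }
  NA_integer_
}

#' Estimate the average read size from contact-distance histograms
#'
#' For the same nucleosome pair, a `+-` contact spans both nucleosome cores
#' while a `++` contact spans one, so their contact-distance histograms are
#' offset by one average read size. The estimator builds 1 bp-bin histograms
#' of short-range `+-` and `++` distances, smooths each with an 11 bp moving
#' average, locates the first local maximum with prominence >= 10% of the
#' global maximum, and returns the difference of the two first-peak centers.
#'
#' @param rec Contact record `data.table` (raw 5' coordinates, not yet
#'   center-shifted).
#' @param max_dist Distances above this are ignored ("short-range"), bp.
#' @param min_count Minimum number of usable records per type.
#' @param band Plausibility band (bp); estimates outside it raise an error
#'   suggesting a manual read size.
#' @return Estimated read size in bp.
#' @export
estimate_read_size <- function(rec, max_dist = 1000L, min_count = 500L,
                               band = c(20, 120)) {
  intra <- rec[rec$chrom1 == rec$chrom2, ]
  d <- intra$pos2 - intra$pos1
  peak_of <- function(type) {
    dd <- d[intra$type == type & d >= 1L & d <= max_dist]
    if (length(dd) < min_count) {
      stop(sprintf(
        "only %d short-range '%s' contacts (< %d); supply the read size manually",
        length(dd), type, min_count))
    }
    .first_peak(tabulate(dd, nbins = max_dist))
  }
  rs <- peak_of("+-") - peak_of("++")
  if (is.na(rs) || rs < band[1] || rs > band[2]) {
    stop(sprintf(
      "estimated read size %s outside plausibility band [%g, %g]; supply it manually",
      format(rs), band[1], band[2]))
  }
  rs
}

#' Shift contact ends to their estimated read centers
#'
#' Moves every end half a read size towards its 3' direction: `+` ends by
#' `+floor(read_size/2)`, `-` ends by `-floor(read_size/2)` (the floor keeps
#' the two strands symmetric for odd sizes). Coordinates are clipped at 1 and,
#' when chromosome lengths are supplied, at the chromosome end. Records are
#' re-normalized to genomic order afterwards.
#'
#' @param rec Contact record `data.table`.
#' @param read_size Average read size in bp (> 0).
#' @param chrom_lengths Optional named vector of chromosome lengths for upper
#'   clipping.
#' @return Center-shifted, re-normalized contact record `data.table`.
#' @export
shift_to_centers <- function(rec, read_size, chrom_lengths = NULL) {
  stopifnot(read_size > 0)
  h <- as.integer(floor(read_size / 2))
  rec <- data.table::copy(data.table::as.data.table(rec))
  shift1 <- ifelse(rec$strand1 == "+", h, -h)
  shift2 <- ifelse(rec$strand2 == "+", h, -h)
  data.table::set(rec, NULL, "pos1", pmax(rec$pos1 + shift1, 1L))
  data.table::set(rec, NULL, "pos2", pmax(rec$pos2 + shift2, 1L))
  if (!is.null(chrom_lengths)) {
    data.table::set(rec, NULL, "pos1",
                    pmin(rec$pos1, chrom_lengths[rec$chrom1]))
    data.table::set(rec, NULL, "pos2",
                    pmin(rec$pos2, chrom_lengths[rec$chrom2]))
  }
  normalize_records(rec)
}

#' Remove short-range contacts after center shifting
#'
#' Drops intra-chromosomal contacts whose center distance is below
#' `min_dist`; both ends of such a contact are excluded. Distances exactly
#' equal to `min_dist` are kept. Inter-chromosomal records pass through.
#'
#' @param rec Center-shifted contact record `data.table`.
#' @param min_dist Minimum retained center distance, bp.
#' @return Filtered `data.table` with attribute `n_dropped`.
#' @export
filter_short <- function(rec, min_dist = 160L) {
  drop <- rec$chrom1 == rec$chrom2 & (rec$pos2 - rec$pos1) < min_dist
  out <- rec[!drop, ]
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Build a per-chromosome read-center set with its contact link table
#'
#' Collects all (center-shifted) contact ends into per-chromosome sorted
#' center arrays and records, for each intra-chromosomal contact, the indices
#' of its two centers. Each center belongs to exactly one contact end.
#'
#' @param rec Center-shifted (and typically short-filtered) contact records.
#' @return An object of class `read_center_set`: a named list per chromosome
#'   with `centers` (sorted integer positions) and `links` (2-column matrix
#'   of center indices, one row per intra-chromosomal contact).
#' @export
read_center_set <- function(rec) {
  rec <- data.table::as.data.table(rec)
  ends <- data.table::rbindlist(list(
    data.table::data.table(chrom = rec$chrom1, pos = rec$pos1,
                           contact = seq_len(nrow(rec)), end = 1L),
    data.table::data.table(chrom = rec$chrom2, pos = rec$pos2,
                           contact = seq_len(nrow(rec)), end = 2L)))
  out <- list()
  for (ch in sort(unique(ends$chrom))) {
    e <- ends[ends$chrom == ch, ]
    ord <- order(e$pos, e$contact, e$end)
    e <- e[ord, ]
    idx_of <- seq_len(nrow(e))
    # link rows: contacts with both ends on this chromosome
    both <- e[, .N, by = "contact"][N == 2L]$contact
    links <- NULL
    if (length(both)) {
      m <- e[e$contact %in% both, ]
      m_idx <- idx_of[e$contact %in% both]
      o <- order(m$contact, m$end)
      links <- matrix(m_idx[o], ncol = 2L, byrow = TRUE)
    } else {
      links <- matrix(integer(), ncol = 2L)
    }
    out[[ch]] <- list(centers = e$pos, links = links)
  }
  structure(out, class = "read_center_set")
}

#' @method print read_center_set
#' @export
print.read_center_set <- function(x, ...) {
  for (ch in names(x)) {
    cat(sprintf("%s: %d centers, %d links\n", ch, length(x[[ch]]$centers),
                nrow(x[[ch]]$links)))
  }
  invisible(x)
}
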