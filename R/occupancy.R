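# Kernel-smoothed, locally normalized nucleosome occupancy. Coverage is
# convolved with a smooth bump kernel and each position is normalized by the
# kernel-mass-scaled sum over a +/-4w neighborhood, giving a statistic that
# approximates the fraction of cells in which a nucleosome covers the
# position.

#' Occupancy smoothing kernel
#'
#' `K(i, w) = (1 - (i/w)^2)^3` for `|i| < w` and 0 outside (strict
#' inequality: the support is the open interval).
#'
#' @param i Offset(s) in bp.
#' @param w Aggregation window in bp (> 0).
#' @return Kernel weight(s).
#' @export
occupancy_kernel <- function(i, w) {
  stopifnot(w > 0)
  ifelse(abs(i) < w, (1 - (i / w)^2)^3, 0)
}

#' Exact occupancy scaling constant
#'
#' The reciprocal of the kernel mass `integral_{-1}^{1} (1 - u^2)^3 du =
#' 32/35`, i.e. 35/32 = 1.09375 (1.09 to two decimals). Dividing the
#' neighborhood sum by `w / scaling` makes a flat track normalize to the
#' kernel's own mass.
#'
#' @return 35/32.
#' @export
occupancy_scaling_constant <- function() 35 / 32

#' Smooth a per-base coverage track with the occupancy kernel
#'
#' `D(i) = sum_j K(i - j, w) d(j)` (discrete convolution; zero-padded at the
#' chromosome ends).
#'
#' @param coverage Non-negative numeric per-base coverage.
#' @param w Kernel window, bp.
#' @return Numeric smoothed track of the same length.
#' @export
smooth_coverage <- function(coverage, w = 30L) {
  stopifnot(all(coverage >= 0))
  L <- length(coverage)
  if (L == 0L) return(numeric(0))
  k <- occupancy_kernel(seq.int(-(w - 1L), w - 1L), w)
  pad <- w - 1L
  x <- c(numeric(pad), coverage, numeric(pad))
  y <- stats::filter(x, k, method = "convolution", sides = 2L)
  as.numeric(y[(pad + 1L):(pad + L)])
}

#' Locally normalized occupancy track
#'
#' `S(i) = D(i) / [ (1 / (c * w)) * sum_{|j - i| <= 4w} D(j) ]` with
#' `c = 35/32` (see [occupancy_scaling_constant()]). Positions with a zero
#' denominator get `S = 0` and are flagged; windows clipped at the
#' chromosome ends are flagged as edge positions.
#'
#' @param D Smoothed track from [smooth_coverage()].
#' @param w Aggregation window, bp (the same `w` used for smoothing).
#' @return List of class `occupancy_track`: `S`, `D`, `w`, `flag_zero`,
#'   `flag_edge`.
#' @export
occupancy_track <- function(D, w = 30L) {
  L <- length(D)
  if (L <= 8L * w + 1L) stop("track shorter than the 8w+1 neighborhood")
  cs <- cumsum(D)
  i <- seq_len(L)
  hi <- pmin(i + 4L * w, L)
  lo <- pmax(i - 4L * w, 1L)
  nb <- cs[hi] - c(0, cs)[lo]
  denom <- nb / (occupancy_scaling_constant() * w)
  S <- ifelse(denom == 0, 0, D / denom)
  structure(list(S = S, D = D, w = as.integer(w),
                 flag_zero = denom == 0,
                 flag_edge = i - 4L * w < 1L | i + 4L * w > L),
            class = "occupancy_track")
}

#' Compute occupancy directly from coverage
#' @inheritParams smooth_coverage
#' @return An `occupancy_track`.
#' @export
occupancy_from_coverage <- function(coverage, w = 30L) {
  occupancy_track(smooth_coverage(coverage, w), w)
}

#' Per-nucleosome positioning level
#'
#' The positioning level of a call is the maximum occupancy value within
#' +/-30 bp of its dyad (clipped at the chromosome ends). Well-positioned
#' nucleosomes produce sharp occupancy peaks and hence high levels.
#'
#' @param calls Nucleosome call table ([call_genome()]).
#' @param tracks Named list of `occupancy_track`s, one per chromosome (a
#'   single track is accepted when all calls share one chromosome).
#' @param halfwin Search half window, bp.
#' @return Numeric vector of levels, one per call.
#' @export
positioning_level <- function(calls, tracks, halfwin = 30L) {
  if (inherits(tracks, "occupancy_track")) {
    chs <- unique(calls$chrom)
    if (length(chs) > 1L) stop("single track given for multiple chromosomes")
    tracks <- stats::setNames(list(tracks), chs)
  }
  missing_ch <- setdiff(unique(calls$chrom), names(tracks))
  if (length(missing_ch)) {
    stop("no occupancy track for chromosome(s): ",
         paste(missing_ch, collapse = ", "))
  }
  vapply(seq_len(nrow(calls)), function(r) {
    S <- tracks[[calls$chrom[r]]]$S
    d <- calls$dyad[r]
    max(S[max(1L, d - halfwin):min(length(S), d + halfwin)])
  }, numeric(1))
}

#' Read a samtools-depth-style coverage TSV
#'
#' Three columns (chrom, 1-based position, depth), with or without a header
#' line. Positions absent from the file get depth 0.
#'
#' @param path TSV path.
#' @param chrom_lengths Optional named lengths; defaults to the maximum
#'   observed position per chromosome.
#' @return Named list of integer coverage vectors.
#' @export
read_depth_tsv <- function(path, chrom_lengths = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (nrow(dt) && is.character(dt[[2L]])) {       # header line present
    dt <- data.table::fread(path, header = TRUE, sep = "\t")
  }
  data.table::setnames(dt, 1:3, c("chrom", "pos", "depth"))
  out <- list()
  for (ch in unique(dt$chrom)) {
    sub <- dt[dt$chrom == ch, ]
    L <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else max(sub$pos)
    v <- integer(L)
    v[sub$pos] <- as.integer(sub$depth)
    out[[ch]] <- v
  }
  out
}

#' Write a numeric per-base track as bedGraph
#' @param values Numeric vector (1-based per-base values).
#' @param chrom Chromosome name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(values, chrom, path) {
  dt <- data.table::data.table(chrom = chrom,
                               start = seq_along(values) - 1L,
                               end = seq_along(values), value = values)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
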