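# Sequence-based nucleosome binding model: AA/AT/TA/TT dinucleotide PFM/PWM
# learned from read centers, genome-wide score scan, and local+z
# normalization into the binding score track B.

# 0/1 vector over dinucleotide start positions 1..L-1: 1 where the
# dinucleotide is AA/AT/TA/TT. N-containing dinucleotides count as "other".
.ww_indicator <- function(seq_string) {
  v <- strsplit(chartr("ACGTN", "10010", as.character(seq_string)), "",
                fixed = TRUE)[[1]] == "1"
  L <- length(v)
  if (L < 2L) return(logical(0))
  v[-L] & v[-1L]
}

#' Count AA/AT/TA/TT dinucleotides around read centers (position frequency
#' matrix)
#'
#' Builds a 2 x (2*halfwin) position frequency matrix over dinucleotide start
#' offsets `-halfwin .. halfwin-1` relative to each read center: row 1 holds
#' the frequency of AA/AT/TA/TT dinucleotides at each offset, row 2 the
#' frequency of all other dinucleotides. Centers whose window overhangs a
#' chromosome end are skipped and reported.
#'
#' @param centers A [read_center_set()] or a named list of integer position
#'   vectors per chromosome.
#' @param genome A [Biostrings::DNAStringSet] covering those chromosomes.
#' @param halfwin Half window in bp (default 80, i.e. a 2 x 160 matrix).
#' @return An object of class `dinuc_pfm` with fields `F` (2 x 2*halfwin),
#'   `offsets`, `n_centers`, `n_skipped`.
#' @export
count_dinucleotides <- function(centers, genome, halfwin = 80L) {
  if (inherits(centers, "read_center_set")) {
    centers <- lapply(centers, `[[`, "centers")
  }
  offsets <- seq.int(-halfwin, halfwin - 1L)
  acc <- numeric(length(offsets))
  n_used <- 0L; n_skipped <- 0L
  for (ch in names(centers)) {
    if (!ch %in% names(genome)) stop("genome does not cover chromosome ", ch)
    L <- Biostrings::width(genome[ch])
    ww <- .ww_indicator(genome[[ch]])
    ctr <- as.integer(centers[[ch]])
    ok <- ctr - halfwin >= 1L & ctr + halfwin <= L
    n_skipped <- n_skipped + sum(!ok)
    ctr <- ctr[ok]
    if (!length(ctr)) next
    idx <- outer(ctr, offsets, `+`)
    acc <- acc + colSums(matrix(ww[idx], nrow = length(ctr)))
    n_used <- n_used + length(ctr)
  }
  if (n_used == 0L) stop("no usable read centers after edge filtering")
  f1 <- acc / n_used
  structure(list(F = rbind(ww = f1, other = 1 - f1), offsets = offsets,
                 n_centers = n_used, n_skipped = n_skipped,
                 halfwin = as.integer(halfwin)),
            class = "dinuc_pfm")
}

#' Genome-wide AA/AT/TA/TT background dinucleotide frequency
#' @param genome A [Biostrings::DNAStringSet].
#' @return Numeric vector `c(ww, other)` summing to 1.
#' @export
background_dinuc_freq <- function(genome) {
  n_ww <- 0; n_tot <- 0
  for (ch in names(genome)) {
    ww <- .ww_indicator(genome[[ch]])
    n_ww <- n_ww + sum(ww)
    n_tot <- n_tot + length(ww)
  }
  if (n_tot == 0L) stop("empty genome")
  c(ww = n_ww / n_tot, other = 1 - n_ww / n_tot)
}

#' Log-odds position weight matrix from a dinucleotide PFM
#'
#' `W[k, j] = log2((F[k, j] + pseudocount) / (b[k] + pseudocount))`, where
#' `b` are the genome-wide background frequencies of the AA/AT/TA/TT class
#' and its complement. The pseudocount keeps zero-count cells finite.
#'
#' @param pfm A `dinuc_pfm`.
#' @param background Length-2 background frequencies (ww, other), positive.
#' @param pseudocount Additive frequency pseudocount.
#' @return An object of class `dinuc_pwm` with fields `W`, `background`,
#'   `offsets`.
#' @export
pwm_from_pfm <- function(pfm, background, pseudocount = 1e-4) {
  stopifnot(inherits(pfm, "dinuc_pfm"), length(background) == 2L)
  if (any(background <= 0)) stop("background frequencies must be positive")
  W <- log2((pfm$F + pseudocount) / (as.numeric(background) + pseudocount))
  structure(list(W = W, background = as.numeric(background),
                 offsets = pfm$offsets, halfwin = pfm$halfwin),
            class = "dinuc_pwm")
}

#' Scan a genome with the dinucleotide PWM (raw binding score D)
#'
#' `D(i)` is the cross-correlation of the PWM with the one-hot dinucleotide
#' indicator of the genome, anchored so that position `i` is scored as a
#' putative dyad: `D(i) = sum_j W[row(i + offset_j), j]` where `row` selects
#' the AA/AT/TA/TT row when the dinucleotide starting at that position is in
#' the class, and the other row otherwise. Positions whose window overhangs a
#' chromosome end are unscored (NA).
#'
#' @param pwm A `dinuc_pwm`.
#' @param genome A [Biostrings::DNAStringSet].
#' @return Object of class `binding_track`: per-chromosome list with `D`
#'   (numeric, NA where unscored) and `scored` (logical mask).
#' @export
scan_binding <- function(pwm, genome) {
  stopifnot(inherits(pwm, "dinuc_pwm"))
  hw <- pwm$halfwin
  dW <- pwm$W[1L, ] - pwm$W[2L, ]
  c0 <- sum(pwm$W[2L, ])
  out <- list()
  for (ch in names(genome)) {
    L <- Biostrings::width(genome[ch])
    D <- rep(NA_real_, L)
    scored <- logical(L)
    if (L > 2L * hw) {
      ww <- as.numeric(.ww_indicator(genome[[ch]]))        # length L-1
      # D(i) = sum_{j=1..2hw} ww[i - hw - 1 + j] * dW[j] + c0
      y <- stats::filter(ww, rev(dW), method = "convolution", sides = 1L)
      # y[t] = sum_j dW[j] ww[t - 2hw + j]  =>  D(i) = y[i + hw - 1] + c0
      i <- seq.int(hw + 1L, L - hw)
      D[i] <- as.numeric(y[i + hw - 1L]) + c0
      scored[i] <- TRUE
    }
    out[[ch]] <- list(D = D, scored = scored)
  }
  structure(out, class = "binding_track")
}

#' Normalize the raw binding score into the z-scored track B
#'
#' Two-step normalization: first each position is divided by the sum of
#' scores in its +/- `local_halfwin` neighborhood (`Btilde`), then `Btilde`
#' is z-normalized over all scored positions (pooled across chromosomes) to
#' give `B` with mean 0 and sd 1. The ratio normalization presumes
#' non-negative scores, but log-odds sums are negative wherever the local
#' sequence looks like background, so `D` is floored at 0 before this step
#' ("no detectable affinity"); positions whose whole neighborhood floors to
#' zero get `Btilde = 0` and are flagged. Unscored edge positions stay NA
#' and are excluded from the z statistics.
#'
#' @param track A `binding_track` from [scan_binding()].
#' @param local_halfwin Local normalization half window, bp.
#' @return The track with `Btilde`, `B`, and `flagged` added per chromosome.
#' @export
normalize_binding <- function(track, local_halfwin = 50L) {
  stopifnot(inherits(track, "binding_track"))
  all_bt <- numeric(0)
  for (ch in names(track)) {
    D <- pmax(track[[ch]]$D, 0)
    scored <- track[[ch]]$scored
    if (sum(scored) > 1L && stats::sd(track[[ch]]$D[scored]) == 0) {
      stop("raw binding score is constant on ", ch,
           "; normalization is degenerate")
    }
    n_sc <- sum(scored)
    bt <- rep(NA_real_, length(D))
    flagged <- logical(length(D))
    if (n_sc >= 2L * local_halfwin + 1L) {
      d0 <- ifelse(scored, D, 0)
      cs <- cumsum(d0)
      L <- length(D)
      hi <- pmin(seq_len(L) + local_halfwin, L)
      lo <- pmax(seq_len(L) - local_halfwin, 1L)
      wsum <- cs[hi] - c(0, cs)[lo]
      bt[scored] <- ifelse(wsum[scored] == 0, 0, D[scored] / wsum[scored])
      flagged[scored] <- wsum[scored] == 0
    } else if (n_sc > 0L) {
      stop(sprintf("chromosome %s has too few scored positions (%d)",
                   ch, n_sc))
    }
    track[[ch]]$Btilde <- bt
    track[[ch]]$flagged <- flagged
    all_bt <- c(all_bt, bt[!is.na(bt)])
  }
  mu <- mean(all_bt)
  sg <- stats::sd(all_bt)
  if (!is.finite(sg) || sg == 0) {
    stop("binding score is constant; z-normalization is degenerate")
  }
  for (ch in names(track)) {
    track[[ch]]$B <- (track[[ch]]$Btilde - mu) / sg
  }
  attr(track, "mean_Btilde") <- mu
  attr(track, "sd_Btilde") <- sg
  track
}

#' Convenience: full binding-score track from read centers and a genome
#'
#' Chains [count_dinucleotides()], [background_dinuc_freq()],
#' [pwm_from_pfm()], [scan_binding()] and [normalize_binding()].
#'
#' @inheritParams count_dinucleotides
#' @param local_halfwin Passed to [normalize_binding()].
#' @param pseudocount Passed to [pwm_from_pfm()].
#' @return A normalized `binding_track` with the `dinuc_pwm` attached as
#'   attribute `"pwm"`.
#' @export
binding_score_track <- function(centers, genome, halfwin = 80L,
                                local_halfwin = 50L, pseudocount = 1e-4) {
  pfm <- count_dinucleotides(centers, genome, halfwin = halfwin)
  pwm <- pwm_from_pfm(pfm, background_dinuc_freq(genome),
                      pseudocount = pseudocount)
  track <- normalize_binding(scan_binding(pwm, genome),
                             local_halfwin = local_halfwin)
  attr(track, "pwm") <- pwm
  track
}

#' Write a binding track as bedGraph
#' @param track Normalized `binding_track`.
#' @param path Output path.
#' @param field Which field to export (`"B"`, `"Btilde"`, or `"D"`).
#' @return `path`, invisibly.
#' @export
write_binding_bedgraph <- function(track, path, field = "B") {
  rows <- list()
  for (ch in names(track)) {
    v <- track[[ch]][[field]]
    i <- which(!is.na(v))
    if (length(i)) {
      rows[[ch]] <- data.table::data.table(chrom = ch, start = i - 1L,
                                           end = i, value = v[i])
    }
  }
  dt <- data.table::rbindlist(rows)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
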