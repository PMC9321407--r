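# Nucleosome dyad calling by hard-assignment DP-mixture clustering of read
# centers. The sigma -> 0 limit of the Gaussian DP mixture reduces to a
# DP-means objective,
#     min sum_c sum_{x in c} d~_c(x)^2 + lambda^2 * k,
# where d~_c(x) = max(0, |x - mu_c| + gamma1*[partner of x in c]
#                        + gamma2 * B(mu_c))
# augments the geometric distance with a cannot-link penalty (the two ends of
# one ligation contact should sit in different clusters) and a binding-score
# term. lambda is exposed in bp: a read farther than lambda from every
# existing center seeds a new cluster.

#' Parameters of the nucleosome caller
#'
#' @param lambda_bp New-cluster distance threshold in bp; the internal
#'   cluster penalty is `lambda_bp^2` per cluster. Roughly half a repeat
#'   length is a sensible scale.
#' @param gamma1 Cannot-link penalty in bp added to the distance between a
#'   read and a cluster already containing its contact partner.
#' @param gamma2 Binding-score weight (bp per z-unit, signed). Negative
#'   values attract cluster centers towards high binding scores.
#' @param window Tiling window in bp.
#' @param overlap Overlap between consecutive windows in bp.
#' @param max_iter Maximum reassign/recenter iterations per window.
#' @param b_clip Binding z-scores are clipped to `[-b_clip, b_clip]` before
#'   entering the objective, bounding the influence of normalization
#'   outliers.
#' @param merge_dist Calls closer than this after window deduplication are
#'   merged (bp; half a nucleosome footprint).
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(lambda_bp = 75, gamma1 = 80, gamma2 = -2,
                          window = 1000L, overlap = 200L, max_iter = 50L,
                          b_clip = 3, merge_dist = 74L) {
  stopifnot(lambda_bp > 0, window > 0, overlap >= 0, overlap < window,
            max_iter >= 1, b_clip > 0, merge_dist >= 0)
  if (window <= 2 * lambda_bp) {
    warning("window <= 2*lambda_bp; clusters may straddle window seams")
  }
  structure(list(lambda_bp = lambda_bp, gamma1 = gamma1, gamma2 = gamma2,
                 window = as.integer(window), overlap = as.integer(overlap),
                 max_iter = as.integer(max_iter), b_clip = b_clip,
                 merge_dist = as.integer(merge_dist)),
            class = "caller_params")
}

# clipped binding lookup; B may be NULL (score 0 everywhere)
.make_bfun <- function(B, b_clip) {
  if (is.null(B)) return(function(mu) numeric(length(mu)) )
  n <- length(B)
  function(mu) {
    i <- as.integer(round(mu))
    v <- ifelse(i >= 1L & i <= n, B[pmin(pmax(i, 1L), n)], NA_real_)
    v[is.na(v)] <- 0
    pmin(pmax(v, -b_clip), b_clip)
  }
}

#' Penalty-adjusted read-to-cluster distance
#'
#' `max(0, |x - mu| + gamma1*[partner in cluster] + gamma2*B(mu))`, the
#' distance used in place of the geometric distance in both the assignment
#' rule and the clustering objective.
#'
#' @param x Read center position (bp).
#' @param mu Cluster center (bp).
#' @param partner_in_c Logical: is the read's contact partner currently in
#'   this cluster?
#' @param B Optional numeric binding-score vector for the chromosome (indexed
#'   by bp); `NULL` means a zero score.
#' @param params A [caller_params()].
#' @return Adjusted distance in bp (non-negative).
#' @export
adjusted_distance <- function(x, mu, partner_in_c = FALSE, B = NULL,
                              params = caller_params()) {
  bfun <- .make_bfun(B, params$b_clip)
  pmax(0, abs(x - mu) + params$gamma1 * as.numeric(partner_in_c) +
         params$gamma2 * bfun(mu))
}

# Core engine: sequential (ICM) reassignment + guarded recentering.
# x sorted ascending; partner[i] = index of the linked read or NA.
.dp_engine <- function(x, partner, lambda, g1, g2, bfun, max_iter,
                       grid_radius = 30L) {
  n <- length(x)
  lam2 <- lambda^2
  if (n == 0L) {
    return(list(centers = numeric(0), labels = integer(0),
                sizes = integer(0), objective = 0, trace = numeric(0),
                iterations = 0L, converged = TRUE))
  }
  if (is.null(partner)) partner <- rep(NA_integer_, n)

  centers <- numeric(0); bc <- numeric(0)
  sizes <- integer(0); sums <- numeric(0)
  labels <- integer(n)

  dtsq <- function(xi, mu_v, b_v, delta_v) {
    pmax(0, abs(xi - mu_v) + g1 * delta_v + g2 * b_v)^2
  }

  # --- initialization: single left-to-right scan over sorted reads
  for (i in seq_len(n)) {
    if (length(centers) == 0L) {
      centers <- x[i]; bc <- bfun(x[i]); sizes <- 1L; sums <- x[i]
      labels[i] <- 1L
      next
    }
    p <- partner[i]
    delta <- if (!is.na(p) && labels[p] > 0L)
      as.numeric(seq_along(centers) == labels[p]) else 0
    cost <- dtsq(x[i], centers, bc, delta)
    cost_new <- lam2 + dtsq(x[i], x[i], bfun(x[i]), 0)
    if (min(cost) <= cost_new) {
      c_best <- which.min(cost)
      labels[i] <- c_best
      sizes[c_best] <- sizes[c_best] + 1L
      sums[c_best] <- sums[c_best] + x[i]
      centers[c_best] <- sums[c_best] / sizes[c_best]
      bc[c_best] <- bfun(centers[c_best])
    } else {
      centers <- c(centers, x[i]); bc <- c(bc, bfun(x[i]))
      sizes <- c(sizes, 1L); sums <- c(sums, x[i])
      labels[i] <- length(centers)
    }
  }

  alive <- sizes > 0L
  objective_of <- function() {
    delta <- rep(0, n)
    has_p <- !is.na(partner)
    delta[has_p] <- as.numeric(labels[partner[has_p]] == labels[has_p])
    sum(dtsq(x, centers[labels], bc[labels], delta)) + lam2 * sum(alive)
  }
  trace <- objective_of()
  eps <- 1e-9

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    moved <- FALSE

    # --- reassignment (sequential; exact objective deltas, centers fixed)
    for (i in seq_len(n)) {
      cur <- labels[i]
      live <- which(alive)
      p <- partner[i]
      plab <- if (!is.na(p)) labels[p] else NA_integer_
      delta_v <- if (!is.na(plab)) as.numeric(live == plab) else
        numeric(length(live))
      own <- dtsq(x[i], centers[live], bc[live], delta_v)
      own_cur <- own[match(cur, live)]
      # partner's term changes when i joins/leaves the partner's cluster
      pdelta <- numeric(length(live))
      if (!is.na(plab)) {
        p_base <- dtsq(x[p], centers[plab], bc[plab], 0)
        p_pen <- dtsq(x[p], centers[plab], bc[plab], 1)
        p_cur <- if (cur == plab) p_pen else p_base
        pdelta <- ifelse(live == plab, p_pen, p_base) - p_cur
      }
      empty_refund <- if (sizes[cur] == 1L) lam2 else 0
      d_obj <- (own - own_cur) + pdelta -
        ifelse(live == cur, 0, empty_refund)
      # new-cluster option (pointless if i is already alone)
      d_new <- if (sizes[cur] > 1L) {
        lam2 + dtsq(x[i], x[i], bfun(x[i]), 0) - own_cur +
          (if (!is.na(plab) && plab == cur) {
            dtsq(x[p], centers[plab], bc[plab], 0) -
              dtsq(x[p], centers[plab], bc[plab], 1)
          } else 0)
      } else Inf
      best <- which.min(d_obj)
      if (d_new < d_obj[best] - eps && d_new < -eps) {
        # move to a fresh cluster seeded at x[i]
        sizes[cur] <- sizes[cur] - 1L; sums[cur] <- sums[cur] - x[i]
        centers <- c(centers, x[i]); bc <- c(bc, bfun(x[i]))
        sizes <- c(sizes, 1L); sums <- c(sums, x[i])
        alive <- c(alive, TRUE)
        labels[i] <- length(centers)
        if (sizes[cur] == 0L) alive[cur] <- FALSE
        moved <- TRUE
      } else if (d_obj[best] < -eps && live[best] != cur) {
        tgt <- live[best]
        sizes[cur] <- sizes[cur] - 1L; sums[cur] <- sums[cur] - x[i]
        sizes[tgt] <- sizes[tgt] + 1L; sums[tgt] <- sums[tgt] + x[i]
        labels[i] <- tgt
        if (sizes[cur] == 0L) alive[cur] <- FALSE
        moved <- TRUE
      }
    }

    # --- recentering (guarded: candidate set always includes the current
    # center, so the objective cannot increase)
    for (c_id in which(alive)) {
      m <- which(labels == c_id)
      mu_mean <- sums[c_id] / sizes[c_id]
      cand <- unique(c(centers[c_id], mu_mean))
      if (g1 != 0 || g2 != 0) {
        cand <- unique(c(cand, round(mu_mean) + seq.int(-grid_radius,
                                                        grid_radius)))
      }
      delta_m <- rep(0, length(m))
      has_p <- !is.na(partner[m])
      delta_m[has_p] <- as.numeric(labels[partner[m[has_p]]] == c_id)
      bcand <- bfun(cand)
      cost <- vapply(seq_along(cand), function(k) {
        sum(dtsq(x[m], cand[k], bcand[k], delta_m))
      }, numeric(1))
      k_best <- which.min(cost)
      if (abs(cand[k_best] - centers[c_id]) > eps) {
        centers[c_id] <- cand[k_best]
        bc[c_id] <- bcand[k_best]
        moved <- TRUE
      }
    }

    trace <- c(trace, objective_of())
    if (!moved) { converged <- TRUE; break }
  }

  # compact to live clusters
  live <- which(alive)
  remap <- integer(length(centers)); remap[live] <- seq_along(live)
  list(centers = centers[live], labels = remap[labels],
       sizes = sizes[live], objective = trace[length(trace)],
       trace = trace, iterations = iter, converged = converged)
}

#' Plain DP-means clustering of 1-D points
#'
#' Hard-assignment clustering where a new cluster is created whenever a point
#' lies farther than `lambda_bp` from every existing center; otherwise the
#' point joins its nearest cluster. After the deterministic left-to-right
#' initialization scan, assignment and mean-recentering alternate until the
#' labels are stable. Minimizes `sum of squared distances + lambda_bp^2 * k`.
#'
#' @param points Numeric vector, sorted ascending.
#' @param lambda_bp New-cluster distance threshold (bp).
#' @param max_iter Iteration cap.
#' @return A `cluster_state` list: `centers`, `labels`, `sizes`,
#'   `objective`, `trace` (objective per iteration), `iterations`,
#'   `converged`.
#' @export
dp_means <- function(points, lambda_bp, max_iter = 50L) {
  if (length(points) && is.unsorted(points)) {
    stop("points must be sorted ascending")
  }
  st <- .dp_engine(points, partner = NULL, lambda = lambda_bp, g1 = 0,
                   g2 = 0, bfun = .make_bfun(NULL, 1), max_iter = max_iter)
  class(st) <- "cluster_state"
  st
}

#' Cluster one window of read centers with cannot-link and binding penalties
#'
#' DP-means over the reads of a single window using the penalty-adjusted
#' distance: two reads linked by a contact are discouraged (penalty
#' `gamma1`) from sharing a cluster, and cluster centers are attracted to
#' (or repelled from, depending on the sign of `gamma2`) high binding
#' scores. With `gamma1 = gamma2 = 0` the result is identical to
#' [dp_means()]. The objective is non-increasing at every iteration.
#'
#' @param reads Numeric vector of read-center positions, sorted ascending.
#' @param links 2-column integer matrix of read indices forming cannot-link
#'   pairs (both indices must reference `reads`).
#' @param B Optional numeric binding-score vector for the chromosome.
#' @param params A [caller_params()].
#' @return A `cluster_state` (see [dp_means()]).
#' @export
call_window <- function(reads, links = NULL, B = NULL,
                        params = caller_params()) {
  if (length(reads) && is.unsorted(reads)) {
    stop("reads must be sorted ascending")
  }
  partner <- rep(NA_integer_, length(reads))
  if (!is.null(links) && nrow(links)) {
    partner[links[, 1L]] <- links[, 2L]
    partner[links[, 2L]] <- links[, 1L]
  }
  st <- .dp_engine(reads, partner = partner, lambda = params$lambda_bp,
                   g1 = params$gamma1, g2 = params$gamma2,
                   bfun = .make_bfun(B, params$b_clip),
                   max_iter = params$max_iter)
  class(st) <- "cluster_state"
  st
}

#' Call nucleosome dyads genome-wide
#'
#' Tiles each chromosome into windows of `params$window` bp advancing by
#' `window - overlap`, clusters the read centers of each window with
#' [call_window()] (links with one end outside the window contribute no
#' penalty), then deduplicates calls across overlap zones: of two calls
#' closer than `params$merge_dist` the one backed by more reads wins (ties
#' go to the leftmost).
#'
#' @param center_set A [read_center_set()].
#' @param B A normalized `binding_track`, or `NULL` to disable the binding
#'   term.
#' @param params A [caller_params()].
#' @param verbose Print per-chromosome call counts.
#' @return A `data.table` of calls: `chrom`, `dyad`, `n_reads`, `fuzziness`
#'   (sd of member read centers, bp), `binding` (B at the dyad, NA if
#'   unscored), sorted by (chrom, dyad).
#' @export
call_genome <- function(center_set, B = NULL, params = caller_params(),
                        verbose = FALSE) {
  stopifnot(inherits(center_set, "read_center_set"))
  step <- params$window - params$overlap
  out <- list()
  for (ch in names(center_set)) {
    xs <- center_set[[ch]]$centers
    if (!length(xs)) next
    links <- center_set[[ch]]$links
    partner_all <- rep(NA_integer_, length(xs))
    if (nrow(links)) {
      partner_all[links[, 1L]] <- links[, 2L]
      partner_all[links[, 2L]] <- links[, 1L]
    }
    Bv <- NULL
    if (!is.null(B) && ch %in% names(B) && !is.null(B[[ch]]$B) &&
        any(!is.na(B[[ch]]$B))) {
      Bv <- B[[ch]]$B
    } else if (!is.null(B) && params$gamma2 != 0) {
      warning("no binding scores for chromosome ", ch,
              "; proceeding without the binding term")
    }
    starts <- seq.int(1L, max(xs), by = step)
    calls <- list()
    for (s in starts) {
      lo <- findInterval(s - 0.5, xs) + 1L
      hi <- findInterval(s + params$window - 0.5, xs)
      if (hi < lo) next
      idx <- lo:hi
      xw <- xs[idx]
      pw <- match(partner_all[idx], idx)
      lw <- which(!is.na(pw) & pw > seq_along(idx))
      links_w <- cbind(lw, pw[lw])
      st <- call_window(xw, links_w, Bv, params)
      if (!length(st$centers)) next
      fz <- vapply(seq_along(st$centers), function(c_id) {
        mm <- xw[st$labels == c_id]
        if (length(mm) > 1L) stats::sd(mm) else 0
      }, numeric(1))
      calls[[length(calls) + 1L]] <- data.table::data.table(
        dyad = as.integer(round(st$centers)), n_reads = st$sizes,
        fuzziness = fz)
    }
    if (!length(calls)) next
    dt <- data.table::rbindlist(calls)
    data.table::setorderv(dt, c("dyad", "n_reads"))
    # greedy dedup of window-overlap duplicates
    keep <- logical(nrow(dt))
    last <- 0L
    for (r in seq_len(nrow(dt))) {
      if (last == 0L || dt$dyad[r] - dt$dyad[last] >= params$merge_dist) {
        keep[r] <- TRUE; last <- r
      } else if (dt$n_reads[r] > dt$n_reads[last]) {
        keep[last] <- FALSE; keep[r] <- TRUE; last <- r
      }
    }
    dt <- dt[keep, ]
    bind <- rep(NA_real_, nrow(dt))
    if (!is.null(Bv)) {
      ii <- dt$dyad
      ok <- ii >= 1L & ii <= length(Bv)
      bind[ok] <- Bv[ii[ok]]
    }
    data.table::set(dt, NULL, "binding", bind)
    data.table::set(dt, NULL, "chrom", ch)
    out[[ch]] <- dt[, c("chrom", "dyad", "n_reads", "fuzziness", "binding"),
                    with = FALSE]
    if (verbose) {
      message(sprintf("%s: %d nucleosome calls", ch, nrow(dt)))
    }
  }
  res <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(chrom = character(), dyad = integer(),
                           n_reads = integer(), fuzziness = numeric(),
                           binding = numeric())
  data.table::setorderv(res, c("chrom", "dyad"))
  res[]
}

#' Write nucleosome calls as BED6+2
#'
#' 1 bp dyad intervals (0-based half-open), score column = member read
#' count, with `fuzziness` and `binding` as extra columns.
#'
#' @param calls Call table from [call_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nucleosomes <- function(calls, path) {
  dt <- data.table::data.table(
    chrom = calls$chrom, start = calls$dyad - 1L, end = calls$dyad,
    name = sprintf("nuc_%d", seq_len(nrow(calls))), score = calls$n_reads,
    strand = ".", fuzziness = calls$fuzziness, binding = calls$binding)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read nucleosome calls written by [write_nucleosomes()]
#' @param path BED6+2 path.
#' @return Call `data.table` (chrom, dyad, n_reads, fuzziness, binding).
#' @export
read_nucleosomes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
    col.names = c("chrom", "start", "end", "name", "score", "strand",
                  "fuzziness", "binding"))
  if (nrow(dt) == 0L) {
    return(data.table::data.table(chrom = character(), dyad = integer(),
                                  n_reads = integer(), fuzziness = numeric(),
                                  binding = numeric()))
  }
  data.table::data.table(chrom = dt$chrom, dyad = dt$end,
                         n_reads = dt$score, fuzziness = dt$fuzziness,
                         binding = dt$binding)
}
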