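# DP-means clustering contract, penalty-adjusted distances, the windowed
# genome caller, and its recovery of planted dyads.

test_that("dp_means solves tiny instances exactly", {
  st <- dp_means(c(99, 100, 101), 75)
  expect_equal(length(st$centers), 1)
  expect_equal(st$centers, 100)

  # brute-force over both partitions of {100, 400}: one cluster costs
  # 2*150^2 + lambda^2, two clusters cost 0 + 2*lambda^2 -> two win
  st2 <- dp_means(c(100, 400), 75)
  expect_equal(sort(st2$centers), c(100, 400))
  expect_equal(st2$objective, 2 * 75^2)

  st0 <- dp_means(numeric(0), 75)
  expect_equal(length(st0$centers), 0)
  expect_error(dp_means(c(5, 1), 75), "sorted")
})

test_that("dp_means matches the exhaustive optimum on separated clusters", {
  # exhaustive oracle over all contiguous partitions of sorted points
  oracle <- function(x, lam) {
    n <- length(x)
    best <- Inf
    for (mask in 0:(2^(n - 1) - 1)) {   # cut points between consecutive pts
      cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
      bounds <- c(0, cuts, n)
      obj <- lam^2 * (length(bounds) - 1)
      for (b in seq_len(length(bounds) - 1)) {
        seg <- x[(bounds[b] + 1):bounds[b + 1]]
        obj <- obj + sum((seg - mean(seg))^2)
      }
      best <- min(best, obj)
    }
    best
  }
  set.seed(51)
  lam <- 60
  for (rep in 1:5) {
    # tight clusters separated by > 2*lambda: the greedy scan attains the
    # global optimum there (it is only locally optimal in general)
    k <- sample(2:3, 1)
    ctr <- cumsum(sample(150:300, k, replace = TRUE))
    x <- sort(unlist(lapply(ctr, function(m) m + sample(-20:20, 3))))
    st <- dp_means(x, lam)
    expect_equal(st$objective, oracle(x, lam), tolerance = 1e-9)
    expect_equal(length(st$centers), k)
  }
})

test_that("adjusted_distance applies the penalty terms of the objective", {
  p <- caller_params(gamma1 = 0, gamma2 = 0)
  expect_equal(adjusted_distance(120, 100, FALSE, NULL, p), 20)
  p2 <- caller_params(gamma1 = 50, gamma2 = 0)
  expect_equal(adjusted_distance(120, 100, TRUE, NULL, p2), 70)
  # negative binding contribution clamps at zero
  B <- rep(0, 200); B[100] <- 2
  p3 <- caller_params(gamma1 = 0, gamma2 = -5)
  expect_equal(adjusted_distance(105, 100, FALSE, B, p3), 0)
})

test_that("cannot-link penalties split linked reads when strong enough", {
  reads <- c(200, 230)
  links <- cbind(1L, 2L)
  st0 <- call_window(reads, links, NULL, caller_params(gamma1 = 0,
                                                       gamma2 = 0))
  expect_equal(length(st0$centers), 1)
  st1 <- call_window(reads, links, NULL, caller_params(gamma1 = 500,
                                                       gamma2 = 0))
  expect_equal(length(st1$centers), 2)
  expect_equal(sort(st1$centers), c(200, 230))
  # enumeration oracle: with gamma1=500, together costs
  # 2*(15+500)^2 + lam^2, apart costs 0 + 2*lam^2
  lam <- 75
  expect_lt(2 * lam^2, 2 * (15 + 500)^2 + lam^2)
  expect_equal(st1$objective, 2 * lam^2)
})

test_that("with zero penalties call_window reduces to dp_means", {
  set.seed(52)
  for (rep in 1:4) {
    x <- sort(sample(1:1000, 100, replace = TRUE))
    links <- matrix(sample(100, 40), ncol = 2)
    st_a <- call_window(x, links, NULL, caller_params(gamma1 = 0,
                                                      gamma2 = 0))
    st_b <- dp_means(x, 75)
    expect_identical(st_a$labels, st_b$labels)
    expect_equal(st_a$centers, st_b$centers)
  }
})

test_that("negative gamma2 pulls centers toward binding peaks when it lowers the objective", {
  B <- rep(0, 400); B[150] <- 3
  reads <- c(130, 140, 150)
  p <- caller_params(gamma1 = 0, gamma2 = -5, b_clip = 3)
  st <- call_window(reads, NULL, B, p)
  expect_equal(length(st$centers), 1)
  # 1-D grid oracle over candidate centers: at the mean (140) the cost is
  # 200; at the binding peak (150) it is (20-15)^2 = 25
  cost <- vapply(120:170, function(mu) {
    b <- if (mu == 150) 3 else 0
    sum(pmax(0, abs(reads - mu) + p$gamma2 * b)^2)
  }, numeric(1))
  mu_star <- (120:170)[which.min(cost)]
  expect_equal(mu_star, 150)
  expect_equal(st$centers, 150)
})

test_that("the objective is non-increasing on random seeded windows", {
  set.seed(53)
  for (rep in 1:100) {
    n <- sample(20:80, 1)
    x <- sort(sample(1:1000, n, replace = TRUE))
    pair_n <- n %/% 2
    perm <- sample(n, 2 * pair_n)
    links <- matrix(perm, ncol = 2)
    B <- stats::rnorm(1000)
    st <- call_window(x, links, B,
                      caller_params(gamma1 = 80, gamma2 = -2))
    expect_true(all(diff(st$trace) <= 1e-6))
    expect_true(st$converged)
  }
})

test_that("converged states are single-read locally optimal", {
  set.seed(54)
  p <- caller_params(gamma1 = 80, gamma2 = 0)
  for (rep in 1:10) {
    n <- 60
    x <- sort(sample(1:900, n, replace = TRUE))
    links <- matrix(sample(n, 30), ncol = 2)
    partner <- rep(NA_integer_, n)
    partner[links[, 1]] <- links[, 2]
    partner[links[, 2]] <- links[, 1]
    st <- call_window(x, links, NULL, p)
    obj_of <- function(labels) {
      k <- length(unique(labels))
      centers <- st$centers
      tot <- p$lambda_bp^2 * k
      for (i in seq_len(n)) {
        delta <- !is.na(partner[i]) && labels[partner[i]] == labels[i]
        tot <- tot + max(0, abs(x[i] - centers[labels[i]]) +
                           p$gamma1 * delta)^2
      }
      tot
    }
    base <- obj_of(st$labels)
    for (i in seq_len(n)) {
      for (c2 in seq_along(st$centers)) {
        if (c2 == st$labels[i]) next
        alt <- st$labels
        alt[i] <- c2
        expect_gte(obj_of(alt), base - 1e-6)
      }
    }
  }
})

test_that("calling is equivariant under translation", {
  f <- fix_sd0()
  ch <- f$truth$chrom
  xs <- f$centers[[ch]]$centers
  links <- f$centers[[ch]]$links
  shift <- 5000L
  cs1 <- structure(list(a = list(centers = xs, links = links)),
                   class = "read_center_set")
  cs2 <- structure(list(a = list(centers = xs + shift, links = links)),
                   class = "read_center_set")
  p <- caller_params(gamma2 = 0)
  c1 <- call_genome(cs1, NULL, p)
  c2 <- call_genome(cs2, NULL, p)
  expect_equal(c2$dyad, c1$dyad + shift)
})

test_that("an isolated cluster yields one call regardless of tiling phase", {
  xs <- sort(as.integer(c(5100 + c(-8, -3, 0, 2, 7))))
  cs <- structure(list(a = list(centers = xs,
                                links = matrix(integer(), ncol = 2))),
                  class = "read_center_set")
  for (window in c(1000L, 900L, 800L)) {
    calls <- call_genome(cs, NULL,
                         caller_params(window = window, gamma2 = 0))
    expect_equal(nrow(calls), 1)
    expect_lte(abs(calls$dyad - round(mean(xs))), 1)
  }
})

test_that("no linked pair shares a cluster on sd=0 data with a strong penalty", {
  f <- fix_sd0()
  ch <- f$truth$chrom
  xs <- f$centers[[ch]]$centers
  links <- f$centers[[ch]]$links[1:200, ]
  w <- which(xs >= 10000 & xs < 11000)
  inw <- links[links[, 1] %in% w & links[, 2] %in% w, , drop = FALSE]
  xw <- xs[w]
  lw <- cbind(match(inw[, 1], w), match(inw[, 2], w))
  st <- call_window(xw, lw, NULL, caller_params(gamma1 = 500, gamma2 = 0))
  if (nrow(lw)) {
    expect_true(all(st$labels[lw[, 1]] != st$labels[lw[, 2]]))
  }
})

test_that("planted dyads are recovered from jittered reads", {
  f <- fix_sd20()
  calls <- call_genome(f$centers, NULL, caller_params(gamma2 = 0))
  err <- vapply(f$truth$dyads, function(d) min(abs(calls$dyad - d)),
                numeric(1))
  expect_lte(stats::median(err), 15)
  expect_gte(mean(err <= 50), 0.9)
  # empty chromosome -> zero calls
  cs0 <- structure(list(z = list(centers = integer(0),
                                 links = matrix(integer(), ncol = 2))),
                   class = "read_center_set")
  expect_equal(nrow(call_genome(cs0, NULL, caller_params(gamma2 = 0))), 0)
})

test_that("nucleosome calls round-trip through BED", {
  f <- fix_map_sd0()
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_nucleosomes(f$calls, tmp)
  back <- read_nucleosomes(tmp)
  expect_equal(back$dyad, f$calls$dyad)
  expect_equal(back$n_reads, f$calls$n_reads)
  expect_equal(back$fuzziness, f$calls$fuzziness, tolerance = 1e-6)
  expect_false(is.unsorted(back$dyad))
})
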