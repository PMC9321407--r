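# Shared synthetic fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_cache)) {
    assign(name, builder(), .fixture_cache)
  }
  get(name, .fixture_cache)
}

# perfectly positioned 60 kb array: exact geometry, exact recovery
fix_sd0 <- function() fixture("sd0", function() {
  tr <- truth_set(60000, nrl = 190, positioning_sd = 0, read_size = 70,
                  seed = 11)
  genome <- make_genome(tr, motif_strength = 0.3)
  rec <- simulate_contacts(tr, 8000)
  rs <- estimate_read_size(rec)
  shifted <- filter_short(shift_to_centers(rec, rs))
  centers <- read_center_set(shifted)
  list(truth = tr, genome = genome, raw = rec, read_size = rs,
       records = shifted, centers = centers)
})

# jittered 60 kb array (the poorly-positioned regime)
fix_sd20 <- function() fixture("sd20", function() {
  tr <- truth_set(60000, nrl = 190, positioning_sd = 20, read_size = 70,
                  seed = 12)
  rec <- simulate_contacts(tr, 8000)
  rs <- estimate_read_size(rec)
  shifted <- filter_short(shift_to_centers(rec, rs))
  list(truth = tr, raw = rec, read_size = rs, records = shifted,
       centers = read_center_set(shifted))
})

# calls + contact map on the sd=0 fixture
fix_map_sd0 <- function() fixture("map_sd0", function() {
  f <- fix_sd0()
  calls <- call_genome(f$centers, NULL, caller_params(gamma2 = 0))
  map <- assign_contacts(f$records, calls)
  list(calls = calls, map = map, truth = f$truth, records = f$records)
})

# tiny deterministic contact-record table for parser/filter unit tests
toy_records <- function() {
  data.table::data.table(
    readID = c("r1", "r2", "r3"),
    chrom1 = c("chr1", "chr1", "chr2"),
    pos1 = c(100L, 500L, 40L),
    strand1 = c("+", "-", "+"),
    chrom2 = c("chr1", "chr1", "chr1"),
    pos2 = c(400L, 250L, 900L),
    strand2 = c("-", "+", "-"))
}

# random sparse symmetric single-chromosome contact map, for oracle tests
toy_map <- function(n_nodes = 12, seed = 5, lam = 3) {
  set.seed(seed)
  nodes <- data.table::data.table(chrom = "chrT",
                                  dyad = cumsum(sample(150:230, n_nodes,
                                                       TRUE)),
                                  node = seq_len(n_nodes))
  pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes), diag = TRUE),
                 arr.ind = TRUE)
  counts <- stats::rpois(nrow(pairs), lam)
  keep <- counts > 0
  edges <- data.table::data.table(chrom = "chrT",
                                  node_i = pairs[keep, 1],
                                  node_j = pairs[keep, 2],
                                  count = counts[keep])
  data.table::set(edges, NULL, "dist",
                  abs(nodes$dyad[edges$node_j] - nodes$dyad[edges$node_i]))
  structure(list(nodes = nodes, edges = edges,
                 assignments = data.table::data.table(),
                 self_count = 0L, skipped = 0L),
            class = "nuc_contact_map")
}

# dense symmetric matrix view of a toy map (independent of .submatrix)
dense_counts <- function(map) {
  n <- nrow(map$nodes)
  M <- matrix(0, n, n)
  M[cbind(map$edges$node_i, map$edges$node_j)] <- map$edges$count
  M[cbind(map$edges$node_j, map$edges$node_i)] <- map$edges$count
  M
}
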