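# End-to-end workflow wiring: prep (parse/shift/filter) -> binding ->
# call -> occupancy -> cmap -> motifs, with a serialized, hashed
# configuration written next to every run's outputs for reproducibility.

# small multiplicative string hash; enough to fingerprint a config without
# extra deps (double arithmetic stays exact below 2^53)
.config_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in s) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Default pipeline configuration
#'
#' All tunable parameters of the workflow with their defaults. Any subset
#' can be overridden via a named list or a YAML file ([read_config()]).
#'
#' @param ... Named overrides.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    pairs = NULL, genome = NULL, depth = NULL, out_dir = "dyadmap_out",
    dialect = "pairs", read_size = "auto", min_dist = 160L,
    lambda_bp = 75, gamma1 = 80, gamma2 = -2, window = 1000L,
    overlap = 200L, max_iter = 50L, b_clip = 3,
    occupancy_w = 30L, flank = 500L, seed = 1L,
    stages = c("prep", "binding", "call", "occupancy", "cmap"))
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over))) {
    over <- over[[1L]]
  }
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  default_config(yaml::read_yaml(path))
}

#' Run the nucleosome-calling workflow
#'
#' Executes the requested stages in order: `prep` (parse pairs, estimate the
#' read size, shift ends to centers, drop sub-160 bp contacts), `binding`
#' (dinucleotide PWM and binding-score track; requires a genome FASTA),
#' `call` (genome-wide dyad calling), `occupancy` (when a depth TSV is
#' given), `cmap` (nucleosome contact map with OE normalization), and
#' `motifs` (tetra features; training requires labels supplied
#' programmatically). Each stage writes its artifact into `out_dir` together
#' with the serialized configuration and its hash.
#'
#' @param config A `run_config`, or a named list of overrides.
#' @return Invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config = default_config()) {
  if (!inherits(config, "run_config")) config <- default_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_plain <- unclass(config)
  cfg_plain$hash <- .config_hash(unclass(config))
  jsonlite::write_json(cfg_plain,
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null")
  res <- list(config = config)
  st <- function(s) s %in% config$stages

  if (st("prep")) {
    if (is.null(config$pairs)) stop("stage prep: 'pairs' input missing")
    rec <- parse_pairs(config$pairs, dialect = config$dialect)
    rs <- if (identical(config$read_size, "auto"))
      estimate_read_size(rec) else as.integer(config$read_size)
    rec <- shift_to_centers(rec, rs)
    rec <- filter_short(rec, min_dist = config$min_dist)
    res$read_size <- rs
    res$records <- rec
    res$centers <- read_center_set(rec)
    write_pairs(rec, file.path(config$out_dir, "prep.pairs"))
  }

  if (st("binding")) {
    if (is.null(config$genome)) stop("stage binding: 'genome' input missing")
    genome <- if (inherits(config$genome, "DNAStringSet")) config$genome
      else Biostrings::readDNAStringSet(config$genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    res$binding <- binding_score_track(res$centers, genome)
    write_binding_bedgraph(res$binding,
                           file.path(config$out_dir, "binding.bedgraph"))
  }

  if (st("call")) {
    params <- caller_params(lambda_bp = config$lambda_bp,
                            gamma1 = config$gamma1, gamma2 = config$gamma2,
                            window = config$window,
                            overlap = config$overlap,
                            max_iter = config$max_iter,
                            b_clip = config$b_clip)
    res$calls <- call_genome(res$centers, res$binding, params)
    write_nucleosomes(res$calls, file.path(config$out_dir, "nucs.bed"))
  }

  if (st("occupancy") && !is.null(config$depth)) {
    cov <- read_depth_tsv(config$depth)
    res$occupancy <- lapply(cov, occupancy_from_coverage,
                            w = config$occupancy_w)
    for (ch in names(res$occupancy)) {
      write_track_bedgraph(res$occupancy[[ch]]$S, ch,
                           file.path(config$out_dir,
                                     sprintf("occupancy_%s.bedgraph", ch)))
    }
    if (!is.null(res$calls)) {
      res$positioning <- positioning_level(res$calls, res$occupancy)
    }
  }

  if (st("cmap")) {
    res$map <- assign_contacts(res$records, res$calls)
    ch <- unique(res$map$nodes$chrom)
    if (length(ch) == 1L) {
      L <- max(res$map$nodes$dyad, res$records$pos2)
      res$map <- oe_normalize(res$map, expected_model(res$map, L))
    }
    write_contact_map(res$map, file.path(config$out_dir, "cmap.tsv"))
  }

  if (st("motifs") && !is.null(res$map)) {
    res$features <- extract_features(res$map)
    data.table::fwrite(res$features,
                       file.path(config$out_dir, "tetra_features.tsv"),
                       sep = "\t")
  }

  invisible(res)
}
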