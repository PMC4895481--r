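#' Pipeline configuration
#'
#' Collects all file paths and tunables for [run_pipeline()]. Flags given
#' on the command line (see `inst/scripts/scaflink`) override config-file
#' values.
#'
#' @param target_gff Target genome GFF3.
#' @param ref_gffs Named character vector: reference genome id -> GFF3
#'   path (names must match tree tips).
#' @param families Gene-family table TSV.
#' @param tree Newick tree path.
#' @param lengths Scaffold length `.fai`/TSV for the target.
#' @param maps Character vector of linkage-map TSV paths.
#' @param target_id Target genome id (a tree tip).
#' @param out_dir Output directory for artifacts.
#' @param feature_type GFF3 feature type treated as a gene.
#' @param max_copy Per-reference family copy-number cap.
#' @param min_genomes,min_weight Link acceptance thresholds.
#' @param window,decay Terminal evidence window and per-offset decay.
#' @param gap_size AGP gap size.
#' @param majority Linkage-group majority threshold.
#' @param seed Integer seed recorded in the run manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(target_gff, ref_gffs, families, tree, lengths,
                            maps, target_id, out_dir,
                            feature_type = "gene", max_copy = 10L,
                            min_genomes = 2L, min_weight = 0,
                            window = 1L, decay = 0.5, gap_size = 100L,
                            majority = 2 / 3, seed = 1L) {
  structure(list(target_gff = target_gff, ref_gffs = ref_gffs,
                 families = families, tree = tree, lengths = lengths,
                 maps = maps, target_id = target_id, out_dir = out_dir,
                 feature_type = feature_type, max_copy = max_copy,
                 min_genomes = min_genomes, min_weight = min_weight,
                 window = window, decay = decay, gap_size = gap_size,
                 majority = majority, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a `key = value` pipeline config file
#'
#' Repeatable keys `ref` take the form `genome_id=path`; `map` may repeat.
#'
#' @param path Config file path.
#' @return A named list of raw values suitable for merging into
#'   [pipeline_config()] arguments.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  out <- list(ref_gffs = character(), maps = character())
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    if (key == "ref") {
      iv <- strsplit(val, ":", fixed = TRUE)[[1L]]
      out$ref_gffs[trimws(iv[1L])] <- trimws(paste(iv[-1L], collapse = ":"))
    } else if (key == "map") {
      out$maps <- c(out$maps, val)
    } else {
      out[[key]] <- val
    }
  }
  out
}

plog <- function(...) message("[scaflink] ", ...)

#' Run the full scaffolding and map-consensus pipeline
#'
#' Executes: read annotations -> build signed gene orders -> filter
#' gene-less scaffolds -> project references onto target family content ->
#' phylogenetic weights -> candidate links -> maximum-weight matching ->
#' chains -> linkage-group anchoring -> precedence graph -> cycle
#' resolution -> topological consensus -> coverage. Writes links TSV,
#' AGP, anchoring TSV, removed-edges TSV, consensus map text, a coverage
#' summary and a run manifest into `config$out_dir`, and logs stage
#' counts.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with every intermediate object and a
#'   `counts` vector of stage statistics.
#' @export
run_pipeline <- function(config) {
  for (p in c(config$target_gff, unname(config$ref_gffs), config$families,
              config$tree, config$lengths, config$maps)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  tree <- read_genome_tree(config$tree, config$target_id,
                           names(config$ref_gffs))
  lengths <- read_lengths(config$lengths)

  tg <- read_gff_genes(config$target_gff, config$families,
                       config$target_id, config$feature_type)
  target <- build_gene_order(tg, config$target_id,
                             seq_ids = names(lengths))
  n_in <- length(target$orders)
  target <- filter_empty_scaffolds(target)
  n_filtered <- attr(target, "n_removed")
  plog("target: ", n_in, " scaffolds in, ", n_filtered,
       " without homologous genes filtered out")
  target_families <- unique(unlist(lapply(target$orders,
                                          function(o) o$family)))

  ref_adj <- list()
  for (gid in names(config$ref_gffs)) {
    rg <- read_gff_genes(config$ref_gffs[[gid]], config$families, gid,
                         config$feature_type)
    ro <- filter_empty_scaffolds(build_gene_order(rg, gid))
    ro <- restrict_to_shared(ro, target_families, config$max_copy)
    ref_adj[[gid]] <- reference_adjacencies(ro)
  }
  weights <- genome_weights(tree, config$target_id, names(config$ref_gffs))

  cand <- candidate_links(target, ref_adj, weights,
                          window = config$window, decay = config$decay)
  accepted <- select_links(cand, config$min_genomes, config$min_weight)
  plog(nrow(cand), " candidate links, ", nrow(accepted), " accepted")
  chains <- build_chains(accepted, names(target$orders))
  plog(length(chains), " chains")

  maps <- lapply(config$maps, read_linkage_map)
  anchoring <- anchor_chains(maps, chains, config$majority)
  n_placed <- sum(anchoring$assignments$status == "placed")
  plog(n_placed, " of ", length(chains), " chains placed in linkage groups")
  graph <- build_constraint_graph(anchoring, maps, chains)
  res <- resolve_cycles(graph)
  consensus <- topological_consensus(res$graph)
  coverage <- lg_coverage(anchoring, lengths, sum(lengths))
  plog("linkage group coverage: ", coverage, " %")

  # artifacts
  write_links_tsv(accepted, file.path(config$out_dir, "links.tsv"))
  write_agp(chains, lengths, config$gap_size,
            file.path(config$out_dir, "chains.agp"))
  anch_tab <- anchoring$assignments
  anch_tab$tally <- vapply(anch_tab$chain_id, function(cid) {
    tl <- anchoring$tally[[cid]]
    if (is.null(tl) || length(tl) == 0L) return("")
    paste0(names(tl), ":", as.integer(tl), collapse = ";")
  }, "")
  utils::write.table(anch_tab, file.path(config$out_dir, "anchoring.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$removed,
                     file.path(config$out_dir, "removed_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_map_text(consensus, file.path(config$out_dir, "consensus_map.txt"))
  counts <- c(scaffolds_in = n_in, scaffolds_filtered = n_filtered,
              candidates = nrow(cand), accepted = nrow(accepted),
              chains = length(chains), placed = n_placed,
              coverage_percent = coverage)
  writeLines(paste0(names(counts), "\t", counts),
             file.path(config$out_dir, "summary.tsv"))
  manifest <- config[c("target_id", "feature_type", "max_copy",
                       "min_genomes", "min_weight", "window", "decay",
                       "gap_size", "majority", "seed")]
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE)

  invisible(list(target = target, weights = weights, candidates = cand,
                 accepted = accepted, chains = chains,
                 anchoring = anchoring, graph = res$graph,
                 removed = res$removed, consensus = consensus,
                 coverage = coverage, counts = counts))
}
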