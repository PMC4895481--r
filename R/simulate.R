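# Gene-order evolution simulator. Generates a root genome of signed
# single-copy gene families on a stated number of chromosomes, evolves it
# along a phylogeny by inversions, translocations, fusions/fissions,
# deletions, insertions and tandem duplications (Poisson event counts per
# branch, rate x branch length), fragments the target leaf into scaffolds
# and emits two partially overlapping noisy linkage maps, all with ground
# truth, so every pipeline stage can be evaluated without external data.

#' Simulation parameters
#'
#' @param tree Newick string or `ape::phylo`. Default: the seven-taxon
#'   teleost-plus-outgroup topology used throughout (target nested among
#'   six references), with every branch length 1 so per-branch event
#'   expectations equal the rates.
#' @param target_id Tip label of the target genome.
#' @param n_families Single-copy families in the root genome.
#' @param n_chrom Root chromosome count.
#' @param rates Named numeric: expected events per unit branch length for
#'   `inversion`, `translocation`, `fusion`, `fission`, `deletion`,
#'   `insertion`, `duplication`.
#' @param max_span Maximum genes affected by one deletion/duplication/
#'   inversion-interval draw.
#' @param breaks_per_chrom Mean (Poisson) number of assembly breaks per
#'   target chromosome.
#' @param markers_per_scaffold Markers typed per scaffold in each map.
#' @param dropout Per-map probability a marker is absent (partial map
#'   overlap).
#' @param spacing_cM Centimorgans between consecutive true scaffold
#'   ordinals.
#' @param noise_sd Gaussian cM noise (truncated at 0).
#' @param swap_prob Probability of locally swapping adjacent scaffolds'
#'   map positions.
#' @param seed Integer seed; fixed seed gives fully reproducible output.
#' @return A `sim_params` list.
#' @export
sim_params <- function(tree = default_sim_tree(),
                       target_id = "Target",
                       n_families = 1000L,
                       n_chrom = 19L,
                       rates = c(inversion = 5, translocation = 1,
                                 fusion = 0, fission = 0, deletion = 1,
                                 insertion = 1, duplication = 0.5),
                       max_span = 5L,
                       breaks_per_chrom = 7,
                       markers_per_scaffold = 2L,
                       dropout = 0.25,
                       spacing_cM = 5,
                       noise_sd = 1,
                       swap_prob = 0.02,
                       seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  base_rates <- c(inversion = 0, translocation = 0, fusion = 0,
                  fission = 0, deletion = 0, insertion = 0,
                  duplication = 0)
  base_rates[names(rates)] <- rates
  stopifnot(all(base_rates >= 0), n_families >= 1L, n_chrom >= 1L,
            dropout >= 0, dropout <= 1, swap_prob >= 0, swap_prob <= 1,
            noise_sd >= 0, spacing_cM > 0, markers_per_scaffold >= 1L,
            breaks_per_chrom >= 0)
  structure(list(tree = tree, target_id = target_id,
                 n_families = as.integer(n_families),
                 n_chrom = as.integer(n_chrom), rates = base_rates,
                 max_span = as.integer(max_span),
                 breaks_per_chrom = breaks_per_chrom,
                 markers_per_scaffold = as.integer(markers_per_scaffold),
                 dropout = dropout, spacing_cM = spacing_cM,
                 noise_sd = noise_sd, swap_prob = swap_prob,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Default seven-taxon simulation tree (newick)
#'
#' Target nested among Fugu, Tetraodon, Medaka, Stickleback, Zebrafish
#' with Coelacanth as outgroup; unit branch lengths.
#' @return Newick string.
#' @export
default_sim_tree <- function() {
  paste0("(((((Fugu:1,Tetraodon:1):1,(Medaka:1,Stickleback:1):1):1,",
         "Zebrafish:1):1,Target:1):1,Coelacanth:1);")
}

with_sim_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# genome state: named list chrom -> data.frame(family, sign)
root_genome <- function(params) {
  fams <- sprintf("fam%05d", seq_len(params$n_families))
  chrom_of <- sort(rep_len(seq_len(params$n_chrom), params$n_families))
  chroms <- sprintf("chr%02d", seq_len(params$n_chrom))
  g <- lapply(split(fams, chrom_of), function(f) {
    data.frame(family = f, sign = rep(1L, length(f)),
               stringsAsFactors = FALSE)
  })
  names(g) <- chroms[as.integer(names(g))]
  g
}

empty_event_log <- function() {
  data.frame(branch = character(), type = character(), chrom = character(),
             pos = integer(), span = integer(), status = character(),
             stringsAsFactors = FALSE)
}

log_event <- function(log, branch, type, chrom, pos, span, status = "applied") {
  rbind(log, data.frame(branch = branch, type = type, chrom = chrom,
                        pos = as.integer(pos), span = as.integer(span),
                        status = status, stringsAsFactors = FALSE))
}

# One event application; returns list(genome, row-for-log) or NULL when
# the event is impossible on the current state.
apply_event <- function(genome, type, max_span, counter_env) {
  sizes <- vapply(genome, nrow, 0L)
  nonempty <- names(genome)[sizes > 0L]
  if (type %in% c("inversion", "deletion", "duplication")) {
    if (length(nonempty) == 0L) return(NULL)
    ch <- sample(nonempty, 1L)
    n <- sizes[[ch]]
    span <- sample.int(min(max_span, n), 1L)
    start <- sample.int(n - span + 1L, 1L)
    idx <- start:(start + span - 1L)
    o <- genome[[ch]]
    if (type == "inversion") {
      seg <- o[rev(idx), , drop = FALSE]
      seg$sign <- -seg$sign
      o[idx, ] <- seg
    } else if (type == "deletion") {
      o <- o[-idx, , drop = FALSE]
    } else {  # tandem duplication
      o <- rbind(o[seq_len(max(idx)), , drop = FALSE],
                 o[idx, , drop = FALSE],
                 if (max(idx) < n) o[(max(idx) + 1L):n, , drop = FALSE])
    }
    rownames(o) <- NULL
    genome[[ch]] <- o
    return(list(genome = genome, chrom = ch, pos = start, span = span))
  }
  if (type == "translocation") {
    if (length(nonempty) == 0L || length(genome) < 2L) return(NULL)
    ch <- sample(nonempty, 1L)
    dest <- sample(setdiff(names(genome), ch), 1L)
    n <- sizes[[ch]]
    span <- sample.int(min(max_span, n), 1L)
    start <- sample.int(n - span + 1L, 1L)
    idx <- start:(start + span - 1L)
    seg <- genome[[ch]][idx, , drop = FALSE]
    genome[[ch]] <- genome[[ch]][-idx, , drop = FALSE]
    at <- sample.int(nrow(genome[[dest]]) + 1L, 1L) - 1L
    d <- genome[[dest]]
    genome[[dest]] <- rbind(if (at > 0L) d[seq_len(at), , drop = FALSE],
                            seg,
                            if (at < nrow(d)) d[(at + 1L):nrow(d), , drop = FALSE])
    rownames(genome[[ch]]) <- rownames(genome[[dest]]) <- NULL
    return(list(genome = genome, chrom = ch, pos = start, span = span))
  }
  if (type == "insertion") {
    if (length(genome) == 0L) return(NULL)
    ch <- sample(names(genome), 1L)
    counter_env$ins <- counter_env$ins + 1L
    fam <- sprintf("nov%05d", counter_env$ins)
    at <- sample.int(nrow(genome[[ch]]) + 1L, 1L) - 1L
    o <- genome[[ch]]
    genome[[ch]] <- rbind(if (at > 0L) o[seq_len(at), , drop = FALSE],
                          data.frame(family = fam,
                                     sign = sample(c(-1L, 1L), 1L),
                                     stringsAsFactors = FALSE),
                          if (at < nrow(o)) o[(at + 1L):nrow(o), , drop = FALSE])
    rownames(genome[[ch]]) <- NULL
    return(list(genome = genome, chrom = ch, pos = at + 1L, span = 1L))
  }
  if (type == "fusion") {
    if (length(genome) < 2L) return(NULL)
    pair <- sample(names(genome), 2L)
    merged <- rbind(genome[[pair[1L]]], genome[[pair[2L]]])
    rownames(merged) <- NULL
    genome[[pair[1L]]] <- merged
    genome[[pair[2L]]] <- NULL
    return(list(genome = genome, chrom = pair[1L], pos = 1L,
                span = nrow(merged)))
  }
  if (type == "fission") {
    big <- names(genome)[sizes >= 2L]
    if (length(big) == 0L) return(NULL)
    ch <- sample(big, 1L)
    n <- nrow(genome[[ch]])
    cut <- sample.int(n - 1L, 1L)
    counter_env$fis <- counter_env$fis + 1L
    newname <- paste0(ch, ".f", counter_env$fis)
    tail_part <- genome[[ch]][(cut + 1L):n, , drop = FALSE]
    genome[[ch]] <- genome[[ch]][seq_len(cut), , drop = FALSE]
    rownames(genome[[ch]]) <- rownames(tail_part) <- NULL
    genome[[newname]] <- tail_part
    return(list(genome = genome, chrom = ch, pos = cut, span = n - cut))
  }
  stop("unknown event type: ", type)
}

#' Simulate gene orders for all leaves of the phylogeny
#'
#' @param params A `sim_params`.
#' @return List: `genomes` (named list of `gene_order`, one per leaf) and
#'   `log` (event data.frame: branch = child node label, type, chrom,
#'   pos, span, status).
#' @export
simulate_genomes <- function(params) {
  with_sim_seed(params$seed, {
    tree <- params$tree
    nt <- length(tree$tip.label)
    root <- nt + 1L
    node_label <- function(i) {
      if (i <= nt) tree$tip.label[i] else paste0("node", i)
    }
    counter_env <- new.env()
    counter_env$ins <- 0L
    counter_env$fis <- 0L
    log <- empty_event_log()
    states <- list()
    states[[node_label(root)]] <- root_genome(params)
    # preorder over edges
    edges <- tree$edge[order(tree$edge[, 1L]), , drop = FALSE]
    elen <- tree$edge.length
    if (is.null(elen)) elen <- rep(1, nrow(tree$edge))
    elen <- elen[order(tree$edge[, 1L])]
    # walk edges so parents are processed first (BFS from root)
    todo <- which(edges[, 1L] == root)
    while (length(todo) > 0L) {
      e <- todo[1L]; todo <- todo[-1L]
      parent <- node_label(edges[e, 1L])
      child <- node_label(edges[e, 2L])
      genome <- states[[parent]]
      counts <- stats::rpois(length(params$rates), params$rates * elen[e])
      types <- rep(names(params$rates), counts)
      if (length(types) > 0L) types <- sample(types)
      for (ty in types) {
        done <- FALSE
        for (try in 1:10) {
          res <- apply_event(genome, ty, params$max_span, counter_env)
          if (!is.null(res)) {
            genome <- res$genome
            log <- log_event(log, child, ty, res$chrom, res$pos, res$span)
            done <- TRUE
            break
          }
        }
        if (!done) log <- log_event(log, child, ty, NA, 0L, 0L, "skipped")
      }
      states[[child]] <- genome
      todo <- c(todo, which(edges[, 1L] == edges[e, 2L]))
    }
    genomes <- lapply(tree$tip.label, function(tip) {
      g <- states[[tip]]
      orders <- lapply(g, function(o) {
        if (nrow(o) == 0L) {
          return(data.frame(family = character(), sign = integer(),
                            gene_id = character(), stringsAsFactors = FALSE))
        }
        data.frame(family = o$family, sign = o$sign,
                   gene_id = sprintf("%s_g%05d", tip, seq_len(nrow(o))),
                   stringsAsFactors = FALSE)
      })
      # unique gene ids across the genome
      k <- 0L
      for (i in seq_along(orders)) {
        n <- nrow(orders[[i]])
        if (n > 0L) {
          orders[[i]]$gene_id <- sprintf("%s_g%05d", tip, k + seq_len(n))
          k <- k + n
        }
      }
      new_gene_order(tip, orders)
    })
    names(genomes) <- tree$tip.label
    list(genomes = genomes, log = log)
  })
}

#' Fragment the target genome into scaffolds with ground truth
#'
#' Each chromosome is split at inter-gene positions sampled without
#' replacement (Poisson number of breaks per chromosome, capped at
#' gene count - 1); scaffolds are named deterministically
#' `<chrom>_s<k>` in chromosomal order and keep the original orientation,
#' so each broken adjacency is recorded as the extremity pair
#' `(<left>:3p, <right>:5p)`.
#'
#' @param target A `gene_order` for the target genome (per-chromosome).
#' @param params A `sim_params` (uses `breaks_per_chrom` and `seed`).
#' @param breaks Optional named list: chromosome -> explicit break
#'   positions (after the i-th gene), overriding random sampling.
#' @return List: `order` (the fragmented `gene_order`) and `truth`
#'   (`sim_truth`: `adjacencies` data.frame with `ext_a`, `ext_b`, `key`;
#'   `membership` data.frame with `scaffold_id`, `chrom`, `ordinal`).
#' @export
fragment_target <- function(target, params, breaks = NULL) {
  run <- function() {
    orders <- list()
    adj <- list()
    membership <- list()
    for (ch in names(target$orders)) {
      o <- target$orders[[ch]]
      n <- nrow(o)
      if (n == 0L) next
      if (!is.null(breaks) && !is.null(breaks[[ch]])) {
        cuts <- sort(unique(as.integer(breaks[[ch]])))
        cuts <- cuts[cuts >= 1L & cuts <= n - 1L]
      } else {
        k <- min(stats::rpois(1L, params$breaks_per_chrom), n - 1L)
        cuts <- if (k > 0L) sort(sample.int(n - 1L, k)) else integer()
      }
      bounds <- c(0L, cuts, n)
      scafs <- sprintf("%s_s%02d", ch, seq_len(length(bounds) - 1L))
      for (i in seq_along(scafs)) {
        seg <- o[(bounds[i] + 1L):bounds[i + 1L], , drop = FALSE]
        rownames(seg) <- NULL
        orders[[scafs[i]]] <- seg
        membership[[length(membership) + 1L]] <- data.frame(
          scaffold_id = scafs[i], chrom = ch, ordinal = i,
          stringsAsFactors = FALSE)
        if (i > 1L) {
          ea <- ext_label(scafs[i - 1L], "3p")
          eb <- ext_label(scafs[i], "5p")
          adj[[length(adj) + 1L]] <- data.frame(
            ext_a = ea, ext_b = eb, key = link_key(ea, eb),
            stringsAsFactors = FALSE)
        }
      }
    }
    adjacencies <- if (length(adj) > 0L) do.call(rbind, adj) else {
      data.frame(ext_a = character(), ext_b = character(),
                 key = character(), stringsAsFactors = FALSE)
    }
    truth <- structure(list(adjacencies = adjacencies,
                            membership = do.call(rbind, membership)),
                       class = "sim_truth")
    list(order = new_gene_order(target$genome_id, orders), truth = truth)
  }
  if (is.null(breaks)) {
    with_sim_seed(params$seed + 1L, run())
  } else {
    run()
  }
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", nrow(x$membership), " scaffold(s), ",
      nrow(x$adjacencies), " true adjacenc(ies)\n", sep = "")
  invisible(x)
}

#' Simulate male and female linkage maps from ground truth
#'
#' Each scaffold carries `markers_per_scaffold` markers per map, each
#' retained with probability `1 - dropout`; positions are
#' `true ordinal x spacing_cM` plus Gaussian noise truncated at 0, after
#' optional local swaps of adjacent scaffold ordinals (probability
#' `swap_prob` per adjacent pair). Linkage group ids equal true
#' chromosome ids.
#'
#' @param truth A `sim_truth` from [fragment_target()].
#' @param params A `sim_params`.
#' @return A list of two `linkage_map` objects named `male`, `female`.
#' @export
simulate_maps <- function(truth, params) {
  with_sim_seed(params$seed + 2L, {
    out <- list()
    for (mid in c("male", "female")) {
      rows <- list()
      for (ch in unique(truth$membership$chrom)) {
        mem <- truth$membership[truth$membership$chrom == ch, , drop = FALSE]
        mem <- mem[order(mem$ordinal), , drop = FALSE]
        ords <- mem$ordinal
        if (nrow(mem) > 1L && params$swap_prob > 0) {
          for (i in seq_len(nrow(mem) - 1L)) {
            if (stats::runif(1L) < params$swap_prob) {
              ords[c(i, i + 1L)] <- ords[c(i + 1L, i)]
            }
          }
        }
        for (i in seq_len(nrow(mem))) {
          for (j in seq_len(params$markers_per_scaffold)) {
            if (stats::runif(1L) < params$dropout) next
            pos <- ords[i] * params$spacing_cM +
              if (params$noise_sd > 0) stats::rnorm(1L, 0, params$noise_sd) else 0
            rows[[length(rows) + 1L]] <- data.frame(
              map_id = mid, lg_id = ch,
              marker_id = sprintf("%s_%s_m%d", mid, mem$scaffold_id[i], j),
              scaffold_id = mem$scaffold_id[i],
              position_cM = max(0, pos), stringsAsFactors = FALSE)
          }
        }
      }
      m <- if (length(rows) > 0L) do.call(rbind, rows) else {
        data.frame(map_id = character(), lg_id = character(),
                   marker_id = character(), scaffold_id = character(),
                   position_cM = numeric(), stringsAsFactors = FALSE)
      }
      out[[mid]] <- as_linkage_map(m)
    }
    out
  })
}

#' Precision/recall of inferred links against simulated truth
#'
#' A link is correct iff its extremity pair (orientation-aware: scaffold
#' plus 5p/3p side) is a true broken adjacency.
#'
#' @param inferred A `candidate_links` data.frame (accepted links).
#' @param truth A `sim_truth`.
#' @return List: `precision` (`NA` when nothing inferred), `recall` (`NA`
#'   when the truth set is empty), `n_inferred`, `n_correct`, `n_truth`.
#' @export
evaluate_links <- function(inferred, truth) {
  truth_keys <- truth$adjacencies$key
  inf_keys <- link_key(inferred$ext_a, inferred$ext_b)
  n_correct <- sum(inf_keys %in% truth_keys)
  list(
    precision = if (length(inf_keys) == 0L) NA_real_ else n_correct / length(inf_keys),
    recall = if (length(truth_keys) == 0L) NA_real_ else n_correct / length(truth_keys),
    n_inferred = length(inf_keys),
    n_correct = n_correct,
    n_truth = length(truth_keys)
  )
}

#' Write a simulated data set to disk in pipeline-ready formats
#'
#' Writes one GFF3 per genome, a combined gene-family table, the tree in
#' newick, the two linkage maps, a target scaffold-length TSV and the
#' ground truth as JSON. Gene coordinates are synthesised (1 kb per gene
#' slot); scaffold length is `(genes + 1) kb`.
#'
#' @param params A `sim_params`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths plus the in-memory
#'   simulation (`genomes`, `log`, `target`, `truth`, `maps`).
#' @export
simulate_to_dir <- function(params, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genomes(params)
  frag <- fragment_target(sim$genomes[[params$target_id]], params)
  maps <- simulate_maps(frag$truth, params)

  fam_rows <- list()
  paths <- list()
  write_genome_gff <- function(order, path) {
    rows <- list()
    for (sid in names(order$orders)) {
      o <- order$orders[[sid]]
      if (nrow(o) == 0L) next
      i <- seq_len(nrow(o))
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = sid, start0 = (i - 1L) * 1000L + 100L,
        end0 = (i - 1L) * 1000L + 600L,
        strand = ifelse(o$sign > 0L, "+", "-"),
        gene_id = o$gene_id, family = o$family, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(
      seqnames = tab$seq_id,
      ranges = IRanges::IRanges(start = tab$start0 + 1L, end = tab$end0),
      strand = tab$strand)
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$ID <- tab$gene_id
    rtracklayer::export(gr, path, format = "gff3")
    tab
  }
  for (gid in names(sim$genomes)) {
    p <- file.path(dir, paste0(gid, ".gff3"))
    ord <- if (gid == params$target_id) frag$order else sim$genomes[[gid]]
    tab <- write_genome_gff(ord, p)
    fam_rows[[gid]] <- tab[, c("gene_id", "family")]
    paths[[paste0("gff_", gid)]] <- p
  }
  fam_path <- file.path(dir, "families.tsv")
  utils::write.table(do.call(rbind, fam_rows), fam_path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = c("gene_id", "family_id"))
  tree_path <- file.path(dir, "tree.nwk")
  ape::write.tree(params$tree, tree_path)
  lens <- vapply(frag$order$orders, function(o) (nrow(o) + 1L) * 1000L, 0L)
  len_path <- file.path(dir, "target_lengths.tsv")
  utils::write.table(data.frame(seq_id = names(lens), length = lens),
                     len_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  map_paths <- c(file.path(dir, "map_male.tsv"), file.path(dir, "map_female.tsv"))
  write_linkage_map(maps$male, map_paths[1L])
  write_linkage_map(maps$female, map_paths[2L])
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(list(adjacencies = frag$truth$adjacencies,
                            membership = frag$truth$membership),
                       truth_path, dataframe = "columns")
  invisible(c(paths, list(
    families = fam_path, tree = tree_path, lengths = len_path,
    map_male = map_paths[1L], map_female = map_paths[2L],
    truth = truth_path,
    genomes = sim$genomes, log = sim$log,
    target = frag$order, truth_obj = frag$truth, maps = maps)))
}
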