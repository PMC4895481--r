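# Shared fixtures and independent oracles.

# Signed order data.frame for building gene_order objects by hand.
ord_df <- function(fams, signs) {
  ids <- if (length(fams) > 0L) paste0("g_", fams, "_", seq_along(fams)) else character()
  data.frame(family = as.character(fams), sign = as.integer(signs),
             gene_id = ids, stringsAsFactors = FALSE)
}

make_order <- function(genome_id, ...) {
  scaflink:::new_gene_order(genome_id, list(...))
}

# Toy-1 instance: target S1=[+a,+b], S2=[+c,+d], S3=[+e];
# refs R1=[+a,+b,+c,+d,+e], R2=[+a,+b,+x,+c,+d,+e], R3=[+a,+b,-d,-c,+e].
toy1 <- function() {
  target <- make_order("T",
                       S1 = ord_df(c("a", "b"), c(1, 1)),
                       S2 = ord_df(c("c", "d"), c(1, 1)),
                       S3 = ord_df("e", 1))
  refs <- list(
    R1 = make_order("R1", c1 = ord_df(c("a", "b", "c", "d", "e"), rep(1, 5))),
    R2 = make_order("R2", c1 = ord_df(c("a", "b", "x", "c", "d", "e"), rep(1, 6))),
    R3 = make_order("R3", c1 = ord_df(c("a", "b", "d", "c", "e"),
                                      c(1, 1, -1, -1, 1))))
  tf <- c("a", "b", "c", "d", "e")
  adj <- lapply(refs, function(r) {
    reference_adjacencies(restrict_to_shared(r, tf))
  })
  list(target = target, adj = adj,
       weights = c(R1 = 1, R2 = 1, R3 = 1), families = tf)
}

# Minimal GFF3 writer for fixtures (1-based inclusive, as the format is).
write_gff3_fixture <- function(path, rows) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    lines <- c(lines, paste(r$seq_id, "test", r$type, r$start, r$end, ".",
                            r$strand, ".", paste0("ID=", r$id), sep = "\t"))
  }
  writeLines(lines, path)
  path
}

write_family_fixture <- function(path, gene_ids, families) {
  writeLines(c("gene_id\tfamily_id", paste(gene_ids, families, sep = "\t")),
             path)
  path
}

write_map_fixture <- function(path, map_id, lg_id, marker_id, scaffold_id,
                              position_cM) {
  df <- data.frame(map_id = map_id, lg_id = lg_id, marker_id = marker_id,
                   scaffold_id = scaffold_id, position_cM = position_cM)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Candidate-links data.frame built directly (for matching tests).
make_candidates <- function(ext_a, ext_b, weight, n_genomes = 2L) {
  n <- length(weight)
  out <- data.frame(ext_a = as.character(pmin(ext_a, ext_b)),
                    ext_b = as.character(pmax(ext_a, ext_b)),
                    total_weight = weight,
                    n_genomes = rep_len(as.integer(n_genomes), n),
                    genomes = rep_len("", n), stringsAsFactors = FALSE)
  out$key <- if (n > 0L) paste(out$ext_a, out$ext_b, sep = "--") else character()
  class(out) <- c("candidate_links", "data.frame")
  out
}

# ---- independent oracles -------------------------------------------------

lex_less_chr <- function(x, y) {
  if (is.null(y)) return(TRUE)
  k <- min(length(x), length(y))
  if (k > 0L) {
    for (i in seq_len(k)) {
      if (x[i] < y[i]) return(TRUE)
      if (x[i] > y[i]) return(FALSE)
    }
  }
  length(x) < length(y)
}

# Exhaustive enumeration over all matchings (include/exclude every edge),
# same tie rule as the spec: max total weight, then lexicographically
# smallest sorted edge-key list.
brute_force_matching <- function(ext_a, ext_b, w, key) {
  n <- length(w)
  best <- list(w = -Inf, keys = NULL)
  rec <- function(i, used, keys, cur) {
    if (i > n) {
      ks <- sort(keys)
      if (cur > best$w ||
          (cur == best$w && lex_less_chr(ks, best$keys))) {
        best <<- list(w = cur, keys = ks)
      }
      return(invisible())
    }
    rec(i + 1L, used, keys, cur)
    if (!(ext_a[i] %in% used) && !(ext_b[i] %in% used)) {
      rec(i + 1L, c(used, ext_a[i], ext_b[i]), c(keys, key[i]), cur + w[i])
    }
    invisible()
  }
  rec(1L, character(), character(), 0)
  best
}

# Random matching instance on <= max_ext extremities; weights are exact
# binary fractions (k/2) so float sums compare exactly.
random_matching_instance <- function(seed, max_ext = 12L) {
  set.seed(seed)
  n_ext <- sample(2:max_ext, 1L)
  exts <- sprintf("S%02d:%s", seq_len(n_ext), sample(c("5p", "3p"), n_ext,
                                                     replace = TRUE))
  pairs <- t(utils::combn(exts, 2L))
  n_edges <- sample.int(min(nrow(pairs), 2L * n_ext), 1L)
  take <- sample.int(nrow(pairs), n_edges)
  make_candidates(pairs[take, 1L], pairs[take, 2L],
                  sample(1:10, n_edges, replace = TRUE) / 2)
}

# Brute-force Nx: scan descending lengths until the cumulative sum
# reaches the threshold.
brute_force_nx <- function(lengths, fraction) {
  s <- sort(lengths, decreasing = TRUE)
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= fraction * sum(lengths)) return(x)
  }
  s[length(s)]
}

# Checks that every edge of a resolved constraint graph is respected by
# the consensus order (chains mapped to their first member's position).
edges_respected <- function(graph, consensus) {
  members <- graph$members
  for (lg in names(graph$lgs)) {
    ord <- consensus[[lg]]
    pos_of_chain <- function(cid) {
      scafs <- members$scaffold_id[members$chain_id == cid]
      min(match(scafs, ord$scaffold_id))
    }
    e <- graph$lgs[[lg]]$edges
    if (nrow(e) == 0L) next
    for (i in seq_len(nrow(e))) {
      if (!(pos_of_chain(e$from[i]) < pos_of_chain(e$to[i]))) return(FALSE)
    }
  }
  TRUE
}

# True per-chromosome scaffold orders from simulator truth.
true_orders <- function(truth) {
  lapply(split(truth$membership, truth$membership$chrom), function(mem) {
    mem$scaffold_id[order(mem$ordinal)]
  })
}

# Shared moderate-rate simulation + inference used by the noise tests.
run_noisy_inference <- function(seed) {
  p <- sim_params(rates = c(inversion = 5, translocation = 1, fusion = 0,
                            fission = 0, deletion = 1, insertion = 1,
                            duplication = 0.5),
                  n_families = 400L, n_chrom = 10L, breaks_per_chrom = 5,
                  seed = seed)
  sim <- simulate_genomes(p)
  frag <- fragment_target(sim$genomes$Target, p)
  tf <- unique(unlist(lapply(frag$order$orders, function(o) o$family)))
  refs <- setdiff(names(sim$genomes), "Target")
  adj <- lapply(sim$genomes[refs], function(g) {
    reference_adjacencies(restrict_to_shared(filter_empty_scaffolds(g), tf))
  })
  w <- genome_weights(p$tree, "Target", refs)
  cand <- candidate_links(filter_empty_scaffolds(frag$order), adj, w)
  acc <- select_links(cand, 2L)
  list(params = p, truth = frag$truth, target = frag$order,
       candidates = cand, accepted = acc,
       eval = evaluate_links(acc, frag$truth))
}
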