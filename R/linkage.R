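# Linkage-map integration: chains (super-scaffolds) are assigned to
# linkage groups by majority vote over their members' markers, the male
# and female maps are merged into a per-group precedence DAG, conflicting
# precedence is resolved by discarding the weakest map evidence, and a
# topological sort yields a consensus scaffold order per group. Only
# ordinal positions are reported: recombination distance between newly
# joined scaffolds is not observable from the maps.

chain_members_table <- function(chains) {
  data.frame(
    chain_id = rep(vapply(chains, chain_id, ""),
                   vapply(chains, function(ch) length(ch$members), 0L)),
    scaffold_id = unlist(lapply(chains, function(ch) ch$members)),
    orientation = unlist(lapply(chains, function(ch) ch$orient)),
    stringsAsFactors = FALSE
  )
}

combine_maps <- function(maps) {
  if (inherits(maps, "linkage_map")) return(maps)
  do.call(rbind, lapply(maps, as.data.frame))
}

#' Anchor chains into linkage groups by marker majority
#'
#' A chain's marker tally aggregates both maps over its member scaffolds.
#' The chain is placed on the linkage group holding at least `majority` of
#' its markers; otherwise it is left unplaced with reason `"ambiguous"`
#' (markers split across groups) or `"no_markers"`.
#'
#' @param maps A `linkage_map` or list of them (e.g. male and female).
#' @param chains A `chain_list`.
#' @param majority Required marker fraction in (0.5, 1], default 2/3:
#'   tolerates one stray marker on small tallies without accepting 50/50
#'   conflicts.
#' @return An `anchoring`: list with `assignments` (data.frame `chain_id`,
#'   `lg_id`, `n_markers`, `status`, `reason`), `tally` (per-chain
#'   per-group marker counts), and `members` (chain membership table).
#' @export
anchor_chains <- function(maps, chains, majority = 2 / 3) {
  stopifnot(majority > 0.5, majority <= 1)
  m <- combine_maps(maps)
  members <- chain_members_table(chains)
  chain_of <- stats::setNames(members$chain_id, members$scaffold_id)

  ids <- vapply(chains, chain_id, "")
  tally <- stats::setNames(vector("list", length(ids)), ids)
  hit <- m[m$scaffold_id %in% names(chain_of), , drop = FALSE]
  if (nrow(hit) > 0L) {
    cnt <- table(chain_of[hit$scaffold_id], hit$lg_id)
    for (cid in rownames(cnt)) {
      v <- stats::setNames(as.integer(cnt[cid, ]), colnames(cnt))
      tally[[cid]] <- v[v > 0]
    }
  }
  assignments <- do.call(rbind, lapply(ids, function(cid) {
    tl <- tally[[cid]]
    if (is.null(tl) || sum(tl) == 0L) {
      return(data.frame(chain_id = cid, lg_id = NA_character_,
                        n_markers = 0L, status = "unplaced",
                        reason = "no_markers", stringsAsFactors = FALSE))
    }
    top <- which.max(tl)
    if (tl[[top]] / sum(tl) >= majority) {
      data.frame(chain_id = cid, lg_id = names(tl)[top],
                 n_markers = as.integer(sum(tl)), status = "placed",
                 reason = NA_character_, stringsAsFactors = FALSE)
    } else {
      data.frame(chain_id = cid, lg_id = NA_character_,
                 n_markers = as.integer(sum(tl)), status = "unplaced",
                 reason = "ambiguous", stringsAsFactors = FALSE)
    }
  }))
  rownames(assignments) <- NULL
  structure(list(assignments = assignments, tally = tally,
                 members = members),
            class = "anchoring")
}

#' @export
print.anchoring <- function(x, ...) {
  n <- nrow(x$assignments)
  cat("<anchoring> ", sum(x$assignments$status == "placed"), "/", n,
      " chain(s) placed\n", sep = "")
  invisible(x)
}

#' Build the per-linkage-group precedence graph from both maps
#'
#' Within each map and linkage group, placed chains carrying at least one
#' marker in that map are ranked by the mean centimorgan position of their
#' markers; a directed edge `u -> v` is added between consecutive distinct
#' ranks (mean(u) < mean(v)). Chains with equal means give no edge.
#' Only consecutive ranks are connected (same transitive closure as all
#' pairs, smaller graph, cleaner removal provenance). Edge provenance
#' records the map, the weaker endpoint's marker count, and the cM gap.
#'
#' @param anchoring An `anchoring` from [anchor_chains()].
#' @param maps A `linkage_map` or list of them.
#' @param chains The `chain_list` the anchoring was built from.
#' @return A `constraint_graph`: per linkage group, `nodes` (data.frame
#'   `chain_id`, `mean_cM`, `n_markers` over both maps) and `edges`
#'   (data.frame `from`, `to`, `type`, `map_id`, `support`, `gap`).
#' @export
build_constraint_graph <- function(anchoring, maps, chains) {
  m <- combine_maps(maps)
  placed <- anchoring$assignments[anchoring$assignments$status == "placed", ,
                                  drop = FALSE]
  members <- anchoring$members
  chain_of <- stats::setNames(members$chain_id, members$scaffold_id)
  m$chain_id <- chain_of[m$scaffold_id]
  m <- m[!is.na(m$chain_id), , drop = FALSE]
  lg_of <- stats::setNames(placed$lg_id, placed$chain_id)
  # only markers on the chain's assigned group constrain its position
  m <- m[!is.na(lg_of[m$chain_id]) & m$lg_id == lg_of[m$chain_id], ,
         drop = FALSE]

  lgs <- sort(unique(placed$lg_id))
  graph <- stats::setNames(vector("list", length(lgs)), lgs)
  for (lg in lgs) {
    node_ids <- sort(placed$chain_id[placed$lg_id == lg])
    mlg <- m[m$lg_id == lg, , drop = FALSE]
    mean_both <- tapply(mlg$position_cM, mlg$chain_id, mean)
    n_both <- table(mlg$chain_id)
    nodes <- data.frame(
      chain_id = node_ids,
      mean_cM = as.numeric(mean_both[node_ids]),
      n_markers = as.integer(n_both[node_ids]),
      stringsAsFactors = FALSE)
    nodes$mean_cM[is.na(nodes$mean_cM)] <- Inf
    nodes$n_markers[is.na(nodes$n_markers)] <- 0L

    edges <- empty_edges()
    for (mid in sort(unique(mlg$map_id))) {
      mm <- mlg[mlg$map_id == mid, , drop = FALSE]
      mu <- tapply(mm$position_cM, mm$chain_id, mean)
      cnt <- table(mm$chain_id)
      mu <- sort(mu)
      # group ties, connect consecutive distinct-mean groups
      groups <- split(names(mu), match(mu, unique(mu)))
      if (length(groups) >= 2L) {
        for (i in seq_len(length(groups) - 1L)) {
          for (u in groups[[i]]) for (v in groups[[i + 1L]]) {
            edges <- rbind(edges, data.frame(
              from = u, to = v, type = "map", map_id = mid,
              support = min(cnt[[u]], cnt[[v]]),
              gap = unname(mu[match(v, names(mu))] -
                             mu[match(u, names(mu))]),
              stringsAsFactors = FALSE))
          }
        }
      }
    }
    edges <- edges[order(edges$from, edges$to, edges$map_id), , drop = FALSE]
    rownames(edges) <- NULL
    graph[[lg]] <- list(nodes = nodes, edges = edges)
  }
  structure(list(lgs = graph, members = members),
            class = "constraint_graph")
}

empty_edges <- function() {
  data.frame(from = character(), to = character(), type = character(),
             map_id = character(), support = integer(), gap = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.constraint_graph <- function(x, ...) {
  ne <- sum(vapply(x$lgs, function(g) nrow(g$edges), 0L))
  cat("<constraint_graph> ", length(x$lgs), " linkage group(s), ", ne,
      " precedence edge(s)\n", sep = "")
  invisible(x)
}

# Deterministic cycle finder: DFS from the smallest node id, neighbours in
# sorted order; returns row indices of the edges on one cycle, or NULL.
find_edge_cycle <- function(nodes, edges) {
  if (nrow(edges) == 0L) return(NULL)
  succ <- split(seq_len(nrow(edges)), edges$from)
  color <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new 1 open 2 done
  stack_rows <- integer()
  found <- NULL
  dfs <- function(v) {
    if (!is.null(found)) return(invisible())
    color[[v]] <<- 1L
    rows <- succ[[v]]
    if (!is.null(rows)) {
      rows <- rows[order(edges$to[rows], edges$map_id[rows])]
      for (r in rows) {
        if (!is.null(found)) return(invisible())
        u <- edges$to[r]
        if (color[[u]] == 1L) {
          # back edge: cycle = rows on stack from u onward, plus r
          onpath <- stack_rows
          start <- match(u, edges$from[onpath])
          found <<- c(onpath[start:length(onpath)], r)
          return(invisible())
        }
        if (color[[u]] == 0L) {
          stack_rows <<- c(stack_rows, r)
          dfs(u)
          stack_rows <<- stack_rows[-length(stack_rows)]
        }
      }
    }
    color[[v]] <<- 2L
    invisible()
  }
  for (v in sort(nodes)) {
    if (color[[v]] == 0L) dfs(v)
    if (!is.null(found)) return(found)
  }
  NULL
}

#' Remove conflicting precedence edges until the graph is acyclic
#'
#' Male and female maps can disagree; while a cycle exists, the edge on it
#' with the lowest supporting-marker count (ties: smallest cM gap, then
#' lexicographic endpoints) is removed and reported. Edges encoding a
#' chain's internal scaffold order are never removed; a cycle consisting
#' solely of such edges indicates inconsistent chains and is an error.
#'
#' @param graph A `constraint_graph`.
#' @return List: the acyclic `graph` and `removed`, a data.frame of the
#'   removed edges with their linkage group and provenance.
#' @export
resolve_cycles <- function(graph) {
  removed <- cbind(data.frame(lg = character(), stringsAsFactors = FALSE),
                   empty_edges())
  for (lg in names(graph$lgs)) {
    g <- graph$lgs[[lg]]
    repeat {
      cyc <- find_edge_cycle(g$nodes$chain_id, g$edges)
      if (is.null(cyc)) break
      cand <- cyc[g$edges$type[cyc] != "chain_internal"]
      if (length(cand) == 0L) {
        stop("inconsistent chains: cycle of chain-internal edges in ", lg)
      }
      pick <- cand[order(g$edges$support[cand], g$edges$gap[cand],
                         g$edges$from[cand], g$edges$to[cand])][1L]
      removed <- rbind(removed,
                       cbind(data.frame(lg = lg, stringsAsFactors = FALSE),
                             g$edges[pick, , drop = FALSE]))
      g$edges <- g$edges[-pick, , drop = FALSE]
    }
    graph$lgs[[lg]] <- g
  }
  rownames(removed) <- NULL
  list(graph = graph, removed = removed)
}

#' Consensus scaffold order per linkage group by topological sort
#'
#' Kahn's algorithm on the resolved precedence graph; when several chains
#' are simultaneously available the one with the smallest mean cM over
#' both maps is emitted first (chains without markers rank last), ties by
#' chain id, so output is deterministic. Chains are then flattened to
#' their member scaffolds with chain orientations; positions are ordinals.
#'
#' @param graph An acyclic `constraint_graph` (run [resolve_cycles()]
#'   first if the maps may conflict).
#' @return A `consensus_order`: named list, one data.frame per linkage
#'   group with columns `position`, `scaffold_id`, `orientation`.
#' @export
topological_consensus <- function(graph) {
  members <- graph$members
  out <- list()
  for (lg in names(graph$lgs)) {
    g <- graph$lgs[[lg]]
    nodes <- g$nodes$chain_id
    prio <- stats::setNames(g$nodes$mean_cM, nodes)
    pairs <- unique(g$edges[, c("from", "to")])
    indeg <- stats::setNames(rep(0L, length(nodes)), nodes)
    if (nrow(pairs) > 0L) {
      tb <- table(pairs$to)
      indeg[names(tb)] <- as.integer(tb)
    }
    emitted <- character()
    while (length(emitted) < length(nodes)) {
      avail <- setdiff(names(indeg)[indeg == 0L], emitted)
      if (length(avail) == 0L) {
        stop("cycle detected in constraint graph for ", lg,
             "; run resolve_cycles() first")
      }
      nxt <- avail[order(prio[avail], avail)][1L]
      emitted <- c(emitted, nxt)
      indeg[nxt] <- -1L
      if (nrow(pairs) > 0L) {
        for (v in pairs$to[pairs$from == nxt]) indeg[v] <- indeg[v] - 1L
      }
    }
    rows <- do.call(rbind, lapply(emitted, function(cid) {
      mm <- members[members$chain_id == cid, , drop = FALSE]
      data.frame(scaffold_id = mm$scaffold_id,
                 orientation = mm$orientation, stringsAsFactors = FALSE)
    }))
    if (is.null(rows)) {
      rows <- data.frame(scaffold_id = character(),
                         orientation = character(), stringsAsFactors = FALSE)
    }
    out[[lg]] <- data.frame(position = seq_len(nrow(rows)),
                            scaffold_id = rows$scaffold_id,
                            orientation = rows$orientation,
                            stringsAsFactors = FALSE)
  }
  if (length(out) > 0L) out <- out[order(names(out))]
  structure(out, class = "consensus_order")
}

#' @export
print.consensus_order <- function(x, ...) {
  cat("<consensus_order> ", length(x), " linkage group(s), ",
      sum(vapply(x, nrow, 0L)), " ordered scaffold(s)\n", sep = "")
  invisible(x)
}

#' Linkage-group coverage of the assembly
#'
#' Percent of assembly bases lying on scaffolds that belong to placed
#' chains; the statistic the anchoring is meant to improve.
#'
#' @param anchoring An `anchoring`.
#' @param lengths Named vector of scaffold lengths in bases.
#' @param total_assembly_bases Total assembly size in bases (> 0).
#' @return Coverage percent, rounded to 0.1.
#' @export
lg_coverage <- function(anchoring, lengths, total_assembly_bases) {
  stopifnot(total_assembly_bases > 0)
  placed_chains <- anchoring$assignments$chain_id[
    anchoring$assignments$status == "placed"]
  scafs <- anchoring$members$scaffold_id[
    anchoring$members$chain_id %in% placed_chains]
  miss <- setdiff(scafs, names(lengths))
  if (length(miss) > 0L) stop("scaffold '", miss[1L], "' has no length entry")
  round(100 * sum(lengths[scafs]) / total_assembly_bases, 1)
}
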