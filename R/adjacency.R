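# Breakpoint-graph machinery. Each signed gene occurrence +g has a tail
# (5' end) and a head (3' end); reading left to right, +g exposes its tail
# on the left and its head on the right, and -g the reverse. An adjacency
# is an unordered pair of endpoints of consecutive genes. Conserved
# adjacencies across reference genomes that straddle two target scaffold
# extremities are the evidence for joining those scaffolds.

endpoint_right <- function(family, sign) {
  paste0(family, ".", ifelse(sign > 0L, "head", "tail"))
}
endpoint_left <- function(family, sign) {
  paste0(family, ".", ifelse(sign > 0L, "tail", "head"))
}
adjacency_key <- function(p, q) {
  paste(pmin(p, q), pmax(p, q), sep = "--")
}
ext_label <- function(scaffold, side) paste0(scaffold, ":", side)
link_key <- function(ext_a, ext_b) {
  paste(pmin(ext_a, ext_b), pmax(ext_a, ext_b), sep = "--")
}

#' Phylogenetic weights for reference genomes
#'
#' A conserved adjacency in a close relative is stronger evidence for the
#' ancestral (hence target) gene order than one in a distant relative, so
#' each genome's vote is weighted by the inverse of its patristic distance
#' to the target on the supplied tree. When any branch length is missing
#' the tree is treated as topology-only and every genome gets weight 1.
#'
#' @param tree An `ape::phylo` tree whose tips are genome ids.
#' @param target_id Target genome tip label.
#' @param ref_ids Reference genome tip labels.
#' @return Named numeric vector of weights, one per reference.
#' @export
genome_weights <- function(tree, target_id, ref_ids) {
  missing <- setdiff(c(target_id, ref_ids), tree$tip.label)
  if (length(missing) > 0L) {
    stop("genome '", missing[1L], "' is not a leaf of the tree")
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    return(stats::setNames(rep(1, length(ref_ids)), ref_ids))
  }
  d <- ape::cophenetic.phylo(tree)[target_id, ref_ids]
  if (any(d <= 0)) stop("zero patristic distance between target and a reference")
  stats::setNames(1 / d, ref_ids)
}

#' Conserved adjacencies of a (projected) reference gene order
#'
#' For each sequence `[x1 ... xn]` emits the endpoint pair
#' `{right(xi), left(xi+1)}` for every consecutive pair; the per-genome
#' multiset is collapsed to a set.
#'
#' @param projected_ref A `gene_order`, typically after
#'   [restrict_to_shared()].
#' @return Character vector of adjacency keys (sorted endpoint pairs
#'   joined by `--`), unique within the genome.
#' @export
reference_adjacencies <- function(projected_ref) {
  keys <- lapply(projected_ref$orders, function(o) {
    n <- nrow(o)
    if (n < 2L) return(character())
    adjacency_key(endpoint_right(o$family[-n], o$sign[-n]),
                  endpoint_left(o$family[-1L], o$sign[-1L]))
  })
  sort(unique(unlist(keys, use.names = FALSE)))
}

# Endpoints exposed at the extremities of each target scaffold.
# For scaffold order [g1...gk]: the 3p extremity exposes right(gk), the 5p
# extremity exposes left(g1). With terminal window k > 1 the outermost
# min(k, len) occurrences also expose their outward-facing endpoint, at
# offset o from the terminus with evidence decay delta^o.
target_exposures <- function(target, window = 1L, decay = 0.5) {
  rows <- list()
  for (sid in names(target$orders)) {
    o <- target$orders[[sid]]
    n <- nrow(o)
    if (n == 0L) next
    k <- min(window, n)
    offs <- seq_len(k) - 1L
    i3 <- n - offs
    rows[[length(rows) + 1L]] <- data.frame(
      ext = ext_label(sid, "3p"), scaffold = sid,
      endpoint = endpoint_right(o$family[i3], o$sign[i3]),
      offset = offs, decay = decay^offs, stringsAsFactors = FALSE)
    i5 <- 1L + offs
    rows[[length(rows) + 1L]] <- data.frame(
      ext = ext_label(sid, "5p"), scaffold = sid,
      endpoint = endpoint_left(o$family[i5], o$sign[i5]),
      offset = offs, decay = decay^offs, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(ext = character(), scaffold = character(),
                      endpoint = character(), offset = integer(),
                      decay = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Score candidate scaffold joins from conserved reference adjacencies
#'
#' For every pair of extremities of distinct target scaffolds whose
#' exposed endpoints match an adjacency conserved in a reference genome,
#' that genome contributes support `weight * decay^(o_a + o_b)` where
#' `o_a`, `o_b` are the offsets of the matched occurrences from their
#' scaffold termini (0 for strict terminal genes). A genome supports a
#' candidate at most once (its best-decay occurrence pair). Candidates
#' with no support are omitted. Extremities whose terminal family is
#' multi-copy in the target still form candidates; the ambiguity is
#' resolved globally by [select_links()].
#'
#' @param target Target `gene_order` (filtered, non-empty scaffolds).
#' @param ref_adjacencies Named list: genome id -> adjacency key vector
#'   from [reference_adjacencies()].
#' @param weights Named numeric vector of genome weights
#'   (see [genome_weights()]).
#' @param window Terminal window size k >= 1 (default 1: strict terminal
#'   evidence).
#' @param decay Per-offset evidence decay in (0, 1] for window > 1
#'   (default 0.5).
#' @return A `candidate_links` data.frame: `ext_a`, `ext_b`,
#'   `total_weight`, `n_genomes`, `genomes` (semicolon-joined
#'   `genome:weight` support), `key`.
#' @export
candidate_links <- function(target, ref_adjacencies, weights,
                            window = 1L, decay = 0.5) {
  stopifnot(window >= 1L, decay > 0, decay <= 1)
  exp_tab <- target_exposures(target, window, decay)
  by_endpoint <- split(seq_len(nrow(exp_tab)), exp_tab$endpoint)

  support <- list()  # key -> named numeric (genome -> best contribution)
  for (g in names(ref_adjacencies)) {
    w <- weights[[g]]
    if (is.null(w) || is.na(w)) stop("no weight for genome '", g, "'")
    for (adj in ref_adjacencies[[g]]) {
      pq <- strsplit(adj, "--", fixed = TRUE)[[1L]]
      ia <- by_endpoint[[pq[1L]]]
      ib <- by_endpoint[[pq[2L]]]
      if (is.null(ia) || is.null(ib)) next
      grid <- expand.grid(a = ia, b = ib)
      grid <- grid[exp_tab$scaffold[grid$a] != exp_tab$scaffold[grid$b], ,
                   drop = FALSE]
      if (nrow(grid) == 0L) next
      kk <- link_key(exp_tab$ext[grid$a], exp_tab$ext[grid$b])
      contrib <- w * exp_tab$decay[grid$a] * exp_tab$decay[grid$b]
      best <- tapply(contrib, kk, max)
      for (j in seq_along(best)) {
        key <- names(best)[j]
        cur <- support[[key]]
        if (is.null(cur)) cur <- numeric()
        if (!(g %in% names(cur)) || best[[j]] > cur[[g]]) {
          cur[[g]] <- best[[j]]
        }
        support[[key]] <- cur
      }
    }
  }
  keys <- sort(names(support))
  if (length(keys) == 0L) return(empty_candidate_links())
  ext_ab <- strsplit(keys, "--", fixed = TRUE)
  out <- data.frame(
    ext_a = vapply(ext_ab, `[[`, "", 1L),
    ext_b = vapply(ext_ab, `[[`, "", 2L),
    total_weight = vapply(keys, function(k) sum(support[[k]]), 0),
    n_genomes = vapply(keys, function(k) length(support[[k]]), 0L),
    genomes = vapply(keys, function(k) {
      s <- support[[k]]
      s <- s[order(names(s))]
      paste0(names(s), ":", format(s, trim = TRUE, digits = 10),
             collapse = ";")
    }, ""),
    key = keys,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("candidate_links", "data.frame")
  out
}

empty_candidate_links <- function() {
  out <- data.frame(ext_a = character(), ext_b = character(),
                    total_weight = numeric(), n_genomes = integer(),
                    genomes = character(), key = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("candidate_links", "data.frame")
  out
}

#' Select a conflict-free set of links by exact maximum-weight matching
#'
#' Candidates are first filtered by the multi-witness rule (`min_genomes`)
#' and a minimum total weight; each extremity can participate in at most
#' one join, so the surviving candidates form a weighted graph on scaffold
#' extremities and the accepted set is a maximum-total-weight matching,
#' computed exactly (branch-and-bound per connected component). Ties
#' between equal-weight matchings are broken by preferring the
#' lexicographically smallest sorted edge list, making the output
#' deterministic.
#'
#' @param candidates A `candidate_links` data.frame.
#' @param min_genomes Minimum number of distinct supporting genomes
#'   (default 2: a single genome's adjacency can be a lineage-specific
#'   rearrangement).
#' @param min_weight Minimum total support weight (default 0).
#' @return The accepted subset of `candidates`, sorted by `key`.
#' @export
select_links <- function(candidates, min_genomes = 2L, min_weight = 0) {
  stopifnot(min_genomes >= 1L, min_weight >= 0)
  keep <- candidates$n_genomes >= min_genomes &
    candidates$total_weight >= min_weight
  cand <- candidates[keep, , drop = FALSE]
  if (nrow(cand) == 0L) {
    out <- cand
    rownames(out) <- NULL
    class(out) <- c("candidate_links", "data.frame")
    return(out)
  }
  sel <- max_weight_matching(cand$ext_a, cand$ext_b, cand$total_weight,
                             cand$key)
  out <- cand[sel, , drop = FALSE]
  out <- out[order(out$key), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_links", "data.frame")
  out
}

# Exact maximum-weight matching on a general graph, small components
# assumed (extremity-conflict graphs are sparse: degree is bounded by the
# number of adjacencies an endpoint takes part in across genomes).
# Returns indices of selected edges. Tie rule: among maximum-weight
# matchings prefer the lexicographically smallest sorted vector of edge
# keys.
max_weight_matching <- function(a, b, w, key) {
  n <- length(a)
  if (n == 0L) return(integer())
  verts <- sort(unique(c(a, b)))
  ai <- match(a, verts); bi <- match(b, verts)
  # union-find on vertices
  parent <- seq_along(verts)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (e in seq_len(n)) {
    ra <- find(ai[e]); rb <- find(bi[e])
    if (ra != rb) parent[ra] <- rb
  }
  comp_of_edge <- vapply(seq_len(n), function(e) find(ai[e]), 0L)

  selected <- integer()
  for (comp in unique(comp_of_edge)) {
    eidx <- which(comp_of_edge == comp)
    selected <- c(selected, eidx[match_component(ai[eidx], bi[eidx],
                                                 w[eidx], key[eidx])])
  }
  sort(selected)
}

# Branch and bound within one connected component. Edges indexed locally.
match_component <- function(ai, bi, w, key) {
  m <- length(w)
  verts <- sort(unique(c(ai, bi)))
  inc <- lapply(verts, function(v) which(ai == v | bi == v))
  names(inc) <- as.character(verts)
  ord <- order(key)  # deterministic branching order

  best_w <- -Inf
  best_keys <- NULL
  best_sel <- integer()

  rec <- function(vpos, used, sel, cur_w) {
    # upper bound: current + all edges not touching a used vertex
    avail <- vapply(seq_len(m), function(e) {
      !(ai[e] %in% used) && !(bi[e] %in% used)
    }, TRUE)
    ub <- cur_w + sum(w[avail])
    if (ub < best_w) return(invisible())
    if (vpos > length(verts)) {
      keys_sorted <- sort(key[sel])
      if (cur_w > best_w ||
          (cur_w == best_w && lex_less(keys_sorted, best_keys))) {
        best_w <<- cur_w
        best_keys <<- keys_sorted
        best_sel <<- sel
      }
      return(invisible())
    }
    v <- verts[vpos]
    if (v %in% used) {
      rec(vpos + 1L, used, sel, cur_w)
      return(invisible())
    }
    # branch: leave v unmatched
    rec(vpos + 1L, used, sel, cur_w)
    # branch: match v along each available incident edge
    for (e in intersect(ord, inc[[as.character(v)]])) {
      u <- if (ai[e] == v) bi[e] else ai[e]
      if (u %in% used) next
      rec(vpos + 1L, c(used, v, u), c(sel, e), cur_w + w[e])
    }
    invisible()
  }
  rec(1L, integer(), integer(), 0)
  best_sel
}

# TRUE if sorted character vector x is lexicographically smaller than y
# (element-wise, shorter prefix wins).
lex_less <- function(x, y) {
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

new_chain <- function(members, orient, links = NULL) {
  structure(list(members = as.character(members),
                 orient = as.character(orient),
                 links = links),
            class = "chain")
}

#' @export
print.chain <- function(x, ...) {
  cat("<chain> ", paste0(x$members, ":", x$orient, collapse = " -> "),
      "\n", sep = "")
  invisible(x)
}

chain_id <- function(chain) paste(sort(chain$members), collapse = "__")

chain_tokens <- function(members, orient) paste0(members, ":", orient)

chain_canonical <- function(members, orient, links = NULL) {
  rev_members <- rev(members)
  rev_orient <- rev(ifelse(orient == "+", "-", "+"))
  fwd <- chain_tokens(members, orient)
  bwd <- chain_tokens(rev_members, rev_orient)
  if (lex_less(bwd, fwd)) {
    new_chain(rev_members, rev_orient, links)
  } else {
    new_chain(members, orient, links)
  }
}

#' Assemble accepted links into oriented super-scaffold chains
#'
#' The accepted links form a matching on extremities, so each scaffold has
#' degree at most two and the link graph decomposes into paths and cycles.
#' Chromosomes are linear, so each cycle is broken at its lowest-weight
#' link (ties by lexicographic link key: the least-supported join is the
#' least trusted). Every path becomes a chain whose member orientations
#' satisfy all internal links (a 3' extremity exits a `+` scaffold on the
#' right, a 5' extremity a `-` one); a chain's canonical form is the
#' lexicographically smaller of itself and its reverse complement.
#' Scaffolds without accepted links become singleton `+` chains.
#'
#' @param accepted Accepted links ([select_links()] output).
#' @param all_scaffolds Character vector of every scaffold id.
#' @return A `chain_list` partitioning `all_scaffolds`, sorted by chain id.
#' @export
build_chains <- function(accepted, all_scaffolds) {
  exts <- c(accepted$ext_a, accepted$ext_b)
  if (anyDuplicated(exts)) {
    stop("accepted links do not form a matching: extremity '",
         exts[duplicated(exts)][1L], "' used twice")
  }
  links <- accepted
  repeat {
    cyc <- find_scaffold_cycle(links)
    if (is.null(cyc)) break
    drop <- cyc[order(links$total_weight[cyc], links$key[cyc])][1L]
    links <- links[-drop, , drop = FALSE]
  }

  split_ext <- function(e) {
    m <- regmatches(e, regexpr(":(5p|3p)$", e))
    c(substr(e, 1L, nchar(e) - 3L), substring(m, 2L))
  }
  # per scaffold: which sides are linked, and to what
  link_at <- list()  # "scaffold:side" -> list(other_scaffold, other_side, row)
  for (i in seq_len(nrow(links))) {
    pa <- split_ext(links$ext_a[i]); pb <- split_ext(links$ext_b[i])
    link_at[[links$ext_a[i]]] <- list(sc = pb[1L], side = pb[2L], row = i)
    link_at[[links$ext_b[i]]] <- list(sc = pa[1L], side = pa[2L], row = i)
  }
  linked_sides <- function(sc) {
    c("5p", "3p")[c(!is.null(link_at[[ext_label(sc, "5p")]]),
                    !is.null(link_at[[ext_label(sc, "3p")]]))]
  }

  linked_scaffolds <- unique(unlist(lapply(seq_len(nrow(links)), function(i) {
    c(split_ext(links$ext_a[i])[1L], split_ext(links$ext_b[i])[1L])
  })))
  chains <- list()
  visited <- character()
  # path endpoints: scaffolds with exactly one linked side
  ends <- sort(Filter(function(sc) length(linked_sides(sc)) == 1L,
                      linked_scaffolds))
  for (start in ends) {
    if (start %in% visited) next
    free_side <- setdiff(c("5p", "3p"), linked_sides(start))
    # orient so the free side faces left: left side of a + scaffold is 5p
    cur <- start
    cur_orient <- if (free_side == "5p") "+" else "-"
    members <- cur
    orient <- cur_orient
    rows <- integer()
    repeat {
      right_side <- if (cur_orient == "+") "3p" else "5p"
      nxt <- link_at[[ext_label(cur, right_side)]]
      if (is.null(nxt)) break
      rows <- c(rows, nxt$row)
      cur <- nxt$sc
      cur_orient <- if (nxt$side == "5p") "+" else "-"
      members <- c(members, cur)
      orient <- c(orient, cur_orient)
    }
    visited <- c(visited, members)
    chains[[length(chains) + 1L]] <-
      chain_canonical(members, orient, links[rows, , drop = FALSE])
  }
  for (sc in sort(setdiff(all_scaffolds, visited))) {
    chains[[length(chains) + 1L]] <- new_chain(sc, "+")
  }
  ids <- vapply(chains, chain_id, "")
  chains <- chains[order(ids)]
  structure(chains, class = "chain_list")
}

# Finds the row indices of links forming one cycle in the scaffold graph,
# or NULL if acyclic. Degree <= 2 per scaffold, so components are paths or
# simple cycles; a component is a cycle iff every member scaffold has both
# extremities linked.
find_scaffold_cycle <- function(links) {
  if (nrow(links) == 0L) return(NULL)
  sc_of <- function(e) sub(":(5p|3p)$", "", e)
  a <- sc_of(links$ext_a); b <- sc_of(links$ext_b)
  deg_ext <- table(c(links$ext_a, links$ext_b))
  scafs <- sort(unique(c(a, b)))
  both_linked <- vapply(scafs, function(sc) {
    !is.na(deg_ext[ext_label(sc, "5p")]) && !is.na(deg_ext[ext_label(sc, "3p")])
  }, TRUE)
  # walk components; a cycle component consists solely of both-linked scaffolds
  seen <- character()
  for (s0 in scafs[both_linked]) {
    if (s0 %in% seen) next
    comp <- s0
    frontier <- s0
    rows <- integer()
    while (length(frontier) > 0L) {
      nxt <- character()
      for (sc in frontier) {
        touch <- which(a == sc | b == sc)
        rows <- union(rows, touch)
        nbr <- setdiff(unique(c(a[touch], b[touch])), comp)
        comp <- c(comp, nbr)
        nxt <- c(nxt, nbr)
      }
      frontier <- nxt
    }
    seen <- c(seen, comp)
    if (all(comp %in% scafs[both_linked])) return(sort(rows))
  }
  NULL
}

#' @export
print.chain_list <- function(x, ...) {
  cat("<chain_list> ", length(x), " chain(s)\n", sep = "")
  for (ch in utils::head(x, 10L)) print(ch)
  if (length(x) > 10L) cat("...\n")
  invisible(x)
}
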