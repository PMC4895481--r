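#' Build a signed gene order from a gene table
#'
#' Represents a genome as, per sequence (scaffold or chromosome), the
#' ordered list of gene-family occurrences with an orientation sign taken
#' from the gene strand. This signed order is the substrate of all
#' adjacency-based scaffolding evidence.
#'
#' Occurrences are sorted by start coordinate; overlapping genes sharing a
#' start are ordered longer-first, then by gene id, so output is
#' deterministic.
#'
#' @param genes Gene table as returned by [read_gff_genes()].
#' @param genome_id Genome identifier.
#' @param seq_ids Optional character vector of all sequence ids of the
#'   genome; sequences without genes are then included as empty orders
#'   (useful for reporting how many scaffolds carry no homologous genes).
#' @return A `gene_order`: list with `genome_id` and `orders`, a named list
#'   of data.frames (`family`, `sign` in `{+1,-1}`, `gene_id`).
#' @export
build_gene_order <- function(genes, genome_id, seq_ids = NULL) {
  orders <- list()
  if (nrow(genes) > 0L) {
    o <- order(genes$seq_id, genes$start, -(genes$end - genes$start),
               genes$gene_id)
    genes <- genes[o, , drop = FALSE]
    for (sid in unique(genes$seq_id)) {
      g <- genes[genes$seq_id == sid, , drop = FALSE]
      orders[[sid]] <- data.frame(
        family = g$family,
        sign = ifelse(g$strand == "+", 1L, -1L),
        gene_id = g$gene_id,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!is.null(seq_ids)) {
    for (sid in setdiff(seq_ids, names(orders))) {
      orders[[sid]] <- data.frame(family = character(), sign = integer(),
                                  gene_id = character(),
                                  stringsAsFactors = FALSE)
    }
    orders <- orders[order(names(orders))]
  }
  new_gene_order(genome_id, orders)
}

new_gene_order <- function(genome_id, orders) {
  structure(list(genome_id = genome_id, orders = orders),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  n_occ <- sum(vapply(x$orders, nrow, 0L))
  cat("<gene_order> genome '", x$genome_id, "': ", length(x$orders),
      " sequence(s), ", n_occ, " gene occurrence(s)\n", sep = "")
  invisible(x)
}

#' Drop sequences that carry no homologous genes
#'
#' Scaffolds without any family-assigned gene contribute no adjacency
#' evidence and are removed before inference.
#'
#' @param order A `gene_order`.
#' @return The filtered `gene_order`, with attribute `n_removed`.
#' @export
filter_empty_scaffolds <- function(order) {
  keep <- vapply(order$orders, nrow, 0L) > 0L
  out <- new_gene_order(order$genome_id, order$orders[keep])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Project a reference gene order onto the target's family content
#'
#' Tolerates gene insertions/deletions and duplications instead of
#' restricting the analysis to universal single-copy genes: occurrences of
#' families absent from the target are deleted from the reference order
#' (they can never match a target extremity), and any family whose total
#' copy number within the reference genome exceeds `max_copy` is removed
#' entirely from that genome's projection, damping repeat-like families
#' that would otherwise generate spurious adjacency evidence. The relative
#' order and signs of surviving occurrences are preserved, so the result is
#' a subsequence of the input.
#'
#' @param ref A reference `gene_order`.
#' @param target_families Character vector (or set) of family ids present
#'   in the target genome.
#' @param max_copy Maximum tolerated copy number per family within the
#'   reference genome (default 10).
#' @return The projected `gene_order`.
#' @export
restrict_to_shared <- function(ref, target_families, max_copy = 10L) {
  stopifnot(max_copy >= 1L)
  copies <- table(unlist(lapply(ref$orders, function(o) o$family),
                         use.names = FALSE))
  over <- names(copies)[copies > max_copy]
  orders <- lapply(ref$orders, function(o) {
    keep <- o$family %in% target_families & !(o$family %in% over)
    o <- o[keep, , drop = FALSE]
    rownames(o) <- NULL
    o
  })
  new_gene_order(ref$genome_id, orders)
}
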