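#' Read genes from a GFF3 annotation with a gene-family assignment table
#'
#' Parses a GFF3 file, keeps features of the requested type, attaches gene
#' family identifiers from a two-column table, and returns a gene table in
#' internal 0-based half-open coordinates. Genes without a family assignment
#' are dropped (and counted): families are the homology alphabet of the
#' downstream gene-order analysis, so unassigned genes carry no evidence.
#'
#' @param gff3_path Path to a GFF3 file (1-based inclusive coordinates on
#'   disk, as the format specifies).
#' @param family_table Path to a tab-separated table mapping `gene_id` to
#'   `family_id`. A header row is optional and detected by name.
#' @param genome_id Identifier for the genome the annotation belongs to.
#' @param feature_type GFF3 feature type to extract (default `"gene"`;
#'   use e.g. `"mRNA"` for transcript-only annotations).
#' @return A `data.frame` with columns `gene_id`, `family`, `seq_id`,
#'   `start`, `end` (0-based half-open), `strand`, sorted by
#'   `(seq_id, start)`, with attributes `genome_id` and `n_dropped`
#'   (number of genes lacking a family assignment).
#' @export
read_gff_genes <- function(gff3_path, family_table, genome_id,
                           feature_type = "gene") {
  stopifnot(is.character(gff3_path), length(gff3_path) == 1L)
  if (!file.exists(gff3_path)) stop("GFF3 file not found: ", gff3_path)
  validate_gff3_lines(gff3_path)
  fam <- read_family_table(family_table)

  gr <- suppressWarnings(rtracklayer::import(gff3_path, format = "gff3"))
  gr <- gr[as.character(gr$type) == feature_type]
  if (length(gr) == 0L) {
    out <- empty_gene_table()
    attr(out, "genome_id") <- genome_id
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  ids <- as.character(S4Vectors::mcols(gr)$ID)
  if (is.null(ids) || anyNA(ids)) {
    nm <- as.character(S4Vectors::mcols(gr)$Name)
    ids[is.na(ids)] <- nm[is.na(ids)]
  }
  if (anyNA(ids)) stop("GFF3 feature of type '", feature_type,
                       "' lacks an ID attribute in ", gff3_path)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    bad <- ids[!strand %in% c("+", "-")][1L]
    stop("gene '", bad, "' has no usable strand (+/-) in ", gff3_path)
  }
  genes <- data.frame(
    gene_id = ids,
    family = unname(fam[ids]),
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,  # to 0-based half-open
    end = BiocGenerics::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
  n_dropped <- sum(is.na(genes$family))
  genes <- genes[!is.na(genes$family), , drop = FALSE]
  genes <- genes[order(genes$seq_id, genes$start, genes$gene_id), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  attr(genes, "genome_id") <- genome_id
  attr(genes, "n_dropped") <- n_dropped
  genes
}

empty_gene_table <- function() {
  data.frame(gene_id = character(), family = character(),
             seq_id = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

# Cheap structural scan so malformed lines are reported with their number;
# rtracklayer then does the real attribute parsing.
validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#")) {
      if (startsWith(ln, "##FASTA")) break
      next
    }
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 9L ||
        is.na(suppressWarnings(as.integer(fields[4L]))) ||
        is.na(suppressWarnings(as.integer(fields[5L])))) {
      stop("malformed GFF3 record at line ", i, " of ", path)
    }
  }
  invisible(TRUE)
}

#' Read a gene-to-family assignment table
#'
#' @param path Two-column TSV (`gene_id`, `family_id`); header optional.
#' @return Named character vector mapping gene id to family id.
#' @export
read_family_table <- function(path) {
  if (!file.exists(path)) stop("family table not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("family table must have two columns: ", path)
  raw <- raw[, 1:2]
  if (nrow(raw) > 0L &&
      grepl("^(gene_?id|gene|id)$", raw[1L, 1L], ignore.case = TRUE)) {
    raw <- raw[-1L, , drop = FALSE]
  }
  if (any(raw[[2L]] == "")) stop("empty family id in ", path)
  dup <- duplicated(raw[[1L]])
  if (any(dup)) {
    for (g in unique(raw[[1L]][dup])) {
      if (length(unique(raw[[2L]][raw[[1L]] == g])) > 1L) {
        stop("gene '", g, "' assigned to conflicting families in ", path)
      }
    }
    raw <- raw[!dup, , drop = FALSE]
  }
  stats::setNames(raw[[2L]], raw[[1L]])
}

#' Read sequence lengths from a FASTA index or two-column TSV
#'
#' @param path A `samtools faidx` `.fai` file or a TSV whose first two
#'   columns are sequence id and length in bases.
#' @return Named numeric vector (seq id to length).
#' @export
read_lengths <- function(path) {
  if (!file.exists(path)) stop("lengths file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) > 0L && is.character(raw[[2L]]) &&
      grepl("^(len|length|size)", raw[1L, 2L], ignore.case = TRUE)) {
    raw <- raw[-1L, , drop = FALSE]
  }
  lens <- as.numeric(raw[[2L]])
  ids <- as.character(raw[[1L]])
  if (anyNA(lens) || any(lens <= 0)) stop("non-positive or unparseable length in ", path)
  if (anyDuplicated(ids)) stop("duplicate sequence id in ", path)
  stats::setNames(lens, ids)
}

#' Read a linkage map TSV
#'
#' Expects columns `map_id`, `lg_id`, `marker_id`, `scaffold_id`,
#' `position_cM`. Entries are grouped by `(map_id, lg_id)` and sorted by
#' centimorgan position; ties are allowed (co-segregating markers).
#'
#' @param tsv_path Path to the map TSV (header required).
#' @return A `linkage_map`: a data.frame with the five columns above.
#' @export
read_linkage_map <- function(tsv_path) {
  if (!file.exists(tsv_path)) stop("linkage map not found: ", tsv_path)
  m <- utils::read.delim(tsv_path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("map_id", "lg_id", "marker_id", "scaffold_id", "position_cM")
  if (!all(need %in% names(m))) {
    stop("linkage map ", tsv_path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  m <- m[, need]
  m$position_cM <- as.numeric(m$position_cM)
  as_linkage_map(m)
}

#' Construct/validate a linkage map object
#'
#' @param m data.frame with columns `map_id`, `lg_id`, `marker_id`,
#'   `scaffold_id`, `position_cM`.
#' @return The validated, sorted `linkage_map`.
#' @export
as_linkage_map <- function(m) {
  if (anyNA(m$position_cM) || any(!is.finite(m$position_cM))) {
    stop("non-numeric or non-finite cM position in linkage map")
  }
  if (any(m$position_cM < 0)) stop("negative cM position in linkage map")
  key <- paste(m$map_id, m$marker_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (map_id, marker_id) in linkage map: ",
         gsub("\r", "/", d, fixed = TRUE))
  }
  m <- m[order(m$map_id, m$lg_id, m$position_cM, m$marker_id), , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("linkage_map", "data.frame")
  m
}

#' Write a linkage map TSV
#' @param map A `linkage_map`.
#' @param path Output path.
#' @export
write_linkage_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phylogenetic tree and check genome ids are leaves
#'
#' @param path Newick file.
#' @param target_id,ref_ids Genome ids that must appear as tips.
#' @return An `ape::phylo` tree.
#' @export
read_genome_tree <- function(path, target_id = NULL, ref_ids = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick tree: ", path)
  for (id in c(target_id, ref_ids)) {
    if (!id %in% tree$tip.label) stop("genome '", id, "' is not a leaf of the tree")
  }
  tree
}

#' Write candidate/accepted links as TSV
#'
#' Columns: `ext_a`, `ext_b` (scaffold extremities as `scaffold:5p|3p`),
#' `weight`, `n_genomes`, `genomes` (semicolon-joined supporting genomes).
#'
#' @param links A `candidate_links` data.frame.
#' @param path Output path.
#' @export
write_links_tsv <- function(links, path) {
  out <- data.frame(ext_a = links$ext_a, ext_b = links$ext_b,
                    weight = links$total_weight,
                    n_genomes = links$n_genomes,
                    genomes = links$genomes,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write super-scaffold chains as AGP 2.1
#'
#' One AGP object per chain; the object name is the sorted member scaffold
#' ids joined by `__` (deterministic). Components are `W` lines in chain
#' orientation; inter-scaffold gaps are `U` lines (unknown size, default
#' 100 bp) with `gap_type` "scaffold", linkage "yes" and evidence
#' "align_genus" (the closest standard code for cross-species gene-order
#' evidence). Object coordinates are 1-based and contiguous.
#'
#' @param chains A `chain_list` (see [build_chains()]).
#' @param lengths Named vector of scaffold lengths in bases.
#' @param gap_size Size written for `U` gap lines (>= 0, default 100).
#' @param out Output path.
#' @export
write_agp <- function(chains, lengths, gap_size = 100L, out) {
  stopifnot(gap_size >= 0)
  con <- file(out, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  for (ch in chains) {
    obj <- chain_id(ch)
    miss <- setdiff(ch$members, names(lengths))
    if (length(miss) > 0L) {
      stop("scaffold '", miss[1L], "' has no length entry")
    }
    pos <- 0L
    part <- 0L
    for (i in seq_along(ch$members)) {
      if (i > 1L && gap_size > 0L) {
        part <- part + 1L
        writeLines(paste(obj, pos + 1L, pos + gap_size, part, "U", gap_size,
                         "scaffold", "yes", "align_genus", sep = "\t"), con)
        pos <- pos + as.integer(gap_size)
      }
      len <- as.integer(lengths[[ch$members[i]]])
      part <- part + 1L
      writeLines(paste(obj, pos + 1L, pos + len, part, "W", ch$members[i],
                       1L, len, ch$orient[i], sep = "\t"), con)
      pos <- pos + len
    }
  }
  invisible(out)
}

#' Read an AGP file back into a chain list
#'
#' Inverse of [write_agp()] for round-trip checks and downstream use.
#'
#' @param path AGP path.
#' @return A `chain_list`.
#' @export
read_agp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & lines != ""]
  if (length(lines) == 0L) return(structure(list(), class = "chain_list"))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  objs <- vapply(fields, `[[`, "", 1L)
  chains <- list()
  for (obj in unique(objs)) {
    rows <- fields[objs == obj]
    rows <- rows[order(as.integer(vapply(rows, `[[`, "", 4L)))]
    comp <- rows[vapply(rows, `[[`, "", 5L) == "W"]
    members <- vapply(comp, `[[`, "", 6L)
    orient <- vapply(comp, `[[`, "", 9L)
    chains[[length(chains) + 1L]] <- new_chain(members, orient)
  }
  structure(chains, class = "chain_list")
}

#' Write consensus scaffold orders as plain map text
#'
#' One block per linkage group: a header line `LG<k>` followed by one line
#' per scaffold with its ordinal position, id and orientation (`?` when the
#' orientation is undetermined). Ordinal positions only: recombination
#' distances between joined scaffolds are not estimated.
#'
#' @param consensus A `consensus_order` (see [topological_consensus()]).
#' @param path Output path.
#' @export
write_map_text <- function(consensus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (lg in names(consensus)) {
    writeLines(lg, con)
    ord <- consensus[[lg]]
    if (nrow(ord) > 0L) {
      writeLines(paste(ord$position, ord$scaffold_id, ord$orientation,
                       sep = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
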