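#' Construct a plastome object
#'
#' A plastome bundles one circular chloroplast genome sequence with its gene
#' annotation and (optionally) the detected quadripartite region partition.
#' The sequence is stored linearly with a declared origin; all coordinates are
#' 1-based and closed.
#'
#' @param id Species or accession label.
#' @param seq DNA string over `{A,C,G,T,N}` (upper-cased on construction).
#' @param genes Tibble of gene features with columns `gene`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `kind` (`"CDS"`, `"tRNA"`, `"rRNA"`),
#'   `function_class` (free text) and `exons` (list column of two-column
#'   matrices with exon `start`,`end`; a single-exon gene may have `NULL`,
#'   meaning one exon spanning `start`..`end`).
#' @param partition Optional [region_partition()].
#' @return An object of class `plastome`.
#' @export
plastome <- function(id, seq, genes = empty_gene_table(), partition = NULL) {
  seq <- toupper(seq)
  check_dna(seq, sprintf("plastome '%s'", id))
  if (nchar(seq) == 0L) abort("plastome sequence is empty")
  genes <- as_tibble(genes)
  genes <- normalize_gene_table(genes, nchar(seq))
  structure(
    list(id = id, seq = seq, genes = genes, partition = partition),
    class = "plastome"
  )
}

empty_gene_table <- function() {
  tibble(
    gene = character(), start = integer(), end = integer(),
    strand = character(), kind = character(), function_class = character(),
    exons = list()
  )
}

normalize_gene_table <- function(genes, len) {
  if (nrow(genes) == 0L) return(empty_gene_table())
  if (!"function_class" %in% names(genes)) genes$function_class <- NA_character_
  if (!"exons" %in% names(genes)) genes$exons <- vector("list", nrow(genes))
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(genes$start < 1L | genes$end > len | genes$start > genes$end)) {
    abort("gene coordinates must satisfy 1 <= start <= end <= genome length")
  }
  key <- paste(genes$gene, genes$start, genes$strand)
  if (anyDuplicated(key)) abort("duplicate gene feature (same name, start, strand)")
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    if (is.null(ex)) next
    ex <- matrix(as.integer(ex), ncol = 2)
    if (any(ex[, 1] > ex[, 2])) abort("exon start > end")
    o <- order(ex[, 1])
    ex <- ex[o, , drop = FALSE]
    if (nrow(ex) > 1 && any(ex[-1, 1] <= ex[-nrow(ex), 2])) {
      abort(sprintf("overlapping exons in gene '%s'", genes$gene[i]))
    }
    genes$exons[[i]] <- ex
  }
  genes[, c("gene", "start", "end", "strand", "kind", "function_class", "exons")]
}

# exon matrix for gene row i (falls back to the full span)
gene_exons <- function(genes, i) {
  ex <- genes$exons[[i]]
  if (is.null(ex)) matrix(c(genes$start[i], genes$end[i]), ncol = 2) else ex
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf(
    "<plastome> %s: %s bp, %d gene feature(s)%s\n",
    x$id, format(nchar(x$seq), big.mark = ","), nrow(x$genes),
    if (is.null(x$partition)) "" else ", partitioned"
  ))
  invisible(x)
}

#' Construct a quadripartite region partition
#'
#' Describes the LSC / IRb / SSC / IRa tiling of a circular plastome. Intervals
#' are 1-based closed in genome coordinates; an interval with `end < start`
#' wraps through the origin.
#'
#' @param lsc,irb,ssc,ira Length-2 integer vectors `c(start, end)`.
#' @param genome_length Genome length the partition tiles.
#' @param ir_identity Fraction in `[0,1]`: identity between IRa and the
#'   reverse complement of IRb.
#' @return An object of class `region_partition` (a tibble of four intervals).
#' @export
region_partition <- function(lsc, irb, ssc, ira, genome_length, ir_identity = NA_real_) {
  tab <- tibble(
    region = c("LSC", "IRb", "SSC", "IRa"),
    start = as.integer(c(lsc[1], irb[1], ssc[1], ira[1])),
    end = as.integer(c(lsc[2], irb[2], ssc[2], ira[2]))
  )
  tab$length <- interval_length(tab$start, tab$end, genome_length)
  if (sum(tab$length) != genome_length) {
    abort("partition intervals must tile the genome exactly")
  }
  if (tab$length[tab$region == "SSC"] >= tab$length[tab$region == "LSC"]) {
    abort("SSC must be shorter than LSC")
  }
  structure(tab,
    genome_length = genome_length, ir_identity = ir_identity,
    class = c("region_partition", class(tab))
  )
}

interval_length <- function(start, end, len) {
  ifelse(end >= start, end - start + 1L, len - start + 1L + end)
}

# integer vector of length L with region label per genome position
partition_labels <- function(partition) {
  len <- attr(partition, "genome_length")
  lab <- character(len)
  for (i in seq_len(nrow(partition))) {
    s <- partition$start[i]; e <- partition$end[i]
    idx <- if (e >= s) s:e else c(s:len, 1:e)
    lab[idx] <- partition$region[i]
  }
  lab
}

#' Extract the sequence of one partition region
#'
#' @param p A [plastome()] with a partition.
#' @param region One of `"LSC"`, `"IRb"`, `"SSC"`, `"IRa"`.
#' @return The region's DNA string (wrap-aware).
#' @export
region_seq <- function(p, region) {
  stopifnot(inherits(p, "plastome"))
  if (is.null(p$partition)) abort("plastome has no partition")
  row <- p$partition[p$partition$region == region, ]
  if (nrow(row) != 1L) abort(sprintf("unknown region '%s'", region))
  len <- nchar(p$seq)
  if (row$end >= row$start) {
    substr(p$seq, row$start, row$end)
  } else {
    paste0(substr(p$seq, row$start, len), substr(p$seq, 1, row$end))
  }
}
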