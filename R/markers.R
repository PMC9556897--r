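# Per-gene marker statistics and the ideal-marker screen.

#' Extract per-gene alignments from a whole-genome alignment
#'
#' Slices the alignment at the columns covering each annotated gene of the
#' reference species (via the reference column map), yielding one aligned CDS
#' per species for every gene.
#'
#' @param x An [msa()].
#' @param ref_id Reference species id in `x`.
#' @param genes Gene table of the reference (see [plastome()]); only rows with
#'   `kind == "CDS"` are used by default.
#' @param kinds Feature kinds to extract.
#' @return Named list of [msa()] objects (one per unique gene name; for genes
#'   annotated twice, e.g. IR duplicates, the first copy is used).
#' @export
extract_gene_msa <- function(x, ref_id, genes, kinds = "CDS") {
  stopifnot(inherits(x, "msa"))
  if (!ref_id %in% x$ids) abort(sprintf("reference '%s' not in alignment", ref_id))
  genes <- genes[genes$kind %in% kinds, , drop = FALSE]
  genes <- genes[!duplicated(genes$gene), , drop = FALSE]
  cm <- x$colmap[[ref_id]]
  out <- list()
  for (i in seq_len(nrow(genes))) {
    cols <- which(!is.na(cm) & cm >= genes$start[i] & cm <= genes$end[i])
    if (!length(cols)) next
    cols <- min(cols):max(cols)  # include internal columns gapped in the reference
    seqs <- vapply(x$seqs, function(s) {
      paste(seq_chars(s)[cols], collapse = "")
    }, character(1))
    out[[genes$gene[i]]] <- msa(setNames(seqs, x$ids))
  }
  out
}

#' Per-gene marker statistics
#'
#' From one gene's alignment: aligned CDS length (alignment columns), SNP
#' count (columns with >= 2 distinct A/C/G/T bases, gaps and N ignored), SNP
#' per site (SNPs / aligned length, to 6 decimals) and indel sites (number of
#' alignment columns gapped in exactly one species).
#'
#' @param gene_msa An [msa()] of one gene across species.
#' @param gene Gene name carried into the output.
#' @param function_class Optional functional classification text.
#' @return One-row tibble: `gene`, `cds_len_aligned`, `snps`, `snp_per_site`,
#'   `function_class`, `indel_sites`.
#' @export
per_gene_stats <- function(gene_msa, gene = NA_character_,
                           function_class = NA_character_) {
  stopifnot(inherits(gene_msa, "msa"))
  if (length(gene_msa$ids) < 2L) abort("gene alignment needs >= 2 sequences")
  m <- msa_matrix(gene_msa)
  counts <- vapply(DNA_BASES, function(b) colSums(m == b), numeric(ncol(m)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  snps <- sum(rowSums(counts > 0) >= 2L)
  len <- ncol(m)
  gap_rows <- colSums(m == "-")
  tibble(
    gene = gene,
    cds_len_aligned = len,
    snps = as.integer(snps),
    snp_per_site = round(snps / len, 6),
    function_class = function_class,
    indel_sites = sum(gap_rows == 1L)
  )
}

#' Build the per-gene marker table for a simulated or real panel
#'
#' Convenience wrapper: extracts each reference CDS from the alignment,
#' computes [per_gene_stats()], and (optionally) joins the codon-bias side
#' classification of the reference copy.
#'
#' @param x An [msa()].
#' @param ref A reference [plastome()] whose `genes` provide the CDS spans.
#' @param codon_side If `TRUE`, compute [codon_stats()] on each reference CDS
#'   and add the [enc_gc3_table()] `side` column.
#' @param tol Curve tolerance passed to [enc_gc3_table()].
#' @return Tibble with one row per gene, Table-1-shaped, plus `codon_side`
#'   when requested.
#' @export
marker_table <- function(x, ref, codon_side = TRUE, tol = 1.0) {
  stopifnot(inherits(ref, "plastome"))
  gene_alns <- extract_gene_msa(x, ref$id, ref$genes, kinds = "CDS")
  genes <- ref$genes[match(names(gene_alns), ref$genes$gene), ]
  stats <- bind_rows(lapply(seq_along(gene_alns), function(i) {
    per_gene_stats(gene_alns[[i]], gene = names(gene_alns)[i],
      function_class = genes$function_class[i])
  }))
  if (codon_side) {
    cs <- bind_rows(lapply(seq_len(nrow(genes)), function(i) {
      seqi <- substr(ref$seq, genes$start[i], genes$end[i])
      if (genes$strand[i] == "-") seqi <- revcomp(seqi)
      # a CDS disrupted in this species (e.g. an acquired internal stop)
      # gets undefined codon statistics rather than aborting the table
      tryCatch(suppressWarnings(codon_stats(seqi, gene = genes$gene[i])),
        error = function(e) tibble(gene = genes$gene[i], n_codons = NA_integer_,
          gc3s = NA_real_, enc = NA_real_, enc_expected = NA_real_,
          enc_delta = NA_real_, low_confidence = TRUE, rscu = list(NULL)))
    }))
    side <- enc_gc3_table(cs, tol = tol)
    stats <- left_join(stats, select(side, "gene", codon_side = "side"), by = "gene")
  }
  stats
}

#' Ideal-marker filter
#'
#' A gene is selected iff its aligned CDS length strictly exceeds `min_len`,
#' its SNP count strictly exceeds `min_snps`, and (when `require_low_bias`)
#' its codon-bias classification is on/near the expected ENC-GC3 curve.
#'
#' @param stats Tibble with `cds_len_aligned` and `snps` (and `codon_side`
#'   when `require_low_bias`).
#' @param min_len Length threshold in bp (strict `>`, default 1000).
#' @param min_snps SNP threshold (strict `>`, default 30).
#' @param require_low_bias Require `codon_side == "on"` (default `TRUE`; set
#'   `FALSE` to apply the length/SNP screen alone).
#' @return `stats` with a logical `ideal` column; selected genes are
#'   `filter(result, ideal)`.
#' @export
ideal_filter <- function(stats, min_len = 1000L, min_snps = 30L,
                         require_low_bias = TRUE) {
  if (nrow(stats) == 0L) abort("empty marker table")
  ideal <- stats$cds_len_aligned > min_len & stats$snps > min_snps
  if (require_low_bias) {
    if (!"codon_side" %in% names(stats)) {
      abort("require_low_bias = TRUE needs a codon_side column")
    }
    ideal <- ideal & !is.na(stats$codon_side) & stats$codon_side == "on"
  }
  out <- mutate(stats, ideal = ideal)
  attr(out, "criteria") <- list(min_len = min_len, min_snps = min_snps,
    require_low_bias = require_low_bias)
  out
}

#' Published per-gene properties of a nine-species Piper plastome panel
#'
#' Loads the bundled per-gene table (79 protein-coding genes): CDS length
#' after multiple alignment, SNP count, SNP per site, functional
#' classification and indel sites, as printed in a published comparative
#' analysis of nine Piper chloroplast genomes.
#'
#' @return Tibble with columns `gene`, `cds_len_aligned`, `snps`,
#'   `snp_per_site`, `function_class`, `indel_sites`.
#' @export
piper_gene_table <- function() {
  path <- system.file("extdata", "piper_gene_properties.tsv",
    package = "plastidscreen", mustWork = TRUE)
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}
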