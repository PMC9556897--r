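#' Read a plastome from FASTA or GenBank
#'
#' FASTA input yields a plastome with an empty gene table; GenBank input maps
#' `CDS`, `tRNA` and `rRNA` features (including `join()` exon locations and
#' `complement()` strands) to gene features. Sequences are upper-cased and
#' ambiguity codes other than `N` are rejected.
#'
#' @param path Path to the file.
#' @param format `"fasta"` or `"genbank"` (default guessed from the extension:
#'   `.gb`/`.gbk`/`.genbank` read as GenBank, anything else as FASTA).
#' @return A [plastome()].
#' @export
read_plastome <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  format <- format %||%
    if (grepl("\\.(gb|gbk|genbank)$", path, ignore.case = TRUE)) "genbank" else "fasta"
  switch(format,
    fasta = {
      set <- Biostrings::readDNAStringSet(path)
      if (length(set) == 0L) abort(sprintf("no sequence record in %s", path))
      if (length(set) > 1L) {
        abort(sprintf("expected a single record in %s, found %d", path, length(set)))
      }
      plastome(id = sub("\\s.*", "", names(set)[1]), seq = as.character(set[[1]]))
    },
    genbank = read_genbank(path),
    abort(sprintf("unknown format '%s' (use 'fasta' or 'genbank')", format))
  )
}

#' Write a plastome to FASTA or GenBank
#'
#' @param p A [plastome()].
#' @param path Output path.
#' @param format `"fasta"` or `"genbank"`.
#' @return `path`, invisibly.
#' @export
write_plastome <- function(p, path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  stopifnot(inherits(p, "plastome"))
  if (format == "fasta") {
    set <- Biostrings::DNAStringSet(setNames(p$seq, p$id))
    Biostrings::writeXStringSet(set, path, width = 70L)
  } else {
    writeLines(format_genbank(p), path)
  }
  invisible(path)
}

# ---- GenBank flat file (minimal: gene/CDS/tRNA/rRNA, join(), complement()) ----

read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) abort(sprintf("%s: malformed GenBank record, no LOCUS line", path))
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]

  feat_from <- grep("^FEATURES", lines)
  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0L) abort(sprintf("%s: malformed GenBank record, no ORIGIN", path))
  seq_lines <- lines[(origin_at[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(seq) == 0L) abort(sprintf("%s: empty sequence", path))

  genes <- empty_gene_table()
  if (length(feat_from) > 0L && origin_at[1] > feat_from[1] + 1L) {
    flines <- lines[(feat_from[1] + 1):(origin_at[1] - 1)]
    genes <- parse_feature_table(flines, path)
  }
  plastome(id = id, seq = seq, genes = genes)
}

parse_feature_table <- function(flines, path) {
  # feature keys start at column 6; continuation/qualifier lines at column 22
  is_key <- grepl("^ {5}\\S", flines)
  idx <- which(is_key)
  recs <- list()
  for (k in seq_along(idx)) {
    from <- idx[k]
    to <- if (k < length(idx)) idx[k + 1] - 1L else length(flines)
    block <- flines[from:to]
    key <- sub("^\\s+", "", substr(block[1], 1, 20))
    key <- sub("\\s.*", "", key)
    if (!key %in% c("CDS", "tRNA", "rRNA", "gene")) next
    rest <- trimws(substr(block[1], 21, nchar(block[1])))
    qual_at <- grep("^\\s+/", block)
    loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(block)
    if (loc_end > 1L) rest <- paste0(rest, trimws(block[2:loc_end]), collapse = "")
    loc <- parse_location(rest, path)
    quals <- trimws(block[grepl("^\\s+/", block)])
    gene_name <- qual_value(quals, "gene")
    note <- qual_value(quals, "note")
    recs[[length(recs) + 1L]] <- tibble(
      gene = gene_name %||% NA_character_,
      start = min(loc$exons[, 1]), end = max(loc$exons[, 2]),
      strand = loc$strand, kind = key,
      function_class = note %||% NA_character_,
      exons = list(loc$exons)
    )
  }
  if (length(recs) == 0L) return(empty_gene_table())
  genes <- bind_rows(recs)
  # drop bare 'gene' features shadowed by a typed feature at the same location
  typed <- genes$kind != "gene"
  if (any(typed) && any(!typed)) {
    keykeep <- paste(genes$gene[typed], genes$start[typed], genes$strand[typed])
    drop <- !typed & paste(genes$gene, genes$start, genes$strand) %in% keykeep
    genes <- genes[!drop, , drop = FALSE]
  }
  genes
}

parse_location <- function(loc, path) {
  raw <- gsub("\\s", "", loc)
  strand <- "+"
  x <- raw
  if (grepl("^complement\\(", x)) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (grepl("^join\\(", x)) x <- sub("^join\\((.*)\\)$", "\\1", x)
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^<?(\\d+)\\.\\.>?(\\d+)$|^(\\d+)$", parts))
  exons <- t(vapply(m, function(g) {
    if (length(g) == 0L || !nzchar(g[1])) {
      abort(sprintf("%s: cannot parse feature location '%s'", path, loc))
    }
    if (nzchar(g[2])) c(as.integer(g[2]), as.integer(g[3])) else rep(as.integer(g[4]), 2)
  }, integer(2)))
  list(strand = strand, exons = exons)
}

qual_value <- function(quals, name) {
  hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
  if (length(hit) == 0L) return(NULL)
  gsub('^"|"$', "", sub(paste0("^/", name, "="), "", hit[1]))
}

format_genbank <- function(p) {
  len <- nchar(p$seq)
  out <- c(
    sprintf("LOCUS       %s %d bp    DNA     circular PLN", p$id, len),
    sprintf("DEFINITION  %s chloroplast genome.", p$id),
    "FEATURES             Location/Qualifiers"
  )
  fmt_loc <- function(ex, strand) {
    loc <- paste(sprintf("%d..%d", ex[, 1], ex[, 2]), collapse = ",")
    if (nrow(ex) > 1) loc <- sprintf("join(%s)", loc)
    if (strand == "-") loc <- sprintf("complement(%s)", loc)
    loc
  }
  for (i in seq_len(nrow(p$genes))) {
    g <- p$genes[i, ]
    out <- c(out, sprintf("     %-16s%s", g$kind, fmt_loc(gene_exons(p$genes, i), g$strand)))
    out <- c(out, sprintf("                     /gene=\"%s\"", g$gene))
    if (!is.na(g$function_class)) {
      out <- c(out, sprintf("                     /note=\"%s\"", g$function_class))
    }
  }
  out <- c(out, "ORIGIN")
  starts <- seq(1L, len, by = 60L)
  for (s in starts) {
    chunk <- substr(p$seq, s, min(s + 59L, len))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", s, tolower(paste(blocks, collapse = " "))))
  }
  c(out, "//")
}

# ---- multiple sequence alignment -------------------------------------------

#' Construct a multiple sequence alignment object
#'
#' Rows are equal-length gapped sequences over `{A,C,G,T,N,-}`. A per-species
#' column map (alignment column to ungapped genome coordinate, `NA` at gaps)
#' is built on construction.
#'
#' @param seqs Named character vector of gapped sequences.
#' @return An object of class `msa`.
#' @export
msa <- function(seqs) {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) abort("alignment rows must be named")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    ragged <- ids[widths != stats::median(widths)]
    abort(sprintf("ragged alignment rows: %s", paste(ragged, collapse = ", ")))
  }
  bad <- gsub("[ACGTN-]", "", seqs)
  if (any(nzchar(bad))) {
    abort(sprintf("alignment rows with invalid characters: %s", paste(ids[nzchar(bad)], collapse = ", ")))
  }
  colmap <- lapply(seqs, function(s) {
    gap <- seq_chars(s) == "-"
    pos <- cumsum(!gap)
    pos[gap] <- NA_integer_
    as.integer(pos)
  })
  structure(
    list(ids = ids, seqs = setNames(unname(seqs), ids), colmap = colmap),
    class = "msa"
  )
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %s columns\n", length(x$ids),
    format(nchar(x$seqs[1]), big.mark = ",")))
  invisible(x)
}

#' Read / write an aligned FASTA file
#'
#' @param path File path.
#' @return For `read_msa()`, an [msa()]; `write_msa()` returns `path` invisibly.
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 1L) abort(sprintf("no records in %s", path))
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*", "", names(set))
  msa(seqs)
}

#' @rdname read_msa
#' @param x An [msa()].
#' @export
write_msa <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  set <- Biostrings::BStringSet(x$seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# alignment as a character matrix (species x columns)
msa_matrix <- function(x) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

# ungapped sequence of one row
msa_ungap <- function(x, id) gsub("-", "", x$seqs[[id]], fixed = TRUE)
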