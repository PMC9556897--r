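# Codon-usage bias: RSCU, GC3s, effective number of codons (ENC) and the
# expected ENC-GC3 curve used to vet candidate markers.

# Synonymous family table under the plastid/bacterial code (translation
# table 11; codon->amino-acid assignments are identical to the standard code,
# table 11 differs only in permitted start codons). Met and Trp are excluded
# from bias statistics; Ile forms its own 3-fold family.
codon_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  keep <- aa != "*"
  tab <- tibble(codon = codons[keep], aa = aa[keep])
  fam_size <- table(tab$aa)
  tab$family_size <- as.integer(fam_size[tab$aa])
  tab
}

TABLE11_STARTS <- c("ATG", "GTG", "TTG")

#' Per-gene codon-usage statistics
#'
#' Computes relative synonymous codon usage (RSCU), GC content at synonymous
#' third positions (GC3s, excluding Met, Trp and stops), the effective number
#' of codons (ENC, Wright's family-homozygosity composition
#' `2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, clamped to `[20, 61]`) and the distance
#' from the expected ENC at the gene's GC3s
#' (`ENCexp(s) = 2 + s + 29/(s^2 + (1-s)^2)`).
#'
#' Families observed fewer than twice (or with zero homozygosity estimate) are
#' omitted from their degeneracy-class average; a missing 3-fold class (Ile)
#' falls back to the mean of the 2- and 4-fold averages; if a 2-, 4- or 6-fold
#' class is entirely missing the ENC is undefined (`NA`).
#'
#' @param cds A coding sequence (string). A trailing partial codon is trimmed
#'   with a warning; an internal stop codon is an error naming the codon
#'   index; a terminal stop codon is excluded from all counts.
#' @param gene Optional gene name carried into the output.
#' @return One-row tibble: `gene`, `n_codons` (counted sense codons), `gc3s`,
#'   `enc`, `enc_expected`, `enc_delta`, `low_confidence` (fewer than 100
#'   codons), and `rscu` (list column: tibble of `codon`, `aa`, `count`,
#'   `rscu`).
#' @export
codon_stats <- function(cds, gene = NA_character_) {
  cds <- toupper(cds)
  check_dna(cds, sprintf("CDS '%s'", gene))
  extra <- nchar(cds) %% 3L
  if (extra != 0L) {
    warn(sprintf("CDS '%s': trimming %d trailing base(s)", gene, extra))
    cds <- substr(cds, 1, nchar(cds) - extra)
  }
  if (nchar(cds) < 6L) abort("CDS too short")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  if (!codons[1] %in% TABLE11_STARTS) {
    warn(sprintf("CDS '%s' does not begin with a table-11 start codon", gene))
  }
  stops <- which(codons %in% STOP_CODONS)
  if (length(stops) && any(stops < length(codons))) {
    abort(sprintf("internal stop codon at codon %d", stops[stops < length(codons)][1]))
  }
  if (length(stops)) codons <- codons[-length(codons)]
  codons <- codons[!grepl("N", codons)]

  fams <- codon_families()
  counts <- table(factor(codons, levels = fams$codon))
  fams$count <- as.integer(counts)
  fam_tot <- tapply(fams$count, fams$aa, sum)
  fams$family_total <- as.integer(fam_tot[fams$aa])
  fams$rscu <- ifelse(fams$family_total > 0,
    fams$count * fams$family_size / fams$family_total, NA_real_)

  n_codons <- sum(fams$count)
  syn <- fams[!fams$aa %in% c("M", "W"), ]
  third <- substr(syn$codon, 3, 3)
  gc3s_den <- sum(syn$count)
  gc3s <- if (gc3s_den > 0) sum(syn$count[third %in% c("G", "C")]) / gc3s_den else NA_real_

  enc <- enc_wright(syn)
  enc_exp <- if (is.na(gc3s)) NA_real_ else enc_expected(gc3s)
  tibble(
    gene = gene, n_codons = n_codons, gc3s = gc3s,
    enc = enc, enc_expected = enc_exp, enc_delta = enc - enc_exp,
    low_confidence = n_codons < 100L,
    rscu = list(select(fams, "codon", "aa", "count", "rscu"))
  )
}

# Wright's ENC from a per-codon table (synonymous families only)
enc_wright <- function(syn) {
  per_fam <- syn |>
    group_by(.data$aa) |>
    summarise(
      size = .data$family_size[1], n = sum(.data$count),
      sum_p2 = if (sum(.data$count) > 0) sum((.data$count / sum(.data$count))^2) else NA_real_,
      .groups = "drop"
    ) |>
    filter(.data$size > 1L)
  per_fam$f_hat <- ifelse(per_fam$n >= 2,
    (per_fam$n * per_fam$sum_p2 - 1) / (per_fam$n - 1), NA_real_)
  per_fam$f_hat[!is.na(per_fam$f_hat) & per_fam$f_hat <= 0] <- NA_real_
  fbar <- function(k) {
    v <- per_fam$f_hat[per_fam$size == k]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }
  f2 <- fbar(2L); f3 <- fbar(3L); f4 <- fbar(4L); f6 <- fbar(6L)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- mean(c(f2, f4))
  if (anyNA(c(f2, f3, f4, f6))) return(NA_real_)
  min(61, max(20, 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6))
}

#' Expected ENC as a function of GC3s
#'
#' The null curve when codon usage is driven by third-position composition
#' alone: `2 + s + 29/(s^2 + (1-s)^2)`.
#'
#' @param s GC3s in `[0,1]` (vectorized).
#' @return Expected ENC value(s).
#' @export
enc_expected <- function(s) 2 + s + 29 / (s^2 + (1 - s)^2)

#' ENC-GC3 table with below/above-curve classification
#'
#' Genes within `tol` ENC units of the expected curve are classified `"on"`
#' (weak codon bias, the marker-vetting criterion); the rest are `"below"`
#' (stronger bias than composition predicts) or `"above"`.
#'
#' @param stats Row-bound [codon_stats()] output (one row per gene).
#' @param tol Curve tolerance in ENC units (default 1).
#' @return `stats` (without the `rscu` list column) plus `side`.
#' @export
enc_gc3_table <- function(stats, tol = 1.0) {
  if (nrow(stats) == 0L) abort("no genes")
  out <- select(stats, -dplyr::any_of("rscu"))
  out$side <- dplyr::case_when(
    is.na(out$enc_delta) ~ NA_character_,
    abs(out$enc_delta) <= tol ~ "on",
    out$enc_delta < 0 ~ "below",
    TRUE ~ "above"
  )
  out
}
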