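# Microsatellite (SSR) and dispersed-repeat detection.

#' Find simple sequence repeats (microsatellites)
#'
#' Detects maximal perfect tandem runs of 1-6 bp motifs. A run is reported
#' when its copy number reaches the class minimum for its motif size and its
#' total length is at least 10 bp (the conventional plastome SSR screen:
#' minimum copies 10, 5, 4, 3, 3, 3 for mono- through hexanucleotides). Runs
#' whose motif is itself periodic (e.g. `ATAT` = 2 x `AT`) are reported once,
#' at the smallest unit. `N` never matches anything. The reported interval
#' covers whole copies only; a trailing partial copy is not counted.
#'
#' @param p A [plastome()] (or a plain DNA string).
#' @param minima Named/positional integer vector: minimum copy number for
#'   each motif length 1..6.
#' @param min_total_len Minimum total repeat length in bp (default 10).
#' @return Tibble with columns `motif` (canonical form: lexicographically
#'   smallest rotation, same strand), `unit_len`, `copies`, `start`, `end`,
#'   sorted by `start`.
#' @export
find_ssrs <- function(p, minima = c(10L, 5L, 4L, 3L, 3L, 3L), min_total_len = 10L) {
  seq <- if (inherits(p, "plastome")) p$seq else toupper(p)
  x <- seq_chars(seq)
  n <- length(x)
  hits <- list()
  for (u in 1:6) {
    if (n < 2L * u) next
    eq <- x[1:(n - u)] == x[(u + 1):n] & x[1:(n - u)] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    runs <- which(r$values)
    for (k in runs) {
      a <- starts[k]
      m <- r$lengths[k] + u          # matched span length in bp
      copies <- m %/% u
      if (copies < minima[u] || u * copies < min_total_len) next
      motif <- chars_seq(x[a:(a + u - 1L)])
      if (motif_period(motif) < u) next  # periodic motif: reported at smaller unit
      hits[[length(hits) + 1L]] <- tibble(
        motif = canonical_rotation(motif), unit_len = u,
        copies = copies, start = a, end = a + u * copies - 1L
      )
    }
  }
  if (!length(hits)) {
    return(tibble(motif = character(), unit_len = integer(), copies = integer(),
      start = integer(), end = integer()))
  }
  arrange(bind_rows(hits), .data$start, .data$unit_len)
}

# smallest period of a motif string (u if primitive)
motif_period <- function(motif) {
  u <- nchar(motif)
  for (d in seq_len(u - 1)) {
    if (u %% d != 0L) next
    if (paste(rep(substr(motif, 1, d), u %/% d), collapse = "") == motif) return(d)
  }
  u
}

canonical_rotation <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(motif)
  rots <- vapply(seq_len(u), function(i) {
    paste0(substr(motif, i, u), substr(motif, 1, i - 1))
  }, character(1))
  min(rots)
}

#' Find dispersed forward and palindromic repeats
#'
#' REPuter-style scan: reports maximal pairs of segments at least `min_len`
#' long where the second is a near-copy of the first (forward) or of its
#' reverse complement (palindromic), with at most `max_mismatch` mismatches
#' and identity at least `min_identity`. Pairs fully contained in an already
#' reported longer pair are suppressed, as are self-pairs.
#'
#' Candidates are seeded with exact 8-mer matches and extended greedily in
#' both directions until the mismatch budget would be exceeded.
#'
#' @param p A [plastome()] or DNA string.
#' @param min_len Minimum repeat length (default 30).
#' @param max_mismatch Maximum Hamming distance (default 3).
#' @param min_identity Minimum identity fraction (default 0.90).
#' @return Tibble with `kind` (`forward`/`palindromic`), `start_a`, `start_b`,
#'   `length`, `mismatches`, `identity`. For palindromic hits `start_b` is the
#'   genome coordinate of the reverse-complemented copy.
#' @export
find_dispersed_repeats <- function(p, min_len = 30L, max_mismatch = 3L,
                                   min_identity = 0.90) {
  seq <- if (inherits(p, "plastome")) p$seq else toupper(p)
  x <- seq_chars(seq)
  n <- length(x)
  fwd <- scan_pairs(x, x, n, min_len, max_mismatch, min_identity, self = TRUE)
  if (nrow(fwd)) {
    fwd <- mutate(fwd, kind = "forward", start_b = .data$start_b_raw)
  }
  rc <- rev(comp_chars(x))
  pal <- scan_pairs(x, rc, n, min_len, max_mismatch, min_identity, self = FALSE)
  if (nrow(pal)) {
    # map coordinates in the reverse complement back to the forward strand
    pal <- mutate(pal, kind = "palindromic",
      start_b = n - (.data$start_b_raw + .data$length - 1L) + 1L)
    # the pair (A, B) and its mirror (B, A) are the same repeat: keep one
    pal <- filter(pal, !duplicated(paste(pmin(.data$start_a, .data$start_b),
      pmax(.data$start_a, .data$start_b), .data$length)))
  }
  out <- bind_rows(fwd, pal)
  if (!nrow(out)) {
    return(tibble(kind = character(), start_a = integer(), start_b = integer(),
      length = integer(), mismatches = integer(), identity = double()))
  }
  out <- select(out, "kind", "start_a", "start_b", "length", "mismatches", "identity")
  arrange(out, .data$start_a, .data$start_b)
}

# seed (k=8) + greedy two-sided extension under a mismatch budget
scan_pairs <- function(x, y, n, min_len, max_mismatch, min_identity, self,
                       k = 8L, max_seed_occ = 25L) {
  if (n < min_len) {
    return(tibble(start_a = integer(), start_b_raw = integer(), length = integer(),
      mismatches = integer(), identity = double()))
  }
  sx <- chars_seq(x); sy <- chars_seq(y)
  nk <- n - k + 1L
  kx <- substring(sx, 1:nk, k:n)
  ky <- substring(sy, 1:nk, k:n)
  tab <- split(seq_len(nk), ky)
  tab <- tab[lengths(tab) <= max_seed_occ]
  hits <- tab[kx]
  keep <- !vapply(hits, is.null, logical(1))
  if (!any(keep)) {
    return(tibble(start_a = integer(), start_b_raw = integer(), length = integer(),
      mismatches = integer(), identity = double()))
  }
  ii <- rep(which(keep), lengths(hits[keep]))
  jj <- unlist(hits[keep], use.names = FALSE)
  d <- ii - jj
  if (self) {
    sel <- ii < jj     # one orientation; skip the self-diagonal
    ii <- ii[sel]; jj <- jj[sel]; d <- d[sel]
  }
  out <- list()
  for (dg in unique(d)) {
    is <- sort(unique(ii[d == dg]))
    done_until <- 0L
    for (i0 in is) {
      if (i0 <= done_until) next
      j0 <- i0 - dg
      ext <- extend_pair(x, y, n, i0, j0, k, max_mismatch)
      done_until <- ext$a_end
      len <- ext$a_end - ext$a_start + 1L
      mm <- ext$mismatches
      if (len < min_len) next
      idn <- (len - mm) / len
      if (idn < min_identity) next
      if (self && ext$b_start <= ext$a_end && ext$a_start <= ext$b_end) next  # overlapping copies
      out[[length(out) + 1L]] <- tibble(
        start_a = ext$a_start, start_b_raw = ext$b_start, length = len,
        mismatches = mm, identity = idn
      )
    }
  }
  if (!length(out)) {
    return(tibble(start_a = integer(), start_b_raw = integer(), length = integer(),
      mismatches = integer(), identity = double()))
  }
  res <- bind_rows(out)
  res <- res[!duplicated(res[, c("start_a", "start_b_raw", "length")]), ]
  drop_nested(res)
}

extend_pair <- function(x, y, n, i0, j0, k, max_mismatch) {
  # exact seed of length k at (i0, j0); extend right then left, spending the
  # mismatch budget greedily (a mismatch is absorbed only if another match
  # follows within the remaining sequence)
  mm <- 0L
  ae <- i0 + k - 1L; be <- j0 + k - 1L
  while (ae < n && be < n) {
    if (x[ae + 1L] != "N" && x[ae + 1L] == y[be + 1L]) {
      ae <- ae + 1L; be <- be + 1L
    } else if (mm < max_mismatch && ae + 2L <= n && be + 2L <= n &&
        x[ae + 2L] != "N" && x[ae + 2L] == y[be + 2L]) {
      mm <- mm + 1L; ae <- ae + 2L; be <- be + 2L
    } else {
      break
    }
  }
  as <- i0; bs <- j0
  while (as > 1L && bs > 1L) {
    if (x[as - 1L] != "N" && x[as - 1L] == y[bs - 1L]) {
      as <- as - 1L; bs <- bs - 1L
    } else if (mm < max_mismatch && as - 2L >= 1L && bs - 2L >= 1L &&
        x[as - 2L] != "N" && x[as - 2L] == y[bs - 2L]) {
      mm <- mm + 1L; as <- as - 2L; bs <- bs - 2L
    } else {
      break
    }
  }
  list(a_start = as, a_end = ae, b_start = bs, b_end = be, mismatches = mm)
}

drop_nested <- function(res) {
  if (nrow(res) < 2L) return(res)
  res <- arrange(res, dplyr::desc(.data$length))
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))[-1]) {
    for (j in which(keep[seq_len(i - 1L)])) {
      if (res$start_a[i] >= res$start_a[j] &&
          res$start_a[i] + res$length[i] <= res$start_a[j] + res$length[j] &&
          res$start_b_raw[i] >= res$start_b_raw[j] &&
          res$start_b_raw[i] + res$length[i] <= res$start_b_raw[j] + res$length[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  res[keep, ]
}

#' Annotate repeat hits with region and gene context
#'
#' Region is assigned by the hit's start coordinate; context is `CDS` if the
#' start falls inside any exon, `intron` if inside a gene span but not an
#' exon, and `intergenic` otherwise (with the gene name where applicable).
#'
#' @param hits Tibble with a `start` column ([find_ssrs()] or
#'   [find_dispersed_repeats()] output; for the latter `start_a` is used).
#' @param p A [plastome()] with a partition (and optionally genes).
#' @return `hits` with `region`, `context` and `gene` columns added.
#' @export
annotate_hits <- function(hits, p) {
  stopifnot(inherits(p, "plastome"))
  if (is.null(p$partition)) abort("plastome has no partition; run detect_partition() first")
  pos <- if ("start" %in% names(hits)) hits$start else hits$start_a
  labels <- partition_labels(p$partition)
  region <- labels[pos]
  context <- rep("intergenic", length(pos))
  gene <- rep(NA_character_, length(pos))
  genes <- p$genes
  for (i in seq_len(nrow(genes))) {
    inside <- pos >= genes$start[i] & pos <= genes$end[i]
    if (!any(inside)) next
    ex <- gene_exons(genes, i)
    in_exon <- rep(FALSE, length(pos))
    for (e in seq_len(nrow(ex))) {
      in_exon <- in_exon | (pos >= ex[e, 1] & pos <= ex[e, 2])
    }
    ctx <- ifelse(in_exon, "CDS", "intron")
    context[inside] <- ctx[inside]
    gene[inside] <- genes$gene[i]
  }
  mutate(hits, region = region, context = context, gene = gene)
}

#' Summarise SSR hits per motif class and region
#'
#' @param hits Annotated [find_ssrs()] output (needs `region`).
#' @return Tibble of counts by `unit_len` and `region`.
#' @export
ssr_summary <- function(hits) {
  if (!"region" %in% names(hits)) abort("hits are not annotated; run annotate_hits() first")
  hits |>
    group_by(.data$unit_len, .data$region) |>
    summarise(n = dplyr::n(), .groups = "drop")
}
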