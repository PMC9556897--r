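# Quadripartite structure detection and junction reporting.

#' Detect the quadripartite LSC/IRb/SSC/IRa partition
#'
#' Finds the longest pair of disjoint segments where one matches the reverse
#' complement of the other at `>= min_identity` over `>= min_ir_len` bases.
#' Those are the inverted-repeat copies; the two single-copy intervals between
#' them become LSC (the longer) and SSC (the shorter). The genome is treated as
#' circular: if no inverted repeat is found on the linear sequence, detection
#' is retried on a half-rotation and coordinates are mapped back, so a repeat
#' spanning the declared origin is still found.
#'
#' Candidate repeats are located by chaining exact 16-mer seed matches between
#' the genome and its reverse complement along anti-diagonals; the reported
#' boundaries are the matched seed span, so on exact inverted repeats they fall
#' exactly at the repeat ends.
#'
#' @param p A [plastome()].
#' @param min_ir_len Minimum single-copy IR length in bp (default 10000).
#' @param min_identity Minimum IRa vs reverse-complemented IRb identity.
#' @return A [region_partition()]; also available via `detect_partition(p)$partition`
#'   when assigned back. Errors with "no IR found" if nothing qualifies.
#' @export
detect_partition <- function(p, min_ir_len = 10000, min_identity = 0.99) {
  stopifnot(inherits(p, "plastome"))
  len <- nchar(p$seq)
  cand <- find_ir_pair(p$seq, min_ir_len, min_identity)
  # a repeat spanning the declared origin is truncated on the linear sequence:
  # also scan a half-rotation and keep whichever yields the longer repeat
  shift <- len %/% 2L
  rot <- paste0(substr(p$seq, shift + 1L, len), substr(p$seq, 1L, shift))
  cand_rot <- find_ir_pair(rot, min_ir_len, min_identity)
  if (!is.null(cand_rot)) {
    unrot <- function(x) ((x - 1L + shift) %% len) + 1L
    cand_rot$a <- unrot(cand_rot$a); cand_rot$b <- unrot(cand_rot$b)
    if (is.null(cand) || cand_rot$len > cand$len) cand <- cand_rot
  }
  if (is.null(cand)) abort("no IR found: no inverted repeat meets min_ir_len/min_identity")
  build_partition_from_irs(cand, len)
}

# Seed-and-chain search for the longest disjoint inverted-repeat pair.
# Returns list(a = c(start, end), b = c(start, end), identity) or NULL.
find_ir_pair <- function(seq, min_ir_len, min_identity, k = 16L, max_gap = 500L) {
  len <- nchar(seq)
  if (len < 2L * min_ir_len || len < 4L * k) return(NULL)
  rc <- revcomp(seq)
  n <- len - k + 1L
  km_s <- substring(seq, 1:n, k:len)
  km_r <- substring(rc, 1:n, k:len)
  # index rc k-mers; skip hyper-repetitive seeds
  tab <- split(seq_len(n), km_r)
  tab <- tab[lengths(tab) <= 10L]
  hits_p <- tab[km_s]
  keep <- !vapply(hits_p, is.null, logical(1))
  if (!any(keep)) return(NULL)
  ii <- rep(which(keep), lengths(hits_p[keep]))
  pp <- unlist(hits_p[keep], use.names = FALSE)
  d <- ii - pp
  best <- NULL
  for (dg in unique(d)) {
    is <- sort(ii[d == dg])
    # chain seeds on this diagonal, splitting at gaps > max_gap
    brk <- c(0L, which(diff(is) > max_gap), length(is))
    for (j in seq_len(length(brk) - 1L)) {
      run <- is[(brk[j] + 1L):brk[j + 1L]]
      a1 <- run[1]; a2 <- run[length(run)] + k - 1L
      m <- a2 - a1 + 1L
      if (m < min_ir_len) next
      # rc coordinates of the partner copy, mapped back to genome coordinates
      p1 <- a1 - dg; p2 <- a2 - dg
      b1 <- len - p2 + 1L; b2 <- len - p1 + 1L
      if (max(a1, b1) <= min(a2, b2)) next  # overlapping copies: not two IRs
      idn <- mean(seq_chars(substr(seq, a1, a2)) ==
        rev(comp_chars(seq_chars(substr(seq, b1, b2)))))
      if (idn < min_identity) next
      if (is.null(best) || m > best$len) {
        best <- list(a = c(a1, a2), b = c(b1, b2), identity = idn, len = m)
      }
    }
  }
  best
}

build_partition_from_irs <- function(cand, len) {
  # order the two copies along the (possibly wrapped) genome
  ir1 <- cand$a; ir2 <- cand$b
  if (circ_start(ir1, len) > circ_start(ir2, len)) { tmp <- ir1; ir1 <- ir2; ir2 <- tmp }
  gap1 <- circ_interval(ir1[2] + 1L, ir2[1] - 1L, len)   # between copy1 and copy2
  gap2 <- circ_interval(ir2[2] + 1L, ir1[1] - 1L, len)   # wraps past the origin
  len1 <- interval_length(gap1[1], gap1[2], len)
  len2 <- interval_length(gap2[1], gap2[2], len)
  if (len1 == 0L || len2 == 0L) abort("degenerate partition: empty single-copy interval")
  if (len1 > len2) {
    # gap1 = LSC; copy following LSC is ir2 -> IRb, gap2 = SSC, ir1 = IRa
    region_partition(lsc = gap1, irb = ir2, ssc = gap2, ira = ir1,
      genome_length = len, ir_identity = cand$identity)
  } else {
    region_partition(lsc = gap2, irb = ir1, ssc = gap1, ira = ir2,
      genome_length = len, ir_identity = cand$identity)
  }
}

circ_start <- function(iv, len) ((iv[1] - 1L) %% len) + 1L

circ_interval <- function(s, e, len) {
  c(((s - 1L) %% len) + 1L, ((e - 1L) %% len) + 1L)
}

#' Report genes at the four region junctions
#'
#' For each junction (LSC/IRb, IRb/SSC, SSC/IRa, IRa/LSC) the nearest gene on
#' each side is reported with its strand and signed distance in bp: `+d` means
#' the gene ends `d` bases before (or starts `d` bases after) the junction,
#' `0` means it abuts the junction, and a gene whose span straddles the
#' junction is reported once as spanning with negative distance equal to the
#' overlap past the junction.
#'
#' @param p A [plastome()] with a partition and gene annotation.
#' @return Tibble with columns `junction`, `side`, `gene`, `strand`,
#'   `distance`, `spanning`.
#' @export
junction_report <- function(p) {
  stopifnot(inherits(p, "plastome"))
  if (is.null(p$partition)) abort("plastome has no partition; run detect_partition() first")
  part <- p$partition
  len <- attr(part, "genome_length")
  ord <- c("LSC", "IRb", "SSC", "IRa")
  junctions <- tibble(
    junction = paste(ord, c(ord[-1], ord[1]), sep = "/"),
    left_end = part$end[match(ord, part$region)]
  )
  genes <- p$genes
  rows <- list()
  for (i in seq_len(nrow(junctions))) {
    e_x <- junctions$left_end[i]
    s_y <- (e_x %% len) + 1L
    jn <- junctions$junction[i]
    if (nrow(genes) == 0L) next
    spans <- genes$start <= e_x & genes$end > e_x
    if (any(spans)) {
      g <- genes[spans, ][1, ]
      rows[[length(rows) + 1L]] <- tibble(
        junction = jn, side = "spanning", gene = g$gene, strand = g$strand,
        distance = -(g$end - e_x), spanning = TRUE
      )
      next
    }
    dl <- (e_x - genes$end) %% len
    dr <- (genes$start - s_y) %% len
    gl <- which.min(dl)
    gr <- which.min(dr)
    rows[[length(rows) + 1L]] <- tibble(
      junction = jn, side = c("upstream", "downstream"),
      gene = genes$gene[c(gl, gr)], strand = genes$strand[c(gl, gr)],
      distance = c(dl[gl], dr[gr]), spanning = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(tibble(junction = character(), side = character(), gene = character(),
      strand = character(), distance = integer(), spanning = logical()))
  }
  bind_rows(rows)
}

#' Project a reference partition onto alignment columns
#'
#' Labels every alignment column with the region (LSC/IRb/SSC/IRa) of the
#' corresponding reference genome position. Columns where the reference is
#' gapped inherit the label of the nearest preceding labeled column (leading
#' gap columns take the first label).
#'
#' @param x An [msa()].
#' @param ref_id Reference species id present in the alignment.
#' @param partition A [region_partition()] in reference coordinates.
#' @return Character vector of region labels, one per alignment column.
#' @export
project_regions <- function(x, ref_id, partition) {
  stopifnot(inherits(x, "msa"))
  if (!ref_id %in% x$ids) abort(sprintf("reference '%s' not in alignment", ref_id))
  labels_by_pos <- partition_labels(partition)
  ref_len <- nchar(msa_ungap(x, ref_id))
  if (length(labels_by_pos) != ref_len) {
    abort("partition genome length does not match the ungapped reference row")
  }
  cm <- x$colmap[[ref_id]]
  lab <- labels_by_pos[cm]
  if (anyNA(lab)) {
    idx <- seq_along(lab)
    last <- cummax(ifelse(!is.na(lab), idx, 0L))
    first_lab <- lab[!is.na(lab)][1]
    lab <- ifelse(last > 0L, lab[pmax(last, 1L)], first_lab)
  }
  lab
}

#' @export
#' @method tidy region_partition
tidy.region_partition <- function(x, ...) {
  tibble(
    region = x$region, start = x$start, end = x$end, length = x$length,
    ir_identity = attr(x, "ir_identity")
  )
}
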