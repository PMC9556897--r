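# SNP/indel tabulation from a whole-genome alignment, substitution spectrum,
# regional tallies, and pairwise ALS / indel-count matrices.
#
# Gap/N handling is pairwise deletion throughout: an alignment column
# contributes to a species pair only when both members hold one of A/C/G/T.

#' Call SNP columns from an alignment
#'
#' A column is a SNP iff it holds at least two distinct bases among
#' `{A,C,G,T}` across species, ignoring gaps and `N`. Multi-allelic columns
#' count once here; pairwise difference flags are evaluated per pair by the
#' downstream matrix/spectrum functions.
#'
#' @param x An [msa()].
#' @param region_labels Optional per-column region labels
#'   (see [project_regions()]).
#' @return Tibble with `column`, `region`, `n_alleles`, and `alleles` (list
#'   column: named vector of the per-species characters at that column).
#' @export
call_snps <- function(x, region_labels = NULL) {
  stopifnot(inherits(x, "msa"))
  if (length(x$ids) < 2L) abort("alignment needs >= 2 rows")
  m <- msa_matrix(x)
  counts <- vapply(DNA_BASES, function(b) colSums(m == b), numeric(ncol(m)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  n_alleles <- rowSums(counts > 0)
  snp_cols <- which(n_alleles >= 2L)
  region <- if (is.null(region_labels)) rep(NA_character_, ncol(m)) else region_labels
  tibble(
    column = snp_cols,
    region = region[snp_cols],
    n_alleles = as.integer(n_alleles[snp_cols]),
    alleles = lapply(snp_cols, function(j) setNames(m[, j], x$ids))
  )
}

all_pairs <- function(ids) {
  idx <- utils::combn(seq_along(ids), 2)
  tibble(i = idx[1, ], j = idx[2, ], a = ids[idx[1, ]], b = ids[idx[2, ]])
}

#' Substitution spectrum (transitions / transversions)
#'
#' Counts the six unordered substitution types over all species pairs at SNP
#' columns and reports the transition/transversion ratio.
#'
#' @param snps Output of [call_snps()].
#' @return Tibble with `substitution`, `class` (`Ts`/`Tv`), `count`; total
#'   transitions, transversions and their ratio (rounded to 2 decimals; `NA`
#'   when there are no transversions) are stored as attributes `ts`, `tv`,
#'   `ratio` and printed by [ts_tv_ratio()].
#' @export
ts_tv_spectrum <- function(snps) {
  types <- c("A<->G", "C<->T", "A<->C", "A<->T", "C<->G", "G<->T")
  cls <- c("Ts", "Ts", "Tv", "Tv", "Tv", "Tv")
  counts <- setNames(rep(0L, 6L), types)
  if (nrow(snps) > 0L) {
    m <- do.call(rbind, snps$alleles)  # columns = species
    ids <- colnames(m)
    pr <- all_pairs(ids)
    for (k in seq_len(nrow(pr))) {
      aa <- m[, pr$i[k]]; bb <- m[, pr$j[k]]
      ok <- aa %in% DNA_BASES & bb %in% DNA_BASES & aa != bb
      if (!any(ok)) next
      key <- paste0(pmin(aa[ok], bb[ok]), "<->", pmax(aa[ok], bb[ok]))
      tt <- table(key)
      counts[names(tt)] <- counts[names(tt)] + as.integer(tt)
    }
  }
  out <- tibble(substitution = types, class = cls, count = as.integer(counts))
  ts <- sum(out$count[out$class == "Ts"])
  tv <- sum(out$count[out$class == "Tv"])
  attr(out, "ts") <- ts
  attr(out, "tv") <- tv
  attr(out, "ratio") <- if (tv == 0L) NA_real_ else round(ts / tv, 2)
  out
}

#' @rdname ts_tv_spectrum
#' @param spectrum A [ts_tv_spectrum()] result.
#' @export
ts_tv_ratio <- function(spectrum) attr(spectrum, "ratio")

#' Call indel events from an alignment
#'
#' Pairwise scope (the default): for each species pair, columns gapped in both
#' members are dropped, and each maximal run of columns gapped in exactly one
#' member is one event. Runs touching either alignment end are excluded as
#' alignment artifacts. Global scope: each maximal run of columns sharing an
#' identical non-empty gap pattern (not all-gap) is one event.
#'
#' @param x An [msa()].
#' @param region_labels Optional per-column region labels.
#' @param scope `"pairwise"` or `"global"`.
#' @return Tibble with `a`, `b` (species pair; `b = NA` for global scope),
#'   `start` (first alignment column of the run), `length`, `region` (label of
#'   the first column).
#' @export
call_indels <- function(x, region_labels = NULL, scope = c("pairwise", "global")) {
  scope <- match.arg(scope)
  stopifnot(inherits(x, "msa"))
  if (length(x$ids) < 2L) abort("alignment needs >= 2 rows")
  m <- msa_matrix(x)
  region <- if (is.null(region_labels)) rep(NA_character_, ncol(m)) else region_labels
  empty <- tibble(a = character(), b = character(), start = integer(),
    length = integer(), region = character())
  if (scope == "pairwise") {
    pr <- all_pairs(x$ids)
    out <- list()
    for (k in seq_len(nrow(pr))) {
      ga <- m[pr$i[k], ] == "-"
      gb <- m[pr$j[k], ] == "-"
      keep <- which(!(ga & gb))
      if (length(keep) < 2L) next
      one <- xor(ga[keep], gb[keep])
      r <- rle(one)
      ends <- cumsum(r$lengths)
      starts <- c(1L, head(ends, -1) + 1L)
      runs <- which(r$values)
      # terminal runs (touching either end of the projected alignment) excluded
      runs <- runs[starts[runs] > 1L & ends[runs] < length(keep)]
      if (!length(runs)) next
      out[[k]] <- tibble(
        a = pr$a[k], b = pr$b[k],
        start = keep[starts[runs]],
        length = r$lengths[runs],
        region = region[keep[starts[runs]]]
      )
    }
    if (!length(out)) return(empty)
    bind_rows(out)
  } else {
    gaps <- m == "-"
    pat <- apply(gaps, 2, function(col) paste(which(col), collapse = ","))
    r <- rle(pat)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    runs <- which(r$values != "" &
      vapply(strsplit(r$values, ","), length, 0L) < length(x$ids))
    if (!length(runs)) return(empty)
    tibble(
      a = vapply(strsplit(r$values[runs], ","), function(ii) {
        paste(x$ids[as.integer(ii)], collapse = "+")
      }, character(1)),
      b = NA_character_,
      start = starts[runs], length = r$lengths[runs],
      region = region[starts[runs]]
    )
  }
}

#' Tally SNPs or indels per genome region
#'
#' Pools the two IR copies as `IR` and reports counts and rounded integer
#' percentages for LSC, IR and SSC.
#'
#' @param records Tibble with a `region` column ([call_snps()] or
#'   [call_indels()] output).
#' @param which Label used in the output (`"snp"` or `"indel"`), cosmetic.
#' @return Tibble with `region`, `count`, `pct` (`NA` percentages when there
#'   are no records) plus a `total` attribute.
#' @export
tally_by_region <- function(records, which = c("snp", "indel")) {
  which <- match.arg(which)
  reg <- ifelse(records$region %in% c("IRa", "IRb"), "IR", records$region)
  out <- tibble(region = c("LSC", "IR", "SSC"))
  out$count <- vapply(out$region, function(r) sum(reg == r, na.rm = TRUE), 0L,
    USE.NAMES = FALSE)
  total <- sum(out$count)
  out$pct <- if (total == 0L) NA_real_ else round(100 * out$count / total)
  out$statistic <- which
  attr(out, "total") <- total
  out
}

# ---- pairwise matrices ------------------------------------------------------

new_pair_matrix <- function(values, statistic, normalized = FALSE,
                            norm_constant = NA_real_, capped = NULL) {
  diag(values) <- NA_real_
  structure(values,
    statistic = statistic, normalized = normalized,
    norm_constant = norm_constant, capped = capped,
    class = c("pair_matrix", "matrix", "array")
  )
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("<pair_matrix> %s, %d species%s\n", attr(x, "statistic"),
    nrow(x), if (attr(x, "normalized")) ", normalized" else ""))
  print(unclass(x)[seq_len(nrow(x)), seq_len(ncol(x))])
  invisible(x)
}

#' @export
#' @method tidy pair_matrix
tidy.pair_matrix <- function(x, ...) {
  ids <- rownames(x)
  pr <- all_pairs(ids)
  tibble(
    a = pr$a, b = pr$b,
    value = x[cbind(pr$i, pr$j)],
    statistic = attr(x, "statistic"),
    normalized = attr(x, "normalized")
  )
}

# region column selector; "IR" pools IRa+IRb
region_columns <- function(region_labels, region) {
  if (region == "IR") {
    which(region_labels %in% c("IRa", "IRb"))
  } else if (region %in% c("LSC", "SSC", "IRa", "IRb")) {
    which(region_labels == region)
  } else {
    abort(sprintf("unknown region '%s'", region))
  }
}

#' Pairwise ALS matrix
#'
#' ALS is the average length of nucleic acid sequence in which one SNP
#' appears, per species pair and region: the number of region columns where
#' both species hold A/C/G/T, divided by the pairwise SNP count there. Larger
#' values mean fewer differences (more similar sequences). Pairs with zero
#' SNPs get the ungapped length itself and are flagged as capped.
#'
#' @param x An [msa()].
#' @param region_labels Per-column region labels.
#' @param region `"LSC"`, `"IR"` or `"SSC"` (single IR copies also accepted).
#' @return A `pair_matrix` (statistic `"ALS"`), with a logical `capped`
#'   attribute matrix marking zero-SNP pairs.
#' @export
als_matrix <- function(x, region_labels, region) {
  cols <- region_columns(region_labels, region)
  if (!length(cols)) abort(sprintf("region '%s' absent from labels", region))
  m <- msa_matrix(x)[, cols, drop = FALSE]
  n <- length(x$ids)
  vals <- matrix(NA_real_, n, n, dimnames = list(x$ids, x$ids))
  capped <- matrix(FALSE, n, n, dimnames = list(x$ids, x$ids))
  pr <- all_pairs(x$ids)
  valid <- matrix(m %in% DNA_BASES, nrow = n)
  for (k in seq_len(nrow(pr))) {
    i <- pr$i[k]; j <- pr$j[k]
    both <- valid[i, ] & valid[j, ]
    L <- sum(both)
    ksnp <- sum(both & m[i, ] != m[j, ])
    if (ksnp == 0L) {
      vals[i, j] <- vals[j, i] <- L
      capped[i, j] <- capped[j, i] <- TRUE
    } else {
      vals[i, j] <- vals[j, i] <- L / ksnp
    }
  }
  new_pair_matrix(vals, "ALS", capped = capped)
}

#' Normalize a pairwise matrix by its maximum
#'
#' Divides every off-diagonal entry by the off-diagonal maximum so the
#' largest value is exactly 1; idempotent.
#'
#' @param m A `pair_matrix`.
#' @return The normalized `pair_matrix` with `norm_constant` recording the
#'   divisor.
#' @export
normalize_matrix <- function(m) {
  stopifnot(inherits(m, "pair_matrix"))
  off <- m[upper.tri(m)]
  off <- off[is.finite(off)]
  if (!length(off)) abort("no finite off-diagonal entries to normalize")
  mx <- max(off)
  if (mx == 0) abort("all-zero matrix cannot be normalized")
  out <- unclass(m) / mx
  new_pair_matrix(out, attr(m, "statistic"), normalized = TRUE,
    norm_constant = mx, capped = attr(m, "capped"))
}

#' Pairwise indel-count matrix
#'
#' Entry (i, j) is the number of pairwise indel events between the two
#' species in the region (higher = less similar).
#'
#' @inheritParams als_matrix
#' @param indels Optional precomputed [call_indels()] pairwise output; called
#'   internally when omitted.
#' @return A `pair_matrix` (statistic `"indel_count"`).
#' @export
indel_matrix <- function(x, region_labels, region, indels = NULL) {
  cols <- region_columns(region_labels, region)
  if (!length(cols)) abort(sprintf("region '%s' absent from labels", region))
  if (is.null(indels)) indels <- call_indels(x, region_labels, scope = "pairwise")
  want <- if (region == "IR") c("IRa", "IRb") else region
  indels <- indels[indels$region %in% want, , drop = FALSE]
  n <- length(x$ids)
  vals <- matrix(0, n, n, dimnames = list(x$ids, x$ids))
  if (nrow(indels)) {
    tt <- table(factor(indels$a, levels = x$ids), factor(indels$b, levels = x$ids))
    vals <- vals + tt + t(tt)
  }
  new_pair_matrix(vals, "indel_count")
}
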