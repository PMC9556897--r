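# Sliding-window nucleotide diversity (Pi) and Pi-threshold species grouping.

#' Sliding-window nucleotide diversity
#'
#' Windows are laid over alignment columns (default 600 bp window, 200 bp
#' step); trailing windows shorter than the window length are dropped. Within
#' a window, Pi is the average over species pairs of (pairwise differences /
#' pairwise valid sites) under pairwise deletion. Windows where the mean
#' fraction of valid pairwise sites falls below `min_valid_frac` are flagged
#' and get `pi = NA`.
#'
#' @param x An [msa()].
#' @param window Window length in alignment columns (default 600).
#' @param step Step size in columns (default 200).
#' @param region_labels Optional per-column region labels; a window is
#'   labeled by its start column.
#' @param min_valid_frac Minimum mean valid-site fraction (default 0.1).
#' @return Tibble with `start`, `end`, `region`, `pi`, `n_valid_sites`
#'   (mean pairwise valid sites, rounded) and `low_coverage`.
#' @export
sliding_pi <- function(x, window = 600L, step = 200L, region_labels = NULL,
                       min_valid_frac = 0.1) {
  stopifnot(inherits(x, "msa"))
  window <- as.integer(window); step <- as.integer(step)
  if (window <= 0L || window < step) abort("need window > 0 and window >= step")
  if (length(x$ids) < 2L) abort("alignment needs >= 2 rows")
  m <- msa_matrix(x)
  nc <- ncol(m)
  starts <- seq(1L, nc - window + 1L, by = step)
  if (nc < window) {
    return(tibble(start = integer(), end = integer(), region = character(),
      pi = double(), n_valid_sites = double(), low_coverage = logical()))
  }
  pr <- all_pairs(x$ids)
  np <- nrow(pr)
  valid <- m %in% DNA_BASES
  dim(valid) <- dim(m)
  # per-pair cumulative sums of diff/valid indicators for O(1) window sums
  cum_diff <- matrix(0, np, nc + 1L)
  cum_valid <- matrix(0, np, nc + 1L)
  for (k in seq_len(np)) {
    both <- valid[pr$i[k], ] & valid[pr$j[k], ]
    diff <- both & m[pr$i[k], ] != m[pr$j[k], ]
    cum_diff[k, ] <- c(0, cumsum(diff))
    cum_valid[k, ] <- c(0, cumsum(both))
  }
  region <- if (is.null(region_labels)) rep(NA_character_, nc) else region_labels
  res <- lapply(starts, function(s) {
    e <- s + window - 1L
    v <- cum_valid[, e + 1L] - cum_valid[, s]
    d <- cum_diff[, e + 1L] - cum_diff[, s]
    ratios <- ifelse(v > 0, d / v, NA_real_)
    mean_valid <- mean(v)
    low <- mean_valid < min_valid_frac * window
    tibble(
      start = s, end = e, region = region[s],
      pi = if (low) NA_real_ else mean(ratios, na.rm = TRUE),
      n_valid_sites = round(mean_valid, 1), low_coverage = low
    )
  })
  bind_rows(res)
}

#' Pairwise mean Pi per region
#'
#' For each species pair, computes two-species sliding-window Pi over the
#' columns of one region and averages the window values. For `"IR"` the two
#' copies are scanned separately (windows never span the non-contiguous
#' copies) and their windows pooled.
#'
#' @inheritParams sliding_pi
#' @param region_labels Per-column region labels.
#' @param region `"LSC"`, `"SSC"` or `"IR"` (single IR copies also accepted).
#' @return A `pair_matrix` (statistic `"mean_pi"`).
#' @export
pairwise_mean_pi <- function(x, region_labels, region, window = 600L, step = 200L) {
  cols <- region_columns(region_labels, region)
  if (!length(cols)) abort(sprintf("region '%s' absent from labels", region))
  # contiguous blocks of the selected columns
  blocks <- split(cols, cumsum(c(1L, diff(cols) != 1L)))
  blocks <- blocks[vapply(blocks, length, 0L) >= window]
  if (!length(blocks)) {
    abort(sprintf("region '%s' has no full %d-column window", region, window))
  }
  m <- msa_matrix(x)
  n <- length(x$ids)
  pr <- all_pairs(x$ids)
  vals <- matrix(NA_real_, n, n, dimnames = list(x$ids, x$ids))
  for (k in seq_len(nrow(pr))) {
    i <- pr$i[k]; j <- pr$j[k]
    window_pis <- unlist(lapply(blocks, function(cc) {
      a <- m[i, cc]; b <- m[j, cc]
      both <- a %in% DNA_BASES & b %in% DNA_BASES
      diff <- both & a != b
      starts <- seq(1L, length(cc) - window + 1L, by = step)
      cs_b <- c(0, cumsum(both)); cs_d <- c(0, cumsum(diff))
      v <- cs_b[starts + window] - cs_b[starts]
      d <- cs_d[starts + window] - cs_d[starts]
      ifelse(v > 0, d / v, NA_real_)
    }))
    vals[i, j] <- vals[j, i] <- mean(window_pis, na.rm = TRUE)
  }
  new_pair_matrix(vals, "mean_pi")
}

#' Group species by a mean-Pi threshold
#'
#' Single-linkage grouping: two species share a group iff they are connected
#' by a chain of pairs whose mean Pi is at or below the threshold. With a
#' threshold below every entry each species is its own group; with a
#' threshold above every entry all species form one group.
#'
#' @param m A `pair_matrix` of mean Pi values ([pairwise_mean_pi()]).
#' @param threshold Non-negative Pi cutoff (default 0.1).
#' @return A `species_grouping`: list with `groups` (list of character
#'   vectors, ordered by first member), `threshold`, `linkage`.
#' @export
group_species <- function(m, threshold = 0.1) {
  stopifnot(inherits(m, "pair_matrix"))
  if (threshold < 0) abort("threshold must be >= 0")
  ids <- rownames(m)
  n <- length(ids)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (!is.na(m[i, j]) && m[i, j] <= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  groups <- unname(split(ids, roots))
  structure(
    list(groups = groups, threshold = threshold, linkage = "single"),
    class = "species_grouping"
  )
}

#' @export
print.species_grouping <- function(x, ...) {
  cat(sprintf("<species_grouping> %d group(s) at mean-Pi threshold %g (%s linkage)\n",
    length(x$groups), x$threshold, x$linkage))
  for (g in x$groups) cat("  {", paste(g, collapse = ", "), "}\n")
  invisible(x)
}

#' @export
#' @method tidy species_grouping
tidy.species_grouping <- function(x, ...) {
  tibble(
    species = unlist(x$groups),
    group = rep(seq_along(x$groups), lengths(x$groups)),
    threshold = x$threshold
  )
}
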