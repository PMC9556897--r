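# Distance-based trees per marker/region and conflict flagging against a
# reference topology. Maximum-likelihood / Bayesian inference is deliberately
# out of scope: the concordance questions asked here are topological, and
# p-distance + neighbor-joining answers them at desk scale. Externally
# computed Newick trees can be supplied wherever a tree is consumed.

#' Pairwise p-distance matrix
#'
#' Entry (i, j) is pairwise differences / pairwise valid sites under pairwise
#' deletion (both species holding A/C/G/T).
#'
#' @param x An [msa()].
#' @return A `pair_matrix` (statistic `"p_distance"`).
#' @export
pdistance_matrix <- function(x) {
  stopifnot(inherits(x, "msa"))
  if (length(x$ids) < 2L) abort("alignment needs >= 2 rows")
  m <- msa_matrix(x)
  valid <- m %in% DNA_BASES
  dim(valid) <- dim(m)
  n <- length(x$ids)
  vals <- matrix(NA_real_, n, n, dimnames = list(x$ids, x$ids))
  pr <- all_pairs(x$ids)
  for (k in seq_len(nrow(pr))) {
    i <- pr$i[k]; j <- pr$j[k]
    both <- valid[i, ] & valid[j, ]
    nv <- sum(both)
    if (nv == 0L) {
      abort(sprintf("species pair (%s, %s) shares no valid sites", pr$a[k], pr$b[k]))
    }
    vals[i, j] <- vals[j, i] <- sum(both & m[i, ] != m[j, ]) / nv
  }
  new_pair_matrix(vals, "p_distance")
}

#' Neighbor-joining tree from a pairwise distance matrix
#'
#' Standard neighbor-joining ([ape::nj()]); negative branch lengths are
#' clamped to zero (recorded in the `n_clamped` attribute). Label order in the
#' matrix fixes tie-breaking, so identical inputs give identical Newick.
#'
#' @param m A symmetric `pair_matrix` (or plain matrix) of distances.
#' @param source Optional marker/region name stored on the tree.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(m, source = NA_character_) {
  vals <- unclass(m)
  if (is.null(rownames(vals)) || nrow(vals) != ncol(vals)) {
    abort("need a square labeled distance matrix")
  }
  diag(vals) <- 0
  if (any(abs(vals - t(vals)) > 1e-12, na.rm = TRUE)) abort("distance matrix is not symmetric")
  if (nrow(vals) < 3L) abort("need >= 3 species for a tree")
  tr <- ape::nj(stats::as.dist(vals))
  n_clamped <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "source") <- source
  attr(tr, "n_clamped") <- n_clamped
  tr
}

#' Robinson-Foulds distance between two trees
#'
#' The number of nontrivial bipartitions present in one tree but not the
#' other, summed over both directions (an even integer; 0 iff the unrooted
#' topologies agree, at most `2(n-3)` for binary trees).
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return Integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    abort("trees have different leaf sets")
  }
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2), check.labels = TRUE))
}

#' Flag markers whose trees conflict with a reference topology
#'
#' @param marker_trees Named list of `phylo` trees (one per marker/window).
#' @param reference_tree The reference `phylo`.
#' @param threshold A marker is flagged conflicting iff its RF distance to the
#'   reference strictly exceeds this (default 2, i.e. anything beyond one
#'   displaced bipartition).
#' @return Tibble `marker`, `rf`, `conflicting`, sorted by `rf` descending.
#' @export
conflict_report <- function(marker_trees, reference_tree, threshold = 2L) {
  if (length(marker_trees) == 0L) abort("no marker trees")
  if (is.null(names(marker_trees))) {
    names(marker_trees) <- paste0("marker", seq_along(marker_trees))
  }
  out <- tibble(
    marker = names(marker_trees),
    rf = vapply(marker_trees, function(t) rf_distance(t, reference_tree), 0L,
      USE.NAMES = FALSE)
  )
  out$conflicting <- out$rf > threshold
  arrange(out, dplyr::desc(.data$rf), .data$marker)
}
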