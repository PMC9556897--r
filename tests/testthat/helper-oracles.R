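# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive results with naive algorithms so the package
# implementations are checked against a second, independent route.

chars_of <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]

rotate_min <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(motif)
  min(vapply(seq_len(u), function(i) {
    paste0(substr(motif, i, u), substr(motif, 1, i - 1))
  }, character(1)))
}

smallest_period <- function(block) {
  u <- length(block)
  for (d in seq_len(u - 1)) {
    if (u %% d == 0L && all(block == rep(block[seq_len(d)], u %/% d))) return(d)
  }
  u
}

# Exhaustive SSR scan: tests every (start, unit) pair, counting whole-copy
# tandem repeats blockwise, keeping left-maximal primitive runs.
brute_ssrs <- function(seq, minima = c(10L, 5L, 4L, 3L, 3L, 3L), min_total = 10L) {
  x <- chars_of(seq)
  n <- length(x)
  out <- list()
  for (u in 1:6) {
    i <- 1L
    while (i + u - 1L <= n) {
      block <- x[i:(i + u - 1L)]
      if (any(block == "N")) { i <- i + 1L; next }
      # left-maximality: the run must not extend one base to the left
      if (i > 1L && x[i - 1L] == x[i - 1L + u] && x[i - 1L] != "N") { i <- i + 1L; next }
      copies <- 1L
      while (TRUE) {
        s2 <- i + copies * u
        if (s2 + u - 1L > n) break
        if (all(x[s2:(s2 + u - 1L)] == block)) copies <- copies + 1L else break
      }
      if (copies >= minima[u] && u * copies >= min_total &&
          smallest_period(block) == u) {
        out[[length(out) + 1L]] <- data.frame(
          motif = rotate_min(paste(block, collapse = "")),
          unit_len = u, copies = copies, start = i, end = i + u * copies - 1L,
          stringsAsFactors = FALSE
        )
      }
      i <- i + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(motif = character(), unit_len = integer(),
      copies = integer(), start = integer(), end = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$unit_len), , drop = FALSE]
}

# Naive window Pi: double loop over species pairs and columns.
naive_window_pi <- function(seqs, start, window) {
  rows <- lapply(seqs, chars_of)
  ids <- seq_along(rows)
  acgt <- c("A", "C", "G", "T")
  ratios <- c()
  for (i in ids) {
    for (j in ids) {
      if (j <= i) next
      d <- 0L; v <- 0L
      for (c in start:(start + window - 1L)) {
        a <- rows[[i]][c]; b <- rows[[j]][c]
        if (a %in% acgt && b %in% acgt) {
          v <- v + 1L
          if (a != b) d <- d + 1L
        }
      }
      ratios <- c(ratios, if (v > 0) d / v else NA_real_)
    }
  }
  mean(ratios, na.rm = TRUE)
}

# Nontrivial bipartitions of an unrooted phylo tree, as canonical strings,
# derived directly from the edge matrix (no tree libraries).
brute_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  tips_below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  splits <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= ntip) next
    side <- sort(tips_below(child))
    other <- sort(setdiff(tree$tip.label, side))
    if (length(side) < 2L || length(other) < 2L) next
    key <- paste(c(min(paste(side, collapse = "|"), paste(other, collapse = "|")),
      max(paste(side, collapse = "|"), paste(other, collapse = "|"))), collapse = " vs ")
    splits <- c(splits, key)
  }
  unique(splits)
}

brute_rf <- function(t1, t2) {
  b1 <- brute_bipartitions(t1)
  b2 <- brute_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# ---- fixture builders -------------------------------------------------------

rand_seq <- function(n, freqs = c(0.3, 0.2, 0.2, 0.3)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs), collapse = "")
}

# random flank guaranteed free of SSR hits and ending/starting away from `avoid`
clean_flank <- function(n, avoid = c("A")) {
  repeat {
    f <- rand_seq(n, freqs = rep(0.25, 4))
    if (nrow(brute_ssrs(f)) > 0L) next
    ch <- chars_of(f)
    if (ch[1] %in% avoid || ch[n] %in% avoid) next
    return(f)
  }
}

# small simulation config for unit tests
tiny_layout <- function() {
  tibble::tibble(
    gene = c("geneA", "geneB"),
    kind = "CDS",
    len = c(300L, 240L),
    region = c("LSC", "SSC"),
    offset = c(200L, 100L),
    strand = c("+", "-"),
    function_class = c("ATP synthase", "others")
  )
}

tiny_cfg <- function(seed = 1L, tree = "(a:0.01,(b:0.01,c:0.02):0.01);", ...) {
  args <- list(
    seed = seed, tree = tree,
    lsc_len = 3000L, ir_len = 800L, ssc_len = 600L,
    gene_layout = tiny_layout(),
    ssr_loci = tibble::tibble(motif = "A", copies = 12L, region = "LSC", offset = 600L),
    ssr_slippage = 0, indel_rate = 0.02
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# plant an approximate copy of a segment elsewhere in a background sequence,
# with flanks forced to break any accidental extension of the match
plant_duplicate <- function(background, src_start, len, dest_start,
                            n_mismatch = 0, palindromic = FALSE) {
  x <- chars_of(background)
  seg <- x[src_start:(src_start + len - 1L)]
  if (n_mismatch > 0) {
    at <- round(seq(4, len - 4, length.out = n_mismatch))
    for (a in at) seg[a] <- setdiff(c("A", "C", "G", "T"), seg[a])[1]
  }
  if (palindromic) {
    seg <- rev(unname(c(A = "T", C = "G", G = "C", T = "A")[seg]))
  }
  x[dest_start:(dest_start + len - 1L)] <- seg
  # force two mismatching flank bases on both sides of both copies
  flip <- function(pos, other_pos) {
    if (pos >= 1L && pos <= length(x) && other_pos >= 1L && other_pos <= length(x)) {
      x[pos] <<- setdiff(c("A", "C", "G", "T"), c(x[other_pos],
        c(A = "T", C = "G", G = "C", T = "A")[x[other_pos]]))[1]
    }
  }
  if (!palindromic) {
    for (o in 1:2) {
      flip(dest_start - o, src_start - o)
      flip(dest_start + len - 1L + o, src_start + len - 1L + o)
    }
  } else {
    for (o in 1:2) {
      flip(dest_start - o, src_start + len - 1L + o)
      flip(dest_start + len - 1L + o, src_start - o)
    }
  }
  paste(x, collapse = "")
}
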