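# Plastome evolution simulator: an ancestral quadripartite genome is evolved
# along a known tree with region-specific substitution rates, indels, SSR
# slippage and concerted inverted repeats (every event in IRa is mirrored into
# IRb). The true alignment is assembled from per-branch event logs, so every
# downstream stage can be tested against known truth.

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic plastome generator: a nine
#' species tree, a ~23 kb quadripartite genome (desk-scale stand-in for a
#' ~160 kb plastome), region rate multipliers SSC >> LSC > IR, HKY-like
#' substitutions, geometric indels, planted SSR loci with slippage, and a gene
#' layout that includes a junction-spanning CDS.
#'
#' @param seed Integer RNG seed.
#' @param tree Rooted tree with branch lengths in expected substitutions per
#'   site (a `phylo` object or a Newick string).
#' @param lsc_len,ir_len,ssc_len Region sizes in bp (both IR copies have
#'   `ir_len`; total genome is `lsc_len + 2*ir_len + ssc_len`).
#' @param region_rate Named multipliers for `LSC`, `SSC` and `IR` applied to
#'   branch lengths.
#' @param indel_rate Indel events per site per unit branch length (scaled by
#'   the region multiplier, so indels share the SNPs' regional profile).
#' @param indel_len_geom_p Geometric length parameter in (0,1]; mean length
#'   `1/p`.
#' @param kappa Transition/transversion rate ratio (>= 0).
#' @param base_freqs Equilibrium base frequencies (A, C, G, T), must sum to 1.
#' @param gene_layout Tibble of gene templates (`gene`, `kind`, `len`,
#'   `region`, `offset`, `strand`, `function_class`). A gene may run off the
#'   SSC end into IRa (junction-spanning); any other overflow errors.
#' @param ssr_loci Tibble of planted SSR loci (`motif`, `copies`, `region`,
#'   `offset`).
#' @param ssr_slippage Slippage events per locus per unit branch length
#'   (each event adds or removes one motif unit).
#' @param allow_cds_indels If `FALSE` (default) indels never land inside a
#'   planted CDS.
#' @param discordant Optional: a second tree (Newick/`phylo`, same leaves)
#'   governing SSC non-coding sites, used to emulate a region whose history
#'   conflicts with the species tree. Indels are disabled in this mode so the
#'   two substitution passes stay coordinate-compatible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       tree = default_species_tree(),
                       lsc_len = 12000L, ir_len = 4000L, ssc_len = 3000L,
                       region_rate = c(LSC = 1, SSC = 10, IR = 0.1),
                       indel_rate = 0.02,
                       indel_len_geom_p = 0.5,
                       kappa = 2,
                       base_freqs = c(A = 0.31, C = 0.19, G = 0.19, T = 0.31),
                       gene_layout = default_gene_layout(),
                       ssr_loci = default_ssr_loci(),
                       ssr_slippage = 0.5,
                       allow_cds_indels = FALSE,
                       discordant = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo") || length(tree$tip.label) < 2L) {
    abort("tree must be a phylo object (or Newick) with >= 2 leaves")
  }
  if (abs(sum(base_freqs) - 1) > 1e-9) abort("base_freqs must sum to 1")
  if (any(region_rate < 0) || !all(c("LSC", "SSC", "IR") %in% names(region_rate))) {
    abort("region_rate needs non-negative LSC, SSC and IR entries")
  }
  if (indel_len_geom_p <= 0 || indel_len_geom_p > 1) abort("indel_len_geom_p must be in (0,1]")
  if (ssc_len >= lsc_len) abort("SSC must be shorter than LSC")
  if (kappa < 0) abort("kappa must be >= 0")
  if (!is.null(discordant)) {
    if (is.character(discordant)) discordant <- ape::read.tree(text = discordant)
    if (!setequal(discordant$tip.label, tree$tip.label)) {
      abort("discordant tree must have the same leaf set as the species tree")
    }
    indel_rate <- 0
    ssr_slippage <- 0
  }
  structure(list(
    seed = as.integer(seed), tree = tree,
    lsc_len = as.integer(lsc_len), ir_len = as.integer(ir_len),
    ssc_len = as.integer(ssc_len),
    region_rate = region_rate, indel_rate = indel_rate,
    indel_len_geom_p = indel_len_geom_p, kappa = kappa,
    base_freqs = base_freqs,
    gene_layout = as_tibble(gene_layout), ssr_loci = as_tibble(ssr_loci),
    ssr_slippage = ssr_slippage, allow_cds_indels = allow_cds_indels,
    discordant = discordant
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d leaves, genome %d bp (LSC %d / IR 2x%d / SSC %d), seed %d\n",
    length(x$tree$tip.label), x$lsc_len + 2L * x$ir_len + x$ssc_len,
    x$lsc_len, x$ir_len, x$ssc_len, x$seed
  ))
  invisible(x)
}

#' Default nine-taxon species tree
#'
#' Branch lengths are expected substitutions per site at the LSC baseline;
#' every internal branch is at least 0.005 so that tree recovery from
#' concatenated markers is well-posed. One long-branch taxon (sp9) mimics the
#' divergent outlier seen in real plastome panels.
#' @return A `phylo` object.
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(((sp1:0.006,sp2:0.006):0.005,((sp3:0.004,sp4:0.004):0.005,sp5:0.008):0.005):0.005,",
    "((sp6:0.007,sp7:0.009):0.006,(sp8:0.010,sp9:0.014):0.005):0.005);"
  ))
}

#' @rdname sim_config
#' @export
default_gene_layout <- function() {
  tibble(
    gene = c("psbA", "matK", "rpoB", "rbcL", "atpH", "trnH-GUG", "petN",
      "rrn16", "ndhF", "ycf1"),
    kind = c("CDS", "CDS", "CDS", "CDS", "CDS", "tRNA", "CDS", "rRNA", "CDS", "CDS"),
    len = c(1050L, 1500L, 2100L, 1440L, 240L, 74L, 90L, 1490L, 1950L, 1200L),
    region = c(rep("LSC", 7), "IRa", "SSC", "SSC"),
    offset = c(500L, 2000L, 4000L, 6500L, 8200L, 9000L, 9500L, 500L, 150L, 2200L),
    strand = c("+", "+", "+", "+", "+", "-", "+", "+", "-", "+"),
    function_class = c("Photosystem II", "others",
      "DNA-directed RNA polymerase subunit alpha", "others", "ATP synthase",
      "tRNA", "cytochrome b6/f complex", "rRNA", "NadH oxidoreductase", "others")
  )
}

#' @rdname sim_config
#' @export
default_ssr_loci <- function() {
  tibble(
    motif = c("A", "AT", "AAG", "T"),
    copies = c(12L, 6L, 5L, 11L),
    region = c("LSC", "LSC", "LSC", "SSC"),
    offset = c(1700L, 3600L, 8600L, 30L)
  )
}

#' Discordant-SSC study design
#'
#' A preset where SSC non-coding sites evolve along a two-set topology
#' ({sp1..sp5} vs {sp6..sp9}) that conflicts with the species tree, while all
#' coding sequences follow the species tree. This emulates a hyper-divergent
#' SSC whose windows yield conflicting trees even though CDS markers remain
#' concordant.
#'
#' @param seed Integer RNG seed.
#' @return A `sim_config`.
#' @export
sim_config_discordant <- function(seed = 1L) {
  species_tree <- paste0(
    "(((sp1:0.008,sp6:0.008):0.006,(sp2:0.008,sp7:0.008):0.006):0.006,",
    "((sp3:0.008,sp8:0.008):0.006,((sp4:0.008,sp9:0.008):0.006,sp5:0.012):0.006):0.006);"
  )
  ssc_tree <- paste0(
    "((((sp1:0.001,sp2:0.001):0.0005,(sp3:0.001,sp4:0.001):0.0005):0.0005,sp5:0.002):0.06,",
    "(((sp6:0.001,sp7:0.001):0.0005,sp8:0.002):0.001,sp9:0.002):0.06);"
  )
  layout <- tibble(
    gene = c("psbA", "matK", "rpoB", "rbcL", "ndhF"),
    kind = "CDS",
    len = c(1050L, 1500L, 2100L, 1440L, 1950L),
    region = c("LSC", "LSC", "LSC", "LSC", "SSC"),
    offset = c(500L, 2000L, 4000L, 6500L, 100L),
    strand = c("+", "+", "+", "+", "-"),
    function_class = c("Photosystem II", "others",
      "DNA-directed RNA polymerase subunit alpha", "others", "NadH oxidoreductase")
  )
  sim_config(
    seed = seed, tree = species_tree, discordant = ssc_tree,
    lsc_len = 12000L, ir_len = 3000L, ssc_len = 6000L,
    gene_layout = layout, indel_rate = 0, ssr_slippage = 0
  )
}

region_starts <- function(cfg) {
  c(LSC = 1L, IRb = cfg$lsc_len + 1L,
    SSC = cfg$lsc_len + cfg$ir_len + 1L,
    IRa = cfg$lsc_len + cfg$ir_len + cfg$ssc_len + 1L)
}

#' Build the ancestral plastome
#'
#' Constructs a quadripartite genome from the configuration: random background
#' with the configured base frequencies, planted open reading frames (start
#' codon, no internal stop, stop codon under translation table 11), planted
#' SSR loci, and IRb set to the exact reverse complement of IRa. Genes placed
#' in IRa are annotated in both IR copies (as in real plastomes).
#'
#' @param cfg A [sim_config()].
#' @return A [plastome()] with partition, gene annotation and an `ssr_truth`
#'   attribute (the planted SSR registry).
#' @export
build_ancestor <- function(cfg) {
  set.seed(cfg$seed)
  build_ancestor_impl(cfg)
}

build_ancestor_impl <- function(cfg) {
  starts <- region_starts(cfg)
  len <- cfg$lsc_len + 2L * cfg$ir_len + cfg$ssc_len
  chars <- seq_chars(random_dna(len, cfg$base_freqs))
  region_len <- c(LSC = cfg$lsc_len, IRb = cfg$ir_len, SSC = cfg$ssc_len, IRa = cfg$ir_len)

  layout <- cfg$gene_layout
  gene_rows <- list()
  for (i in seq_len(nrow(layout))) {
    g <- layout[i, ]
    a <- starts[[g$region]] + g$offset - 1L
    b <- a + g$len - 1L
    region_end <- starts[[g$region]] + region_len[[g$region]] - 1L
    if (b > len) abort(sprintf("gene '%s' overflows the genome", g$gene))
    if (b > region_end && !(g$region == "SSC")) {
      abort(sprintf("gene '%s' overflows region %s", g$gene, g$region))
    }
    if (g$kind == "CDS") {
      if (g$len %% 3L != 0L) abort(sprintf("CDS '%s' length not a multiple of 3", g$gene))
      cds <- make_orf(g$len, cfg$base_freqs)
      if (g$strand == "-") cds <- revcomp(cds)
      chars[a:b] <- seq_chars(cds)
    }
    gene_rows[[i]] <- tibble(
      gene = g$gene, start = a, end = b, strand = g$strand, kind = g$kind,
      function_class = g$function_class, exons = list(NULL)
    )
  }

  ssr_truth <- tibble(motif = character(), copies = integer(),
    start = integer(), end = integer(), region = character())
  for (i in seq_len(nrow(cfg$ssr_loci))) {
    s <- cfg$ssr_loci[i, ]
    a <- starts[[s$region]] + s$offset - 1L
    unit <- seq_chars(s$motif)
    run <- rep(unit, s$copies)
    b <- a + length(run) - 1L
    if (b + 1L > len || a < 2L) abort("SSR locus outside genome")
    chars[a:b] <- run
    # pin the flanks so the planted run has exactly the recorded copy number
    chars[a - 1L] <- setdiff(DNA_BASES, unit[length(unit)])[1]
    chars[b + 1L] <- setdiff(DNA_BASES, unit[1])[1]
    ssr_truth <- bind_rows(ssr_truth, tibble(
      motif = s$motif, copies = s$copies, start = a, end = b, region = s$region
    ))
  }

  # concerted IRs: IRb is the exact reverse complement of IRa
  ira_idx <- starts[["IRa"]]:(starts[["IRa"]] + cfg$ir_len - 1L)
  irb_idx <- starts[["IRb"]]:(starts[["IRb"]] + cfg$ir_len - 1L)
  chars[irb_idx] <- rev(comp_chars(chars[ira_idx]))
  # pin the single-copy bases flanking the IRs so no chance reverse-complement
  # symmetry extends the repeat past the construction joints
  ssc_first <- starts[["SSC"]]
  ssc_last <- starts[["IRa"]] - 1L
  if (chars[ssc_first] == comp_chars(chars[ssc_last])) {
    chars[ssc_first] <- setdiff(DNA_BASES, comp_chars(chars[ssc_last]))[1]
  }
  lsc_last <- starts[["IRb"]] - 1L
  if (chars[lsc_last] == comp_chars(chars[1L])) {
    chars[lsc_last] <- setdiff(DNA_BASES, comp_chars(chars[1L]))[1]
  }

  genes <- if (length(gene_rows)) bind_rows(gene_rows) else empty_gene_table()
  # mirror annotations for genes fully inside IRa
  if (nrow(genes) > 0L) {
    ira_start <- starts[["IRa"]]; ira_end <- ira_start + cfg$ir_len - 1L
    inside <- genes$start >= ira_start & genes$end <= ira_end
    if (any(inside)) {
      mir <- genes[inside, ]
      new_start <- starts[["IRb"]] + (ira_end - mir$end)
      new_end <- starts[["IRb"]] + (ira_end - mir$start)
      mir$start <- new_start; mir$end <- new_end
      mir$strand <- ifelse(mir$strand == "+", "-", "+")
      genes <- bind_rows(genes, mir)
    }
  }

  part <- region_partition(
    lsc = c(1L, cfg$lsc_len),
    irb = c(starts[["IRb"]], starts[["IRb"]] + cfg$ir_len - 1L),
    ssc = c(starts[["SSC"]], starts[["SSC"]] + cfg$ssc_len - 1L),
    ira = c(starts[["IRa"]], starts[["IRa"]] + cfg$ir_len - 1L),
    genome_length = len, ir_identity = 1.0
  )
  p <- plastome("ancestor", chars_seq(chars), genes = genes, partition = part)
  attr(p, "ssr_truth") <- ssr_truth
  p
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

make_orf <- function(len, base_freqs) {
  n_codon <- len %/% 3L
  all_codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste, collapse = "")
  sense <- setdiff(all_codons, STOP_CODONS)
  w <- vapply(strsplit(sense, ""), function(cc) prod(base_freqs[match(cc, DNA_BASES)]), 0)
  mid <- sample(sense, n_codon - 2L, replace = TRUE, prob = w)
  paste0("ATG", paste(mid, collapse = ""), "TAA")
}

# ---- branch machinery -------------------------------------------------------

ir_mult <- function(region, region_rate) {
  unname(region_rate[ifelse(region %in% c("IRa", "IRb"), "IR", region)])
}

new_state <- function(chars, region, prot) {
  list(chars = chars, region = region, anc = seq_along(chars), prot = prot)
}

# mirrored IRb index for a vector of IRa indices (and vice versa)
mirror_index <- function(idx, state, from = "IRa", to = "IRb") {
  ia <- which(state$region == from)
  ib <- which(state$region == to)
  ib[length(ib) - match(idx, ia) + 1L]
}

draw_new_bases <- function(cur, cfg) {
  out <- character(length(cur))
  for (b in DNA_BASES) {
    sel <- which(cur == b)
    if (!length(sel)) next
    targets <- setdiff(DNA_BASES, b)
    w <- cfg$base_freqs[match(targets, DNA_BASES)] *
      ifelse(is_transition(b, targets), cfg$kappa, 1)
    out[sel] <- sample(targets, length(sel), replace = TRUE, prob = w)
  }
  out
}

# Apply one branch: substitutions (all at once, parent coordinates), then
# indel/slippage events sequentially. Everything hitting IRa is mirrored into
# IRb. Returns the child state, the parent-position map and the event logs.
apply_branch <- function(state, bl, cfg, mode = "standard") {
  n <- length(state$chars)
  mult <- ir_mult(state$region, cfg$region_rate)
  prob <- pmin(bl * mult, 1)
  prob[state$region == "IRb"] <- 0
  masked <- !is.na(state$anc) & state$anc %in% attr(cfg, "masked_anc")
  if (mode == "skip_masked") {
    prob[masked] <- 0
    # in the discordant design, SSC coding sequence is conserved: it follows
    # the species tree at the LSC baseline rate, not the hot SSC rate
    ssc_cds <- state$region == "SSC" & !masked
    prob[ssc_cds] <- pmin(bl * cfg$region_rate[["LSC"]], 1)
  }
  if (mode == "only_masked") prob[!masked] <- 0

  chars <- state$chars
  hit <- which(runif(n) < prob)
  subs <- tibble(pos = integer(), from = character(), to = character(),
    region = character(), mirrored = logical())
  if (length(hit)) {
    newb <- draw_new_bases(chars[hit], cfg)
    from <- chars[hit]
    chars[hit] <- newb
    subs <- tibble(pos = hit, from = from, to = newb,
      region = state$region[hit], mirrored = FALSE)
    in_ira <- which(state$region[hit] == "IRa")
    if (length(in_ira)) {
      midx <- mirror_index(hit[in_ira], state)
      mfrom <- chars[midx]
      chars[midx] <- comp_chars(newb[in_ira])
      subs <- bind_rows(subs, tibble(pos = midx, from = mfrom,
        to = comp_chars(newb[in_ira]), region = "IRb", mirrored = TRUE))
    }
  }

  st <- list(chars = chars, region = state$region, anc = state$anc, prot = state$prot)
  ppos <- seq_len(n)
  indels <- list()

  log_indel <- function(kind, pos, len, seq, mirrored) {
    indels[[length(indels) + 1L]] <<- tibble(
      kind = kind, pos = pos, len = len, seq = seq,
      region = if (pos <= length(st$region)) st$region[pos] else st$region[length(st$region)],
      mirrored = mirrored
    )
  }

  do_delete <- function(run, kind, mirrored = FALSE) {
    log_indel(kind, run[1], length(run), NA_character_, mirrored)
    st$chars <<- st$chars[-run]; st$region <<- st$region[-run]
    st$anc <<- st$anc[-run]; st$prot <<- st$prot[-run]
    ppos <<- ppos[-run]
  }
  do_insert <- function(after, bases, region, prot, kind, mirrored = FALSE) {
    log_indel(kind, after, length(bases), chars_seq(bases), mirrored)
    st$chars <<- append(st$chars, bases, after = after)
    st$region <<- append(st$region, rep(region, length(bases)), after = after)
    st$anc <<- append(st$anc, rep(NA_integer_, length(bases)), after = after)
    st$prot <<- append(st$prot, rep(prot, length(bases)), after = after)
    ppos <<- append(ppos, rep(NA_integer_, length(bases)), after = after)
  }

  place_indel <- function(is_insertion, len, pos) {
    reg <- st$region[pos]
    if (is_insertion) {
      if (!cfg$allow_cds_indels && pos < length(st$prot) &&
          st$prot[pos] && st$prot[pos + 1L]) {
        return(FALSE)
      }
      bases <- sample(DNA_BASES, len, replace = TRUE, prob = cfg$base_freqs)
      if (reg == "IRa") {
        ia <- which(st$region == "IRa")
        o <- match(pos, ia)
        ib <- which(st$region == "IRb")
        mir_after <- if (o == length(ia)) ib[1] - 1L else ib[length(ib) - o]
        do_insert(pos, bases, reg, st$prot[pos], "ins")
        # positions shifted only at/after `pos`; the IRb mirror site precedes it
        st2_ib_after <- mir_after
        do_insert(st2_ib_after, rev(comp_chars(bases)), "IRb", FALSE, "ins", mirrored = TRUE)
      } else {
        do_insert(pos, bases, reg, st$prot[pos], "ins")
      }
      TRUE
    } else {
      run <- pos:(pos + len - 1L)
      if (run[length(run)] > length(st$chars)) return(FALSE)
      if (length(unique(st$region[run])) != 1L) return(FALSE)
      if (!cfg$allow_cds_indels && any(st$prot[run])) return(FALSE)
      if (reg == "IRa") {
        mrun <- sort(mirror_index(run, st))
        do_delete(run, "del")  # IRa run is after IRb: indices of mrun unaffected
        do_delete(mrun, "del", mirrored = TRUE)
      } else {
        do_delete(run, "del")
      }
      TRUE
    }
  }

  if (cfg$indel_rate > 0 && mode != "only_masked") {
    lambda <- cfg$indel_rate * bl * sum(mult[prob > 0])
    n_ev <- rpois(1L, lambda)
    for (ev in seq_len(n_ev)) {
      ok <- FALSE
      for (try in 1:25) {
        m2 <- ir_mult(st$region, cfg$region_rate)
        elig <- which(st$region != "IRb" & m2 > 0)
        if (!length(elig)) break
        pos <- elig[sample.int(length(elig), 1L, prob = m2[elig])]
        len <- rgeom(1L, cfg$indel_len_geom_p) + 1L
        ok <- place_indel(runif(1) < 0.5, len, pos)
        if (ok) break
      }
    }
  }

  # SSR slippage: +/- one motif unit at surviving planted loci
  loci <- attr(cfg, "ssr_truth")
  if (!is.null(loci) && cfg$ssr_slippage > 0 && nrow(loci) > 0 && mode != "only_masked") {
    for (i in seq_len(nrow(loci))) {
      n_slip <- rpois(1L, cfg$ssr_slippage * bl)
      if (n_slip == 0L) next
      ul <- nchar(loci$motif[i])
      for (s in seq_len(n_slip)) {
        pos <- which(st$anc == loci$start[i])
        if (!length(pos)) break
        pos <- pos[1]
        if (st$region[pos] == "IRb") next
        gain <- runif(1) < 0.5
        if (gain) {
          place_indel(TRUE, ul, pos)
        } else {
          if (pos + 2L * ul - 1L > length(st$chars)) next
          place_indel(FALSE, ul, pos + ul)  # keep the anchor unit
        }
      }
    }
  }

  list(
    state = st, parent_pos = ppos,
    subs = subs,
    indels = if (length(indels)) bind_rows(indels) else
      tibble(kind = character(), pos = integer(), len = integer(),
        seq = character(), region = character(), mirrored = logical())
  )
}

# ---- true-alignment bookkeeping --------------------------------------------

# translate a subtree alignment from child coordinates to node coordinates
translate_cols <- function(sub, parent_pos) {
  mapped_val <- ifelse(is.na(parent_pos), 0L, parent_pos)
  prevmap <- cummax(mapped_val)
  pos <- sub$pos; anchor <- sub$anchor
  new_pos <- rep(NA_integer_, length(pos))
  new_anchor <- rep(NA_integer_, length(pos))
  is_mapped <- !is.na(pos)
  q <- pos[is_mapped]
  mp <- parent_pos[q]
  new_pos[is_mapped] <- mp
  born_here <- is_mapped
  born_here[is_mapped] <- is.na(mp)
  new_anchor[born_here] <- prevmap[pos[born_here]]
  is_ins <- !is_mapped
  a <- anchor[is_ins]
  new_anchor[is_ins] <- ifelse(a == 0L, 0L,
    ifelse(!is.na(parent_pos[pmax(a, 1L)]), parent_pos[pmax(a, 1L)], prevmap[pmax(a, 1L)]))
  sub$pos <- new_pos
  sub$anchor <- new_anchor
  sub
}

merge_aligned <- function(parts) {
  P <- sort(unique(unlist(lapply(parts, function(s) s$pos[!is.na(s$pos)]))))
  nmap <- length(P)
  ins_anchors <- unlist(lapply(parts, function(s) s$anchor[is.na(s$pos)]))
  total_ins <- length(ins_anchors)
  ncol_final <- nmap + total_ins
  keys <- c(2 * P, 2 * ins_anchors + 1)
  rows_list <- list()
  ins_offset <- nmap
  for (s in parts) {
    nr <- nrow(s$rows)
    m <- matrix("-", nr, ncol_final)
    mapped <- which(!is.na(s$pos))
    if (length(mapped)) m[, match(s$pos[mapped], P)] <- s$rows[, mapped, drop = FALSE]
    ins <- which(is.na(s$pos))
    if (length(ins)) m[, ins_offset + seq_along(ins)] <- s$rows[, ins, drop = FALSE]
    ins_offset <- ins_offset + length(ins)
    rows_list[[length(rows_list) + 1L]] <- m
  }
  ord <- order(keys)
  list(
    rows = do.call(rbind, rows_list)[, ord, drop = FALSE],
    ids = unlist(lapply(parts, `[[`, "ids")),
    pos = c(P, rep(NA_integer_, total_ins))[ord],
    anchor = c(rep(NA_integer_, nmap), ins_anchors)[ord]
  )
}

# ---- evolution along the tree ----------------------------------------------

#' Evolve an ancestral plastome along the configured tree
#'
#' Substitutions are drawn per site with probability `branch_length x region
#' multiplier` (HKY-like target choice governed by `kappa` and `base_freqs`),
#' indels as maximal-run events with geometric lengths, and every event in one
#' IR copy is mirrored into the other so the two copies stay identical
#' (concerted evolution). The true multiple alignment is assembled from the
#' event logs, and leaf replays of the logs are verified to reproduce each
#' leaf exactly before returning.
#'
#' @param ancestor A [build_ancestor()] plastome.
#' @param cfg The [sim_config()] used to build it.
#' @return A `plastome_sim` object: list with `leaves` (named list of
#'   [plastome()]s with per-species partitions and lifted gene annotations),
#'   `alignment` (the true [msa()]), `region_labels` (per alignment column),
#'   `sub_log`, `indel_log`, `ssr_truth`, `tree` and `config`.
#' @export
evolve_plastomes <- function(ancestor, cfg) {
  set.seed(cfg$seed + 1L)
  stopifnot(inherits(ancestor, "plastome"))
  attr(cfg, "ssr_truth") <- attr(ancestor, "ssr_truth")

  root_region <- partition_labels(ancestor$partition)
  prot <- rep(FALSE, nchar(ancestor$seq))
  cds <- ancestor$genes[ancestor$genes$kind == "CDS", ]
  for (i in seq_len(nrow(cds))) prot[cds$start[i]:cds$end[i]] <- TRUE
  root_state <- new_state(seq_chars(ancestor$seq), root_region, prot)

  if (!is.null(cfg$discordant)) {
    masked <- which(root_region == "SSC" & !prot)
    attr(cfg, "masked_anc") <- masked
    res_main <- run_tree(root_state, cfg$tree, cfg, mode = "skip_masked")
    res_disc <- run_tree(root_state, cfg$discordant, cfg, mode = "only_masked")
    # indels are off in discordant mode: rows are positionally compatible
    rows <- res_main$aln$rows
    ids <- res_main$aln$ids
    for (lid in ids) {
      i_main <- match(lid, res_main$aln$ids)
      i_disc <- match(lid, res_disc$aln$ids)
      rows[i_main, masked] <- res_disc$aln$rows[i_disc, masked]
      res_main$leaf_states[[lid]]$chars[masked] <-
        res_disc$leaf_states[[lid]]$chars[masked]
    }
    res_main$aln$rows <- rows
    res_main$sub_log <- bind_rows(
      mutate(res_main$sub_log, pass = "species_tree"),
      mutate(res_disc$sub_log, pass = "discordant_ssc")
    )
    res_main$branch_order_disc <- res_disc$branch_order
    res <- res_main
  } else {
    attr(cfg, "masked_anc") <- integer(0)
    res <- run_tree(root_state, cfg$tree, cfg, mode = "standard")
    res$sub_log$pass <- "species_tree"
  }

  aln_seqs <- apply(res$aln$rows, 1, paste, collapse = "")
  names(aln_seqs) <- res$aln$ids
  true_msa <- msa(aln_seqs[cfg$tree$tip.label])

  col_src <- ifelse(is.na(res$aln$pos), pmax(res$aln$anchor, 1L), res$aln$pos)
  region_labels <- root_region[col_src]

  leaves <- list()
  for (lid in cfg$tree$tip.label) {
    stt <- res$leaf_states[[lid]]
    leaves[[lid]] <- leaf_plastome(lid, stt, ancestor)
  }

  out <- structure(list(
    ancestor = ancestor, leaves = leaves, alignment = true_msa,
    region_labels = region_labels,
    sub_log = res$sub_log, indel_log = res$indel_log,
    branch_order = res$branch_order,
    branch_order_disc = res$branch_order_disc,
    ssr_truth = attr(ancestor, "ssr_truth"),
    tree = cfg$tree, config = cfg
  ), class = "plastome_sim")

  verify_replay(out)
  for (lid in cfg$tree$tip.label) {
    if (msa_ungap(true_msa, lid) != leaves[[lid]]$seq) {
      abort(sprintf("internal error: alignment row for %s does not ungap to its sequence", lid))
    }
  }
  out
}

#' Simulate a full plastome panel in one call
#'
#' `build_ancestor()` followed by [evolve_plastomes()].
#' @inheritParams build_ancestor
#' @return A `plastome_sim` (see [evolve_plastomes()]).
#' @export
simulate_plastomes <- function(cfg) {
  evolve_plastomes(build_ancestor(cfg), cfg)
}

run_tree <- function(root_state, tree, cfg, mode) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  node_label <- function(v) if (v <= ntip) tree$tip.label[v] else paste0("node", v)
  env <- new.env()
  env$sub_log <- list(); env$indel_log <- list(); env$leaf_states <- list()
  env$branch_order <- list()

  recurse <- function(node, state) {
    kids <- which(tree$edge[, 1] == node)
    if (!length(kids)) {
      env$leaf_states[[tree$tip.label[node]]] <- state
      return(list(rows = matrix(state$chars, nrow = 1),
        ids = tree$tip.label[node],
        pos = seq_along(state$chars), anchor = rep(NA_integer_, length(state$chars))))
    }
    parts <- list()
    for (e in kids) {
      child <- tree$edge[e, 2]
      bl <- tree$edge.length[e]
      br <- apply_branch(state, bl, cfg, mode = mode)
      lab <- node_label(child)
      if (nrow(br$subs)) env$sub_log[[lab]] <- mutate(br$subs, branch = lab)
      if (nrow(br$indels)) env$indel_log[[lab]] <- mutate(br$indels, branch = lab)
      env$branch_order[[lab]] <- node_label(node)
      sub <- recurse(child, br$state)
      parts[[length(parts) + 1L]] <- translate_cols(sub, br$parent_pos)
    }
    merge_aligned(parts)
  }

  root <- ntip + 1L
  aln <- recurse(root, root_state)
  list(
    aln = aln,
    leaf_states = env$leaf_states,
    sub_log = if (length(env$sub_log)) bind_rows(env$sub_log) else
      tibble(pos = integer(), from = character(), to = character(),
        region = character(), mirrored = logical(), branch = character()),
    indel_log = if (length(env$indel_log)) bind_rows(env$indel_log) else
      tibble(kind = character(), pos = integer(), len = integer(), seq = character(),
        region = character(), mirrored = logical(), branch = character()),
    branch_order = env$branch_order
  )
}

leaf_plastome <- function(lid, state, ancestor) {
  genes <- ancestor$genes
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    sel <- which(!is.na(state$anc) & state$anc >= genes$start[i] & state$anc <= genes$end[i])
    if (!length(sel)) next
    rows[[length(rows) + 1L]] <- tibble(
      gene = genes$gene[i], start = min(sel), end = max(sel),
      strand = genes$strand[i], kind = genes$kind[i],
      function_class = genes$function_class[i], exons = list(NULL)
    )
  }
  part <- partition_from_labels(state$region, state$chars)
  plastome(lid, chars_seq(state$chars),
    genes = if (length(rows)) bind_rows(rows) else empty_gene_table(),
    partition = part)
}

partition_from_labels <- function(region, chars) {
  r <- rle(region)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  iv <- function(lab) {
    k <- which(r$values == lab)
    c(starts[k[1]], ends[k[1]])
  }
  len <- length(region)
  ira <- iv("IRa"); irb <- iv("IRb")
  idn <- mean(chars[ira[1]:ira[2]] == rev(comp_chars(chars[irb[1]:irb[2]])))
  region_partition(lsc = iv("LSC"), irb = irb, ssc = iv("SSC"), ira = ira,
    genome_length = len, ir_identity = idn)
}

# Replays the per-branch event logs from the ancestor down to every leaf and
# checks the result matches the emitted leaf sequences exactly.
verify_replay <- function(sim) {
  for (lid in names(sim$leaves)) {
    got <- replay_leaf(sim, lid)
    if (got != sim$leaves[[lid]]$seq) {
      abort(sprintf("event-log replay does not reproduce leaf %s", lid))
    }
  }
  invisible(TRUE)
}

#' Replay logged events from the ancestor to one leaf
#'
#' Applies the per-branch substitution and indel logs along the path from the
#' root to `leaf`, independent of the alignment bookkeeping. Used to verify
#' that the event logs are a complete record of the simulation.
#'
#' @param sim A `plastome_sim`.
#' @param leaf Leaf label.
#' @return The reconstructed leaf sequence (character scalar).
#' @export
replay_leaf <- function(sim, leaf) {
  path_of <- function(order_map) {
    path <- character(0)
    cur <- leaf
    while (!is.null(order_map[[cur]])) {
      path <- c(cur, path)
      cur <- order_map[[cur]]
    }
    path
  }
  chars <- seq_chars(sim$ancestor$seq)
  for (lab in path_of(sim$branch_order)) {
    sl <- sim$sub_log[sim$sub_log$branch == lab & sim$sub_log$pass != "discordant_ssc", ]
    il <- sim$indel_log[sim$indel_log$branch == lab, ]
    chars <- apply_logged(chars, sl, il)
  }
  if (!is.null(sim$config$discordant)) {
    # discordant pass: same leaves, separate path through the other tree
    chars_d <- seq_chars(sim$ancestor$seq)
    for (lab in path_of(sim$branch_order_disc)) {
      sl <- sim$sub_log[sim$sub_log$branch == lab & sim$sub_log$pass == "discordant_ssc", ]
      chars_d <- apply_logged(chars_d, sl, NULL)
    }
    masked <- attr(sim$config, "masked_anc")
    chars[masked] <- chars_d[masked]
  }
  chars_seq(chars)
}

cds_mask <- function(p) {
  prot <- rep(FALSE, nchar(p$seq))
  cds <- p$genes[p$genes$kind == "CDS", ]
  for (i in seq_len(nrow(cds))) prot[cds$start[i]:cds$end[i]] <- TRUE
  prot
}

apply_logged <- function(chars, subs, indels = NULL) {
  if (nrow(subs)) chars[subs$pos] <- subs$to
  if (is.null(indels)) return(chars)
  for (i in seq_len(nrow(indels))) {
    ev <- indels[i, ]
    if (ev$kind %in% c("del")) {
      chars <- chars[-(ev$pos:(ev$pos + ev$len - 1L))]
    } else {
      chars <- append(chars, seq_chars(ev$seq), after = ev$pos)
    }
  }
  chars
}

#' @export
print.plastome_sim <- function(x, ...) {
  cat(sprintf(
    "<plastome_sim> %d leaves, alignment %s columns, %d substitution(s), %d indel event(s)\n",
    length(x$leaves), format(nchar(x$alignment$seqs[1]), big.mark = ","),
    nrow(x$sub_log), nrow(x$indel_log)
  ))
  invisible(x)
}

#' @export
#' @method glance plastome_sim
glance.plastome_sim <- function(x, ...) {
  tibble(
    n_leaves = length(x$leaves),
    genome_length = nchar(x$ancestor$seq),
    alignment_columns = nchar(x$alignment$seqs[1]),
    n_substitutions = nrow(x$sub_log),
    n_indel_events = nrow(x$indel_log),
    seed = x$config$seed
  )
}
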