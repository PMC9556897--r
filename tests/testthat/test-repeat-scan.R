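test_that("SSR class minima and the 10 bp screen are enforced", {
  set.seed(31)
  f1 <- clean_flank(100, avoid = "A")
  f2 <- clean_flank(100, avoid = "A")
  # a planted mono-A run of exactly 10
  seq <- paste0(f1, paste(rep("A", 10), collapse = ""), f2)
  hits <- find_ssrs(seq)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$motif, "A")
  expect_identical(hits$copies, 10L)
  expect_identical(hits$start, 101L)

  # (AG) x 4 = 8 bp: below both the copy minimum and the length screen
  g1 <- clean_flank(60, avoid = c("A", "G"))
  g2 <- clean_flank(60, avoid = c("A", "G"))
  expect_identical(nrow(find_ssrs(paste0(g1, "AGAGAGAG", g2))), 0L)
  # (AG) x 5 = 10 bp passes
  h3 <- find_ssrs(paste0(g1, "AGAGAGAGAG", g2))
  expect_identical(h3$motif, "AG")
  expect_identical(h3$copies, 5L)
})

test_that("periodic motifs are reported once at the smallest unit", {
  set.seed(32)
  f1 <- clean_flank(50, avoid = c("A", "T"))
  f2 <- clean_flank(50, avoid = c("A", "T"))
  hits <- find_ssrs(paste0(f1, paste(rep("AT", 8), collapse = ""), f2))
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$unit_len, 2L)
  expect_identical(hits$motif, "AT")
})

test_that("SSR scan matches the exhaustive brute-force oracle on random sequences", {
  for (s in 1:40) {
    set.seed(s)
    n <- sample(300:2500, 1)
    seq <- rand_seq(n, freqs = c(0.35, 0.15, 0.15, 0.35))  # AT-rich, run-prone
    got <- as.data.frame(find_ssrs(seq))
    want <- brute_ssrs(seq)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want, info = paste("seed", s))
  }
})

test_that("raising any class minimum never adds hits", {
  set.seed(41)
  seq <- rand_seq(3000, freqs = c(0.4, 0.1, 0.1, 0.4))
  base <- find_ssrs(seq)
  for (u in 1:6) {
    minima <- c(10L, 5L, 4L, 3L, 3L, 3L)
    minima[u] <- minima[u] + 2L
    stricter <- find_ssrs(seq, minima = minima)
    expect_true(all(paste(stricter$start, stricter$unit_len) %in%
      paste(base$start, base$unit_len)))
    expect_lte(nrow(stricter), nrow(base))
  }
})

test_that("planted dispersed duplicates are found with the right mismatch count", {
  set.seed(51)
  bg <- rand_seq(3000, freqs = rep(0.25, 4))
  # 40 bp forward duplicate with 2 mismatches
  seq <- plant_duplicate(bg, src_start = 500, len = 40, dest_start = 2000,
    n_mismatch = 2)
  hits <- find_dispersed_repeats(seq)
  fwd <- hits[hits$kind == "forward", ]
  expect_identical(nrow(fwd), 1L)
  expect_identical(fwd$start_a, 500L)
  expect_identical(fwd$start_b, 2000L)
  expect_identical(fwd$length, 40L)
  expect_identical(fwd$mismatches, 2L)
  expect_equal(fwd$identity, 38 / 40)

  # 35 bp exact reverse-complement copy
  seq2 <- plant_duplicate(bg, src_start = 700, len = 35, dest_start = 2400,
    palindromic = TRUE)
  pal <- find_dispersed_repeats(seq2)
  pal <- pal[pal$kind == "palindromic", ]
  expect_identical(nrow(pal), 1L)
  expect_identical(sort(c(pal$start_a, pal$start_b)), c(700L, 2400L))
  expect_identical(pal$length, 35L)
  expect_equal(pal$identity, 1.0)

  # 25 bp exact duplicate: below the 30 bp minimum
  seq3 <- plant_duplicate(bg, src_start = 900, len = 25, dest_start = 2700)
  expect_identical(nrow(find_dispersed_repeats(seq3)), 0L)
})

test_that("palindromic detection is strand-symmetric", {
  set.seed(52)
  bg <- rand_seq(2000, freqs = rep(0.25, 4))
  seq <- plant_duplicate(bg, src_start = 300, len = 40, dest_start = 1500,
    n_mismatch = 1, palindromic = TRUE)
  n <- nchar(seq)
  h1 <- find_dispersed_repeats(seq)
  h2 <- find_dispersed_repeats(revcomp(seq))
  h1 <- h1[h1$kind == "palindromic", ]
  h2 <- h2[h2$kind == "palindromic", ]
  expect_identical(nrow(h1), nrow(h2))
  # map h2 coordinates back to the forward strand: a segment starting at s of
  # length L sits at n - (s + L - 1) + 1 on the other strand
  back <- sort(n - (c(h2$start_a, h2$start_b) + h2$length - 1) + 1)
  expect_identical(sort(c(h1$start_a, h1$start_b)), as.integer(back))
  expect_identical(h1$length, h2$length)
  expect_identical(h1$mismatches, h2$mismatches)
})

test_that("hit annotation assigns region by start and gene context by exons", {
  cfg <- tiny_cfg(seed = 3)
  anc <- build_ancestor(cfg)
  hits <- annotate_hits(find_ssrs(anc), anc)
  truth <- attr(anc, "ssr_truth")
  planted <- hits[hits$start %in% truth$start, ]
  expect_identical(planted$region, truth$region)
  expect_true(all(planted$context == "intergenic"))

  # a synthetic hit table exercising the start rule and gene contexts
  fake <- tibble::tibble(start = c(50L, 250L, 2999L, 3001L))
  ann <- annotate_hits(fake, anc)
  expect_identical(ann$region, c("LSC", "LSC", "LSC", "IRb"))
  expect_identical(ann$context[2], "CDS")   # inside planted geneA exon
  expect_identical(ann$gene[2], "geneA")

  expect_error(annotate_hits(fake, plastome("x", "ACGTACGT")), "no partition")

  # region + context counts always sum to the total number of hits
  expect_identical(sum(table(ann$region)), nrow(ann))
  expect_identical(sum(table(ann$context)), nrow(ann))
})

test_that("hits inside an annotated intron are labeled intron with the gene name", {
  set.seed(61)
  seq <- rand_seq(2000)
  genes <- tibble::tibble(
    gene = "g_int", start = 200L, end = 800L, strand = "+", kind = "CDS",
    function_class = NA_character_,
    exons = list(matrix(c(200L, 400L, 601L, 800L), ncol = 2, byrow = TRUE))
  )
  p <- plastome("toy", seq, genes = genes)
  p$partition <- region_partition(c(1, 1200), c(1201, 1500), c(1501, 1700),
    c(1701, 2000), genome_length = 2000)
  ann <- annotate_hits(tibble::tibble(start = c(300L, 500L, 900L)), p)
  expect_identical(ann$context, c("CDS", "intron", "intergenic"))
  expect_identical(ann$gene, c("g_int", "g_int", NA_character_))
})
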