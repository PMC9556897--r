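test_that("FASTA reading gives an annotated-free plastome with the right length", {
  set.seed(11)
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">toy some description", rand_seq(1000)), tmp)
  p <- read_plastome(tmp)
  expect_s3_class(p, "plastome")
  expect_identical(p$id, "toy")
  expect_identical(nchar(p$seq), 1000L)
  expect_identical(nrow(p$genes), 0L)

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_plastome(empty), "no sequence")
  expect_error(read_plastome("/nonexistent/x.fa"), "not found")
})

test_that("ambiguity codes other than N are rejected", {
  expect_error(plastome("x", "ACGTRY"), "outside")
  expect_silent(plastome("x", "ACGTN"))
})

test_that("GenBank coordinates are 1-based inclusive and strands/joins parse", {
  tmp <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       toy 200 bp    DNA     circular PLN",
    "FEATURES             Location/Qualifiers",
    "     CDS             10..99",
    "                     /gene=\"aaa\"",
    "     tRNA            complement(120..190)",
    "                     /gene=\"trnX\"",
    "     CDS             join(101..110,115..118)",
    "                     /gene=\"bbb\"",
    "ORIGIN",
    paste0("        1 ", tolower(rand_seq(60))),
    paste0("       61 ", tolower(rand_seq(60))),
    paste0("      121 ", tolower(rand_seq(60))),
    paste0("      181 ", tolower(rand_seq(20))),
    "//"
  ), tmp)
  p <- read_plastome(tmp)
  expect_identical(nchar(p$seq), 200L)
  g <- p$genes
  expect_identical(g$start[g$gene == "aaa"], 10L)
  expect_identical(g$end[g$gene == "aaa"], 99L)
  expect_identical(g$strand[g$gene == "trnX"], "-")
  expect_identical(nrow(g[g$gene == "bbb", ]), 1L)
  expect_equal(g$exons[g$gene == "bbb"][[1]][, 1], c(101, 115))
})

test_that("generator-written GenBank round-trips", {
  p <- build_ancestor(tiny_cfg(seed = 3))
  tmp <- withr::local_tempfile(fileext = ".gb")
  write_plastome(p, tmp, format = "genbank")
  q <- read_plastome(tmp)
  expect_identical(q$seq, p$seq)
  expect_identical(q$id, p$id)
  key <- function(g) paste(g$gene, g$start, g$end, g$strand, g$kind)
  expect_setequal(key(q$genes), key(p$genes))

  # FASTA round trip too
  tf <- withr::local_tempfile(fileext = ".fasta")
  write_plastome(p, tf, format = "fasta")
  expect_identical(read_plastome(tf)$seq, p$seq)
})

test_that("partition detection recovers construction joints exactly", {
  set.seed(21)
  l <- rand_seq(5000); r <- rand_seq(2000); s <- rand_seq(1000)
  p <- plastome("toy", paste0(l, r, s, revcomp(r)))
  part <- detect_partition(p, min_ir_len = 1000)
  tab <- tidy(part)
  expect_identical(tab$start[tab$region == "LSC"], 1L)
  expect_identical(tab$end[tab$region == "LSC"], 5000L)
  expect_identical(tab$start[tab$region == "IRb"], 5001L)
  expect_identical(tab$end[tab$region == "IRb"], 7000L)
  expect_identical(tab$start[tab$region == "SSC"], 7001L)
  expect_identical(tab$end[tab$region == "SSC"], 8000L)
  expect_identical(tab$start[tab$region == "IRa"], 8001L)
  expect_identical(tab$end[tab$region == "IRa"], 10000L)
  expect_identical(sum(tab$length), 10000L)
  expect_equal(attr(part, "ir_identity"), 1.0)
})

test_that("a genome without an inverted repeat raises a 'no IR found' error", {
  set.seed(22)
  p <- plastome("r", rand_seq(10000))
  expect_error(detect_partition(p, min_ir_len = 1000), "no IR found")
})

test_that("partition detection matches generator truth on ancestors and leaves", {
  cfg <- tiny_cfg(seed = 5)
  anc <- build_ancestor(cfg)
  det <- detect_partition(anc, min_ir_len = 500)
  expect_equal(tidy(det)[, c("region", "start", "end")],
    tidy(anc$partition)[, c("region", "start", "end")])
  expect_equal(attr(det, "ir_identity"), 1.0)

  sim <- evolve_plastomes(anc, cfg)
  for (lf in sim$leaves) {
    det <- tidy(detect_partition(lf, min_ir_len = 500))
    truth <- tidy(lf$partition)
    # leaf junction flanks evolve freely, so a detected (maximal) IR may
    # overrun a construction joint by a few chance-symmetric bases
    expect_true(all(abs(det$start - truth$start) <= 8), info = lf$id)
    expect_true(all(abs(det$end - truth$end) <= 8), info = lf$id)
    ir_det <- det$length[det$region == "IRa"]
    expect_gte(ir_det, truth$length[truth$region == "IRa"])
  }
})

test_that("partition detection handles an IR spanning the declared origin", {
  set.seed(23)
  l <- rand_seq(5000); r <- rand_seq(2000); s <- rand_seq(1000)
  genome <- paste0(l, r, s, revcomp(r))
  # rotate so that the trailing IR copy wraps through the origin
  rot <- paste0(substr(genome, 9001, 10000), substr(genome, 1, 9000))
  part <- detect_partition(plastome("rot", rot), min_ir_len = 1000)
  tab <- tidy(part)
  expect_identical(sum(tab$length), 10000L)
  expect_identical(tab$length[tab$region == "LSC"], 5000L)
  expect_identical(tab$length[tab$region == "SSC"], 1000L)
  expect_identical(sort(tab$length[grepl("IR", tab$region)]), c(2000L, 2000L))
})

test_that("junction distances and spanning flags follow from coordinates", {
  set.seed(24)
  seq <- paste0(rand_seq(5000), rand_seq(2000), rand_seq(1000), "")
  seq <- paste0(seq, revcomp(substr(seq, 5001, 7000)))
  genes <- tibble::tibble(
    gene = c("g1", "g2"),
    start = c(4900L, 7900L), end = c(4963L, 8120L),
    strand = c("+", "+"), kind = "CDS",
    function_class = NA_character_, exons = list(NULL, NULL)
  )
  p <- plastome("toy", seq, genes = genes)
  p$partition <- region_partition(c(1, 5000), c(5001, 7000), c(7001, 8000),
    c(8001, 10000), genome_length = 10000)
  rep <- junction_report(p)
  # g1 ends 37 bp before the LSC/IRb junction at 5000
  r1 <- rep[rep$junction == "LSC/IRb" & rep$side == "upstream", ]
  expect_identical(r1$gene, "g1")
  expect_identical(as.integer(r1$distance), 37L)
  expect_false(r1$spanning)
  # g2 spans the SSC/IRa junction at 8000 by 120 bp
  r2 <- rep[rep$junction == "SSC/IRa", ]
  expect_identical(unique(r2$side), "spanning")
  expect_identical(as.integer(r2$distance), -120L)
  expect_true(all(r2$spanning))

  expect_error(junction_report(plastome("x", "ACGT")), "no partition")
})

test_that("generator junction-spanning gene is reported as planted", {
  anc <- build_ancestor(sim_config(seed = 2))
  rep <- junction_report(anc)
  r <- rep[rep$junction == "SSC/IRa", ]
  expect_identical(r$gene, "ycf1")
  expect_identical(unique(r$side), "spanning")
  # planted tail extends 399 bp into IRa
  expect_identical(as.integer(r$distance), -399L)
})

test_that("alignment column maps and round trips behave", {
  x <- msa(c(s1 = "ACGT", s2 = "ACGT"))
  expect_identical(x$colmap$s1, 1:4)
  x2 <- msa(c(s1 = "AC--GT", s2 = "ACCCGT"))
  expect_identical(x2$colmap$s1, c(1L, 2L, NA, NA, 3L, 4L))
  expect_error(msa(c(a = "ACGT", b = "ACG")), "ragged.*b")

  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_msa(x2, tmp)
  y <- read_msa(tmp)
  expect_identical(y$seqs, x2$seqs)
  expect_identical(y$ids, x2$ids)
})

test_that("region projection labels every column, gaps inheriting backwards", {
  part <- region_partition(c(1, 100), c(101, 130), c(131, 150), c(151, 180),
    genome_length = 180)
  ungapped <- msa(c(r = paste(rep("A", 180), collapse = ""),
    o = paste(rep("A", 180), collapse = "")))
  lab <- project_regions(ungapped, "r", part)
  expect_identical(lab[1:100], rep("LSC", 100))
  expect_identical(lab[101:130], rep("IRb", 30))
  expect_identical(lab[180], "IRa")

  gapped <- msa(c(
    r = paste0(paste(rep("A", 50), collapse = ""), "---",
      paste(rep("A", 130), collapse = "")),
    o = paste(rep("C", 183), collapse = "")
  ))
  lab2 <- project_regions(gapped, "r", part)
  expect_identical(lab2[51:53], rep("LSC", 3))  # ref gap run inside LSC
  expect_identical(length(lab2), 183L)
  expect_error(project_regions(gapped, "zz", part), "not in alignment")
})

test_that("generator true alignment projects to the generator's region labels", {
  cfg <- tiny_cfg(seed = 9)
  sim <- simulate_plastomes(cfg)
  ref <- sim$leaves[[1]]
  lab <- project_regions(sim$alignment, ref$id, ref$partition)
  # truth labels and projection may differ only at columns where the
  # reference is gapped (projection inherits backwards by construction)
  ref_gap <- is.na(sim$alignment$colmap[[ref$id]])
  expect_identical(lab[!ref_gap], sim$region_labels[!ref_gap])
})
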