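test_that("ancestor construction honors sizes, IR symmetry and planted features", {
  cfg <- sim_config(seed = 1, lsc_len = 6000L, ir_len = 2000L, ssc_len = 1500L,
    gene_layout = tiny_layout(),
    ssr_loci = tibble::tibble(motif = "A", copies = 12L, region = "LSC", offset = 900L))
  anc <- build_ancestor(cfg)
  expect_identical(nchar(anc$seq), 11500L)
  det <- detect_partition(anc, min_ir_len = 1000)
  expect_equal(tidy(det)[, c("region", "start", "end")],
    tidy(anc$partition)[, c("region", "start", "end")])
  expect_identical(region_seq(anc, "IRb"), revcomp(region_seq(anc, "IRa")))

  # planted mono-A SSR is found at the planted locus with >= 12 copies
  hits <- find_ssrs(anc)
  truth <- attr(anc, "ssr_truth")
  hit <- hits[hits$start == truth$start[1], ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$motif, "A")
  expect_gte(hit$copies, 12L)
})

test_that("planted CDSs are valid open reading frames", {
  anc <- build_ancestor(sim_config(seed = 4))
  cds <- anc$genes[anc$genes$kind == "CDS" & anc$genes$gene != "ycf1", ]
  cds <- cds[!duplicated(cds$gene), ]
  for (i in seq_len(nrow(cds))) {
    s <- substr(anc$seq, cds$start[i], cds$end[i])
    if (cds$strand[i] == "-") s <- revcomp(s)
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_identical(codons[1], "ATG", info = cds$gene[i])
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"), info = cds$gene[i])
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")),
      info = cds$gene[i])
  }
  # overflow errors
  bad <- tiny_layout(); bad$offset[1] <- 2900L
  expect_error(build_ancestor(tiny_cfg(seed = 1, gene_layout = bad)), "overflows")
})

test_that("gene-free, SSR-free ancestors are random background with the configured composition", {
  cfg <- sim_config(seed = 8, gene_layout = default_gene_layout()[0, ],
    ssr_loci = default_ssr_loci()[0, ])
  anc <- build_ancestor(cfg)
  obs <- table(factor(strsplit(anc$seq, "")[[1]], levels = c("A", "C", "G", "T")))
  expect_gt(stats::chisq.test(obs, p = cfg$base_freqs)$p.value, 0.01)
})

test_that("identical configurations give bit-identical simulations", {
  s1 <- simulate_plastomes(tiny_cfg(seed = 13))
  s2 <- simulate_plastomes(tiny_cfg(seed = 13))
  expect_identical(s1$alignment$seqs, s2$alignment$seqs)
  expect_identical(s1$sub_log, s2$sub_log)
  expect_identical(s1$indel_log, s2$indel_log)
  s3 <- simulate_plastomes(tiny_cfg(seed = 14))
  expect_false(identical(s1$alignment$seqs, s3$alignment$seqs))
})

test_that("zero rates leave every leaf identical to the ancestor, gap-free", {
  cfg <- tiny_cfg(seed = 2, region_rate = c(LSC = 0, SSC = 0, IR = 0),
    indel_rate = 0)
  anc <- build_ancestor(cfg)
  sim <- evolve_plastomes(anc, cfg)
  for (lf in sim$leaves) expect_identical(lf$seq, anc$seq)
  expect_false(any(grepl("-", sim$alignment$seqs, fixed = TRUE)))
})

test_that("alignment rows ungap to leaf sequences and replay reproduces leaves", {
  sim <- simulate_plastomes(tiny_cfg(seed = 6, indel_rate = 0.1))
  for (id in names(sim$leaves)) {
    expect_identical(gsub("-", "", sim$alignment$seqs[[id]]), sim$leaves[[id]]$seq)
    expect_identical(replay_leaf(sim, id), sim$leaves[[id]]$seq)
  }
  # indels present, so this exercised the full bookkeeping
  expect_gt(nrow(sim$indel_log), 0L)
})

test_that("IR copies stay identical under concerted evolution, with mirrored events", {
  cfg <- tiny_cfg(seed = 7, indel_rate = 0.2,
    region_rate = c(LSC = 1, SSC = 2, IR = 2))
  sim <- simulate_plastomes(cfg)
  for (lf in sim$leaves) {
    expect_identical(region_seq(lf, "IRb"), revcomp(region_seq(lf, "IRa")),
      info = lf$id)
  }
  sl <- sim$sub_log
  expect_identical(sum(sl$region == "IRa"), sum(sl$region == "IRb" & sl$mirrored))
})

test_that("observed divergence matches the binomial expectation", {
  diffs <- vapply(1:200, function(s) {
    cfg <- sim_config(seed = s, tree = "(a:0.01,b:0.01);",
      lsc_len = 10000L, ir_len = 600L, ssc_len = 500L,
      region_rate = c(LSC = 1, SSC = 0, IR = 0),
      indel_rate = 0, ssr_slippage = 0,
      gene_layout = default_gene_layout()[0, ], ssr_loci = default_ssr_loci()[0, ])
    sim <- simulate_plastomes(cfg)
    a <- strsplit(sim$leaves$a$seq, "")[[1]]
    b <- strsplit(sim$leaves$b$seq, "")[[1]]
    sum(a[1:10000] != b[1:10000])
  }, 0)
  # expectation 10,000 x 0.02 (tiny deflation from double hits); 3 SE band
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 200), 3 * se + 1)
})

test_that("with kappa = 1 and equal frequencies a third of changes are transitions", {
  cfg <- sim_config(seed = 3, tree = "(a:0.05,b:0.05);",
    lsc_len = 20000L, ir_len = 600L, ssc_len = 500L,
    kappa = 1, base_freqs = rep(0.25, 4),
    region_rate = c(LSC = 1, SSC = 0, IR = 0), indel_rate = 0, ssr_slippage = 0,
    gene_layout = default_gene_layout()[0, ], ssr_loci = default_ssr_loci()[0, ])
  sim <- simulate_plastomes(cfg)
  sl <- sim$sub_log
  is_ts <- (sl$from %in% c("A", "G") & sl$to %in% c("A", "G")) |
    (sl$from %in% c("C", "T") & sl$to %in% c("C", "T"))
  frac <- mean(is_ts)
  n <- length(is_ts)
  expect_lt(abs(frac - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / n))
})

test_that("indels never split planted CDSs by default", {
  cfg <- tiny_cfg(seed = 10, indel_rate = 0.3)
  sim <- simulate_plastomes(cfg)
  expect_gt(nrow(sim$indel_log), 0L)
  for (lf in sim$leaves) {
    for (g in c("geneA", "geneB")) {
      row <- lf$genes[lf$genes$gene == g, ]
      planted <- tiny_layout()
      expect_identical(row$end - row$start + 1L,
        planted$len[planted$gene == g], info = paste(lf$id, g))
    }
  }
})

test_that("discordant preset splices a conflicting SSC history without indels", {
  cfg <- sim_config_discordant(seed = 2)
  expect_identical(cfg$indel_rate, 0)
  sim <- simulate_plastomes(cfg)
  expect_identical(nrow(sim$indel_log), 0L)
  expect_true(any(sim$sub_log$pass == "discordant_ssc"))
  for (id in names(sim$leaves)) {
    expect_identical(replay_leaf(sim, id), sim$leaves[[id]]$seq)
  }
})
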