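mk_msa <- function(...) msa(c(...))

test_that("SNP calling ignores gaps and N and requires two real bases", {
  x <- mk_msa(s1 = "AAC", s2 = "A-C", s3 = "GAC")
  snps <- call_snps(x)
  expect_identical(snps$column, 1L)       # col 2 is A/-/A, col 3 invariant
  expect_identical(snps$n_alleles, 2L)
  x2 <- mk_msa(s1 = "ANT", s2 = "ANT")
  expect_identical(nrow(call_snps(x2)), 0L)
  expect_error(call_snps(msa(c(only = "ACGT"))), ">= 2 rows")
})

test_that("substitution spectrum counts pairwise types and the Ts/Tv ratio", {
  x <- mk_msa(s1 = "ACA", s2 = "GTT")
  sp <- ts_tv_spectrum(call_snps(x))
  expect_identical(sp$count[sp$substitution == "A<->G"], 1L)
  expect_identical(sp$count[sp$substitution == "C<->T"], 1L)
  expect_identical(sp$count[sp$substitution == "A<->T"], 1L)
  expect_identical(sum(sp$count), 3L)
  expect_equal(ts_tv_ratio(sp), 2.00)

  # Tv = 0 -> undefined ratio, not infinity
  y <- mk_msa(s1 = "A", s2 = "G")
  expect_true(is.na(ts_tv_ratio(ts_tv_spectrum(call_snps(y)))))
})

test_that("spectrum equals a brute-force per-pair recount on random alignments", {
  for (s in 1:5) {
    set.seed(s + 70)
    rows <- replicate(4, paste(sample(c("A", "C", "G", "T", "-", "N"), 200,
      replace = TRUE, prob = c(0.23, 0.23, 0.23, 0.23, 0.05, 0.03)), collapse = ""))
    x <- msa(setNames(rows, paste0("t", 1:4)))
    sp <- ts_tv_spectrum(call_snps(x))
    # brute force: double loop over pairs and columns
    mm <- do.call(rbind, lapply(rows, chars_of))
    want <- setNames(rep(0L, 6), sp$substitution)
    for (i in 1:3) for (j in (i + 1):4) for (c in 1:200) {
      a <- mm[i, c]; b <- mm[j, c]
      if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T") && a != b) {
        # only columns that are SNP columns overall contribute
        col <- mm[, c]
        if (length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2) {
          key <- paste0(min(a, b), "<->", max(a, b))
          want[key] <- want[key] + 1L
        }
      }
    }
    expect_identical(setNames(sp$count, sp$substitution), want, info = paste("seed", s))
  }
})

test_that("pairwise indel events are maximal single-row gap runs, terminal runs excluded", {
  x <- mk_msa(a = "ACGT--TT", b = "ACGTCCTT")
  ev <- call_indels(x)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$start, 5L)
  expect_identical(ev$length, 2L)

  y <- mk_msa(a = "--ACGT", b = "CCACGT")
  expect_identical(nrow(call_indels(y)), 0L)

  # columns gapped in both members are dropped before run detection
  z <- mk_msa(a = "AC--GT", b = "AC--GT")
  expect_identical(nrow(call_indels(z)), 0L)
})

test_that("pairwise indel counts equal the generator's logs projected to pairs", {
  cfg <- tiny_cfg(seed = 12, tree = "(a:0.004,b:0.004);", indel_rate = 0.15,
    region_rate = c(LSC = 1, SSC = 1, IR = 0.1))
  sim <- simulate_plastomes(cfg)
  ev <- call_indels(sim$alignment)
  # two-leaf tree: every logged non-mirrored indel event separates the pair,
  # except that adjacent events merged into one run would merge; in this
  # low-rate regime events are sparse and counts match exactly
  logged <- sim$indel_log[!sim$indel_log$mirrored, ]
  expect_identical(nrow(ev), nrow(logged) + sum(sim$indel_log$mirrored))
})

test_that("regional tallies pool the IRs and reproduce printed-style percentages", {
  rec <- tibble::tibble(region = c("LSC", "LSC", "SSC"))
  t1 <- tally_by_region(rec, "snp")
  expect_identical(t1$count, c(2L, 0L, 1L))
  expect_equal(t1$pct, c(67, 0, 33))

  t0 <- tally_by_region(rec[0, , drop = FALSE], "snp")
  expect_identical(sum(t0$count), 0L)
  expect_true(all(is.na(t0$pct)))
})

test_that("SNP region tallies equal generator truth in the low-rate regime", {
  cfg <- tiny_cfg(seed = 15, tree = "(a:0.002,b:0.003);", indel_rate = 0,
    region_rate = c(LSC = 1, SSC = 2, IR = 0.5))
  sim <- simulate_plastomes(cfg)
  snps <- call_snps(sim$alignment, sim$region_labels)
  tal <- tally_by_region(snps, "snp")
  # expected hits/site well below 0.05: substitution columns = distinct hit sites
  truth_sites <- unique(sim$sub_log[!sim$sub_log$mirrored, c("pos", "region")])
  truth <- table(ifelse(truth_sites$region %in% c("IRa", "IRb"), "IR",
    truth_sites$region))
  for (rg in c("LSC", "SSC")) {
    expect_identical(tal$count[tal$region == rg], unname(truth[rg]) * 1L,
      info = rg)
  }
  # mirrored IR events appear in both copies: twice the distinct IRa sites
  expect_identical(tal$count[tal$region == "IR"],
    2L * sum(truth_sites$region == "IRa"))
})

test_that("ALS is region length over pairwise SNP count, with zero-SNP capping", {
  a <- paste(rep("A", 1000), collapse = "")
  b <- paste(c(rep("A", 990), rep("G", 10)), collapse = "")
  x <- mk_msa(s1 = a, s2 = b, s3 = a)
  labels <- rep("LSC", 1000)
  m <- als_matrix(x, labels, "LSC")
  expect_equal(m["s1", "s2"], 100)
  expect_equal(m["s2", "s3"], 100)
  expect_equal(m["s1", "s3"], 1000)          # no SNPs: capped at L
  expect_true(attr(m, "capped")["s1", "s3"])
  expect_false(attr(m, "capped")["s1", "s2"])
  expect_error(als_matrix(x, labels, "SSC"), "absent")
})

test_that("normalization divides by the off-diagonal maximum and is idempotent", {
  v <- matrix(c(NA, 4, 4, NA), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  m <- plastidscreen:::new_pair_matrix(v, "ALS")
  n1 <- normalize_matrix(m)
  expect_equal(n1["a", "b"], 1)
  expect_equal(attr(n1, "norm_constant"), 4)

  set.seed(81)
  vv <- matrix(runif(25, 1, 100), 5, 5)
  vv <- (vv + t(vv)) / 2
  dimnames(vv) <- list(letters[1:5], letters[1:5])
  m2 <- plastidscreen:::new_pair_matrix(vv, "ALS")
  n2 <- normalize_matrix(m2)
  n3 <- normalize_matrix(n2)
  expect_equal(matrix(as.numeric(n3), 5), matrix(as.numeric(n2), 5))
  off <- n2[upper.tri(n2)]
  expect_equal(max(off), 1)
  expect_true(all(off > 0 & off <= 1))

  zero <- plastidscreen:::new_pair_matrix(
    matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))), "x")
  expect_error(normalize_matrix(zero), "all-zero")
})

test_that("indel matrices are symmetric pairwise event counts", {
  x <- mk_msa(a = "ACGTACGTAA", b = "ACG---GTAA", c = "ACGTACGTAA")
  labels <- rep("LSC", 10)
  m <- indel_matrix(x, labels, "LSC")
  expect_identical(unname(m["a", "b"]), 1)
  expect_identical(unname(m["b", "c"]), 1)
  expect_identical(unname(m["a", "c"]), 0)
  expect_true(isSymmetric(unclass(unname(m))))

  sim <- simulate_plastomes(tiny_cfg(seed = 16, indel_rate = 0.1))
  lab <- sim$region_labels
  for (rg in c("LSC", "IR", "SSC")) {
    mm <- indel_matrix(sim$alignment, lab, rg)
    expect_true(isSymmetric(unclass(unname(mm))), info = rg)
  }
})

test_that("regional counts always sum to the global total", {
  sim <- simulate_plastomes(tiny_cfg(seed = 17, indel_rate = 0.05))
  snps <- call_snps(sim$alignment, sim$region_labels)
  tal <- tally_by_region(snps, "snp")
  expect_identical(sum(tal$count), nrow(snps))
  ind <- call_indels(sim$alignment, sim$region_labels, scope = "global")
  tali <- tally_by_region(ind, "indel")
  expect_identical(sum(tali$count), nrow(ind))
})
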