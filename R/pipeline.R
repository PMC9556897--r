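# End-to-end orchestration: partition -> repeats -> variation -> diversity ->
# codon bias -> marker screen -> trees -> conflict report, with deterministic
# outputs (no timestamps; the seed and effective configuration are echoed into
# the summary).

#' Run the full screening pipeline
#'
#' Either simulates a plastome panel (`simulate = TRUE`, the default) or
#' consumes a whole-genome alignment plus a GenBank reference. All stage
#' outputs are written as TSV/JSON under `out_dir`, linked from
#' `summary.json` with md5 checksums. Reruns with the same configuration are
#' byte-identical.
#'
#' @param config A named list (or path to a YAML file) with any of:
#'   `seed` (default 1), `simulate` (default `TRUE`), `preset`
#'   (`"default"`/`"discordant"`), `sim` (argument list for [sim_config()]),
#'   `alignment` + `reference` (+ `ref_id`) for real inputs, `window`, `step`,
#'   `grouping_threshold`, `marker_min_len`, `marker_min_snps`,
#'   `require_low_bias`, `conflict_threshold`, `reference_tree` (Newick path
#'   overriding the concatenated-marker tree).
#' @param out_dir Output directory (created; must be empty or absent unless
#'   `overwrite = TRUE`).
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Invisibly, the summary list (also written to
#'   `out_dir/summary.json`).
#' @export
run_pipeline <- function(config = list(), out_dir, overwrite = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    seed = 1L, simulate = TRUE, preset = "default", sim = list(),
    window = 600L, step = 200L, grouping_threshold = 0.1,
    marker_min_len = 1000L, marker_min_snps = 30L, require_low_bias = FALSE,
    conflict_threshold = 2L, ref_id = NULL,
    alignment = NULL, reference = NULL, reference_tree = NULL
  ), config)

  # validate before creating anything
  if (!cfg$simulate) {
    if (is.null(cfg$alignment) || !file.exists(cfg$alignment)) {
      abort("config error: alignment path missing or not found")
    }
    if (!is.null(cfg$reference) && !file.exists(cfg$reference)) {
      abort("config error: reference path not found")
    }
  }
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite) {
    abort(sprintf("output directory %s is not empty", out_dir))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, name)
    path
  }
  emit_matrix <- function(m, name) {
    df <- data.frame(species = rownames(m), unclass(m), check.names = FALSE)
    emit(df, name)
  }

  stage <- "input"
  res <- tryCatch({
    if (cfg$simulate) {
      simcfg <- do.call(sim_config, utils::modifyList(
        c(list(seed = cfg$seed),
          if (identical(cfg$preset, "discordant")) {
            as.list(sim_config_discordant(cfg$seed))[
              c("tree", "discordant", "lsc_len", "ir_len", "ssc_len",
                "gene_layout", "indel_rate", "ssr_slippage")]
          } else list()),
        cfg$sim))
      sim <- simulate_plastomes(simcfg)
      aln <- sim$alignment
      ref_id <- cfg$ref_id %||% aln$ids[1]
      ref <- sim$leaves[[ref_id]]
    } else {
      sim <- NULL
      aln <- read_msa(cfg$alignment)
      ref_id <- cfg$ref_id %||% aln$ids[1]
      if (!is.null(cfg$reference)) {
        ref <- read_plastome(cfg$reference)
        ref$id <- ref_id
        ref$seq <- msa_ungap(aln, ref_id)
      } else {
        ref <- plastome(ref_id, msa_ungap(aln, ref_id))
      }
    }

    stage <- "partition"
    ref$partition <- detect_partition(ref,
      min_ir_len = min(10000L, nchar(ref$seq) %/% 10L))
    emit(tidy(ref$partition), "partition.tsv")
    emit(junction_report(ref), "junctions.tsv")

    stage <- "repeats"
    ssrs <- annotate_hits(find_ssrs(ref), ref)
    emit(ssrs, "ssr_hits.tsv")
    disp <- find_dispersed_repeats(ref)
    emit(annotate_hits(disp, ref), "dispersed_repeats.tsv")

    stage <- "variation"
    labels <- project_regions(aln, ref_id, ref$partition)
    snps <- call_snps(aln, labels)
    spec <- ts_tv_spectrum(snps)
    emit(spec, "substitution_spectrum.tsv")
    snp_tally <- tally_by_region(snps, "snp")
    emit(snp_tally, "snp_region_tally.tsv")
    indels <- call_indels(aln, labels, scope = "pairwise")
    indel_tally <- tally_by_region(
      call_indels(aln, labels, scope = "global"), "indel")
    emit(indel_tally, "indel_region_tally.tsv")
    for (rg in c("LSC", "IR", "SSC")) {
      emit_matrix(normalize_matrix(als_matrix(aln, labels, rg)),
        sprintf("als_%s_normalized.tsv", tolower(rg)))
      emit_matrix(indel_matrix(aln, labels, rg, indels = indels),
        sprintf("indels_%s.tsv", tolower(rg)))
    }

    stage <- "diversity"
    windows <- sliding_pi(aln, cfg$window, cfg$step, labels)
    emit(windows, "pi_windows.tsv")
    mp_ssc <- pairwise_mean_pi(aln, labels, "SSC",
      window = cfg$window, step = cfg$step)
    emit_matrix(mp_ssc, "mean_pi_ssc.tsv")
    grouping <- group_species(mp_ssc, cfg$grouping_threshold)
    jsonlite::write_json(
      list(threshold = cfg$grouping_threshold, linkage = grouping$linkage,
        groups = grouping$groups),
      file.path(out_dir, "grouping.json"), auto_unbox = TRUE, pretty = TRUE)
    files <- c(files, "grouping.json")

    stage <- "markers"
    mt <- marker_table(aln, ref, codon_side = TRUE)
    screened <- ideal_filter(mt, cfg$marker_min_len, cfg$marker_min_snps,
      require_low_bias = cfg$require_low_bias)
    emit(screened, "marker_table.tsv")
    selected <- screened$gene[screened$ideal]

    stage <- "trees"
    gene_alns <- extract_gene_msa(aln, ref_id, ref$genes)
    marker_trees <- lapply(gene_alns[selected], function(g) {
      nj_tree(pdistance_matrix(g))
    })
    if (!is.null(cfg$reference_tree)) {
      ref_tree <- ape::read.tree(cfg$reference_tree)
    } else if (length(selected)) {
      concat <- msa(setNames(vapply(aln$ids, function(id) {
        paste(vapply(gene_alns[selected], function(g) g$seqs[[id]], character(1)),
          collapse = "")
      }, character(1)), aln$ids))
      ref_tree <- nj_tree(pdistance_matrix(concat), source = "concatenated_markers")
    } else {
      ref_tree <- nj_tree(pdistance_matrix(aln), source = "whole_genome")
    }
    ape::write.tree(ref_tree, file.path(out_dir, "reference_tree.nwk"))
    files <- c(files, "reference_tree.nwk")
    if (length(marker_trees)) {
      ape::write.tree(do.call(c, unname(marker_trees)),
        file.path(out_dir, "marker_trees.nwk"))
      files <- c(files, "marker_trees.nwk")
      emit(conflict_report(marker_trees, ref_tree, cfg$conflict_threshold),
        "conflict_report.tsv")
    }

    list(aln = aln, ref = ref, selected = selected, grouping = grouping,
      snp_tally = snp_tally, sim = sim)
  }, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })

  summary <- list(
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "sim")],
    reference = res$ref$id,
    n_species = length(res$aln$ids),
    selected_markers = res$selected,
    files = lapply(setNames(files, files), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    })
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}
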