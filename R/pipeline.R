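## Pipeline orchestration: simulate -> differential -> enrichment ->
## network -> qpcr -> dosimetry, exchanging stage outputs as files in a
## run directory so every stage is individually re-runnable, with a
## consolidated summary report and a provenance log. Deterministic under a
## fixed seed (stage seeds are derived from the master seed).

#' Default pipeline configuration
#'
#' All thresholds default to the study's printed values: fold-change
#' cutoffs 1.2/0.83 with BH-adjusted P <= 0.1 for differential calling,
#' Fisher P <= 0.05 for enrichment, |log2FC| > 0.263 for network
#' modulation classes and top-10 hubs. Synthetic-data defaults emulate the
#' study design: 1000 quantified proteins, 10% planted effects with
#' |log2FC| in [1, 1.5], technical noise sd 0.1 on the log2 scale, three
#' comparison groups in duplicate, a 800-node scale-free interactome with
#' a planted 20-node dense module, a 4-gene qPCR panel with two reference
#' genes and 5 samples per group, and 40 dosimetry subjects.
#'
#' @param seed master RNG seed for the whole run.
#' @return named list accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = check_seed(seed),
    ## synthetic data
    n_proteins = 1000L, de_fraction = 0.1,
    effect_range_log2 = c(1, 1.5), replicate_noise_sd = 0.1,
    up_proportion = 0.5, n_replicates = 2L,
    n_terms = 50L, term_size_range = c(10L, 40L), n_enriched = 5L,
    enrichment_odds = 5,
    interactome_nodes = 800L, attachment_m = 2L,
    planted_module_size = 20L, planted_density = 0.8,
    qpcr_targets = c("GENE_A", "GENE_B", "GENE_C", "GENE_D"),
    qpcr_ref_genes = c("ACTB", "GAPDH"),
    qpcr_planted_log2fc = c(GENE_A = 1, GENE_B = 0.585, GENE_C = -1,
                            GENE_D = 0),
    qpcr_n_per_group = 5L, ct_noise_sd = 0.2,
    n_subjects = 40L, rate_range_uR_per_h = c(10, 300),
    occupancy_indoor = 0.8,
    ## analysis thresholds
    fc_up = 1.2, fc_down = 0.83, alpha_adj = 0.1, enrich_alpha = 0.05,
    hub_log2fc_cut = 0.263, top_k = 10L,
    n_permutations = 1000L, gcc_null = "uniform",
    boundary_1.5 = "HLNRA", conversion_factor = 0.0767,
    calibrator_group = "I", qpcr_alpha = 0.05)
}

#' Validate a pipeline configuration
#'
#' @param config configuration list (see [default_config()]).
#' @return the config, invisibly, or an error naming the offending field.
#' @export
validate_config <- function(config) {
  base <- default_config()
  miss <- setdiff(names(base), names(config))
  stop_if(length(miss) > 0, "config is missing field(s): %s",
          paste(miss, collapse = ", "))
  extra <- setdiff(names(config), names(base))
  stop_if(length(extra) > 0, "unknown config field(s): %s",
          paste(extra, collapse = ", "))
  stop_if(config$fc_up <= 1, "'fc_up' must be > 1")
  stop_if(config$fc_down >= 1 || config$fc_down <= 0,
          "'fc_down' must be in (0, 1)")
  for (f in c("alpha_adj", "enrich_alpha", "qpcr_alpha"))
    check_proportion(config[[f]], f)
  check_positive(config$hub_log2fc_cut, "hub_log2fc_cut")
  check_count(config$top_k, "top_k")
  check_count(config$n_permutations, "n_permutations", min = 1000L)
  check_seed(config$seed)
  invisible(config)
}

#' Override configuration fields from "key=value" strings
#'
#' Convenience for command-line style overrides; values are parsed with
#' the type of the default field.
#'
#' @param config configuration list.
#' @param sets character vector like `c("n_proteins=500", "seed=7")`.
#' @return updated config.
#' @export
config_set <- function(config, sets) {
  for (s in sets) {
    kv <- strsplit(s, "=", fixed = TRUE)[[1]]
    stop_if(length(kv) != 2L, "override must be key=value: '%s'", s)
    key <- kv[1]
    stop_if(!key %in% names(config), "unknown config field '%s'", key)
    old <- config[[key]]
    val <- strsplit(kv[2], ",", fixed = TRUE)[[1]]
    config[[key]] <- if (is.numeric(old)) {
      v <- as.numeric(val)
      if (!is.null(names(old))) stats::setNames(v, names(old)) else v
    } else val
  }
  config
}

stage_seed <- function(config, k) (config$seed %% 100000L) * 10L + k

pipe_path <- function(outdir, ...) file.path(outdir, sprintf(...))

#' Generate all pipeline inputs with planted truth
#'
#' Writes quant.tsv, truth.tsv, annotation.gmt, interactome.tsv, ct.tsv,
#' dosimetry.tsv and planted.json (planted proteins, module members,
#' enriched terms, qPCR planted fold changes) into the run directory.
#'
#' @param config validated configuration.
#' @param outdir run directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
stage_simulate <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sq <- sim_quant(config$n_proteins, config$de_fraction,
                  config$effect_range_log2, config$replicate_noise_sd,
                  config$up_proportion, config$n_replicates,
                  seed = stage_seed(config, 1L))
  write_tsv(sq$quant, pipe_path(outdir, "quant.tsv"))
  write_tsv(sq$truth, pipe_path(outdir, "truth.tsv"))
  terms <- sim_annotation(sq, config$n_terms, config$term_size_range,
                          config$n_enriched, config$enrichment_odds,
                          seed = stage_seed(config, 2L))
  write_gmt(terms, pipe_path(outdir, "annotation.gmt"))
  net <- sim_interactome(sq, config$interactome_nodes, config$attachment_m,
                         config$planted_module_size, config$planted_density,
                         seed = stage_seed(config, 3L))
  write_tsv(net$edges, pipe_path(outdir, "interactome.tsv"))
  ct <- sim_ct(config$qpcr_targets, config$qpcr_ref_genes,
               config$qpcr_planted_log2fc, config$qpcr_n_per_group,
               config$ct_noise_sd, seed = stage_seed(config, 4L))
  write_tsv(ct, pipe_path(outdir, "ct.tsv"))
  dose <- sim_dosimetry(config$n_subjects, config$rate_range_uR_per_h,
                        config$occupancy_indoor,
                        seed = stage_seed(config, 5L))
  write_tsv(dose, pipe_path(outdir, "dosimetry.tsv"))
  jsonlite::write_json(
    list(planted_proteins = sq$planted, module = net$module,
         enriched_terms = attr(terms, "planted_terms"),
         qpcr_planted_log2fc = as.list(config$qpcr_planted_log2fc)),
    pipe_path(outdir, "planted.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(outdir)
}

#' Differential-calling stage
#'
#' Reads quant.tsv; writes differential_calls.tsv, volcano.tsv, venn.json,
#' qc_excluded.tsv and normality.tsv.
#'
#' @inheritParams stage_simulate
#' @return the differential call list, invisibly.
#' @export
stage_differential <- function(config, outdir) {
  quant <- read_tsv(pipe_path(outdir, "quant.tsv"))
  dd <- call_differential(quant, config$fc_up, config$fc_down,
                          config$alpha_adj, config$n_replicates)
  write_tsv(dd$calls, pipe_path(outdir, "differential_calls.tsv"))
  write_tsv(volcano_table(dd$calls), pipe_path(outdir, "volcano.tsv"))
  write_tsv(dd$qc_excluded, pipe_path(outdir, "qc_excluded.tsv"))
  if (!is.null(dd$normality))
    write_tsv(dd$normality, pipe_path(outdir, "normality.tsv"))
  sets <- split(dd$calls$protein_id[dd$calls$status != "unchanged"],
                dd$calls$group[dd$calls$status != "unchanged"])
  jsonlite::write_json(as.list(venn_partition(sets)),
                       pipe_path(outdir, "venn.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dd)
}

#' Enrichment stage
#'
#' Reads differential_calls.tsv and annotation.gmt; writes one
#' enrichment_<group>.tsv per group plus the term x group -log10(p)
#' matrix.
#'
#' @inheritParams stage_simulate
#' @return named list of enrichment tables, invisibly.
#' @export
stage_enrichment <- function(config, outdir) {
  calls <- read_tsv(pipe_path(outdir, "differential_calls.tsv"))
  terms <- read_gmt(pipe_path(outdir, "annotation.gmt"))
  background <- unique(calls$protein_id)
  res <- list()
  for (g in unique(calls$group)) {
    sel <- calls$protein_id[calls$group == g & calls$status != "unchanged"]
    if (length(sel) == 0L) next
    e <- fisher_enrich(sel, background, terms, config$enrich_alpha)
    write_tsv(e, pipe_path(outdir, "enrichment_%s.tsv", g))
    res[[g]] <- e
  }
  if (length(res)) {
    m <- enrichment_matrix(res)
    write_tsv(cbind(term_id = rownames(m), as.data.frame(m)),
              pipe_path(outdir, "enrichment_matrix.tsv"))
  }
  invisible(res)
}

#' Network stage
#'
#' Reads differential_calls.tsv and interactome.tsv; per group, builds the
#' annotated network, writes GraphML + GEXF exports, the hub table and the
#' GCC permutation-significance JSON.
#'
#' @inheritParams stage_simulate
#' @return named list with per-group network, gcc and hub results,
#'   invisibly.
#' @export
stage_network <- function(config, outdir) {
  calls <- read_tsv(pipe_path(outdir, "differential_calls.tsv"))
  interactome <- read_tsv(pipe_path(outdir, "interactome.tsv"))
  diff_union <- unique(calls$protein_id[calls$status %in% c("up", "down")])
  inter_nodes <- unique(c(interactome$protein_a, interactome$protein_b))
  n_mapped <- length(intersect(diff_union, inter_nodes))
  res <- list()
  for (g in unique(calls$group)) {
    net <- tryCatch(
      build_group_network(calls, g, interactome, config$hub_log2fc_cut),
      error = function(e) NULL)
    if (is.null(net)) next
    net <- annotate_network(net)
    gcc <- extract_gcc(net)
    sig <- gcc_significance(interactome,
                            n_selected = n_mapped,
                            observed_gcc = gcc$size,
                            n_permutations = config$n_permutations,
                            seed = stage_seed(config, 6L),
                            null = config$gcc_null)
    hubs <- hub_rank(net, min(config$top_k, igraph::vcount(net)))
    export_network(net, pipe_path(outdir, "network_%s.graphml", g),
                   "graphml")
    export_network(net, pipe_path(outdir, "network_%s.gexf", g), "gexf")
    write_tsv(hubs, pipe_path(outdir, "hubs_%s.tsv", g))
    jsonlite::write_json(sig, pipe_path(outdir, "gcc_%s.json", g),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res[[g]] <- list(network = net, gcc = gcc, significance = sig,
                     hubs = hubs)
  }
  stop_if(length(res) == 0L, "no group yielded a non-empty network")
  invisible(res)
}

#' qPCR stage
#'
#' Reads ct.tsv; writes reference_stability.tsv and qpcr_results.tsv (also
#' the bar-plot data: mean fold +/- SEM per gene and group).
#'
#' @inheritParams stage_simulate
#' @return the [qpcr_analysis()] result, invisibly.
#' @export
stage_qpcr <- function(config, outdir) {
  ct <- read_tsv(pipe_path(outdir, "ct.tsv"))
  qa <- qpcr_analysis(ct, config$qpcr_targets, config$qpcr_ref_genes,
                      config$calibrator_group, config$qpcr_alpha)
  write_tsv(qa$stability, pipe_path(outdir, "reference_stability.tsv"))
  write_tsv(qa$results, pipe_path(outdir, "qpcr_results.tsv"))
  invisible(qa)
}

#' Dosimetry stage
#'
#' Reads dosimetry.tsv; writes doses.tsv with annual dose and group.
#'
#' @inheritParams stage_simulate
#' @return the stratified table, invisibly.
#' @export
stage_dosimetry <- function(config, outdir) {
  dose <- read_tsv(pipe_path(outdir, "dosimetry.tsv"))
  out <- stratify_doses(dose, config$conversion_factor, config$boundary_1.5)
  write_tsv(out, pipe_path(outdir, "doses.tsv"))
  invisible(out)
}

#' Consolidated summary report
#'
#' Reads the stage outputs and writes summary.json: per-group up/down
#' counts, the Venn partition, significantly enriched terms, GCC
#' significance, top hubs, qPCR results, dose-group sizes and — when
#' planted truth is present — planted-signal recovery (fraction of planted
#' proteins called with the correct sign).
#'
#' @inheritParams stage_simulate
#' @return the summary list, invisibly.
#' @export
stage_report <- function(config, outdir) {
  calls <- read_tsv(pipe_path(outdir, "differential_calls.tsv"))
  groups <- sort(unique(calls$group))
  updown <- lapply(stats::setNames(groups, groups), function(g) {
    cg <- calls[calls$group == g, ]
    list(up = sum(cg$status == "up"), down = sum(cg$status == "down"),
         differential = sum(cg$status != "unchanged"))
  })
  venn <- jsonlite::read_json(pipe_path(outdir, "venn.json"))
  enriched <- lapply(stats::setNames(groups, groups), function(g) {
    f <- pipe_path(outdir, "enrichment_%s.tsv", g)
    if (!file.exists(f)) return(NULL)
    e <- read_tsv(f)
    e$term_id[e$significant]
  })
  gcc <- lapply(stats::setNames(groups, groups), function(g) {
    f <- pipe_path(outdir, "gcc_%s.json", g)
    if (file.exists(f)) jsonlite::read_json(f) else NULL
  })
  hubs <- lapply(stats::setNames(groups, groups), function(g) {
    f <- pipe_path(outdir, "hubs_%s.tsv", g)
    if (file.exists(f)) read_tsv(f)$protein_id else NULL
  })
  qpcr <- read_tsv(pipe_path(outdir, "qpcr_results.tsv"))
  doses <- read_tsv(pipe_path(outdir, "doses.tsv"))

  summary <- list(
    config = config[c("fc_up", "fc_down", "alpha_adj", "enrich_alpha",
                      "hub_log2fc_cut", "top_k", "n_permutations", "seed")],
    differential = updown, venn = venn, enriched_terms = enriched,
    gcc_significance = gcc, top_hubs = hubs,
    qpcr = split(qpcr[setdiff(names(qpcr), "gene")], qpcr$gene),
    dose_groups = as.list(table(doses$group)))

  truth_file <- pipe_path(outdir, "truth.tsv")
  if (file.exists(truth_file)) {
    truth <- read_tsv(truth_file)
    mg <- merge(calls, truth, by = c("protein_id", "group"))
    planted <- mg[mg$true_status != "null", ]
    recovered <- planted$status == planted$true_status
    summary$planted_recovery <- list(
      n_planted_calls = nrow(planted),
      n_recovered = sum(recovered),
      recovery_fraction = if (nrow(planted)) mean(recovered) else NA,
      false_positive_fraction =
        mean(mg$status[mg$true_status == "null"] != "unchanged"))
  }
  jsonlite::write_json(summary, pipe_path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional), differential, enrichment, network, qpcr,
#' dosimetry and report stages into `outdir`. Every output is a text file;
#' the run is deterministic given `config$seed`, so re-running the same
#' configuration reproduces every file byte for byte. A provenance log
#' (provenance.json) records the full configuration and package version.
#' A stage failure aborts the run with the stage name in the error.
#'
#' @param config configuration list (see [default_config()],
#'   [config_set()]).
#' @param outdir run directory.
#' @param simulate generate synthetic inputs first (set `FALSE` when
#'   quant.tsv etc. are already in `outdir`, e.g. real data).
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config = default_config(), outdir,
                         simulate = TRUE) {
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- c(if (simulate) "simulate",
              "differential", "enrichment", "network", "qpcr", "dosimetry",
              "report")
  for (st in stages) {
    fn <- get(paste0("stage_", st), mode = "function")
    tryCatch(fn(config, outdir),
             error = function(e) stop("stage '", st, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }
  prov <- list(package = "itraqnet",
               version = as.character(utils::packageVersion("itraqnet")),
               config = config, stages = stages)
  jsonlite::write_json(prov, pipe_path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(jsonlite::read_json(pipe_path(outdir, "summary.json")))
}

#' Checksum a run directory
#'
#' MD5 of every file, for determinism checks across reruns.
#'
#' @param outdir run directory.
#' @return named character vector of md5 sums keyed by file name.
#' @export
run_checksums <- function(outdir) {
  files <- sort(list.files(outdir, full.names = TRUE, recursive = TRUE))
  sums <- tools::md5sum(files)
  names(sums) <- basename(names(sums))
  sums
}
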