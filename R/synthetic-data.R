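## Synthetic-data generators.
##
## Every pipeline input can be simulated with known planted truth: an iTRAQ
## quantitation table (one reference channel, three comparison dose groups,
## two technical replicates of a pooled sample each), a GMT annotation set
## with terms enriched in the planted proteins, a scale-free interactome
## carrying a dense module among planted proteins, qPCR Ct tables with
## planted fold changes, and survey-meter dosimetry readings.

GROUPS_HLNRA <- c("II", "III", "IV")

#' Simulate an iTRAQ quantitation table with planted differential proteins
#'
#' Emulates a 4-plex design: one reference pool (reporter 114, dose group I)
#' and three comparison pools (115/116/117, dose groups II-IV), each measured
#' in `n_replicates` technical replicates. Ratios are comparison/reference
#' reporter peak-area ratios. A fraction `de_fraction` of proteins is planted
#' as differentially regulated: their replicate log2 ratios are centred on a
#' true effect drawn from `effect_range_log2` (sign per `up_proportion`),
#' the rest are centred on 0. Noise is Gaussian on the log2 scale, i.e.
#' multiplicative on ratios, matching the error structure of reporter-ion
#' ratios.
#'
#' @param n_proteins number of quantified proteins.
#' @param de_fraction proportion of proteins planted as regulated.
#' @param effect_range_log2 length-2 interval for |true log2 fold change| of
#'   planted proteins; the lower bound must be at least `log2(1.2)` so every
#'   planted effect clears the fold-change calling cutoff.
#' @param replicate_noise_sd technical noise sd on the log2 scale.
#' @param up_proportion proportion of planted proteins that are up-regulated
#'   (the remainder are down-regulated). Default 0.5.
#' @param n_replicates technical replicates per group (default 2).
#' @param groups comparison group labels.
#' @param seed RNG seed; the same seed reproduces the output exactly.
#' @return list with `quant` (data frame: protein_id, group, replicate,
#'   ratio), `truth` (data frame: protein_id, group, true_status,
#'   true_log2fc) and `planted` (planted protein ids).
#' @export
sim_quant <- function(n_proteins, de_fraction = 0.1,
                      effect_range_log2 = c(log2(1.2), 1.5),
                      replicate_noise_sd = 0.1, up_proportion = 0.5,
                      n_replicates = 2L, groups = GROUPS_HLNRA, seed = 1L) {
  n_proteins <- check_count(n_proteins, "n_proteins")
  de_fraction <- check_proportion(de_fraction, "de_fraction")
  up_proportion <- check_proportion(up_proportion, "up_proportion")
  n_replicates <- check_count(n_replicates, "n_replicates")
  stop_if(length(effect_range_log2) != 2L ||
            effect_range_log2[1] > effect_range_log2[2],
          "'effect_range_log2' must be a non-empty interval")
  stop_if(de_fraction > 0 && effect_range_log2[1] < log2(1.2) - 1e-12,
          "lower bound of 'effect_range_log2' must be >= log2(1.2) = %.4f",
          log2(1.2))
  check_positive(replicate_noise_sd + 1, "replicate_noise_sd + 1")  # sd >= 0
  stop_if(replicate_noise_sd < 0, "'replicate_noise_sd' must be >= 0")

  with_seed(seed, {
    ids <- sprintf("P%05d", seq_len(n_proteins))
    n_de <- round(n_proteins * de_fraction)
    planted <- sort(sample(ids, n_de))
    n_up <- round(n_de * up_proportion)
    status_planted <- rep(c("up", "down"), c(n_up, n_de - n_up))
    names(status_planted) <- planted

    truth <- expand.grid(protein_id = ids, group = groups,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    truth$true_status <- "null"
    truth$true_log2fc <- 0
    idx <- truth$protein_id %in% planted
    truth$true_status[idx] <- status_planted[truth$protein_id[idx]]
    mag <- stats::runif(sum(idx), effect_range_log2[1], effect_range_log2[2])
    truth$true_log2fc[idx] <- ifelse(truth$true_status[idx] == "up", mag, -mag)

    quant <- truth[rep(seq_len(nrow(truth)), each = n_replicates),
                   c("protein_id", "group")]
    quant$replicate <- rep(seq_len(n_replicates), nrow(truth))
    log2r <- rep(truth$true_log2fc, each = n_replicates) +
      stats::rnorm(nrow(quant), 0, replicate_noise_sd)
    quant$ratio <- 2^log2r
    rownames(quant) <- NULL
    list(quant = quant, truth = truth, planted = planted)
  })
}

#' Simulate a GMT annotation set with terms enriched in planted proteins
#'
#' `n_enriched` of the `n_terms` terms draw their members with sampling
#' weight `enrichment_odds` on planted proteins (weight 1 elsewhere); the
#' remaining terms draw uniformly from the whole simulated proteome.
#' `enrichment_odds = Inf` forces enriched terms to consist of planted
#' proteins only.
#'
#' @param truth output of [sim_quant()] (uses `truth$protein_id` and
#'   `planted`).
#' @param n_terms number of annotation terms.
#' @param term_size_range length-2 integer interval of term sizes.
#' @param n_enriched number of terms planted as enriched.
#' @param enrichment_odds sampling odds of a planted protein relative to a
#'   background protein within enriched terms.
#' @param seed RNG seed.
#' @return named list of character vectors (term id -> member ids), with a
#'   `"planted_terms"` attribute naming the enriched term ids.
#' @export
sim_annotation <- function(truth, n_terms = 50L, term_size_range = c(10L, 40L),
                           n_enriched = 5L, enrichment_odds = 5,
                           seed = 1L) {
  n_terms <- check_count(n_terms, "n_terms")
  n_enriched <- check_count(n_enriched, "n_enriched", min = 0L)
  stop_if(n_enriched > n_terms, "'n_enriched' must be <= 'n_terms'")
  universe <- unique(truth$truth$protein_id)
  stop_if(term_size_range[2] > length(universe),
          "term size exceeds proteome size (%d)", length(universe))
  planted <- truth$planted
  stop_if(enrichment_odds < 1, "'enrichment_odds' must be >= 1")

  with_seed(seed, {
    sizes <- sample(seq(term_size_range[1], term_size_range[2]), n_terms,
                    replace = TRUE)
    w <- rep(1, length(universe))
    terms <- vector("list", n_terms)
    names(terms) <- sprintf("T%04d", seq_len(n_terms))
    enriched_ids <- names(terms)[seq_len(n_enriched)]
    for (i in seq_len(n_terms)) {
      if (i <= n_enriched && length(planted)) {
        if (is.infinite(enrichment_odds)) {
          sz <- min(sizes[i], length(planted))
          terms[[i]] <- sort(sample(planted, sz))
          next
        }
        wi <- w
        wi[universe %in% planted] <- enrichment_odds
        terms[[i]] <- sort(sample(universe, sizes[i], prob = wi))
      } else {
        terms[[i]] <- sort(sample(universe, sizes[i]))
      }
    }
    attr(terms, "planted_terms") <- enriched_ids
    terms
  })
}

#' Simulate a scale-free interactome with a planted dense module
#'
#' The background is a preferential-attachment (Barabasi-Albert) graph over
#' `n_nodes` proteins of the simulated proteome. A module of
#' `planted_module_size` proteins chosen from the planted differential set
#' receives extra edges until the module's internal edge density reaches
#' `planted_density`. No self-loops, no duplicate unordered pairs.
#'
#' @param truth output of [sim_quant()].
#' @param n_nodes interactome size (<= number of simulated proteins).
#' @param attachment_m edges added per node in the preferential-attachment
#'   background (m = 1 yields a tree).
#' @param planted_module_size module size (0 disables the module).
#' @param planted_density target internal edge density of the module in
#'   (0, 1].
#' @param seed RNG seed.
#' @return list with `edges` (data frame: protein_a, protein_b, source,
#'   evidence) and `module` (module member ids).
#' @export
sim_interactome <- function(truth, n_nodes, attachment_m = 2L,
                            planted_module_size = 0L, planted_density = 0.8,
                            seed = 1L) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2L)
  attachment_m <- check_count(attachment_m, "attachment_m")
  planted_module_size <- check_count(planted_module_size,
                                     "planted_module_size", min = 0L)
  stop_if(planted_density <= 0 || planted_density > 1,
          "'planted_density' must be in (0, 1]")
  universe <- unique(truth$truth$protein_id)
  stop_if(n_nodes > length(universe),
          "'n_nodes' exceeds the simulated proteome")

  with_seed(seed, {
    nodes <- if (n_nodes == length(universe)) universe else
      sort(sample(universe, n_nodes))
    planted_in <- intersect(truth$planted, nodes)
    stop_if(planted_module_size > length(planted_in),
            "'planted_module_size' (%d) exceeds planted proteins in the interactome (%d)",
            planted_module_size, length(planted_in))
    ## shuffle id assignment so protein index carries no degree information
    node_order <- sample(nodes)
    g <- igraph::sample_pa(n_nodes, m = attachment_m, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- cbind(node_order[el[, 1]], node_order[el[, 2]])

    module <- character(0)
    if (planted_module_size >= 2) {
      module <- sort(sample(planted_in, planted_module_size))
      pairs <- t(utils::combn(module, 2))
      n_target <- ceiling(planted_density * nrow(pairs))
      keep <- sample(nrow(pairs), n_target)
      edges <- rbind(edges, pairs[keep, , drop = FALSE])
    }

    a <- pmin(edges[, 1], edges[, 2])
    b <- pmax(edges[, 1], edges[, 2])
    ok <- a != b & !duplicated(paste(a, b, sep = "\r"))
    sources <- c("HPRD", "IntAct", "MINT", "CORUM", "PhosphoSitePlus")
    evidences <- c("physical", "physical", "physical", "complex",
                   "kinase-substrate")
    src_i <- sample(length(sources), sum(ok), replace = TRUE)
    out <- data.frame(protein_a = a[ok], protein_b = b[ok],
                      source = sources[src_i], evidence = evidences[src_i],
                      stringsAsFactors = FALSE)
    list(edges = out, module = module)
  })
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Each gene gets a fixed baseline Ct; in non-calibrator groups the target
#' genes' Ct is shifted by minus the planted log2 fold change (one PCR cycle
#' per doubling), reference genes stay flat. Gaussian cycle noise is added
#' per well.
#'
#' @param genes target gene ids.
#' @param ref_genes reference (housekeeping) gene ids; must not overlap
#'   `genes` and must have planted fold change 0.
#' @param planted_log2fc named numeric vector of per-target log2 fold
#'   changes (unnamed scalar is recycled to all targets).
#' @param n_per_group samples per group.
#' @param ct_noise_sd per-well Ct noise sd in cycles.
#' @param groups group labels; the first is the calibrator.
#' @param seed RNG seed.
#' @return data frame: sample, group, gene, ct.
#' @export
sim_ct <- function(genes, ref_genes = c("ACTB", "GAPDH"), planted_log2fc = 0,
                   n_per_group = 5L, ct_noise_sd = 0.2,
                   groups = c("I", "II", "III"), seed = 1L) {
  stop_if(length(intersect(genes, ref_genes)) > 0,
          "target and reference gene ids overlap: %s",
          paste(intersect(genes, ref_genes), collapse = ", "))
  n_per_group <- check_count(n_per_group, "n_per_group")
  stop_if(ct_noise_sd < 0, "'ct_noise_sd' must be >= 0")
  if (is.null(names(planted_log2fc))) {
    stop_if(length(planted_log2fc) != 1L,
            "'planted_log2fc' must be named or a scalar")
    planted_log2fc <- stats::setNames(rep(planted_log2fc, length(genes)),
                                      genes)
  }
  stop_if(!all(genes %in% names(planted_log2fc)),
          "'planted_log2fc' missing entries for some target genes")

  with_seed(seed, {
    all_genes <- c(genes, ref_genes)
    base_ct <- stats::setNames(stats::runif(length(all_genes), 18, 28),
                               all_genes)
    out <- expand.grid(idx = seq_len(n_per_group), group = groups,
                       gene = all_genes, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
    out$sample <- sprintf("S_%s_%02d", out$group, out$idx)
    shift <- ifelse(out$gene %in% genes & out$group != groups[1],
                    -planted_log2fc[out$gene], 0)
    shift[is.na(shift)] <- 0
    out$ct <- base_ct[out$gene] + shift +
      stats::rnorm(nrow(out), 0, ct_noise_sd)
    out[order(out$sample, out$gene), c("sample", "group", "gene", "ct")]
  })
}

#' Simulate survey-meter dosimetry readings
#'
#' Indoor and outdoor exposure rates are each reported as the mean of three
#' simulated readings drawn uniformly from `rate_range_uR_per_h`, mirroring
#' field survey practice of averaging three instrument readings per
#' location.
#'
#' @param n_subjects number of subjects (0 gives an empty table).
#' @param rate_range_uR_per_h length-2 interval of exposure rates in
#'   micro-roentgen per hour; a degenerate interval fixes every reading.
#' @param occupancy_indoor indoor occupancy fraction applied to every
#'   subject.
#' @param seed RNG seed.
#' @return data frame: subject, indoor_rate, outdoor_rate, occupancy_indoor.
#' @export
sim_dosimetry <- function(n_subjects, rate_range_uR_per_h = c(10, 300),
                          occupancy_indoor = 0.8, seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects", min = 0L)
  occupancy_indoor <- check_proportion(occupancy_indoor, "occupancy_indoor")
  stop_if(any(rate_range_uR_per_h <= 0), "exposure rates must be positive")
  stop_if(rate_range_uR_per_h[1] > rate_range_uR_per_h[2],
          "'rate_range_uR_per_h' must be a valid interval")

  with_seed(seed, {
    mean3 <- function(n) {
      r <- matrix(stats::runif(3 * n, rate_range_uR_per_h[1],
                               rate_range_uR_per_h[2]), nrow = 3)
      colMeans(r)
    }
    data.frame(subject = sprintf("SUBJ%03d", seq_len(n_subjects)),
               indoor_rate = mean3(n_subjects),
               outdoor_rate = mean3(n_subjects),
               occupancy_indoor = rep(occupancy_indoor, n_subjects),
               stringsAsFactors = FALSE)
  })
}
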