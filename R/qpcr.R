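## Relative qPCR quantification with the dual-reference 2^-ddCt method:
## per-sample dCt = target Ct - mean(reference Cts); ddCt = dCt - mean dCt
## of the calibrator group; fold change = 2^-ddCt. Reference-gene stability
## is validated first; groups are compared to the calibrator with a
## two-sample Student's t-test and summarised as mean +/- SEM.

check_ct_table <- function(ct_table) {
  need <- c("sample", "group", "gene", "ct")
  stop_if(!all(need %in% names(ct_table)),
          "Ct table must have columns: %s", paste(need, collapse = ", "))
  stop_if(any(!is.finite(ct_table$ct)) || any(ct_table$ct <= 0),
          "Ct values must be finite and > 0")
  stop_if(anyDuplicated(paste(ct_table$sample, ct_table$gene)) > 0,
          "(sample, gene) must be unique")
  ct_table
}

#' Validate reference-gene stability
#'
#' Reports the spread of each reference gene's Ct across all samples (sd
#' and CV) with a pass/fail flag at a configurable sd threshold. A failing
#' reference gene yields a warning, not an error, so the analyst decides.
#'
#' @param ct_table data frame: sample, group, gene, ct.
#' @param ref_genes reference gene ids; each needs >= 3 samples.
#' @param sd_threshold maximum acceptable Ct sd in cycles (default 1).
#' @return data frame: gene, n, mean_ct, sd_ct, cv_percent, pass.
#' @export
reference_stability <- function(ct_table, ref_genes, sd_threshold = 1) {
  check_ct_table(ct_table)
  miss <- setdiff(ref_genes, ct_table$gene)
  stop_if(length(miss) > 0, "reference gene(s) missing from Ct table: %s",
          paste(miss, collapse = ", "))
  out <- do.call(rbind, lapply(ref_genes, function(g) {
    ct <- ct_table$ct[ct_table$gene == g]
    stop_if(length(ct) < 3L,
            "reference gene '%s' has fewer than 3 samples", g)
    data.frame(gene = g, n = length(ct), mean_ct = mean(ct),
               sd_ct = stats::sd(ct),
               cv_percent = 100 * stats::sd(ct) / mean(ct),
               pass = stats::sd(ct) <= sd_threshold,
               stringsAsFactors = FALSE)
  }))
  if (any(!out$pass))
    warning("unstable reference gene(s): ",
            paste(out$gene[!out$pass], collapse = ", "))
  out
}

#' Per-sample relative expression by 2^-ddCt
#'
#' The target Ct is normalised to the arithmetic mean Ct of the reference
#' genes (equivalent to the geometric mean of their linear quantities),
#' then to the calibrator group's mean dCt; amplification efficiency is
#' assumed to be 2 per the standard 2^-ddCt model. Samples missing the
#' target or any reference gene are excluded with a message. By
#' construction the calibrator group's fold changes average 1 on the log
#' scale (geometric mean exactly 1).
#'
#' @param ct_table data frame: sample, group, gene, ct.
#' @param target target gene id.
#' @param ref_genes reference gene ids.
#' @param calibrator_group group used as calibrator (default `"I"`).
#' @return data frame: sample, group, delta_ct, ddct, fold.
#' @export
ddct <- function(ct_table, target, ref_genes, calibrator_group = "I") {
  check_ct_table(ct_table)
  stop_if(!target %in% ct_table$gene, "target '%s' missing from Ct table",
          target)
  stop_if(!calibrator_group %in% ct_table$group,
          "calibrator group '%s' missing from Ct table", calibrator_group)
  stop_if(target %in% ref_genes, "target cannot be a reference gene")

  samples <- unique(ct_table$sample)
  rows <- lapply(samples, function(s) {
    st <- ct_table[ct_table$sample == s, ]
    tgt <- st$ct[st$gene == target]
    refs <- st$ct[match(ref_genes, st$gene)]
    if (length(tgt) != 1L || any(is.na(refs))) {
      message("sample '", s, "' excluded: missing target or reference Ct")
      return(NULL)
    }
    data.frame(sample = s, group = st$group[1],
               delta_ct = tgt - mean(refs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  stop_if(is.null(out), "no sample has complete target + reference Cts")
  cal <- out$delta_ct[out$group == calibrator_group]
  stop_if(length(cal) == 0L, "no usable calibrator-group samples")
  out$ddct <- out$delta_ct - mean(cal)
  out$fold <- 2^(-out$ddct)
  rownames(out) <- NULL
  out
}

#' Compare per-group relative expression to the calibrator
#'
#' Mean, SEM and a two-sided two-sample Student's t-test of each group's
#' fold changes against the calibrator group's. Degenerate comparisons
#' (zero variance in both groups) give p = 1 when the means are equal and
#' are otherwise flagged with `p = NA`.
#'
#' @param folds output of [ddct()] (needs group and fold columns).
#' @param calibrator_group calibrator group label.
#' @param alpha significance threshold for the `significant` flag.
#' @return data frame: group, n, mean_fold, sem, p, significant.
#' @export
group_compare <- function(folds, calibrator_group = "I", alpha = 0.05) {
  stop_if(!all(c("group", "fold") %in% names(folds)),
          "'folds' needs columns group and fold")
  cal <- folds$fold[folds$group == calibrator_group]
  stop_if(length(cal) < 2L, "calibrator group needs >= 2 samples")
  groups <- unique(folds$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    x <- folds$fold[folds$group == g]
    stop_if(length(x) < 2L, "group '%s' has a single sample; SEM undefined",
            g)
    p <- if (g == calibrator_group) NA_real_
    else if (stats::sd(x) == 0 && stats::sd(cal) == 0) {
      if (mean(x) == mean(cal)) 1 else {
        warning("zero-variance comparison for group '", g,
                "' with unequal means; p undefined")
        NA_real_
      }
    } else stats::t.test(x, cal)$p.value
    data.frame(group = g, n = length(x), mean_fold = mean(x),
               sem = stats::sd(x) / sqrt(length(x)), p = p,
               significant = !is.na(p) & p <= alpha,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Full qPCR analysis for a panel of target genes
#'
#' Runs [reference_stability()], then [ddct()] and [group_compare()] per
#' target gene; the per-group rows double as bar-plot data (mean +/- SEM
#' per gene and group).
#'
#' @param ct_table data frame: sample, group, gene, ct.
#' @param targets target gene ids.
#' @param ref_genes reference gene ids.
#' @param calibrator_group calibrator group label.
#' @param alpha significance threshold.
#' @return list with `stability` and `results` (gene, group, n, mean_fold,
#'   sem, p, significant).
#' @export
qpcr_analysis <- function(ct_table, targets, ref_genes = c("ACTB", "GAPDH"),
                          calibrator_group = "I", alpha = 0.05) {
  stability <- reference_stability(ct_table, ref_genes)
  res <- do.call(rbind, lapply(targets, function(tg) {
    gc <- group_compare(ddct(ct_table, tg, ref_genes, calibrator_group),
                        calibrator_group, alpha)
    cbind(gene = tg, gc, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  list(stability = stability, results = res)
}
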