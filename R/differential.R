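## Differential-protein calling from iTRAQ reporter-ion ratios.
##
## Each comparison group (II, III, IV) carries one pooled sample measured in
## two technical replicates; ratios are relative to the reference channel
## (group I). The calling scheme: impute the mean of the two replicate
## ratios as a third value, test the log2-transformed triple against 0 with
## a one-sample Student's t-test (df = 2), adjust per group with
## Benjamini-Hochberg, and call a protein up if fold change >= 1.2, down if
## <= 0.83, both gated at adjusted P <= 0.1.

#' Impute the third technical replicate
#'
#' Completes a duplicate measurement to a triple by appending the arithmetic
#' mean of the two replicate ratios (the mean fold change serves as the
#' missing third value).
#'
#' @param r1,r2 replicate ratios, both > 0.
#' @return numeric vector `c(r1, r2, mean(r1, r2))`.
#' @export
impute_triplicate <- function(r1, r2) {
  check_positive(r1, "r1")
  check_positive(r2, "r2")
  stop_if(length(r1) != 1L || length(r2) != 1L,
          "'r1' and 'r2' must be scalars")
  c(r1, r2, (r1 + r2) / 2)
}

#' One-sample t-test of a ratio triple against no change
#'
#' Tests the log2-transformed triple against 0 (equivalently, the ratios
#' against 1) with a two-sided one-sample Student's t-test on 2 degrees of
#' freedom. A zero-variance triple (identical replicates) is degenerate and
#' returns `NA` rather than an artificially extreme p-value.
#'
#' @param triple positive ratios from [impute_triplicate()].
#' @return two-sided p-value, or `NA_real_` for a degenerate triple.
#' @export
protein_t_test <- function(triple) {
  check_positive(triple, "triple")
  x <- log2(triple)
  if (stats::sd(x) < .Machine$double.eps^0.5) return(NA_real_)
  stats::t.test(x, mu = 0)$p.value
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the values against a normal distribution with the
#' sample mean and sd. Reported as per-group QC for the log2 ratio
#' distribution; it does not gate differential calls.
#'
#' @param values numeric vector, at least 3 finite values with positive sd.
#' @return list with `statistic` and `p`.
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  stop_if(length(values) < 3L, "need at least 3 finite values")
  s <- stats::sd(values)
  stop_if(s == 0, "degenerate input: zero standard deviation")
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean = mean(values), sd = s))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, returned in input order. `NA`
#' entries (untestable proteins) are left `NA` and excluded from the number
#' of tests.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  stop_if(any(p_values[ok] < 0 | p_values[ok] > 1),
          "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Classify a protein's modulation status
#'
#' @param fold_change mean replicate ratio (comparison/reference).
#' @param p_adj BH-adjusted p-value (`NA` = untestable, never called).
#' @param fc_up,fc_down,alpha calling thresholds: up if
#'   `fold_change >= fc_up`, down if `fold_change <= fc_down`, both gated at
#'   `p_adj <= alpha`.
#' @return character vector in `{"up", "down", "unchanged"}` (vectorised).
#' @export
classify_modulation <- function(fold_change, p_adj, fc_up = 1.2,
                                fc_down = 0.83, alpha = 0.1) {
  stop_if(any(!is.finite(fold_change)) || any(fold_change <= 0),
          "'fold_change' must be positive and finite")
  stop_if(fc_down >= 1 || fc_up <= 1, "need fc_down < 1 < fc_up")
  sig <- !is.na(p_adj) & p_adj <= alpha
  ifelse(sig & fold_change >= fc_up, "up",
         ifelse(sig & fold_change <= fc_down, "down", "unchanged"))
}

#' Percentage coefficient of variation of technical replicates
#'
#' `100 * sd / mean` over the measured replicate ratios. Computed on the
#' real replicates only: including the imputed third value would deflate
#' the CV.
#'
#' @param replicates at least two positive ratios.
#' @return CV in percent.
#' @export
percent_cv <- function(replicates) {
  check_positive(replicates, "replicates")
  stop_if(length(replicates) < 2L, "need at least 2 replicate values")
  100 * stats::sd(replicates) / mean(replicates)
}

#' Call differentially regulated proteins per dose group
#'
#' Runs the full per-protein scheme on a long quantitation table: for every
#' protein x group with a complete replicate pair, impute the third value,
#' t-test the log2 triple, BH-adjust within the group, compute %CV on the
#' real replicates, and classify against the fold-change and adjusted-P
#' cutoffs. Proteins with missing replicates in a group are excluded from
#' that group's testing and listed in the QC table.
#'
#' @param quant data frame with columns protein_id, group, replicate, ratio.
#' @param fc_up,fc_down,alpha calling thresholds (see
#'   [classify_modulation()]).
#' @param n_replicates required replicates per protein x group.
#' @return list with `calls` (protein_id, group, fold_change, log2_fc,
#'   p_raw, p_adj, cv_percent, status, testable), `qc_excluded` (rows
#'   lacking a complete replicate set) and `normality` (per-group KS check
#'   of the log2 fold changes).
#' @export
call_differential <- function(quant, fc_up = 1.2, fc_down = 0.83,
                              alpha = 0.1, n_replicates = 2L) {
  need <- c("protein_id", "group", "replicate", "ratio")
  stop_if(!all(need %in% names(quant)),
          "quant table must have columns: %s", paste(need, collapse = ", "))
  check_positive(quant$ratio, "ratio")
  key <- paste(quant$protein_id, quant$group, quant$replicate)
  stop_if(anyDuplicated(key) > 0,
          "(protein_id, group, replicate) must be unique")

  res <- list()
  qc <- list()
  norm <- list()
  for (g in unique(quant$group)) {
    qg <- quant[quant$group == g, ]
    cnt <- table(qg$protein_id)
    complete <- names(cnt)[cnt == n_replicates]
    excl <- setdiff(names(cnt), complete)
    if (length(excl)) {
      qc[[g]] <- data.frame(protein_id = excl, group = g,
                            n_replicates = as.integer(cnt[excl]),
                            stringsAsFactors = FALSE)
    }
    qg <- qg[qg$protein_id %in% complete, ]
    qg <- qg[order(qg$protein_id, qg$replicate), ]
    m <- matrix(qg$ratio, ncol = n_replicates, byrow = TRUE)
    ids <- unique(qg$protein_id)

    fc <- rowMeans(m)
    triples <- cbind(m, rowMeans(m))
    lg <- log2(triples)
    mu <- rowMeans(lg)
    s <- apply(lg, 1, stats::sd)
    testable <- s >= .Machine$double.eps^0.5
    tstat <- ifelse(testable, mu / (s / sqrt(ncol(lg))), NA_real_)
    p_raw <- 2 * stats::pt(abs(tstat), df = ncol(lg) - 1, lower.tail = FALSE)
    p_adj <- bh_adjust(p_raw)
    cv <- apply(m, 1, percent_cv)

    res[[g]] <- data.frame(
      protein_id = ids, group = g, fold_change = fc, log2_fc = log2(fc),
      p_raw = p_raw, p_adj = p_adj, cv_percent = cv,
      status = classify_modulation(fc, p_adj, fc_up, fc_down, alpha),
      testable = testable, stringsAsFactors = FALSE)
    if (length(ids) >= 3 && stats::sd(log2(fc)) > 0) {
      kt <- ks_normality(log2(fc))
      norm[[g]] <- data.frame(group = g, ks_statistic = kt$statistic,
                              ks_p = kt$p, stringsAsFactors = FALSE)
    }
  }
  list(calls = do.call(rbind, c(res, list(make.row.names = FALSE))),
       qc_excluded = if (length(qc))
         do.call(rbind, c(qc, list(make.row.names = FALSE))) else
           data.frame(protein_id = character(0), group = character(0),
                      n_replicates = integer(0)),
       normality = if (length(norm))
         do.call(rbind, c(norm, list(make.row.names = FALSE))) else NULL)
}

#' Volcano-plot coordinates from a differential call table
#'
#' @param calls `calls` component of [call_differential()].
#' @return data frame: protein_id, group, log2_fc, neg_log10_p_adj, status.
#' @export
volcano_table <- function(calls) {
  data.frame(protein_id = calls$protein_id, group = calls$group,
             log2_fc = calls$log2_fc,
             neg_log10_p_adj = -log10(calls$p_adj),
             status = calls$status, stringsAsFactors = FALSE)
}

#' Venn partition of differential protein sets
#'
#' Exact region counts of the Venn diagram over the given sets (7 regions
#' for 3 groups). Region names join the member group labels with "&".
#'
#' @param diff_sets named list of protein id vectors, one per group.
#' @return named integer vector of region counts; the counts sum to the
#'   size of the union.
#' @export
venn_partition <- function(diff_sets) {
  stop_if(is.null(names(diff_sets)) || anyDuplicated(names(diff_sets)) > 0,
          "'diff_sets' must be a named list with distinct names")
  gs <- names(diff_sets)
  univ <- unique(unlist(diff_sets, use.names = FALSE))
  member <- vapply(diff_sets, function(s) univ %in% s,
                   logical(length(univ)))
  if (length(univ) == 1L) member <- matrix(member, nrow = 1,
                                           dimnames = list(NULL, gs))
  combos <- unlist(lapply(seq_along(gs), function(k)
    utils::combn(gs, k, simplify = FALSE)), recursive = FALSE)
  out <- stats::setNames(integer(length(combos)),
                         vapply(combos, paste, "", collapse = "&"))
  if (length(univ)) {
    pattern <- apply(member, 1, function(r) paste(gs[r], collapse = "&"))
    tab <- table(pattern)
    out[names(tab)] <- as.integer(tab)
  }
  out
}
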