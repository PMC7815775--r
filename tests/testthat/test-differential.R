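test_that("third-replicate imputation appends the arithmetic mean ratio", {
  expect_equal(impute_triplicate(1.2, 1.8), c(1.2, 1.8, 1.5))
  expect_equal(impute_triplicate(1, 1), c(1, 1, 1))
  expect_equal(impute_triplicate(0.5, 1.5), c(0.5, 1.5, 1.0))
  expect_error(impute_triplicate(-1, 2), "positive")
  expect_error(impute_triplicate(0, 2), "positive")
})

test_that("ratio-triple t-test matches a hand computation on log2 values", {
  triple <- impute_triplicate(1.2, 1.8)
  x <- log2(triple)
  tstat <- mean(x) / (sd(x) / sqrt(3))
  expect_equal(tstat, 3.3422, tolerance = 1e-4)  # frozen hand value
  expect_equal(protein_t_test(triple), 2 * pt(-abs(tstat), df = 2))

  ## zero-variance triples are degenerate, never p = 0
  expect_true(is.na(protein_t_test(c(1, 1, 1))))
  expect_true(is.na(protein_t_test(impute_triplicate(1.4, 1.4))))
  expect_error(protein_t_test(c(1, -1, 1)), "positive")
})

test_that("KS normality check flags gross non-normality only", {
  set.seed(42)
  reruns <- replicate(100, ks_normality(rnorm(1000))$p)
  expect_gte(mean(reruns > 0.05), 0.95)

  two_point <- rep(c(-1, 1), 500)
  expect_lt(ks_normality(two_point)$p, 1e-3)
  expect_error(ks_normality(rep(2, 10)), "degenerate")
  expect_error(ks_normality(c(1, 2)), "3 finite values")
})

test_that("BH adjustment matches the brute-force oracle", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(2:200, 1))
    expect_equal(bh_adjust(p), bh_brute(p))
  }
  ## monotone in the raw p's and never below them
  p <- runif(100)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("modulation calling applies fold-change and adjusted-P gates", {
  expect_equal(classify_modulation(1.25, 0.05), "up")
  expect_equal(classify_modulation(1.25, 0.20), "unchanged")
  expect_equal(classify_modulation(0.80, 0.01), "down")
  expect_equal(classify_modulation(1.2, 0.1), "up")    # inclusive cutoffs
  expect_equal(classify_modulation(0.83, 0.1), "down")
  expect_equal(classify_modulation(1.1, 1e-9), "unchanged")
  expect_equal(classify_modulation(2, NA_real_), "unchanged")

  ## monotone: raising p_adj never creates a call
  set.seed(1)
  fc <- exp(rnorm(200, 0, 0.5))
  p1 <- runif(200)
  p2 <- pmin(1, p1 + runif(200, 0, 0.5))
  s1 <- classify_modulation(fc, p1)
  s2 <- classify_modulation(fc, p2)
  expect_true(all(!(s1 == "unchanged" & s2 != "unchanged")))
})

test_that("percent CV is scale invariant and uses the sample sd", {
  expect_equal(percent_cv(c(10, 10)), 0)
  expect_equal(percent_cv(c(8, 12)), 100 * (4 / sqrt(2)) / 10)
  expect_equal(round(percent_cv(c(8, 12)), 2), 28.28)
  expect_equal(percent_cv(c(1.2, 1.8)), percent_cv(c(8, 12)))
  expect_error(percent_cv(5), "2 replicate")
})

test_that("whole-table differential calling recovers planted signals", {
  sq <- sim_quant(400, de_fraction = 0.1, effect_range_log2 = c(1, 1.5),
                  replicate_noise_sd = 0.1, seed = 21)
  dd <- call_differential(sq$quant)
  expect_setequal(names(dd), c("calls", "qc_excluded", "normality"))
  calls <- dd$calls
  expect_equal(nrow(calls), 400 * 3)
  expect_true(all(calls$p_adj >= calls$p_raw, na.rm = TRUE))
  expect_true(all(calls$p_adj <= 1, na.rm = TRUE))
  expect_equal(calls$log2_fc, log2(calls$fold_change))
  ## every up call satisfies the published thresholds
  up <- calls[calls$status == "up", ]
  expect_true(all(up$fold_change >= 1.2 & up$p_adj <= 0.1))
  dn <- calls[calls$status == "down", ]
  expect_true(all(dn$fold_change <= 0.83 & dn$p_adj <= 0.1))

  mg <- merge(calls, sq$truth, by = c("protein_id", "group"))
  planted <- mg[mg$true_status != "null", ]
  expect_gte(mean(planted$status == planted$true_status), 0.95)
})

test_that("proteins missing a replicate go to the QC table, not the calls", {
  sq <- sim_quant(50, 0, seed = 2)
  quant <- sq$quant[-1, ]  # drop one replicate of one protein x group
  dd <- call_differential(quant)
  lost <- sq$quant$protein_id[1]
  expect_true(lost %in% dd$qc_excluded$protein_id)
  expect_false(any(dd$calls$protein_id == lost &
                     dd$calls$group == sq$quant$group[1]))
  expect_error(call_differential(rbind(sq$quant, sq$quant[1, ])), "unique")
})

test_that("under the global null the calling scheme controls false positives", {
  ## conservative FDR smoke test: n = 3 with an imputed midpoint is
  ## pseudo-replication, so observed false-call rates sit well below alpha
  fp <- vapply(1:40, function(s) {
    sq <- sim_quant(150, de_fraction = 0, replicate_noise_sd = 0.1,
                    seed = 1000 + s)
    calls <- call_differential(sq$quant)$calls
    mean(calls$status != "unchanged" & abs(calls$log2_fc) >= 0.263)
  }, 0)
  expect_lte(mean(fp), 0.1 + 3 * sd(fp) / sqrt(length(fp)))
})

test_that("Venn partition enumerates regions that sum to the union", {
  v <- venn_partition(list(A = c("1", "2", "3"), B = c("2", "3", "4"),
                           C = "3"))
  expect_equal(unname(v[c("A", "B", "C", "A&B", "A&B&C", "A&C", "B&C")]),
               c(1L, 1L, 0L, 1L, 1L, 0L, 0L))
  expect_equal(sum(v), 4L)  # |union|

  same <- venn_partition(list(X = letters[1:3], Y = letters[1:3],
                              Z = letters[1:3]))
  expect_equal(unname(same["X&Y&Z"]), 3L)
  expect_equal(sum(same), 3L)

  disj <- venn_partition(list(X = "a", Y = "b", Z = "c"))
  expect_equal(unname(disj[c("X", "Y", "Z")]), c(1L, 1L, 1L))
  expect_equal(sum(disj), 3L)

  set.seed(3)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j) sample(letters, sample(0:20, 1)))
    names(sets) <- c("a", "b", "c")
    expect_equal(sum(venn_partition(sets)),
                 length(unique(unlist(sets))))
  }
})

test_that("volcano table mirrors the call table's axes", {
  sq <- sim_quant(50, 0.2, seed = 4)
  calls <- call_differential(sq$quant)$calls
  v <- volcano_table(calls)
  expect_equal(v$log2_fc, calls$log2_fc)
  expect_equal(v$neg_log10_p_adj, -log10(calls$p_adj))
  expect_equal(v$status, calls$status)
})
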