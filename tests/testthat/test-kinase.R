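test_that("localization filter is strict at the 0.75 boundary and idempotent", {
  sites <- data.frame(site_id = paste0("P1:S", 1:4),
                      localization_prob = c(0.76, 0.75, 1.0, 0.2),
                      stringsAsFactors = FALSE)
  kept <- filter_localization(sites)
  expect_identical(kept$site_id, c("P1:S1", "P1:S3"))
  expect_identical(filter_localization(kept), kept)  # idempotence
  all1 <- data.frame(localization_prob = rep(1, 5))
  expect_identical(nrow(filter_localization(all1)), 5L)
  # missing probabilities: dropped with warning by default, keepable
  nas <- data.frame(localization_prob = c(0.9, NA))
  expect_warning(out <- filter_localization(nas), "missing")
  expect_identical(nrow(out), 1L)
  expect_identical(nrow(filter_localization(nas, missing = "keep")), 2L)
  # binomial sanity: uniform probabilities keep ~25%
  set.seed(3)
  u <- data.frame(localization_prob = runif(10000))
  frac <- nrow(filter_localization(u)) / 10000
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(frac - 0.25), 3 * se)
})

test_that("KSEA z-score matches its closed form and responds monotonically", {
  # z = (mean_s - mean_p) * sqrt(m) / sd_p; with mean_s = 1, mean_p = 0,
  # sd_p = 1 and m = 9 substrates the closed form gives z = 3
  expect_equal((1 - 0) * sqrt(9) / 1, 3)
  set.seed(14)
  fc <- c(rep(1, 9), rnorm(991))
  names(fc) <- paste0("P", seq_along(fc), ":S1")
  ks <- data.frame(kinase = "K1", protein = paste0("P", 1:9), site = "S1")
  res <- ksea(fc, ks)
  z_manual <- (mean(fc[1:9]) - mean(fc)) * sqrt(9) / sd(fc)
  expect_equal(res$z, z_manual)
  expect_equal(res$p, 2 * pnorm(-abs(z_manual)))
  expect_identical(res$m, 9L)
  # monotonicity: shifting all substrates up strictly increases z
  fc2 <- fc; fc2[1:9] <- fc2[1:9] + 0.5
  expect_gt(ksea(fc2, ks)$z, res$z)
  # sd_p = 0 is an error; unmatched kinases are omitted
  const <- setNames(rep(1, 10), paste0("P", 1:10, ":S1"))
  expect_error(ksea(const, ks), "SD")
  ks2 <- rbind(ks, data.frame(kinase = "K2", protein = "NOPE",
                              site = "S999"))
  expect_false("K2" %in% ksea(fc, ks2)$kinase)
})

test_that("KSEA null calibration: background-drawn substrates give z ~ N(0,1)", {
  set.seed(101)
  n_sites <- 3000
  fc <- rnorm(n_sites, 0, 0.7)
  names(fc) <- paste0("P", seq_len(n_sites), ":S1")
  zs <- replicate(300, {
    subs <- sample(names(fc), 10)
    (mean(fc[subs]) - mean(fc)) * sqrt(10) / sd(fc)
  })
  expect_lt(abs(mean(zs)), 0.2)
  expect_gt(sd(zs), 0.85); expect_lt(sd(zs), 1.15)
})

test_that("active flag needs FDR < 0.05 AND more than five substrates", {
  set.seed(21)
  fc <- rnorm(2000, 0, 0.5)
  names(fc) <- paste0("P", 1:2000, ":S1")
  fc[1:10] <- fc[1:10] + 1.5    # strong kinase with 10 substrates
  fc[11:15] <- fc[11:15] + 3    # even stronger but only 5 substrates
  ks <- rbind(
    data.frame(kinase = "BIG", protein = paste0("P", 1:10), site = "S1"),
    data.frame(kinase = "FEW", protein = paste0("P", 11:15), site = "S1"),
    data.frame(kinase = "NULL1", protein = paste0("P", 16:25),
               site = "S1"))
  res <- ksea(fc, ks)
  expect_true(res$active[res$kinase == "BIG"])
  expect_false(res$active[res$kinase == "FEW"])   # m = 5 is not > 5
  expect_true(res$fdr[res$kinase == "FEW"] < 0.05)
  expect_equal(res$fdr, p.adjust(res$p, "BH"))
})

driver_fixture <- function(driver_fold = 2, cv = 0.1, n_lines = 6,
                           n_reps = 3, n_feat = 10, seed = 1,
                           plant = TRUE) {
  set.seed(seed)
  lines <- sprintf("L%02d", seq_len(n_lines))
  meta <- data.frame(
    sample = paste0(rep(lines, each = n_reps), "_r", seq_len(n_reps)),
    cell_line = rep(lines, each = n_reps),
    replicate = paste0("r", seq_len(n_reps)), lineage = "x",
    stringsAsFactors = FALSE)
  mk <- function() {
    base <- matrix(1000, n_feat, nrow(meta),
                   dimnames = list(sprintf("P%02d", seq_len(n_feat)),
                                   meta$sample))
    noise <- matrix(rnorm(length(base), 0, cv), n_feat, nrow(meta))
    lin <- base * exp(noise)
    if (plant) lin["P01", meta$cell_line == "L01"] <-
        lin["P01", meta$cell_line == "L01"] * driver_fold
    m <- abundance_matrix(lin, meta, "raw")
    log2p1_median_normalize(impute_global_min(m))
  }
  list(protein = mk(), phospho = mk())
}

test_that("driver screen arithmetic: fold and replicate-floor clauses", {
  # top mean 3.1 vs best other 2.0 (linear) -> 1.55-fold passes clause (a);
  # replicate floor: top reps (10,4) vs other max 9 -> 4 > 4.5 fails (b)
  expect_gt(3.1 / 2.0, 1.5)
  expect_false(4 > 0.5 * 9)
  lines <- c("A", "B")
  meta <- data.frame(sample = c("A_r1", "A_r2", "B_r1", "B_r2"),
                     cell_line = rep(lines, each = 2),
                     replicate = c("r1", "r2", "r1", "r2"), lineage = "x",
                     stringsAsFactors = FALSE)
  mk <- function(v) abundance_matrix(log2(v + 1), meta, "log2p1")
  # top reps (10, 4): floor fails against the other lines' max of 9
  prot <- mk(matrix(c(10, 4, 9, 1), 1, 4,
                    dimnames = list("P1", meta$sample)))
  expect_identical(nrow(screen_driver_kinases(prot, prot, fold = 1.3)), 0L)
  # top reps (10, 4.6): 4.6 > 4.5 passes the cross-line floor but fails
  # the within-line reading (4.6 < 0.5 * 10)
  prot2 <- mk(matrix(c(10, 4.6, 9, 1), 1, 4,
                     dimnames = list("P1", meta$sample)))
  hits <- screen_driver_kinases(prot2, prot2, fold = 1.3)
  expect_identical(hits$cell_line, "A")
  expect_equal(hits$protein_fold, 7.3 / 5)
  expect_identical(
    nrow(screen_driver_kinases(prot2, prot2, fold = 1.3,
                               floor_within = TRUE)), 0L)
})

test_that("driver screen recovers a planted dual-level driver and stays silent under the null", {
  fx <- driver_fixture(seed = 7)
  hits <- screen_driver_kinases(fx$protein, fx$phospho)
  expect_identical(hits$feature, "P01")
  expect_identical(hits$cell_line, "L01")
  expect_gt(hits$protein_fold, 1.5)
  # null: exchangeable lines, no hits expected
  n_hits <- sum(vapply(1:20, function(s) {
    fx0 <- driver_fixture(seed = 100 + s, plant = FALSE)
    nrow(screen_driver_kinases(fx0$protein, fx0$phospho))
  }, numeric(1)))
  expect_identical(n_hits, 0)
})

test_that("phospho-protein correlation bins and protein adjustment behave", {
  lines <- paste0("L", 1:8)
  meta <- data.frame(sample = lines, cell_line = lines,
                     replicate = "mean", lineage = "x",
                     stringsAsFactors = FALSE)
  prot <- matrix(c(1:8, 8:1), 2, 8, byrow = TRUE,
                 dimnames = list(c("P1", "P2"), lines))
  phos <- rbind("P1:S5" = 1:8,         # identical ranks -> r = 1
                "P2:T9" = 1:8,         # against 8:1 -> r = -1
                "P3:Y2" = 1:8)         # parent protein unmeasured
  colnames(phos) <- lines
  pm <- abundance_matrix(prot, meta, "collapsed")
  hm <- abundance_matrix(phos, meta, "collapsed")
  expect_message(res <- phospho_protein_correlation(hm, pm), NA)
  expect_equal(res$r[res$site == "P1:S5"], 1)
  expect_identical(res$bin[res$site == "P1:S5"], "strong")
  expect_equal(res$r[res$site == "P2:T9"], -1)
  expect_identical(res$bin[res$site == "P2:T9"], "none")
  expect_false("P3:Y2" %in% res$site)
  # adjustment subtracts the parent protein element-wise
  expect_message(adj <- adjust_phospho_by_protein(hm, pm), "dropped")
  expect_equal(unname(adj$values["P1:S5", ]), (1:8) - (1:8))
  expect_equal(unname(adj$values["P2:T9", ]), (1:8) - (8:1))
  # constant parent: adjustment preserves Spearman with any covariate
  prot2 <- prot; prot2["P2", ] <- 5
  pm2 <- abundance_matrix(prot2, meta, "collapsed")
  adj2 <- suppressMessages(adjust_phospho_by_protein(hm, pm2))
  expect_equal(cor(adj2$values["P2:T9", ], 1:8, method = "spearman"),
               cor(phos["P2:T9", ], 1:8, method = "spearman"))
})

test_that("protein-level phospho sums pool sites on the linear scale", {
  meta <- data.frame(sample = c("S1", "S2"), cell_line = c("A", "B"),
                     replicate = "r1", lineage = "x",
                     stringsAsFactors = FALSE)
  v <- rbind("P1:S5" = c(10, NA), "P1:T2" = c(5, NA), "P2:S9" = c(1, 2))
  colnames(v) <- meta$sample
  m <- abundance_matrix(v, meta, "raw")
  s <- sum_phospho_by_protein(m)
  expect_equal(s$values["P1", "S1"], 15)
  expect_true(is.na(s$values["P1", "S2"]))   # no observed site
  expect_equal(unname(s$values["P2", ]), c(1, 2))
})
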