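toy_genotypes <- function(seed = 1, n = 60, m = 200, ...) {
  cfg <- sim_config(seed = seed, n_samples = n, n_markers = m, ...)
  simulate_genotypes(cfg)
}

test_that("PLINK-1 binary files round-trip exactly", {
  gt <- toy_genotypes(seed = 2, n = 37, m = 101, missing_rate = 0.05)
  pre <- file.path(tempdir(), "rt")
  write_plink1(pre, gt$G, gt$map, gt$sample_ids)
  rt <- read_plink1(pre)
  expect_identical(unname(rt$G), unname(gt$G))
  expect_equal(rt$map$pos, gt$map$pos)
  expect_equal(rt$fam$iid, gt$sample_ids)
})

test_that("bed encoding matches the 2-bit specification", {
  # 2 samples x 2 SNPs, hand-encoded: codes 00=2, 10=1, 11=0, 01=missing
  G <- matrix(c(2L, 1L, 0L, NA), 2, 2)
  pre <- file.path(tempdir(), "enc")
  write_plink1(pre, G, data.frame(chr = 1, id = c("s1", "s2"), pos = c(10, 20)),
               c("i1", "i2"))
  raw <- readBin(paste0(pre, ".bed"), "raw", 100)
  expect_identical(raw[1:3], as.raw(c(0x6c, 0x1b, 0x01)))
  # SNP 1: sample1 code 00, sample2 code 10, padding 11 -> 11 11 10 00 = 0xF8
  expect_identical(raw[4], as.raw(0xF8))
  # SNP 2: sample1 code 11, sample2 code 01 -> 11 11 01 11 = 0xF7
  expect_identical(raw[5], as.raw(0xF7))
})

test_that("malformed bed files are rejected", {
  pre <- file.path(tempdir(), "bad")
  gt <- toy_genotypes(seed = 3, n = 10, m = 20)
  write_plink1(pre, gt$G, gt$map, gt$sample_ids)
  raw <- readBin(paste0(pre, ".bed"), "raw", 1e6)
  writeBin(c(as.raw(c(0, 0, 1)), raw[-(1:3)]), paste0(pre, ".bed"))
  expect_error(read_plink1(pre), "magic")
  writeBin(raw[-length(raw)], paste0(pre, ".bed"))
  expect_error(read_plink1(pre), "truncated")
})

test_that("QC removes low call-rate and low-MAF markers by the stated rules", {
  G <- cbind(
    rep(c(0L, 1L, 2L, NA), each = 25),            # call rate 0.75 -> out
    rep(c(0L, 1L), 50),                           # MAF 0.5 -> kept
    c(rep(0L, 96), rep(1L, 4)),                   # MAF 0.02 -> out
    c(rep(0L, 90), rep(1L, 10)),                  # MAF 0.05 -> kept (rule is < 0.05)
    c(rep(0L, 92), rep(1L, 8)))                   # MAF 0.04 -> out
  qc <- qc_filter(G, map = data.frame(chr = 1, id = paste0("m", 1:5),
                                      pos = 1:5))
  expect_equal(qc$map$id, c("m2", "m4"))
  expect_equal(qc$report$n, c(5L, 1L, 2L, 2L))
  # brute-force survivor count on a random matrix
  gt <- toy_genotypes(seed = 4, n = 80, m = 300, missing_rate = 0.03)
  qc2 <- qc_filter(gt$G)
  brute <- sum(sapply(seq_len(ncol(gt$G)), function(j) {
    g <- gt$G[, j]
    cr <- mean(!is.na(g))
    p <- mean(g, na.rm = TRUE) / 2
    cr > 0.95 && min(p, 1 - p) >= 0.05
  }))
  expect_equal(ncol(qc2$G), brute)
  expect_error(qc_filter(matrix(NA_integer_, 10, 2)), "all markers")
})

test_that("LD pruning removes duplicates and enforces the r2 ceiling", {
  set.seed(10)
  base <- matrix(rbinom(50 * 30, 2, 0.4), 50, 30)
  G <- cbind(base[, 1], base[, 1], base[, -1])     # a duplicated marker
  map <- data.frame(chr = 1, id = paste0("m", seq_len(ncol(G))),
                    pos = seq_len(ncol(G)) * 1000)
  pr <- ld_prune(G, map, window = 10, step = 3, r2_max = 0.5)
  expect_true(xor(pr$kept[1], pr$kept[2]))         # exactly one of the pair
  expect_true(pr$kept[1])                          # the earlier one survives
  # independent markers survive
  ind <- matrix(rbinom(200 * 20, 2, 0.5), 200, 20)
  pr2 <- ld_prune(ind, data.frame(chr = 1, id = paste0("i", 1:20),
                                  pos = 1:20), window = 10, step = 5)
  expect_true(all(pr2$kept))
  # post-condition: no surviving within-window pair exceeds the ceiling
  gt <- toy_genotypes(seed = 5, n = 100, m = 100)
  G3 <- cbind(gt$G, gt$G[, 1:10] + matrix(rbinom(1000, 1, 0.05), 100, 10))
  G3 <- pmin(G3, 2L)
  map3 <- data.frame(chr = 1, id = paste0("x", seq_len(ncol(G3))),
                     pos = seq_len(ncol(G3)))
  pr3 <- ld_prune(G3, map3, window = 50, step = 5, r2_max = 0.5)
  kept <- which(pr3$kept)
  # any pair within 45 original positions is guaranteed to have shared a window
  worst <- 0
  for (a in seq_along(kept)) {
    for (b in seq_along(kept)) {
      if (b > a && kept[b] - kept[a] <= 45) {
        r2 <- suppressWarnings(cor(G3[, kept[a]], G3[, kept[b]]))^2
        if (!is.na(r2)) worst <- max(worst, r2)
      }
    }
  }
  expect_lte(worst, 0.5 + 1e-8)
})

test_that("GRM matches hand arithmetic and is PSD", {
  G <- matrix(c(0, 1, 2, 2, 1, 0, 1, 1, 0, 0, 2, 2), 3, 4)
  Zc <- scale(G, center = TRUE, scale = FALSE)
  expect_equal(grm_centered(G), tcrossprod(Zc) / 4, ignore_attr = TRUE)
  # two identical samples: off-diagonal equals diagonal
  G2 <- rbind(c(0, 2, 1), c(0, 2, 1))
  K2 <- grm_centered(G2)
  expect_equal(K2[1, 2], K2[1, 1])
  gt <- toy_genotypes(seed = 6, n = 50, m = 400)
  K <- grm_centered(gt$G)
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_error(grm_centered(gt$G[, 0]), "no markers")
})

test_that("stratification PCs are orthogonal and separate subpopulations", {
  gt <- toy_genotypes(seed = 7, n = 120, m = 800, fst = 0.15)
  W <- stratification_pcs(gt$G, 10)
  expect_equal(ncol(W), 11)
  cp <- crossprod(W[, -1])
  expect_lt(max(abs(cp[upper.tri(cp)])) / max(diag(cp)), 1e-8)
  r <- abs(cor(W[, "PC1"], gt$truth$subpop))
  expect_gt(r, 0.9)
  expect_equal(ncol(stratification_pcs(gt$G, 0)), 1)
  expect_error(stratification_pcs(gt$G, 120), "n_pcs")
})

test_that("null-model lambda tracks the generating variance ratio", {
  gt <- toy_genotypes(seed = 8, n = 150, m = 600, missing_rate = 0)
  K <- grm_centered(gt$G)
  W <- matrix(1, 150, 1)
  # pure-noise phenotype: lambda at the lower boundary region
  set.seed(1)
  nl <- suppressWarnings(lmm_null(rnorm(150), W, K))
  expect_lt(nl$lambda, 0.1)
  # phenotype = breeding values from K: lambda large
  L <- chol(K + 1e-6 * diag(150))
  g <- as.numeric(t(L) %*% rnorm(150))
  nl2 <- suppressWarnings(lmm_null(g + 0.05 * rnorm(150), W, K))
  expect_gt(nl2$lambda, 10)
  # K = I: unidentifiable ratio is pinned with a warning
  expect_warning(lmm_null(rnorm(150), W, diag(150)), "boundary")
})

test_that("Wald scan reduces to OLS as lambda approaches zero", {
  gt <- toy_genotypes(seed = 9, n = 80, m = 60, missing_rate = 0)
  K <- grm_centered(gt$G)
  y <- gt$phenotype
  W <- cbind(1, rnorm(80))
  ee <- eigen(K, symmetric = TRUE)
  null0 <- list(lambda = 1e-14, d = pmax(ee$values, 0), U = ee$vectors,
                ys = as.numeric(crossprod(ee$vectors, y)),
                Ws = crossprod(ee$vectors, W), tau_inv = 1)
  scan <- wald_scan(y, W, gt$G, K, null = null0)
  j <- 13
  lmfit <- summary(lm(y ~ W[, 2] + gt$G[, j]))$coefficients
  expect_equal(scan$beta[j], lmfit[3, 1], tolerance = 1e-8)
  expect_equal(scan$se[j], lmfit[3, 2], tolerance = 1e-8)
  expect_equal(scan$p_wald[j], lmfit[3, 4], tolerance = 1e-8)
})

test_that("monomorphic markers are flagged and p-values are proper", {
  gt <- toy_genotypes(seed = 10, n = 60, m = 40, missing_rate = 0)
  G <- gt$G
  G[, 5] <- 1L   # monomorphic
  scan <- suppressWarnings(wald_scan(gt$phenotype, matrix(1, 60, 1), G,
                                     grm_centered(gt$G)))
  expect_true(is.na(scan$p_wald[5]))
  ok <- scan$p_wald[!is.na(scan$p_wald)]
  expect_true(all(ok > 0 & ok <= 1))
})

test_that("hit tables are internally consistent", {
  res <- data.frame(chr = 1, rs = paste0("m", 1:5), ps = 1:5,
                    n_miss = 0,
                    beta = c(-5.414, -4.382, -4.290, -5.936, -4.530),
                    se = 1, p_wald = c(7e-5, 9e-6, 2e-5, 3e-6, 5e-5))
  hits <- significant_hits(res)
  expect_equal(nrow(hits), 5)
  expect_equal(attr(hits, "mean_abs_beta"), mean(abs(res$beta)))
  expect_equal(hits$rs[1], "m4")       # sorted by p
  expect_equal(sum(hits$genomewide), 2)
  none <- significant_hits(res, suggestive = 1e-10)
  expect_equal(nrow(none), 0)
  expect_true(is.na(attr(none, "mean_abs_beta")))
  all_ <- significant_hits(res, suggestive = 1.0)
  expect_equal(nrow(all_), 5)
})

test_that("candidate-gene windows use closed intervals", {
  hits <- data.frame(chr = "4", rs = "mk", ps = 1000000)
  genes <- data.frame(gene = c("G_in", "G_edge", "G_far", "G_otherchr"),
                      chr = c("4", "4", "4", "5"),
                      start = c(990000, 1500000, 2000000, 990000),
                      end = c(995000, 1600000, 2100000, 995000))
  out <- candidate_genes(hits, genes, flank = 5e5)
  expect_setequal(out$gene, c("G_in", "G_edge"))   # start exactly at ps+flank
  expect_equal(out$distance[out$gene == "G_in"], 5000)
  expect_equal(nrow(candidate_genes(hits, genes[0, ])), 0)
  expect_warning(candidate_genes(hits, genes[4, , drop = FALSE]), "chromosome")
})

test_that("QC, pruning and GRM are invariant to sample order", {
  gt <- toy_genotypes(seed = 11, n = 40, m = 150, missing_rate = 0.02)
  perm <- sample(40)
  qc1 <- qc_filter(gt$G)
  qc2 <- qc_filter(gt$G[perm, ])
  expect_identical(colnames(qc1$G), colnames(qc2$G))
  K1 <- grm_centered(gt$G)
  K2 <- grm_centered(gt$G[perm, ])
  expect_equal(K2, K1[perm, perm], tolerance = 1e-12)
  map <- data.frame(chr = 1, id = colnames(gt$G), pos = seq_len(ncol(gt$G)))
  expect_identical(ld_prune(gt$G, map)$kept, ld_prune(gt$G[perm, ], map)$kept)
})
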