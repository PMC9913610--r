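test_that("one seed fixes the whole dataset bit-exactly", {
  cfg <- sim_config(seed = 42, n_founders = 40, n_generations = 2,
                    cows_per_generation = 60, n_markers = 300, n_samples = 40)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$records, d2$records)
  expect_identical(d1$truth$bv, d2$truth$bv)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$G, g2$G)
  expect_identical(g1$phenotype, g2$phenotype)
})

test_that("pedigree generator produces founders-only or inbred populations", {
  cfg0 <- sim_config(seed = 1, n_generations = 0, n_founders = 30)
  ped0 <- sort_pedigree(simulate_pedigree(cfg0))
  expect_true(all(inbreeding_meuwissen_luo(ped0) == 0))
  cfg <- sim_config(seed = 2, n_founders = 40, n_generations = 5,
                    cows_per_generation = 80, n_sires_per_generation = 3)
  sp <- sort_pedigree(simulate_pedigree(cfg))
  F <- inbreeding_meuwissen_luo(sp)
  last_gen <- grepl("^G5_", sp$animal)
  expect_gt(mean(F[last_gen]), 0)
})

test_that("breeding values reproduce the coefficient covariance", {
  # founders: empirical covariance of coefficients approaches Ka
  cfg <- sim_config(seed = 3, n_founders = 5000, n_generations = 0)
  ped <- sort_pedigree(simulate_pedigree(cfg))
  set.seed(33)
  Ka <- default_ka_true()
  bv <- simulate_breeding_values(ped, Ka)
  emp <- cov(bv)
  se_approx <- sqrt(outer(diag(Ka), diag(Ka)) + Ka^2) / sqrt(5000)
  expect_true(all(abs(emp - Ka) < 3.5 * se_approx))
  # non-inbred full-sib offspring coefficient covariance = 0.5 Ka (Mendelian)
  trio <- sort_pedigree(data.frame(animal = c("s", "d", "c"),
                                   sire = c(NA, NA, "s"), dam = c(NA, NA, "d")))
  set.seed(34)
  dev <- replicate(4000, {
    b <- simulate_breeding_values(trio, Ka)
    b["c", ] - 0.5 * (b["s", ] + b["d", ])
  })
  expect_true(all(abs(cov(t(dev)) - 0.5 * Ka) <
                    3.5 * sqrt(outer(diag(Ka), diag(Ka)) + Ka^2) / sqrt(2 * 4000)))
})

test_that("pedigree-wide coefficient covariance approaches A x Ka", {
  ped <- sort_pedigree(random_pedigree(60, n_founders = 15, seed = 12))
  A <- a_matrix_tabular(ped)
  Ka <- matrix(4)     # scalar case keeps the Monte-Carlo affordable
  set.seed(55)
  B <- replicate(3000, simulate_breeding_values(ped, Ka)[, 1])
  emp <- cov(t(B))
  expect_lt(max(abs(emp - 4 * A)) / 4, 0.25)
  expect_gt(cor(as.numeric(emp), as.numeric(4 * A)), 0.97)
})

test_that("record generator matches the declared variance structure", {
  cfg <- sim_config(seed = 6, n_founders = 100, n_generations = 3,
                    cows_per_generation = 400,
                    Ka_true = matrix(91.82), sigma_p2_true = 105.55,
                    sigma_hys2_true = 27.38, sigma_e2_true = rep(79.52, 6),
                    cn_effect = rep(0, 9), fc_slope = 0)
  dat <- simulate_dataset(cfg)
  # total phenotypic variance of first records ~ sum of components = 304.27
  v <- var(dat$records$Re)
  expect_gt(v, 304.27 * 0.8)
  expect_lt(v, 304.27 * 1.25)
  expect_equal(dat$records$res_class, pmin(dat$records$Cn, 6L))
  expect_true(all(dat$records$Cn >= 1 & dat$records$Cn <= 9))
  # capped generation stays within (0, 100]
  cap <- simulate_dataset(cfg, cap = TRUE)
  expect_lte(max(cap$records$Re), 100)
  # constant records when every source of variation is silenced
  cfg0 <- sim_config(seed = 7, n_founders = 40, n_generations = 2,
                     cows_per_generation = 50,
                     Ka_true = matrix(1e-12), sigma_p2_true = 1e-12,
                     sigma_hys2_true = 1e-12, sigma_e2_true = rep(1e-12, 6),
                     cn_effect = rep(0, 9), fc_slope = 0)
  d0 <- simulate_dataset(cfg0)
  expect_lt(diff(range(d0$records$Re)), 1e-4)
  expect_equal(mean(d0$records$Re), 72, tolerance = 1e-6)
})

test_that("generated records flow through the phenotype module", {
  cfg <- sim_config(seed = 8, n_founders = 50, n_generations = 2,
                    cows_per_generation = 80)
  dat <- simulate_dataset(cfg)
  rec <- dat$records
  hys <- assign_hys(rec$herd, rec$year, rec$season)
  expect_true(all(hys == rec$HYS))
  flt <- filter_records(rec)
  expect_equal(nrow(flt), nrow(rec))
})

test_that("genotype block has calibrated frequencies and null option", {
  cfg <- sim_config(seed = 9, n_samples = 400, n_markers = 500,
                    missing_rate = 0)
  gt <- simulate_genotypes(cfg)
  p_hat <- colMeans(gt$G) / 2
  ci <- 3.5 * sqrt(gt$truth$maf * (1 - gt$truth$maf) / (2 * 400))
  expect_gt(mean(abs(p_hat - gt$truth$maf) < ci), 0.99)
  # null trait is independent of the causal score
  cfg0 <- sim_config(seed = 10, n_samples = 300, n_markers = 400,
                     causal_h2 = 0, missing_rate = 0)
  gt0 <- simulate_genotypes(cfg0)
  score <- gt0$G[, match(gt0$truth$causal_ids, colnames(gt0$G))] %*%
    gt0$truth$causal_effects
  expect_gt(cor.test(as.numeric(score), gt0$phenotype)$p.value, 0.01)
  # missingness is injected at the requested rate
  cfgm <- sim_config(seed = 11, n_samples = 200, n_markers = 300,
                     missing_rate = 0.05)
  gm <- simulate_genotypes(cfgm)
  expect_equal(mean(is.na(gm$G)), 0.05, tolerance = 0.01)
})

test_that("configuration validation is strict", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, Ka_true = matrix(-1)), "eigen|positive")
  expect_error(sim_config(seed = 1, sigma_e2_true = rep(-1, 6)))
  expect_error(sim_config(seed = 1, n_causal = 100, n_markers = 10))
})
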