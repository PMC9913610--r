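test_that("sort_pedigree orders parents first and handles edge cases", {
  # child -> sire -> grandsire supplied youngest-first
  ped <- data.frame(animal = c("c", "s", "g"),
                    sire = c("s", "g", NA), dam = c(NA, NA, NA))
  sp <- sort_pedigree(ped)
  expect_equal(sp$animal, c("g", "s", "c"))
  expect_true(all(sp$sire_id < sp$id | sp$sire_id == 0))

  # founders-only pedigree unchanged in content
  f <- data.frame(animal = c("a", "b"), sire = NA, dam = NA)
  expect_setequal(sort_pedigree(f)$animal, c("a", "b"))

  # an animal as its own sire is a cycle
  expect_error(sort_pedigree(data.frame(animal = "x", sire = "x", dam = NA)),
               "cycle")
  # duplicated ids rejected
  expect_error(sort_pedigree(data.frame(animal = c("x", "x"),
                                        sire = NA, dam = NA)),
               "duplicated")
  # parents without own rows are added as founders
  sp2 <- sort_pedigree(data.frame(animal = "k", sire = "u1", dam = "u2"))
  expect_setequal(sp2$animal, c("u1", "u2", "k"))
})

test_that("inbreeding has the textbook closed forms", {
  f <- sort_pedigree(data.frame(animal = c("a", "b"), sire = NA, dam = NA))
  expect_equal(unname(inbreeding_meuwissen_luo(f)), c(0, 0))

  # offspring of full sibs with unrelated grandparents: F = 0.25
  ped <- data.frame(animal = c("s", "d", "c1", "c2", "x"),
                    sire = c(NA, NA, "s", "s", "c1"),
                    dam = c(NA, NA, "d", "d", "c2"))
  F <- inbreeding_meuwissen_luo(sort_pedigree(ped))
  expect_equal(unname(F[["x"]]), 0.25)
})

test_that("tabular A has textbook entries and is PSD", {
  trio <- sort_pedigree(data.frame(animal = c("s", "d", "c"),
                                   sire = c(NA, NA, "s"),
                                   dam = c(NA, NA, "d")))
  A <- a_matrix_tabular(trio)
  expect_equal(A["s", "c"], 0.5)
  sibs <- sort_pedigree(data.frame(animal = c("s", "d", "c1", "c2"),
                                   sire = c(NA, NA, "s", "s"),
                                   dam = c(NA, NA, "d", "d")))
  expect_equal(a_matrix_tabular(sibs)["c1", "c2"], 0.5)

  sp <- sort_pedigree(random_pedigree(50, seed = 3))
  ev <- eigen(a_matrix_tabular(sp), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)

  expect_error(a_matrix_tabular(sp, max_n = 10), "refused")
})

test_that("Meuwissen-Luo F equals tabular diagonal on random pedigrees", {
  for (seed in 1:3) {
    sp <- sort_pedigree(random_pedigree(300, seed = seed))
    F <- inbreeding_meuwissen_luo(sp)
    A <- a_matrix_tabular(sp)
    expect_lt(max(abs(F - (diag(A) - 1))), 1e-12)
    expect_gt(max(F), 0)  # sampled ancestries do create inbreeding
  }
})

test_that("sparse A-inverse inverts the tabular A", {
  trio <- sort_pedigree(data.frame(animal = c("s", "d", "c"),
                                   sire = c(NA, NA, "s"),
                                   dam = c(NA, NA, "d")))
  Ainv <- a_inverse_sparse(trio)
  expect_equal(as.matrix(Ainv)["c", "c"], 2.0)
  single <- sort_pedigree(data.frame(animal = "z", sire = NA, dam = NA))
  expect_equal(as.matrix(a_inverse_sparse(single)), matrix(1, 1, 1,
               dimnames = list("z", "z")))

  sp <- sort_pedigree(random_pedigree(500, seed = 7))
  A <- a_matrix_tabular(sp)
  Ainv <- a_inverse_sparse(sp)
  expect_lt(max(abs(as.matrix(Ainv %*% A) - diag(nrow(A)))), 1e-8)
  # log-determinant identity used by the REML engine
  expect_equal(attr(Ainv, "logdet_A"),
               as.numeric(determinant(A)$modulus), tolerance = 1e-10)
})

test_that("F is invariant to relabeling animal ids", {
  ped <- random_pedigree(150, seed = 11)
  F1 <- inbreeding_meuwissen_luo(sort_pedigree(ped))
  relab <- ped
  key <- setNames(sprintf("Z%03d", rev(seq_len(nrow(ped)))), ped$animal)
  relab$animal <- unname(key[relab$animal])
  relab$sire <- ifelse(is.na(relab$sire), NA, unname(key[relab$sire]))
  relab$dam <- ifelse(is.na(relab$dam), NA, unname(key[relab$dam]))
  F2 <- inbreeding_meuwissen_luo(sort_pedigree(relab))
  expect_equal(unname(sort(F1)), unname(sort(F2)), tolerance = 1e-14)
  expect_equal(unname(F2[key[names(F1)]]), unname(F1), tolerance = 1e-14)
})

test_that("inbreeding classes follow the fixed-width rule with capping", {
  expect_equal(inbreeding_classes(0), 0L)
  expect_equal(inbreeding_classes(0.03, width = 0.02), 1L)
  expect_equal(inbreeding_classes(0.46, width = 0.02, n_classes = 15), 14L)
  expect_equal(inbreeding_classes(c(0, 0.019, 0.02), width = 0.02),
               c(0L, 0L, 1L))
})
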