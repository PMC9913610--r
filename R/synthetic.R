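#' Default coefficient covariance of the synthetic genetic trajectory
#'
#' A positive-definite 3x3 covariance matrix of random-regression
#' coefficients (intercept, slope, quadratic on the normalized Legendre
#' basis) whose implied genetic-variance trajectory declines from about 120
#' at the first calving to about 40 at the ninth with all between-parity
#' genetic correlations above 0.66 — the magnitudes and shape reported for
#' reproductive efficiency in beef cattle.
#'
#' @return 3x3 numeric matrix.
#' @export
default_ka_true <- function() {
  matrix(c(95.4926, -17.3724,  5.0377,
           -17.3724,  11.2600, -2.3544,
             5.0377,  -2.3544,  1.9876), 3, 3, byrow = TRUE)
}

#' Simulation configuration
#'
#' Assembles (and validates) the parameter list driving the synthetic-data
#' generator. Defaults emulate the reproductive-efficiency study system: a
#' multi-generation pedigree with sire reuse (hence nonzero inbreeding),
#' Re records over calvings 1-9 with a population mean near 72%, additive
#' genetic structure from \code{Ka_true}, permanent-environment and
#' herd-year-season components, six residual classes with variance declining
#' over parities, and a biallelic genotype block with planted causal loci.
#'
#' @param seed Integer seed (mandatory; fixes every downstream draw).
#' @param n_founders Number of founder animals.
#' @param n_generations Number of non-founder generations.
#' @param cows_per_generation Offspring produced per generation.
#' @param n_sires_per_generation Males in service per generation (small
#'   values create inbreeding).
#' @param Ka_true Coefficient covariance of the additive genetic effect
#'   (any size k x k; k = 1 gives a repeatability-type scalar animal
#'   effect).
#' @param sigma_p2_true,sigma_hys2_true Permanent-environment and HYS
#'   variances.
#' @param sigma_e2_true Residual variances for classes 1..6 (class =
#'   min(Cn, 6)).
#' @param mu Population mean of Re (%).
#' @param cn_effect Fixed calving-number effect, length 9.
#' @param fc_slope Fixed regression of Re on the cow's inbreeding
#'   coefficient (inbreeding depression when negative).
#' @param n_herds,years_span,n_seasons Contemporary-group layout.
#' @param retention Per-calving probability a cow stays for another record.
#' @param n_samples,n_markers,n_causal,causal_h2,maf_range,missing_rate,fst
#'   Genotype block: samples, markers, causal loci, variance explained by
#'   them, allele-frequency range, missing-call rate, and a two-subpopulation
#'   differentiation level (0 = panmictic).
#' @return Named list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed,
                       n_founders = 120,
                       n_generations = 5,
                       cows_per_generation = 300,
                       n_sires_per_generation = 12,
                       Ka_true = default_ka_true(),
                       sigma_p2_true = 25,
                       sigma_hys2_true = 12,
                       sigma_e2_true = c(349.75, 117.38, 61.71,
                                         39.72, 28.97, 8.87),
                       mu = 72,
                       cn_effect = seq(-6, 6, length.out = 9),
                       fc_slope = -15,
                       n_herds = 8,
                       years_span = 12,
                       n_seasons = 2,
                       retention = 0.8,
                       n_samples = 252,
                       n_markers = 5000,
                       n_causal = 5,
                       causal_h2 = 0.15,
                       maf_range = c(0.05, 0.5),
                       missing_rate = 0.01,
                       fst = 0) {
  if (missing(seed)) stop("a seed is mandatory")
  Ka_true <- as.matrix(Ka_true)
  stopifnot(nrow(Ka_true) == ncol(Ka_true),
            all(eigen(Ka_true, symmetric = TRUE, only.values = TRUE)$values > 0),
            sigma_p2_true > 0, sigma_hys2_true > 0, all(sigma_e2_true > 0),
            length(sigma_e2_true) == 6, length(cn_effect) == 9,
            retention > 0, retention <= 1, n_causal <= n_markers,
            causal_h2 >= 0, causal_h2 < 1)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an overlapping-generation pedigree
#'
#' Founders plus \code{n_generations} rounds of random mating in which a
#' small rotating team of sires serves dams drawn from the previous two
#' generations; sire reuse concentrates ancestry and produces nonzero
#' inbreeding in later generations.
#'
#' @param cfg A [sim_config()] list.
#' @return Unsorted pedigree data.frame (\code{animal, sire, dam,
#'   birth_year, sex}).
#' @export
simulate_pedigree <- function(cfg) {
  set.seed(cfg$seed)
  y0 <- 2000L
  founders <- data.frame(
    animal = sprintf("F%04d", seq_len(cfg$n_founders)),
    sire = NA_character_, dam = NA_character_,
    birth_year = y0 + sample(0:2, cfg$n_founders, replace = TRUE),
    sex = sample(rep(c("M", "F"), length.out = cfg$n_founders)),
    stringsAsFactors = FALSE)
  ped <- founders
  pool <- list(founders, founders)   # previous two cohorts
  for (g in seq_len(cfg$n_generations)) {
    avail <- do.call(rbind, pool)
    males <- avail$animal[avail$sex == "M"]
    females <- avail$animal[avail$sex == "F"]
    sires <- sample(males, min(cfg$n_sires_per_generation, length(males)))
    n_off <- cfg$cows_per_generation
    off <- data.frame(
      animal = sprintf("G%d_%04d", g, seq_len(n_off)),
      sire = sample(sires, n_off, replace = TRUE),
      dam = sample(females, n_off, replace = TRUE),
      birth_year = y0 + 2L + g * 2L + sample(0:1, n_off, replace = TRUE),
      sex = sample(c("M", "F"), n_off, replace = TRUE, prob = c(0.3, 0.7)),
      stringsAsFactors = FALSE)
    ped <- rbind(ped, off)
    pool <- list(pool[[2]], off)
  }
  ped
}

#' Simulate breeding-value regression coefficients down a pedigree
#'
#' Founders draw coefficient vectors from N(0, Ka); each descendant gets the
#' parent average plus a Mendelian-sampling deviation with covariance
#' \eqn{d_i K_a}, \eqn{d_i} the Mendelian-sampling variance from the
#' pedigree (so the full coefficient panel has covariance \eqn{A \otimes
#' K_a}).
#'
#' @param ped Sorted pedigree ([sort_pedigree()]).
#' @param Ka_true k x k positive-definite coefficient covariance.
#' @param F Optional precomputed inbreeding vector.
#' @return Matrix (animals x k) of true coefficients, rows named by animal.
#' @export
simulate_breeding_values <- function(ped, Ka_true, F = NULL) {
  .assert_sorted(ped)
  Ka_true <- as.matrix(Ka_true)
  if (is.null(F)) F <- inbreeding_meuwissen_luo(ped)
  d <- mendelian_variance(ped, F)
  n <- nrow(ped)
  k <- nrow(Ka_true)
  L <- t(chol(Ka_true))
  Z <- matrix(stats::rnorm(n * k), n, k) %*% t(L)   # N(0, Ka) rows
  a <- matrix(0, n, k)
  s <- ped$sire_id
  dm <- ped$dam_id
  for (i in seq_len(n)) {
    pa <- numeric(k)
    if (s[i] > 0L) pa <- pa + 0.5 * a[s[i], ]
    if (dm[i] > 0L) pa <- pa + 0.5 * a[dm[i], ]
    a[i, ] <- pa + sqrt(d[i]) * Z[i, ]
  }
  rownames(a) <- ped$animal
  a
}

#' Simulate reproductive-efficiency records
#'
#' Generates the analysis table the mixed models consume:
#' \deqn{Re = \mu + CnEff_{Cn} + b_F F + \Phi(Cn) a_m + p + HYS + e_{class}}
#' with cows leaving the herd after each calving with probability
#' \code{1 - retention} (capped at 9 calvings). Calving dates consistent
#' with the Re definition are attached so the record can also be pushed
#' through [compute_re()].
#'
#' @param ped Sorted pedigree.
#' @param bvs Coefficient matrix from [simulate_breeding_values()] (k
#'   columns; k = 1 means a parity-constant animal effect).
#' @param cfg A [sim_config()] list.
#' @param cap Cap the generated Re at 100 (default FALSE: the uncapped value
#'   is the linear-model truth; cap when emulating field data).
#' @return List: \code{records} (analysis table with cow, Cn, Re, F,
#'   Fc_class, herd, year, season, HYS, res_class, age_months,
#'   calving_date), and \code{truth} ledger (true coefficients, per-calving
#'   true EGVs, variance components, effect profiles, per-cow pe and HYS
#'   effect maps).
#' @export
simulate_records <- function(ped, bvs, cfg, cap = FALSE) {
  .assert_sorted(ped)
  set.seed(cfg$seed + 1L)
  F <- inbreeding_meuwissen_luo(ped)
  k <- ncol(bvs)
  Phi <- if (k > 1) cn_basis(k - 1) else matrix(1, 9, 1, dimnames = list(1:9, NULL))
  cows <- ped$animal[ped$sex == "F" & ped$sire_id > 0L]
  if (!length(cows)) stop("no non-founder females to record")
  n_cow <- length(cows)
  # sequential retention: P(>= c calvings) = retention^(c-1), capped at 9
  u <- matrix(stats::runif(n_cow * 8), n_cow, 8)
  n_calv <- 1L + as.integer(rowSums(t(apply(u < cfg$retention, 1, cumprod))))
  herd <- sample(sprintf("H%02d", seq_len(cfg$n_herds)), n_cow, replace = TRUE)
  pe <- stats::rnorm(n_cow, 0, sqrt(cfg$sigma_p2_true))
  names(pe) <- cows
  names(herd) <- cows
  idx <- match(cows, ped$animal)
  afc <- stats::rnorm(n_cow, 33, 4)         # realized age at first calving
  ci <- stats::rnorm(n_cow, 14.5, 1.5)      # realized mean calving interval

  rec <- do.call(rbind, lapply(seq_len(n_cow), function(c_i) {
    cn <- seq_len(n_calv[c_i])
    data.frame(cow = cows[c_i], Cn = cn,
               age_months = afc[c_i] + (cn - 1) * ci[c_i],
               stringsAsFactors = FALSE)
  }))
  cow_i <- match(rec$cow, cows)
  rec$herd <- herd[cow_i]
  birth_year <- ped$birth_year[idx][cow_i]
  if (all(is.na(birth_year))) birth_year <- rep(2000L, nrow(rec))
  rec$year <- birth_year + floor(rec$age_months / 12)
  rec$season <- sample(seq_len(cfg$n_seasons), nrow(rec), replace = TRUE)
  rec$HYS <- paste(rec$herd, rec$year, rec$season, sep = "_")
  hys_levels <- unique(rec$HYS)
  hys_eff <- stats::rnorm(length(hys_levels), 0, sqrt(cfg$sigma_hys2_true))
  names(hys_eff) <- hys_levels
  rec$res_class <- pmin(rec$Cn, 6L)
  e <- stats::rnorm(nrow(rec), 0, sqrt(cfg$sigma_e2_true[rec$res_class]))
  Fc <- F[match(rec$cow, ped$animal)]
  g <- rowSums(Phi[rec$Cn, , drop = FALSE] * bvs[match(rec$cow, rownames(bvs)), , drop = FALSE])
  rec$Re <- cfg$mu + cfg$cn_effect[rec$Cn] + cfg$fc_slope * Fc +
    g + pe[cow_i] + hys_eff[rec$HYS] + e
  if (cap) rec$Re <- pmin(rec$Re, 100)
  rec$F <- Fc
  rec$Fc_class <- inbreeding_classes(Fc)
  # dates consistent with the age scale (birth on 15 March of birth year)
  bdate <- as.Date(sprintf("%d-03-15", ifelse(is.na(birth_year), 2000L, birth_year)))
  rec$calving_date <- bdate + round(rec$age_months * 365.25 / 12)
  truth <- list(
    bv = bvs,
    egv_true = if (k > 1) egv_trajectory(bvs, Phi) else bvs %*% t(Phi),
    Ka_true = cfg$Ka_true,
    sigma_p2 = cfg$sigma_p2_true,
    sigma_hys2 = cfg$sigma_hys2_true,
    sigma_e2 = cfg$sigma_e2_true,
    mu = cfg$mu, cn_effect = cfg$cn_effect, fc_slope = cfg$fc_slope,
    pe = pe, hys_eff = hys_eff)
  list(records = rec, truth = truth)
}

#' Simulate a reproductive-efficiency dataset end to end
#'
#' Pedigree, true breeding values and the record table in one call, with the
#' truth ledger attached.
#'
#' @param cfg A [sim_config()] list.
#' @param cap Cap generated Re at 100.
#' @return List: \code{pedigree} (sorted), \code{records}, \code{truth}.
#' @export
simulate_dataset <- function(cfg, cap = FALSE) {
  ped <- sort_pedigree(simulate_pedigree(cfg))
  set.seed(cfg$seed + 2L)
  bvs <- simulate_breeding_values(ped, cfg$Ka_true)
  out <- simulate_records(ped, bvs, cfg, cap = cap)
  list(pedigree = ped, records = out$records, truth = out$truth)
}

#' Simulate biallelic genotypes and an index pseudo-phenotype
#'
#' Marker allele frequencies are uniform on \code{maf_range};
#' genotypes are Hardy-Weinberg draws, optionally from two subpopulations
#' with Balding-Nichols differentiation \code{fst}. \code{n_causal} markers
#' receive standard-normal effects; the pseudo-phenotype is the standardized
#' causal score scaled to explain \code{causal_h2} of its variance plus
#' Gaussian noise (a null trait when \code{causal_h2 = 0}). Missing calls
#' are injected at \code{missing_rate}.
#'
#' @param cfg A [sim_config()] list.
#' @param phenotype_scale SD the pseudo-phenotype is scaled to (default 1).
#' @return List: \code{G} (samples x markers dosage matrix with NAs),
#'   \code{map} (chr, id, pos), \code{sample_ids}, \code{phenotype},
#'   \code{truth} (causal ids, effects, subpopulation labels).
#' @export
simulate_genotypes <- function(cfg, phenotype_scale = 1) {
  set.seed(cfg$seed + 3L)
  n <- cfg$n_samples
  m <- cfg$n_markers
  p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  if (cfg$fst > 0) {
    a <- p * (1 - cfg$fst) / cfg$fst
    b <- (1 - p) * (1 - cfg$fst) / cfg$fst
    p1 <- stats::rbeta(m, a, b)
    p2 <- stats::rbeta(m, a, b)
    pop <- rep(1:2, length.out = n)
    P <- rbind(p1, p2)[pop, , drop = FALSE]
    G <- matrix(stats::rbinom(n * m, 2, P), n, m)
  } else {
    pop <- rep(1L, n)
    G <- matrix(stats::rbinom(n * m, 2, rep(p, each = n)), n, m)
  }
  n_chr <- 29L
  chr <- sort(rep_len(seq_len(n_chr), m))
  pos <- unlist(lapply(split(seq_len(m), chr), function(ix)
    sort(sample.int(1e8, length(ix)))), use.names = FALSE)
  ids <- sprintf("AX-%06d", seq_len(m))
  causal <- sample.int(m, cfg$n_causal)
  eff <- stats::rnorm(cfg$n_causal)
  score <- as.numeric(G[, causal, drop = FALSE] %*% eff)
  if (cfg$causal_h2 > 0 && stats::sd(score) > 0) {
    y <- sqrt(cfg$causal_h2) * as.numeric(scale(score)) +
      sqrt(1 - cfg$causal_h2) * stats::rnorm(n)
  } else {
    y <- stats::rnorm(n)
  }
  y <- y * phenotype_scale
  if (cfg$missing_rate > 0) {
    nm <- stats::rbinom(1, n * m, cfg$missing_rate)
    G[sample.int(n * m, nm)] <- NA_integer_
  }
  sample_ids <- sprintf("S%04d", seq_len(n))
  rownames(G) <- sample_ids
  colnames(G) <- ids
  list(G = G,
       map = data.frame(chr = chr, id = ids, pos = pos,
                        stringsAsFactors = FALSE),
       sample_ids = sample_ids,
       phenotype = stats::setNames(y, sample_ids),
       truth = list(causal_ids = ids[causal], causal_effects = eff,
                    subpop = pop, maf = p))
}
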