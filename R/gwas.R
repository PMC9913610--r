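# Genotype QC, genomic relationship matrix, and the univariate LMM
# association scan (GEMMA-style model, re-implemented) on the composite
# index pseudo-phenotype.

# ---- PLINK-1 binary IO ----------------------------------------------------
# bed is SNP-major; 2-bit codes per sample, 4 samples/byte, LSB first:
#   00 hom A1/A1 (dosage 2), 01 missing, 10 het (1), 11 hom A2/A2 (0).

.plink_lut <- function() {
  dose <- c(2L, NA_integer_, 1L, 0L)
  b <- 0:255
  cbind(dose[bitwAnd(b, 3L) + 1L],
        dose[bitwAnd(bitwShiftR(b, 2L), 3L) + 1L],
        dose[bitwAnd(bitwShiftR(b, 4L), 3L) + 1L],
        dose[bitwAnd(bitwShiftR(b, 6L), 3L) + 1L])
}

#' Write genotypes as a PLINK-1 fileset (bed/bim/fam)
#'
#' @param prefix Output path prefix.
#' @param G Dosage matrix (samples x markers), codes 0/1/2/NA counting the
#'   A1 allele.
#' @param map data.frame with \code{chr}, \code{id}, \code{pos}.
#' @param sample_ids Character vector of sample identifiers.
#' @return Invisibly, the prefix.
#' @export
write_plink1 <- function(prefix, G, map, sample_ids = rownames(G)) {
  stopifnot(nrow(map) == ncol(G), length(sample_ids) == nrow(G))
  n <- nrow(G)
  m <- ncol(G)
  code <- matrix(3L, n, m)                # dosage 0 -> code 11
  code[!is.na(G) & G == 1] <- 2L
  code[!is.na(G) & G == 2] <- 0L
  code[is.na(G)] <- 1L
  pad <- (4 - n %% 4) %% 4
  if (pad) code <- rbind(code, matrix(3L, pad, m))
  dim(code) <- c(4L, (n + pad) / 4 * m)
  bytes <- code[1, ] + 4L * code[2, ] + 16L * code[3, ] + 64L * code[4, ]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  utils::write.table(
    data.frame(map$chr, map$id, 0, map$pos, "A", "B"),
    paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(sample_ids, sample_ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK-1 binary fileset
#'
#' Decodes the SNP-major 2-bit genotype codes into a dosage matrix
#' (counting A1), preserving missing calls as NA.
#'
#' @param prefix Path prefix of the bed/bim/fam triplet.
#' @return List: \code{G} (samples x markers), \code{map} (chr, id, pos,
#'   A1, A2), \code{fam} (sample table).
#' @export
read_plink1 <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chr", "id", "cm", "pos", "A1", "A2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           col.names = c("fid", "iid", "father", "mother",
                                         "sex", "pheno"),
                           colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed, "raw", n = file.info(bed)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK-1 bed file (bad magic bytes): ", bed)
  }
  if (raw[3] != as.raw(0x01)) stop("bed file is not SNP-major: ", bed)
  bps <- ceiling(n / 4)
  expected <- 3 + bps * m
  if (length(raw) != expected) {
    stop("truncated bed file: expected ", expected, " bytes, got ",
         length(raw), " (offset ", length(raw), ")")
  }
  lut <- .plink_lut()
  doses <- lut[as.integer(raw[-(1:3)]) + 1L, , drop = FALSE]
  G <- matrix(as.vector(t(doses)), nrow = 4 * bps)[seq_len(n), , drop = FALSE]
  rownames(G) <- fam$iid
  colnames(G) <- bim$id
  list(G = G, map = bim[, c("chr", "id", "pos", "A1", "A2")], fam = fam)
}

# ---- QC -------------------------------------------------------------------

#' Marker quality control
#'
#' Removes markers with call rate at or below \code{call_rate_min} (the
#' exclusion rule is "call rate <= threshold") or minor allele frequency
#' strictly below \code{maf_min}.
#'
#' @param G Dosage matrix (samples x markers).
#' @param map Optional marker map subset alongside.
#' @param call_rate_min Call-rate threshold (default 0.95, exclusive bound).
#' @param maf_min MAF threshold (default 0.05; markers with MAF >= kept).
#' @return List: \code{G}, \code{map}, \code{report} (counts per rule).
#' @export
qc_filter <- function(G, map = NULL, call_rate_min = 0.95, maf_min = 0.05) {
  cr <- colMeans(!is.na(G))
  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  fail_cr <- cr <= call_rate_min
  fail_maf <- !fail_cr & (is.na(maf) | maf < maf_min)
  keep <- !(fail_cr | fail_maf)
  if (!any(keep)) stop("all markers removed by QC")
  list(G = G[, keep, drop = FALSE],
       map = if (is.null(map)) NULL else map[keep, , drop = FALSE],
       report = data.frame(rule = c("input", "call_rate", "maf", "retained"),
                           n = c(ncol(G), sum(fail_cr), sum(fail_maf),
                                 sum(keep))))
}

#' Greedy windowed LD pruning
#'
#' Within each sliding window of \code{window} markers (slid by \code{step})
#' on a chromosome, pairs with squared correlation above \code{r2_max} are
#' resolved by removing the later marker (position order), until no
#' violating pair remains — the \emph{indep-pairwise} procedure.
#'
#' @param G QC'd dosage matrix.
#' @param map Marker map (chr, id, pos) aligned with \code{G}'s columns.
#' @param window Window size in markers (default 50).
#' @param step Window slide in markers (default 5).
#' @param r2_max Pairwise r-squared ceiling (default 0.5).
#' @return List: \code{G}, \code{map}, \code{kept} (logical over input
#'   markers).
#' @export
ld_prune <- function(G, map, window = 50, step = 5, r2_max = 0.5) {
  stopifnot(nrow(map) == ncol(G))
  keep <- rep(TRUE, ncol(G))
  for (ch in unique(map$chr)) {
    ix <- which(map$chr == ch)
    ix <- ix[order(map$pos[ix])]
    start <- 1L
    repeat {
      win <- ix[start:min(start + window - 1L, length(ix))]
      win <- win[keep[win]]
      if (length(win) > 1) {
        R2 <- suppressWarnings(stats::cor(G[, win, drop = FALSE],
                                          use = "pairwise.complete.obs"))^2
        for (a in seq_len(length(win) - 1L)) {
          if (!keep[win[a]]) next
          for (b in seq((a + 1L), length(win))) {
            if (keep[win[b]] && !is.na(R2[a, b]) && R2[a, b] > r2_max) {
              keep[win[b]] <- FALSE
            }
          }
        }
      }
      if (start + window - 1L >= length(ix)) break
      start <- start + step
    }
  }
  list(G = G[, keep, drop = FALSE], map = map[keep, , drop = FALSE],
       kept = keep)
}

# ---- Relationship matrix and stratification PCs ---------------------------

.impute_mean <- function(G) {
  mu <- colMeans(G, na.rm = TRUE)
  nas <- which(is.na(G), arr.ind = TRUE)
  if (nrow(nas)) G[nas] <- mu[nas[, 2]]
  G
}

#' Centered genomic relationship matrix
#'
#' \eqn{K = Z_c Z_c' / m} with \eqn{Z_c} the column-centered (mean-imputed)
#' dosage matrix — the marker-based relationship matrix of the association
#' model.
#'
#' @param G Dosage matrix.
#' @return Symmetric positive semi-definite matrix (samples x samples).
#' @export
grm_centered <- function(G) {
  if (!ncol(G)) stop("no markers")
  Zc <- scale(.impute_mean(G), center = TRUE, scale = FALSE)
  K <- tcrossprod(Zc) / ncol(G)
  (K + t(K)) / 2
}

#' Population-stratification principal components
#'
#' Top sample-level PCs of the standardized genotype matrix, returned as
#' covariate columns (appended to an intercept) for the association model.
#'
#' @param G (Pruned) dosage matrix.
#' @param n_pcs Number of components (default 10; 0 gives intercept-only).
#' @return Matrix \code{W}: intercept column plus \code{n_pcs} PC scores.
#' @export
stratification_pcs <- function(G, n_pcs = 10) {
  n <- nrow(G)
  if (n_pcs >= n) stop("n_pcs must be < number of samples")
  W <- matrix(1, n, 1, dimnames = list(rownames(G), "intercept"))
  if (n_pcs == 0) return(W)
  Z <- .impute_mean(G)
  sds <- apply(Z, 2, stats::sd)
  Z <- scale(Z[, sds > 0, drop = FALSE])
  sv <- svd(Z, nu = n_pcs, nv = 0)
  pcs <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  colnames(pcs) <- paste0("PC", seq_len(n_pcs))
  cbind(W, pcs)
}

# ---- Linear mixed model ---------------------------------------------------

#' REML null model of the association LMM
#'
#' Model \eqn{y = W\alpha + u + \epsilon}, \eqn{u \sim N(0, \lambda
#' \tau^{-1} K)}, \eqn{\epsilon \sim N(0, \tau^{-1} I)}. \eqn{K} is
#' eigendecomposed once and the REML log-likelihood is profiled down to a
#' one-dimensional optimization over \eqn{\log \lambda}.
#'
#' @param y Phenotype vector.
#' @param W Covariate matrix (with intercept).
#' @param K Genomic relationship matrix.
#' @param lambda_range Search interval for \eqn{\lambda} (default
#'   \code{c(1e-5, 1e5)}).
#' @return List: \code{lambda}, \code{tau_inv} (residual variance
#'   \eqn{\tau^{-1}}), \code{logL}, \code{boundary} flag, and the
#'   eigen-rotation pieces (\code{U}, \code{d}, \code{ys}, \code{Ws}) reused
#'   by [wald_scan()].
#' @export
lmm_null <- function(y, W, K, lambda_range = c(1e-5, 1e5)) {
  n <- length(y)
  W <- as.matrix(W)
  stopifnot(nrow(W) == n, nrow(K) == n)
  ee <- eigen(K, symmetric = TRUE)
  d <- pmax(ee$values, 0)
  U <- ee$vectors
  ys <- as.numeric(crossprod(U, y))
  Ws <- crossprod(U, W)
  c_ <- ncol(W)
  neg2_reml <- function(loglam) {
    lam <- exp(loglam)
    v <- lam * d + 1
    A <- 1 / sqrt(v)
    Wt <- Ws * A
    yt <- ys * A
    qw <- qr(Wt)
    if (qw$rank < c_) return(1e10)
    r <- qr.resid(qw, yt)
    s2 <- sum(r^2) / (n - c_)
    Rmat <- qr.R(qw)
    (n - c_) * (1 + log(2 * pi * s2)) + sum(log(v)) +
      2 * sum(log(abs(diag(Rmat))))
  }
  opt <- stats::optimize(neg2_reml, log(lambda_range), tol = 1e-8)
  lam <- exp(opt$minimum)
  # a flat profile (e.g. K proportional to I) leaves lambda unidentified
  edge <- c(neg2_reml(log(lambda_range[1])), neg2_reml(log(lambda_range[2])))
  flat <- max(edge) - opt$objective < 1e-6
  boundary <- flat || opt$minimum < log(lambda_range[1]) + 1e-3 ||
    opt$minimum > log(lambda_range[2]) - 1e-3
  if (flat) {
    lam <- lambda_range[1]
    warning("flat REML profile: lambda is unidentifiable, ",
            "pinned at the lower search boundary")
  } else if (boundary) {
    warning("lambda estimate pinned near the search boundary (",
            signif(lam, 3), ")")
  }
  v <- lam * d + 1
  A <- 1 / sqrt(v)
  qw <- qr(Ws * A)
  r <- qr.resid(qw, ys * A)
  tau_inv <- sum(r^2) / (n - ncol(W))
  list(lambda = lam, tau_inv = tau_inv, logL = -0.5 * opt$objective,
       boundary = boundary, U = U, d = d, ys = ys, Ws = Ws)
}

#' Wald association scan
#'
#' Per-marker generalized least squares at the null-model variance ratio:
#' each marker enters the rotated, whitened regression alongside the
#' covariates; its effect, standard error and an F(1, n - c - 1) Wald
#' p-value are reported (c = number of covariate columns). Monomorphic
#' markers yield NA and are flagged.
#'
#' @param y Phenotype vector.
#' @param W Covariate matrix.
#' @param X Dosage matrix (samples x markers); missing calls are mean-imputed.
#' @param K Genomic relationship matrix.
#' @param null Optional prefit from [lmm_null()] (computed if missing).
#' @param map Optional marker map (chr, id, pos) carried into the result.
#' @return data.frame: chr, rs, ps, n_miss, beta, se, p_wald; attributes
#'   \code{lambda} and \code{tau_inv}.
#' @export
wald_scan <- function(y, W, X, K, null = NULL, map = NULL) {
  if (is.null(null)) null <- lmm_null(y, W, K)
  n <- length(y)
  c_ <- ncol(as.matrix(W))
  n_miss <- colSums(is.na(X))
  Xi <- .impute_mean(X)
  v <- null$lambda * null$d + 1
  A <- 1 / sqrt(v)
  yt <- null$ys * A
  Wt <- null$Ws * A
  Xt <- crossprod(null$U, Xi) * A
  qw <- qr(Wt)
  ey <- qr.resid(qw, yt)
  EX <- qr.resid(qw, Xt)
  xx <- colSums(EX^2)
  xy <- as.numeric(crossprod(EX, ey))
  df <- n - c_ - 1
  beta <- ifelse(xx > 1e-10, xy / xx, NA_real_)
  rss <- sum(ey^2) - ifelse(xx > 1e-10, xy^2 / xx, 0)
  se <- sqrt(pmax(rss, 0) / df / xx)
  se[xx <= 1e-10] <- NA_real_
  Fstat <- (beta / se)^2
  p <- stats::pf(Fstat, 1, df, lower.tail = FALSE)
  out <- data.frame(
    chr = if (!is.null(map)) map$chr else NA,
    rs = if (!is.null(map)) map$id else colnames(X) %||% seq_len(ncol(X)),
    ps = if (!is.null(map)) map$pos else NA,
    n_miss = n_miss, beta = beta, se = se, p_wald = p,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "lambda") <- null$lambda
  attr(out, "tau_inv") <- null$tau_inv
  out
}

#' Genomic-control inflation factor
#'
#' Median Wald chi-square of the scan over its null expectation.
#'
#' @param p Vector of p-values.
#' @return Scalar lambda_GC.
#' @export
gc_lambda <- function(p) {
  p <- p[!is.na(p)]
  stats::median(stats::qchisq(p, 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, 1)
}

#' Significant-hit table
#'
#' Markers below the suggestive threshold, sorted by p-value, with the
#' genome-wide flag and the mean absolute effect of the hits.
#'
#' @param res Scan result from [wald_scan()].
#' @param suggestive Suggestive p-value threshold (default 1e-4, the hit
#'   rule).
#' @param genomewide Genome-wide threshold (default 1e-5).
#' @return data.frame of hits with a \code{genomewide} flag; attribute
#'   \code{mean_abs_beta} (NA when empty).
#' @export
significant_hits <- function(res, suggestive = 1e-4, genomewide = 1e-5) {
  hits <- res[!is.na(res$p_wald) & res$p_wald < suggestive, , drop = FALSE]
  hits <- hits[order(hits$p_wald), , drop = FALSE]
  hits$genomewide <- hits$p_wald < genomewide
  rownames(hits) <- NULL
  attr(hits, "mean_abs_beta") <-
    if (nrow(hits)) mean(abs(hits$beta)) else NA_real_
  hits
}

#' Candidate genes around significant markers
#'
#' Genes whose (1-based, inclusive) interval overlaps the closed window
#' \eqn{[pos - flank, pos + flank]} of each hit.
#'
#' @param hits Hit table with \code{chr}, \code{rs}, \code{ps}.
#' @param gene_table data.frame with \code{gene}, \code{chr}, \code{start},
#'   \code{end}.
#' @param flank Window half-width in bp (default 500 kb).
#' @return data.frame: rs, chr, ps, gene, start, end, distance (0 when the
#'   marker lies inside the gene).
#' @export
candidate_genes <- function(hits, gene_table, flank = 5e5) {
  if (!nrow(hits) || !nrow(gene_table)) {
    return(data.frame(rs = character(0), chr = character(0),
                      ps = integer(0), gene = character(0),
                      start = integer(0), end = integer(0),
                      distance = numeric(0)))
  }
  if (!any(as.character(gene_table$chr) %in% as.character(hits$chr))) {
    warning("no chromosome shared between hits and gene table")
  }
  out <- do.call(rbind, lapply(seq_len(nrow(hits)), function(h) {
    same <- as.character(gene_table$chr) == as.character(hits$chr[h])
    lo <- hits$ps[h] - flank
    hi <- hits$ps[h] + flank
    sel <- same & gene_table$end >= lo & gene_table$start <= hi
    if (!any(sel)) return(NULL)
    g <- gene_table[sel, , drop = FALSE]
    data.frame(rs = hits$rs[h], chr = hits$chr[h], ps = hits$ps[h],
               gene = g$gene, start = g$start, end = g$end,
               distance = pmax(0, pmax(g$start - hits$ps[h],
                                       hits$ps[h] - g$end)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- data.frame(rs = character(0), chr = character(0),
                                      ps = integer(0), gene = character(0),
                                      start = integer(0), end = integer(0),
                                      distance = numeric(0))
  rownames(out) <- NULL
  out
}
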