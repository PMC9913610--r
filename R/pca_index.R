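# Principal-component composite index over the per-calving EGV panel
# (Togashi-Lin style summary of a random-regression evaluation).

#' Column-standardize an EGV panel
#'
#' Z-scores each per-calving EGV column (sample SD) so the subsequent PCA
#' operates on the correlation structure.
#'
#' @param egvs Numeric matrix, animals x calvings.
#' @return Standardized matrix of the same shape.
#' @export
standardize_panel <- function(egvs) {
  egvs <- as.matrix(egvs)
  if (nrow(egvs) < 2) stop("need at least 2 animals")
  sds <- apply(egvs, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance EGV column(s): ",
         paste(which(sds == 0), collapse = ", "))
  }
  scale(egvs, center = TRUE, scale = sds)
}

#' Eigen-decomposition of the standardized EGV panel
#'
#' PCA on the correlation matrix of the panel. Eigenvector signs are fixed
#' deterministically: the largest-magnitude loading of each component is
#' made positive (under which a panel of uniformly positively correlated
#' parities gets an all-positive first eigenvector).
#'
#' @param panel Standardized panel from [standardize_panel()].
#' @return List: \code{values} (eigenvalues, descending), \code{vectors}
#'   (columns = unit-norm eigenvectors), \code{variance_pct} (share of total
#'   variance, sums to 100).
#' @export
pca_eigen <- function(panel) {
  R <- stats::cor(panel)
  ee <- eigen(R, symmetric = TRUE)
  V <- ee$vectors
  for (j in seq_len(ncol(V))) {
    m <- which.max(abs(V[, j]))
    if (V[m, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(panel)
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  list(values = ee$values,
       vectors = V,
       variance_pct = 100 * ee$values / sum(ee$values))
}

#' Principal-component composite index
#'
#' Per-animal scores on the first two components of the standardized EGV
#' panel and their sum:
#' \deqn{Ipc_1 = \sum_i PC1ev_i\, EGV_i,\quad Ipc_2 = \sum_i PC2ev_i\,
#' EGV_i,\quad IpcT = Ipc_1 + Ipc_2.}
#'
#' @param panel Standardized EGV panel.
#' @param PC1ev,PC2ev Eigenvectors from [pca_eigen()].
#' @return data.frame: animal, Ipc1, Ipc2, IpcT, rank (1 = highest IpcT).
#' @export
ipc_index <- function(panel, PC1ev, PC2ev) {
  stopifnot(length(PC1ev) == ncol(panel), length(PC2ev) == ncol(panel))
  ipc1 <- as.numeric(panel %*% PC1ev)
  ipc2 <- as.numeric(panel %*% PC2ev)
  ipct <- ipc1 + ipc2
  data.frame(animal = rownames(panel) %||% seq_len(nrow(panel)),
             Ipc1 = ipc1, Ipc2 = ipc2, IpcT = ipct,
             rank = rank(-ipct, ties.method = "first"),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Composite index from an EGV panel in one call
#'
#' Standardizes, decomposes and scores; the number of summed components is
#' configurable (default 2).
#'
#' @param egvs Raw EGV panel (animals x calvings).
#' @param n_pc Number of leading components summed into the total index.
#' @return List: \code{index} (data.frame as [ipc_index()]), \code{pca}
#'   (from [pca_eigen()]).
#' @export
pca_index <- function(egvs, n_pc = 2) {
  panel <- standardize_panel(egvs)
  pp <- pca_eigen(panel)
  stopifnot(n_pc >= 1, n_pc <= ncol(panel))
  scores <- panel %*% pp$vectors[, seq_len(n_pc), drop = FALSE]
  ipct <- rowSums(scores)
  idx <- data.frame(animal = rownames(panel) %||% seq_len(nrow(panel)),
                    Ipc1 = scores[, 1],
                    Ipc2 = if (n_pc >= 2) scores[, 2] else 0,
                    IpcT = ipct,
                    rank = rank(-ipct, ties.method = "first"),
                    stringsAsFactors = FALSE)
  rownames(idx) <- NULL
  list(index = idx, pca = pp)
}

#' Select a genotyping cohort from the index distribution
#'
#' The union of a top slice (largest IpcT) and a negative-index slice, the
#' design used to contrast extreme animals in an association study.
#'
#' @param index data.frame from [pca_index()] / [ipc_index()].
#' @param n_top Animals taken from the top of the IpcT ranking.
#' @param n_negative Animals sampled from those with IpcT < 0 (the lowest
#'   ones are taken).
#' @return Character vector of animal ids.
#' @export
select_cohort <- function(index, n_top = 212, n_negative = 40) {
  ord <- index[order(-index$IpcT), ]
  if (n_top > nrow(ord)) {
    warning("requested ", n_top, " top animals, only ", nrow(ord), " available")
    n_top <- nrow(ord)
  }
  top <- ord$animal[seq_len(n_top)]
  neg_pool <- ord$animal[ord$IpcT < 0]
  if (n_negative > length(neg_pool)) {
    warning("requested ", n_negative, " negative-index animals, only ",
            length(neg_pool), " available")
    n_negative <- length(neg_pool)
  }
  neg <- if (n_negative > 0) rev(neg_pool)[seq_len(n_negative)] else character(0)
  unique(c(top, neg))
}
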