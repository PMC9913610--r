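#' Read a pedigree from delimited text
#'
#' Expected columns: \code{animal, sire, dam, birth_year, sex} (header
#' required). \code{"0"}, \code{""} or \code{NA} denote an unknown parent.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator (default comma).
#' @return A \code{data.frame} pedigree (see [sort_pedigree()]).
#' @export
read_pedigree <- function(path, sep = ",") {
  ped <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  names(ped) <- tolower(names(ped))
  req <- c("animal", "sire", "dam")
  if (!all(req %in% names(ped))) {
    stop("pedigree file must have columns animal, sire, dam")
  }
  for (col in c("sire", "dam")) {
    ped[[col]][ped[[col]] %in% c("", "0", "NA")] <- NA_character_
  }
  if ("birth_year" %in% names(ped)) ped$birth_year <- as.integer(ped$birth_year)
  ped
}

#' Topologically sort a pedigree
#'
#' Orders animals so that every parent precedes its offspring, the
#' precondition for the recursive relationship and inbreeding algorithms.
#' Unknown parents ("0", "" or NA) are kept as \code{NA}. A parent that has
#' no own row is added as a founder.
#'
#' @param ped data.frame with columns \code{animal}, \code{sire}, \code{dam}
#'   and optionally \code{birth_year}, \code{sex}.
#' @return The pedigree reordered parents-first, with integer columns
#'   \code{id}, \code{sire_id}, \code{dam_id} (0 = unknown) appended;
#'   attribute \code{"order"} holds the sort.
#' @export
sort_pedigree <- function(ped) {
  ped$animal <- as.character(ped$animal)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  ped$sire[ped$sire %in% c("", "0")] <- NA
  ped$dam[ped$dam %in% c("", "0")] <- NA
  if (anyDuplicated(ped$animal)) {
    stop("duplicated animal ids: ",
         paste(unique(ped$animal[duplicated(ped$animal)]), collapse = ", "))
  }
  parents <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$animal)
  if (length(parents)) {
    add <- ped[rep(NA_integer_, length(parents)), , drop = FALSE]
    add$animal <- parents
    add$sire <- NA
    add$dam <- NA
    ped <- rbind(add, ped)
    rownames(ped) <- NULL
  }
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])

  # Kahn's algorithm on parent -> offspring edges
  indeg <- (si > 0L) + (di > 0L)
  order_out <- integer(n)
  ready <- which(indeg == 0L)
  children <- vector("list", n)
  for (i in idx) {
    if (si[i] > 0L) children[[si[i]]] <- c(children[[si[i]]], i)
    if (di[i] > 0L) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  k <- 0L
  while (length(ready)) {
    i <- ready[1L]
    ready <- ready[-1L]
    k <- k + 1L
    order_out[k] <- i
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (k < n) {
    cyc <- ped$animal[indeg > 0L]
    stop("pedigree contains a cycle involving: ",
         paste(utils::head(cyc, 10), collapse = " -> "))
  }
  out <- ped[order_out, , drop = FALSE]
  rownames(out) <- NULL
  idx2 <- seq_len(n)
  names(idx2) <- out$animal
  out$id <- idx2
  out$sire_id <- ifelse(is.na(out$sire), 0L, unname(idx2[out$sire]))
  out$dam_id <- ifelse(is.na(out$dam), 0L, unname(idx2[out$dam]))
  attr(out, "order") <- order_out
  attr(out, "sorted") <- TRUE
  out
}

.assert_sorted <- function(ped) {
  if (!isTRUE(attr(ped, "sorted"))) stop("pedigree must come from sort_pedigree()")
  ped
}

#' Mendelian-sampling variances of a sorted pedigree
#'
#' \eqn{d_i} with both parents known: \eqn{0.5 - 0.25 (F_s + F_d)}; one
#' parent known: \eqn{0.75 - 0.25 F_{known}}; founders: 1. These are the
#' diagonal of D in A = TDT' and drive both the sparse inverse of A and
#' breeding-value simulation.
#'
#' @param ped Sorted pedigree.
#' @param F Inbreeding coefficients in pedigree order (from
#'   [inbreeding_meuwissen_luo()]).
#' @return Numeric vector \code{d} in pedigree order.
#' @export
mendelian_variance <- function(ped, F) {
  .assert_sorted(ped)
  s <- ped$sire_id
  d <- ped$dam_id
  Fs <- ifelse(s > 0L, F[pmax(s, 1L)], 0)
  Fd <- ifelse(d > 0L, F[pmax(d, 1L)], 0)
  known <- (s > 0L) + (d > 0L)
  ifelse(known == 2L, 0.5 - 0.25 * (Fs + Fd),
         ifelse(known == 1L, 0.75 - 0.25 * (Fs + Fd), 1))
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes F for every animal without forming the dense relationship
#' matrix, by accumulating \eqn{a_{ii} = \sum_j L_{ij}^2 d_j} over each
#' animal's ancestors (A = TDT' decomposition). Memory and time are linear
#' in pedigree size times mean ancestry depth.
#'
#' @param ped Sorted pedigree from [sort_pedigree()].
#' @return Numeric vector of inbreeding coefficients in pedigree order,
#'   named by animal id.
#' @export
inbreeding_meuwissen_luo <- function(ped) {
  .assert_sorted(ped)
  n <- nrow(ped)
  s <- ped$sire_id
  d <- ped$dam_id
  F <- numeric(n)
  dvec <- numeric(n)
  L <- numeric(n)
  for (i in seq_len(n)) {
    Fs <- if (s[i] > 0L) F[s[i]] else 0
    Fd <- if (d[i] > 0L) F[d[i]] else 0
    nk <- (s[i] > 0L) + (d[i] > 0L)
    dvec[i] <- if (nk == 2L) 0.5 - 0.25 * (Fs + Fd)
               else if (nk == 1L) 0.75 - 0.25 * (Fs + Fd) else 1
    if (nk < 2L) { F[i] <- 0; next }   # a parent unknown => unrelated parents
    # a_ii = sum_j L_j^2 d_j over ancestors j (including i itself)
    L[] <- 0
    L[i] <- 1
    aii <- 0
    for (j in i:1) {           # sorted order: ancestors have smaller index
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * dvec[j]
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * L[j]
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * L[j]
    }
    F[i] <- aii - 1
  }
  names(F) <- ped$animal
  F
}

#' Dense numerator relationship matrix by the tabular method
#'
#' Test oracle for small pedigrees: \eqn{a_{ij} = 0.5 (a_{i,s_j} +
#' a_{i,d_j})} for i < j and \eqn{a_{jj} = 1 + 0.5 a_{s_j, d_j}}. Refuses
#' pedigrees beyond \code{max_n} animals; model fitting always goes through
#' the sparse inverse instead.
#'
#' @param ped Sorted pedigree.
#' @param max_n Size guard (default 5000).
#' @return Dense symmetric matrix with animal ids as dimnames.
#' @export
a_matrix_tabular <- function(ped, max_n = 5000) {
  .assert_sorted(ped)
  n <- nrow(ped)
  if (n > max_n) stop("tabular A refused for ", n, " > ", max_n, " animals")
  s <- ped$sire_id
  d <- ped$dam_id
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    if (j > 1L) {
      i <- seq_len(j - 1L)
      as_ <- if (s[j] > 0L) A[i, s[j]] else 0
      ad_ <- if (d[j] > 0L) A[i, d[j]] else 0
      A[i, j] <- 0.5 * (as_ + ad_)
      A[j, i] <- A[i, j]
    }
    asd <- if (s[j] > 0L && d[j] > 0L) A[s[j], d[j]] else 0
    A[j, j] <- 1 + 0.5 * asd
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds \eqn{A^{-1}} directly from parent triplets by Henderson's rules
#' accounting for inbreeding: with \eqn{\alpha_i = 1/d_i}, each animal
#' contributes \eqn{\alpha_i} at (i,i), \eqn{-\alpha_i/2} at (i, parent)
#' and \eqn{\alpha_i/4} between its known parents.
#'
#' @param ped Sorted pedigree.
#' @param F Optional inbreeding vector (computed if missing).
#' @return \code{dsCMatrix} sparse symmetric matrix; attribute
#'   \code{"logdet_A"} carries \eqn{\log|A| = \sum_i \log d_i}.
#' @export
a_inverse_sparse <- function(ped, F = NULL) {
  .assert_sorted(ped)
  if (is.null(F)) F <- inbreeding_meuwissen_luo(ped)
  n <- nrow(ped)
  dvec <- mendelian_variance(ped, F)
  alpha <- 1 / dvec
  s <- ped$sire_id
  d <- ped$dam_id
  both <- s > 0L & d > 0L
  ii <- c(seq_len(n),                       # own diagonal
          which(s > 0L), which(d > 0L),     # animal-parent
          s[s > 0L], d[d > 0L],             # parent diagonals
          pmax(s, d)[both])                 # sire-dam cross
  jj <- c(seq_len(n),
          s[s > 0L], d[d > 0L],
          s[s > 0L], d[d > 0L],
          pmin(s, d)[both])
  xx <- c(alpha,
          -0.5 * alpha[s > 0L], -0.5 * alpha[d > 0L],
          0.25 * alpha[s > 0L], 0.25 * alpha[d > 0L],
          0.25 * alpha[both])
  lower_i <- pmax(ii, jj)
  lower_j <- pmin(ii, jj)
  Ainv <- Matrix::sparseMatrix(i = lower_i, j = lower_j, x = xx,
                               dims = c(n, n), symmetric = TRUE,
                               dimnames = list(ped$animal, ped$animal))
  attr(Ainv, "logdet_A") <- sum(log(dvec))
  Ainv
}

#' Cluster inbreeding coefficients into fixed-width classes
#'
#' Class index \code{min(floor(F / width), n_classes - 1)} (0-based), the
#' clustering used for the fixed inbreeding effect.
#'
#' @param F Numeric inbreeding coefficients.
#' @param width Class width on the F scale (default 0.02).
#' @param n_classes Number of classes (default 15; the top class absorbs
#'   everything above).
#' @return Integer vector of 0-based class indices.
#' @export
inbreeding_classes <- function(F, width = 0.02, n_classes = 15) {
  stopifnot(width > 0, n_classes >= 1)
  pmin(as.integer(floor(F / width)), n_classes - 1L)
}
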