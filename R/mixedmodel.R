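# REML engine for the repeatability and random-regression animal models.
#
# Both models are fitted through the sparse mixed-model equations: one
# likelihood evaluation = assemble C(theta), one sparse Cholesky, and the
# standard identity
#   -2 logL_R = log|R| + log|G| + log|C| + y'Py + (n - p) log 2pi .
# theta is optimized by nlminb on an unconstrained scale (log variances;
# log-Cholesky factor of Ka), which keeps every component positive and Ka
# positive definite by construction.

.drop_collinear <- function(X) {
  XtX <- as.matrix(Matrix::crossprod(X))
  qr_ <- qr(XtX)
  if (qr_$rank < ncol(X)) {
    keep <- sort(qr_$pivot[seq_len(qr_$rank)])
    X <- X[, keep, drop = FALSE]
  }
  X
}

# Fixed-effect design for either model.
#  - "classes": intercept + Cn class factors + Fc class factors (Rep form)
#  - "legendre": intercept + phi_1..phi_r(Cn) + phi_1..phi_r(Fc midpoint)
.fixed_design <- function(records, form, r = 2, max_cn = 9) {
  cn <- pmin(records$Cn, max_cn)
  if (form == "classes") {
    df <- data.frame(cn_f = factor(cn), fc_f = factor(records$Fc_class))
    tt <- if (nlevels(df$fc_f) > 1 && nlevels(df$cn_f) > 1) ~ cn_f + fc_f
          else if (nlevels(df$cn_f) > 1) ~ cn_f
          else if (nlevels(df$fc_f) > 1) ~ fc_f else ~ 1
    X <- Matrix::sparse.model.matrix(tt, df)
  } else {
    Phi_cn <- legendre_basis(standardize_cn(cn, 1, max_cn), r)
    fc <- records$Fc_class
    if (length(unique(fc)) > 1) {
      xfc <- -1 + 2 * (fc - min(fc)) / (max(fc) - min(fc))
      Phi_fc <- legendre_basis(xfc, r)[, -1, drop = FALSE]
      colnames(Phi_fc) <- paste0("fc_", colnames(Phi_fc))
      X <- methods::as(cbind(Phi_cn, Phi_fc), "CsparseMatrix")
    } else {
      X <- methods::as(Phi_cn, "CsparseMatrix")
    }
  }
  .drop_collinear(X)
}

# Design matrices and per-residual-class cross-products shared by every
# likelihood evaluation.
.build_mme <- function(records, ped, Ainv, form, r, k, n_res_classes,
                       max_cn = 9) {
  stopifnot(nrow(records) > 0)
  if (!all(records$cow %in% ped$animal)) {
    stop("records reference cows absent from the pedigree")
  }
  n <- nrow(records)
  X <- .fixed_design(records, form, r = r, max_cn = max_cn)
  p <- ncol(X)
  n_anim <- nrow(ped)
  anim_i <- match(records$cow, ped$animal)
  cn <- pmin(records$Cn, max_cn)
  if (k > 1) {
    Phi <- cn_basis(k - 1, 1, max_cn)
    Za <- Matrix::sparseMatrix(
      i = rep(seq_len(n), each = k),
      j = as.integer(t(outer(anim_i - 1L, seq_len(k), function(a, s) a * k + s))),
      x = as.numeric(t(Phi[cn, , drop = FALSE])),
      dims = c(n, n_anim * k))
  } else {
    Za <- Matrix::sparseMatrix(i = seq_len(n), j = anim_i, x = 1,
                               dims = c(n, n_anim))
  }
  cow_f <- factor(records$cow)
  Zp <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(cow_f), x = 1,
                             dims = c(n, nlevels(cow_f)))
  hys_f <- factor(records$HYS)
  Zh <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(hys_f), x = 1,
                             dims = c(n, nlevels(hys_f)))
  W <- cbind(X, Za, Zp, Zh)
  y <- records$Re
  res_class <- if (n_res_classes > 1) pmin(cn, n_res_classes) else rep(1L, n)
  WtW <- vector("list", n_res_classes)
  Wty <- vector("list", n_res_classes)
  yy <- numeric(n_res_classes)
  n_c <- integer(n_res_classes)
  for (c_ in seq_len(n_res_classes)) {
    rows <- which(res_class == c_)
    n_c[c_] <- length(rows)
    if (!length(rows)) {
      WtW[[c_]] <- NULL
      next
    }
    Wc <- W[rows, , drop = FALSE]
    WtW[[c_]] <- Matrix::forceSymmetric(Matrix::crossprod(Wc))
    Wty[[c_]] <- Matrix::crossprod(Wc, y[rows])
    yy[c_] <- sum(y[rows]^2)
  }
  mme <- list(X = X, W = W, y = y, p = p, k = k, n = n,
       n_anim = n_anim, q_p = nlevels(cow_f), q_h = nlevels(hys_f),
       pe_levels = levels(cow_f), hys_levels = levels(hys_f),
       Ainv = Ainv, logdet_A = attr(Ainv, "logdet_A"),
       WtW = WtW, Wty = Wty, yy = yy, n_c = n_c,
       n_res_classes = n_res_classes, anim_ids = ped$animal,
       Phi = if (k > 1) cn_basis(k - 1, 1, max_cn) else NULL)
  c(mme, .mme_template(mme))
}

# upper-triangle entries of a symmetric sparse matrix
.sym_entries <- function(m) {
  m <- methods::as(Matrix::forceSymmetric(methods::as(m, "CsparseMatrix")),
                   "symmetricMatrix")
  if (m@uplo == "L") m <- Matrix::t(m)
  j <- rep.int(seq_len(ncol(m)), diff(m@p))
  list(i = m@i + 1L, j = j, x = m@x)
}

# Precomputed assembly template: the coefficient matrix's fixed sparsity
# pattern plus index maps from every variance structure into its x slot,
# so each likelihood evaluation is pure value assembly + one numeric
# Cholesky (symbolic factorization reused).
.mme_template <- function(mme) {
  k <- mme$k
  p <- mme$p
  na <- mme$n_anim
  off_a <- p                      # animal block offset
  off_p <- p + na * k
  off_h <- off_p + mme$q_p
  N <- off_h + mme$q_h
  ae <- .sym_entries(mme$Ainv)
  if (k > 1) {
    # expand A-inverse entries into k x k coefficient blocks (upper storage)
    ut <- which(upper.tri(matrix(0, k, k), diag = TRUE))
    st_all <- seq_len(k * k)
    s_of <- rep(seq_len(k), times = k)
    t_of <- rep(seq_len(k), each = k)
    dia <- ae$i == ae$j
    n_d <- sum(dia); n_o <- sum(!dia)
    kron_i <- c(rep((ae$i[dia] - 1L) * k, each = length(ut)) + s_of[ut],
                rep((ae$i[!dia] - 1L) * k, each = k * k) + s_of)
    kron_j <- c(rep((ae$j[dia] - 1L) * k, each = length(ut)) + t_of[ut],
                rep((ae$j[!dia] - 1L) * k, each = k * k) + t_of)
    kron_e <- c(rep(which(dia), each = length(ut)),
                rep(which(!dia), each = k * k))
    kron_st <- c(rep.int(ut, n_d), rep.int(st_all, n_o))
    g_i <- off_a + kron_i
    g_j <- off_a + kron_j
  } else {
    g_i <- off_a + ae$i
    g_j <- off_a + ae$j
    kron_e <- seq_along(ae$x)
    kron_st <- rep(1L, length(ae$x))
  }
  pe_i <- off_p + seq_len(mme$q_p)
  hy_i <- off_h + seq_len(mme$q_h)
  wtw <- lapply(mme$WtW, function(m) if (is.null(m)) NULL else .sym_entries(m))
  all_i <- c(g_i, pe_i, hy_i, unlist(lapply(wtw, `[[`, "i")))
  all_j <- c(g_j, pe_i, hy_i, unlist(lapply(wtw, `[[`, "j")))
  key <- function(i, j) (pmax(i, j) - 1) * N + pmin(i, j)
  Mt <- Matrix::sparseMatrix(i = pmin(all_i, all_j), j = pmax(all_i, all_j),
                             x = 1, dims = c(N, N), symmetric = TRUE)
  stopifnot(Mt@uplo == "U")   # @x slot order must match .sym_entries()
  te <- .sym_entries(Mt)
  tkey <- key(te$i, te$j)
  idx_of <- function(i, j) {
    m <- match(key(i, j), tkey)
    stopifnot(!anyNA(m))
    m
  }
  list(tmpl = Mt, nnz_t = length(tkey), N = N,
       ainv_x = ae$x,
       idx_g = idx_of(g_i, g_j), kron_e = kron_e, kron_st = kron_st,
       idx_pe = idx_of(pe_i, pe_i), idx_hy = idx_of(hy_i, hy_i),
       idx_w = lapply(wtw, function(e) if (is.null(e)) NULL
                      else idx_of(e$i, e$j)),
       wtw_x = lapply(wtw, `[[`, "x"),
       cache = new.env(parent = emptyenv()))
}

# theta -> variance components. Layout:
#   k = 1 : (log sa2, log sp2, log sh2, log se2[1..ncls])
#   k > 1 : (log-chol Ka [k(k+1)/2], log sp2, log sh2, log se2[1..ncls])
.theta_to_comp <- function(theta, k, n_res_classes) {
  if (k == 1) {
    list(Ka = matrix(exp(theta[1]), 1, 1),
         sp2 = exp(theta[2]), sh2 = exp(theta[3]),
         se2 = exp(theta[3 + seq_len(n_res_classes)]))
  } else {
    nk <- k * (k + 1) / 2
    L <- matrix(0, k, k)
    L[lower.tri(L, diag = TRUE)] <- theta[seq_len(nk)]
    diag(L) <- exp(diag(L))
    Ka <- L %*% t(L)
    list(Ka = Ka,
         sp2 = exp(theta[nk + 1]), sh2 = exp(theta[nk + 2]),
         se2 = exp(theta[nk + 2 + seq_len(n_res_classes)]))
  }
}

.comp_to_theta <- function(Ka, sp2, sh2, se2) {
  k <- nrow(Ka)
  if (k == 1) return(c(log(Ka[1, 1]), log(sp2), log(sh2), log(se2)))
  L <- t(chol(Ka))
  diag(L) <- log(diag(L))
  c(L[lower.tri(L, diag = TRUE)], log(sp2), log(sh2), log(se2))
}

# -2 REML logL (and, on request, the solution vector) at theta.
# Assembles values into the precomputed template and reuses the cached
# symbolic Cholesky factorization.
.reml_deviance <- function(theta, mme, solve_out = FALSE) {
  cmp <- .theta_to_comp(theta, mme$k, mme$n_res_classes)
  k <- mme$k
  Kainv <- tryCatch(solve(cmp$Ka), error = function(e) NULL)
  if (is.null(Kainv)) return(1e10)
  ldKa <- as.numeric(determinant(cmp$Ka)$modulus)
  xv <- numeric(mme$nnz_t)
  vals_g <- if (k > 1) mme$ainv_x[mme$kron_e] * as.numeric(Kainv)[mme$kron_st]
            else mme$ainv_x / cmp$Ka[1, 1]
  xv[mme$idx_g] <- xv[mme$idx_g] + vals_g
  xv[mme$idx_pe] <- xv[mme$idx_pe] + 1 / cmp$sp2
  xv[mme$idx_hy] <- xv[mme$idx_hy] + 1 / cmp$sh2
  rhs <- numeric(mme$N)
  yRy <- 0
  logR <- 0
  for (c_ in seq_len(mme$n_res_classes)) {
    if (!mme$n_c[c_]) next
    w <- 1 / cmp$se2[c_]
    ix <- mme$idx_w[[c_]]
    xv[ix] <- xv[ix] + w * mme$wtw_x[[c_]]
    rhs <- rhs + w * as.numeric(mme$Wty[[c_]])
    yRy <- yRy + w * mme$yy[c_]
    logR <- logR + mme$n_c[c_] * log(cmp$se2[c_])
  }
  M <- mme$tmpl
  M@x <- xv
  cache <- mme$cache
  Ch <- NULL
  if (!is.null(cache$Ch)) {
    Ch <- tryCatch(stats::update(cache$Ch, M), error = function(e) NULL)
  }
  if (is.null(Ch)) {
    Ch <- tryCatch(Matrix::Cholesky(M, LDL = FALSE), error = function(e) NULL)
    if (is.null(Ch)) return(1e10)
    cache$Ch <- Ch
  }
  ldC <- as.numeric(determinant(Ch, sqrt = FALSE)$modulus)
  sol <- Matrix::solve(Ch, rhs)
  yPy <- yRy - sum(rhs * as.numeric(sol))
  logG <- (if (k > 1) k * mme$logdet_A + mme$n_anim * ldKa
           else mme$n_anim * log(cmp$Ka[1, 1]) + mme$logdet_A) +
    mme$q_p * log(cmp$sp2) + mme$q_h * log(cmp$sh2)
  dev <- logR + logG + ldC + yPy + (mme$n - mme$p) * log(2 * pi)
  if (!is.finite(dev)) return(1e10)
  if (solve_out) attr(dev, "solution") <- as.numeric(sol)
  dev
}

.extract_solutions <- function(sol, mme) {
  p <- mme$p
  k <- mme$k
  na <- mme$n_anim
  fixed <- sol[seq_len(p)]
  a <- sol[p + seq_len(na * k)]
  amat <- matrix(a, nrow = na, ncol = k, byrow = TRUE,
                 dimnames = list(mme$anim_ids, NULL))
  pe <- sol[p + na * k + seq_len(mme$q_p)]
  names(pe) <- mme$pe_levels
  hys <- sol[p + na * k + mme$q_p + seq_len(mme$q_h)]
  names(hys) <- mme$hys_levels
  list(fixed = fixed, animal = amat, pe = pe, hys = hys)
}

.fit_reml <- function(mme, theta0, control, pin = integer(0)) {
  lower <- rep(-Inf, length(theta0))
  upper <- rep(Inf, length(theta0))
  vy <- stats::var(mme$y)
  floor_log <- log(1e-8 * vy)
  # bounds apply to the log-variance entries (and Ka log-diagonal)
  if (mme$k == 1) {
    lower[] <- floor_log
  } else {
    nk <- mme$k * (mme$k + 1) / 2
    diag_pos <- c(1, 1 + cumsum(rev(seq_len(mme$k))[-mme$k]))
    lower[diag_pos] <- floor_log / 2
    lower[(nk + 1):length(theta0)] <- floor_log
  }
  if (length(pin)) {        # unidentifiable components held at the floor
    theta0[pin] <- lower[pin]
    upper[pin] <- lower[pin]
  }
  opt <- stats::nlminb(theta0, function(th) .reml_deviance(th, mme),
                       lower = lower, upper = upper,
                       control = list(iter.max = control$max_iter,
                                      eval.max = control$max_eval,
                                      rel.tol = control$rel_tol))
  converged <- opt$convergence == 0
  dev <- .reml_deviance(opt$par, mme, solve_out = TRUE)
  pinned <- opt$par <= lower + 1e-6
  pinned[pin] <- FALSE        # already warned about deliberately pinned ones
  if (any(pinned)) {
    warning("variance parameter(s) pinned at the lower boundary: ",
            paste(which(pinned), collapse = ", "))
  }
  pinned[pin] <- TRUE
  list(theta = opt$par, deviance = as.numeric(dev),
       logL = -0.5 * as.numeric(dev),
       solution = attr(dev, "solution"),
       converged = converged, n_iter = opt$iterations,
       pinned = pinned)
}

.fit_control <- function(max_iter = 200, max_eval = 2000, rel_tol = 1e-8) {
  list(max_iter = max_iter, max_eval = max_eval, rel_tol = rel_tol)
}

#' Fit the repeatability animal model by REML
#'
#' Model: \eqn{y = X\beta + Z_a a + Z_p p + Z_h h + e} with
#' \eqn{a \sim N(0, A\sigma^2_a)}, scalar permanent-environment, HYS and
#' residual components; fixed effects are calving-number and inbreeding
#' class factors. Heritability \eqn{\sigma^2_a / \sigma^2_{tot}} and
#' repeatability \eqn{(\sigma^2_a + \sigma^2_p)/\sigma^2_{tot}} are reported
#' from the estimated components.
#'
#' @param records Analysis table with columns \code{cow, Cn, Re, Fc_class,
#'   HYS}.
#' @param ped Sorted pedigree covering every cow.
#' @param Ainv Optional precomputed sparse inverse relationship matrix
#'   (from [a_inverse_sparse()]); computed if missing.
#' @param start Optional list(Ka, sp2, sh2, se2) of starting values; by
#'   default the phenotypic variance is split 40/30/10/20 over
#'   animal/pe/HYS/residual.
#' @param control List from [.fit_control()]-style entries: \code{max_iter},
#'   \code{max_eval}, \code{rel_tol}.
#' @return Object of class \code{re_fit}: variance components, logL,
#'   heritability, repeatability, solutions (fixed, animal EGVs, pe, HYS),
#'   convergence information.
#' @export
fit_repeatability <- function(records, ped, Ainv = NULL, start = NULL,
                              control = list()) {
  control <- utils::modifyList(.fit_control(), control)
  if (is.null(Ainv)) Ainv <- a_inverse_sparse(ped)
  mme <- .build_mme(records, ped, Ainv, form = "classes", r = 0, k = 1,
                    n_res_classes = 1)
  vy <- stats::var(records$Re)
  theta0 <- if (is.null(start)) {
    log(vy * c(0.4, 0.3, 0.1, 0.2))
  } else .comp_to_theta(as.matrix(start$Ka), start$sp2, start$sh2, start$se2)
  pin <- integer(0)
  if (max(table(records$cow)) == 1L) {
    warning("single record per cow: permanent-environment variance is not ",
            "identifiable and is pinned at the boundary")
    pin <- 2L
  }
  res <- .fit_reml(mme, theta0, control, pin = pin)
  cmp <- .theta_to_comp(res$theta, 1, 1)
  sols <- .extract_solutions(res$solution, mme)
  comp <- c(additive = cmp$Ka[1, 1], pe = cmp$sp2, hys = cmp$sh2,
            residual = cmp$se2[1])
  tot <- sum(comp)
  out <- list(model = "rep", components = comp, total = tot,
              h2 = comp[["additive"]] / tot,
              repeatability = (comp[["additive"]] + comp[["pe"]]) / tot,
              logL = res$logL, n_params = 4L, n_records = mme$n,
              n_fixed = mme$p,
              converged = res$converged, n_iter = res$n_iter,
              pinned = res$pinned,
              solutions = sols, egv = stats::setNames(sols$animal[, 1],
                                                      mme$anim_ids))
  class(out) <- "re_fit"
  out
}

#' Fit a random-regression animal model by REML
#'
#' The animal effect is an order-\code{r} Legendre regression on the
#' calving-number scale with coefficient covariance \eqn{K_a} (so the
#' genetic covariance of the full panel is \eqn{A \otimes K_a}), alongside
#' scalar permanent-environment and HYS components and
#' \code{n_res_classes} residual classes indexed by \code{min(Cn, 6)}.
#' \eqn{K_a} is optimized through its Cholesky factor and is therefore
#' positive definite at every iterate. Variance-parameter count is
#' \eqn{(r+1)(r+2)/2 + 2 + n_{res}} (14 for r = 2 with 6 classes).
#'
#' @inheritParams fit_repeatability
#' @param r Legendre order of the animal regression (0, 1 or 2).
#' @param n_res_classes Number of residual variance classes (default 6).
#' @param fixed_form \code{"legendre"} (default: fixed order-r regressions
#'   on Cn and Fc) or \code{"classes"} (the repeatability model's class
#'   factors, which makes r = 0 with one residual class an exact
#'   reparameterization of [fit_repeatability()]).
#' @return Object of class \code{re_fit} with \code{Ka}, scalar components,
#'   per-animal coefficient matrix and the 9-parity EGV panel.
#' @export
fit_rrm <- function(records, ped, r = 2, Ainv = NULL, n_res_classes = 6,
                    fixed_form = c("legendre", "classes"),
                    start = NULL, control = list()) {
  fixed_form <- match.arg(fixed_form)
  stopifnot(r %in% 0:2)
  control <- utils::modifyList(.fit_control(), control)
  if (is.null(Ainv)) Ainv <- a_inverse_sparse(ped)
  k <- r + 1L
  mme <- .build_mme(records, ped, Ainv, form = fixed_form, r = r, k = k,
                    n_res_classes = n_res_classes)
  vy <- stats::var(records$Re)
  theta0 <- if (is.null(start)) {
    Ka0 <- diag(vy * c(0.8, 0.08, 0.02)[seq_len(k)], k)
    .comp_to_theta(Ka0, 0.3 * vy, 0.1 * vy, rep(0.2 * vy, n_res_classes))
  } else .comp_to_theta(start$Ka, start$sp2, start$sh2, start$se2)
  pin <- integer(0)
  if (max(table(records$cow)) == 1L) {
    warning("single record per cow: permanent-environment variance is not ",
            "identifiable and is pinned at the boundary")
    pin <- k * (k + 1L) %/% 2L + 1L
  }
  res <- .fit_reml(mme, theta0, control, pin = pin)
  cmp <- .theta_to_comp(res$theta, k, n_res_classes)
  sols <- .extract_solutions(res$solution, mme)
  # for r = 0 the animal design is a plain incidence: a flat trajectory
  Phi <- if (k > 1) cn_basis(r) else matrix(1, 9, 1, dimnames = list(1:9, NULL))
  egv <- sols$animal %*% t(Phi)
  colnames(egv) <- 1:9
  n_par <- k * (k + 1) / 2 + 2 + n_res_classes
  comp <- c(pe = cmp$sp2, hys = cmp$sh2,
            stats::setNames(cmp$se2, paste0("residual_", seq_len(n_res_classes))))
  out <- list(model = paste0("ra", r), r = r, Ka = cmp$Ka,
              components = comp,
              logL = res$logL, n_params = as.integer(n_par),
              n_records = mme$n, n_fixed = mme$p,
              converged = res$converged, n_iter = res$n_iter,
              pinned = res$pinned,
              solutions = sols, coefficients = sols$animal, egv = egv)
  class(out) <- "re_fit"
  out
}

#' @export
print.re_fit <- function(x, ...) {
  cat("REML fit:", x$model, "| records:", x$n_records,
      "| logL:", format(x$logL, digits = 10),
      "| converged:", x$converged, "\n")
  if (x$model == "rep") {
    cat("components:\n"); print(round(x$components, 3))
    cat("h2:", round(x$h2, 3), " repeatability:",
        round(x$repeatability, 3), "\n")
  } else {
    cat("Ka:\n"); print(round(x$Ka, 3))
    cat("components:\n"); print(round(x$components, 3))
  }
  invisible(x)
}

#' Genetic-parameter trajectory of a fitted random-regression model
#'
#' Parity-specific genetic variance, total variance, heritability and the
#' full genetic-correlation matrix implied by the fitted covariance
#' function.
#'
#' @param fit \code{re_fit} from [fit_rrm()].
#' @return List: \code{table} (calving, genetic_var, total_var, h2) and
#'   \code{rg} (9x9 genetic correlation matrix).
#' @export
rrm_trajectory <- function(fit) {
  stopifnot(inherits(fit, "re_fit"), fit$model != "rep")
  k <- nrow(fit$Ka)
  Phi <- if (k > 1) cn_basis(k - 1) else matrix(1, 9, 1,
                                                dimnames = list(1:9, NULL))
  se2 <- fit$components[grep("^residual", names(fit$components))]
  ncls <- length(se2)
  vg <- sapply(1:9, function(i) covfun_variance(fit$Ka, Phi[i, ]))
  tot <- vg + fit$components[["pe"]] + fit$components[["hys"]] +
    se2[pmin(1:9, ncls)]
  G <- covfun_matrix(fit$Ka, Phi)
  rg <- suppressWarnings(stats::cov2cor(G))
  list(table = data.frame(calving = 1:9, genetic_var = vg,
                          total_var = as.numeric(tot),
                          h2 = vg / as.numeric(tot)),
       rg = rg)
}

#' Akaike and Bayesian information criteria
#'
#' \eqn{AIC = -2 logL + 2k}; \eqn{BIC = -2 logL + k \ln n} with n the number
#' of records.
#'
#' @param logL REML log-likelihood.
#' @param k Number of variance parameters.
#' @param n Number of records (may be NA for AIC only).
#' @return Named numeric vector (AIC, BIC).
#' @export
information_criteria <- function(logL, k, n = NA) {
  c(AIC = -2 * logL + 2 * k,
    BIC = if (is.na(n)) NA_real_ else -2 * logL + k * log(n))
}

#' Relative importance of variance components
#'
#' Each component as a percentage of their sum.
#'
#' @param components Named non-negative numeric vector.
#' @return Percentages summing to 100.
#' @export
relative_importance <- function(components) {
  tot <- sum(components)
  if (tot <= 0) stop("total variance must be positive")
  100 * components / tot
}

#' Yearly genetic trend
#'
#' Mean EGV by birth year, with counts and SDs — the genetic-progress curve.
#'
#' @param egv Named numeric vector of per-animal EGVs (or one column of an
#'   EGV panel).
#' @param birth_year Named or parallel integer vector of birth years.
#' @return data.frame (year, n, mean_egv, sd_egv) ordered by year.
#' @export
genetic_trend <- function(egv, birth_year) {
  if (!is.null(names(egv)) && !is.null(names(birth_year))) {
    birth_year <- birth_year[names(egv)]
  }
  keep <- !is.na(birth_year)
  sp <- split(egv[keep], birth_year[keep])
  out <- data.frame(
    year = as.integer(names(sp)),
    n = lengths(sp),
    mean_egv = vapply(sp, mean, 0),
    sd_egv = vapply(sp, function(v) if (length(v) > 1) stats::sd(v) else NA_real_, 0))
  rownames(out) <- NULL
  out[order(out$year), ]
}
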