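# Binomial GLMM with a kinship random effect, fitted by penalized
# quasi-likelihood (PQL), and the per-site DMC scan built on it.

#' Additive relationship (kinship) matrix from a pedigree
#'
#' Tabular method: founders have diagonal 1 and 0 off-diagonal;
#' `A[i, j] = 0.5 (A[j, sire_i] + A[j, dam_i])` for j preceding i, and
#' `A[i, i] = 1 + 0.5 A[sire_i, dam_i]`. Parent ids that never occur as
#' individuals are treated as unobserved, unrelated founders and added
#' internally (they are dropped from the returned matrix).
#'
#' @param records `data.frame` with `individual_id` and optional `sire_id`,
#'   `dam_id` columns (a sample sheet works: rows are de-duplicated by
#'   individual).
#' @return Numeric matrix with individual ids as dimnames.
#' @export
kinship_from_pedigree <- function(records) {
  for (col in c("sire_id", "dam_id"))
    if (!col %in% names(records)) records[[col]] <- NA_character_
  ped <- unique(records[, c("individual_id", "sire_id", "dam_id")])
  if (anyDuplicated(ped$individual_id))
    stop("individual listed with conflicting parentage")
  implicit <- setdiff(c(ped$sire_id, ped$dam_id), c(ped$individual_id, NA))
  if (length(implicit))
    ped <- rbind(ped, data.frame(individual_id = implicit,
                                 sire_id = NA_character_,
                                 dam_id = NA_character_))
  n <- nrow(ped)
  ids <- ped$individual_id
  sire <- match(ped$sire_id, ids)
  dam <- match(ped$dam_id, ids)
  # topological order, parents first; failure to make progress = cycle
  placed <- logical(n); ord <- integer(0)
  while (length(ord) < n) {
    ready <- which(!placed &
      (is.na(sire) | placed[ifelse(is.na(sire), 1L, sire)]) &
      (is.na(dam) | placed[ifelse(is.na(dam), 1L, dam)]))
    if (!length(ready)) stop("cyclic pedigree")
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  done <- integer(0)
  for (i in ord) {
    s <- sire[i]; d <- dam[i]
    for (j in done) {
      aij <- 0
      if (!is.na(s)) aij <- aij + 0.5 * A[j, s]
      if (!is.na(d)) aij <- aij + 0.5 * A[j, d]
      A[i, j] <- A[j, i] <- aij
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    done <- c(done, i)
  }
  keep <- match(unique(records$individual_id), ids)
  A[keep, keep, drop = FALSE]
}

#' Expand an individual kinship matrix to sample level
#'
#' Two samples of the same individual (e.g. its muscle and testis) share
#' its genetic random effect, so the sample-level covariance repeats the
#' individual-level entries.
#'
#' @param A Individual kinship matrix from [kinship_from_pedigree()].
#' @param samples Sample sheet with `sample_id` and `individual_id`.
#' @return Samples x samples matrix.
#' @export
expand_kinship <- function(A, samples) {
  idx <- match(samples$individual_id, rownames(A))
  if (anyNA(idx)) stop("individual(s) missing from kinship matrix: ",
                       paste(samples$individual_id[is.na(idx)], collapse = ", "))
  K <- A[idx, idx, drop = FALSE]
  dimnames(K) <- list(samples$sample_id, samples$sample_id)
  K
}

# Satterthwaite effective df per coefficient for the working linear mixed
# model in its rotated basis: cov(zs) = tau D + phi I with
# psi = (tau, phi). df_c = 2 g_c^2 / (grad g_c' H^-1 grad g_c), H the
# numeric REML Hessian in psi. Falls back to the residual df n - p when
# the information is degenerate; clamped to [1, n - p].
.satterthwaite_df <- function(Xs, zs, d, tau, phi, n, p) {
  fallback <- rep(n - p, p)
  negreml <- function(psi) {
    v <- psi[1] * d + psi[2]
    if (any(v <= 1e-10)) return(NA_real_)
    XtVX <- crossprod(Xs, Xs / v)
    bh <- solve(XtVX, crossprod(Xs, zs / v))
    res <- zs - drop(Xs %*% bh)
    0.5 * (sum(log(v)) + determinant(XtVX, logarithm = TRUE)$modulus +
             sum(res^2 / v))
  }
  gfun <- function(psi) {
    v <- psi[1] * d + psi[2]
    diag(solve(crossprod(Xs, Xs / v)))
  }
  psi <- c(tau, phi)
  h <- pmax(abs(psi), 0.05) * 1e-3
  # central differences where the boundary allows, forward otherwise
  lo_ok <- psi - h > 0
  num_hess <- matrix(NA_real_, 2, 2)
  f0 <- negreml(psi)
  for (a in 1:2) {
    ea <- c(0, 0); ea[a] <- h[a]
    if (lo_ok[a]) {
      fp <- negreml(psi + ea); fm <- negreml(psi - ea)
      num_hess[a, a] <- (fp - 2 * f0 + fm) / h[a]^2
    } else {
      fp <- negreml(psi + ea); fpp <- negreml(psi + 2 * ea)
      num_hess[a, a] <- (fpp - 2 * fp + f0) / h[a]^2
    }
  }
  sa <- if (lo_ok[1]) c(-1, 1) else c(0, 1)
  sb <- if (lo_ok[2]) c(-1, 1) else c(0, 1)
  ff <- matrix(NA_real_, 2, 2)
  for (ia in 1:2) for (ib in 1:2)
    ff[ia, ib] <- negreml(psi + c(sa[ia] * h[1], sb[ib] * h[2]))
  num_hess[1, 2] <- num_hess[2, 1] <-
    (ff[2, 2] - ff[2, 1] - ff[1, 2] + ff[1, 1]) /
    ((sa[2] - sa[1]) * h[1] * (sb[2] - sb[1]) * h[2])
  if (anyNA(num_hess)) return(fallback)
  vpsi <- tryCatch(solve(num_hess), error = function(e) NULL)
  if (is.null(vpsi)) return(fallback)
  g0 <- gfun(psi)
  grad <- matrix(0, 2, p)
  for (a in 1:2) {
    ea <- c(0, 0); ea[a] <- h[a]
    grad[a, ] <- if (lo_ok[a])
      (gfun(psi + ea) - gfun(psi - ea)) / (2 * h[a])
    else (gfun(psi + ea) - g0) / h[a]
  }
  df_c <- vapply(seq_len(p), function(c0) {
    denom <- drop(crossprod(grad[, c0], vpsi %*% grad[, c0]))
    if (!is.finite(denom) || denom <= 0) return(n - p)
    2 * g0[c0]^2 / denom
  }, numeric(1))
  pmin(pmax(df_c, 1), n - p)
}

#' Fit a binomial GLMM with kinship by penalized quasi-likelihood
#'
#' Model: `y_i ~ Binomial(r_i, pi_i)`, `logit(pi) = X beta + g`,
#' `g ~ N(0, sigma2 K)`. Each PQL iteration forms the working response
#' `z = eta + (y/r - pi) / (pi (1 - pi))` with weights
#' `w = r pi (1 - pi)`, then fits the Gaussian mixed model
#' `z = X beta + g + e`, `e ~ N(0, W^-1)` exactly via an eigendecomposition
#' of `W^1/2 K W^1/2` (profiled REML-type criterion in `sigma2`, bounded
#' below at 0). Wald p-values use the standard-normal reference.
#'
#' @param y Methylated counts.
#' @param r Total counts (all >= 1).
#' @param X Design matrix, full column rank.
#' @param K Symmetric PSD kinship matrix.
#' @param tol Convergence tolerance on `max(|d beta|, |d sigma2|)`.
#' @param max_iter Maximum PQL iterations.
#' @param sigma2_fixed Fix the variance component (e.g. 0 for the ordinary
#'   GLM limit) instead of estimating it.
#' @param sigma2_max Upper bound of the variance search.
#' @param dispersion `NULL` (default) profiles a multiplicative
#'   quasi-likelihood dispersion out of the working mixed model, which
#'   keeps Wald tests calibrated under extra-binomial variation
#'   (bisulfite counts are overdispersed); a numeric value fixes it
#'   (1 reproduces the pure binomial GLM standard errors when
#'   `sigma2_fixed = 0`).
#' @return List of class `GlmmFit`: `beta`, `se`, `wald_p`, `sigma2_g`,
#'   `dispersion`, `g` (BLUP), `converged`, `n_iter`, `quasi_separated`.
#' @export
fit_binomial_glmm_pql <- function(y, r, X, K, tol = 1e-5, max_iter = 100,
                                  sigma2_fixed = NULL, sigma2_max = 25,
                                  dispersion = NULL) {
  y <- as.numeric(y); r <- as.numeric(r); X <- as.matrix(X)
  n <- length(y)
  stopifnot(length(r) == n, nrow(X) == n, nrow(K) == n, ncol(K) == n)
  if (any(r < 1)) stop("all totals must be >= 1")
  if (any(y < 0) || any(y > r)) stop("need 0 <= y <= r")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  quasi_sep <- all(y == 0) || all(y == r)
  p <- ncol(X)
  eta <- stats::qlogis(pmin(pmax((y + 0.5) / (r + 1), 1e-4), 1 - 1e-4))
  beta <- stats::coef(stats::lm.fit(X, eta))
  eta <- drop(X %*% beta)
  sigma2 <- if (is.null(sigma2_fixed)) 0.1 else sigma2_fixed
  g <- rep(0, n)
  converged <- FALSE
  covb <- NULL
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    pi <- stats::plogis(eta)
    pi <- pmin(pmax(pi, 1e-6), 1 - 1e-6)
    w <- r * pi * (1 - pi)
    z <- eta + (y / r - pi) / (pi * (1 - pi))
    sw <- sqrt(w)
    M <- K * tcrossprod(sw)          # W^1/2 K W^1/2
    eg <- eigen(M, symmetric = TRUE)
    d <- pmax(eg$values, 0)
    U <- eg$vectors
    zs <- drop(crossprod(U, sw * z))
    Xs <- crossprod(U, sw * X)
    # REML-type criterion in the rotated basis; a multiplicative
    # dispersion phi is profiled out unless fixed
    crit <- function(s2) {
      v <- s2 * d + 1
      XtVX <- crossprod(Xs, Xs / v)
      bh <- solve(XtVX, crossprod(Xs, zs / v))
      res <- zs - drop(Xs %*% bh)
      rss <- max(sum(res^2 / v), 1e-12)  # guards separated/degenerate fits
      ldet <- sum(log(v)) + determinant(XtVX, logarithm = TRUE)$modulus
      out <- if (is.null(dispersion))
        0.5 * ((n - p) * log(rss / (n - p)) + ldet)
      else
        0.5 * (ldet + rss / dispersion)
      if (!is.finite(out)) out <- .Machine$double.xmax / 2
      out
    }
    s2 <- if (is.null(sigma2_fixed)) {
      opt <- stats::optimize(crit, c(0, sigma2_max))
      if (crit(0) <= opt$objective) 0 else opt$minimum
    } else sigma2_fixed
    v <- s2 * d + 1
    XtVX <- crossprod(Xs, Xs / v)
    bh <- drop(solve(XtVX, crossprod(Xs, zs / v)))
    rss <- sum((zs - drop(Xs %*% bh))^2 / v)
    phi <- if (is.null(dispersion)) rss / (n - p) else dispersion
    covb <- phi * solve(XtVX)
    resid_s <- (zs - drop(Xs %*% bh)) / v
    gnew <- drop(s2 * (K %*% (sw * drop(U %*% resid_s))))
    db <- max(abs(bh - beta)); ds <- abs(s2 - sigma2)
    beta <- bh; sigma2 <- s2; g <- gnew
    eta <- drop(X %*% beta) + g
    if (db < tol && ds < tol) {
      converged <- TRUE
      break
    }
  }
  se <- sqrt(diag(covb))
  names(beta) <- names(se) <- colnames(X)
  # With estimated variance parameters the Wald statistic is t-like; the
  # effective df per coefficient comes from a Satterthwaite approximation
  # based on the REML information of (tau, phi) = (phi sigma2, phi) at the
  # final working model. With fixed dispersion the standard-normal
  # reference applies (the pure GLM limit).
  if (is.null(dispersion)) {
    df_c <- .satterthwaite_df(Xs, zs, d, tau = phi * sigma2, phi = phi,
                              n = n, p = p)
    wald_p <- 2 * stats::pt(-abs(beta / se), df = df_c)
  } else {
    df_c <- rep(Inf, p)
    wald_p <- 2 * stats::pnorm(-abs(beta / se))
  }
  structure(list(beta = beta, se = se,
                 wald_p = wald_p, df = df_c,
                 sigma2_g = sigma2, dispersion = phi, g = g,
                 converged = converged, n_iter = iter,
                 quasi_separated = quasi_sep),
            class = "GlmmFit")
}

#' @export
print.GlmmFit <- function(x, ...) {
  cat("Binomial GLMM (PQL): sigma2_g =", signif(x$sigma2_g, 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(data.frame(beta = x$beta, se = x$se, wald_p = x$wald_p))
  invisible(x)
}

#' Scan all sites for differential methylation against a design factor
#'
#' Per retained site, tests the two-level `factor` column of the sample
#' sheet either with the kinship-aware binomial GLMM (method `"pql"`; age
#' in years enters as a covariate by default, matching the analysis model)
#' or with the pooled beta-posterior minimum-difference test
#' (method `"mindiff"`).
#'
#' @param mat A filtered `MethCountMatrix`.
#' @param samples Sample sheet covering the matrix columns.
#' @param factor Sheet column to test; must have exactly 2 levels among the
#'   scanned samples.
#' @param covariates Sheet columns used as fixed covariates for `"pql"`
#'   (default `"age_years"`; set `NULL` for none).
#' @param method `"pql"` or `"mindiff"`.
#' @param alpha Significance threshold (default 0.01).
#' @param delta Minimum level difference for `"mindiff"` (default 0.3).
#' @param kinship Optional precomputed sample-level kinship; derived from
#'   the sheet's pedigree columns when `NULL`.
#' @param min_per_group Minimum samples per factor level (default 2).
#' @param grid_n Quadrature size for `"mindiff"`.
#' @param keep_all Return all tested sites, not only the significant ones.
#' @return `data.frame` of DMC results: site columns, `estimate_logit`
#'   (PQL beta for the factor; `NA` for mindiff), `level_diff` (group B
#'   minus group A observed/posterior mean difference), `direction`
#'   (`"up"` when the second factor level is higher), `p_value`, `method`.
#'   Attributes: `n_tested`, `n_skipped`, `factor_levels`.
#' @export
dmc_scan <- function(mat, samples, factor, covariates = "age_years",
                     method = c("pql", "mindiff"), alpha = 0.01,
                     delta = 0.3, kinship = NULL, min_per_group = 2,
                     grid_n = 512, keep_all = FALSE) {
  method <- match.arg(method)
  samples <- samples[match(mat$samples, samples$sample_id), ]
  f <- samples[[factor]]
  if (is.null(f)) stop("factor '", factor, "' is not a sample-sheet column")
  levs <- sort(unique(f))
  if (length(levs) < 2) stop("factor '", factor, "' is constant")
  if (length(levs) > 2) stop("factor '", factor, "' has more than 2 levels")
  idx_a <- which(f == levs[1]); idx_b <- which(f == levs[2])
  if (length(idx_a) < min_per_group || length(idx_b) < min_per_group)
    stop("each '", factor, "' group needs at least ", min_per_group,
         " samples")
  if (method == "mindiff") {
    res <- .mindiff_scan(mat, idx_a, idx_b, delta, alpha, grid_n)
    out <- data.frame(res[, c("chrom", "pos", "strand")],
                      estimate_logit = NA_real_,
                      level_diff = res$level_diff,
                      direction = res$direction,
                      p_value = res$p_small,
                      is_dmc = res$is_dmc,
                      method = "mindiff", stringsAsFactors = FALSE)
    skipped <- sum(is.na(res$p_small))
  } else {
    if (is.null(kinship)) {
      A <- kinship_from_pedigree(samples)
      kinship <- expand_kinship(A, samples)
    }
    xcols <- cbind(`(Intercept)` = 1,
                   grp = as.numeric(f == levs[2]))
    for (cv in covariates) {
      v <- samples[[cv]]
      if (is.null(v)) stop("covariate '", cv, "' is not a sheet column")
      if (length(unique(v)) > 1) xcols <- cbind(xcols, as.numeric(v))
    }
    colnames(xcols) <- c("(Intercept)", "grp",
                         if (ncol(xcols) > 2)
                           covariates[seq_len(ncol(xcols) - 2)])
    lv <- meth_levels(mat)
    n <- nrow(mat$sites)
    pval <- rep(NA_real_, n); est <- rep(NA_real_, n)
    ldiff <- rowMeans(lv[, idx_b, drop = FALSE], na.rm = TRUE) -
      rowMeans(lv[, idx_a, drop = FALSE], na.rm = TRUE)
    skipped <- 0L
    for (i in seq_len(n)) {
      obs <- which(!is.na(mat$total[i, ]))
      if (sum(obs %in% idx_a) < min_per_group ||
          sum(obs %in% idx_b) < min_per_group) {
        skipped <- skipped + 1L
        next
      }
      yi <- mat$meth[i, obs]; ri <- mat$total[i, obs]
      Xi <- xcols[obs, , drop = FALSE]
      # zero-variance sites carry no information for the working model
      if (length(unique(yi / ri)) == 1L) {
        skipped <- skipped + 1L
        next
      }
      fit <- tryCatch(
        fit_binomial_glmm_pql(yi, ri, Xi, kinship[obs, obs, drop = FALSE]),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        skipped <- skipped + 1L
        next
      }
      pval[i] <- fit$wald_p["grp"]
      est[i] <- fit$beta["grp"]
    }
    out <- data.frame(mat$sites,
                      estimate_logit = est,
                      level_diff = ldiff,
                      direction = ifelse(est >= 0, "up", "down"),
                      p_value = pval,
                      is_dmc = !is.na(pval) & pval <= alpha,
                      method = "pql", stringsAsFactors = FALSE)
  }
  attr(out, "n_tested") <- sum(!is.na(out$p_value))
  attr(out, "n_skipped") <- skipped
  attr(out, "factor_levels") <- levs
  if (!keep_all) {
    att <- attributes(out)
    out <- out[out$is_dmc, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_tested") <- att$n_tested
    attr(out, "n_skipped") <- att$n_skipped
    attr(out, "factor_levels") <- att$factor_levels
  }
  out
}
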