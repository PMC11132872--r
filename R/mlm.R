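#' @importFrom stats optimize optim pchisq pnorm qnorm cor cor.test sd var
NULL

# REML log-likelihood for y = Xb + g + e with V = sg2 (A + delta I),
# on the eigenbasis of A. Returns the profile over log(delta).
# eig: list(values, vectors); ystar, Xstar already rotated.
.reml_ll <- function(log_delta, d, ystar, Xstar) {
  delta <- exp(log_delta)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xstar * w, Xstar)
  XtWy <- crossprod(Xstar * w, ystar)
  bh <- solve(XtWX, XtWy)
  r <- ystar - Xstar %*% bh
  n <- length(ystar); p <- ncol(Xstar)
  sg2 <- sum(w * r^2) / (n - p)
  -0.5 * ((n - p) * log(sg2) + sum(log(d + delta)) +
          determinant(XtWX, logarithm = TRUE)$modulus[1] + (n - p))
}

# fit variance components by REML given eigen(A); returns delta, sg2, se2, ll
.reml_fit <- function(d, ystar, Xstar) {
  opt <- optimize(function(ld) .reml_ll(ld, d, ystar, Xstar),
                  interval = c(-10, 12), maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  w <- 1 / (d + delta)
  bh <- solve(crossprod(Xstar * w, Xstar), crossprod(Xstar * w, ystar))
  r <- ystar - Xstar %*% bh
  sg2 <- sum(w * r^2) / (length(ystar) - ncol(Xstar))
  list(delta = delta, sg2 = sg2, se2 = sg2 * delta,
       h2 = 1 / (1 + delta), ll = opt$objective)
}

#' Precompute leave-one-chromosome-out rotations
#'
#' For each chromosome, eigendecomposes the LOCO GRM (ridge-regularizing a
#' non-positive-definite matrix with a logged epsilon) and rotates the
#' intercept and that chromosome's dosage columns into the eigenbasis, so
#' repeated association scans (many phenotypes, as in eQTL mapping) reuse
#' the expensive part.
#'
#' @param g \linkS4class{GenotypeMatrix}.
#' @param grms named list of per-chromosome LOCO GRMs
#'   (see \code{\link{locoGRMs}}).
#' @return list keyed by chromosome with eigenvalues, rotated intercept,
#'   rotated genotypes, rotation matrix and variant indices.
#' @export
locoRotations <- function(g, grms) {
  vi <- variantInfo(g)
  d <- imputeMean(dosages(g))
  out <- list()
  for (ch in names(grms)) {
    A <- grms[[ch]]
    eig <- eigen(unclass(A), symmetric = TRUE)
    if (min(eig$values) < 1e-8) {
      eps <- abs(min(eig$values)) + 1e-6
      message("GRM for ", ch, " not positive definite; adding ridge ",
              format(eps, digits = 3))
      eig$values <- eig$values + eps
    }
    idx <- which(vi$chrom == ch)
    Ut <- t(eig$vectors)
    out[[ch]] <- list(d = eig$values, Ut = Ut,
                      ones = Ut %*% rep(1, nrow(A)),
                      G = Ut %*% d[, idx, drop = FALSE],
                      idx = idx)
  }
  out
}

#' Mixed-linear-model association with LOCO kinship
#'
#' For each variant fits \eqn{y = \mu + x\beta + g + e} with the polygenic
#' term \eqn{g \sim N(0, \sigma^2_g A_{LOCO})}, where the kinship matrix
#' excludes the tested variant's chromosome. Variance components are
#' estimated once per chromosome by REML on the null model (profile
#' likelihood over the variance ratio on the GRM eigenbasis); each variant
#' is then tested by generalized least squares at those components. Setting
#' \code{per_variant_reml = TRUE} re-estimates the variance components for
#' every variant (exact, much slower; at an identity GRM this reproduces
#' ordinary least squares exactly).
#'
#' @param g \linkS4class{GenotypeMatrix}.
#' @param y named phenotype vector (accession ids); NAs dropped.
#' @param grms named per-chromosome list of LOCO GRMs.
#' @param rot optional precomputed \code{\link{locoRotations}} (must match
#'   \code{g}, \code{grms} and a phenotype with no missing values).
#' @param per_variant_reml re-estimate variance components per variant.
#' @return data.frame with id, chrom, pos, maf, beta, se, t, p and a
#'   \code{flag} column ("monomorphic" rows carry NA statistics).
#' @export
fitMLMLoco <- function(g, y, grms, rot = NULL, per_variant_reml = FALSE) {
  acc <- accessionInfo(g)$id
  if (!is.null(names(y))) y <- y[acc]
  keep <- !is.na(y)
  if (!all(keep)) {
    g <- g[which(keep), ]
    y <- y[keep]
    rot <- NULL
    grms <- lapply(grms, function(A) {
      out <- unclass(A)[keep, keep]
      out
    })
  }
  if (stats::sd(y) == 0) stop("phenotype is constant")
  vi <- variantInfo(g)
  if (is.null(rot)) rot <- locoRotations(g, grms)
  res <- vector("list", length(rot))
  for (ci in seq_along(rot)) {
    ro <- rot[[ci]]
    ystar <- ro$Ut %*% y
    fit <- .reml_fit(ro$d, ystar, ro$ones)
    w <- 1 / (fit$sg2 * (ro$d + fit$delta))
    S11 <- sum(w * ro$ones^2)
    S1y <- sum(w * ro$ones * ystar)
    wG <- ro$G * w
    Sxx <- colSums(ro$G * wG)
    Sxy <- colSums(wG * as.vector(ystar))
    Sx1 <- colSums(wG * as.vector(ro$ones))
    denom <- Sxx - Sx1^2 / S11
    beta <- (Sxy - Sx1 * S1y / S11) / denom
    se <- sqrt(1 / denom)
    flag <- rep("", length(ro$idx))
    bad <- is.na(vi$maf[ro$idx]) | vi$maf[ro$idx] == 0 | denom <= 1e-12
    beta[bad] <- NA; se[bad] <- NA
    flag[bad] <- "monomorphic"
    if (per_variant_reml) {
      for (k in which(!bad)) {
        X2 <- cbind(ro$ones, ro$G[, k])
        f2 <- .reml_fit(ro$d, ystar, X2)
        w2 <- 1 / (f2$sg2 * (ro$d + f2$delta))
        XtWX <- crossprod(X2 * w2, X2)
        bh <- solve(XtWX, crossprod(X2 * w2, ystar))
        beta[k] <- bh[2]
        se[k] <- sqrt(solve(XtWX)[2, 2])
      }
    }
    tv <- beta / se
    res[[ci]] <- data.frame(
      id = vi$id[ro$idx], chrom = as.character(vi$chrom[ro$idx]),
      pos = vi$pos[ro$idx], maf = vi$maf[ro$idx],
      beta = beta, se = se, t = tv,
      p = pchisq(tv^2, 1, lower.tail = FALSE), flag = flag)
  }
  out <- do.call(rbind, res)
  out <- out[order(match(out$id, vi$id)), ]
  rownames(out) <- NULL
  out
}

#' Effective number of independent tests and Bonferroni threshold
#'
#' simpleM-style: per chromosome, the LD correlation matrix is examined in
#' sliding (non-overlapping) windows; the effective test count of a window
#' is the number of leading eigenvalues needed to reach
#' \code{trace_frac} of the trace, summed over windows and chromosomes.
#'
#' @param g \linkS4class{GenotypeMatrix} (pruned or full).
#' @param window window size in variants (200).
#' @param trace_frac fraction of the eigenvalue trace (0.995).
#' @param alpha family-wise error rate for the threshold (0.05).
#' @return list with \code{m_eff} and \code{threshold} = alpha / m_eff.
#' @export
effectiveTests <- function(g, window = 200, trace_frac = 0.995,
                           alpha = 0.05) {
  vi <- variantInfo(g)
  d <- dosages(g)
  m_eff <- 0
  for (chr in unique(as.character(vi$chrom))) {
    idx <- which(vi$chrom == chr & !is.na(vi$maf) & vi$maf > 0)
    if (length(idx) == 0) next
    starts <- seq(1, length(idx), by = window)
    for (s in starts) {
      win <- idx[s:min(s + window - 1, length(idx))]
      if (length(win) == 1) { m_eff <- m_eff + 1; next }
      std <- .std_dosage(d[, win, drop = FALSE])
      cc <- crossprod(std) / (nrow(std) - 1)
      ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
      ev <- pmax(ev, 0)
      k <- which(cumsum(ev) >= trace_frac * sum(ev))[1]
      m_eff <- m_eff + k
    }
  }
  if (m_eff == 0) stop("no polymorphic variants")
  list(m_eff = m_eff, threshold = alpha / m_eff)
}

#' Greedy LD-based result clumping
#'
#' Repeatedly takes the most significant unassigned variant with
#' \code{p <= p1} as a lead, and assigns to its locus every unassigned
#' variant with \code{p <= p2}, within \code{kb} kilobases, and
#' r^2 >= \code{r2} with the lead. Ties on p break by (chrom, pos).
#'
#' @param results association data.frame (id, chrom, pos, p).
#' @param g \linkS4class{GenotypeMatrix} supplying LD.
#' @param p1 lead significance threshold.
#' @param p2 member threshold (0.01).
#' @param r2 LD threshold (0.5).
#' @param kb radius in kb (500).
#' @return data.frame of loci: lead id, chrom, pos, p, n_members, span, and
#'   a list-column \code{members} of member variant ids (lead included).
#' @export
clumpResults <- function(results, g, p1, p2 = 0.01, r2 = 0.5, kb = 500) {
  res <- results[!is.na(results$p), ]
  vi <- variantInfo(g)
  d <- imputeMean(dosages(g))
  cand <- res[res$p <= p2, ]
  cand <- cand[order(cand$p, cand$chrom, cand$pos), ]
  assigned <- rep(FALSE, nrow(cand))
  loci <- list()
  repeat {
    lead_i <- which(!assigned & cand$p <= p1)[1]
    if (is.na(lead_i)) break
    lead <- cand[lead_i, ]
    jlead <- match(lead$id, vi$id)
    near <- which(!assigned & cand$chrom == lead$chrom &
                  abs(cand$pos - lead$pos) <= kb * 1000)
    xl <- d[, jlead]
    mem <- vapply(near, function(i) {
      j <- match(cand$id[i], vi$id)
      if (j == jlead) return(TRUE)
      if (stats::sd(d[, j]) == 0 || stats::sd(xl) == 0) return(FALSE)
      stats::cor(xl, d[, j])^2 >= r2
    }, logical(1))
    members <- near[mem]
    assigned[members] <- TRUE
    assigned[lead_i] <- TRUE
    ids <- unique(c(lead$id, cand$id[members]))
    loci[[length(loci) + 1]] <- data.frame(
      lead = lead$id, chrom = lead$chrom, pos = lead$pos, p = lead$p,
      n_members = length(ids),
      start = min(cand$pos[members], lead$pos),
      end = max(cand$pos[members], lead$pos),
      members = I(list(ids)))
  }
  if (length(loci) == 0) {
    return(data.frame(lead = character(), chrom = character(),
                      pos = integer(), p = numeric(), n_members = integer(),
                      start = integer(), end = integer(),
                      members = I(list())))
  }
  do.call(rbind, loci)
}

#' Bivariate REML genetic correlation
#'
#' Fits the two-trait mixed model with a shared GRM: genetic covariance
#' matrix \eqn{V_g} and residual covariance \eqn{V_e} (each 2x2) are
#' estimated by restricted maximum likelihood on the GRM eigenbasis, where
#' the covariance of each rotated observation pair is the 2x2 block
#' \eqn{d_i V_g + V_e}. Parametrized by log-Cholesky factors and maximized
#' with quasi-Newton iterations; the genetic correlation
#' \eqn{r_g = V_{g,12}/\sqrt{V_{g,11} V_{g,22}}} gets a standard error from
#' the inverse information (numerical Hessian) by the delta method.
#'
#' @param y1,y2 named phenotype vectors (both traits on the same
#'   accessions; only the shared non-missing set is used).
#' @param grm whole-genome GRM matrix.
#' @param max_iter maximum optimizer iterations (200).
#' @return list: \code{Vg}, \code{Ve}, \code{rg}, \code{se_rg},
#'   \code{h2} (per trait), \code{converged}, \code{loglik}.
#' @export
bivariateGREML <- function(y1, y2, grm, max_iter = 200) {
  ids <- intersect(names(y1), names(y2))
  ids <- ids[!is.na(y1[ids]) & !is.na(y2[ids])]
  A <- unclass(grm)[ids, ids]
  y1 <- as.numeric(scale(y1[ids])); y2 <- as.numeric(scale(y2[ids]))
  n <- length(ids)
  eig <- eigen(A, symmetric = TRUE)
  d <- pmax(eig$values, 1e-8)
  Ut <- t(eig$vectors)
  Y <- cbind(Ut %*% y1, Ut %*% y2)
  u <- as.vector(Ut %*% rep(1, n))
  chol2 <- function(th) {
    L <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2, 2)
    tcrossprod(L)
  }
  negll <- function(th) {
    if (any(!is.finite(th)) || any(abs(th) > 30)) return(1e10)
    Vg <- chol2(th[1:3]); Ve <- chol2(th[4:6])
    # per-eigenvalue 2x2 blocks d_i Vg + Ve, inverted in closed form
    s11 <- d * Vg[1, 1] + Ve[1, 1]
    s12 <- d * Vg[1, 2] + Ve[1, 2]
    s22 <- d * Vg[2, 2] + Ve[2, 2]
    det <- s11 * s22 - s12^2
    if (any(!is.finite(det)) || any(det <= 0) || any(s11 <= 0)) return(1e10)
    i11 <- s22 / det; i12 <- -s12 / det; i22 <- s11 / det
    ll <- -0.5 * sum(log(det))
    u2 <- u^2
    XtVX <- matrix(c(sum(u2 * i11), sum(u2 * i12),
                     sum(u2 * i12), sum(u2 * i22)), 2, 2)
    XtVy <- c(sum(u * (i11 * Y[, 1] + i12 * Y[, 2])),
              sum(u * (i12 * Y[, 1] + i22 * Y[, 2])))
    detX <- XtVX[1, 1] * XtVX[2, 2] - XtVX[1, 2]^2
    if (!is.finite(detX) || detX <= 1e-12) return(1e10)
    bh <- c(XtVX[2, 2] * XtVy[1] - XtVX[1, 2] * XtVy[2],
            -XtVX[1, 2] * XtVy[1] + XtVX[1, 1] * XtVy[2]) / detX
    r1 <- Y[, 1] - u * bh[1]; r2 <- Y[, 2] - u * bh[2]
    q <- sum(i11 * r1^2 + 2 * i12 * r1 * r2 + i22 * r2^2)
    nll <- -(ll - 0.5 * determinant(XtVX, logarithm = TRUE)$modulus[1] -
             0.5 * q)
    if (!is.finite(nll)) 1e10 else nll
  }
  # log-Cholesky parameters reproducing a target 2x2 covariance
  theta_of <- function(S) {
    S <- S + diag(2) * 1e-4
    L <- t(chol(S))
    c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
  }
  S <- cov(cbind(y1, y2))
  inits <- list(c(theta_of(S / 2), theta_of(S / 2)),
                c(theta_of(S * 0.05), theta_of(S * 0.95)),
                c(theta_of(S * 0.95), theta_of(S * 0.05)))
  opt <- NULL
  for (init in inits) {
    o <- optim(init, negll, method = "Nelder-Mead",
               control = list(maxit = max_iter * 10, reltol = 1e-10))
    o <- optim(o$par, negll, method = "BFGS", hessian = TRUE,
               control = list(maxit = max_iter))
    if (is.null(opt) || o$value < opt$value) opt <- o
  }
  th <- opt$par
  Vg <- chol2(th[1:3]); Ve <- chol2(th[4:6])
  rg <- Vg[1, 2] / sqrt(Vg[1, 1] * Vg[2, 2])
  # delta method through the numerical Hessian
  se_rg <- NA_real_
  H <- opt$hessian
  ok <- all(is.finite(H))
  if (ok) {
    Vpar <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vpar)) {
      grad <- numeric(6)
      h <- 1e-5
      for (k in 1:6) {
        tp <- th; tp[k] <- tp[k] + h
        Vgp <- chol2(tp[1:3])
        rp <- Vgp[1, 2] / sqrt(Vgp[1, 1] * Vgp[2, 2])
        grad[k] <- (rp - rg) / h
      }
      v <- drop(t(grad) %*% Vpar %*% grad)
      if (is.finite(v) && v >= 0) se_rg <- sqrt(v)
    }
  }
  h2 <- c(Vg[1, 1] / (Vg[1, 1] + Ve[1, 1]), Vg[2, 2] / (Vg[2, 2] + Ve[2, 2]))
  list(Vg = Vg, Ve = Ve, rg = rg, se_rg = se_rg, h2 = h2,
       converged = opt$convergence == 0, loglik = -opt$value)
}

#' Cross-trait correlation of signed t statistics
#'
#' Pearson correlation of per-variant signed t-values (beta / se) between
#' two association result sets over their shared variants.
#'
#' @param res_a,res_b association data.frames from
#'   \code{\link{fitMLMLoco}}.
#' @return list with \code{r}, \code{p} and \code{n_shared}.
#' @export
signedTCorrelation <- function(res_a, res_b) {
  m <- merge(res_a[!is.na(res_a$t), c("id", "t")],
             res_b[!is.na(res_b$t), c("id", "t")], by = "id")
  if (nrow(m) < 3) stop("fewer than 3 shared variants")
  ct <- cor.test(m$t.x, m$t.y)
  list(r = unname(ct$estimate), p = ct$p.value, n_shared = nrow(m))
}
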