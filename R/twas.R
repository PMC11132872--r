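#' Cis heritability of gene expression
#'
#' REML fit of a single variance component on the cis-variant GRM
#' (gene span plus \code{window} flanking), with a likelihood-ratio test
#' against zero heritability using the boundary-corrected half-half
#' chi-square mixture.
#'
#' @param gene gene id.
#' @param g \linkS4class{GenotypeMatrix}.
#' @param expr_vec named expression vector for the gene (will be quantile
#'   normalized unless \code{normalize = FALSE}).
#' @param gene_coords GRanges or data.frame with gene, chrom, start, end.
#' @param window cis window in bp (5e5).
#' @param min_cis minimum cis variant count (30).
#' @param normalize quantile-normalize the expression first (TRUE).
#' @return list: \code{h2}, \code{p}, \code{n_cis}, \code{cis_ids}; NULL
#'   (with a message) when the gene has too few cis variants or a
#'   degenerate cis GRM.
#' @export
cisH2 <- function(gene, g, expr_vec, gene_coords, window = 5e5,
                  min_cis = 30, normalize = TRUE) {
  cis <- cisVariants(gene, g, gene_coords, window)
  if (length(cis) < min_cis) {
    message("gene ", gene, ": only ", length(cis), " cis variants; skipped")
    return(NULL)
  }
  y <- expr_vec[accessionInfo(g)$id]
  if (normalize) y <- quantileNormalize(y)
  K <- buildGRM(g[, cis], maf_min = 0, min_variants = 2)
  eig <- tryCatch(eigen(unclass(K), symmetric = TRUE),
                  error = function(e) NULL)
  if (is.null(eig) || max(eig$values) <= 1e-10) {
    message("gene ", gene, ": degenerate cis GRM; skipped")
    return(NULL)
  }
  eig$values <- pmax(eig$values, 1e-10)
  Ut <- t(eig$vectors)
  ystar <- Ut %*% y
  ones <- Ut %*% rep(1, length(y))
  fit <- .reml_fit(eig$values, ystar, ones)
  # null (h2 = 0, i.e. delta -> infinity) is the iid-residual REML, which
  # is the exact limit of the alternative's restricted likelihood
  n <- length(y); p <- 1
  r0 <- ystar - ones %*% solve(crossprod(ones), crossprod(ones, ystar))
  s0 <- sum(r0^2) / (n - p)
  ll0 <- -0.5 * ((n - p) * log(s0) +
                 determinant(crossprod(ones), logarithm = TRUE)$modulus[1] +
                 (n - p))
  lrt <- max(0, 2 * (fit$ll - ll0))
  pval <- 0.5 * stats::pchisq(lrt, 1, lower.tail = FALSE)
  list(h2 = fit$h2, p = pval, n_cis = length(cis), cis_ids = cis)
}

#' Cis variant ids for a gene
#'
#' @param gene gene id.
#' @param g \linkS4class{GenotypeMatrix}.
#' @param gene_coords GRanges or data.frame (gene, chrom, start, end).
#' @param window flanking window in bp (5e5).
#' @return character vector of variant ids in the window, polymorphic only.
#' @export
cisVariants <- function(gene, g, gene_coords, window = 5e5) {
  gc <- if (inherits(gene_coords, "GRanges")) {
    data.frame(gene = gene_coords$gene,
               chrom = as.character(GenomicRanges::seqnames(gene_coords)),
               start = GenomicRanges::start(gene_coords),
               end = GenomicRanges::end(gene_coords))
  } else gene_coords
  i <- match(gene, gc$gene)
  if (is.na(i)) stop("unknown gene id ", gene)
  vi <- variantInfo(g)
  vi$id[vi$chrom == gc$chrom[i] & vi$pos >= gc$start[i] - window &
        vi$pos <= gc$end[i] + window & !is.na(vi$maf) & vi$maf > 0]
}

# one model's weight fit on (X, y); returns weight vector over ncol(X)
.fit_one_model <- function(model, X, y, seed) {
  m <- ncol(X)
  w <- numeric(m)
  if (model == "top1") {
    z <- abs(crossprod(X, y)) / sqrt(colSums(X^2))
    j <- which.max(z)
    w[j] <- sum(X[, j] * y) / sum(X[, j]^2)
  } else if (model == "blup") {
    # ridge with lambda from the REML variance ratio of the cis GRM
    K <- tcrossprod(X) / m
    eig <- eigen(K, symmetric = TRUE)
    eig$values <- pmax(eig$values, 1e-10)
    Ut <- t(eig$vectors)
    fit <- .reml_fit(eig$values, Ut %*% y, Ut %*% rep(1, length(y)))
    lambda <- m * fit$delta
    w <- drop(solve(crossprod(X) + lambda * diag(m), crossprod(X, y)))
  } else {
    alpha <- if (model == "lasso") 1 else 0.5
    set.seed(seed)
    cv <- glmnet::cv.glmnet(X, y, alpha = alpha, nfolds = 5,
                            standardize = FALSE)
    w <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
  }
  w
}

#' Fit TWAS expression weights with cross-validated model selection
#'
#' Fits the candidate weight models on standardized cis dosages: marginal
#' top variant (top1), ridge BLUP with the REML shrinkage, lasso and
#' elastic net (mixing 0.5). Each model's predictive R-squared
#' (1 - SSE/SST) is measured by k-fold cross-validation with shared folds;
#' the best model is refit on the full data. Genes where no model predicts
#' (all cv R-squared <= 0) are dropped.
#'
#' @param gene gene id.
#' @param g \linkS4class{GenotypeMatrix}.
#' @param expr_vec named expression vector.
#' @param gene_coords GRanges or data.frame of gene spans.
#' @param models candidate models.
#' @param k_folds folds (5).
#' @param window cis window (5e5).
#' @param seed RNG seed (fold assignment and glmnet CV).
#' @param normalize quantile-normalize expression first (TRUE).
#' @return list: \code{gene}, \code{model} (selected), \code{weights}
#'   (named by variant), \code{cv_r2} (per model), \code{cis_ids}; NULL if
#'   the gene is dropped.
#' @export
fitWeights <- function(gene, g, expr_vec,
                       gene_coords, models = c("top1", "blup", "lasso",
                                               "enet"),
                       k_folds = 5, window = 5e5, seed = 1L,
                       normalize = TRUE) {
  cis <- cisVariants(gene, g, gene_coords, window)
  if (length(cis) < 2) return(NULL)
  y <- expr_vec[accessionInfo(g)$id]
  if (normalize) y <- quantileNormalize(y)
  y <- as.numeric(scale(y))
  X <- .std_dosage(dosages(g)[, cis, drop = FALSE])
  n <- length(y)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k_folds), n))
  cv_r2 <- stats::setNames(numeric(length(models)), models)
  for (mod in models) {
    pred <- numeric(n)
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      w <- .fit_one_model(mod, X[tr, , drop = FALSE], y[tr], seed + f)
      pred[!tr] <- X[!tr, , drop = FALSE] %*% w
    }
    cv_r2[mod] <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  }
  if (all(cv_r2 <= 0)) {
    message("gene ", gene, ": no model predicts (all cv R2 <= 0); dropped")
    return(NULL)
  }
  best <- names(which.max(cv_r2))
  w <- .fit_one_model(best, X, y, seed)
  names(w) <- cis
  list(gene = gene, model = best, weights = w, cv_r2 = cv_r2,
       cis_ids = cis)
}

#' TWAS Z statistic from expression weights and GWAS summary statistics
#'
#' \eqn{z = w^T z_{gwas} / \sqrt{w^T R w}} where R is the LD correlation of
#' the weighted variants in the reference genotype panel. R is
#' ridge-regularized (\code{R + ridge I}, then rescaled to unit diagonal)
#' before forming the quadratic form, so a single-indicator weight vector
#' reproduces that variant's GWAS z exactly. Weighted variants missing
#' from the GWAS results have their weight zeroed with a warning.
#'
#' @param weights list from \code{\link{fitWeights}} (or a named weight
#'   vector).
#' @param gwas_results association data.frame with id and t (signed z).
#' @param ld_ref \linkS4class{GenotypeMatrix} LD reference.
#' @param ridge regularization constant (0.1).
#' @return list: \code{gene}, \code{z}, \code{p}, plus the lead GWAS
#'   variant in the weighted set and its p when present in
#'   \code{gwas_results}.
#' @export
twasZ <- function(weights, gwas_results, ld_ref, ridge = 0.1) {
  w <- if (is.list(weights)) weights$weights else weights
  gene <- if (is.list(weights)) weights$gene else NA_character_
  w <- w[w != 0]
  if (length(w) == 0) stop("empty weight vector")
  zmap <- stats::setNames(gwas_results$t, gwas_results$id)
  miss <- !(names(w) %in% names(zmap)) | is.na(zmap[names(w)])
  if (any(miss)) {
    warning(sum(miss), " weighted variants missing from GWAS results; ",
            "weights zeroed")
    w <- w[!miss]
    if (length(w) == 0) stop("no weighted variants with GWAS z-scores")
  }
  z_gwas <- zmap[names(w)]
  vi <- variantInfo(ld_ref)
  X <- .std_dosage(dosages(ld_ref)[, match(names(w), vi$id), drop = FALSE])
  R <- crossprod(X) / (nrow(X) - 1)
  if (ridge > 0) {
    R <- R + ridge * diag(nrow(R))
    R <- stats::cov2cor(R)
  }
  denom <- drop(t(w) %*% R %*% w)
  if (denom <= 0) stop("non-positive quadratic form; gene skipped")
  z <- drop(sum(w * z_gwas)) / sqrt(denom)
  pg <- gwas_results[match(names(w), gwas_results$id), ]
  lead <- pg[which.min(pg$p), ]
  list(gene = gene, z = z, p = 2 * stats::pnorm(-abs(z)),
       lead_gwas_id = lead$id, lead_gwas_p = lead$p)
}

#' Candidate-gene calls from TWAS (and optionally eGWAS) Z-scores
#'
#' Retains genes with |Z| at or above \code{z_min} per trait; when an
#' eGWAS Z column is present and \code{joint = TRUE} the rule is applied to
#' both scores jointly.
#'
#' @param twas_results data.frame with trait, gene, z (TWAS) and optional
#'   egwas_z, lead GWAS columns.
#' @param z_min threshold (3).
#' @param joint require both TWAS and eGWAS |Z| >= z_min when egwas_z is
#'   available (TRUE).
#' @return the candidate subset, with a per-trait count in attribute
#'   \code{"counts"}.
#' @export
callCandidates <- function(twas_results, z_min = 3, joint = TRUE) {
  keep <- abs(twas_results$z) >= z_min
  if (joint && "egwas_z" %in% colnames(twas_results)) {
    keep <- keep & abs(twas_results$egwas_z) >= z_min
  }
  out <- twas_results[keep, , drop = FALSE]
  attr(out, "counts") <- table(out$trait)
  out
}

#' Published TWAS candidate-gene table fixture
#'
#' Loads the packaged candidate-gene table (22 rows: trait, gene, lead
#' GWAS SNP, GWAS p, TWAS Z, TWAS p, annotation) used for bookkeeping
#' checks of the |Z| >= 3 candidate rule.
#'
#' @return data.frame.
#' @export
readCandidateTable <- function() {
  path <- system.file("extdata", "twas_published_candidates.tsv", package = "seedomics")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
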