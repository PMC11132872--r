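# one fastICA run: symmetric fixed-point iteration with logcosh contrast
# Z: whitened data (genes x k, unit-variance uncorrelated columns)
.fastica_once <- function(Z, k, maxit = 200, tol = 1e-4) {
  n <- nrow(Z)
  W <- matrix(rnorm(k * k), k, k)
  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    S <- Z %*% W                      # genes x k sources
    G <- tanh(S)
    Gp <- 1 - G^2
    W_new <- crossprod(Z, G) / n - W %*% diag(colMeans(Gp), k, k)
    W_new <- sym_orth(W_new)
    delta <- max(abs(abs(colSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(W = W, converged = converged)
}

#' Independent-component-analysis coexpression modules
#'
#' Decomposes a centered, standardized expression matrix (genes x
#' accessions) into statistically independent gene-weight vectors and their
#' per-accession eigen-expression profiles. The component count is the
#' smallest number of principal components explaining at least
#' \code{var_cutoff} percent of the variance. The fastICA fixed-point
#' algorithm (logcosh contrast, symmetric decorrelation, iterated to
#' convergence) is run \code{n_runs} times from seeded random rotations,
#' allowing up to \code{max_iter} re-initializations per run when the
#' fixed point does not stabilize; components are matched across runs by
#' absolute correlation of gene weights, sign-aligned, and averaged over
#' the well-matched (converged) runs, with a per-component stability index
#' (mean matched |r|).
#' Signs are fixed so each component's weight skewness is positive; module
#' membership is |weight| above \code{member_sd} standard deviations.
#'
#' @param expr_mat numeric matrix, genes x accessions (e.g. log TPM of
#'   filtered genes).
#' @param var_cutoff percent variance for choosing the component count
#'   (70).
#' @param max_iter maximum random re-initializations per run before the
#'   last (possibly unconverged) attempt is accepted (10).
#' @param n_runs independent restarts (15).
#' @param member_sd membership cutoff in weight SDs (2).
#' @param seed RNG seed.
#' @return object of class \code{ICAResult}: list with \code{weights}
#'   (genes x k), \code{eigen} (k x accessions eigen-expression,
#'   standardized), \code{members} (list of gene-id vectors),
#'   \code{stability}, \code{k}.
#' @export
runICA <- function(expr_mat, var_cutoff = 70, max_iter = 10, n_runs = 15,
                   member_sd = 2, seed = 1L) {
  X <- t(scale(t(expr_mat)))            # center+standardize each gene
  X[!is.finite(X)] <- 0
  n <- nrow(X)
  sv <- svd(X)
  ev <- sv$d^2
  k <- which(cumsum(ev) >= var_cutoff / 100 * sum(ev))[1]
  if (k >= min(dim(X))) stop("component count reaches matrix rank; lower var_cutoff")
  Z <- sqrt(n) * sv$u[, seq_len(k), drop = FALSE]
  set.seed(seed)
  runs <- lapply(seq_len(n_runs), function(r) {
    for (attempt in seq_len(max_iter)) {
      fit <- .fastica_once(Z, k)
      if (fit$converged) break
    }
    fit$W
  })
  S_ref <- Z %*% runs[[1]]
  acc <- matrix(0, n, k)
  nacc <- rep(0, k)
  stab <- matrix(NA_real_, n_runs, k)
  for (r in seq_len(n_runs)) {
    S <- Z %*% runs[[r]]
    cc <- stats::cor(S_ref, S)
    # greedy matching on |correlation|; only well-matched (converged)
    # components contribute to the average
    taken_ref <- rep(FALSE, k); taken <- rep(FALSE, k)
    ord <- order(-abs(cc))
    for (o in ord) {
      i <- (o - 1) %% k + 1; j <- (o - 1) %/% k + 1
      if (taken_ref[i] || taken[j]) next
      taken_ref[i] <- TRUE; taken[j] <- TRUE
      stab[r, i] <- abs(cc[i, j])
      if (abs(cc[i, j]) >= 0.8) {
        acc[, i] <- acc[, i] + sign(cc[i, j]) * S[, j]
        nacc[i] <- nacc[i] + 1
      }
    }
  }
  S_avg <- sweep(acc, 2, pmax(nacc, 1), "/")
  S_avg[, nacc == 0] <- S_ref[, nacc == 0]
  # positive weight skewness convention
  for (c in seq_len(k)) {
    sk <- mean((S_avg[, c] - mean(S_avg[, c]))^3) / stats::sd(S_avg[, c])^3
    if (sk < 0) S_avg[, c] <- -S_avg[, c]
  }
  S_avg <- scale(S_avg)
  # eigen-expression: least-squares factor profiles given the gene weights
  eigenexp <- solve(crossprod(S_avg), crossprod(S_avg, X))
  eigenexp <- t(scale(t(eigenexp)))
  rownames(S_avg) <- rownames(expr_mat)
  comp_ids <- paste0("IC", seq_len(k))
  colnames(S_avg) <- comp_ids
  rownames(eigenexp) <- comp_ids
  colnames(eigenexp) <- colnames(expr_mat)
  members <- lapply(seq_len(k), function(c) {
    w <- S_avg[, c]
    rownames(expr_mat)[abs(w) > member_sd * stats::sd(w)]
  })
  names(members) <- comp_ids
  out <- list(weights = S_avg, eigen = eigenexp, members = members,
              stability = colMeans(stab, na.rm = TRUE), k = k)
  class(out) <- "ICAResult"
  out
}

#' @export
print.ICAResult <- function(x, ...) {
  cat("ICAResult:", x$k, "independent components over", nrow(x$weights),
      "genes x", ncol(x$eigen), "accessions\n")
  cat("  module sizes:", paste(lengths(x$members), collapse = ", "), "\n")
  cat(sprintf("  mean stability: %.3f\n", mean(x$stability)))
  invisible(x)
}

#' Module-trait correlations
#'
#' Pearson correlation of each component's eigen-expression with each
#' trait's BLUE values, with Benjamini-Hochberg q-values across
#' modules x traits. Constant eigen-expressions are skipped.
#'
#' @param ica \code{ICAResult} from \code{\link{runICA}}.
#' @param blues named list of trait BLUE vectors (names = accession ids).
#' @param min_shared minimum shared accessions (10).
#' @return data.frame: module, trait, r, p, q.
#' @export
moduleTraitCorrelation <- function(ica, blues, min_shared = 10) {
  rows <- list()
  for (cmp in rownames(ica$eigen)) {
    e <- ica$eigen[cmp, ]
    for (tr in names(blues)) {
      b <- blues[[tr]]
      ids <- intersect(names(b), colnames(ica$eigen))
      ids <- ids[!is.na(b[ids])]
      if (length(ids) < min_shared) stop("fewer than ", min_shared,
                                         " shared accessions")
      if (stats::sd(e[ids]) == 0) next
      ct <- stats::cor.test(e[ids], b[ids])
      rows[[length(rows) + 1]] <- data.frame(
        module = cmp, trait = tr, r = unname(ct$estimate), p = ct$p.value)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' GWAS of a module eigen-expression
#'
#' Runs the LOCO mixed-model scan with one component's eigen-expression as
#' the phenotype and clumps the results at the given threshold.
#'
#' @param ica \code{ICAResult}.
#' @param component component id (e.g. "IC1").
#' @param g \linkS4class{GenotypeMatrix}.
#' @param grms per-chromosome LOCO GRMs.
#' @param threshold lead p-value threshold; default the effective-test
#'   Bonferroni threshold of \code{g}.
#' @param rot optional precomputed rotations.
#' @param ... passed to \code{\link{clumpResults}}.
#' @return list with \code{loci} (clumped) and \code{results} (full scan).
#' @export
moduleGWAS <- function(ica, component, g, grms, threshold = NULL,
                       rot = NULL, ...) {
  y <- stats::setNames(ica$eigen[component, ], colnames(ica$eigen))
  if (stats::sd(y) == 0) stop("eigen-expression is constant")
  if (is.null(threshold)) threshold <- effectiveTests(g)$threshold
  res <- fitMLMLoco(g, y, grms, rot = rot)
  loci <- clumpResults(res[!is.na(res$p), ], g, p1 = threshold, ...)
  list(loci = loci, results = res)
}

#' Permutation test for module-level distal regulation
#'
#' For each candidate locus, counts how many module genes it distally
#' regulates (per the eQTL records); the null distribution is the maximum
#' such count across loci when the module is replaced by a random gene set
#' of the same size. A locus passes when its observed count strictly
#' exceeds the \code{1 - alpha} null quantile.
#'
#' @param module_genes character vector of module gene ids.
#' @param locus_targets named list: locus id -> character vector of genes
#'   it distally regulates (build from classified eQTL records).
#' @param all_genes the genome-wide gene universe to sample from.
#' @param n_perm permutations (1000).
#' @param alpha tail probability (0.01).
#' @param seed RNG seed.
#' @return list with \code{table} (locus, observed, passes),
#'   \code{threshold}, \code{null_max}.
#' @export
moduleDistalTest <- function(module_genes, locus_targets, all_genes,
                             n_perm = 1000, alpha = 0.01, seed = 1L) {
  if (length(module_genes) < 1) stop("empty module")
  if (length(module_genes) > length(all_genes)) {
    stop("module larger than the gene universe")
  }
  obs <- vapply(locus_targets, function(tg)
    length(intersect(module_genes, tg)), integer(1))
  set.seed(seed)
  msize <- length(module_genes)
  null_max <- vapply(seq_len(n_perm), function(b) {
    rnd <- sample(all_genes, msize)
    max(vapply(locus_targets, function(tg)
      length(intersect(rnd, tg)), integer(1)))
  }, integer(1))
  threshold <- sort(null_max)[ceiling((1 - alpha) * n_perm)]
  list(table = data.frame(locus = names(locus_targets), observed = obs,
                          passes = obs > threshold),
       threshold = threshold, null_max = null_max)
}

#' Distal target sets of loci, from classified eQTL records
#'
#' Convenience builder for \code{\link{moduleDistalTest}}: for each locus
#' (clump from a module GWAS or any region table) collect the genes whose
#' distal eQTL lead falls within the locus span extended by \code{pad_kb}.
#'
#' @param loci data.frame with chrom, start, end (and optionally lead).
#' @param records classified eQTL records (distal rows used).
#' @param pad_kb span padding in kb (100).
#' @return named list of gene-id vectors.
#' @export
locusDistalTargets <- function(loci, records, pad_kb = 100) {
  distal <- records[records$class == "distal", , drop = FALSE]
  out <- lapply(seq_len(nrow(loci)), function(i) {
    hit <- distal$chrom == loci$chrom[i] &
      distal$pos >= loci$start[i] - pad_kb * 1000 &
      distal$pos <= loci$end[i] + pad_kb * 1000
    unique(distal$gene[hit])
  })
  names(out) <- if ("lead" %in% colnames(loci)) loci$lead else
    paste0(loci$chrom, ":", loci$start, "-", loci$end)
  out
}

#' Louvain partition of a module into submodules
#'
#' Builds a gene graph with edges where the Spearman rho of expression
#' reaches \code{corr_min} (positive correlations define connectivity, so
#' anti-correlated gene groups fall into different submodules, matching
#' the sign-coherent submodule structure seen in seed coexpression
#' modules; set \code{use_abs = TRUE} for |rho| edges) and applies Louvain
#' community detection at the given resolution; communities smaller than
#' \code{min_size} are merged into the community with the strongest mean
#' edge weight to them. An empty graph yields a single community.
#'
#' @param expr_mat genes x accessions matrix.
#' @param member_genes genes to partition (at least 3).
#' @param corr_min correlation threshold (0.3).
#' @param min_size minimum community size (5).
#' @param resolution Louvain resolution (1).
#' @param seed RNG seed (Louvain is stochastic).
#' @param use_abs connect on |rho| instead of positive rho (FALSE).
#' @return named integer vector: gene -> submodule id.
#' @export
partitionSubmodules <- function(expr_mat, member_genes, corr_min = 0.3,
                                min_size = 5, resolution = 1, seed = 1L,
                                use_abs = FALSE) {
  if (length(member_genes) < 3) stop("need at least 3 member genes")
  X <- expr_mat[member_genes, , drop = FALSE]
  rho <- suppressWarnings(stats::cor(t(X), method = "spearman"))
  rho[!is.finite(rho)] <- 0
  diag(rho) <- 0
  adj <- if (use_abs) abs(rho) * (abs(rho) >= corr_min) else
    rho * (rho >= corr_min)
  if (all(adj == 0)) {
    return(stats::setNames(rep(1L, length(member_genes)), member_genes))
  }
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(gr, resolution = resolution)
  memb <- igraph::membership(cl)
  repeat {
    sizes <- table(memb)
    small <- names(sizes)[sizes < min_size]
    if (length(small) == 0 || length(sizes) == 1) break
    cm <- small[1]
    in_cm <- names(memb)[memb == cm]
    others <- setdiff(unique(memb), as.integer(cm))
    mw <- vapply(others, function(o) {
      in_o <- names(memb)[memb == o]
      mean(adj[in_cm, in_o, drop = FALSE])
    }, numeric(1))
    memb[in_cm] <- others[which.max(mw)]
  }
  ids <- as.integer(factor(memb))
  stats::setNames(ids, names(memb))
}

#' Per-gene correlations with both traits
#'
#' Pearson correlation (and p) of each member gene's expression with each
#' trait; genes significant for both traits at \code{p_max} are flagged,
#' with sign concordance recorded. Constant expression rows are excluded
#' and flagged.
#'
#' @param member_genes gene ids.
#' @param expr_mat genes x accessions matrix.
#' @param blues named list of two trait BLUE vectors.
#' @param p_max dual-significance threshold (0.01).
#' @param min_shared minimum shared accessions (10).
#' @return data.frame: gene, r and p per trait, \code{dual_significant},
#'   \code{same_sign}, \code{flag}.
#' @export
geneTraitCorrelations <- function(member_genes, expr_mat, blues,
                                  p_max = 0.01, min_shared = 10) {
  stopifnot(length(blues) == 2)
  tn <- names(blues)
  rows <- lapply(member_genes, function(gene) {
    x <- expr_mat[gene, ]
    ids <- intersect(names(blues[[1]]), names(x))
    ids <- intersect(ids, names(blues[[2]]))
    if (length(ids) < min_shared) stop("fewer than ", min_shared,
                                       " shared accessions")
    if (stats::sd(x[ids]) == 0) {
      return(data.frame(gene = gene, r1 = NA, p1 = NA, r2 = NA, p2 = NA,
                        dual_significant = FALSE, same_sign = NA,
                        flag = "constant"))
    }
    c1 <- stats::cor.test(x[ids], blues[[1]][ids])
    c2 <- stats::cor.test(x[ids], blues[[2]][ids])
    data.frame(gene = gene, r1 = unname(c1$estimate), p1 = c1$p.value,
               r2 = unname(c2$estimate), p2 = c2$p.value,
               dual_significant = c1$p.value < p_max & c2$p.value < p_max,
               same_sign = sign(c1$estimate) == sign(c2$estimate),
               flag = "")
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0("r_", tn[1]), paste0("p_", tn[1]),
                       paste0("r_", tn[2]), paste0("p_", tn[2]))
  out
}
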