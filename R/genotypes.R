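#' Read a VCF and apply genotype-level quality filters
#'
#' Applies the resequencing-panel genotype filters: heterozygous calls with
#' GQ below \code{gq_min} or DP below \code{dp_het_min} are set to missing,
#' homozygous calls with DP below \code{dp_hom_min} are set to missing, and
#' sites whose post-masking heterozygote fraction (over all accessions)
#' exceeds \code{het_site_frac} are dropped entirely. Multiallelic records
#' are split into one biallelic record per ALT allele; genotype calls
#' carrying a different ALT count toward REF in the split record.
#'
#' @param path path to a VCF (4.2) file with GT and, normally, GQ and DP
#'   FORMAT fields.
#' @param gq_min minimum genotype quality for a heterozygous call (20).
#' @param dp_het_min minimum depth for a heterozygous call (4).
#' @param dp_hom_min minimum depth for a homozygous call (2).
#' @param het_site_frac maximum tolerated fraction of heterozygous
#'   accessions per site (0.02); sites strictly above are removed.
#' @param missing_format_ok if TRUE (default) a missing GQ or DP FORMAT
#'   field is treated as passing, with a warning; if FALSE it is an error.
#' @return A \linkS4class{GenotypeMatrix}. The per-site drop log (variant
#'   id and reason) is attached as attribute \code{"drop_log"}.
#' @export
readFilterVCF <- function(path, gq_min = 20, dp_het_min = 4, dp_hom_min = 2,
                          het_site_frac = 0.02, missing_format_ok = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  fmt <- unique(unlist(strsplit(unname(vcf@gt[, "FORMAT"]), ":")))
  get_num <- function(el) {
    if (!(el %in% fmt)) {
      if (!missing_format_ok) stop("FORMAT field ", el, " absent in ", path)
      warning("FORMAT field ", el, " absent; treating all calls as passing")
      return(NULL)
    }
    suppressWarnings(vcfR::extract.gt(vcf, element = el, as.numeric = TRUE))
  }
  gq <- get_num("GQ")
  dp <- get_num("DP")
  samples <- colnames(gt_raw)
  nacc <- length(samples)

  rows <- list(); drop_log <- list()
  for (r in seq_len(nrow(gt_raw))) {
    alts <- strsplit(fix[r, "ALT"], ",")[[1]]
    gts <- gt_raw[r, ]
    al <- strsplit(gsub("\\|", "/", gts), "/")
    a1 <- suppressWarnings(as.integer(vapply(al, `[`, "", 1)))
    a2 <- suppressWarnings(as.integer(vapply(al, function(x)
      if (length(x) >= 2) x[2] else NA_character_, "")))
    miss <- is.na(a1) | is.na(a2)
    mask <- rep(FALSE, nacc)
    if (!is.null(gq)) mask <- mask | (!miss & (a1 != a2) & !is.na(gq[r, ]) & gq[r, ] < gq_min)
    if (!is.null(dp)) {
      mask <- mask | (!miss & (a1 != a2) & !is.na(dp[r, ]) & dp[r, ] < dp_het_min)
      mask <- mask | (!miss & (a1 == a2) & !is.na(dp[r, ]) & dp[r, ] < dp_hom_min)
    }
    a1[mask] <- NA; a2[mask] <- NA
    miss <- is.na(a1) | is.na(a2)
    for (ai in seq_along(alts)) {
      dos <- (a1 == ai) + (a2 == ai)
      dos[miss] <- NA
      het_frac <- sum(!is.na(dos) & dos == 1) / nacc
      vid <- paste0(fix[r, "CHROM"], "_", fix[r, "POS"],
                    if (length(alts) > 1) paste0("_", alts[ai]) else "")
      if (het_frac > het_site_frac) {
        drop_log[[length(drop_log) + 1]] <- data.frame(
          variant = vid, reason = sprintf("het_frac=%.4f", het_frac))
        next
      }
      rows[[length(rows) + 1]] <- list(
        dos = dos, chrom = fix[r, "CHROM"], pos = as.integer(fix[r, "POS"]),
        ref = fix[r, "REF"], alt = alts[ai], id = vid)
    }
  }
  if (length(rows) == 0) stop("no variants survive filtering in ", path)
  dosage <- t(vapply(rows, function(x) as.numeric(x$dos), numeric(nacc)))
  variants <- data.frame(
    chrom = vapply(rows, `[[`, "", "chrom"),
    pos = vapply(rows, function(x) x$pos, integer(1)),
    ref = vapply(rows, `[[`, "", "ref"),
    alt = vapply(rows, `[[`, "", "alt"),
    id = vapply(rows, `[[`, "", "id"))
  ord <- order(variants$chrom, variants$pos)
  g <- GenotypeMatrix(t(dosage)[, ord, drop = FALSE],
                      variants[ord, ], samples)
  attr(g, "drop_log") <- if (length(drop_log)) do.call(rbind, drop_log) else
    data.frame(variant = character(), reason = character())
  g
}

#' Per-variant minor-allele frequency
#'
#' MAF is \code{min(p, 1-p)} of the alternate-allele frequency computed over
#' non-missing alleles only. All-missing variants get \code{NA} and are
#' listed in the \code{"flagged"} attribute.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @return numeric vector of MAFs, named by variant id.
#' @export
computeMAF <- function(g) {
  maf <- .maf_from_dosage(dosages(g))
  names(maf) <- variantInfo(g)$id
  attr(maf, "flagged") <- names(maf)[is.na(maf)]
  maf
}

#' Pairwise LD r-squared between two variants
#'
#' Squared Pearson correlation of dosages over accessions non-missing at
#' both variants.
#'
#' @param g \linkS4class{GenotypeMatrix}.
#' @param a,b variant index or id.
#' @return r^2 in [0, 1]; NA (with attribute \code{"flagged"}) when fewer
#'   than two shared non-missing accessions or a variant is monomorphic.
#' @export
ldR2 <- function(g, a, b) {
  vi <- variantInfo(g)
  if (is.character(a)) a <- match(a, vi$id)
  if (is.character(b)) b <- match(b, vi$id)
  x <- dosages(g)[, a]; y <- dosages(g)[, b]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    out <- NA_real_; attr(out, "flagged") <- TRUE; return(out)
  }
  stats::cor(x[ok], y[ok])^2
}

#' Greedy windowed LD pruning
#'
#' PLINK-style \code{--indep-pairwise}: variants are first screened on MAF
#' and missing rate, then within each sliding window any pair with
#' r^2 above \code{r2_max} loses its later-positioned member; the window
#' advances by \code{step} variants until the surviving set has no
#' within-window pair above the threshold.
#'
#' @param g \linkS4class{GenotypeMatrix}.
#' @param window window size in variants (50).
#' @param step step in variants (10).
#' @param r2_max r^2 threshold (0.2).
#' @param maf_min minimum MAF (0.05).
#' @param miss_max maximum missing rate (0.05; strictly below passes).
#' @return character vector of surviving variant ids.
#' @export
ldPrune <- function(g, window = 50, step = 10, r2_max = 0.2,
                    maf_min = 0.05, miss_max = 0.05) {
  vi <- variantInfo(g)
  d <- dosages(g)
  missr <- colMeans(is.na(d))
  keep0 <- which(!is.na(vi$maf) & vi$maf >= maf_min & missr < miss_max)
  kept <- rep(FALSE, nVariants(g)); kept[keep0] <- TRUE
  for (chr in unique(as.character(vi$chrom))) {
    idx <- which(kept & vi$chrom == chr)
    if (length(idx) < 2) next
    std <- .std_dosage(d[, idx, drop = FALSE])
    alive <- rep(TRUE, length(idx))
    starts <- seq(1, max(length(idx) - 1, 1), by = step)
    for (s in starts) {
      win <- s:min(s + window - 1, length(idx))
      repeat {
        w <- win[alive[win]]
        if (length(w) < 2) break
        cc <- suppressWarnings(stats::cor(std[, w, drop = FALSE]))^2
        cc[!is.finite(cc)] <- 0
        diag(cc) <- 0
        hit <- which(cc > r2_max, arr.ind = TRUE)
        if (nrow(hit) == 0) break
        # drop the later-positioned member of the first offending pair
        pr <- hit[1, ]
        alive[w[max(pr)]] <- FALSE
      }
    }
    kept[idx[!alive]] <- FALSE
  }
  vi$id[kept]
}

# --- two-locus haplotype EM and D' confidence interval -----------------

# EM estimate of haplotype frequencies from unphased dosage pairs
.hap_em <- function(x, y, max_iter = 50, tol = 1e-8) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  p <- mean(x) / 2; q <- mean(y) / 2
  # haplotypes: 11 (alt-alt), 10, 01, 00 frequencies
  f <- c(p * q, p * (1 - q), (1 - p) * q, (1 - p) * (1 - q))
  dh <- sum(x == 1 & y == 1)                 # double heterozygotes
  counts <- function(f) {
    # expected count of 1-1 haplotypes contributed by double hets
    cis <- f[1] * f[4]; tr <- f[2] * f[3]
    w <- if (cis + tr > 0) cis / (cis + tr) else 0.5
    n11 <- 2 * sum(x == 2 & y == 2) + sum(x == 2 & y == 1) +
      sum(x == 1 & y == 2) + dh * w
    n10 <- 2 * sum(x == 2 & y == 0) + sum(x == 2 & y == 1) +
      sum(x == 1 & y == 0) + dh * (1 - w)
    n01 <- 2 * sum(x == 0 & y == 2) + sum(x == 1 & y == 2) +
      sum(x == 0 & y == 1) + dh * (1 - w)
    n00 <- 2 * sum(x == 0 & y == 0) + sum(x == 1 & y == 0) +
      sum(x == 0 & y == 1) + dh * w
    c(n11, n10, n01, n00)
  }
  for (it in seq_len(max_iter)) {
    cn <- counts(f)
    f_new <- cn / sum(cn)
    if (max(abs(f_new - f)) < tol) { f <- f_new; break }
    f <- f_new
  }
  list(f = f, p = f[1] + f[2], q = f[1] + f[3], n = n,
       x = x, y = y)
}

# log-likelihood of unphased genotype data given haplotype freqs
.hap_ll <- function(x, y, f) {
  gp <- matrix(0, 3, 3)   # P(genotype pair); rows x=0..2, cols y=0..2
  h <- c(f[1], f[2], f[3], f[4])  # 11 10 01 00
  # haplotype j contributes (alt at locus1?, alt at locus2?)
  a1 <- c(1, 1, 0, 0); a2 <- c(1, 0, 1, 0)
  for (i in 1:4) for (j in 1:4) {
    gx <- a1[i] + a1[j]; gy <- a2[i] + a2[j]
    gp[gx + 1, gy + 1] <- gp[gx + 1, gy + 1] + h[i] * h[j]
  }
  ll <- 0
  for (gx in 0:2) for (gy in 0:2) {
    cnt <- sum(x == gx & y == gy)
    if (cnt > 0) ll <- ll + cnt * log(max(gp[gx + 1, gy + 1], 1e-300))
  }
  ll
}

# D' point estimate and likelihood-profile CI (0.05 / 0.95 bounds)
.dprime_ci <- function(x, y) {
  em <- .hap_em(x, y)
  p <- em$p; q <- em$q
  if (p <= 0 || p >= 1 || q <= 0 || q >= 1) return(NULL)
  D <- em$f[1] - p * q
  dmax <- if (D >= 0) min(p * (1 - q), (1 - p) * q) else
    min(p * q, (1 - p) * (1 - q))
  if (dmax <= 0) return(NULL)
  dp_hat <- abs(D) / dmax
  sgn <- if (D >= 0) 1 else -1
  grid <- seq(0, 1, by = 0.01)
  ll <- vapply(grid, function(dp) {
    Dg <- sgn * dp * dmax
    f <- c(p * q + Dg, p * (1 - q) - Dg, (1 - p) * q - Dg,
           (1 - p) * (1 - q) + Dg)
    if (any(f < -1e-9)) return(-Inf)
    .hap_ll(em$x, em$y, pmax(f, 0))
  }, numeric(1))
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  cw <- cumsum(w)
  low <- grid[which(cw >= 0.05)[1]]
  high <- grid[which(cw >= 0.95)[1]]
  list(dprime = dp_hat, low = low, high = high)
}

#' Gabriel-style haplotype block detection
#'
#' D' between variant pairs is estimated by EM over unphased genotypes, with
#' a likelihood-profile confidence interval. Pairs whose CI lower bound is
#' at least \code{strong_lowci} and upper bound at least
#' \code{strong_highci} are "strong LD"; pairs with upper bound below
#' \code{recomb_highci} show "strong recombination". A candidate block
#' (outermost pair in strong LD, span at most \code{max_kb}) is accepted
#' when the informative strong fraction reaches \code{inform_frac}; blocks
#' are taken greedily by decreasing span without overlap.
#'
#' @param g \linkS4class{GenotypeMatrix}.
#' @param max_kb maximum block span in kb (5000).
#' @param strong_lowci,strong_highci strong-LD CI bounds (0.70, 0.98).
#' @param recomb_highci recombination CI bound (0.9).
#' @param inform_frac required informative strong fraction (0.8).
#' @param max_markers cap on within-block marker distance considered per
#'   pair (keeps the EM pair count bounded; 40).
#' @return data.frame with \code{chrom}, \code{start_pos}, \code{end_pos},
#'   \code{n_members} and a list-column \code{members} of variant ids.
#' @export
detectLDBlocks <- function(g, max_kb = 5000, strong_lowci = 0.70,
                           strong_highci = 0.98, recomb_highci = 0.9,
                           inform_frac = 0.8, max_markers = 40) {
  vi <- variantInfo(g)
  d <- dosages(g)
  out <- list()
  for (chr in unique(as.character(vi$chrom))) {
    idx <- which(vi$chrom == chr & !is.na(vi$maf) & vi$maf > 0)
    if (length(idx) < 2) next
    pos <- vi$pos[idx]
    k <- length(idx)
    status <- matrix(NA_integer_, k, k)  # 1 strong, -1 recomb, 0 other
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):min(i + max_markers, k)) {
        if (pos[j] - pos[i] > max_kb * 1000) break
        ci <- .dprime_ci(d[, idx[i]], d[, idx[j]])
        if (is.null(ci)) next
        status[i, j] <- if (ci$low >= strong_lowci && ci$high >= strong_highci) 1L
          else if (ci$high < recomb_highci) -1L else 0L
      }
    }
    cand <- list()
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):min(i + max_markers, k)) {
        if (pos[j] - pos[i] > max_kb * 1000) break
        if (is.na(status[i, j]) || status[i, j] != 1L) next
        sub <- status[i:j, i:j]
        ns <- sum(sub == 1L, na.rm = TRUE)
        nr <- sum(sub == -1L, na.rm = TRUE)
        if (ns + nr == 0) next
        if (ns / (ns + nr) >= inform_frac) {
          cand[[length(cand) + 1]] <- c(i, j)
        }
      }
    }
    if (length(cand) == 0) next
    cand <- cand[order(-vapply(cand, function(z) pos[z[2]] - pos[z[1]],
                               numeric(1)))]
    used <- rep(FALSE, k)
    for (cc in cand) {
      if (any(used[cc[1]:cc[2]])) next
      used[cc[1]:cc[2]] <- TRUE
      out[[length(out) + 1]] <- data.frame(
        chrom = chr, start_pos = pos[cc[1]], end_pos = pos[cc[2]],
        n_members = cc[2] - cc[1] + 1,
        members = I(list(vi$id[idx[cc[1]:cc[2]]])))
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start_pos = integer(),
                      end_pos = integer(), n_members = integer(),
                      members = I(list())))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start_pos), ]
}

#' Principal component analysis of standardized dosages
#'
#' Missing dosages are mean-imputed, columns standardized, and the
#' eigendecomposition of the accession covariance taken. PCs are ordered by
#' decreasing eigenvalue; each component's sign is fixed so its
#' largest-magnitude variant loading is positive.
#'
#' @param g a pruned, MAF-filtered \linkS4class{GenotypeMatrix}.
#' @param n_components number of PCs to return.
#' @return list with \code{scores} (accessions x n_components),
#'   \code{eigenvalues} (all), \code{prop_var} and \code{total_var}.
#' @export
pcaGenotypes <- function(g, n_components = 10) {
  if (n_components > nAccessions(g)) {
    stop("n_components exceeds number of accessions")
  }
  std <- .std_dosage(dosages(g))
  keep <- apply(std, 2, function(z) any(z != 0))
  std <- std[, keep, drop = FALSE]
  pc <- stats::prcomp(std, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) scores[, k] <- -scores[, k]
  }
  rownames(scores) <- accessionInfo(g)$id
  list(scores = scores, eigenvalues = ev, prop_var = ev / sum(ev),
       total_var = sum(apply(std, 2, stats::var)))
}

#' Genomic relationship matrix (GRM)
#'
#' Standardized-dosage GRM:
#' \eqn{A_{ij} = m^{-1} \sum_k (x_{ik}-2p_k)(x_{jk}-2p_k) / (2 p_k (1-p_k))}.
#' Missing dosages are mean-imputed and therefore contribute zero deviation.
#' Optionally excludes one chromosome, the leave-one-chromosome-out kinship
#' used by the mixed-model association scan.
#'
#' @param g \linkS4class{GenotypeMatrix}.
#' @param exclude_chrom chromosome to leave out, or NULL.
#' @param maf_min variants below this MAF are not used (0.01).
#' @param min_variants error if fewer variants remain (100).
#' @return accession x accession matrix of class \code{GRM} with attributes
#'   \code{variant_set} and \code{excluded_chrom}.
#' @export
buildGRM <- function(g, exclude_chrom = NULL, maf_min = 0.01,
                     min_variants = 100) {
  vi <- variantInfo(g)
  keep <- !is.na(vi$maf) & vi$maf >= maf_min
  if (!is.null(exclude_chrom)) keep <- keep & vi$chrom != exclude_chrom
  if (sum(keep) == 0) stop("chromosome exclusion removed all variants")
  if (sum(keep) < min_variants) {
    stop("only ", sum(keep), " variants available for GRM; need ",
         min_variants)
  }
  x <- imputeMean(dosages(g)[, keep, drop = FALSE])
  p <- colMeans(x) / 2
  W <- sweep(x, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(W) / ncol(W)
  dimnames(A) <- list(accessionInfo(g)$id, accessionInfo(g)$id)
  attr(A, "variant_set") <- vi$id[keep]
  attr(A, "excluded_chrom") <- exclude_chrom
  class(A) <- c("GRM", class(A))
  A
}

#' Per-chromosome leave-one-chromosome-out GRMs
#'
#' @param g \linkS4class{GenotypeMatrix}.
#' @param maf_min,min_variants passed to \code{\link{buildGRM}}.
#' @return named list of GRM matrices, one per chromosome, each built from
#'   all variants except that chromosome's.
#' @export
locoGRMs <- function(g, maf_min = 0.01, min_variants = 100) {
  chroms <- unique(as.character(variantInfo(g)$chrom))
  out <- lapply(chroms, function(ch)
    buildGRM(g, exclude_chrom = ch, maf_min = maf_min,
             min_variants = min_variants))
  names(out) <- chroms
  out
}
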