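#' Expression-level and variance filter
#'
#' Keeps genes that are expressed (TPM at or above \code{tpm_min}) in at
#' least \code{1 - frac} of accessions and whose expression varies (ratio
#' of the 95th to the 5th percentile at least \code{fold_min}; a zero 5th
#' percentile passes the fold criterion).
#'
#' @param expr \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   \code{tpm} assay (genes x accessions).
#' @param tpm_min expression floor (5).
#' @param frac genes below the floor in more than this fraction of
#'   accessions are dropped (0.95).
#' @param fold_min minimum 95th/5th percentile ratio (2).
#' @return the filtered SummarizedExperiment; counts of genes failing each
#'   criterion are in attribute \code{"filter_counts"}.
#' @export
filterExpression <- function(expr, tpm_min = 5, frac = 0.95, fold_min = 2) {
  tpm <- SummarizedExperiment::assay(expr, "tpm")
  expressed <- rowMeans(tpm >= tpm_min) >= (1 - frac)
  q <- t(apply(tpm, 1, stats::quantile, probs = c(0.05, 0.95), names = FALSE))
  fold_ok <- q[, 1] <= 0 | (q[, 2] / q[, 1]) >= fold_min
  keep <- expressed & fold_ok
  if (!any(keep)) {
    stop("no genes pass filters (", sum(!expressed), " low expression, ",
         sum(!fold_ok), " low variance)")
  }
  out <- expr[keep, ]
  attr(out, "filter_counts") <- c(low_expression = sum(!expressed),
                                  low_variance = sum(!fold_ok),
                                  kept = sum(keep))
  out
}

#' Rank-based quantile normalization to the standard normal
#'
#' Maps ranks (ties averaged) to \eqn{\Phi^{-1}((rank - 0.5)/n)}. NAs are
#' preserved in place.
#'
#' @param x numeric vector with at least 3 non-missing values.
#' @return normalized vector of the same length.
#' @export
quantileNormalize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 3) stop("need at least 3 non-missing values")
  if (stats::sd(x[ok]) == 0) stop("cannot rank a constant vector")
  r <- rank(x[ok], ties.method = "average")
  out <- x
  out[ok] <- stats::qnorm((r - 0.5) / sum(ok))
  out
}

# strong-LD merge of a gene's lead variants: pairwise D' CI, connected
# components, representative = smallest p
.merge_leads <- function(lead_rows, g, max_kb = 5000,
                         strong_lowci = 0.70, strong_highci = 0.98) {
  if (nrow(lead_rows) < 2) return(lead_rows)
  d <- dosages(g)
  vi <- variantInfo(g)
  k <- nrow(lead_rows)
  adj <- diag(TRUE, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (lead_rows$chrom[i] != lead_rows$chrom[j]) next
      if (abs(lead_rows$pos[i] - lead_rows$pos[j]) > max_kb * 1000) next
      ci <- .dprime_ci(d[, match(lead_rows$lead[i], vi$id)],
                       d[, match(lead_rows$lead[j], vi$id)])
      if (is.null(ci)) next
      if (ci$low >= strong_lowci && ci$high >= strong_highci) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  keep <- vapply(seq_len(max(comp)), function(cmp) {
    ii <- which(comp == cmp)
    ii[which.min(lead_rows$p[ii])]
  }, integer(1))
  lead_rows[sort(keep), , drop = FALSE]
}

#' Genome-wide eQTL mapping
#'
#' Per gene: quantile-normalized expression is scanned with the LOCO mixed
#' model; associations with \code{p < p_assoc} are LD-clumped (default
#' r^2 0.2 within 250 kb); clump leads significant at \code{lead_p}
#' (default 1 / number of variants) and carrying at least
#' \code{min_proxies} LD proxies are retained as putative eQTLs; finally,
#' a gene's leads that fall in one LD block (strong-LD D' criterion) are
#' merged and represented by the most significant lead.
#'
#' @param g \linkS4class{GenotypeMatrix}.
#' @param expr filtered \link[SummarizedExperiment]{SummarizedExperiment}
#'   (assay \code{tpm}).
#' @param grms per-chromosome LOCO GRMs (\code{\link{locoGRMs}}).
#' @param p_assoc association threshold (1e-4).
#' @param clump_r2,clump_kb clumping parameters (0.2, 250).
#' @param lead_p lead threshold; default \code{1 / nVariants(g)}.
#' @param min_proxies minimum LD proxies (non-lead clump members) for a
#'   lead to be retained (2); with \code{strict_proxies = TRUE} the rule is
#'   strictly more than \code{min_proxies}.
#' @param strict_proxies see above (FALSE).
#' @param rot optional precomputed \code{\link{locoRotations}}.
#' @param genes optional subset of gene ids to map.
#' @return data.frame of eQTL records: gene, lead, chrom, pos, p,
#'   n_proxies.
#' @export
mapEQTLs <- function(g, expr, grms, p_assoc = 1e-4, clump_r2 = 0.2,
                     clump_kb = 250, lead_p = NULL, min_proxies = 2,
                     strict_proxies = FALSE, rot = NULL, genes = NULL) {
  if (is.null(lead_p)) lead_p <- 1 / nVariants(g)
  if (is.null(rot)) rot <- locoRotations(g, grms)
  tpm <- SummarizedExperiment::assay(expr, "tpm")
  if (!is.null(genes)) tpm <- tpm[intersect(genes, rownames(tpm)), , drop = FALSE]
  recs <- list()
  for (gene in rownames(tpm)) {
    y <- tryCatch(quantileNormalize(tpm[gene, ]), error = function(e) NULL)
    if (is.null(y)) next
    res <- fitMLMLoco(g, stats::setNames(y, colnames(tpm)), grms, rot = rot)
    sig <- res[!is.na(res$p) & res$p < p_assoc, ]
    if (nrow(sig) == 0) next
    loci <- clumpResults(sig, g, p1 = p_assoc, p2 = p_assoc,
                         r2 = clump_r2, kb = clump_kb)
    if (nrow(loci) == 0) next
    nprox <- loci$n_members - 1
    ok <- loci$p < lead_p &
      (if (strict_proxies) nprox > min_proxies else nprox >= min_proxies)
    loci <- loci[ok, , drop = FALSE]
    if (nrow(loci) == 0) next
    lead_rows <- data.frame(gene = gene, lead = loci$lead,
                            chrom = loci$chrom, pos = loci$pos, p = loci$p,
                            n_proxies = loci$n_members - 1)
    recs[[gene]] <- .merge_leads(lead_rows, g)
  }
  if (length(recs) == 0) {
    return(data.frame(gene = character(), lead = character(),
                      chrom = character(), pos = integer(), p = numeric(),
                      n_proxies = integer()))
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Classify eQTLs as local or distal
#'
#' Distance is zero when the lead falls inside the gene span, otherwise the
#' gap to the nearer span edge. Same chromosome and distance at or below
#' \code{cutoff} (boundary inclusive) is local; anything else, including a
#' different chromosome, is distal. \code{mode = "tss"} measures to the TSS
#' instead of the span.
#'
#' @param records eQTL record data.frame from \code{\link{mapEQTLs}}.
#' @param gene_coords GRanges (with \code{gene} and \code{tss} metadata,
#'   e.g. \code{rowRanges} of the expression object) or a data.frame with
#'   gene, chrom, start, end, tss.
#' @param cutoff distance cutoff in bp (1e6).
#' @param mode "span" (default) or "tss".
#' @return records with added \code{class} and \code{distance} columns.
#' @export
classifyLocalDistal <- function(records, gene_coords, cutoff = 1e6,
                                mode = c("span", "tss")) {
  mode <- match.arg(mode)
  gc <- if (inherits(gene_coords, "GRanges")) {
    data.frame(gene = gene_coords$gene,
               chrom = as.character(GenomicRanges::seqnames(gene_coords)),
               start = GenomicRanges::start(gene_coords),
               end = GenomicRanges::end(gene_coords),
               tss = gene_coords$tss)
  } else gene_coords
  gi <- match(records$gene, gc$gene)
  if (anyNA(gi)) stop("unknown gene id: ",
                      paste(records$gene[is.na(gi)], collapse = ", "))
  dist <- if (mode == "span") {
    .gap_to_span(records$pos, gc$start[gi], gc$end[gi])
  } else abs(records$pos - gc$tss[gi])
  same <- records$chrom == gc$chrom[gi]
  records$distance <- ifelse(same, dist, NA)
  records$class <- ifelse(same & dist <= cutoff, "local", "distal")
  records
}

#' Expression variance explained by an eQTL lead
#'
#' Squared Pearson correlation between lead dosage and the gene's
#' quantile-normalized expression.
#'
#' @param records eQTL record data.frame.
#' @param g \linkS4class{GenotypeMatrix}.
#' @param expr SummarizedExperiment with \code{tpm} assay.
#' @return records with an added \code{r2} column.
#' @export
explainedVariance <- function(records, g, expr) {
  tpm <- SummarizedExperiment::assay(expr, "tpm")
  d <- imputeMean(dosages(g))
  vi <- variantInfo(g)
  records$r2 <- vapply(seq_len(nrow(records)), function(i) {
    x <- d[, match(records$lead[i], vi$id)]
    if (stats::sd(x) == 0) stop("monomorphic lead ", records$lead[i])
    y <- quantileNormalize(tpm[records$gene[i], ])
    stats::cor(x, y)^2
  }, numeric(1))
  records
}

# distinct distal eGene count per sliding window for one position vector
.window_counts <- function(pos_by_chrom, gene_by_chrom, windows) {
  vapply(seq_len(nrow(windows)), function(i) {
    ch <- windows$chrom[i]
    p <- pos_by_chrom[[ch]]
    if (is.null(p)) return(0L)
    inw <- p >= windows$start[i] & p <= windows$end[i]
    length(unique(gene_by_chrom[[ch]][inw]))
  }, integer(1))
}

#' Permutation-calibrated distal-eQTL hotspot detection
#'
#' Slides a \code{window_bp} window by \code{step_bp} and counts the
#' distinct distal eGenes whose eQTL lead falls in the window. The null is
#' built by \code{n_perm} random relocations of the distal-eQTL lead
#' positions (uniform per chromosome, preserving per-chromosome counts and
#' the eGene links); the genome-wide maximum window count is recorded per
#' permutation and the threshold is the \code{1 - alpha} quantile of those
#' maxima. Windows whose observed count strictly exceeds the threshold are
#' flagged; overlapping flagged windows are merged into one hotspot.
#'
#' @param records classified eQTL records (only \code{class == "distal"}
#'   rows are used).
#' @param genome data.frame with \code{chrom} and \code{length}.
#' @param window_bp,step_bp window geometry (1 Mb, 100 kb).
#' @param n_perm permutations (1000).
#' @param alpha tail probability for the threshold (0.01).
#' @param seed RNG seed for the permutations.
#' @return list with \code{hotspots} (merged windows: chrom, start, end,
#'   n_egenes), \code{threshold}, \code{windows} (all window counts) and
#'   \code{null_max} (the permutation maxima).
#' @export
detectHotspots <- function(records, genome, window_bp = 1e6, step_bp = 1e5,
                           n_perm = 1000, alpha = 0.01, seed = 1L) {
  distal <- records[records$class == "distal", , drop = FALSE]
  windows <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    starts <- seq(1, max(genome$length[i] - window_bp + 1, 1), by = step_bp)
    data.frame(chrom = genome$chrom[i], start = starts,
               end = pmin(starts + window_bp - 1, genome$length[i]))
  }))
  if (nrow(distal) == 0) {
    return(list(hotspots = data.frame(chrom = character(), start = numeric(),
                                      end = numeric(), n_egenes = integer()),
                threshold = 0, windows = cbind(windows, n_egenes = 0L),
                null_max = integer(n_perm)))
  }
  split_pos <- split(distal$pos, distal$chrom)
  split_gene <- split(distal$gene, distal$chrom)
  obs <- .window_counts(split_pos, split_gene, windows)
  set.seed(seed)
  chr_len <- stats::setNames(genome$length, genome$chrom)
  null_max <- vapply(seq_len(n_perm), function(b) {
    perm_pos <- lapply(names(split_pos), function(ch)
      sample.int(chr_len[[ch]], length(split_pos[[ch]]), replace = TRUE))
    names(perm_pos) <- names(split_pos)
    max(.window_counts(perm_pos, split_gene, windows))
  }, integer(1))
  threshold <- sort(null_max)[ceiling((1 - alpha) * n_perm)]
  flagged <- windows[obs > threshold, , drop = FALSE]
  flagged$n_egenes <- obs[obs > threshold]
  hot <- if (nrow(flagged) == 0) {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_egenes = integer())
  } else {
    gr <- GenomicRanges::GRanges(flagged$chrom,
                                 IRanges::IRanges(flagged$start, flagged$end))
    red <- GenomicRanges::reduce(gr)
    ov <- GenomicRanges::findOverlaps(red, gr)
    nmax <- vapply(seq_along(red), function(i)
      max(flagged$n_egenes[S4Vectors::subjectHits(ov)[
        S4Vectors::queryHits(ov) == i]]), integer(1))
    data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
               start = GenomicRanges::start(red),
               end = GenomicRanges::end(red), n_egenes = nmax)
  }
  list(hotspots = hot, threshold = threshold,
       windows = cbind(windows, n_egenes = obs), null_max = null_max)
}

#' Enrichment of eQTL leads in open chromatin regions
#'
#' Compares the observed number of eQTL leads overlapping OCR intervals to
#' a null built by relocating the OCRs uniformly within their chromosome
#' (lengths preserved; a bounded number of retries avoids overlaps among
#' relocated intervals).
#'
#' @param leads data.frame with \code{chrom} and \code{pos} (eQTL lead
#'   positions).
#' @param ocr GRanges of OCR intervals, or a data.frame with chrom,
#'   start, end (1-based inclusive).
#' @param genome data.frame with chrom, length.
#' @param n_perm permutations (1000).
#' @param seed RNG seed.
#' @param max_retries retries per interval to avoid overlap (10).
#' @return list: \code{observed}, \code{null_mean}, \code{ci95}
#'   (2.5/97.5 percentiles of the null), \code{p} (empirical, add-one).
#' @export
ocrEnrichment <- function(leads, ocr, genome, n_perm = 1000, seed = 1L,
                          max_retries = 10) {
  if (inherits(ocr, "GRanges")) {
    ocr <- data.frame(chrom = as.character(GenomicRanges::seqnames(ocr)),
                      start = GenomicRanges::start(ocr),
                      end = GenomicRanges::end(ocr))
  }
  chr_len <- stats::setNames(genome$length, genome$chrom)
  if (any(ocr$end > chr_len[ocr$chrom])) {
    stop("OCR interval exceeds chromosome length")
  }
  count_overlap <- function(iv) {
    tot <- 0L
    for (ch in unique(iv$chrom)) {
      pp <- leads$pos[leads$chrom == ch]
      if (length(pp) == 0) next
      sub <- iv[iv$chrom == ch, , drop = FALSE]
      hit <- vapply(pp, function(p) any(p >= sub$start & p <= sub$end),
                    logical(1))
      tot <- tot + sum(hit)
    }
    tot
  }
  observed <- count_overlap(ocr)
  set.seed(seed)
  len <- ocr$end - ocr$start + 1
  nulls <- vapply(seq_len(n_perm), function(b) {
    placed <- vector("list", nrow(ocr))
    for (i in seq_len(nrow(ocr))) {
      L <- chr_len[[ocr$chrom[i]]]
      for (try in seq_len(max_retries)) {
        s <- sample.int(L - len[i] + 1, 1)
        e <- s + len[i] - 1
        clash <- FALSE
        for (j in seq_len(i - 1)) {
          pj <- placed[[j]]
          if (!is.null(pj) && pj$chrom == ocr$chrom[i] &&
              s <= pj$end && e >= pj$start) { clash <- TRUE; break }
        }
        if (!clash || try == max_retries) break
      }
      placed[[i]] <- list(chrom = ocr$chrom[i], start = s, end = e)
    }
    iv <- data.frame(chrom = vapply(placed, `[[`, "", "chrom"),
                     start = vapply(placed, `[[`, 0, "start"),
                     end = vapply(placed, `[[`, 0, "end"))
    count_overlap(iv)
  }, integer(1))
  list(observed = observed, null_mean = mean(nulls),
       ci95 = stats::quantile(nulls, c(0.025, 0.975), names = FALSE),
       p = (1 + sum(nulls >= observed)) / (n_perm + 1))
}

#' Integer percentages (half away from zero)
#'
#' @param counts named numeric vector of class counts.
#' @return named integer percentages summing approximately to 100.
#' @export
classPercentages <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(stats::setNames(rep(0L, length(counts)), names(counts)))
  stats::setNames(as.integer(roundHalfUp(100 * counts / tot)), names(counts))
}

#' Summarize eQTL classes and eGene regulation categories
#'
#' Counts local and distal eQTL records and partitions eGenes into
#' local-only / distal-only / both categories, with integer percentages
#' (rounded half away from zero).
#'
#' @param records classified eQTL records.
#' @return list with \code{eqtl_counts}, \code{eqtl_pct},
#'   \code{egene_counts}, \code{egene_pct}, \code{n_eqtls},
#'   \code{n_egenes}.
#' @export
summarizeEQTLClasses <- function(records) {
  if (nrow(records) == 0) {
    z <- c(local = 0L, distal = 0L)
    zz <- c(local_only = 0L, distal_only = 0L, both = 0L)
    return(list(eqtl_counts = z, eqtl_pct = z, egene_counts = zz,
                egene_pct = zz, n_eqtls = 0L, n_egenes = 0L))
  }
  cls <- factor(records$class, levels = c("local", "distal"))
  eqtl_counts <- table(cls)
  by_gene <- split(records$class, records$gene)
  cat <- vapply(by_gene, function(cl) {
    has_l <- "local" %in% cl; has_d <- "distal" %in% cl
    if (has_l && has_d) "both" else if (has_l) "local_only" else "distal_only"
  }, character(1))
  egene_counts <- table(factor(cat, levels = c("local_only", "distal_only",
                                               "both")))
  list(eqtl_counts = c(eqtl_counts), eqtl_pct = classPercentages(c(eqtl_counts)),
       egene_counts = c(egene_counts),
       egene_pct = classPercentages(c(egene_counts)),
       n_eqtls = nrow(records), n_egenes = length(by_gene))
}
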