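#' Read motifs in minimal MEME format
#'
#' Parses the MEME text format: the \code{Background letter frequencies}
#' line and each \code{MOTIF} block's letter-probability matrix
#' (alength 4, ACGT column order).
#'
#' @param path path to a MEME-format motif file.
#' @return named list of 4 x width probability matrices (rows A, C, G, T),
#'   with the background frequencies attached as attribute \code{"bg"}.
#' @export
readMEME <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    tok <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    vals <- as.numeric(tok[seq(2, length(tok), 2)])
    names(vals) <- tok[seq(1, length(tok), 2)]
    bg[names(vals)] <- vals
  }
  motifs <- list()
  mi <- grep("^MOTIF", lines)
  for (i in mi) {
    name <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    hj <- grep("^letter-probability matrix", lines[(i + 1):length(lines)])[1]
    hdr <- lines[i + hj]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    rows <- lines[(i + hj + 1):(i + hj + w)]
    m <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    mat <- t(m)
    rownames(mat) <- c("A", "C", "G", "T")
    motifs[[name]] <- mat
  }
  attr(motifs, "bg") <- bg
  motifs
}

# log-odds matrix from a probability matrix, with pseudocount
.pwm_logodds <- function(pwm, bg, pseudo = 0.01) {
  p <- sweep(pwm + pseudo, 2, colSums(pwm + pseudo), "/")
  log2(sweep(p, 1, bg[rownames(p)], "/"))
}

# exact null distribution of the max-per-position score under the 0-order
# background, by discretized DP convolution; returns the smallest score s
# with P(single-position score >= s) <= p_target
.pwm_threshold <- function(lo, bg, p_target = 1e-4, scale = 100) {
  w <- ncol(lo)
  li <- round(lo * scale)
  dist <- stats::setNames(1, "0")
  for (j in seq_len(w)) {
    nd <- new.env()
    for (s in names(dist)) {
      ps <- dist[[s]]
      for (b in rownames(li)) {
        key <- as.character(as.integer(s) + li[b, j])
        nd[[key]] <- (if (is.null(nd[[key]])) 0 else nd[[key]]) + ps * bg[[b]]
      }
    }
    dist <- unlist(as.list(nd))
  }
  sc <- as.integer(names(dist))
  ord <- order(sc, decreasing = TRUE)
  cum <- cumsum(dist[ord])
  i <- which(cum > p_target)[1]
  if (is.na(i)) return(min(sc) / scale)
  if (i == 1) return((sc[ord][1] + 1) / scale)
  sc[ord][i - 1] / scale
}

# max log-odds score of a motif over both strands of one sequence
.scan_seq <- function(lo, seq_chr) {
  w <- ncol(lo)
  s <- strsplit(seq_chr, "")[[1]]
  n <- length(s)
  if (n < w) return(-Inf)
  idx <- match(s, c("A", "C", "G", "T"))
  comp <- c(4L, 3L, 2L, 1L)
  best <- -Inf
  scores_f <- numeric(n - w + 1)
  scores_r <- numeric(n - w + 1)
  for (j in seq_len(w)) {
    col <- lo[, j]
    col <- c(col, NA)
    ii <- idx[j:(j + n - w)]
    ii[is.na(ii)] <- 5L
    scores_f <- scores_f + col[ii]
    # reverse complement: position j of motif matches base n-?? ; score the
    # minus strand by scanning the complement backwards
    jr <- w - j + 1
    colr <- lo[, jr]
    colr <- c(colr, NA)
    ic <- comp[idx[j:(j + n - w)]]
    ic[is.na(ic)] <- 5L
    scores_r <- scores_r + colr[ic]
  }
  max(c(scores_f, scores_r), na.rm = TRUE)
}

#' Promoter motif enrichment (hypergeometric)
#'
#' Scans module and background promoter sets with each PWM (log-odds, both
#' strands, 0-order background); a promoter is a hit when its best score
#' reaches the score threshold corresponding to a per-position p-value of
#' \code{p_hit} under the background model. Enrichment of hit-bearing
#' promoters in the module versus the background universe is tested by a
#' one-sided hypergeometric, BH-corrected across motifs. The background set
#' is the universe and should contain the module promoters.
#'
#' @param member_promoters \link[Biostrings]{DNAStringSet} (module).
#' @param background_promoters \link[Biostrings]{DNAStringSet} (universe).
#' @param pwms named list of probability matrices from \code{\link{readMEME}}
#'   (or compatible), background in attribute \code{"bg"}.
#' @param p_hit per-position score p-value defining a hit (1e-4).
#' @return data.frame: motif, hits_in_module, hits_in_background, fold, p,
#'   q. Empty PWM list gives an empty result.
#' @export
motifEnrichment <- function(member_promoters, background_promoters, pwms,
                            p_hit = 1e-4) {
  if (length(pwms) == 0) {
    return(data.frame(motif = character(), hits_in_module = integer(),
                      hits_in_background = integer(), fold = numeric(),
                      p = numeric(), q = numeric()))
  }
  bg <- attr(pwms, "bg")
  if (is.null(bg)) bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  mod_chr <- as.character(member_promoters)
  bgd_chr <- as.character(background_promoters)
  rows <- lapply(names(pwms), function(nm) {
    lo <- .pwm_logodds(pwms[[nm]], bg)
    thr <- .pwm_threshold(lo, bg, p_hit)
    hm <- sum(vapply(mod_chr, function(s) .scan_seq(lo, s) >= thr,
                     logical(1)))
    hb <- sum(vapply(bgd_chr, function(s) .scan_seq(lo, s) >= thr,
                     logical(1)))
    k <- length(mod_chr); N <- length(bgd_chr)
    p <- stats::phyper(hm - 1, hb, N - hb, k, lower.tail = FALSE)
    fold <- (hm / k) / max(hb / N, 1e-12)
    data.frame(motif = nm, hits_in_module = hm, hits_in_background = hb,
               fold = fold, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Strand-aware promoter sequences
#'
#' Extracts the \code{width} bases upstream of each gene's TSS from a set
#' of chromosome sequences, reverse-complementing minus-strand promoters;
#' truncated at chromosome bounds.
#'
#' @param chrom_seqs named \link[Biostrings]{DNAStringSet} of chromosomes.
#' @param gene_coords GRanges with \code{gene} and \code{tss} metadata, or
#'   data.frame with gene, chrom, strand, tss.
#' @param width promoter length in bp (2000).
#' @return \link[Biostrings]{DNAStringSet} named by gene.
#' @export
promoterSeqs <- function(chrom_seqs, gene_coords, width = 2000) {
  gc <- if (inherits(gene_coords, "GRanges")) {
    data.frame(gene = gene_coords$gene,
               chrom = as.character(GenomicRanges::seqnames(gene_coords)),
               strand = as.character(GenomicRanges::strand(gene_coords)),
               tss = gene_coords$tss)
  } else gene_coords
  seqs <- lapply(seq_len(nrow(gc)), function(i) {
    L <- length(chrom_seqs[[gc$chrom[i]]])
    if (gc$strand[i] == "+") {
      s <- max(1, gc$tss[i] - width); e <- max(1, gc$tss[i] - 1)
      sub <- Biostrings::subseq(chrom_seqs[[gc$chrom[i]]], s, min(e, L))
    } else {
      s <- min(L, gc$tss[i] + 1); e <- min(L, gc$tss[i] + width)
      sub <- Biostrings::reverseComplement(
        Biostrings::subseq(chrom_seqs[[gc$chrom[i]]], s, e))
    }
    sub
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- gc$gene
  out
}
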