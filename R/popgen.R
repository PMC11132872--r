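# sliding window grid for one chromosome length
.tile_windows <- function(len, window_bp, step_bp) {
  starts <- seq(1, max(len - window_bp + 1, 1), by = step_bp)
  data.frame(start = starts, end = pmin(starts + window_bp - 1, len))
}

#' Windowed nucleotide diversity (pi)
#'
#' Per site, the unbiased heterozygosity \eqn{2 p (1-p) \, n/(n-1)} over
#' non-missing alleles (n = allele count); window pi is the sum of site
#' heterozygosities divided by the full window length in bp.
#'
#' @param g_panel \linkS4class{GenotypeMatrix} (at least 2 accessions).
#' @param window_bp window size (1e5).
#' @param step_bp step (1e4).
#' @param genome optional data.frame (chrom, length); defaults to the
#'   maximum variant position per chromosome.
#' @return data.frame: chrom, start, end, pi, n_sites, flag
#'   ("no_sites" where the window holds no genotyped site).
#' @export
windowedPi <- function(g_panel, window_bp = 1e5, step_bp = 1e4,
                       genome = NULL) {
  if (nAccessions(g_panel) < 2) stop("panel needs at least 2 accessions")
  vi <- variantInfo(g_panel)
  d <- dosages(g_panel)
  nall <- 2 * colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / nall
  het <- ifelse(nall > 1, 2 * p * (1 - p) * nall / (nall - 1), NA)
  if (is.null(genome)) {
    genome <- stats::aggregate(pos ~ chrom, as.data.frame(vi), max)
    names(genome) <- c("chrom", "length")
  }
  out <- list()
  for (i in seq_len(nrow(genome))) {
    ch <- genome$chrom[i]
    wins <- .tile_windows(genome$length[i], window_bp, step_bp)
    idx <- which(vi$chrom == ch & !is.na(het))
    pi_w <- vapply(seq_len(nrow(wins)), function(k) {
      inw <- idx[vi$pos[idx] >= wins$start[k] & vi$pos[idx] <= wins$end[k]]
      sum(het[inw])
    }, numeric(1))
    ns <- vapply(seq_len(nrow(wins)), function(k)
      sum(vi$pos[idx] >= wins$start[k] & vi$pos[idx] <= wins$end[k]),
      numeric(1))
    out[[i]] <- data.frame(chrom = ch, start = wins$start, end = wins$end,
                           pi = pi_w / window_bp, n_sites = ns,
                           flag = ifelse(ns == 0, "no_sites", ""))
  }
  do.call(rbind, out)
}

#' Pi-ratio selective-sweep scan
#'
#' Ratio of windowed diversity between two panels with an empirical
#' genome-wide threshold: windows in the top \code{top_frac} of ratios are
#' flagged as sweep candidates. 0/0 windows are excluded; x/0 windows are
#' capped at the maximum finite ratio and flagged.
#'
#' @param pi_a,pi_b windowed pi tables from \code{\link{windowedPi}} on
#'   the same tiling (a is the more diverse panel, e.g. wild).
#' @param top_frac upper tail fraction (0.05).
#' @return list: \code{windows} (chrom, start, end, ratio, flagged, note),
#'   \code{threshold}.
#' @export
piRatioScan <- function(pi_a, pi_b, top_frac = 0.05) {
  if (nrow(pi_a) != nrow(pi_b) ||
      !all(pi_a$start == pi_b$start & pi_a$chrom == pi_b$chrom)) {
    stop("window tilings differ between panels")
  }
  ratio <- pi_a$pi / pi_b$pi
  note <- rep("", length(ratio))
  both0 <- pi_a$pi == 0 & pi_b$pi == 0
  div0 <- pi_b$pi == 0 & pi_a$pi > 0
  finite_max <- suppressWarnings(max(ratio[is.finite(ratio)], na.rm = TRUE))
  ratio[div0] <- finite_max
  note[div0] <- "capped"
  ratio[both0] <- NA
  note[both0] <- "excluded"
  ok <- !is.na(ratio)
  sorted <- sort(ratio[ok])
  thr <- sorted[ceiling((1 - top_frac) * length(sorted))]
  out <- data.frame(chrom = pi_a$chrom, start = pi_a$start, end = pi_a$end,
                    pi_a = pi_a$pi, pi_b = pi_b$pi, ratio = ratio,
                    flagged = !is.na(ratio) & ratio >= thr, note = note)
  list(windows = out, threshold = thr)
}

# Weir-Cockerham (1984) per-site variance components for two populations
.wc_site <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                    (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                            (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

#' Windowed Weir-Cockerham F_ST
#'
#' Per-site variance components of the Weir-Cockerham estimator are
#' aggregated per window as a ratio of sums; negative aggregates are
#' reported as computed. Windows without shared polymorphic sites are NA,
#' flagged.
#'
#' @param panel_a,panel_b \linkS4class{GenotypeMatrix} panels sharing the
#'   variant set (each at least 2 accessions).
#' @param window_bp window size (2e4).
#' @param step_bp step (5e3).
#' @param genome optional chrom/length table.
#' @return data.frame: chrom, start, end, fst, n_sites, flag.
#' @export
windowedFst <- function(panel_a, panel_b, window_bp = 2e4, step_bp = 5e3,
                        genome = NULL) {
  if (nAccessions(panel_a) < 2 || nAccessions(panel_b) < 2) {
    stop("both panels need at least 2 accessions")
  }
  via <- variantInfo(panel_a)
  if (!all(via$id == variantInfo(panel_b)$id)) {
    stop("panels must share the variant set")
  }
  da <- dosages(panel_a); db <- dosages(panel_b)
  n1 <- colSums(!is.na(da)); n2 <- colSums(!is.na(db))
  p1 <- colSums(da, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(db, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(da == 1, na.rm = TRUE) / n1
  h2 <- colSums(db == 1, na.rm = TRUE) / n2
  poly <- n1 >= 2 & n2 >= 2 & ((p1 > 0 | p2 > 0) & (p1 < 1 | p2 < 1))
  comps <- matrix(NA_real_, length(n1), 3)
  for (j in which(poly)) {
    comps[j, ] <- .wc_site(n1[j], n2[j], p1[j], p2[j], h1[j], h2[j])
  }
  if (is.null(genome)) {
    genome <- stats::aggregate(pos ~ chrom, as.data.frame(via), max)
    names(genome) <- c("chrom", "length")
  }
  out <- list()
  for (i in seq_len(nrow(genome))) {
    ch <- genome$chrom[i]
    wins <- .tile_windows(genome$length[i], window_bp, step_bp)
    idx <- which(via$chrom == ch & poly)
    fst <- vapply(seq_len(nrow(wins)), function(k) {
      inw <- idx[via$pos[idx] >= wins$start[k] & via$pos[idx] <= wins$end[k]]
      if (length(inw) == 0) return(NA_real_)
      sum(comps[inw, 1]) / sum(comps[inw, ])
    }, numeric(1))
    ns <- vapply(seq_len(nrow(wins)), function(k)
      sum(via$pos[idx] >= wins$start[k] & via$pos[idx] <= wins$end[k]),
      numeric(1))
    out[[i]] <- data.frame(chrom = ch, start = wins$start, end = wins$end,
                           fst = fst, n_sites = ns,
                           flag = ifelse(ns == 0, "no_poly_sites", ""))
  }
  do.call(rbind, out)
}

#' Haplotype spectrum over defining variants across panels
#'
#' Concatenates alleles at the defining variants into per-accession
#' pseudo-haplotypes (two per accession, phase-free: one haplotype carries
#' the alternate allele wherever dosage is at least 1, the other wherever
#' dosage is 2 -- frequencies are phase-invariant). Accessions missing any
#' defining genotype are excluded from that panel's denominator.
#' Haplotypes are ranked by pooled frequency; all beyond \code{top_n} are
#' pooled as "other".
#'
#' @param panels named list of \linkS4class{GenotypeMatrix} sharing the
#'   variant set.
#' @param defining_variants variant ids.
#' @param top_n haplotypes reported individually (4).
#' @return list: \code{haplotypes} (id, allele string, pooled_freq),
#'   \code{freq} (panels x haplotypes frequency matrix), \code{counts}.
#' @export
haplotypeSpectrum <- function(panels, defining_variants, top_n = 4) {
  vi <- variantInfo(panels[[1]])
  j <- match(defining_variants, vi$id)
  if (anyNA(j) || length(j) == 0) stop("defining variants absent from panels")
  hap_strings <- lapply(panels, function(g) {
    d <- dosages(g)[, j, drop = FALSE]
    ok <- rowSums(is.na(d)) == 0
    d <- d[ok, , drop = FALSE]
    h1 <- (d >= 1) * 1L
    h2 <- (d == 2) * 1L
    c(apply(h1, 1, paste, collapse = ""), apply(h2, 1, paste, collapse = ""))
  })
  all_h <- unlist(hap_strings)
  pooled <- sort(table(all_h), decreasing = TRUE)
  ids <- names(pooled)
  top <- ids[seq_len(min(top_n, length(ids)))]
  lab <- function(h) ifelse(h %in% top,
                            paste0("Hap", match(h, top)), "other")
  levs <- c(paste0("Hap", seq_along(top)), "other")
  counts <- t(vapply(hap_strings, function(h)
    table(factor(lab(h), levels = levs)), numeric(length(levs))))
  freq <- counts / rowSums(counts)
  list(haplotypes = data.frame(id = paste0("Hap", seq_along(top)),
                               alleles = top,
                               pooled_freq = as.numeric(pooled[top] /
                                                        sum(pooled))),
       freq = freq, counts = counts)
}
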