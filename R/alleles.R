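#' Superior alleles of candidate genes
#'
#' The superior allele at a candidate gene's lead GWAS variant is the
#' trait-increasing allele by the sign of the GWAS effect on alternate
#' dosage: beta > 0 means the alternate allele is superior, beta < 0 the
#' reference allele. Candidates whose lead variant is absent from the
#' results are skipped with a message.
#'
#' @param candidates data.frame with gene, trait and \code{lead_gwas_id}.
#' @param gwas_results association data.frame with id and beta.
#' @return data.frame: gene, trait, lead, superior ("ref" or "alt"), beta.
#' @export
defineSuperiorAlleles <- function(candidates, gwas_results) {
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    j <- match(candidates$lead_gwas_id[i], gwas_results$id)
    if (is.na(j) || is.na(gwas_results$beta[j])) {
      message("lead ", candidates$lead_gwas_id[i], " absent; candidate ",
              candidates$gene[i], " skipped")
      return(NULL)
    }
    data.frame(gene = candidates$gene[i], trait = candidates$trait[i],
               lead = candidates$lead_gwas_id[i],
               superior = if (gwas_results$beta[j] > 0) "alt" else "ref",
               beta = gwas_results$beta[j])
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no candidates with usable lead variants")
  out
}

#' Superior-allele aggregation and top-vs-bottom test
#'
#' Counts superior-allele dosage (0/1/2 per candidate locus; alternate
#' dosage when the superior allele is alt, 2 minus it when ref) per
#' accession, ranks accessions by trait BLUE, and compares the counts of
#' the top-k and bottom-k accessions with a two-sided Wilcoxon rank-sum
#' test. Ties spanning the k-th rank break deterministically by accession
#' id. \code{binary = TRUE} counts carrier status (0/1) instead of dosage.
#'
#' @param sas superior-allele table from
#'   \code{\link{defineSuperiorAlleles}} (one trait).
#' @param g \linkS4class{GenotypeMatrix}.
#' @param blues named BLUE vector for the trait.
#' @param k group size (50).
#' @param binary carrier-status counting (FALSE).
#' @return list: \code{counts} (per accession), \code{p},
#'   \code{top_ids}, \code{bottom_ids}, \code{mean_top},
#'   \code{mean_bottom}.
#' @export
aggregateAndTest <- function(sas, g, blues, k = 50, binary = FALSE) {
  acc <- accessionInfo(g)$id
  if (2 * k > length(acc)) stop("2k exceeds accession count")
  vi <- variantInfo(g)
  d <- imputeMean(dosages(g))
  counts <- rep(0, length(acc))
  for (i in seq_len(nrow(sas))) {
    j <- match(sas$lead[i], vi$id)
    x <- d[, j]
    sup <- if (sas$superior[i] == "alt") x else 2 - x
    if (binary) sup <- as.numeric(sup > 0)
    counts <- counts + sup
  }
  names(counts) <- acc
  b <- blues[acc]
  ord <- order(-b, acc)
  top_ids <- acc[ord][seq_len(k)]
  bottom_ids <- acc[rev(ord)][seq_len(k)]
  wt <- suppressWarnings(
    stats::wilcox.test(counts[top_ids], counts[bottom_ids],
                       exact = (k <= 12)))
  list(counts = counts, p = wt$p.value, top_ids = top_ids,
       bottom_ids = bottom_ids, mean_top = mean(counts[top_ids]),
       mean_bottom = mean(counts[bottom_ids]))
}

#' MAF-versus-effect architecture profile
#'
#' Restricts association results to significant variants, orients effects
#' to the minor allele (the effect of adding one minor-allele copy), and
#' summarizes the architecture: Spearman rank correlation between MAF and
#' |effect| and the sign balance of minor-allele effects in MAF bins. A
#' persistent negative MAF-|effect| correlation with predominantly
#' negative minor-allele effects is the signature of negative selection.
#'
#' @param gwas_results association data.frame (id, maf, beta, p); effects
#'   must be on alternate-allele dosage with an \code{alt_freq} column, or
#'   alt is assumed minor when absent and maf equals the alt frequency
#'   clipped at 0.5.
#' @param p_threshold significance threshold.
#' @param bins MAF bin breaks (seq(0, 0.5, 0.1)).
#' @return list: \code{table} (per-variant maf, effect_minor, sign),
#'   \code{rank_cor}, \code{rank_p}, \code{sign_by_bin}; with fewer than 3
#'   significant variants the summary fields are NA and \code{flag} set.
#' @export
mafEffectProfile <- function(gwas_results, p_threshold,
                             bins = seq(0, 0.5, 0.1)) {
  sig <- gwas_results[!is.na(gwas_results$p) &
                      gwas_results$p < p_threshold, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(list(table = data.frame(id = character(), maf = numeric(),
                                   effect_minor = numeric(),
                                   sign = integer()),
                rank_cor = NA, rank_p = NA, sign_by_bin = NULL,
                flag = "no_significant_variants"))
  }
  alt_minor <- if ("alt_freq" %in% colnames(sig)) sig$alt_freq <= 0.5 else
    rep(TRUE, nrow(sig))
  effect_minor <- ifelse(alt_minor, sig$beta, -sig$beta)
  tab <- data.frame(id = sig$id, maf = sig$maf,
                    effect_minor = effect_minor,
                    sign = sign(effect_minor))
  if (nrow(tab) < 3) {
    return(list(table = tab, rank_cor = NA, rank_p = NA,
                sign_by_bin = NULL, flag = "too_few_variants"))
  }
  ct <- suppressWarnings(stats::cor.test(tab$maf, abs(tab$effect_minor),
                                         method = "spearman"))
  bin <- cut(tab$maf, bins, include.lowest = TRUE)
  sign_by_bin <- t(vapply(levels(bin), function(b) {
    s <- tab$sign[bin == b]
    c(n = length(s), pos = sum(s > 0), neg = sum(s < 0))
  }, numeric(3)))
  list(table = tab, rank_cor = unname(ct$estimate), rank_p = ct$p.value,
       sign_by_bin = sign_by_bin, flag = "")
}
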