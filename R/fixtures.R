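#' Write a GenotypeMatrix as VCF 4.2 with GT:GQ:DP
#'
#' Genotypes are written unphased ("0/0", "0/1", "1/1", "./."). GQ and DP
#' values are drawn to pass the standard quality filters, except for a
#' \code{missing_rate} fraction of calls which receive filter-tripping
#' values (low GQ for heterozygotes, low DP for homozygotes); the matrix
#' returned invisibly has those calls masked to missing, i.e. the dosage
#' matrix a filtering reader reproduces.
#'
#' @param g \linkS4class{GenotypeMatrix}.
#' @param path output file.
#' @param missing_rate fraction of calls given failing GQ/DP (0).
#' @param seed RNG seed for the GQ/DP draw.
#' @param het_site_frac the site-level heterozygote-fraction filter the
#'   returned matrix anticipates (0.02): sites whose post-masking het
#'   fraction exceeds it are dropped from the returned object, matching
#'   what \code{\link{readFilterVCF}} reproduces from the file.
#' @return invisibly, the post-filter \linkS4class{GenotypeMatrix}.
#' @export
writeVCF <- function(g, path, missing_rate = 0, seed = 1L,
                     het_site_frac = 0.02) {
  set.seed(seed)
  vi <- variantInfo(g)
  d <- dosages(g)
  n <- nrow(d); m <- ncol(d)
  gq <- matrix(sample(60:99, n * m, replace = TRUE), n, m)
  dp <- matrix(sample(6:30, n * m, replace = TRUE), n, m)
  masked <- d
  if (missing_rate > 0) {
    nbad <- rbinom(1, n * m, missing_rate)
    bad <- sample.int(n * m, nbad)
    for (ij in bad) {
      if (!is.na(d[ij]) && d[ij] == 1) gq[ij] <- sample(0:19, 1)
      else dp[ij] <- sample(0:1, 1)
      masked[ij] <- NA
    }
  }
  gt_str <- matrix("./.", n, m)
  gt_str[!is.na(d) & d == 0] <- "0/0"
  gt_str[!is.na(d) & d == 1] <- "0/1"
  gt_str[!is.na(d) & d == 2] <- "1/1"
  cells <- matrix(paste0(gt_str, ":", gq, ":", dp), n, m)
  cells[is.na(d)] <- "./.:.:."
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(as.character(vi$chrom)), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", accessionInfo(g)$id), collapse = "\t"))
  body <- vapply(seq_len(m), function(j) {
    paste(c(as.character(vi$chrom[j]), vi$pos[j], vi$id[j], vi$ref[j],
            vi$alt[j], ".", "PASS", ".", "GT:GQ:DP", cells[, j]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  het_frac <- colSums(!is.na(masked) & masked == 1) / n
  keep <- het_frac <= het_site_frac
  invisible(GenotypeMatrix(masked[, keep, drop = FALSE],
                           as.data.frame(vi[keep, setdiff(colnames(vi),
                                                          "maf")]),
                           as.data.frame(accessionInfo(g))))
}

#' Write the full synthetic fixture set
#'
#' Generates genotypes, expression, traits and open-chromatin intervals
#' from one configuration and writes: \code{genotypes.vcf} (GT:GQ:DP, with
#' \code{missing_rate} filter-tripping calls), \code{expression.tsv}
#' (genes x accessions TPM), \code{phenotypes.tsv} (accession_id, trait,
#' year, value, blue), \code{genes.gff3}, \code{ocr.bed} (0-based
#' half-open) and \code{truth_*.tsv} tables. Output is byte-identical for
#' identical configurations.
#'
#' @param outdir output directory (created).
#' @param cfg \code{\link{simConfig}}.
#' @return invisibly, list with the generated objects (\code{geno},
#'   \code{geno_masked}, \code{expr}, \code{pheno}, \code{truth},
#'   \code{paths}).
#' @export
writeFixtureSet <- function(outdir, cfg) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  geno <- simulateGenotypes(cfg)
  sim <- simulateExpression(geno, cfg)
  tr <- simulateTraits(geno, cfg, truth = sim$truth)
  paths <- list(
    vcf = file.path(outdir, "genotypes.vcf"),
    expr = file.path(outdir, "expression.tsv"),
    pheno = file.path(outdir, "phenotypes.tsv"),
    gff = file.path(outdir, "genes.gff3"),
    bed = file.path(outdir, "ocr.bed"),
    truth_local = file.path(outdir, "truth_local_eqtls.tsv"),
    truth_hot = file.path(outdir, "truth_hotspots.tsv"),
    truth_mod = file.path(outdir, "truth_modules.tsv"),
    truth_trait = file.path(outdir, "truth_trait_effects.tsv"))
  geno_masked <- writeVCF(geno, paths$vcf, missing_rate = cfg$missing_rate,
                          seed = cfg$seed + 7L)
  tpm <- SummarizedExperiment::assay(sim$expr, "tpm")
  utils::write.table(
    data.frame(gene_id = rownames(tpm), signif(tpm, 6),
               check.names = FALSE),
    paths$expr, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tr$pheno, paths$pheno, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gr <- SummarizedExperiment::rowRanges(sim$expr)
  gff <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    source = "seedomics", type = "gene",
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    score = ".", strand = as.character(GenomicRanges::strand(gr)),
    phase = ".", attributes = paste0("ID=", gr$gene, ";Name=", gr$gene))
  writeLines(c("##gff-version 3",
               apply(gff, 1, paste, collapse = "\t")), paths$gff)
  # OCRs: intervals around a random subset of TSSs plus random background
  set.seed(cfg$seed + 8L)
  tssn <- sample(length(gr), max(2, round(0.2 * length(gr))))
  ocr <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr))[tssn],
    start = pmax(gr$tss[tssn] - 1500, 1),
    end = gr$tss[tssn] + 1500)
  rnd <- data.frame(
    chrom = paste0("chr", sample.int(cfg$n_chromosomes,
                                     nrow(ocr), replace = TRUE)),
    start = sample.int(cfg$chrom_length_bp - 4000L, nrow(ocr)))
  rnd$end <- rnd$start + 2999
  ocr <- rbind(ocr, rnd)
  ocr <- ocr[order(ocr$chrom, ocr$start), ]
  # BED is 0-based half-open
  writeLines(paste(ocr$chrom, ocr$start - 1, ocr$end, sep = "\t"),
             paths$bed)
  truth <- tr$truth
  utils::write.table(truth@local_eqtls, paths$truth_local, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  hot <- do.call(rbind, lapply(truth@hotspots, function(h)
    data.frame(variant = h$variant, target = h$targets,
               effect = h$effects)))
  utils::write.table(hot, paths$truth_hot, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth@modules, paths$truth_mod, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth@trait_effects, paths$truth_trait, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(geno = geno, geno_masked = geno_masked, expr = sim$expr,
                 pheno = tr$pheno, genetic_values = tr$genetic_values,
                 truth = truth, paths = paths))
}

#' Read an expression TSV (gene_id column + accession columns)
#'
#' @param path TSV written by \code{\link{writeFixtureSet}}.
#' @param gene_coords optional GRanges to attach as rowRanges.
#' @return \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   \code{tpm} assay.
#' @export
readExpressionTSV <- function(path, gene_coords = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  tpm <- as.matrix(df[, -1, drop = FALSE])
  rownames(tpm) <- df$gene_id
  if (!is.null(gene_coords)) {
    SummarizedExperiment::SummarizedExperiment(
      assays = list(tpm = tpm),
      rowRanges = gene_coords[match(rownames(tpm), gene_coords$gene)])
  } else {
    SummarizedExperiment::SummarizedExperiment(assays = list(tpm = tpm))
  }
}

#' Read gene models from a GFF3 file
#'
#' Imports \code{gene} features and derives the strand-aware TSS.
#'
#' @param path GFF3 file.
#' @return GRanges with \code{gene} and \code{tss} metadata.
#' @export
readGeneGFF3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  gr$gene <- gr$ID
  gr$tss <- ifelse(as.character(GenomicRanges::strand(gr)) == "+",
                   GenomicRanges::start(gr), GenomicRanges::end(gr))
  gr
}

#' Read OCR intervals from a BED file (to 1-based inclusive)
#'
#' @param path BED file (0-based half-open).
#' @return GRanges (1-based inclusive, the internal convention).
#' @export
readOCRBed <- function(path) {
  rtracklayer::import(path, format = "bed")
}
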