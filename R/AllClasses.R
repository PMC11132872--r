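#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' GenotypeMatrix: diploid dosage matrix with variant and accession metadata
#'
#' The central genotype container: an accessions x variants matrix of
#' alternate-allele dosages (0, 1, 2 or \code{NA} for missing calls),
#' together with per-variant metadata (chromosome, 1-based position, REF and
#' ALT alleles, minor-allele frequency) and per-accession metadata (id and an
#' optional subpopulation or panel label).
#'
#' Variants are kept position-sorted within chromosome and the stored MAF is
#' recomputed whenever dosages change, so that \code{variantInfo(x)$maf}
#' always reflects the current matrix (missing genotypes are excluded from
#' the allele-frequency denominator).
#'
#' @slot dosage numeric matrix, accessions in rows, variants in columns.
#' @slot variants \code{DataFrame} with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{maf}; one row per variant.
#' @slot accessions \code{DataFrame} with columns \code{id} and optionally
#'   \code{subpop}; one row per accession.
#'
#' @aliases GenotypeMatrix
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  slots = c(
    dosage = "matrix",
    variants = "DataFrame",
    accessions = "DataFrame"
  )
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  d <- object@dosage
  v <- object@variants
  a <- object@accessions
  if (ncol(d) != nrow(v)) {
    msg <- c(msg, "number of dosage columns must equal number of variant rows")
  }
  if (nrow(d) != nrow(a)) {
    msg <- c(msg, "number of dosage rows must equal number of accession rows")
  }
  need <- c("chrom", "pos", "ref", "alt", "maf")
  if (!all(need %in% colnames(v))) {
    msg <- c(msg, paste("variants must have columns:", paste(need, collapse = ", ")))
  } else {
    if (nrow(v) > 0) {
      byc <- split(v$pos, as.character(v$chrom))
      if (!all(vapply(byc, function(p) !is.unsorted(p), logical(1)))) {
        msg <- c(msg, "variant positions must be sorted within chromosome")
      }
      ok <- is.na(v$maf) | (v$maf >= 0 & v$maf <= 0.5 + 1e-12)
      if (!all(ok)) msg <- c(msg, "maf must lie in [0, 0.5] (or NA)")
    }
  }
  if (!("id" %in% colnames(a))) msg <- c(msg, "accessions must have an 'id' column")
  bad <- d[!is.na(d) & !(d %in% 0:2)]
  if (length(bad) > 0) msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage accessions x variants matrix of dosages in \{0,1,2,NA\}.
#' @param variants data.frame or DataFrame with chrom, pos, ref, alt
#'   (maf is recomputed).
#' @param accessions data.frame or DataFrame with id (and optional subpop),
#'   or a character vector of ids.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(dosage, variants, accessions) {
  if (is.character(accessions)) accessions <- DataFrame(id = accessions)
  variants <- DataFrame(variants)
  accessions <- DataFrame(accessions)
  variants$maf <- .maf_from_dosage(dosage)
  rownames(dosage) <- accessions$id
  vid <- if ("id" %in% colnames(variants)) variants$id else
    paste0(variants$chrom, "_", variants$pos)
  variants$id <- vid
  colnames(dosage) <- vid
  new("GenotypeMatrix", dosage = dosage, variants = variants,
      accessions = accessions)
}

.maf_from_dosage <- function(dosage) {
  if (ncol(dosage) == 0) return(numeric(0))
  alt <- colSums(dosage, na.rm = TRUE)
  n2 <- 2 * colSums(!is.na(dosage))
  p <- ifelse(n2 > 0, alt / n2, NA_real_)
  pmin(p, 1 - p)
}

#' @describeIn GenotypeMatrix-class number of accessions
#' @param x a GenotypeMatrix
#' @export
nAccessions <- function(x) nrow(x@dosage)

#' @describeIn GenotypeMatrix-class number of variants
#' @export
nVariants <- function(x) ncol(x@dosage)

#' Accessors for GenotypeMatrix
#'
#' \code{dosages} returns the accessions x variants dosage matrix;
#' \code{variantInfo} the per-variant metadata; \code{accessionInfo} the
#' per-accession metadata.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @return matrix or DataFrame.
#' @export
dosages <- function(x) x@dosage

#' @rdname dosages
#' @export
variantInfo <- function(x) x@variants

#' @rdname dosages
#' @export
accessionInfo <- function(x) x@accessions

#' Subset a GenotypeMatrix by accessions (i) and variants (j)
#'
#' MAF is recomputed on the retained accessions.
#'
#' @param x GenotypeMatrix
#' @param i accession index
#' @param j variant index
#' @param ... ignored
#' @param drop ignored, always FALSE
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nAccessions(x))
  if (missing(j)) j <- seq_len(nVariants(x))
  if (is.character(i)) i <- match(i, x@accessions$id)
  if (is.character(j)) j <- match(j, x@variants$id)
  GenotypeMatrix(x@dosage[i, j, drop = FALSE],
                 x@variants[j, setdiff(colnames(x@variants), "maf"), drop = FALSE],
                 x@accessions[i, , drop = FALSE])
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nAccessions(object), "accessions x",
      nVariants(object), "variants\n")
  cat("  chromosomes:",
      paste(unique(as.character(object@variants$chrom)), collapse = ", "), "\n")
  miss <- mean(is.na(object@dosage))
  cat(sprintf("  missing genotype rate: %.3f\n", miss))
  if ("subpop" %in% colnames(object@accessions)) {
    tb <- table(object@accessions$subpop)
    cat("  subpopulations:",
        paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
})

#' Ground truth of a synthetic data set
#'
#' Records every planted signal of the generator so downstream analyses can
#' be scored against it: local eQTLs (variant, gene, effect), trans-hotspot
#' regulators with their distal target sets, module memberships, per-variant
#' trait effects and mediator genes, and the swept-haplotype frequencies per
#' panel.
#'
#' @slot local_eqtls data.frame: variant, gene, effect.
#' @slot hotspots list: one element per regulator, each with
#'   \code{variant}, \code{targets} (gene ids), \code{effects}.
#' @slot modules data.frame: gene, module.
#' @slot trait_effects data.frame: variant, effect_sw, effect_oil.
#' @slot mediator_genes character vector of genes whose local eQTL variant
#'   also carries a trait effect (the expression-mediated chain TWAS should
#'   recover).
#' @slot sweep list with \code{region} (chrom, start, end),
#'   \code{haplotype} (allele string), \code{panel_freq} (named numeric).
#' @slot module_factors accessions x modules matrix of the latent factors
#'   that generated the module coexpression (for source-recovery scoring).
#' @exportClass TruthTable
setClass("TruthTable",
  slots = c(
    local_eqtls = "data.frame",
    hotspots = "list",
    modules = "data.frame",
    trait_effects = "data.frame",
    mediator_genes = "character",
    sweep = "list",
    module_factors = "matrix"
  )
)

setMethod("show", "TruthTable", function(object) {
  cat("TruthTable:", nrow(object@local_eqtls), "planted local eQTLs,",
      length(object@hotspots), "hotspot regulators,",
      length(unique(object@modules$module)), "modules,",
      nrow(object@trait_effects), "trait-effect variants\n")
})

#' @describeIn TruthTable-class planted local eQTL table
#' @param x a TruthTable
#' @export
plantedLocalEQTLs <- function(x) x@local_eqtls

#' @describeIn TruthTable-class planted hotspot regulators
#' @export
plantedHotspots <- function(x) x@hotspots

#' @describeIn TruthTable-class planted module membership
#' @export
plantedModules <- function(x) x@modules

#' @describeIn TruthTable-class planted trait effects per variant
#' @export
plantedTraitEffects <- function(x) x@trait_effects

#' @describeIn TruthTable-class genes with an expression-mediated trait effect
#' @export
mediatorGenes <- function(x) x@mediator_genes

#' @describeIn TruthTable-class swept haplotype description
#' @export
plantedSweep <- function(x) x@sweep

#' @describeIn TruthTable-class latent module factors (accessions x modules)
#' @export
moduleFactors <- function(x) x@module_factors
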