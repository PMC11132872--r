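#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' structure of a mid-sized resequenced crop panel: a few hundred accessions
#' drawn from a handful of subpopulations, genome-wide SNPs with block-wise
#' LD, genes with local eQTLs near their TSS, trans-regulatory hotspots each
#' driving a set of distant genes, coexpressed gene modules, and two
#' positively genetically correlated quantitative traits.
#'
#' @param n_accessions number of accessions (default 400).
#' @param n_chromosomes number of chromosomes (default 5).
#' @param chrom_length_bp chromosome length in bp (default 30e6).
#' @param n_variants total number of biallelic variants (default 5000).
#' @param n_subpops number of subpopulations (default 4).
#' @param target_fst differentiation among subpopulations under the
#'   Balding-Nichols model, in [0, 1) (default 0.1).
#' @param maf_floor lower bound of the ancestral allele-frequency draw
#'   (default 0.05).
#' @param ld_decay_bp length scale (bp) of the exponential decay of
#'   haplotype correlation along a chromosome (default 3e5; LD persists
#'   over long distances in selfing crop panels).
#' @param n_genes number of genes (default 1000).
#' @param frac_local_egenes fraction of genes given a planted local eQTL
#'   within 100 kb of the TSS (default 0.3).
#' @param n_hotspots number of trans-regulator variants (default 2).
#' @param genes_per_hotspot distal targets per regulator, all > 1 Mb away
#'   (default 20).
#' @param n_modules number of coexpression modules driven by non-Gaussian
#'   latent factors (default 3).
#' @param module_size genes per module (default 60).
#' @param trait_h2 length-2 vector of narrow-sense heritabilities for
#'   (seed weight, oil content) (default c(0.7, 0.5)).
#' @param trait_rg genetic correlation planted between the two traits
#'   (default 0.39).
#' @param n_causal_variants polygenic background variants per trait
#'   (default 300).
#' @param noise_sd residual SD of log-scale expression (default 1).
#' @param het_rate residual per-genotype heterozygosity of the (selfing)
#'   panel (default 0.005).
#' @param missing_rate fraction of genotype calls given GQ/DP values that
#'   trip the quality filters (default 0.02).
#' @param panel_size accessions per wild/landrace/cultivar panel
#'   (default 200).
#' @param sweep_freqs swept-haplotype target frequency in the wild,
#'   landrace and cultivar panels (default c(0.3, 0.8, 0.95)).
#' @param sweep_region_bp width of the swept region (default 2e5).
#' @param seed integer seed; all generator output is a pure function of the
#'   configuration including this seed.
#' @return A list of class \code{SimConfig}.
#' @export
simConfig <- function(n_accessions = 400, n_chromosomes = 5,
                      chrom_length_bp = 30e6, n_variants = 5000,
                      n_subpops = 4, target_fst = 0.1, maf_floor = 0.05,
                      ld_decay_bp = 3e5, n_genes = 1000,
                      frac_local_egenes = 0.3, n_hotspots = 2,
                      genes_per_hotspot = 20, n_modules = 3,
                      module_size = 60, trait_h2 = c(0.7, 0.5),
                      trait_rg = 0.39, n_causal_variants = 300,
                      noise_sd = 1, het_rate = 0.005, missing_rate = 0.02,
                      panel_size = 200,
                      sweep_freqs = c(wild = 0.3, landrace = 0.8,
                                      cultivar = 0.95),
                      sweep_region_bp = 2e5, seed = 1L) {
  cfg <- list(n_accessions = n_accessions, n_chromosomes = n_chromosomes,
              chrom_length_bp = chrom_length_bp, n_variants = n_variants,
              n_subpops = n_subpops, target_fst = target_fst,
              maf_floor = maf_floor, ld_decay_bp = ld_decay_bp,
              n_genes = n_genes, frac_local_egenes = frac_local_egenes,
              n_hotspots = n_hotspots, genes_per_hotspot = genes_per_hotspot,
              n_modules = n_modules, module_size = module_size,
              trait_h2 = trait_h2, trait_rg = trait_rg,
              n_causal_variants = n_causal_variants, noise_sd = noise_sd,
              het_rate = het_rate, missing_rate = missing_rate,
              panel_size = panel_size,
              sweep_freqs = sweep_freqs, sweep_region_bp = sweep_region_bp,
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

#' Validate a SimConfig
#'
#' Checks count positivity, fraction ranges and internal consistency;
#' called by \code{\link{simConfig}} and by every generator entry point.
#'
#' @param cfg a SimConfig.
#' @return invisibly \code{TRUE}; stops with a message on violation.
#' @export
validateSimConfig <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  counts <- c("n_accessions", "n_chromosomes", "n_variants", "n_subpops",
              "n_genes", "n_hotspots", "genes_per_hotspot", "n_modules",
              "module_size", "panel_size")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 1) {
      stop("SimConfig field '", nm, "' must be a count >= 1")
    }
  }
  if (cfg$target_fst < 0 || cfg$target_fst >= 1) {
    stop("target_fst must lie in [0, 1)")
  }
  if (cfg$maf_floor < 0 || cfg$maf_floor >= 0.5) {
    stop("maf_floor must lie in [0, 0.5)")
  }
  if (cfg$frac_local_egenes < 0 || cfg$frac_local_egenes > 1) {
    stop("frac_local_egenes must lie in [0, 1]")
  }
  if (cfg$frac_local_egenes * cfg$n_genes < 1) {
    stop("frac_local_egenes * n_genes must be >= 1")
  }
  if (abs(cfg$trait_rg) > 1) stop("|trait_rg| must be <= 1")
  if (any(cfg$trait_h2 < 0 | cfg$trait_h2 > 1) || length(cfg$trait_h2) != 2) {
    stop("trait_h2 must be two fractions in [0, 1]")
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$n_variants < cfg$n_chromosomes) {
    stop("n_variants must be >= n_chromosomes")
  }
  invisible(TRUE)
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig:", x$n_accessions, "accessions,", x$n_variants,
      "variants on", x$n_chromosomes, "chromosomes,", x$n_genes,
      "genes; seed", x$seed, "\n")
  invisible(x)
}

# split n items as evenly as possible over k groups
.split_counts <- function(n, k) diff(round(seq(0, n, length.out = k + 1)))

# rows x variants matrix of AR(1) standard normals whose autocorrelation
# decays as exp(-distance / decay) along each chromosome
.ar1_latent <- function(nrow, chrom, pos, decay) {
  m <- length(pos)
  Z <- matrix(0, nrow, m)
  z <- rnorm(nrow)
  Z[, 1] <- z
  if (m > 1) {
    for (j in 2:m) {
      a_j <- if (chrom[j] == chrom[j - 1]) {
        exp(-(pos[j] - pos[j - 1]) / decay)
      } else 0
      z <- a_j * z + sqrt(1 - a_j^2) * rnorm(nrow)
      Z[, j] <- z
    }
  }
  Z
}

# Balding-Nichols subpopulation frequencies around ancestral p0, spatially
# autocorrelated via a Gaussian copula through the Beta marginals (nearby
# variants get similar frequencies, as shared genealogy produces)
.bn_freqs <- function(p0, Fst, n_pops, chrom, pos, decay) {
  m <- length(p0)
  if (Fst <= 0) {
    return(matrix(rep(p0, each = n_pops), nrow = n_pops))
  }
  a <- p0 * (1 - Fst) / Fst
  b <- (1 - p0) * (1 - Fst) / Fst
  V <- .ar1_latent(n_pops, chrom, pos, decay)
  t(vapply(seq_len(n_pops), function(s)
    qbeta(pnorm(V[s, ]), a, b), numeric(m)))
}

#' Simulate a structured, LD-patterned genotype panel
#'
#' Allele frequencies follow a Balding-Nichols model: an ancestral frequency
#' is drawn uniformly above \code{maf_floor} for each variant, and each
#' subpopulation's frequency is a Beta draw around it with variance governed
#' by \code{target_fst}. Haplotypes are generated by thresholding a latent
#' AR(1) Gaussian process whose autocorrelation decays as
#' \code{exp(-distance / ld_decay_bp)}, which preserves the per-variant
#' marginal frequencies while inducing realistic block-wise LD.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param subpop_freqs optional matrix (n_subpops x n_variants) of
#'   per-subpopulation allele frequencies, overriding the Balding-Nichols
#'   draw (used internally for the panel generator).
#' @param variants optional data.frame (chrom, pos) fixing the variant
#'   coordinates, so several panels can share one variant set.
#' @return A \linkS4class{GenotypeMatrix} with a \code{subpop} accession
#'   column.
#' @examples
#' g <- simulateGenotypes(simConfig(n_accessions = 40, n_variants = 200,
#'                                  n_chromosomes = 2, seed = 7))
#' g
#' @export
simulateGenotypes <- function(cfg, subpop_freqs = NULL, variants = NULL) {
  validateSimConfig(cfg)
  set.seed(cfg$seed)
  m <- cfg$n_variants
  n <- cfg$n_accessions
  if (is.null(variants)) {
    per_chrom <- .split_counts(m, cfg$n_chromosomes)
    chrom <- rep(paste0("chr", seq_len(cfg$n_chromosomes)), per_chrom)
    pos <- unlist(lapply(per_chrom, function(k)
      sort(sample.int(cfg$chrom_length_bp - 1000L, k)) + 500L))
  } else {
    chrom <- as.character(variants$chrom)
    pos <- variants$pos
    m <- length(pos)
  }
  # ancestral frequencies: uniform marginal above maf_floor, spatially
  # autocorrelated so that linked variants have similar frequencies
  p0 <- cfg$maf_floor + (1 - 2 * cfg$maf_floor) *
    pnorm(.ar1_latent(1, chrom, pos, 2 * cfg$ld_decay_bp)[1, ])
  if (is.null(subpop_freqs)) {
    subpop_freqs <- .bn_freqs(p0, cfg$target_fst, cfg$n_subpops, chrom, pos,
                              2 * cfg$ld_decay_bp)
  }
  subpop <- rep_len(seq_len(nrow(subpop_freqs)), n)
  # selfing panel: one founder haplotype per accession (dosage 2 x hap),
  # with a small residual per-genotype heterozygosity injected afterwards
  thr <- qnorm(subpop_freqs)            # subpop x variant
  Z <- .ar1_latent(n, chrom, pos, cfg$ld_decay_bp)
  haps <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    haps[, j] <- as.integer(Z[, j] < thr[subpop, j])
  }
  dos <- 2L * haps
  if (cfg$het_rate > 0) {
    nh <- rbinom(1, n * m, cfg$het_rate)
    if (nh > 0) dos[sample.int(n * m, nh)] <- 1L
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  acc <- DataFrame(id = sprintf("acc%04d", seq_len(n)),
                   subpop = paste0("pop", subpop))
  GenotypeMatrix(dos,
                 data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt),
                 acc)
}

# evenly spaced gene models along the simulated chromosomes
.sim_gene_coords <- function(cfg) {
  per_chrom <- .split_counts(cfg$n_genes, cfg$n_chromosomes)
  out <- do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(k) {
    ng <- per_chrom[k]
    if (ng == 0) return(NULL)
    start <- round(seq(1e4, cfg$chrom_length_bp - 2e4, length.out = ng))
    data.frame(chrom = paste0("chr", k), start = start, end = start + 2999L,
               strand = rep_len(c("+", "-"), ng),
               stringsAsFactors = FALSE)
  }))
  out$gene <- sprintf("gene%04d", seq_len(nrow(out)))
  out$tss <- ifelse(out$strand == "+", out$start, out$end)
  out
}

#' Simulate a population expression matrix with planted regulatory structure
#'
#' Expression is assembled on the log scale as the sum of a gene baseline,
#' planted local-eQTL effects (a variant within 100 kb of the TSS), planted
#' trans-hotspot effects (each regulator variant drives
#' \code{genes_per_hotspot} genes more than 1 Mb away), non-Gaussian module
#' latent factors, and Gaussian noise, then exponentiated to a pseudo-TPM
#' scale so that expression-level filters are exercisable. A fraction of
#' genes is given a low baseline so the TPM filter removes them.
#'
#' Hotspot target sets are nested inside module gene sets (module k is
#' driven by regulator k for k up to \code{n_hotspots}), and each such
#' module's latent factor includes the regulator's standardized dosage, so
#' module-level association scans can recover the planted regulators.
#'
#' @param geno \linkS4class{GenotypeMatrix} from
#'   \code{\link{simulateGenotypes}} (same cfg).
#' @param cfg the \code{\link{simConfig}} used for \code{geno}.
#' @return A list with \code{expr}, a
#'   \link[SummarizedExperiment]{SummarizedExperiment} (assay \code{tpm},
#'   genes x accessions, gene coordinates in \code{rowRanges}); and
#'   \code{truth}, a \linkS4class{TruthTable}.
#' @export
simulateExpression <- function(geno, cfg) {
  validateSimConfig(cfg)
  set.seed(cfg$seed + 1L)
  genes <- .sim_gene_coords(cfg)
  n <- nAccessions(geno)
  vi <- variantInfo(geno)
  dos <- dosages(geno)
  dos_imp <- imputeMean(dos)
  E <- matrix(rnorm(cfg$n_genes * n, 0, cfg$noise_sd), cfg$n_genes, n)
  base <- rnorm(cfg$n_genes, 3, 0.5)
  low <- sample.int(cfg$n_genes, round(0.08 * cfg$n_genes))
  base[low] <- rnorm(length(low), -1, 0.3)

  # module gene sets first, so hotspot targets can be nested inside them
  mod_genes <- list()
  pool <- setdiff(seq_len(cfg$n_genes), low)
  for (k in seq_len(cfg$n_modules)) {
    pick <- sample(pool, min(cfg$module_size, length(pool)))
    mod_genes[[k]] <- pick
    pool <- setdiff(pool, pick)
  }

  # planted hotspots: regulator variant + distal targets inside module k
  hotspots <- list()
  if (cfg$n_hotspots > 0) {
    reg_chroms <- rep_len(unique(vi$chrom), cfg$n_hotspots)
    for (k in seq_len(cfg$n_hotspots)) {
      cand <- which(vi$chrom == reg_chroms[k] & vi$maf > 0.2 &
                    vi$pos > 2e6 & vi$pos < cfg$chrom_length_bp - 2e6)
      reg <- sample(cand, 1)
      host <- if (k <= length(mod_genes)) mod_genes[[k]] else
        sample(setdiff(seq_len(cfg$n_genes), low), cfg$genes_per_hotspot)
      far <- host[genes$chrom[host] != vi$chrom[reg] |
                  abs(genes$tss[host] - vi$pos[reg]) > 1e6]
      targets <- far[seq_len(min(cfg$genes_per_hotspot, length(far)))]
      eff <- sample(c(-1, 1), length(targets), TRUE) * runif(length(targets), 0.4, 0.8)
      x <- scale(dos_imp[, reg])[, 1]
      E[targets, ] <- E[targets, ] + outer(eff, x)
      hotspots[[k]] <- list(variant = vi$id[reg], targets = genes$gene[targets],
                            effects = eff)
    }
  }

  # module latent factors: skewed (non-Gaussian) so ICA can separate them;
  # modules hosting a hotspot also load on the regulator dosage
  factors <- matrix(0, n, length(mod_genes),
                    dimnames = list(accessionInfo(geno)$id,
                                    paste0("M", seq_along(mod_genes))))
  for (k in seq_along(mod_genes)) {
    u <- scale(rgamma(n, shape = 2))[, 1]
    if (k <= length(hotspots)) {
      xreg <- scale(dos_imp[, match(hotspots[[k]]$variant, vi$id)])[, 1]
      u <- 0.8 * xreg + 0.6 * u
    }
    factors[, k] <- u
    w <- sample(c(-1, 1), length(mod_genes[[k]]), TRUE) *
      runif(length(mod_genes[[k]]), 0.6, 1.2)
    E[mod_genes[[k]], ] <- E[mod_genes[[k]], ] + outer(w, u)
  }

  # planted local eQTLs within 100 kb of the TSS
  n_local <- round(cfg$frac_local_egenes * cfg$n_genes)
  local_hosts <- sample(setdiff(seq_len(cfg$n_genes), low), n_local)
  le <- lapply(local_hosts, function(gi) {
    same <- which(vi$chrom == genes$chrom[gi] &
                  abs(vi$pos - genes$tss[gi]) <= 1e5 & vi$maf >= 0.15)
    if (length(same) == 0) return(NULL)
    v <- same[sample.int(length(same), 1)]
    b <- sample(c(-1, 1), 1) * runif(1, 0.6, 1.2)
    E[gi, ] <<- E[gi, ] + b * dos_imp[, v]
    data.frame(variant = vi$id[v], gene = genes$gene[gi], effect = b)
  })
  local_eqtls <- do.call(rbind, le[!vapply(le, is.null, logical(1))])

  tpm <- exp(E + base)
  rownames(tpm) <- genes$gene
  colnames(tpm) <- accessionInfo(geno)$id
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end),
                               strand = genes$strand)
  names(gr) <- genes$gene
  gr$gene <- genes$gene
  gr$tss <- genes$tss
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = tpm), rowRanges = gr,
    colData = accessionInfo(geno))
  mods <- data.frame(
    gene = genes$gene[unlist(mod_genes)],
    module = rep(paste0("M", seq_along(mod_genes)),
                 lengths(mod_genes)))
  truth <- new("TruthTable", local_eqtls = local_eqtls, hotspots = hotspots,
               modules = mods,
               trait_effects = data.frame(variant = character(),
                                          effect_sw = numeric(),
                                          effect_oil = numeric()),
               mediator_genes = character(), sweep = list(),
               module_factors = factors)
  list(expr = se, truth = truth)
}

#' Simulate two genetically correlated traits
#'
#' Per-variant effects for the two traits are drawn from a bivariate normal
#' with correlation \code{trait_rg}; genetic values are scaled to the target
#' heritabilities and independent environmental noise is added per year.
#' When a \linkS4class{TruthTable} from \code{\link{simulateExpression}} is
#' supplied, hotspot regulator variants receive strong same-sign effects on
#' both traits (so the hosting module correlates with both traits, the
#' pattern seen for pleiotropic seed-trait modules) and a few local-eQTL
#' variants are promoted to expression-mediated trait effects, recorded as
#' mediator genes for TWAS scoring.
#'
#' @param geno \linkS4class{GenotypeMatrix}.
#' @param cfg the matching \code{\link{simConfig}}.
#' @param truth optional \linkS4class{TruthTable} to align trait effects
#'   with planted regulatory structure.
#' @param n_mediators number of local eGenes promoted to mediators
#'   (default 5).
#' @return list with \code{pheno} (long data.frame: accession_id, trait,
#'   year, value, blue), \code{genetic_values} (accessions x 2 matrix) and
#'   \code{truth} (updated TruthTable, or NULL if none supplied).
#' @export
simulateTraits <- function(geno, cfg, truth = NULL, n_mediators = 5) {
  validateSimConfig(cfg)
  if (abs(cfg$trait_rg) > 1) stop("|trait_rg| must be <= 1")
  set.seed(cfg$seed + 2L)
  vi <- variantInfo(geno)
  dos_imp <- imputeMean(dosages(geno))
  n <- nAccessions(geno)
  m <- nVariants(geno)
  nc <- min(cfg$n_causal_variants, m)
  causal <- sort(sample.int(m, nc))
  rg <- cfg$trait_rg
  z1 <- rnorm(nc)
  z2 <- rg * z1 + sqrt(1 - rg^2) * rnorm(nc)
  eff <- cbind(sw = z1, oil = z2)
  ids <- vi$id[causal]
  med_genes <- character()
  if (!is.null(truth)) {
    for (h in truth@hotspots) {
      j <- match(h$variant, vi$id)
      if (!(j %in% causal)) { causal <- c(causal, j); ids <- c(ids, h$variant)
        eff <- rbind(eff, c(0, 0)) }
      k <- match(h$variant, ids)
      # fixed variance share regardless of the regulator's MAF
      sx <- max(stats::sd(dos_imp[, j]), 0.3)
      eff[k, ] <- c(9, 9) / sx     # major pleiotropic locus, same sign
    }
    le <- truth@local_eqtls
    if (nrow(le) > 0) {
      med <- le[sample.int(nrow(le), min(n_mediators, nrow(le))), ]
      for (r in seq_len(nrow(med))) {
        j <- match(med$variant[r], vi$id)
        if (!(j %in% causal)) { causal <- c(causal, j)
          ids <- c(ids, med$variant[r]); eff <- rbind(eff, c(0, 0)) }
        k <- match(med$variant[r], ids)
        # trait effect aligned with the expression effect => mediation chain
        sx <- max(stats::sd(dos_imp[, j]), 0.3)
        eff[k, ] <- eff[k, ] + (4.5 / sx) * sign(med$effect[r])
      }
      med_genes <- med$gene
    }
  }
  G <- dos_imp[, causal, drop = FALSE] %*% eff
  h2 <- cfg$trait_h2
  gv <- matrix(0, n, 2, dimnames = list(accessionInfo(geno)$id,
                                        c("seed_weight", "oil_content")))
  pheno <- NULL
  for (t in 1:2) {
    g <- G[, t]
    sg <- stats::sd(g)
    g <- if (sg > 0 && h2[t] > 0) (g - mean(g)) / sg * sqrt(h2[t]) else g * 0
    gv[, t] <- g
    for (year in c(2019L, 2020L)) {
      e <- rnorm(n, 0, sqrt(max(1 - h2[t], 0)))
      pheno <- rbind(pheno, data.frame(
        accession_id = accessionInfo(geno)$id,
        trait = colnames(gv)[t], year = year, value = g + e))
    }
  }
  blue <- stats::aggregate(value ~ accession_id + trait, pheno, mean)
  names(blue)[3] <- "blue"
  pheno <- merge(pheno, blue, by = c("accession_id", "trait"), sort = FALSE)
  pheno <- pheno[order(pheno$trait, pheno$year, pheno$accession_id), ]
  rownames(pheno) <- NULL
  if (!is.null(truth)) {
    truth@trait_effects <- data.frame(variant = ids, effect_sw = eff[, 1],
                                      effect_oil = eff[, 2])
    truth@mediator_genes <- med_genes
  }
  list(pheno = pheno, genetic_values = gv, truth = truth)
}

#' Extract per-accession BLUE values for one trait
#'
#' @param pheno long phenotype data.frame as produced by
#'   \code{\link{simulateTraits}} (or read from the fixture TSV).
#' @param trait trait name.
#' @param accessions optional id vector controlling order.
#' @return named numeric vector of BLUEs.
#' @export
traitBlues <- function(pheno, trait, accessions = NULL) {
  p <- pheno[pheno$trait == trait, c("accession_id", "blue")]
  p <- p[!duplicated(p$accession_id), ]
  v <- stats::setNames(p$blue, p$accession_id)
  if (!is.null(accessions)) v <- v[accessions]
  v
}

#' Simulate wild / landrace / cultivar panels with a selective sweep
#'
#' Three panels share one variant set; panel allele frequencies are
#' Balding-Nichols draws around shared ancestral frequencies with
#' divergence increasing from wild to cultivar. In one designated region a
#' fixed haplotype is swept: each panel haplotype is replaced by the swept
#' allele string with the panel's target probability, which raises its
#' frequency along the domestication series and collapses flanking
#' diversity in the later panels.
#'
#' @param cfg a \code{\link{simConfig}}; \code{sweep_freqs},
#'   \code{sweep_region_bp} and \code{panel_size} control the sweep.
#' @return list with \code{panels} (named list of
#'   \linkS4class{GenotypeMatrix}: wild, landrace, cultivar) and
#'   \code{truth} (a \linkS4class{TruthTable} with the \code{sweep} slot
#'   filled).
#' @export
simulatePanels <- function(cfg) {
  validateSimConfig(cfg)
  set.seed(cfg$seed + 3L)
  base_seed <- cfg$seed + 3L
  panel_fst <- c(wild = 0.02, landrace = 0.10, cultivar = 0.15)
  m <- cfg$n_variants
  per_chrom <- .split_counts(m, cfg$n_chromosomes)
  chrom0 <- rep(paste0("chr", seq_len(cfg$n_chromosomes)), per_chrom)
  pos0 <- unlist(lapply(per_chrom, function(k)
    sort(sample.int(cfg$chrom_length_bp - 1000L, k)) + 500L))
  p0 <- cfg$maf_floor + (1 - 2 * cfg$maf_floor) *
    pnorm(.ar1_latent(1, chrom0, pos0, 2 * cfg$ld_decay_bp)[1, ])
  region_chrom <- "chr1"
  centre <- cfg$chrom_length_bp / 2
  region <- c(centre - cfg$sweep_region_bp / 2,
              centre + cfg$sweep_region_bp / 2)
  swept_string <- NULL
  panels <- list()
  vdf <- data.frame(chrom = chrom0, pos = pos0)
  for (i in seq_along(panel_fst)) {
    Fp <- panel_fst[i]
    set.seed(base_seed + 10L * i)
    pf <- .bn_freqs(p0, Fp, 1L, chrom0, pos0, 2 * cfg$ld_decay_bp)
    pcfg <- cfg
    pcfg$n_accessions <- cfg$panel_size
    pcfg$n_subpops <- 1L
    pcfg$seed <- base_seed + 10L * i + 1L
    g <- simulateGenotypes(pcfg, subpop_freqs = pf, variants = vdf)
    panels[[names(panel_fst)[i]]] <- g
  }
  # shared coordinates: copy variant metadata from the wild panel
  vi <- variantInfo(panels$wild)
  in_region <- which(vi$chrom == region_chrom & vi$pos >= region[1] &
                     vi$pos <= region[2])
  if (length(in_region) == 0) stop("sweep region contains no variants")
  # swept haplotype = minor-allele string of the wild panel, so its
  # baseline frequency is low and the planted trajectory dominates
  set.seed(base_seed + 99L)
  wild_d <- dosages(panels$wild)[, in_region, drop = FALSE]
  swept_alleles <- as.integer(colMeans(wild_d) / 2 < 0.5)
  swept_string <- paste(swept_alleles, collapse = "")
  for (nm in names(panels)) {
    g <- panels[[nm]]
    d <- dosages(g)
    f <- cfg$sweep_freqs[[nm]]
    set.seed(base_seed + 200L + match(nm, names(panels)))
    n <- nrow(d)
    # inbred accessions carry two copies of one haplotype: replacing both
    # region haplotypes gives the swept haplotype that frequency while
    # preserving homozygosity; the replacement rate is calibrated against
    # the panel's baseline carrier frequency q so the realized frequency
    # hits the target in expectation
    carrier <- rowSums(abs(sweep(d[, in_region, drop = FALSE], 2,
                                 2L * swept_alleles, "-"))) == 0
    q <- mean(carrier)
    fr <- if (q >= f) 0 else (f - q) / (1 - q)
    swap <- !carrier & (runif(n) < fr)
    if (any(swap)) {
      d[swap, in_region] <- rep(2L * swept_alleles, each = sum(swap))
    }
    panels[[nm]] <- GenotypeMatrix(
      d, as.data.frame(vi[, setdiff(colnames(vi), "maf")]),
      as.data.frame(accessionInfo(g)))
  }
  truth <- new("TruthTable",
               local_eqtls = data.frame(variant = character(),
                                        gene = character(),
                                        effect = numeric()),
               hotspots = list(), modules = data.frame(),
               trait_effects = data.frame(variant = character(),
                                          effect_sw = numeric(),
                                          effect_oil = numeric()),
               mediator_genes = character(),
               sweep = list(region = list(chrom = region_chrom,
                                          start = region[1], end = region[2]),
                            haplotype = swept_string,
                            defining_variants = vi$id[in_region],
                            panel_freq = cfg$sweep_freqs))
  list(panels = panels, truth = truth)
}
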