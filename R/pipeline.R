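#' Run the integrated analysis pipeline on synthetic data
#'
#' End-to-end orchestration: simulate a panel (genotypes, expression, two
#' correlated traits), then run GWAS for both traits (LOCO mixed model,
#' effective-test threshold, clumping), bivariate REML genetic
#' correlation, signed-t effect correlation, eQTL mapping with
#' local/distal classification and hotspot detection, ICA coexpression
#' modules with module-trait association and module GWAS, TWAS over the
#' planted mediator genes plus a null sample, the wild/landrace/cultivar
#' selection scan, and the superior-allele aggregation test. Stages can be
#' toggled; a manifest records every parameter and per-stage seed.
#'
#' Stage seeds are derived deterministically from the configuration seed,
#' so stages are independently reproducible.
#'
#' @param cfg \code{\link{simConfig}}.
#' @param stages character vector among "gwas", "eqtl", "coexpr", "twas",
#'   "popgen", "alleles" (default all).
#' @param n_perm permutations for hotspot / module tests (200).
#' @param max_eqtl_genes cap on genes scanned for eQTLs (NULL = all
#'   filtered genes).
#' @param twas_null_genes extra non-mediator genes put through TWAS (10).
#' @param verbose print stage progress (TRUE).
#' @return list of stage results plus \code{manifest}.
#' @export
runPipeline <- function(cfg, stages = c("gwas", "eqtl", "coexpr", "twas",
                                        "popgen", "alleles"),
                        n_perm = 200, max_eqtl_genes = NULL,
                        twas_null_genes = 10, verbose = TRUE) {
  t0 <- proc.time()[3]
  say <- function(...) if (verbose) message(sprintf("[%6.1fs] ",
                                                    proc.time()[3] - t0), ...)
  out <- list()
  manifest <- list(config = unclass(cfg),
                   stage_seeds = lapply(stats::setNames(stages, stages),
                                        function(s) .stage_seed(cfg$seed, s)))
  if ("twas" %in% stages && !("gwas" %in% stages)) {
    stop("stage 'twas' requires stage 'gwas' results")
  }
  if ("alleles" %in% stages && !all(c("gwas", "twas") %in% stages)) {
    stop("stage 'alleles' requires 'gwas' and 'twas' results")
  }
  say("simulating genotypes, expression, traits")
  geno <- simulateGenotypes(cfg)
  sim <- simulateExpression(geno, cfg)
  tr <- simulateTraits(geno, cfg, truth = sim$truth)
  truth <- tr$truth
  out$geno <- geno; out$expr <- sim$expr; out$pheno <- tr$pheno
  out$truth <- truth
  genome <- data.frame(chrom = paste0("chr", seq_len(cfg$n_chromosomes)),
                       length = cfg$chrom_length_bp)
  grms <- locoGRMs(geno)
  rot <- locoRotations(geno, grms)
  blues <- list(
    seed_weight = traitBlues(tr$pheno, "seed_weight"),
    oil_content = traitBlues(tr$pheno, "oil_content"))

  if ("gwas" %in% stages) {
    say("GWAS (both traits)")
    eff <- effectiveTests(geno)
    gw <- lapply(blues, function(b) fitMLMLoco(geno, b, grms, rot = rot))
    loci <- lapply(gw, function(res)
      clumpResults(res[!is.na(res$p), ], geno, p1 = eff$threshold))
    say("bivariate REML genetic correlation")
    grm_all <- buildGRM(geno)
    rg <- bivariateGREML(blues$seed_weight, blues$oil_content, grm_all)
    stc <- signedTCorrelation(gw$seed_weight, gw$oil_content)
    out$gwas <- list(results = gw, loci = loci, effective = eff,
                     rg = rg, signed_t = stc)
  }

  if ("eqtl" %in% stages) {
    say("eQTL mapping")
    fexpr <- filterExpression(sim$expr)
    gene_sel <- rownames(fexpr)
    if (!is.null(max_eqtl_genes) && length(gene_sel) > max_eqtl_genes) {
      set.seed(.stage_seed(cfg$seed, "eqtl"))
      keep <- unique(c(truth@local_eqtls$gene,
                       unlist(lapply(truth@hotspots, `[[`, "targets"))))
      keep <- intersect(keep, gene_sel)
      extra <- sample(setdiff(gene_sel, keep),
                      max(0, max_eqtl_genes - length(keep)))
      gene_sel <- c(keep, extra)
    }
    recs <- mapEQTLs(geno, fexpr, grms, rot = rot, genes = gene_sel)
    recs <- classifyLocalDistal(recs, SummarizedExperiment::rowRanges(fexpr))
    recs <- explainedVariance(recs, geno, fexpr)
    say("hotspot detection (", nrow(recs), " eQTL records)")
    hot <- detectHotspots(recs, genome, n_perm = n_perm,
                          seed = .stage_seed(cfg$seed, "eqtl"))
    out$eqtl <- list(records = recs, hotspots = hot,
                     summary = summarizeEQTLClasses(recs),
                     expr_filtered = fexpr)
  }

  if ("coexpr" %in% stages) {
    say("ICA coexpression modules")
    fexpr <- if (!is.null(out$eqtl)) out$eqtl$expr_filtered else
      filterExpression(sim$expr)
    lg <- log2(SummarizedExperiment::assay(fexpr, "tpm") + 1)
    ica <- runICA(lg, seed = .stage_seed(cfg$seed, "coexpr"))
    mtc <- moduleTraitCorrelation(ica, blues)
    # the module most associated with both traits, same sign
    best <- NULL
    for (mod in unique(mtc$module)) {
      sub <- mtc[mtc$module == mod, ]
      if (all(sub$q < 0.05) && length(unique(sign(sub$r))) == 1) {
        best <- mod; break
      }
    }
    mg <- NULL
    if (!is.null(best) && "gwas" %in% stages) {
      say("module GWAS for ", best)
      mg <- moduleGWAS(ica, best, geno, grms,
                       threshold = out$gwas$effective$threshold, rot = rot)
    }
    out$coexpr <- list(ica = ica, module_trait = mtc, dual_module = best,
                       module_gwas = mg)
  }

  if ("twas" %in% stages) {
    say("TWAS")
    fexpr <- if (!is.null(out$eqtl)) out$eqtl$expr_filtered else
      filterExpression(sim$expr)
    gr <- SummarizedExperiment::rowRanges(fexpr)
    tpm <- SummarizedExperiment::assay(fexpr, "tpm")
    set.seed(.stage_seed(cfg$seed, "twas"))
    med <- intersect(truth@mediator_genes, rownames(tpm))
    nulls <- sample(setdiff(rownames(tpm), med),
                    min(twas_null_genes, nrow(tpm) - length(med)))
    tw <- list()
    for (gene in c(med, nulls)) {
      wts <- fitWeights(gene, geno, tpm[gene, ], gr,
                        seed = .stage_seed(cfg$seed, paste0("w", gene)))
      if (is.null(wts)) next
      for (trait in names(blues)) {
        zz <- tryCatch(twasZ(wts, out$gwas$results[[trait]], geno),
                       error = function(e) NULL)
        if (is.null(zz)) next
        tw[[length(tw) + 1]] <- data.frame(
          trait = trait, gene = gene, model = wts$model, z = zz$z,
          p = zz$p, lead_gwas_id = zz$lead_gwas_id,
          lead_gwas_p = zz$lead_gwas_p,
          mediator = gene %in% med)
      }
    }
    twtab <- do.call(rbind, tw)
    out$twas <- list(results = twtab,
                     candidates = if (!is.null(twtab))
                       callCandidates(twtab) else NULL)
  }

  if ("popgen" %in% stages) {
    say("selection scan across panels")
    pan <- simulatePanels(cfg)
    pi_w <- lapply(pan$panels, windowedPi)
    scan_wl <- piRatioScan(pi_w$wild, pi_w$landrace, top_frac = 0.1)
    scan_lc <- piRatioScan(pi_w$landrace, pi_w$cultivar, top_frac = 0.1)
    fst_wl <- windowedFst(pan$panels$wild, pan$panels$landrace,
                          window_bp = 1e5, step_bp = 1e4)
    hap <- haplotypeSpectrum(pan$panels,
                             pan$truth@sweep$defining_variants)
    out$popgen <- list(panels = pan$panels, sweep_truth = pan$truth@sweep,
                       pi = pi_w, scan_wild_landrace = scan_wl,
                       scan_landrace_cultivar = scan_lc, fst = fst_wl,
                       haplotypes = hap)
  }

  if ("alleles" %in% stages) {
    say("superior-allele aggregation")
    cand <- out$twas$candidates
    agg <- NULL
    if (!is.null(cand) && nrow(cand) > 0) {
      k <- min(50, floor(nAccessions(geno) / 2))
      agg <- lapply(names(blues), function(trait) {
        ct <- cand[cand$trait == trait, , drop = FALSE]
        if (nrow(ct) == 0) return(NULL)
        sas <- defineSuperiorAlleles(ct, out$gwas$results[[trait]])
        aggregateAndTest(sas, geno, blues[[trait]], k = k)
      })
      names(agg) <- names(blues)
    }
    prof <- lapply(names(blues), function(trait)
      mafEffectProfile(out$gwas$results[[trait]],
                       out$gwas$effective$threshold))
    names(prof) <- names(blues)
    out$alleles <- list(aggregation = agg, maf_effect = prof)
  }
  manifest$elapsed_s <- unname(proc.time()[3] - t0)
  out$manifest <- manifest
  say("done")
  out
}
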