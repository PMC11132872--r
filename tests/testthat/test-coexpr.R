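test_that("ICA separates planted non-Gaussian sources", {
  # sparse module-style gene weights (each gene loads on one latent
  # factor), the structure population transcriptomes present
  set.seed(10)
  n_genes <- 200; n_acc <- 120
  S_true <- matrix(0, n_genes, 3)
  blocks <- split(1:120, rep(1:3, each = 40))
  for (k in 1:3) S_true[blocks[[k]], k] <- runif(40, 0.8, 1.5) *
      sample(c(-1, 1), 40, TRUE)
  A_mix <- t(scale(matrix(rgamma(3 * n_acc, shape = 2), n_acc, 3)))
  X <- S_true %*% A_mix + matrix(rnorm(n_genes * n_acc, 0, 0.2),
                                 n_genes, n_acc)
  rownames(X) <- paste0("g", 1:n_genes); colnames(X) <- paste0("a", 1:n_acc)
  ica <- runICA(X, var_cutoff = 70, seed = 3)
  expect_gte(ica$k, 3)
  # recovered eigen-expression matches the true factor profiles
  cc <- abs(cor(t(A_mix), t(ica$eigen)))
  best <- apply(cc, 1, max)
  expect_true(all(best > 0.9))
  # and the matched components put their members in the right block
  matched <- apply(cc, 1, which.max)
  for (k in 1:3) {
    mem <- ica$members[[matched[k]]]
    expect_gt(length(intersect(mem, paste0("g", blocks[[k]]))) /
                length(mem), 0.8)
  }
  # determinism
  ica2 <- runICA(X, var_cutoff = 70, seed = 3)
  expect_identical(ica$weights, ica2$weights)
  # planted components are reproducible across restarts well above chance
  expect_true(all(ica$stability[matched] > 0.5))
})

test_that("ICA reconstruction retains the explained-variance floor", {
  st <- sim_study()
  lg <- log2(SummarizedExperiment::assay(st$fexpr, "tpm") + 1)
  ica <- runICA(lg, var_cutoff = 70, seed = 4)
  X <- t(scale(t(lg)))
  proj <- ica$weights %*% solve(crossprod(ica$weights),
                                crossprod(ica$weights, X))
  r2 <- 1 - sum((X - proj)^2) / sum(X^2)
  expect_gte(r2, 0.70 - 0.02)
  # eigen-expression dimensions
  expect_equal(ncol(ica$eigen), ncol(lg))
  expect_equal(nrow(ica$eigen), ica$k)
})

test_that("module-trait correlation flags the planted dual-trait module", {
  st <- sim_study()
  lg <- log2(SummarizedExperiment::assay(st$fexpr, "tpm") + 1)
  ica <- runICA(lg, seed = 5)
  u <- moduleFactors(st$truth)[colnames(ica$eigen), "M1"]
  j <- which.max(abs(cor(t(ica$eigen), u)))
  expect_gt(abs(cor(ica$eigen[j, ], u)), 0.9)
  mtc <- moduleTraitCorrelation(ica, st$blues)
  sub <- mtc[mtc$module == rownames(ica$eigen)[j], ]
  expect_equal(nrow(sub), 2)
  expect_length(unique(sign(sub$r)), 1)
  expect_true(all(sub$q < 0.05))
  # identity: a trait equal to the eigen-expression correlates at 1
  fake <- list(x = setNames(ica$eigen[j, ], colnames(ica$eigen)))
  self <- moduleTraitCorrelation(ica, fake)
  expect_equal(max(self$r[self$module == rownames(ica$eigen)[j]]), 1,
               tolerance = 1e-8)
})

test_that("permuted traits leave modules unassociated at the nominal rate", {
  st <- sim_study()
  lg <- log2(SummarizedExperiment::assay(st$fexpr, "tpm") + 1)
  ica <- runICA(lg, seed = 5)
  set.seed(77)
  perm <- st$blues
  perm$seed_weight <- setNames(sample(perm$seed_weight),
                               names(perm$seed_weight))
  perm$oil_content <- setNames(sample(perm$oil_content),
                               names(perm$oil_content))
  mtc <- moduleTraitCorrelation(ica, perm)
  expect_lte(mean(mtc$p < 0.05), 0.10)
})

test_that("module GWAS finds the planted regulator locus", {
  st <- sim_study()
  lg <- log2(SummarizedExperiment::assay(st$fexpr, "tpm") + 1)
  ica <- runICA(lg, seed = 5)
  u <- moduleFactors(st$truth)[colnames(ica$eigen), "M1"]
  j <- which.max(abs(cor(t(ica$eigen), u)))
  comp <- rownames(ica$eigen)[j]
  mg <- moduleGWAS(ica, comp, st$geno, st$grms, rot = st$rot)
  reg <- plantedHotspots(st$truth)[[1]]$variant
  vi <- variantInfo(st$geno)
  reg_pos <- vi$pos[match(reg, vi$id)]
  reg_chr <- as.character(vi$chrom[match(reg, vi$id)])
  near <- mg$loci$chrom == reg_chr & abs(mg$loci$pos - reg_pos) < 5e5
  expect_true(any(near))
  # permuted eigen-expression: no loci at the genome-wide threshold
  set.seed(12)
  ica_perm <- ica
  ica_perm$eigen[comp, ] <- sample(ica$eigen[comp, ])
  mg0 <- moduleGWAS(ica_perm, comp, st$geno, st$grms, rot = st$rot)
  expect_lte(nrow(mg0$loci), 1)
})

test_that("module distal test passes only the planted regulator locus", {
  # synthetic records: locus L1 distally regulates the module genes
  all_genes <- paste0("g", 1:500)
  module <- paste0("g", 1:40)
  locus_targets <- list(
    L1 = c(paste0("g", 1:30), paste0("g", 481:490)),  # the true regulator
    L2 = paste0("g", 101:130),
    L3 = sample(all_genes, 25))
  md <- moduleDistalTest(module, locus_targets, all_genes,
                         n_perm = 300, seed = 6)
  expect_true(md$table$passes[md$table$locus == "L1"])
  expect_false(any(md$table$passes[md$table$locus != "L1"]))
  # brute-force threshold oracle with the same seed
  set.seed(6)
  nm <- sapply(1:300, function(b) {
    rnd <- sample(all_genes, length(module))
    max(sapply(locus_targets, function(tg) length(intersect(rnd, tg))))
  })
  expect_equal(md$threshold, sort(nm)[ceiling(0.99 * 300)])
  # random module: no locus passes
  set.seed(9)
  ok <- sapply(1:10, function(i) {
    rnd_mod <- sample(all_genes, 40)
    !any(moduleDistalTest(rnd_mod, locus_targets, all_genes,
                          n_perm = 150, seed = 100 + i)$table$passes)
  })
  expect_gte(mean(ok), 0.9)
  expect_error(moduleDistalTest(paste0("x", 1:600), locus_targets,
                                all_genes), "larger than")
})

test_that("Louvain submodules recover planted anti-correlated blocks", {
  set.seed(4)
  n <- 100; u <- rnorm(n)
  X <- rbind(t(sapply(1:15, function(i) u + rnorm(n, 0, 0.4))),
             t(sapply(1:15, function(i) -u + rnorm(n, 0, 0.4))))
  rownames(X) <- paste0("g", 1:30); colnames(X) <- paste0("a", 1:n)
  ps <- partitionSubmodules(X, rownames(X), corr_min = 0.3, seed = 2)
  expect_length(unique(ps), 2)
  expect_length(unique(ps[1:15]), 1)
  expect_length(unique(ps[16:30]), 1)
  expect_false(ps[1] == ps[16])
  # determinism
  ps2 <- partitionSubmodules(X, rownames(X), corr_min = 0.3, seed = 2)
  expect_identical(ps, ps2)
  # fully connected equal-weight graph collapses to one community
  Xc <- t(sapply(1:12, function(i) u + rnorm(n, 0, 0.1)))
  rownames(Xc) <- paste0("h", 1:12); colnames(Xc) <- paste0("a", 1:n)
  psc <- partitionSubmodules(Xc, rownames(Xc), corr_min = 0.3, seed = 2)
  expect_length(unique(psc), 1)
})

test_that("gene-trait correlations flag planted pleiotropic genes", {
  set.seed(5)
  n <- 150
  acc <- paste0("a", 1:n)
  t1 <- rnorm(n); t2 <- 0.5 * t1 + rnorm(n, 0, sqrt(0.75))
  X <- rbind(both = 0.6 * (t1 + t2) + rnorm(n, 0, 0.5),
             none = rnorm(n),
             copy = t1,
             flat = rep(1, n))
  colnames(X) <- acc
  blues <- list(sw = setNames(t1, acc), oil = setNames(t2, acc))
  gt <- geneTraitCorrelations(rownames(X), X, blues)
  expect_true(gt$dual_significant[gt$gene == "both"])
  expect_true(gt$same_sign[gt$gene == "both"])
  expect_false(gt$dual_significant[gt$gene == "none"])
  expect_equal(gt$r_sw[gt$gene == "copy"], 1, tolerance = 1e-10)
  expect_equal(gt$flag[gt$gene == "flat"], "constant")
  # null rate of double significance is ~p_max^2 (here: rarely > 1/300)
  set.seed(6)
  Xn <- matrix(rnorm(300 * n), 300, n,
               dimnames = list(paste0("n", 1:300), acc))
  gtn <- geneTraitCorrelations(rownames(Xn), Xn,
                               list(sw = setNames(rnorm(n), acc),
                                    oil = setNames(rnorm(n), acc)))
  expect_lte(sum(gtn$dual_significant), 3)
})

test_that("motif enrichment detects a planted consensus and stays null-calm", {
  set.seed(4)
  rseq <- function(n, len) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
    character(1))
  motif <- "TGACGTCA"
  universe <- rseq(200, 300)
  module_idx <- 1:40
  with_motif <- sample(module_idx, 32)
  for (i in with_motif) {
    p <- sample(290, 1)
    universe[i] <- paste0(substr(universe[i], 1, p - 1), motif,
                          substr(universe[i], p + 8, 300))
  }
  pwm <- matrix(0.01 / 3, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in 1:8) pwm[substr(motif, i, i), i] <- 0.99
  pwms <- list(PLANTED = pwm)
  attr(pwms, "bg") <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  mod <- Biostrings::DNAStringSet(universe[module_idx])
  bgs <- Biostrings::DNAStringSet(universe)
  me <- motifEnrichment(mod, bgs, pwms)
  expect_lt(me$q, 0.01)
  expect_gt(me$fold, 3)
  # a random module subset is not enriched
  me0 <- motifEnrichment(Biostrings::DNAStringSet(sample(universe[41:200], 40)),
                         bgs, pwms)
  expect_gt(me0$p, 0.05)
  # empty PWM set -> empty result
  empty <- motifEnrichment(mod, bgs, structure(list(), bg = NULL))
  expect_equal(nrow(empty), 0)
  # promoter shorter than the motif counts as no-hit, not an error
  short <- Biostrings::DNAStringSet(c("ACGT", universe[1]))
  expect_silent(motifEnrichment(short, bgs, pwms))
})

test_that("promoter extraction is strand-aware", {
  chrom <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep("ACGT", 300), collapse = "")))
  gc <- data.frame(gene = c("plus", "minus"), chrom = "chr1",
                   strand = c("+", "-"), tss = c(500, 500))
  pr <- promoterSeqs(chrom, gc, width = 100)
  expect_equal(as.character(pr[["plus"]]),
               as.character(Biostrings::subseq(chrom[[1]], 400, 499)))
  expect_equal(as.character(pr[["minus"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::subseq(chrom[[1]], 501, 600))))
})
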