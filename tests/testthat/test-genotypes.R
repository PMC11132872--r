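test_that("VCF genotype filters apply the GQ/DP/het-site rules", {
  # 100 accessions: 3 heterozygotes (all passing GQ/DP) -> site dropped;
  # a second site with one het at GQ 19 -> masked, site retained
  n <- 100
  gt1 <- rep("0/0", n); gt1[1:3] <- "0/1"
  gt2 <- rep("0/0", n); gt2[5] <- "0/1"; gt2[6] <- "1/1"
  gt <- rbind(gt1, gt2)
  gq <- matrix(99, 2, n); gq[2, 5] <- 19
  dp <- matrix(30, 2, n)
  path <- write_test_vcf(tempfile(fileext = ".vcf"), gt, gq, dp)
  g <- readFilterVCF(path)
  expect_equal(nVariants(g), 1)           # 3% het site dropped
  expect_match(attr(g, "drop_log")$reason, "het_frac")
  d <- dosages(g)[, 1]
  expect_true(is.na(d[5]))                # GQ 19 het masked
  expect_equal(unname(d[6]), 2)           # hom call untouched
})

test_that("het DP and hom DP thresholds mask genotypes independently", {
  n <- 60
  gt <- matrix(rep("0/0", 2 * n), 2, n)
  gt[1, 1] <- "0/1"; gt[1, 2] <- "1/1"; gt[1, 3] <- "0/0"
  gq <- matrix(99, 2, n)
  dp <- matrix(30, 2, n)
  dp[1, 1] <- 3      # het below DP 4 -> missing
  dp[1, 2] <- 1      # hom below DP 2 -> missing
  dp[1, 3] <- 2      # hom at DP 2 -> kept
  path <- write_test_vcf(tempfile(fileext = ".vcf"), gt, gq, dp)
  g <- readFilterVCF(path)
  d <- dosages(g)[, 1]
  expect_true(is.na(d[1]) && is.na(d[2]))
  expect_equal(unname(d[3]), 0)
  # all-hom site with adequate depth is retained unchanged
  expect_equal(sum(is.na(dosages(g)[, 2])), 0)
})

test_that("missing FORMAT fields fall back with a warning, or error", {
  gt <- matrix(rep("0/1", 8), 2, 4)
  gt[2, ] <- "0/0"
  path <- write_test_vcf(tempfile(fileext = ".vcf"), gt)
  w <- capture_warnings(g <- readFilterVCF(path, het_site_frac = 1))
  expect_match(w, "treating all calls as passing", all = TRUE)
  expect_equal(nVariants(g), 2)
  expect_error(suppressWarnings(
    readFilterVCF(path, missing_format_ok = FALSE)), "absent")
})

test_that("multiallelic records split into per-ALT biallelic records", {
  gt <- matrix(c("0/0", "1/1", "2/2", "1/2"), 1, 4)
  gq <- matrix(99, 1, 4); dp <- matrix(30, 1, 4)
  path <- write_test_vcf(tempfile(fileext = ".vcf"), gt, gq, dp,
                         alt = "T,G")
  g <- readFilterVCF(path, het_site_frac = 1)
  expect_equal(nVariants(g), 2)
  d <- dosages(g)
  expect_equal(unname(d[, 1]), c(0, 2, 0, 1))   # ALT1 dosage
  expect_equal(unname(d[, 2]), c(0, 0, 2, 1))   # ALT2 dosage
})

test_that("MAF computation excludes missing alleles", {
  d <- matrix(c(0, 0, 0, 0,
                2, 2, 0, 0,
                2, 1, 0, NA), 4, 3)
  g <- toy_geno(d)
  maf <- computeMAF(g)
  expect_equal(as.numeric(maf), c(0, 0.5, 0.5))  # last: 3 alt of 6 alleles
})

test_that("LD r2 equals brute-force Pearson correlation squared", {
  expect_equal(ldR2(toy_geno(cbind(c(0, 2, 0, 2), c(0, 2, 0, 2))), 1, 2), 1)
  expect_equal(ldR2(toy_geno(cbind(c(0, 2, 0, 2), c(0, 0, 2, 2))), 1, 2), 0)
  set.seed(8)
  d <- matrix(rbinom(40, 2, 0.4), 20, 2)
  g <- toy_geno(d)
  expect_equal(ldR2(g, 1, 2), cor(d[, 1], d[, 2])^2)
  # monomorphic pair flagged
  gm <- toy_geno(cbind(rep(0, 5), c(0, 1, 2, 1, 0)))
  expect_true(is.na(ldR2(gm, 1, 2)))
})

test_that("LD pruning leaves no within-window pair above the threshold", {
  # forced removal: perfect duplicate columns
  x <- rbinom(40, 2, 0.5)
  g2 <- toy_geno(cbind(x, x))
  kept <- ldPrune(g2, maf_min = 0, miss_max = 1)
  expect_length(kept, 1)
  # independent variants unchanged
  set.seed(3)
  ind <- sapply(1:20, function(i) rbinom(200, 2, 0.5))
  gi <- toy_geno(ind)
  expect_length(ldPrune(gi, maf_min = 0, miss_max = 1), 20)
  # exhaustive post-condition on a correlated fixture
  cfg <- simConfig(n_accessions = 150, n_variants = 100, n_chromosomes = 1,
                   ld_decay_bp = 5e5, seed = 6)
  gs <- simulateGenotypes(cfg)
  kept3 <- ldPrune(gs, r2_max = 0.2)
  idx <- match(kept3, variantInfo(gs)$id)
  std <- scale(imputeMean(dosages(gs))[, idx])
  cc <- cor(std)^2; diag(cc) <- 0
  expect_lt(max(cc[1:min(50, length(idx)), 1:min(50, length(idx))]), 0.201)
})

test_that("haplotype blocks recover a planted high-LD segment", {
  set.seed(2)
  base <- rbinom(40, 1, 0.5) * 2
  seg <- sapply(1:8, function(i) {
    x <- base; fl <- sample(40, 1); x[fl] <- 2 - x[fl]; x
  })
  free <- sapply(1:6, function(i) rbinom(40, 1, 0.5) * 2)
  pos <- sort(c(seq(1000, 8000, 1000), seq(2e5, 7e5, 1e5)))
  g <- toy_geno(cbind(seg, free), pos = pos)
  bl <- detectLDBlocks(g)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$start_pos, 1000)
  expect_equal(bl$end_pos, 8000)
  expect_lte(max(bl$end_pos - bl$start_pos), 5000 * 1000)
  # independent variants: no blocks
  bl0 <- detectLDBlocks(toy_geno(free, pos = seq(2e5, 7e5, 1e5)))
  expect_equal(nrow(bl0), 0)
})

test_that("PCA separates planted subpopulations and conserves variance", {
  cfg <- simConfig(n_accessions = 200, n_variants = 600, n_chromosomes = 2,
                   n_subpops = 2, target_fst = 0.2, seed = 13)
  g <- simulateGenotypes(cfg)
  pc <- pcaGenotypes(g, 4)
  lab <- as.numeric(factor(accessionInfo(g)$subpop))
  expect_gt(abs(cor(pc$scores[, 1], lab)), 0.9)
  expect_equal(sum(pc$eigenvalues), pc$total_var, tolerance = 1e-6)
  # duplicated accessions get identical coordinates
  d <- dosages(g)[c(1:30, 1), ]
  gd <- GenotypeMatrix(d, as.data.frame(
    variantInfo(g)[, c("chrom", "pos", "ref", "alt")]),
    sprintf("a%03d", 1:31))
  pcd <- pcaGenotypes(gd, 2)
  expect_equal(pcd$scores[1, ], pcd$scores[31, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pcaGenotypes(g, 300), "exceeds")
})

test_that("GRM equals the brute-force double-loop computation", {
  set.seed(4)
  d <- sapply(runif(400, 0.2, 0.8), function(p) rbinom(50, 2, p))
  g <- toy_geno(d)
  A <- buildGRM(g, min_variants = 10)
  # naive O(n^2 m) oracle
  p <- colMeans(d) / 2
  keep <- variantInfo(g)$maf >= 0.01
  dk <- d[, keep]; pk <- p[keep]
  n <- nrow(dk); m <- ncol(dk)
  A2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    A2[i, j] <- sum((dk[i, ] - 2 * pk) * (dk[j, ] - 2 * pk) /
                    (2 * pk * (1 - pk))) / m
  }
  expect_equal(unclass(A), A2, tolerance = 1e-10, ignore_attr = TRUE)
  # HWE panel: mean diagonal near 1
  expect_lt(abs(mean(diag(A2)) - 1), 0.1)
  # GRM invariant to variant order
  g_shuf <- toy_geno(d[, sample(ncol(d))])
  A3 <- suppressWarnings(buildGRM(g_shuf, min_variants = 10))
  expect_equal(unclass(A3), A2, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(buildGRM(toy_geno(d[, 1:5]), min_variants = 10), "need")
})

test_that("accession duplication yields self-relatedness in the GRM", {
  set.seed(9)
  d <- sapply(runif(300, 0.2, 0.8), function(p) rbinom(30, 2, p))
  d <- rbind(d, d[1, ])
  g <- toy_geno(d)
  A <- buildGRM(g, min_variants = 10)
  expect_equal(A[1, 31], A[1, 1], tolerance = 1e-10)
})
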