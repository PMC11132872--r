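test_that("MLM with identity kinship reproduces OLS exactly", {
  set.seed(1)
  n <- 120
  d <- sapply(runif(60, 0.1, 0.9), function(p) rbinom(n, 2, p))
  g <- toy_geno(d)
  acc <- accessionInfo(g)$id
  y <- setNames(rnorm(n) + 0.4 * d[, 7], acc)
  I <- diag(n); dimnames(I) <- list(acc, acc)
  res <- fitMLMLoco(g, y, list(chr1 = I), per_variant_reml = TRUE)
  for (j in c(3, 7, 20)) {
    ols <- summary(lm(y ~ d[, j]))$coefficients
    expect_equal(res$beta[j], ols[2, 1], tolerance = 1e-6)
    expect_equal(res$se[j], ols[2, 2], tolerance = 1e-6)
  }
  expect_true(all(sign(res$t) == sign(res$beta), na.rm = TRUE))
  expect_true(all(res$p > 0 & res$p <= 1, na.rm = TRUE))
})

test_that("MLM type-I error is nominal on a permuted phenotype", {
  st <- sim_study()
  set.seed(99)
  y <- st$blues$seed_weight[sample(nAccessions(st$geno))]
  names(y) <- accessionInfo(st$geno)$id
  res <- fitMLMLoco(st$geno, y, st$grms, rot = st$rot)
  frac <- mean(res$p[!is.na(res$p)] < 0.05)
  m <- sum(!is.na(res$p))
  ci <- qnorm(c(0.005, 0.995), 0.05, sqrt(0.05 * 0.95 / m))
  # LD makes tests dependent; allow 3x the binomial band half-width
  half <- (ci[2] - 0.05) * 3
  expect_lt(abs(frac - 0.05), half)
})

test_that("planted variant effects are recovered within sampling error", {
  covered <- 0; total <- 0
  for (s in 1:3) {
    set.seed(300 + s)
    n <- 400
    d <- sapply(runif(300, 0.2, 0.8), function(p) rbinom(n, 2, p))
    g <- toy_geno(d)
    acc <- accessionInfo(g)$id
    j <- 150
    b <- sqrt(0.05 * var(rnorm(n)) / var(d[, j]))  # ~5% variance
    y <- setNames(b * d[, j] + rnorm(n, 0, sqrt(1 - 0.05)), acc)
    I <- diag(n); dimnames(I) <- list(acc, acc)
    res <- fitMLMLoco(g, y, list(chr1 = I))
    total <- total + 1
    if (abs(res$beta[j] - b) <= 2 * res$se[j]) covered <- covered + 1
  }
  expect_gte(covered, 2)
})

test_that("structured-null inflation of the MLM is at most that of OLS", {
  cfg <- simConfig(n_accessions = 250, n_variants = 1200, n_chromosomes = 2,
                   n_subpops = 2, target_fst = 0.2, trait_h2 = c(0.6, 0.5),
                   seed = 77)
  g <- simulateGenotypes(cfg)
  # structured phenotype: polygenic only, no single causal variant matters
  tr <- simulateTraits(g, cfg)
  y <- traitBlues(tr$pheno, "seed_weight")
  grms <- suppressMessages(locoGRMs(g))
  res <- fitMLMLoco(g, y, grms)
  d <- imputeMean(dosages(g))
  p_ols <- apply(d, 2, function(x) {
    if (sd(x) == 0) return(NA)
    summary(lm(y ~ x))$coefficients[2, 4]
  })
  lambda <- function(p) {
    p <- p[!is.na(p)]
    median(qchisq(p, 1, lower.tail = FALSE)) / qchisq(0.5, 1)
  }
  expect_lte(lambda(res$p), lambda(p_ols) + 0.02)
})

test_that("effective-test count interpolates between the LD limits", {
  set.seed(5)
  # mutually independent variants: m_eff = m
  ind <- sapply(1:40, function(i) rbinom(500, 2, 0.5))
  gi <- toy_geno(ind)
  eff <- effectiveTests(gi, window = 40)
  expect_equal(eff$m_eff, 40)
  expect_equal(eff$threshold, 0.05 / 40)
  # perfectly correlated variants: m_eff collapses to ~1
  x <- rbinom(300, 2, 0.5)
  gp <- toy_geno(sapply(1:30, function(i) x))
  expect_equal(effectiveTests(gp, window = 30)$m_eff, 1)
  # monotone non-increasing in LD strength
  effs <- sapply(c(2e4, 2e5, 8e5), function(ld) {
    cfg <- simConfig(n_accessions = 200, n_variants = 300,
                     n_chromosomes = 1, ld_decay_bp = ld, seed = 4)
    effectiveTests(simulateGenotypes(cfg), window = 150)$m_eff
  })
  expect_true(all(diff(effs) < 0))
})

test_that("clumping matches a brute-force oracle on planted signals", {
  # singleton
  res1 <- data.frame(id = "chr1_1000", chrom = "chr1", pos = 1000,
                     p = 1e-10)
  g1 <- toy_geno(matrix(rbinom(60, 2, 0.5), 30, 2))
  cl1 <- clumpResults(res1, g1, p1 = 1e-6)
  expect_equal(nrow(cl1), 1)
  expect_equal(cl1$n_members, 1)

  # two perfectly linked significant variants merge; lead has smaller p
  x <- rbinom(50, 2, 0.5)
  g2 <- toy_geno(cbind(x, x), pos = c(1000, 11000))
  res2 <- data.frame(id = variantInfo(g2)$id, chrom = "chr1",
                     pos = c(1000, 11000), p = c(1e-8, 1e-12))
  cl2 <- clumpResults(res2, g2, p1 = 1e-6)
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$lead, "chr1_11000")
  expect_equal(cl2$n_members, 2)

  # 50-variant toy with 3 planted independent signals
  set.seed(21)
  n <- 200
  sig_idx <- c(10, 25, 40)
  blocks <- lapply(sig_idx, function(i) rbinom(n, 2, 0.5))
  d <- matrix(0, n, 50)
  for (k in seq_len(50)) {
    nearest <- which.min(abs(sig_idx - k))
    if (abs(sig_idx[nearest] - k) <= 3) {
      base <- blocks[[nearest]]
      flip <- sample(n, round(0.05 * n))
      base[flip] <- 2 - base[flip]
      d[, k] <- base
    } else d[, k] <- rbinom(n, 2, 0.5)
  }
  g3 <- toy_geno(d, pos = seq(1e4, by = 1e4, length.out = 50))
  p <- runif(50, 0.2, 1)
  p[sig_idx] <- c(1e-9, 1e-12, 1e-8)
  res3 <- data.frame(id = variantInfo(g3)$id, chrom = "chr1",
                     pos = variantInfo(g3)$pos, p = p)
  cl3 <- clumpResults(res3, g3, p1 = 1e-6, p2 = 0.01, r2 = 0.5, kb = 500)
  expect_equal(nrow(cl3), 3)
  expect_setequal(cl3$lead, variantInfo(g3)$id[sig_idx])
  # leads are mutually unlinked at the clump r2
  for (i in 1:2) for (j in (i + 1):3) {
    expect_lt(ldR2(g3, cl3$lead[i], cl3$lead[j]), 0.5)
  }
  # members partition: no variant in two loci
  all_members <- unlist(cl3$members)
  expect_equal(anyDuplicated(all_members), 0)
})

test_that("bivariate REML recovers planted genetic correlations", {
  st <- sim_study()
  grm <- buildGRM(st$geno)
  fit <- bivariateGREML(st$blues$seed_weight, st$blues$oil_content, grm)
  expect_true(fit$converged)
  expect_true(abs(fit$rg) <= 1 + 1e-6)
  expect_gt(fit$rg, 0)           # planted positive correlation
  expect_true(is.finite(fit$se_rg) && fit$se_rg > 0)

  # a trait duplicated as both phenotypes gives rg = 1
  y <- st$blues$seed_weight
  set.seed(2)
  fit2 <- bivariateGREML(y, y + rnorm(length(y), 0, 1e-5), grm)
  expect_equal(fit2$rg, 1, tolerance = 1e-3)
})

test_that("independent genetic values give a null genetic correlation", {
  ests <- c(); ses <- c()
  for (s in 1:3) {
    cfg <- simConfig(n_accessions = 300, n_variants = 1200,
                     n_chromosomes = 3, trait_rg = 0, trait_h2 = c(0.5, 0.5),
                     seed = 500 + s)
    g <- simulateGenotypes(cfg)
    tr <- simulateTraits(g, cfg)
    fit <- bivariateGREML(traitBlues(tr$pheno, "seed_weight"),
                          traitBlues(tr$pheno, "oil_content"),
                          buildGRM(g))
    ests <- c(ests, fit$rg); ses <- c(ses, fit$se_rg)
  }
  expect_lt(abs(mean(ests)), 2 * mean(ses, na.rm = TRUE))
})

test_that("signed-t correlation has the identity and sign-flip limits", {
  st <- sim_study()
  res <- fitMLMLoco(st$geno, st$blues$seed_weight, st$grms, rot = st$rot)
  self <- signedTCorrelation(res, res)
  expect_equal(self$r, 1, tolerance = 1e-12)
  flip <- res; flip$t <- -flip$t
  expect_equal(signedTCorrelation(res, flip)$r, -1, tolerance = 1e-12)
  expect_error(signedTCorrelation(res[1:2, ], res[1:2, ]), "3 shared")
  # planted positive rg shows as positive effect correlation
  res2 <- fitMLMLoco(st$geno, st$blues$oil_content, st$grms, rot = st$rot)
  both <- signedTCorrelation(res, res2)
  expect_gt(both$r, 0)
  expect_lt(both$p, 0.05)
})
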