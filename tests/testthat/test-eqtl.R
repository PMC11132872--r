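test_that("expression filter applies TPM floor and fold-change rules", {
  n <- 238
  # pass: TPM 10 in 6% of accessions, fold > 2
  g1 <- c(rep(10, 15), rep(0.5, n - 15))
  # fail: constant gene (fold = 1)
  g2 <- rep(100, n)
  # fail: expressed nowhere
  g3 <- rep(0.1, n)
  # pass: zero 5th percentile passes the fold criterion
  g4 <- c(rep(0, 20), rep(8, n - 20))
  tpm <- rbind(g1, g2, g3, g4)
  rownames(tpm) <- paste0("g", 1:4); colnames(tpm) <- paste0("a", 1:n)
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(tpm = tpm))
  out <- filterExpression(se)
  expect_setequal(rownames(out), c("g1", "g4"))
  expect_equal(unname(attr(out, "filter_counts")["kept"]), 2)
  # planted pass/fail labels over a random fixture
  set.seed(6)
  m <- 400
  labels <- rep(c(TRUE, FALSE), length.out = m)
  tpm2 <- t(sapply(seq_len(m), function(i) {
    if (labels[i]) exp(rnorm(n, 3, 1)) else rep(0.2, n)
  }))
  rownames(tpm2) <- paste0("x", seq_len(m)); colnames(tpm2) <- paste0("a", 1:n)
  se2 <- SummarizedExperiment::SummarizedExperiment(assays = list(tpm = tpm2))
  out2 <- filterExpression(se2)
  expect_setequal(rownames(out2), paste0("x", which(labels)))
})

test_that("quantile normalization maps ranks to normal quantiles", {
  x <- c(3, 10, 1, 7, 5)
  qn <- quantileNormalize(x)
  expect_equal(sort(qn), qnorm(c(0.1, 0.3, 0.5, 0.7, 0.9)))
  # rank invariance under monotone transforms
  expect_equal(quantileNormalize(exp(x)), qn)
  expect_equal(quantileNormalize(rank(x)), qn)
  # moments at realistic n
  set.seed(1)
  z <- quantileNormalize(rexp(238))
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(sd(z) - 1), 0.05)
  expect_error(quantileNormalize(rep(1, 10)), "constant")
  expect_error(quantileNormalize(c(1, 2, NA, NA)), "3 non-missing")
})

test_that("local/distal classification uses the 1 Mb span rule", {
  gc <- data.frame(gene = "gA", chrom = "chr1", start = 5e6, end = 5.01e6,
                   tss = 5e6)
  rec <- function(pos, chrom = "chr1") {
    data.frame(gene = "gA", lead = "v", chrom = chrom, pos = pos, p = 1e-9,
               n_proxies = 3)
  }
  expect_equal(classifyLocalDistal(rec(4.5e6), gc)$class, "local")
  expect_equal(classifyLocalDistal(rec(5.005e6), gc)$distance, 0)
  # exactly 1 Mb from the span edge: boundary inclusive -> local
  expect_equal(classifyLocalDistal(rec(4e6), gc)$class, "local")
  expect_equal(classifyLocalDistal(rec(4e6 - 1), gc)$class, "distal")
  expect_equal(classifyLocalDistal(rec(5e6, "chr2"), gc)$class, "distal")
  expect_error(classifyLocalDistal(
    data.frame(gene = "nope", lead = "v", chrom = "chr1", pos = 1, p = 1),
    gc), "unknown gene")
})

test_that("explained variance matches the planted effect size", {
  set.seed(3)
  n <- 400
  x <- rbinom(n, 2, 0.5)
  g <- toy_geno(cbind(x, rbinom(n, 2, 0.5)))
  # noise-free: r2 ~ 1 (rank-normalization keeps it just below 1)
  tpm <- rbind(gA = exp(0.8 * x), gB = exp(rnorm(n)))
  colnames(tpm) <- accessionInfo(g)$id
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(tpm = tpm))
  rec <- data.frame(gene = "gA", lead = variantInfo(g)$id[1],
                    chrom = "chr1", pos = 1000, p = 1e-20, n_proxies = 0)
  r2 <- explainedVariance(rec, g, se)$r2
  expect_gt(r2, 0.95)
  # planted 20%-variance effects: mean estimate near 0.2
  r2s <- replicate(30, {
    y <- sqrt(0.2 / var(x)) * x + rnorm(n, 0, sqrt(0.8))
    cor(x, quantileNormalize(exp(y)))^2
  })
  expect_lt(abs(mean(r2s) - 0.2), 0.05)
})

test_that("eQTL mapping recovers planted signals and classes", {
  st <- sim_study()
  pl <- plantedLocalEQTLs(st$truth)
  genes <- intersect(pl$gene, rownames(st$fexpr))[1:25]
  recs <- mapEQTLs(st$geno, st$fexpr, st$grms, rot = st$rot, genes = genes)
  recs <- classifyLocalDistal(recs,
                              SummarizedExperiment::rowRanges(st$fexpr))
  hit <- vapply(genes, function(gn)
    any(recs$gene == gn & recs$class == "local"), logical(1))
  expect_gte(mean(hit), 0.8)
  # recovered local leads sit near the planted variant
  vi <- variantInfo(st$geno)
  for (gn in genes[hit][1:5]) {
    planted_pos <- vi$pos[match(pl$variant[pl$gene == gn], vi$id)]
    local_rows <- recs[recs$gene == gn & recs$class == "local", ]
    expect_lt(min(abs(local_rows$pos - planted_pos)), 1e6)
  }
  # explained variance: local records stronger than distal on average
  recs <- explainedVariance(recs, st$geno, st$fexpr)
  expect_true(all(recs$r2 >= 0 & recs$r2 <= 1))
})

test_that("null genes rarely yield eQTL records", {
  st <- sim_study()
  # pure-noise phenotype genes, mapped through the same machinery
  set.seed(11)
  n <- nAccessions(st$geno)
  tpm <- t(sapply(1:40, function(i) exp(rnorm(n, 3, 1))))
  rownames(tpm) <- paste0("null", 1:40)
  colnames(tpm) <- accessionInfo(st$geno)$id
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(tpm = tpm))
  recs <- mapEQTLs(st$geno, se, st$grms, rot = st$rot)
  expect_lte(nrow(recs), 2)   # <= 5% of 40 genes
})

test_that("hotspot detection is calibrated by its permutation null", {
  # empty input
  genome <- data.frame(chrom = c("chr1", "chr2"), length = c(5e6, 5e6))
  empty <- data.frame(gene = character(), lead = character(),
                      chrom = character(), pos = integer(), p = numeric(),
                      class = character())
  h0 <- detectHotspots(empty, genome, n_perm = 50, seed = 1)
  expect_equal(nrow(h0$hotspots), 0)
  expect_gte(h0$threshold, 0)

  # tiny instance: threshold equals a brute-force recomputation (same seed)
  set.seed(7)
  recs <- data.frame(gene = paste0("g", 1:20),
                     lead = paste0("v", 1:20),
                     chrom = sample(c("chr1", "chr2"), 20, TRUE),
                     pos = sample.int(5e6, 20), p = 1e-8, class = "distal")
  hs <- detectHotspots(recs, genome, window_bp = 1e6, step_bp = 5e5,
                       n_perm = 200, alpha = 0.01, seed = 31)
  # oracle: replay the permutation scheme independently
  windows <- do.call(rbind, lapply(1:2, function(i) {
    starts <- seq(1, 5e6 - 1e6 + 1, by = 5e5)
    data.frame(chrom = genome$chrom[i], start = starts,
               end = starts + 1e6 - 1)
  }))
  split_pos <- split(recs$pos, recs$chrom)
  split_gene <- split(recs$gene, recs$chrom)
  set.seed(31)
  null_max <- sapply(1:200, function(b) {
    pp <- lapply(names(split_pos), function(ch)
      sample.int(5e6, length(split_pos[[ch]]), replace = TRUE))
    names(pp) <- names(split_pos)
    max(sapply(seq_len(nrow(windows)), function(k) {
      ch <- windows$chrom[k]
      inw <- pp[[ch]] >= windows$start[k] & pp[[ch]] <= windows$end[k]
      length(unique(split_gene[[ch]][inw]))
    }))
  })
  expect_equal(hs$threshold, sort(null_max)[ceiling(0.99 * 200)])

  # planted regulator with 25 distal targets over scattered background
  set.seed(8)
  bg <- data.frame(gene = paste0("b", 1:60), lead = paste0("w", 1:60),
                   chrom = sample(c("chr1", "chr2"), 60, TRUE),
                   pos = sample.int(5e6, 60), p = 1e-8, class = "distal")
  hot <- data.frame(gene = paste0("t", 1:25), lead = paste0("h", 1:25),
                    chrom = "chr1", pos = 2.5e6 + sample.int(2e5, 25),
                    p = 1e-9, class = "distal")
  hs2 <- detectHotspots(rbind(bg, hot), genome, n_perm = 300, seed = 5)
  expect_gte(nrow(hs2$hotspots), 1)
  ok <- hs2$hotspots$chrom == "chr1" & hs2$hotspots$start <= 2.7e6 &
    hs2$hotspots$end >= 2.5e6
  expect_true(any(ok))
})

test_that("hotspot permutation is reproducible and threshold monotone", {
  genome <- data.frame(chrom = "chr1", length = 4e6)
  mk <- function(k) data.frame(gene = paste0("g", 1:k),
                               lead = paste0("v", 1:k), chrom = "chr1",
                               pos = sample.int(4e6, k, replace = TRUE),
                               p = 1e-8, class = "distal")
  set.seed(2); r1 <- mk(30)
  a <- detectHotspots(r1, genome, n_perm = 100, seed = 9)
  b <- detectHotspots(r1, genome, n_perm = 100, seed = 9)
  expect_identical(a$null_max, b$null_max)
  set.seed(2); dense <- mk(120)
  thr_dense <- detectHotspots(dense, genome, n_perm = 100, seed = 9)$threshold
  expect_gte(thr_dense, a$threshold)
})

test_that("OCR enrichment detects planted overlap and saturates", {
  genome <- data.frame(chrom = "chr1", length = 1e6)
  # saturation: OCRs covering the whole chromosome
  leads <- data.frame(chrom = "chr1", pos = sample.int(1e6, 30))
  ocr_all <- data.frame(chrom = "chr1", start = 1, end = 1e6)
  en <- ocrEnrichment(leads, ocr_all, genome, n_perm = 50, seed = 1)
  expect_equal(en$observed, 30)
  expect_equal(en$p, 1)
  # planted: all leads inside 5% coverage
  set.seed(3)
  ocr <- data.frame(chrom = "chr1", start = seq(1, 9.5e5, 1e5),
                    end = seq(1, 9.5e5, 1e5) + 4999)
  inleads <- data.frame(chrom = "chr1",
                        pos = ocr$start[sample(10, 40, TRUE)] +
                          sample.int(4000, 40, TRUE))
  en2 <- ocrEnrichment(inleads, ocr, genome, n_perm = 200, seed = 2)
  expect_lte(en2$p, 0.01)
  expect_gt(en2$observed, en2$ci95[2])
  # bounds check
  expect_error(ocrEnrichment(leads, data.frame(chrom = "chr1", start = 1,
                                               end = 2e6), genome),
               "exceeds")
})

test_that("class bookkeeping reproduces printed-count percentages", {
  expect_equal(unname(classPercentages(c(local = 1974, distal = 3302))),
               c(37L, 63L))
  expect_equal(unname(classPercentages(c(local_only = 1116,
                                         distal_only = 1655, both = 576))),
               c(33L, 49L, 17L))
  # single local record
  one <- data.frame(gene = "g", lead = "v", chrom = "chr1", pos = 1,
                    p = 1e-9, class = "local")
  s1 <- summarizeEQTLClasses(one)
  expect_equal(unname(s1$eqtl_pct), c(100L, 0L))
  # sums are conserved
  set.seed(4)
  recs <- data.frame(gene = sample(paste0("g", 1:30), 60, TRUE),
                     lead = paste0("v", 1:60), chrom = "chr1",
                     pos = 1:60, p = 1e-9,
                     class = sample(c("local", "distal"), 60, TRUE))
  s <- summarizeEQTLClasses(recs)
  expect_equal(sum(s$eqtl_counts), nrow(recs))
  expect_equal(sum(s$egene_counts), length(unique(recs$gene)))
  # empty input
  s0 <- summarizeEQTLClasses(recs[0, ])
  expect_equal(sum(s0$eqtl_counts), 0)
})
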