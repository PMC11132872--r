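# shared lazy-built fixtures (built once per test run)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# mid-sized simulated study: genotypes + expression + traits + GRMs
sim_study <- function(seed = 42) {
  cached(paste0("study", seed), function() {
    cfg <- simConfig(n_accessions = 300, n_variants = 3000,
                     n_chromosomes = 3, n_genes = 300, module_size = 40,
                     genes_per_hotspot = 20, seed = seed)
    g <- simulateGenotypes(cfg)
    sim <- simulateExpression(g, cfg)
    tr <- simulateTraits(g, cfg, truth = sim$truth)
    grms <- suppressMessages(locoGRMs(g))
    rot <- suppressMessages(locoRotations(g, grms))
    list(cfg = cfg, geno = g, expr = sim$expr,
         fexpr = filterExpression(sim$expr), pheno = tr$pheno,
         gv = tr$genetic_values, truth = tr$truth, grms = grms, rot = rot,
         blues = list(seed_weight = traitBlues(tr$pheno, "seed_weight"),
                      oil_content = traitBlues(tr$pheno, "oil_content")),
         genome = data.frame(chrom = paste0("chr", 1:3), length = 30e6))
  })
}

# tiny GenotypeMatrix from a raw dosage matrix
toy_geno <- function(d, pos = NULL, chrom = "chr1") {
  m <- ncol(d)
  if (is.null(pos)) pos <- seq(1000, by = 1000, length.out = m)
  GenotypeMatrix(d, data.frame(chrom = rep_len(chrom, m), pos = pos,
                               ref = "A", alt = "T"),
                 sprintf("acc%03d", seq_len(nrow(d))))
}

# independent Hudson-type FST oracle (ratio of averages over variants)
hudson_fst <- function(d, pop) {
  ps <- lapply(unique(pop), function(s) colMeans(d[pop == s, , drop = FALSE],
                                                 na.rm = TRUE) / 2)
  ns <- vapply(unique(pop), function(s) sum(pop == s), numeric(1))
  p1 <- ps[[1]]; p2 <- ps[[2]]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (ns[1] - 1) -
    p2 * (1 - p2) / (ns[2] - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num, na.rm = TRUE) / sum(den, na.rm = TRUE)
}

# write a minimal VCF from explicit genotype strings (one FORMAT per file)
write_test_vcf <- function(path, gt, gq = NULL, dp = NULL,
                           chrom = "chr1", pos = NULL, ref = "A",
                           alt = "T") {
  m <- nrow(gt); n <- ncol(gt)
  if (is.null(pos)) pos <- seq(100, by = 100, length.out = m)
  fmt <- "GT"
  if (!is.null(gq)) fmt <- paste0(fmt, ":GQ")
  if (!is.null(dp)) fmt <- paste0(fmt, ":DP")
  ref <- rep_len(ref, m); alt <- rep_len(alt, m)
  lines <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", unique(chrom), ">"),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
             "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Q\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"D\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sprintf("s%02d", 1:n)),
                   collapse = "\t"))
  for (i in seq_len(m)) {
    cells <- gt[i, ]
    if (!is.null(gq)) cells <- paste0(cells, ":", gq[i, ])
    if (!is.null(dp)) cells <- paste0(cells, ":", dp[i, ])
    lines <- c(lines, paste(c(rep_len(chrom, m)[i], pos[i], ".", ref[i],
                              alt[i], ".", "PASS", ".", fmt, cells),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  path
}
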