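#' Mean-impute missing dosages
#'
#' Replaces missing genotype calls by the per-variant mean dosage, the
#' convention used for PCA, GRM construction and association scans
#' (it preserves allele frequencies and adds no between-accession signal).
#'
#' @param dosage accessions x variants dosage matrix.
#' @return matrix of the same shape without NAs.
#' @export
imputeMean <- function(dosage) {
  if (!anyNA(dosage)) return(dosage)
  mu <- colMeans(dosage, na.rm = TRUE)
  idx <- which(is.na(dosage), arr.ind = TRUE)
  dosage[idx] <- mu[idx[, 2]]
  dosage
}

# center/scale dosage columns; zero-variance columns become all-zero
.std_dosage <- function(dosage) {
  x <- imputeMean(dosage)
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[s == 0] <- Inf
  sweep(sweep(x, 2, mu, "-"), 2, s, "/")
}

# deterministic child seed derived from a base seed and a stage label,
# kept below 2^31
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 97L + as.integer(h %% 100000L)) %% 2000000000L
}

# gap between a point and an interval [s, e]; 0 if inside
.gap_to_span <- function(pos, s, e) {
  ifelse(pos < s, s - pos, ifelse(pos > e, pos - e, 0))
}

#' Round half away from zero to integer percent
#'
#' @param x numeric.
#' @return integer vector; 0.5 rounds away from zero (the convention used
#'   in the reported class percentages).
#' @export
roundHalfUp <- function(x) {
  trunc(abs(x) + 0.5) * sign(x)
}
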