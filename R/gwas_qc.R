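#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed genotype
#' counts against the proportions expected from the sample allele
#' frequencies. Monomorphic variants return p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (vectorised).
#' @return P-value(s) in (0, 1].
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  counts <- cbind(n_AA, n_Aa, n_aa)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  n <- rowSums(counts)
  if (any(n < 1)) stop("all-zero genotype counts")
  p <- (2 * counts[, 1] + counts[, 2]) / (2 * n)
  q <- 1 - p
  e <- cbind(n * p^2, 2 * n * p * q, n * q^2)
  stat <- rowSums((counts - e)^2 / ifelse(e > 0, e, 1))
  out <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  out[p == 0 | p == 1] <- 1  # monomorphic
  unname(out)
}

#' QC thresholds for the variant panel
#'
#' Defaults follow standard biobank-scale GWAS practice: drop variants with
#' imputation INFO < 0.3, missingness > 0.05, minor allele frequency
#' < 2e-4, or Hardy-Weinberg p < 1e-6.
#'
#' @param min_info,max_missing,min_maf,min_hwe_p Filter thresholds.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_info = 0.3, max_missing = 0.05,
                          min_maf = 2e-4, min_hwe_p = 1e-6) {
  stopifnot(min_info >= 0, min_info <= 1, max_missing >= 0, max_missing <= 1,
            min_maf > 0, min_maf <= 0.5, min_hwe_p > 0, min_hwe_p < 1)
  structure(list(min_info = min_info, max_missing = max_missing,
                 min_maf = min_maf, min_hwe_p = min_hwe_p),
            class = "qc_thresholds")
}

#' Filter a genotype panel on QC metrics
#'
#' Applies the filters in a fixed order — INFO, missingness, MAF, HWE — and
#' counts each removed variant once, under the first filter it fails, so
#' per-filter removal counts are reproducible. HWE p-values are computed
#' from the observed dosage counts via [hwe_test()]; the other metrics come
#' from the variant metadata.
#'
#' @param geno A `genotype_matrix`.
#' @param thr A `qc_thresholds` object.
#' @return The retained `genotype_matrix`, with a removal report attached as
#'   attribute `"qc_report"` (per-filter counts plus totals).
#' @export
qc_filter <- function(geno, thr = qc_thresholds()) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(thr, "qc_thresholds"))
  v <- geno$variants
  d <- geno$dosages
  nAA <- colSums(d == 2, na.rm = TRUE)
  nAa <- colSums(d == 1, na.rm = TRUE)
  naa <- colSums(d == 0, na.rm = TRUE)
  hwe_p <- hwe_test(nAA, nAa, naa)
  fail_info <- v$info < thr$min_info
  fail_miss <- v$missingness > thr$max_missing
  fail_maf <- v$maf < thr$min_maf
  fail_hwe <- hwe_p < thr$min_hwe_p
  first_fail <- rep("pass", nrow(v))
  first_fail[fail_hwe] <- "hwe"
  first_fail[fail_maf] <- "maf"
  first_fail[fail_miss] <- "missingness"
  first_fail[fail_info] <- "info"
  keep <- first_fail == "pass"
  counts <- c(info = sum(first_fail == "info"),
              missingness = sum(first_fail == "missingness"),
              maf = sum(first_fail == "maf"),
              hwe = sum(first_fail == "hwe"))
  out <- subset_variants(geno, keep)
  attr(out, "qc_report") <- list(
    removed = counts, n_removed = sum(counts), n_retained = sum(keep),
    thresholds = thr)
  out
}
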