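#' Simulate a biallelic genotype dosage panel
#'
#' Draws per-sample effect-allele counts for `n_variants` biallelic SNPs.
#' Under Hardy-Weinberg equilibrium each dosage is binomial(2, p) with p the
#' variant's effect-allele frequency; with `hwe = FALSE` genotypes are drawn
#' with inbreeding coefficient `inbreeding` so that heterozygotes are
#' depleted and the HWE filter has something to catch. Per-variant imputation
#' INFO scores and missingness fractions are drawn from mixture
#' distributions so that a small share of variants fails each QC filter.
#'
#' @param n_samples,n_variants Panel dimensions (`n_samples >= 2`).
#' @param maf_range Interval within (0, 0.5] from which declared allele
#'   frequencies are drawn uniformly.
#' @param hwe Draw genotypes in Hardy-Weinberg proportions (default `TRUE`).
#' @param seed Integer seed; identical seeds give identical panels.
#' @param n_chr Number of chromosomes the panel is spread over.
#' @param fst_shift Optional allele-frequency shift: the sample is split in
#'   two subpopulations with frequencies p +/- `fst_shift` (used to exercise
#'   the principal-component operation; default 0 = unstructured).
#' @param inbreeding Inbreeding coefficient used when `hwe = FALSE`.
#' @param dosage_missing Fraction of dosages set to `NA` per variant
#'   (default 0; mean imputation downstream is exercised in tests).
#' @return A `genotype_matrix`: list with `dosages` (n x M matrix),
#'   `variants` (id, chr, pos, effect/other allele, maf, info, missingness)
#'   and `sample_ids`.
#' @export
simulate_genotypes <- function(n_samples, n_variants,
                               maf_range = c(0.05, 0.5),
                               hwe = TRUE, seed = 1L, n_chr = 4L,
                               fst_shift = 0, inbreeding = 0.3,
                               dosage_missing = 0) {
  if (n_samples < 2 || n_variants < 1) stop("non-positive panel dimensions")
  if (length(maf_range) != 2 || diff(maf_range) < 0 ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("maf_range must be a non-empty interval within (0, 0.5]")
  }
  .set_seed(seed, 1L)
  M <- as.integer(n_variants); n <- as.integer(n_samples)
  maf <- stats::runif(M, maf_range[1], maf_range[2])
  chr <- sort(sample.int(n_chr, M, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(M), chr), function(ix)
    cumsum(sample.int(50000L, length(ix), replace = TRUE)) + 10000L),
    use.names = FALSE)
  lowq <- stats::runif(M) < 0.08
  info <- ifelse(lowq, stats::runif(M, 0.05, 0.6), stats::runif(M, 0.6, 1))
  himiss <- stats::runif(M) < 0.08
  missf <- ifelse(himiss, stats::runif(M, 0.05, 0.15), stats::runif(M, 0, 0.04))
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, M, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), "")

  p <- maf
  if (fst_shift > 0) {
    grp <- rep(c(0L, 1L), length.out = n)
    p0 <- pmin(pmax(maf - fst_shift, 0.01), 0.99)
    p1 <- pmin(pmax(maf + fst_shift, 0.01), 0.99)
    d0 <- matrix(stats::rbinom(n * M, 2L, rep(p0, each = n)), n, M)
    d1 <- matrix(stats::rbinom(n * M, 2L, rep(p1, each = n)), n, M)
    dos <- d0
    dos[grp == 1L, ] <- d1[grp == 1L, ]
  } else if (hwe) {
    dos <- matrix(stats::rbinom(n * M, 2L, rep(p, each = n)), n, M)
  } else {
    # excess homozygosity: with probability `inbreeding` both alleles copy
    # a single draw, otherwise two independent draws
    pm <- rep(p, each = n)
    ibd <- stats::runif(n * M) < inbreeding
    a1 <- stats::rbinom(n * M, 1L, pm)
    a2 <- ifelse(ibd, a1, stats::rbinom(n * M, 1L, pm))
    dos <- matrix(a1 + a2, n, M)
  }
  if (dosage_missing > 0) {
    dos[stats::runif(n * M) < dosage_missing] <- NA_integer_
  }
  ids <- sprintf("rs%d_%d", chr, pos)
  dimnames(dos) <- list(sprintf("S%06d", seq_len(n)), ids)
  variants <- data.frame(id = ids, chr = chr, pos = pos,
                         effect_allele = unname(ea), other_allele = unname(oa),
                         maf = maf, info = info, missingness = missf,
                         stringsAsFactors = FALSE)
  out <- list(dosages = dos, variants = variants, sample_ids = rownames(dos))
  if (fst_shift > 0) out$subpop <- grp
  class(out) <- "genotype_matrix"
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants,",
      length(unique(x$variants$chr)), "chromosome(s)\n")
  invisible(x)
}

#' Subset a genotype panel by variant
#' @param geno A `genotype_matrix`.
#' @param keep Logical or index vector over variants.
#' @return The subset `genotype_matrix`.
#' @export
subset_variants <- function(geno, keep) {
  out <- list(dosages = geno$dosages[, keep, drop = FALSE],
              variants = geno$variants[keep, , drop = FALSE],
              sample_ids = geno$sample_ids, subpop = geno$subpop)
  class(out) <- "genotype_matrix"
  out
}

#' Family-block relatedness structure
#'
#' Assigns samples to family blocks of a fixed size and records the
#' within-block kinship coefficient; downstream the blocks carry a shared
#' Gaussian random effect, a desk-scale stand-in for a sparse genetic
#' relatedness matrix.
#'
#' @param n_samples Number of samples.
#' @param block_size Family size (default 4).
#' @param coefficient Within-block kinship coefficient in [0, 0.5]
#'   (default 0.25, full siblings).
#' @return A `kinship_structure`: `family` assignment, `coefficient`, and a
#'   sparse `pairs` table (i, j, coefficient).
#' @export
make_kinship <- function(n_samples, block_size = 4L, coefficient = 0.25) {
  stopifnot(n_samples >= 1, block_size >= 1,
            coefficient >= 0, coefficient <= 0.5)
  fam <- rep(seq_len(ceiling(n_samples / block_size)), each = block_size)[seq_len(n_samples)]
  pairs <- do.call(rbind, lapply(split(seq_len(n_samples), fam), function(ix) {
    if (length(ix) < 2) return(NULL)
    cbind(t(utils::combn(ix, 2)))
  }))
  out <- list(family = fam, coefficient = coefficient,
              pairs = data.frame(i = pairs[, 1], j = pairs[, 2],
                                 coefficient = coefficient))
  class(out) <- "kinship_structure"
  out
}
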