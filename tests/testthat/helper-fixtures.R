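# Hand-constructed genotype panels for deterministic tests.

# Build a genotype_matrix from an explicit dosage matrix and metadata.
toy_geno <- function(dosages, maf = NULL, info = NULL, missingness = NULL,
                     chr = NULL, pos = NULL) {
  M <- ncol(dosages)
  if (is.null(maf)) maf <- pmin(colMeans(dosages, na.rm = TRUE) / 2, 0.5)
  if (is.null(info)) info <- rep(0.95, M)
  if (is.null(missingness)) missingness <- rep(0.01, M)
  if (is.null(chr)) chr <- rep(1L, M)
  if (is.null(pos)) pos <- seq(1e5, by = 1e6, length.out = M)
  ids <- sprintf("v%02d", seq_len(M))
  colnames(dosages) <- ids
  rownames(dosages) <- sprintf("S%04d", seq_len(nrow(dosages)))
  g <- list(dosages = dosages,
            variants = data.frame(id = ids, chr = chr, pos = pos,
                                  effect_allele = "A", other_allele = "G",
                                  maf = maf, info = info,
                                  missingness = missingness),
            sample_ids = rownames(dosages))
  class(g) <- "genotype_matrix"
  g
}

# Dosage column realizing exact genotype counts (n_aa zeros, n_Aa ones,
# n_AA twos), shuffled deterministically.
hwe_column <- function(n_AA, n_Aa, n_aa, seed = 1) {
  set.seed(seed)
  sample(rep(c(2, 1, 0), c(n_AA, n_Aa, n_aa)))
}

# Minimal outcome_table built directly from vectors.
toy_outcome <- function(entry, exit, event, sex = NULL, subsite = NULL) {
  n <- length(entry)
  if (is.null(sex)) sex <- rep(0L, n)
  if (is.null(subsite)) {
    subsite <- ifelse(event == 1, "colon", "censored")
  }
  out <- data.frame(entry_age = entry, exit_age = exit, event = event,
                    subsite = factor(subsite, c("censored", "colon", "rectal")),
                    sex = sex)
  class(out) <- c("outcome_table", "data.frame")
  out
}

# Per-instrument summary statistics with strong, diet-GWAS-like exposure
# effects; optional horizontal pleiotropy on the outcome side.
sim_summary <- function(k, theta = 0.2, pleio_mean = 0, pleio_sd = 0,
                        se_exp = 0.01, se_out = 0.03) {
  be_true <- runif(k, 0.02, 0.2)
  be <- rnorm(k, be_true, se_exp)
  alpha <- rnorm(k, pleio_mean, pleio_sd)
  bo <- rnorm(k, theta * be_true + alpha, se_out)
  list(be = be, se_exp = rep(se_exp, k), bo = bo, se_out = rep(se_out, k))
}

# Exponential proportional-hazards event times on the age scale.
toy_surv_times <- function(entry, lp, rate = 0.01, censor_age = 75) {
  t_event <- entry + stats::rexp(length(entry), rate * exp(lp))
  list(exit = pmin(t_event, censor_age),
       event = as.integer(t_event <= censor_age))
}
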