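#!/usr/bin/env Rscript
# Instrument construction: flag lead variants associated with multiple
# dietary traits, screen leads against the outcome (exclusion restriction,
# p < 0.05), build internally weighted allele scores for the full and the
# reduced (sensitivity) instrument sets, and record instrument strength.

library(dietmr)
source("analysis/config.R")

geno <- cfg_geno()
qcd <- qc_filter(geno)
loci_flat <- read.delim(file.path(cfg$table_dir, "loci.tsv"))
traits <- read.delim(file.path(cfg$data_dir, "derived_traits.tsv"))
traits$milk <- traits$milk / 100
covars <- read.delim(file.path(cfg$data_dir, "covariates.tsv"))
outcome <- read.delim(file.path(cfg$data_dir, "outcome.tsv"))
class(outcome) <- c("outcome_table", "data.frame")

loci_by_trait <- split(loci_flat, loci_flat$trait)
loci_by_trait <- lapply(loci_by_trait, function(d) {
  d$lead_id <- as.character(d$lead_id); d
})
flags <- cross_trait_flags(lapply(loci_by_trait, function(d)
  data.frame(lead_id = d$lead_id)), min_traits = 2)
message(sum(flags$flagged), " lead variant(s) associated with >= 2 traits")

leads <- unique(loci_flat$lead_id)
lead_geno <- subset_variants(qcd, match(leads, qcd$variants$id))
ostats <- outcome_scan(outcome, lead_geno, covars[, c("age", "sex")])
message(sum(ostats$p < 0.05, na.rm = TRUE),
        " lead variant(s) associated with the outcome at p < 0.05")

rows <- list(); scores <- data.frame(sample_id = traits$sample_id)
for (tr in names(loci_by_trait)) {
  l <- loci_by_trait[[tr]]
  ivs <- build_instruments(tr, l, qcd)
  s1 <- first_stage(traits[[tr]], ivs$score, allow_weak = TRUE)
  red <- tryCatch(apply_exclusions(ivs, flags, ostats, qcd),
                  error = function(e) NULL)
  f_red <- if (!is.null(red)) {
    first_stage(traits[[tr]], red$score, allow_weak = TRUE)$diagnostics$F
  } else NA_real_
  rows[[tr]] <- data.frame(trait = tr, n_iv = nrow(ivs$variants),
                           f_full = s1$diagnostics$F,
                           n_iv_reduced = if (is.null(red)) 0L else nrow(red$variants),
                           f_reduced = f_red)
  scores[[paste0(tr, "_full")]] <- ivs$score
  if (!is.null(red)) scores[[paste0(tr, "_reduced")]] <- red$score
  message(sprintf("%-12s %2d IVs (F = %.0f), %2d after exclusions (F = %.0f)",
                  tr, nrow(ivs$variants), s1$diagnostics$F,
                  if (is.null(red)) 0 else nrow(red$variants), f_red))
}
write.table(do.call(rbind, rows),
            file.path(cfg$table_dir, "instrument_strength.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(scores, file.path(cfg$data_dir, "allele_scores.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
message("wrote allele scores and instrument-strength table")
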