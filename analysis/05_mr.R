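#!/usr/bin/env Rscript
# One-sample Mendelian randomisation: two-stage least squares with an
# age-scale Cox second stage per trait (full and reduced instrument sets),
# MR-Egger and MR-PRESSO pleiotropy diagnostics on the per-instrument
# estimates, sex and subsite subgroups for the headline trait, and
# multivariable MR over correlated allele-score groups.

library(dietmr)
source("analysis/config.R")

geno <- cfg_geno()
qcd <- qc_filter(geno)
traits <- read.delim(file.path(cfg$data_dir, "derived_traits.tsv"))
traits$milk <- traits$milk / 100
covars <- read.delim(file.path(cfg$data_dir, "covariates.tsv"))
outcome <- read.delim(file.path(cfg$data_dir, "outcome.tsv"))
class(outcome) <- c("outcome_table", "data.frame")
scores <- read.delim(file.path(cfg$data_dir, "allele_scores.tsv"))
loci_flat <- read.delim(file.path(cfg$table_dir, "loci.tsv"))
covs <- covars[, c("age", "sex")]

trait_names <- unique(loci_flat$trait)
res <- list()
for (tr in trait_names) {
  for (set in c("full", "reduced")) {
    sc <- scores[[paste0(tr, "_", set)]]
    if (is.null(sc)) next
    est <- tryCatch(mr_fit(traits[[tr]], sc, outcome, covs),
                    error = function(e) {
                      message(tr, " (", set, "): ", conditionMessage(e)); NULL
                    })
    if (is.null(est)) next
    d <- as.data.frame(est); d$trait <- tr; d$iv_set <- set
    res[[paste(tr, set)]] <- d
  }
}

# pleiotropy diagnostics per trait on the lead-variant summary estimates
pleio <- list()
for (tr in trait_names) {
  l <- loci_flat[loci_flat$trait == tr, ]
  if (nrow(l) < 4) next
  lg <- subset_variants(qcd, match(l$lead_id, qcd$variants$id))
  os <- outcome_scan(outcome, lg, covs)
  eg <- mr_egger(l$beta, l$se, os$beta, os$se)
  pr <- mr_presso(l$beta, l$se, os$beta, os$se, n_sim = 1000, seed = cfg$seed)
  pleio[[tr]] <- data.frame(trait = tr, k = nrow(l),
                            egger_intercept = eg$intercept,
                            egger_intercept_p = eg$intercept_p,
                            presso_global_p = pr$global_p,
                            n_outliers = nrow(pr$outliers),
                            distortion_p = pr$distortion_p)
  message(sprintf("%-12s Egger intercept p = %.2f, PRESSO global p = %.2f",
                  tr, eg$intercept_p, pr$global_p))
}
write.table(do.call(rbind, pleio), file.path(cfg$table_dir, "pleiotropy.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

# subgroups for the headline trait
if ("total_fruits_full" %in% names(scores)) {
  sub <- subgroup_run(outcome, by = c("sex", "subsite"),
                      estimator = function(o, rows) {
                        mr_fit(traits$total_fruits[rows],
                               scores$total_fruits_full[rows],
                               o, covs[rows, ])
                      })
  sub$trait <- "total_fruits"; sub$iv_set <- "full"
  res[["fruit subgroups"]] <- sub[sub$subgroup != "all", ]
}

# multivariable MR over correlated allele-score groups
sc_cols <- grep("_full$", names(scores), value = TRUE)
sc_mat <- scores[, sc_cols]
names(sc_mat) <- sub("_full$", "", sc_cols)
mv <- multivariable_mr(traits[, names(sc_mat)], sc_mat, outcome, covs)
message("MVMR groups: ", paste(vapply(mv$groups, paste, "", collapse = "+"),
                               collapse = " | "))
for (tr in names(mv$results)) {
  d <- as.data.frame(mv$results[[tr]]); d$trait <- tr; d$iv_set <- "full"
  res[[paste("mvmr", tr)]] <- d
}

tab <- do.call(rbind, res)
tab <- tab[, c("trait", "iv_set", "method", "subgroup", "hr", "ci_low",
               "ci_high", "f", "n", "events")]
write.table(tab, file.path(cfg$table_dir, "mr_estimates.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
print(tab[tab$method != "MVMR" & tab$subgroup == "all",
          c("trait", "iv_set", "hr", "ci_low", "ci_high", "f")],
      row.names = FALSE, digits = 3)
message("wrote MR estimate and pleiotropy tables")
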