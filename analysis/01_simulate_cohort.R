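#!/usr/bin/env Rscript
# Simulate the synthetic biobank-style cohort: genotypes, dietary traits
# with additive genetic architecture plus a latent confounder, categorical
# FFQ responses, baseline covariates, and the age-scale time-to-event
# colorectal-cancer outcome. Writes cohort tables (TSV) and the generating
# truth (YAML); the genotype panel is reproduced downstream from the seed.

library(dietmr)
source("analysis/config.R")

geno <- cfg_geno()
arch <- cfg_arch(geno)
cohort <- simulate_traits(geno, arch, seed = cfg$seed)
outcome <- simulate_outcome(cohort, arch, seed = cfg$seed)

message("cohort: ", cfg$n, " participants, ", cfg$M, " variants; event fraction ",
        round(attr(outcome, "event_fraction"), 3))
print(cohort$truth$decomposition, row.names = FALSE)

# Item-level FFQ responses: composite traits are split into their items
# (equal shares plus item-level noise), frequency items are binned into the
# questionnaire categories, quantitative items stay numeric.
set.seed(cfg$seed + 1)
n <- cfg$n
split3 <- function(x) {
  parts <- lapply(1:3, function(i) pmax(x / 3 + rnorm(n, 0, 0.15), 0))
  parts
}
rm_items <- split3(cohort$traits$red_meat)
fruit_fresh <- pmax(cohort$traits$fruits * 0.8 + rnorm(n, 0, 0.1), 0)
fruit_dried <- pmax((cohort$traits$fruits - fruit_fresh) * 2, 0)
veg_cooked <- pmax(cohort$traits$vegetables * 0.6 + rnorm(n, 0, 0.1), 0)
veg_raw <- pmax(cohort$traits$vegetables - veg_cooked, 0)
tea_cups <- pmax(cohort$traits$tea, 0)
coffee_cups <- pmax(rnorm(n, 2, 1), 0)
milk_ml <- pmax(cohort$traits$milk, 0) * 100   # trait is on the 100 mL/day scale
cereal_bowls <- pmax((milk_ml - 25 * coffee_cups - 35 * tea_cups) / 100, 0)
milk_type <- sample(c("full cream", "semi-skimmed", "skimmed"), n, replace = TRUE)

ffq <- data.frame(
  sample_id = rownames(cohort$covariates),
  pork = simulate_ffq(rm_items[[1]], "meat"),
  beef = simulate_ffq(rm_items[[2]], "meat"),
  lamb = simulate_ffq(rm_items[[3]], "meat"),
  cheese = simulate_ffq(pmax(cohort$traits$cheese, 0), "cheese"),
  alcohol = simulate_ffq(pmax(cohort$traits$alcohol, 0), "alcohol"),
  milk_type = milk_type,
  cereal_bowls = round(cereal_bowls, 1),
  coffee_cups = round(coffee_cups, 1),
  tea_cups = round(tea_cups, 1),
  fresh_fruit = round(fruit_fresh, 1),
  dried_fruit = round(fruit_dried, 1),
  cooked_veg = round(veg_cooked, 1),
  raw_veg = round(veg_raw, 1)
)

write.table(ffq, file.path(cfg$data_dir, "ffq_responses.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(cbind(sample_id = rownames(cohort$covariates), cohort$covariates),
            file.path(cfg$data_dir, "covariates.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(cbind(sample_id = rownames(outcome), as.data.frame(outcome)),
            file.path(cfg$data_dir, "outcome.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(cbind(sample_id = rownames(cohort$covariates), cohort$traits),
            file.path(cfg$data_dir, "generator_traits.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

truth <- list(seed = cfg$seed, n = cfg$n, M = cfg$M,
              h2 = as.list(arch$h2), log_hr = as.list(arch$log_hr),
              confounder_log_hr = arch$confounder_log_hr,
              n_causal = lapply(arch$causal, length),
              shared_causal_milk_tea = unname(arch$shared_causal["milk", "tea"]),
              event_fraction = attr(outcome, "event_fraction"))
yaml::write_yaml(truth, file.path(cfg$data_dir, "truth.yaml"))
message("wrote cohort tables and truth record under ", cfg$data_dir)
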