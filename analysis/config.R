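# Shared settings for the analysis scripts. Scripts re-derive the genotype
# panel from (n, M, seed) instead of writing a multi-hundred-MB dosage TSV:
# the generator is deterministic in the seed.

cfg <- list(
  seed = 2024L,
  n = 12000L,     # participants
  M = 1200L,      # QC-scale variant panel
  data_dir = "results/data",
  table_dir = "results/tables"
)

cfg_geno <- function() dietmr::simulate_genotypes(cfg$n, cfg$M, seed = cfg$seed)

cfg_arch <- function(geno) {
  set.seed(cfg$seed)
  ids <- geno$variants$id
  milk_causal <- sample(ids, 50)
  tea_causal <- c(milk_causal[1:43], sample(setdiff(ids, milk_causal), 7))
  dietmr::make_architecture(
    geno,
    h2 = c(red_meat = 0.055, cheese = 0.1048, milk = 0.0901, tea = 0.0834,
           fruits = 0.0783, vegetables = 0.055, alcohol = 0.0971),
    n_causal = c(red_meat = 15, cheese = 59, fruits = 60, vegetables = 50,
                 alcohol = 57),
    causal = list(milk = milk_causal, tea = tea_causal),
    log_hr = c(fruits = log(0.8), vegetables = log(0.85),
               red_meat = log(1.05), milk = log(0.95)),
    confounder_frac = c(red_meat = 0.05, alcohol = 0.05),
    confounder_log_hr = 0.3,
    trait_mean = 2.5, trait_sd = 1, seed = cfg$seed)
}

dir.create(cfg$data_dir, recursive = TRUE, showWarnings = FALSE)
dir.create(cfg$table_dir, recursive = TRUE, showWarnings = FALSE)
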