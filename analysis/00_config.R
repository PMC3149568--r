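# Shared configuration for the analysis scripts. Sourced, not run.
# One master seed governs every stage; the benchmark design is a two-class
# cohort with ten equicorrelated blocks and ten planted discriminative
# variables sitting inside the first two blocks.

library(sparsesig)

master_seed <- 20260101

benchmark_spec <- function(n_informative = 10) {
  synthetic_spec(n_samples = 100, n_variables = 500, block_size = 5,
                 n_blocks = 10, within_block_corr = 0.5,
                 n_informative = n_informative, effect_size = 1.5,
                 seed = master_seed)
}

data_dir <- "results/data"
results_dir <- "results"
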