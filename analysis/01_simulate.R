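#!/usr/bin/env Rscript
# Stage 1: generate the synthetic experiment.
# Two populations of ground-truth cells are drawn: a coincidence-tuned
# population (supralinear at dT = 0, sublinear elsewhere) and an
# FM-feature population (off-axis supralinear cluster with asymmetric
# suppression coupled to sweep direction preference). A small sample of
# trial traces is exported as a plain-text dataset container.

suppressPackageStartupMessages(library(stimap))
SEED <- 42L
N_CELLS <- 60L
dir.create("results", showWarnings = FALSE)

protocol <- build_protocol(seed = SEED)
print(protocol)

coin_pop <- simulate_population(N_CELLS, "a2_coincident", seed = SEED,
                                include_sweeps = FALSE)
asym_pop <- simulate_population(N_CELLS, "a1_asymmetric", seed = SEED + 1L)

gt <- data.frame(
  population = rep(c("coincidence", "asymmetric"), each = N_CELLS),
  cell = c(vapply(coin_pop, `[[`, "", "id"), vapply(asym_pop, `[[`, "", "id")),
  base_amp = c(vapply(coin_pop, `[[`, 1, "base_amp_center"),
               vapply(asym_pop, `[[`, 1, "base_amp_center")),
  mean_li = c(vapply(coin_pop, function(c) mean(c$li_kernel), 1),
              vapply(asym_pop, function(c) mean(c$li_kernel), 1)))
write.csv(gt, "results/ground_truth_cells.csv", row.names = FALSE)

# export a 3-cell sample with full traces for inspection / reuse
sample_traces <- lapply(coin_pop[1:3], synthesize_trial_traces,
                        protocol = protocol, seed = SEED)
write_dataset(sample_traces, "results/dataset_sample")

cat(sprintf("simulated %d + %d cells; mean ground-truth LI %.3f (coincidence) vs %.3f (asymmetric)\n",
            N_CELLS, N_CELLS, mean(gt$mean_li[gt$population == "coincidence"]),
            mean(gt$mean_li[gt$population == "asymmetric"])))
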