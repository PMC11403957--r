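#!/usr/bin/env Rscript
# Generate the synthetic CCMQ survey all downstream analyses run on:
# n = 2000 respondents, 60 Likert items, nine correlated subscale traits,
# two planted core items per biased subscale.

library(ccmqrapid)

dir.create("results", showWarnings = FALSE)
cfg <- sim_config(n = 2000, seed = 1)
sim <- simulate_responses(cfg)

write_responses(sim$responses, "results/responses.csv")
jsonlite::write_json(planted_truth(cfg), "results/planted_truth.json",
                     pretty = TRUE)

cat("Simulated", nrow(sim$responses), "respondents x",
    ncol(sim$responses), "items (seed", cfg$seed, ")\n")
cat("Planted core items:",
    paste(names(cfg$planted), sapply(cfg$planted, paste, collapse = "+"),
          sep = ":", collapse = "  "), "\n")
cat("-> results/responses.csv, results/planted_truth.json\n")
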