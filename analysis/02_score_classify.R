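#!/usr/bin/env Rscript
# Score the survey: converted subscale scores (0-100), nine-type
# classification, and prevalence. Expects results/responses.csv from
# analysis/01_simulate.R.

library(ccmqrapid)

spec <- load_spec()
responses <- load_responses("results/responses.csv", spec)

scores <- score_all(responses, spec)
classification <- classify_bc(scores)
prevalence <- prevalence_summary(classification)

write.csv(scores, "results/scores.csv", row.names = FALSE)
write.csv(classification, "results/classification.csv", row.names = FALSE)
write.csv(prevalence, "results/prevalence.csv", row.names = FALSE)

cat("Scored", nrow(scores), "respondents.\n")
cat("Presence rates (%), present only vs present-or-tendency:\n")
print(prevalence, row.names = FALSE, digits = 3)
n_multi <- sum(rowSums(classification[biased_types()] == "present") > 1)
cat(sprintf("%d respondents (%.1f%%) exhibit more than one biased type.\n",
            n_multi, 100 * n_multi / nrow(classification)))
cat("-> results/scores.csv, classification.csv, prevalence.csv\n")
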