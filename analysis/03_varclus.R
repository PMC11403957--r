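#!/usr/bin/env Rscript
# Divisive variable clustering of the 60 items: the full K = 1..60
# hierarchy, the K-versus-average-explained curve, and the representative
# items at the least K whose representatives explain 80% of within-cluster
# variance on average.

library(ccmqrapid)

spec <- load_spec()
responses <- load_responses("results/responses.csv", spec)

model <- correlation_model(unclass(responses))
hierarchy <- build_hierarchy(model)
sel <- select_partition(hierarchy, model, threshold = 0.8)

part <- hierarchy$partitions[[sel$selected_K]]
write.csv(data.frame(item = unlist(part),
                     cluster = rep(seq_along(part), lengths(part))),
          "results/varclus_partition.csv", row.names = FALSE)
write.csv(sel$representatives$representatives,
          "results/varclus_representatives.csv", row.names = FALSE)
write.csv(sel$curve, "results/varclus_curve.csv", row.names = FALSE)

cat(sprintf("Least K with average explained >= 0.8: K = %d (%.3f; %.3f at K-1)\n",
            sel$selected_K,
            sel$curve$average_explained[sel$selected_K],
            sel$curve$average_explained[sel$selected_K - 1]))
cat("Representative items:",
    paste(sort(sel$representatives$representatives$item), collapse = " "),
    "\n")
cat("-> results/varclus_{partition,representatives,curve}.csv\n")
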