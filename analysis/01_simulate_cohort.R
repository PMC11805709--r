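#!/usr/bin/env Rscript
# Simulate the study cohort: 300 children in 5 latent BMI-trajectory
# clusters observed on a 20-visit schedule (birth to 10 y) with 20% of
# visits missing, plus consistent weight/height pairs so the Jenss-Bayley
# weight/height pathway can be exercised. Children are split 200/100 into
# training and test sets at the child level.

suppressMessages(library(gpgrowth))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(n_children = 300, seed = 42, emit_wh = TRUE)
g <- generate_cohort(cfg)
split <- split_train_test(g$cohort, n_train = 200, seed = 42)

write_cohort(split$train, "results/cohort_train.csv")
write_cohort(split$test, "results/cohort_test.csv")
utils::write.csv(
  data.frame(child_id = names(g$truth$labels), cluster = g$truth$labels),
  "results/cohort_truth_labels.csv", row.names = FALSE)

means <- g$truth$cluster_means
cat(sprintf("Simulated %d children (%d records); %d train / %d test.\n",
            n_children(g$cohort), nrow(g$cohort$records),
            n_children(split$train), n_children(split$test)))
cat("Cluster mean BMI at birth :", round(means[, 1], 1), "\n")
cat("Cluster mean BMI at 10 y  :", round(means[, ncol(means)], 1), "\n")
cat("Cluster sizes             :",
    tabulate(g$truth$labels, cfg$k_true), "\n")
cat("The infant BMI peak of every cluster mean lies near 9 months;",
    "the upper cluster grows towards ~26 kg/m^2 at age 10.\n")
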