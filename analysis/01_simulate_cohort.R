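#!/usr/bin/env Rscript
# Simulate the study cohort: 24 subjects (12 female), nine 5-min analysis
# periods spanning waiting (T1-T2), stress test (T3-T5) and recovery (T6-T9),
# with per-period RR baselines, LF/HF modulation, within-window drift,
# occasional ectopic beats, and VAS scores with a little missingness.
# Writes the same plain-text formats a real recording session would yield.

suppressMessages(library(hrvsd))

out_dir <- "results/data"
master_seed <- 1234L

cat("Simulating the default 24-subject TSST cohort (seed", master_seed, ")\n")
co <- generate_cohort(cohort_spec(seed = master_seed))
write_cohort(co, out_dir)

n_beats <- sum(sapply(co$subjects, function(s) length(s$beats$times)))
n_ect <- sum(sapply(co$subjects, function(s) sum(s$beats$labels == "V")))
cat(sprintf("  %d subjects, %d beats total, %d injected ectopic beats (%.2f%%)\n",
            length(co$subjects), n_beats, n_ect, 100 * n_ect / n_beats))
cat(sprintf("  VAS scores: %d observed, %d missing\n",
            sum(!is.na(co$vas$score)), sum(is.na(co$vas$score))))
cat("  wrote beat CSVs, tachograms, markers.csv, vas.csv, gender.csv to ",
    out_dir, "\n")
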