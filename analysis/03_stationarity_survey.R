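#!/usr/bin/env Rscript
# Survey of nonstationarities: how many of the 216 analysis windows (24
# subjects x 9 periods) are flagged nonstationary in the RR series, and
# whether the corresponding difference series pass both tests. Also writes
# the per-period distribution of stationary-segment counts.

suppressMessages(library(hrvsd))

sub_dir <- "results/subjects"
data_dir <- "results/data"
files <- list.files(sub_dir, pattern = "_windows\\.csv$", full.names = TRUE)
reps <- lapply(files, read.csv)
all <- do.call(rbind, reps)

n_win <- nrow(all)
seg_nonstat <- sum(all$n_segments > 1)
rws_mean_sig <- sum(all$rws_p_mean <= 0.05)
rws_var_sig <- sum(all$rws_p_var <= 0.05)
cat(sprintf("RR interval series, %d windows:\n", n_win))
cat(sprintf("  segmented (nonstationary): %d of %d\n", seg_nonstat, n_win))
cat(sprintf("  RWS different means: %d of %d; different variances: %d of %d\n",
            rws_mean_sig, n_win, rws_var_sig, n_win))

# difference series: recompute both tests on every window's delta-RR
markers <- read_markers(file.path(data_dir, "markers.csv"))
drr_pass <- 0L; n_checked <- 0L
for (f in list.files(data_dir, pattern = "_beats\\.csv$", full.names = TRUE)) {
  rr <- beats_to_rr(replace_ectopic(read_beats(f)))
  for (w in seq_len(nrow(markers))) {
    win <- extract_window(rr, analysis_window(markers$time_ms[w],
                                              markers$label[w]))
    drr <- rr_diff(win)
    n_checked <- n_checked + 1L
    if (segment_series(drr)$stationary &&
        rws_test(drr, seed = 1234L + n_checked)$stationary)
      drr_pass <- drr_pass + 1L
  }
}
cat(sprintf("Delta-RR series: stationary by both tests in %d of %d windows\n",
            drr_pass, n_checked))

seg_by_period <- aggregate(n_segments ~ window, all, median)
cat("\nMedian number of stationary segments per period:\n")
print(seg_by_period, row.names = FALSE)
dir.create("results", showWarnings = FALSE)
write.csv(seg_by_period, "results/stationarity_by_period.csv",
          row.names = FALSE)
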