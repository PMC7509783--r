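# Shared fixture builders; everything is generated in code at test time.

# rr_series of i.i.d. Gaussian intervals (no physiologic-range warnings)
rr_gauss <- function(n, mean = 800, sd = 20) {
  rr_series(rnorm(n, mean, sd))
}

# symbolic_sequence wrapping raw 0/1 symbols (for null-distribution checks)
raw_symbols <- function(symbols, encoding = "sign", tau = NULL) {
  structure(list(symbols = as.integer(symbols), encoding = encoding, tau = tau),
            class = "symbolic_sequence")
}

# uniform series in the shape resample_tachogram() returns
uniform_series <- function(x, fs = 4) {
  list(t = seq(0, by = 1 / fs, length.out = length(x)), x = x, fs = fs)
}

# tachogram whose RR value traces given sinusoids of time (onset convention)
sinusoid_rr <- function(duration_s = 300, base = 800, amp = c(lf = 0),
                        freq = c(lf = 0.1), mean_rr = base) {
  t <- 0
  onsets <- numeric(0)
  rrs <- numeric(0)
  while (t < duration_s) {
    r <- base + sum(amp * sin(2 * pi * freq * t))
    onsets <- c(onsets, t)
    rrs <- c(rrs, r)
    t <- t + r / 1000
  }
  rr_series(rrs, start_times = onsets * 1000)
}

# brute-force pattern-category oracle: classify every word independently
pattern_oracle <- function(symbols) {
  n <- length(symbols)
  cats <- vapply(seq_len(n - 2), function(i)
    classify_word(symbols[i:(i + 2)]), character(1))
  c(`0V` = sum(cats == "0V"), `1V` = sum(cats == "1V"),
    `2V` = sum(cats == "2V"))
}
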