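# Independent, deliberately literal transcription of the notch rule, kept
# free of the package's vectorized implementation: a notch is present when
# any threshold at 3, 4 or 6 kHz exceeds the average of the 0.5 and 1 kHz
# thresholds by at least 15 dB HL, and the 8 kHz threshold is at least
# 5 dB HL lower (better) than the maximum threshold at 3, 4 and 6 kHz.
oracle_notch <- function(t500, t1000, t3000, t4000, t6000, t8000) {
  if (anyNA(c(t500, t1000, t3000, t4000, t6000, t8000))) return(NA)
  avg_low <- (t500 + t1000) / 2
  exceeds <- FALSE
  for (t in c(t3000, t4000, t6000)) {
    if (t >= avg_low + 15) exceeds <- TRUE
  }
  max_high <- t3000
  if (t4000 > max_high) max_high <- t4000
  if (t6000 > max_high) max_high <- t6000
  recovered <- t8000 <= max_high - 5
  exceeds && recovered
}

oracle_notch_rows <- function(g) {
  vapply(seq_len(nrow(g)), function(i) {
    oracle_notch(g$t500[i], g$t1000[i], g$t3000[i], g$t4000[i],
                 g$t6000[i], g$t8000[i])
  }, logical(1))
}
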