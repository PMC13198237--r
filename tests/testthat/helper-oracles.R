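# Independent oracles shared across test files.

# Benjamini-Hochberg step-up written directly from the definition:
# q_(i) = min over j >= i of p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q[q > 1] <- 1
  out <- numeric(m)
  out[o] <- q
  out
}

# Minimal differential result carrying chosen signed fold changes.
fake_result <- function(ids, signed_fc, unique_peptides = NA_integer_) {
  r <- data.frame(feature_id = ids, modality = "protein",
                  unique_peptides = unique_peptides,
                  log2FC = log2(abs(signed_fc)) * sign(signed_fc),
                  fc = ifelse(signed_fc >= 1, signed_fc, -1 / signed_fc),
                  signed_fc = signed_fc, p = 0.01, q = 0.01,
                  detection_case = 1, detection_control = 1,
                  direction = ifelse(signed_fc > 0, "up", "down"),
                  testable = TRUE, stringsAsFactors = FALSE)
  class(r) <- c("DifferentialResult", "data.frame")
  r
}
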