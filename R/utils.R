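# deterministic fan-out of one global seed into per-stage / per-cell seeds:
# a small polynomial hash of the label folded into the seed, kept below 2^31
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}
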