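# ascending integer sequence that is empty (not descending) when lo > hi
safe_seq <- function(lo, hi) {
  if (lo > hi) integer(0) else seq.int(lo, hi)
}
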