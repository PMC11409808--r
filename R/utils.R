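# Seed each generator from a distinct stream so that passing the same user
# seed to successive simulation stages never replays the same underlying
# uniforms (event times must not share randomness with dosage draws).
.set_seed <- function(seed, stream) {
  s <- (as.numeric(as.integer(seed)) * 48271 + stream * 1013904223) %% 2147483647
  set.seed(as.integer(s))
}
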