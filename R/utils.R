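# Derive a reproducible 31-bit sub-seed for a named random stream, so each
# component (view, method, ...) draws from its own stream and adding one
# component never perturbs another's draws.
.stream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(as.character(name))) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

.frob <- function(M) sqrt(sum(M * M))
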