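# Seed derivation: one root seed, named child streams per stage so that
# toggling one stage never shifts another stage's draws.

# deterministic 31-bit hash of label strings
label_hash <- function(...) {
  s <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 131 + k) %% 2147483647
  h
}

# child seed for a named stream; always in [1, 2^31 - 2]
derive_seed <- function(seed, ...) {
  h <- (as.numeric(seed) %% 2147483647) * 48271 %% 2147483647
  as.integer((h + label_hash(...)) %% 2147483646 + 1)
}
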