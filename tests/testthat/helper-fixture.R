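# one fixture genome shared across test files (generation is a few seconds;
# results are deterministic in the seed, so sharing does not couple tests)
.fixture_cache <- new.env(parent = emptyenv())

shared_fixture <- function(seed = 42L) {
  key <- as.character(seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  dir <- file.path(tempdir(), sprintf("sosdep_fx_%d", seed))
  fx <- generate_fixture(fixture_spec(seed = seed), dir)
  .fixture_cache[[key]] <- fx
  fx
}
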