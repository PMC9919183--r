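# Shared fixtures, all generated in code. Expensive datasets are memoized
# per test run so acceptance and unit tests reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# synthetic record -> model-rate segments with RR features attached
prep_synth <- function(seed, duration, noise_percent = 5, drop_na = TRUE) {
  rec <- synthesize_record(synthetic_config(
    duration = duration, seed = seed, noise_percent = noise_percent
  ))
  rec128 <- resample_record(rec, 128)
  seg <- append_rr_features(segment_beats(rec128), rec128)
  if (drop_na) drop_unavailable_rr(seg) else seg
}

small_sets <- function() {
  memo("small_sets", list(
    train = prep_synth(11, 240),
    val = prep_synth(12, 120),
    test = prep_synth(13, 240)
  ))
}

# acceptance-scale data: >= 2000 training beats, fixed seeds
big_sets <- function() {
  memo("big_sets", list(
    train = prep_synth(1, 1600),
    val = prep_synth(2, 400),
    test = prep_synth(3, 800),
    test_clean = prep_synth(3, 800, noise_percent = 0)
  ))
}

small_bank <- function(feature_kind = "derivative", nk = 32L) {
  memo(paste0("bank_", feature_kind, "_", nk), {
    extract_templates(small_sets()$train, "sub_class", feature_kind, nk)
  })
}
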