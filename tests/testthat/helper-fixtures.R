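# Small fixtures built in code at test time.

# Desk-scale cohort: 8 subjects x 150 s gives 4 windows per subject.
small_cohort_config <- function(seed = 7L, ...) {
  cohort_config(n_subjects = 8L, duration = 150, seed = seed, ...)
}

# A preprocessed small cohort with its subject split (memoized per session).
small_preprocessed <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- simulate_cohort(small_cohort_config())
      split <- subject_split(cohort)
      cache <<- list(pp = preprocess_cohort(cohort, split$train), split = split)
    }
    cache
  }
})

# Plain window object wrapper for signal matrices.
as_window <- function(signal, fs = 128, label = 0L, subject = "S01") {
  list(signal = signal, sampling_rate = fs, label = label,
       context = numeric(4), subject_id = subject, start = 0)
}

# A tiny sequence-mode model configuration (cheap decode steps).
tiny_seq_config <- function() {
  model_config(n_encoder_layers = 1L, n_decoder_layers = 1L, n_heads = 2L,
               d_model = 8L, d_ffn = 8L, head_mode = "token_sequence")
}
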