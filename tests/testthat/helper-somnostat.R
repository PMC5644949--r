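# Shared fixture builders; everything is generated in code.

# A mouse hypnogram from a run-length description, e.g.
# runs_hypnogram(NREM = 10, WAKE = 10).
runs_hypnogram <- function(..., species = "mouse", artifact = FALSE) {
  runs <- c(...)
  hypnogram(rep(names(runs), runs), species = species, artifact = artifact)
}

# Constant-valued spectra on the standard mouse axis.
flat_spectra <- function(n_epochs, value = 1, fmax = 49) {
  freq <- seq(0.25, fmax, by = 0.25)
  spectra(matrix(value, n_epochs, length(freq)), freq)
}

# A small cached noise-free recording for pipeline-level tests.
noise_free_recording <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_mouse_recording("wt", seed = 2, sigma = 0)
    }
    cache
  }
})

# All valid arm sequences of a given length (no consecutive repeats).
all_entry_sequences <- function(len) {
  arms <- c("A", "B", "C")
  seqs <- lapply(arms, function(a) a)
  for (i in seq_len(len - 1)) {
    seqs <- unlist(
      lapply(seqs, function(s) {
        lapply(setdiff(arms, s[length(s)]), function(a) c(s, a))
      }),
      recursive = FALSE
    )
  }
  seqs
}
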