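# Small deterministic fixtures shared across test files.

# Integer-valued m x n slice with smooth structure, no RNG.
waveSlice <- function(m = 16, n = 16, amp = 20000, offset = 30000,
                      fi = 5, fj = 7) {
  outer(seq_len(m), seq_len(n),
        function(i, j) round(offset + amp * sin(i / fi) * cos(j / fj)))
}

# Deterministic uniform draws under a local seed (global RNG untouched).
seededRunif <- function(n, seed, min = 0, max = 1) {
  withr::with_seed(seed, stats::runif(n, min, max))
}

randomBlock <- function(seed, min = 0, max = 1) {
  matrix(seededRunif(16, seed, min, max), 4, 4)
}

tmpNii <- function(ext = ".nii") {
  tempfile(fileext = ext)
}
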