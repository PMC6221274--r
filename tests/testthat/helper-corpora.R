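# Small corpora built in code, shared across test files.

# Two labeled transcripts with hand-enumerable n-gram content.
toy_corpus <- function() {
  list(
    transcript("A", "positive",
               list(c("the", "boy", "is", "falling"),
                    c("water", "overflows", "in", "the", "sink"))),
    transcript("B", "control",
               list(c("the", "boy", "is", "falling"),
                    c("the", "girl", "is", "laughing"))))
}

# Independent n-gram enumerator: nested loops, no shared code with the
# package implementation.
enumerate_ngrams <- function(sentences, n) {
  out <- character(0)
  for (s in sentences) {
    if (length(s) >= n) {
      for (i in seq_len(length(s) - n + 1))
        out <- c(out, paste(s[i:(i + n - 1)], collapse = " "))
    }
  }
  out
}

# Balanced two-class Gaussian point clouds, linearly separable by
# construction (all class-1 x1 < 0 < all class-2 x1).
separable_points <- function(n_per_class = 15, seed = 1) {
  set.seed(seed)
  x <- rbind(cbind(rnorm(n_per_class, -3, 0.5), rnorm(n_per_class)),
             cbind(rnorm(n_per_class, 3, 0.5), rnorm(n_per_class)))
  y <- rep(c("control", "positive"), each = n_per_class)
  stopifnot(max(x[y == "control", 1]) < min(x[y == "positive", 1]))
  list(x = x, y = y)
}

# Small synthetic corpus at a given divergence.
small_corpus <- function(divergence, seed = 1, n_per_group = 19L)
  make_groups(generator_spec(divergence = divergence, seed = seed,
                             transcripts_per_group = n_per_group))
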