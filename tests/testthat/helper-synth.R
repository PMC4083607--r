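# Shared fixtures, built in code.  Simulated datasets are cached per key so
# several test files can reuse one simulation.

synth_cache <- new.env(parent = emptyenv())

cached_dataset <- function(key, ...) {
  if (is.null(synth_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("cbep_ds_", key))
    suppressWarnings(simulate_dataset(dir, ...))  # patch-count reduction is expected
    synth_cache[[key]] <- load_dataset(dir)
  }
  synth_cache[[key]]
}

# A small fully populated record with deterministic random profiles.
tiny_record <- function(id = "t1", len = 12, seed = 1) {
  withr::with_seed(seed, {
    sequence <- paste(sample(c("A", "C", "D", "E", "G", "K", "R", "S"),
                             len, replace = TRUE), collapse = "")
    pssm <- matrix(sample(-8:8, len * 20, replace = TRUE), len, 20)
    raw <- matrix(runif(len * 3), len, 3)
    ss2 <- round(raw / rowSums(raw), 3)
    for (i in seq_len(len)) {
      j <- which.max(ss2[i, ])
      ss2[i, j] <- round(ss2[i, j] + (1 - sum(ss2[i, ])), 3)
    }
    disorder <- rbinom(len, 1, 0.2)
    labels <- as.integer(seq_len(len) %in% c(2, 3, 4))
    antigen_record(id, sequence, labels = labels, pssm = pssm,
                   ss2 = ss2, disorder = disorder)
  })
}

# Linearly separable two-class feature matrix for classifier tests:
# informative first columns, pure-noise remainder.
toy_classes <- function(n = 60, informative = 2, noise = 3,
                        shift = 2, pos_frac = 0.5, seed = 1) {
  withr::with_seed(seed, {
    y <- as.integer(runif(n) < pos_frac)
    x <- matrix(rnorm(n * (informative + noise)), n)
    x[, seq_len(informative)] <- x[, seq_len(informative)] + shift * y
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    list(x = x, y = y)
  })
}
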