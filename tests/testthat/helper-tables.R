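# Small hand-built descriptor tables for unit tests.

make_tiny_table <- function(n = 3, seed = 1) {
  withr::with_seed(seed, {
    df <- data.frame(molecule_id = paste0("m", seq_len(n)),
                     y_type = rep("S", n),
                     split = c(rep("train", n - 1), "test"),
                     expt_bde = round(runif(n, 25, 45), 4),
                     stringsAsFactors = FALSE)
    for (d in canonical_descriptors()) df[[d]] <- round(rnorm(n), 4)
    descriptor_table(df)
  })
}

# printed benchmark correlations, canonical descriptor order
printed_r_631gd <- c(0.64, 0.46, 0.49, 0.02, 0.12, 0.18, 0.28, 0.43, 0.51,
                     0.17, 0.05, 0.27)
printed_r_sto3g <- c(0.35, 0.39, 0.43, 0.05, 0.12, 0.03, 0.31, 0.40, 0.48,
                     0.06, 0.05, 0.34)
named_r <- function(r) stats::setNames(r, canonical_descriptors())
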