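# Shared fixtures: all test data is generated in code at test time.

write_fasta_file <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}

fasta_from_seqs <- function(seqs, ids = sprintf("s%d", seq_along(seqs))) {
  write_fasta_file(as.vector(rbind(paste0(">", ids), seqs)))
}

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                                  collapse = "")

# small architecture/training settings for fast end-to-end tests
tiny_model <- function(...) {
  model_config(window_length = 17, conv_filters = 8, gn_groups = 4,
               pool_size = 3, fc_units = 6, ...)
}

tiny_training <- function(max_epochs = 8, ...) {
  train_config(max_epochs = max_epochs, early_stop_patience = 8,
               lr_reduce_patience = 5, ...)
}

tiny_dataset <- function(n_pos = 30, n_neg = 30, seed = 1, ...) {
  generate_dataset(n_pos, n_neg, window_length = 17, motif = "GAGG", seed = seed, ...)
}
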