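# Small shared fixtures, all built in code.

write_tmp_fasta <- function(lines, dir = tempdir()) {
  path <- tempfile("seqs", fileext = ".fasta", tmpdir = dir)
  writeLines(lines, path)
  path
}

# A scaled-down but structurally complete configuration used by the training
# and experiment unit tests (short windows, small hidden size) so each
# training run takes seconds.
tiny_config <- function(...) {
  cfg <- capstf_config(
    window = list(length = 120L),
    model = list(embed_dim = 8L, hidden = 8L, n_out = 4L, d_out = 8L,
                 dense = c(16L, 8L)),
    train = list(epochs = 30L, batch_size = 16L, seed = 3L, patience = 8L,
                 learning_rate = 1e-3)
  )
  over <- list(...)
  if (length(over))
    cfg <- structure(utils::modifyList(unclass(cfg), over),
                     class = c("capstf_config", "list"))
  cfg
}

# Matching short-sequence generator settings (lengths ~90-340 residues).
tiny_synth <- function(seed, n_pos = 60L, n_neg = 60L, ...) {
  synth_config(n_pos = n_pos, n_neg = n_neg,
               length_meanlog = log(150), length_sdlog = 0.3,
               length_min = 51L, length_max = 400L,
               region_k = 100L, seed = seed, ...)
}
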