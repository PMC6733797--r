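# shared helpers for building small test fixtures in code

# a batch of clean moderate-sedation background segments (no artifacts)
clean_segment_batch <- function(n, seed_base = 0L, fs = 62.5) {
  segs <- array(0, dim = c(n, 2L, as.integer(4 * fs)))
  for (i in seq_len(n)) {
    sp <- state_spec(-2L, 0.42, 0.33, 0.25, 15)
    segs[i, , ] <- generate_state_signal(sp, 4, fs = fs,
                                         seed = seed_base + i)$data
  }
  structure(list(tensor = segs, fs = fs,
                 segment_times = (seq_len(n) - 1L) * 4,
                 overlap_mode = "contiguous"),
            class = "segment_batch")
}

# wrap a plain matrix as a contiguous segment batch
as_batch <- function(tensor, fs = 62.5) {
  structure(list(tensor = tensor, fs = fs,
                 segment_times = (seq_len(dim(tensor)[1L]) - 1L) * 4,
                 overlap_mode = "contiguous"),
            class = "segment_batch")
}

# single-segment batch from a channels x samples matrix
one_segment_batch <- function(mat, fs = 62.5) {
  tensor <- array(0, dim = c(1L, nrow(mat), ncol(mat)))
  tensor[1L, , ] <- mat
  as_batch(tensor, fs)
}

# an untrained sedation model with a tiny architecture (for contracts
# that need a full differentiable stack but no training)
blank_model <- function(seed = 1L, n_blocks = 2L, lstm_hidden = 4L) {
  cfg <- model_config(n_blocks = n_blocks, kernel = 5L, filters0 = 4L,
                      double_every = 2L, pool_every = 1L,
                      lstm_hidden = lstm_hidden, transfer_M = 1L)
  eegtrack:::.with_seed(seed, {
    enc <- eegtrack:::make_encoder(cfg)
    structure(list(config = cfg, task = "rass", encoder = enc,
                   head1 = eegtrack:::make_head(enc$D, "ordinal"),
                   lstm1 = eegtrack:::nn_lstm_init(enc$D, lstm_hidden),
                   head2 = eegtrack:::make_head(lstm_hidden, "ordinal"),
                   lstm2 = eegtrack:::nn_lstm_init(lstm_hidden, lstm_hidden),
                   head3 = eegtrack:::make_head(lstm_hidden, "ordinal"),
                   seed = seed),
              class = "sedation_model")
  })
}

expect_no_flags <- function(mask) {
  expect_equal(sum(mask$flags), 0L)
}
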