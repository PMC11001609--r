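# shared fixture builders -----------------------------------------------------

# compressed-timeline feature-stream patient (single channel keeps the
# column count at 59 and unit tests fast)
small_stream <- function(seed = 1, n_seizures = 4, gap_hours = 2,
                         true_sop = 20, effect_size = 2, ...) {
  spec <- synthetic_spec(n_channels = 1, n_seizures = n_seizures,
                         gap_hours = gap_hours, true_sop = true_sop,
                         effect_size = effect_size, seed = seed, ...)
  generate_feature_stream(spec)
}

# feature matrix with hand-set epoch times, for labelling arithmetic
grid_features <- function(t_end, step = 5, n_feat = 3) {
  times <- seq(0, t_end - step, by = step)
  feature_matrix(matrix(0, length(times), n_feat),
                 paste0("f", seq_len(n_feat)), "chX", times,
                 window_length = step)
}

# two well-separated Gaussian blobs (rows x 2), labels 0/1
blob_data <- function(n_per = 10, sep = 10, sd = 0.1, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per, -sep, sd), n_per),
             matrix(rnorm(2 * n_per, sep, sd), n_per))
  list(x = x, y = rep(c(0L, 1L), each = n_per))
}
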