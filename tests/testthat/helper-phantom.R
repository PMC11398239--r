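# Shared fixtures. Phantom sessions are generated once per test run and
# cached; every fixture is built in code (no stored data).

table_patches <- function(offset_y = 0) {
  list(roi_box(y = offset_y + c(14, 15.9)),
       roi_box(y = offset_y + c(-15.9, -14)))
}

.fixture_env <- new.env(parent = emptyenv())

# short trials emit a "no breaths" warning that some tests do not care about
process_session_quiet <- function(...) suppressWarnings(process_session(...))

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# default-condition phantom trial (30 s) processed with ground-truth tracks
default_session <- function() {
  cached("default_session", {
    ph <- generate_sequence(phantom_config(duration = 30, seed = 4))
    list(phantom = ph,
         session = process_session(ph$sequence, ph$truth$markers,
                                   table_patches()))
  })
}

# minimal depth_signals object for cross-section unit tests
make_signals <- function(r, frame_rate = 30, col_y = seq(-9, 9, length.out = 7)) {
  n <- nrow(r)
  channels <- expand.grid(j = 1:7, i = c(1, 3, 5))[, c("i", "j")]
  structure(list(r = r, n_points = NULL,
                 row_x = matrix(seq(-9, 9, length.out = 7), n, 7, byrow = TRUE),
                 col_y = matrix(col_y, n, 7, byrow = TRUE),
                 frame_rate = frame_rate, d = 53, channels = channels,
                 central = "r_3_4"),
            class = "depth_signals")
}

channel_names <- function() sprintf("r_%d_%d", rep(c(1, 3, 5), each = 7), 1:7)

# constant-depth signal matrix
constant_signals <- function(n = 10, depth = 5) {
  r <- matrix(depth, n, 21, dimnames = list(NULL, channel_names()))
  make_signals(r)
}
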