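# shared fixtures: toy profiles built in code, independent oracles

# minimal contiguous profile with free parameters, for hand-traceable cases
toy_profile <- function(edges = c(100, 300, 480, 600), step = 1,
                        min_width = 10, f_min = edges[1],
                        deactivated = integer(0), brand = "toy") {
  n <- length(edges) - 1L
  device_profile(brand,
                 cbind(edges[-length(edges)], edges[-1L]),
                 freq_step_hz = step, min_band_width_hz = min_width,
                 deactivated = deactivated, global_f_min = f_min)
}

all_shipped_profiles <- function() {
  lapply(shipped_profile_names(), shipped_profile)
}

# independent brute-force oracle for the signed-rank test: enumerate the
# 2^n sign assignments directly on the data (not on precomputed ranks)
brute_force_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    bits <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    sum(r[bits])
  }, numeric(1))
  min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
}

# scripted fitness: returns queued scores in order, then aborts
scripted_fitness <- function(scores) {
  i <- 0L
  function(fmap, context) {
    i <<- i + 1L
    if (i > length(scores)) session_abort_signal("script exhausted")
    scores[i]
  }
}
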