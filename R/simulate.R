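#' Paired gain study of the evolutionary fitting against random parents
#'
#' For each seed, draws a fresh simulated listener (hidden ideal map sampled
#' with \code{listener_seed_offset + seed}, kept off the session stream so
#' the parents cannot replicate the ideal draw), runs a full seeded session,
#' and records the paired comparison the protocol is judged by: the best
#' observed score among the four random parents versus the best observed
#' score of the whole session, plus the corresponding hidden octave
#' mismatches of the best-scoring parent and of the finally selected map.
#'
#' @param profile a \code{device_profile}.
#' @param seeds integer vector of session seeds.
#' @param noise_mode listener scoring mode, \code{"binomial"} or
#'   \code{"noise_free"}.
#' @param n_words words per simulated intermediate test.
#' @param config an \code{evolution_config} (its seed is overridden per
#'   session).
#' @param listener_seed_offset offset separating listener seeds from
#'   session seeds.
#' @param ... further arguments to [simulated_listener()] (slopes, weights).
#' @return data.frame with one row per seed: \code{seed},
#'   \code{best_parent_wrs}, \code{best_session_wrs}, \code{gain},
#'   \code{best_parent_mismatch}, \code{selected_mismatch}.
#' @export
simulate_gain_study <- function(profile, seeds = 0:199,
                                noise_mode = c("binomial", "noise_free"),
                                n_words = 10L,
                                config = evolution_config(),
                                listener_seed_offset = 1000000L, ...) {
  noise_mode <- match.arg(noise_mode)
  rows <- lapply(as.integer(seeds), function(s) {
    listener <- simulated_listener(profile, noise_mode = noise_mode,
                                   seed = listener_seed_offset + s, ...)
    res <- run_session(profile, make_simulated_fitness(listener, n_words),
                       config, seed = s)
    maps <- res$state$individuals
    parents <- Filter(function(m) m$origin == "parent", maps)
    p_scores <- vapply(parents, function(m) m$score, numeric(1))
    all_scores <- vapply(maps, function(m) m$score, numeric(1))
    best_parent <- parents[[which.max(p_scores)]]
    data.frame(
      seed = s,
      best_parent_wrs = max(p_scores),
      best_session_wrs = max(all_scores),
      gain = max(all_scores) - max(p_scores),
      best_parent_mismatch = mismatch(listener, best_parent),
      selected_mismatch = mismatch(listener, res$best)
    )
  })
  do.call(rbind, rows)
}
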