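#' Word recognition score result
#'
#' Speech audiometry in noise scores a list of monosyllabic words at a fixed,
#' per-listener signal-to-noise ratio: 10-word lists during fitting
#' (intermediate tests), 20-word lists at the initial and final evaluations.
#' Scores are conventionally expressed out of ten, so a 20-word test can
#' yield half-point values.
#'
#' @param score integer words correct.
#' @param n_words words presented (10 or 20 in the clinical protocol).
#' @param snr_db signal-to-noise ratio of the test, dB (metadata).
#' @return an object of class \code{wrs_result} with fields \code{score},
#'   \code{n_words}, \code{snr_db}, \code{score_out_of_ten}.
#' @export
wrs_result <- function(score, n_words = 10L, snr_db = NA_real_) {
  score <- as.integer(score)
  n_words <- as.integer(n_words)
  if (is.na(score) || score < 0L || score > n_words)
    stop("score must be an integer in 0..", n_words)
  structure(list(score = score, n_words = n_words,
                 snr_db = as.numeric(snr_db),
                 score_out_of_ten = 10 * score / n_words),
            class = "wrs_result")
}

#' @export
print.wrs_result <- function(x, ...) {
  cat(sprintf("<wrs_result> %d/%d words (%.1f/10)%s\n",
              x$score, x$n_words, x$score_out_of_ten,
              if (is.na(x$snr_db)) "" else sprintf(" at SNR %+g dB", x$snr_db)))
  invisible(x)
}

#' Simulated bimodal listener
#'
#' A synthetic stand-in for the human listener, for automated testing of the
#' evolutionary loop. The listener hides an ideal frequency map; the
#' probability of recognizing a word under a candidate map is a logistic
#' function of the weighted octave distance between the candidate's and the
#' ideal map's per-electrode center frequencies, and the observed 10-word
#' score is binomial around it (or its rounded expectation in noise-free
#' mode). Weights decay geometrically toward the base so the simulated
#' optimum is most sensitive to apical (low-frequency) allocation, where
#' bimodal listeners interact with their acoustic ear.
#'
#' Defaults place the explorable mismatch range (roughly 0 to 0.35 weighted
#' octaves on a 12-channel profile with 1.2x headroom) on the steep part of
#' the logistic: \code{slope_a = 2.2} gives a recognition probability of
#' about 0.90 at zero mismatch (9/10 noise-free) and \code{slope_b = 12}
#' per weighted octave drops it to near 0.1 at the far edge of the domain.
#'
#' @param profile the \code{device_profile} the listener is fitted with.
#' @param ideal_map hidden optimal \code{frequency_map}; if omitted, sampled
#'   uniformly from the exploration domain (seeded by \code{seed}).
#' @param weights per-active-electrode non-negative weights (normalized to
#'   sum 1); default geometric decay by \code{weight_decay} from the apex.
#' @param weight_decay base-ward decay factor of the default weights.
#' @param slope_a psychometric intercept (logit of recognition probability
#'   at zero mismatch).
#' @param slope_b psychometric slope per weighted octave of mismatch.
#' @param noise_mode \code{"binomial"} (default) or \code{"noise_free"}.
#' @param snr_db nominal test SNR carried as metadata.
#' @param seed seed used only to sample \code{ideal_map} when it is omitted.
#' @return an object of class \code{simulated_listener}.
#' @export
simulated_listener <- function(profile, ideal_map = NULL, weights = NULL,
                               weight_decay = 0.7, slope_a = 2.2,
                               slope_b = 12, noise_mode = c("binomial", "noise_free"),
                               snr_db = 0, seed = NULL) {
  noise_mode <- match.arg(noise_mode)
  domain <- exploration_domain(profile)
  if (is.null(ideal_map)) {
    ideal_map <- local({
      if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv()))
          get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
      }
      chain_and_repair(sample_f_high(profile, domain), profile, domain,
                       id = "ideal", origin = "default")
    })
  }
  n <- length(ideal_map$electrode)
  if (is.null(weights)) weights <- weight_decay^(seq_len(n) - 1L)
  weights <- as.numeric(weights)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be ", n, " non-negative values with positive sum")
  weights <- weights / sum(weights)
  stopifnot(slope_b > 0)
  structure(list(profile = profile, ideal_map = ideal_map,
                 weights = weights, slope_a = as.numeric(slope_a),
                 slope_b = as.numeric(slope_b), noise_mode = noise_mode,
                 snr_db = as.numeric(snr_db)),
            class = "simulated_listener")
}

#' @export
print.simulated_listener <- function(x, ...) {
  cat(sprintf(
    "<simulated_listener> %s, %s mode, slope a=%g b=%g/octave, p(match)=%.3f\n",
    x$profile$brand, x$noise_mode, x$slope_a, x$slope_b,
    stats::plogis(x$slope_a)))
  invisible(x)
}

#' Weighted octave mismatch between a map and the listener's ideal
#'
#' \eqn{\sum_i w_i |log2 Fc_i(map) - log2 Fc_i(ideal)|}: the weighted sum of
#' absolute per-electrode center-frequency distances, in octaves.
#'
#' @param listener a \code{simulated_listener}.
#' @param fmap a \code{frequency_map} on the same active-electrode set.
#' @return non-negative dimensionless distance.
#' @export
mismatch <- function(listener, fmap) {
  ideal <- listener$ideal_map
  if (!identical(fmap$electrode, ideal$electrode))
    stop("map and ideal map are on different electrode sets")
  fc_m <- center_frequency(fmap$f_low, fmap$f_high)
  fc_i <- center_frequency(ideal$f_low, ideal$f_high)
  sum(listener$weights * abs(log2(fc_m) - log2(fc_i)))
}

#' Simulate a word recognition test
#'
#' Recognition probability \eqn{p = logit^{-1}(a - b \cdot mismatch)};
#' the score is Binomial(\code{n_words}, p) in binomial mode (consumes the
#' current RNG stream) or \code{round(n_words * p)} in noise-free mode.
#'
#' @param listener a \code{simulated_listener}.
#' @param fmap candidate \code{frequency_map}.
#' @param n_words words in the simulated list.
#' @return a \code{wrs_result}.
#' @export
simulate_wrs <- function(listener, fmap, n_words = 10L) {
  stopifnot(n_words >= 1L)
  p <- stats::plogis(listener$slope_a - listener$slope_b * mismatch(listener, fmap))
  score <- if (listener$noise_mode == "binomial")
    stats::rbinom(1L, n_words, p)
  else
    round(n_words * p)
  wrs_result(score, n_words, listener$snr_db)
}

#' Fitness callback backed by the simulated listener
#'
#' @param listener a \code{simulated_listener}.
#' @param n_words words per simulated intermediate test.
#' @return function \code{(fmap, context) -> integer score} suitable for
#'   [run_session()].
#' @export
make_simulated_fitness <- function(listener, n_words = 10L) {
  force(listener); force(n_words)
  function(fmap, context) simulate_wrs(listener, fmap, n_words)$score
}

#' Interactive fitness callback (human listener at a terminal)
#'
#' Presents each candidate map and asks for the words-correct count of the
#' just-administered 10-word test. Out-of-range or non-integer entries are
#' re-prompted; end of input aborts the session via
#' [session_abort_signal()], leaving a resumable state.
#'
#' @param input connection to read scores from (default \code{stdin()}).
#' @param output connection for prompts.
#' @return a fitness callback for [run_session()].
#' @export
interactive_fitness <- function(input = stdin(), output = stdout()) {
  function(fmap, context) {
    writeLines(sprintf("-- candidate %s (generation %d) --",
                       context$id, context$generation), output)
    df <- as.data.frame(fmap)
    writeLines(paste(utils::capture.output(print(df, row.names = FALSE)),
                     collapse = "\n"), output)
    repeat {
      writeLines(sprintf("WRS out of %d for %s: ",
                         context$n_words, context$id), output)
      line <- readLines(input, n = 1L)
      if (length(line) == 0L) session_abort_signal("end of input")
      val <- suppressWarnings(as.integer(trimws(line)))
      if (!is.na(val) && val >= 0L && val <= context$n_words) return(val)
      writeLines(sprintf("please enter an integer 0..%d", context$n_words),
                 output)
    }
  }
}

#' Read or write a simulated-listener specification as JSON
#'
#' Schema: \code{profile} (path to a profile JSON or a shipped profile
#' name), optional \code{ideal_f_high} (upper-edge vector of the hidden
#' ideal map), \code{weights}, \code{weight_decay}, \code{slope_a},
#' \code{slope_b}, \code{noise_mode}, \code{snr_db}, \code{seed}.
#'
#' @param path file path.
#' @param profile optional \code{device_profile} overriding the file's
#'   \code{profile} field.
#' @return a \code{simulated_listener}.
#' @export
read_listener <- function(path, profile = NULL) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(profile)) {
    profile <- if (j$profile %in% shipped_profile_names())
      shipped_profile(j$profile)
    else read_device_profile(j$profile)
  }
  ideal <- NULL
  if (!is.null(j$ideal_f_high))
    ideal <- chain_and_repair(j$ideal_f_high, profile, id = "ideal")
  simulated_listener(profile, ideal_map = ideal,
                     weights = j$weights,
                     weight_decay = j$weight_decay %||% 0.7,
                     slope_a = j$slope_a %||% 2.2,
                     slope_b = j$slope_b %||% 12,
                     noise_mode = j$noise_mode %||% "binomial",
                     snr_db = j$snr_db %||% 0,
                     seed = j$seed)
}
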