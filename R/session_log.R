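#' Persist a session as an append-only JSONL event log
#'
#' One JSON object per line: a header carrying the device profile and the
#' configuration, then one line per event (\code{init}, \code{propose},
#' \code{score}, \code{survivors}, \code{select_best}, \code{abort}), each
#' with the RNG checkpoint current at that point. A truncated log is a
#' valid prefix: [replay_session_log()] rebuilds the partial state and
#' [resume_session()] continues it on the exact random stream, which is how
#' a fitting interrupted between speech tests is picked up later.
#'
#' @param state an \code{ea_session}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_session_log <- function(state, path) {
  header <- list(
    kind = "header",
    profile = list(
      brand = state$profile$brand,
      default_bands = mapply(c, state$profile$default_bands$f_low,
                             state$profile$default_bands$f_high,
                             SIMPLIFY = FALSE),
      freq_step_hz = state$profile$freq_step_hz,
      min_band_width_hz = state$profile$min_band_width_hz,
      deactivated = state$profile$deactivated,
      global_f_min = state$profile$global_f_min
    ),
    config = unclass(state$config)
  )
  lines <- c(
    jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA, null = "null"),
    vapply(state$events, function(e)
      as.character(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA,
                                    null = "null")),
      character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Rebuild a session state from its event log
#'
#' @param path a JSONL file written by [write_session_log()]; a truncated
#'   prefix (e.g. from an interrupted session) is accepted and yields the
#'   corresponding partial, resumable state.
#' @return an \code{ea_session}.
#' @export
replay_session_log <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty session log")
  parse_line <- function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
             error = function(e)
               stop("corrupted session log at line ", i, ": ",
                    conditionMessage(e)))
  }
  header <- parse_line(1L)
  if (is.null(header$kind) || header$kind != "header")
    stop("corrupted session log at line 1: missing header")
  hb <- header$profile$default_bands
  profile <- device_profile(
    brand = header$profile$brand,
    default_bands = if (is.matrix(hb)) hb
                    else matrix(unlist(hb), ncol = 2, byrow = TRUE),
    freq_step_hz = header$profile$freq_step_hz,
    min_band_width_hz = header$profile$min_band_width_hz,
    deactivated = header$profile$deactivated %||% integer(0),
    global_f_min = header$profile$global_f_min
  )
  cfg <- header$config
  config <- evolution_config(
    n_parents = cfg$n_parents,
    children_per_generation = cfg$children_per_generation,
    n_generations = cfg$n_generations,
    mutation_prob = cfg$mutation_prob,
    mutation_sigma_frac = cfg$mutation_sigma_frac,
    sigma_basis = cfg$sigma_basis,
    domain_expansion = cfg$domain_expansion,
    tournament_size = cfg$tournament_size,
    tournament_win_prob = cfg$tournament_win_prob,
    crossover_mix = cfg$crossover_mix,
    n_words_intermediate = cfg$n_words_intermediate,
    final_tie_break = cfg$final_tie_break,
    rng_seed = cfg$rng_seed
  )
  state <- structure(
    list(profile = profile,
         domain = exploration_domain(profile, config$domain_expansion),
         config = config,
         individuals = list(), pending = character(0),
         pool = character(0), events = list(),
         rng = NULL, aborted = FALSE, complete = FALSE,
         best_id = NA_character_),
    class = "ea_session")
  for (i in seq_along(lines)[-1L]) {
    e <- parse_line(i)
    if (is.null(e$kind))
      stop("corrupted session log at line ", i, ": no event kind")
    p <- e$payload
    switch(e$kind,
      init = NULL,
      propose = {
        m <- chain_and_repair(as.numeric(p$f_high), profile, state$domain,
                              id = p$id,
                              origin = if (p$origin == "parent") "parent"
                                       else "child",
                              generation = as.integer(p$generation))
        state$individuals[[p$id]] <- m
        state$pending <- c(state$pending, p$id)
      },
      score = {
        if (is.null(state$individuals[[p$id]]))
          stop("corrupted session log at line ", i,
               ": score for unknown map ", p$id)
        state$individuals[[p$id]]$score <- as.numeric(p$score)
        state$pending <- setdiff(state$pending, p$id)
      },
      survivors = {
        state$pool <- as.character(p$pool)
      },
      select_best = {
        state$complete <- TRUE
        state$best_id <- p$id
      },
      abort = {
        state$aborted <- TRUE
      },
      stop("corrupted session log at line ", i, ": unknown event kind '",
           e$kind, "'")
    )
    if (!is.null(e$rng)) state$rng <- as.integer(e$rng)
    e$payload <- p
    state$events[[length(state$events) + 1L]] <- e
  }
  state
}
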