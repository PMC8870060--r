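#' Stepwise fitting session
#'
#' A session is the evolutionary bookkeeping of one fitting: every generated
#' map with its word recognition score, the elitist survivor pool, the
#' generation counter, an append-only event log, and an RNG checkpoint so
#' that a session interrupted between tests (listeners do abandon the
#' procedure) resumes deterministically.
#'
#' The stepwise surface (\code{session_start}, \code{session_score},
#' \code{session_next}, \code{session_best}) mirrors the clinical flow:
#' propose a map, test it, feed the score back. [run_session()] drives the
#' same machine with a fitness callback for batch and simulation use.
#'
#' @param profile a \code{device_profile}.
#' @param config an \code{evolution_config}; \code{config$rng_seed} (if set)
#'   seeds the session stream.
#' @return \code{session_start}: an object of class \code{ea_session} with
#'   the parent maps proposed and awaiting scores.
#' @seealso [run_session()], [write_session_log()], [replay_session_log()]
#' @export
session_start <- function(profile, config = evolution_config()) {
  domain <- exploration_domain(profile, config$domain_expansion)
  state <- structure(
    list(profile = profile, domain = domain, config = config,
         individuals = list(), pending = character(0),
         pool = character(0), events = list(),
         rng = NULL, aborted = FALSE, complete = FALSE,
         best_id = NA_character_),
    class = "ea_session")
  state <- log_event(state, "init",
                     list(brand = profile$brand,
                          seed = config$rng_seed %||% NA))
  rng_restore(state)
  parents <- init_parents(profile, config, domain)
  state <- rng_capture(state)
  for (m in parents) {
    state$individuals[[m$id]] <- m
    state <- log_event(state, "propose",
                       list(id = m$id, origin = m$origin,
                            generation = m$generation,
                            f_high = m$f_high))
  }
  state$pending <- vapply(parents, function(m) m$id, character(1))
  state
}

## The session owns one RNG stream: rng_restore() makes it the active
## global stream (seeding it on first use), rng_capture() checkpoints it
## into the state so an interrupted session resumes deterministically.
rng_restore <- function(state) {
  if (!is.null(state$rng)) {
    assign(".Random.seed", state$rng, envir = globalenv())
  } else if (!is.null(state$config$rng_seed)) {
    set.seed(state$config$rng_seed)
  } else if (!exists(".Random.seed", envir = globalenv())) {
    stats::runif(1)
  }
  invisible(state)
}

rng_capture <- function(state) {
  state$rng <- get(".Random.seed", envir = globalenv())
  state
}

## each event carries the session RNG checkpoint current at that point, so
## a truncated event log resumes on the exact stream
log_event <- function(state, kind, payload = list()) {
  state$events[[length(state$events) + 1L]] <-
    list(kind = kind, payload = payload, rng = state$rng)
  state
}

#' @rdname session_start
#' @param state an \code{ea_session}.
#' @return \code{session_pending}: character vector of map ids awaiting a
#'   score.
#' @export
session_pending <- function(state) state$pending

#' Record a word recognition score for a proposed map
#'
#' @param state an \code{ea_session}.
#' @param id id of a pending map.
#' @param score integer words correct, between 0 and
#'   \code{config$n_words_intermediate}.
#' @return the updated session.
#' @export
session_score <- function(state, id, score) {
  if (!id %in% state$pending)
    stop("map ", id, " is not awaiting a score")
  nw <- state$config$n_words_intermediate
  score <- as.numeric(score)
  if (length(score) != 1L || is.na(score) || score < 0 || score > nw)
    stop("score must be a single value in 0..", nw)
  state$individuals[[id]]$score <- score
  state$pending <- setdiff(state$pending, id)
  state <- log_event(state, "score", list(id = id, score = score))
  if (length(state$pending) == 0L) state <- maybe_close_generation(state)
  state
}

## at a generation boundary, recompute the elitist survivor pool from the
## full history: top n_parents by score, ties to earlier generation then
## earlier creation index
recompute_pool <- function(state) {
  maps <- state$individuals
  score <- vapply(maps, function(m) m$score, numeric(1))
  gen <- vapply(maps, function(m) m$generation, integer(1))
  ord <- order(-score, gen, seq_along(maps))
  names(maps)[ord[seq_len(min(state$config$n_parents, length(maps)))]]
}

children_done <- function(state) {
  sum(vapply(state$individuals, function(m) m$origin == "child", logical(1)))
}

maybe_close_generation <- function(state) {
  cd <- children_done(state)
  boundary <- cd %% state$config$children_per_generation == 0L
  if (!boundary) return(state)
  state$pool <- recompute_pool(state)
  state <- log_event(state, "survivors",
                     list(pool = state$pool,
                          drawn_from = length(state$individuals)))
  if (cd == state$config$children_per_generation * state$config$n_generations)
    state <- finalize_session(state)
  state
}

finalize_session <- function(state) {
  state$complete <- TRUE
  cand <- session_best_candidates(state)
  state$best_id <- switch(state$config$final_tie_break,
                          latest = cand[length(cand)],
                          earliest = cand[1L])
  log_event(state, "select_best",
            list(id = state$best_id, candidates = cand))
}

#' Propose the next child map
#'
#' Requires all previously proposed maps to be scored. Two tournament
#' selections within the current survivor pool give the two breeding
#' parents (possibly the same individual); locus-wise crossover and Gaussian
#' mutation produce a raw upper-edge vector which [chain_and_repair()] turns
#' into a valid map.
#'
#' @param state an \code{ea_session} with no pending scores.
#' @return the updated session, with one new pending child (no-op on a
#'   complete session).
#' @export
session_next <- function(state) {
  if (length(state$pending)) stop("scores pending for: ",
                                  paste(state$pending, collapse = ", "))
  if (state$complete) return(state)
  cd <- children_done(state)
  g <- cd %/% state$config$children_per_generation + 1L
  rng_restore(state)
  pool_maps <- state$individuals[state$pool]
  ia <- tournament_select(pool_maps, state$config)
  ib <- tournament_select(pool_maps, state$config)
  v <- crossover(pool_maps[[ia]], pool_maps[[ib]],
                 mix = state$config$crossover_mix)
  v <- mutate_f_high(v, state$profile, state$domain, state$config)
  state <- rng_capture(state)
  id <- paste0("C", cd + 1L)
  m <- chain_and_repair(v, state$profile, state$domain,
                        id = id, origin = "child", generation = g)
  state$individuals[[id]] <- m
  state$pending <- id
  state <- log_event(state, "propose",
                     list(id = id, origin = "child", generation = g,
                          f_high = m$f_high,
                          parents = c(names(pool_maps)[ia],
                                      names(pool_maps)[ib])))
  state
}

#' Ids of the maps sharing the session's best score
#'
#' @param state an \code{ea_session}.
#' @return character vector in creation order.
#' @export
session_best_candidates <- function(state) {
  scored <- Filter(function(m) !is.na(m$score), state$individuals)
  if (length(scored) == 0L) stop("no scored individuals yet")
  s <- vapply(scored, function(m) m$score, numeric(1))
  names(scored)[s == max(s)]
}

#' The selected (best-scoring) map of a session
#'
#' Several maps often share the top score; clinically the listener then
#' chooses by sound quality. In batch mode the tie is resolved by
#' \code{config$final_tie_break}; \code{choose} overrides it.
#'
#' @param state an \code{ea_session}.
#' @param choose optional explicit id among the tied candidates (the
#'   interactive analogue of the listener's preference).
#' @return the selected \code{frequency_map} (score attached).
#' @export
session_best <- function(state, choose = NULL) {
  cand <- session_best_candidates(state)
  if (!is.null(choose)) {
    if (!choose %in% cand)
      stop(choose, " is not among the top-scoring maps (",
           paste(cand, collapse = ", "), ")")
    return(state$individuals[[choose]])
  }
  id <- if (!is.na(state$best_id)) state$best_id
        else switch(state$config$final_tie_break,
                    latest = cand[length(cand)], earliest = cand[1L])
  state$individuals[[id]]
}

#' Abort condition for fitness callbacks
#'
#' A fitness callback signals that the listener abandoned the procedure by
#' calling \code{session_abort_signal()}; [run_session()] catches it, marks
#' the session aborted, and returns the partial (resumable) state.
#'
#' @param message condition message.
#' @export
session_abort_signal <- function(message = "session aborted") {
  stop(structure(class = c("eafit_abort", "error", "condition"),
                 list(message = message, call = NULL)))
}

#' Run (or resume) a full session against a fitness callback
#'
#' Drives the stepwise session machine to completion: proposes maps,
#' obtains scores from \code{fitness(fmap, context)} (context carries
#' \code{id}, \code{generation} and \code{n_words}), and returns the
#' selected best map together with the full session state. A fitness
#' callback may abort via [session_abort_signal()]; the partial session is
#' returned with \code{aborted = TRUE} and can be resumed later by passing
#' it to \code{resume_session} with a (new) fitness callback.
#'
#' @param profile a \code{device_profile}.
#' @param fitness function \code{(fmap, context) -> score}.
#' @param config an \code{evolution_config}.
#' @param seed convenience override of \code{config$rng_seed}.
#' @return list with elements \code{best} (a \code{frequency_map}; over the
#'   scored individuals if aborted) and \code{state} (the \code{ea_session}).
#' @export
run_session <- function(profile, fitness, config = evolution_config(),
                        seed = NULL) {
  if (!is.null(seed)) config$rng_seed <- as.integer(seed)
  state <- session_start(profile, config)
  resume_session(state, fitness)
}

#' @rdname run_session
#' @param state a partially completed \code{ea_session}.
#' @export
resume_session <- function(state, fitness) {
  state$aborted <- FALSE
  repeat {
    while (length(state$pending)) {
      id <- state$pending[1L]
      m <- state$individuals[[id]]
      ctx <- list(id = id, generation = m$generation,
                  n_words = state$config$n_words_intermediate)
      rng_restore(state)
      score <- tryCatch(fitness(m, ctx), eafit_abort = function(e) NULL)
      state <- rng_capture(state)
      if (is.null(score)) {
        state$aborted <- TRUE
        state <- log_event(state, "abort", list(at = id))
        return(list(best = session_best(state), state = state))
      }
      state <- session_score(state, id, score)
    }
    if (state$complete) break
    state <- session_next(state)
  }
  list(best = session_best(state), state = state)
}

#' Produce and score one full generation of children
#'
#' Convenience wrapper over [session_next()] and [session_score()]: requires
#' all current individuals to be scored, then generates and evaluates
#' \code{children_per_generation} children and recomputes the survivor pool.
#'
#' @param state an \code{ea_session} with no pending scores.
#' @param fitness function \code{(fmap, context) -> score}.
#' @return the updated session.
#' @export
make_generation <- function(state, fitness) {
  if (length(state$pending)) stop("scores pending for: ",
                                  paste(state$pending, collapse = ", "))
  if (state$complete) stop("session already complete")
  for (i in seq_len(state$config$children_per_generation)) {
    state <- session_next(state)
    id <- state$pending[1L]
    m <- state$individuals[[id]]
    ctx <- list(id = id, generation = m$generation,
                n_words = state$config$n_words_intermediate)
    rng_restore(state)
    score <- fitness(m, ctx)
    state <- rng_capture(state)
    state <- session_score(state, id, score)
  }
  state
}

#' Number of maps evaluated so far
#' @param state an \code{ea_session}.
#' @return integer count of scored individuals.
#' @export
session_evaluated <- function(state) {
  sum(vapply(state$individuals, function(m) !is.na(m$score), logical(1)))
}

#' @export
print.ea_session <- function(x, ...) {
  cat(sprintf("<ea_session> %s: %d maps (%d scored)%s%s\n",
              x$profile$brand, length(x$individuals), session_evaluated(x),
              if (x$complete) ", complete" else "",
              if (x$aborted) ", ABORTED" else ""))
  if (length(x$pool)) cat("  survivor pool:", paste(x$pool, collapse = ", "), "\n")
  if (session_evaluated(x) > 0) {
    sc <- vapply(x$individuals, function(m) m$score, numeric(1))
    cat("  scores:", paste(sprintf("%s=%g", names(sc), sc), collapse = " "), "\n")
  }
  invisible(x)
}
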