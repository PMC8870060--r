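#' Configuration of the interactive evolutionary loop
#'
#' Defaults follow the clinical protocol the package implements: 4 randomly
#' initialized parents, 3 children per generation, a fixed 3-generation
#' schedule (13 maps evaluated in total), size-2 tournament selection with
#' replacement, locus-wise crossover, and Gaussian mutation applied to each
#' band's upper edge with probability 0.2 and standard deviation 0.1 times
#' the band width.
#'
#' @param n_parents number of parents (and survivor-pool size).
#' @param children_per_generation children produced per generation.
#' @param n_generations fixed number of generations (stop criterion).
#' @param mutation_prob per-band mutation probability Pm.
#' @param mutation_sigma_frac mutation standard deviation as a fraction of
#'   band width.
#' @param sigma_basis band width used for the mutation sigma: width of the
#'   chained candidate itself (\code{"current"}, default) or the factory
#'   band width (\code{"default"}).
#' @param domain_expansion headroom factor of the exploration domain
#'   (upper edges may grow to this multiple of the factory upper edge).
#' @param tournament_size individuals drawn (with replacement) per tournament.
#' @param tournament_win_prob probability that the best-scoring drawn
#'   individual wins the tournament (1 = deterministic winner).
#' @param crossover_mix probability that a band's upper edge is taken from
#'   the first parent rather than the second.
#' @param n_words_intermediate words per intermediate recognition test
#'   (scores are validated against this).
#' @param final_tie_break how [session_best()] resolves several maps sharing
#'   the top score: \code{"latest"} (most recently generated; batch proxy
#'   for the listener's sound-quality preference) or \code{"earliest"}.
#' @param rng_seed integer seed consumed once at session start.
#' @return an object of class \code{evolution_config}.
#' @export
evolution_config <- function(n_parents = 4L,
                             children_per_generation = 3L,
                             n_generations = 3L,
                             mutation_prob = 0.2,
                             mutation_sigma_frac = 0.1,
                             sigma_basis = c("current", "default"),
                             domain_expansion = 1.2,
                             tournament_size = 2L,
                             tournament_win_prob = 1.0,
                             crossover_mix = 0.5,
                             n_words_intermediate = 10L,
                             final_tie_break = c("latest", "earliest"),
                             rng_seed = NULL) {
  cfg <- list(
    n_parents = as.integer(n_parents),
    children_per_generation = as.integer(children_per_generation),
    n_generations = as.integer(n_generations),
    mutation_prob = as.numeric(mutation_prob),
    mutation_sigma_frac = as.numeric(mutation_sigma_frac),
    sigma_basis = match.arg(sigma_basis),
    domain_expansion = as.numeric(domain_expansion),
    tournament_size = as.integer(tournament_size),
    tournament_win_prob = as.numeric(tournament_win_prob),
    crossover_mix = as.numeric(crossover_mix),
    n_words_intermediate = as.integer(n_words_intermediate),
    final_tie_break = match.arg(final_tie_break),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  )
  stopifnot(cfg$n_parents >= 1L, cfg$children_per_generation >= 1L,
            cfg$n_generations >= 1L, cfg$tournament_size >= 1L,
            cfg$mutation_prob >= 0, cfg$mutation_prob <= 1,
            cfg$mutation_sigma_frac > 0,
            cfg$tournament_win_prob >= 0, cfg$tournament_win_prob <= 1,
            cfg$crossover_mix >= 0, cfg$crossover_mix <= 1)
  class(cfg) <- "evolution_config"
  cfg
}

resample <- function(x) x[sample.int(length(x), 1L)]

#' Sample the initial parent population
#'
#' Each parent is built apex to base: given the already-sampled previous
#' upper edge, the next upper edge is drawn uniformly on the feasible part
#' of its exploration interval (at least one minimum band width above the
#' chained lower edge), then the whole vector is chained, clamped and
#' snapped to the fitting grid by [chain_and_repair()].
#'
#' Consumes the current RNG stream.
#'
#' @param profile a \code{device_profile}.
#' @param config an \code{evolution_config}.
#' @param domain an \code{exploration_domain}; derived from the profile and
#'   \code{config$domain_expansion} if omitted.
#' @return list of \code{n_parents} valid \code{frequency_map}s, ids
#'   \code{P1..Pn}, generation 0.
#' @export
init_parents <- function(profile, config = evolution_config(), domain = NULL) {
  if (is.null(domain))
    domain <- exploration_domain(profile, config$domain_expansion)
  lapply(seq_len(config$n_parents), function(p) {
    v <- sample_f_high(profile, domain)
    chain_and_repair(v, profile, domain,
                     id = paste0("P", p), origin = "parent", generation = 0L)
  })
}

## one uniform apex->base draw of an upper-edge vector (pre-repair)
sample_f_high <- function(profile, domain) {
  n <- nrow(domain)
  v <- numeric(n)
  prev <- profile$global_f_min
  for (i in seq_len(n)) {
    lb <- max(prev + profile$min_band_width_hz, domain$lo[i])
    if (grid_snap(lb, profile, "up") > grid_snap(domain$hi[i], profile, "down") + 1e-9)
      stop("infeasible exploration domain at electrode ", domain$electrode[i])
    u <- stats::runif(1, lb, domain$hi[i])
    x <- grid_snap(u, profile, "nearest")
    x <- min(max(x, grid_snap(lb, profile, "up")),
             grid_snap(domain$hi[i], profile, "down"))
    v[i] <- x
    prev <- x
  }
  v
}

#' Tournament selection among scored individuals
#'
#' Draws \code{tournament_size} individuals uniformly with replacement and
#' returns the index of the one with the highest score; ties among the drawn
#' maximum are broken uniformly at random. With
#' \code{tournament_win_prob < 1} the best drawn individual wins only with
#' that probability (otherwise a uniformly chosen non-best drawn individual
#' is returned).
#'
#' @param pool list of scored \code{frequency_map}s.
#' @param config an \code{evolution_config}.
#' @return integer index into \code{pool} of the selected individual.
#' @export
tournament_select <- function(pool, config = evolution_config()) {
  if (length(pool) == 0L) stop("empty selection pool")
  scores <- vapply(pool, function(m) m$score, numeric(1))
  if (anyNA(scores)) stop("unscored individual in selection pool")
  drawn <- sample.int(length(pool), config$tournament_size, replace = TRUE)
  s <- scores[drawn]
  best <- drawn[s == max(s)]
  rest <- drawn[s != max(s)]
  if (length(rest) == 0L || stats::runif(1) < config$tournament_win_prob)
    resample(best)
  else
    resample(rest)
}

#' Locus-wise crossover of two parent maps
#'
#' For each electrode the child's upper edge is copied (never averaged) from
#' one parent or the other, chosen by an independent Bernoulli draw with
#' probability \code{mix} for the first parent. The returned raw vector may
#' be non-monotone; [chain_and_repair()] restores validity.
#'
#' @param parent_a,parent_b \code{frequency_map}s on the same electrode set.
#' @param mix per-locus probability of inheriting from \code{parent_a}.
#' @return numeric vector of upper edges.
#' @export
crossover <- function(parent_a, parent_b, mix = 0.5) {
  if (!identical(parent_a$electrode, parent_b$electrode))
    stop("parents are defined on different electrode sets")
  take_a <- stats::runif(length(parent_a$f_high)) < mix
  ifelse(take_a, parent_a$f_high, parent_b$f_high)
}

#' Gaussian mutation of an upper-edge vector
#'
#' Independently for each electrode, with probability
#' \code{config$mutation_prob} a Gaussian perturbation with standard
#' deviation \code{config$mutation_sigma_frac} times the band width is added
#' to the proposed upper edge, and the result is clamped to the exploration
#' interval. Band widths are measured on the chained-and-repaired version of
#' the input vector (or on the factory bands if
#' \code{sigma_basis = "default"}), so the sigma is well defined even for a
#' non-monotone post-crossover vector. Only upper edges are perturbed; lower
#' edges follow by chaining, which spans the same space of maps without a
#' second repair pass.
#'
#' @param f_high numeric vector of proposed upper edges.
#' @param profile a \code{device_profile}.
#' @param domain an \code{exploration_domain}.
#' @param config an \code{evolution_config}.
#' @return numeric vector of (possibly perturbed) upper edges, clamped to
#'   the domain; not yet chained or snapped.
#' @export
mutate_f_high <- function(f_high, profile, domain,
                          config = evolution_config()) {
  n <- length(f_high)
  width <- if (config$sigma_basis == "default") {
    b <- active_default_bands(profile)
    b$f_high - b$f_low
  } else {
    m <- chain_and_repair(f_high, profile, domain)
    m$f_high - m$f_low
  }
  hit <- stats::runif(n) < config$mutation_prob
  out <- f_high
  if (any(hit)) {
    out[hit] <- out[hit] +
      stats::rnorm(sum(hit), 0, config$mutation_sigma_frac * width[hit])
    out <- pmin(pmax(out, domain$lo), domain$hi)
  }
  out
}
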