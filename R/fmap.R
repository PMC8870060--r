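#' Frequency allocation map (fMAP)
#'
#' An fMAP assigns one contiguous analysis band \code{[f_low, f_high]} to each
#' active electrode, apex-first. Bands are contiguous (no gaps, no overlaps):
#' each band's lower edge equals the previous band's upper edge, and the most
#' apical band starts at the profile's \code{global_f_min}.
#'
#' @param f_low,f_high numeric vectors of band edges in Hz, apex-first, one
#'   entry per active electrode.
#' @param electrode integer vector of electrode indices the bands belong to.
#' @param id identifier (e.g. \code{"P1"}, \code{"C3"}).
#' @param origin one of \code{"default"}, \code{"parent"}, \code{"child"}.
#' @param generation integer generation label (0 = parents).
#' @param score optional word recognition score attached to the map.
#' @return an object of class \code{frequency_map}.
#' @export
frequency_map <- function(f_low, f_high, electrode = seq_along(f_low),
                          id = NA_character_,
                          origin = c("default", "parent", "child"),
                          generation = 0L, score = NA_real_) {
  origin <- match.arg(origin)
  stopifnot(length(f_low) == length(f_high),
            length(electrode) == length(f_low))
  structure(
    list(
      electrode = as.integer(electrode),
      f_low = as.numeric(f_low),
      f_high = as.numeric(f_high),
      id = as.character(id),
      origin = origin,
      generation = as.integer(generation),
      score = as.numeric(score)
    ),
    class = "frequency_map"
  )
}

#' @export
print.frequency_map <- function(x, ...) {
  cat(sprintf("<frequency_map> %s (%s, generation %d)%s\n",
              x$id, x$origin, x$generation,
              if (is.na(x$score)) "" else sprintf(", WRS %g", x$score)))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.frequency_map <- function(x, ...) {
  data.frame(electrode = x$electrode, f_low_hz = x$f_low, f_high_hz = x$f_high)
}

#' The factory map of a profile, over active electrodes
#'
#' @param profile a \code{device_profile}.
#' @return a \code{frequency_map} with origin \code{"default"}.
#' @export
default_fmap <- function(profile) {
  b <- active_default_bands(profile)
  frequency_map(b$f_low, b$f_high, b$electrode,
                id = "default", origin = "default")
}

#' Exploration domain for band upper edges
#'
#' For each active electrode the admissible interval for its band's upper
#' edge runs from the default band's lower edge to \code{expansion} times
#' the default upper edge (1.2 by default), with the upper bound snapped
#' down to the device's fitting grid.
#'
#' @param profile a \code{device_profile}.
#' @param expansion multiplicative headroom on each default upper edge.
#' @return an object of class \code{exploration_domain}: a data.frame with
#'   columns \code{electrode}, \code{lo}, \code{hi}.
#' @export
exploration_domain <- function(profile, expansion = 1.2) {
  stopifnot(expansion > 0)
  b <- active_default_bands(profile)
  if (nrow(b) == 0L) stop("profile has no active electrodes")
  hi <- grid_snap(expansion * b$f_high, profile, "down")
  d <- data.frame(electrode = b$electrode, lo = b$f_low, hi = hi)
  if (any(d$lo >= d$hi))
    stop("degenerate exploration domain (lo >= hi) at electrode ",
         d$electrode[which(d$lo >= d$hi)[1]])
  class(d) <- c("exploration_domain", "data.frame")
  d
}

#' Chain lower edges and repair a proposed vector of band upper edges
#'
#' Takes one proposed upper edge per active electrode (possibly non-monotone,
#' e.g. straight out of crossover) and turns it into a valid frequency map:
#' working apex to base, each band's lower edge is set to the previous band's
#' upper edge (the first to \code{global_f_min}); the proposed upper edge is
#' clamped into \code{[max(f_low + min_band_width, domain lo), domain hi]}
#' and snapped to the fitting grid. Apex-to-base order makes the repair
#' deterministic and leaves the apical bands least perturbed.
#'
#' @param f_high numeric vector of proposed upper edges (Hz), one per active
#'   electrode, apex-first.
#' @param profile a \code{device_profile}.
#' @param domain an \code{exploration_domain}; computed from the profile if
#'   omitted.
#' @param ... passed to [frequency_map()] (id, origin, generation, score).
#' @return a valid \code{frequency_map}.
#' @export
chain_and_repair <- function(f_high, profile, domain = NULL, ...) {
  if (is.null(domain)) domain <- exploration_domain(profile)
  n <- nrow(domain)
  if (length(f_high) != n)
    stop("f_high must have one entry per active electrode (", n, ")")
  out_high <- numeric(n)
  out_low <- numeric(n)
  prev <- profile$global_f_min
  for (i in seq_len(n)) {
    out_low[i] <- prev
    lb <- max(prev + profile$min_band_width_hz, domain$lo[i])
    lb_grid <- grid_snap(lb, profile, "up")
    ub_grid <- grid_snap(domain$hi[i], profile, "down")
    if (lb_grid > ub_grid + 1e-9)
      stop("repair infeasible at electrode ", domain$electrode[i],
           ": minimum admissible upper edge ", lb_grid,
           " Hz exceeds domain limit ", ub_grid, " Hz")
    x <- grid_snap(min(max(f_high[i], lb), domain$hi[i]), profile, "nearest")
    x <- min(max(x, lb_grid), ub_grid)
    out_high[i] <- x
    prev <- x
  }
  frequency_map(out_low, out_high, domain$electrode, ...)
}

#' Center frequency of a band
#'
#' The geometric mean of the band edges (the conventional single-frequency
#' summary of a logarithmically laid-out analysis channel); the arithmetic
#' mean is available for comparison.
#'
#' @param f_low,f_high band edges in Hz, positive.
#' @param method \code{"geometric"} (default) or \code{"arithmetic"}.
#' @return center frequency in Hz (vectorized).
#' @export
center_frequency <- function(f_low, f_high,
                             method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  if (any(f_low <= 0) || any(f_high <= 0))
    stop("band edges must be positive")
  if (any(f_high < f_low)) stop("f_high must be >= f_low")
  switch(method,
         geometric = sqrt(f_low * f_high),
         arithmetic = (f_low + f_high) / 2)
}

#' Diagnose constraint violations of a frequency map
#'
#' Checks every map invariant against the profile (and, optionally, an
#' exploration domain): the active-electrode set, contiguity of bands,
#' minimum band width, grid alignment of every edge, and domain bounds.
#' Diagnostics, not exceptions: an empty result means the map is valid.
#'
#' @param fmap a \code{frequency_map}.
#' @param profile a \code{device_profile}.
#' @param domain optional \code{exploration_domain} to additionally check
#'   upper edges against.
#' @return data.frame with columns \code{electrode}, \code{rule},
#'   \code{detail}; zero rows iff the map is valid.
#' @export
validate_fmap <- function(fmap, profile, domain = NULL) {
  v <- list()
  bad <- function(electrode, rule, detail) {
    v[[length(v) + 1L]] <<- data.frame(electrode = as.integer(electrode),
                                       rule = rule, detail = detail)
  }
  act <- active_electrodes(profile)
  if (!identical(fmap$electrode, act)) {
    bad(NA, "electrode_set",
        sprintf("map electrodes (%s) != active electrodes (%s)",
                paste(fmap$electrode, collapse = ","),
                paste(act, collapse = ",")))
    return(do.call(rbind, v))
  }
  n <- length(fmap$electrode)
  if (abs(fmap$f_low[1] - profile$global_f_min) > 1e-6)
    bad(fmap$electrode[1], "global_f_min",
        sprintf("first f_low %g != global_f_min %g",
                fmap$f_low[1], profile$global_f_min))
  if (n > 1L) {
    gap <- which(abs(fmap$f_low[-1L] - fmap$f_high[-n]) > 1e-6)
    for (i in gap)
      bad(fmap$electrode[i + 1L], "contiguity",
          sprintf("f_low %g != previous f_high %g",
                  fmap$f_low[i + 1L], fmap$f_high[i]))
  }
  w <- fmap$f_high - fmap$f_low
  for (i in which(w < profile$min_band_width_hz - 1e-6))
    bad(fmap$electrode[i], "min_width",
        sprintf("width %g < minimum %g", w[i], profile$min_band_width_hz))
  off <- which(!on_grid(fmap$f_high, profile) | !on_grid(fmap$f_low, profile))
  for (i in off)
    bad(fmap$electrode[i], "quantization",
        sprintf("edge(s) (%g, %g) off the %g Hz grid from %g Hz",
                fmap$f_low[i], fmap$f_high[i],
                profile$freq_step_hz, profile$global_f_min))
  if (!is.null(domain)) {
    for (i in which(fmap$f_high > domain$hi + 1e-6 |
                    fmap$f_high < domain$lo - 1e-6))
      bad(fmap$electrode[i], "domain",
          sprintf("f_high %g outside domain [%g, %g]",
                  fmap$f_high[i], domain$lo[i], domain$hi[i]))
  }
  if (length(v) == 0L)
    data.frame(electrode = integer(0), rule = character(0),
               detail = character(0))
  else do.call(rbind, v)
}

#' Read or write a frequency map
#'
#' JSON carries the full object (id, origin, generation, score, bands);
#' CSV is the flat three-column form \code{electrode, f_low_hz, f_high_hz}.
#'
#' @param path file path; format chosen by extension (\code{.json} or
#'   \code{.csv}).
#' @return \code{read_fmap}: a \code{frequency_map}.
#' @export
read_fmap <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    frequency_map(j$bands$f_low_hz, j$bands$f_high_hz, j$bands$electrode,
                  id = j$id %||% NA_character_,
                  origin = j$origin %||% "default",
                  generation = j$generation %||% 0L,
                  score = j$score %||% NA_real_)
  } else {
    d <- utils::read.csv(path)
    frequency_map(d$f_low_hz, d$f_high_hz, d$electrode)
  }
}

#' @param fmap a \code{frequency_map}.
#' @rdname read_fmap
#' @export
write_fmap <- function(fmap, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- list(id = fmap$id, origin = fmap$origin,
              generation = fmap$generation, score = fmap$score,
              bands = data.frame(electrode = fmap$electrode,
                                 f_low_hz = fmap$f_low,
                                 f_high_hz = fmap$f_high))
    jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    utils::write.csv(as.data.frame(fmap), path, row.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
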