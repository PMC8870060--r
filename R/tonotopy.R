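#' Greenwood place-frequency function of the human cochlea
#'
#' \eqn{F = 165.4\,(10^{2.1 x} - 0.88)} Hz, with \eqn{x \in [0, 1]} the
#' relative position along the basilar membrane measured from the apex
#' (x = 0 at the apex, about 19.85 Hz; x = 1 at the base, about 20.68 kHz).
#' Note the orientation: some imaging workflows measure electrode distance
#' from the round window; [electrode_geometry()] converts explicitly.
#'
#' @param x_rel relative position(s) in \code{[0, 1]}, apex = 0.
#' @return characteristic frequency in Hz (vectorized, strictly increasing
#'   in \code{x_rel}).
#' @seealso [greenwood_position()] for the closed-form inverse.
#' @export
greenwood_frequency <- function(x_rel) {
  if (any(x_rel < 0 | x_rel > 1, na.rm = TRUE))
    stop("relative position must lie in [0, 1]")
  165.4 * (10^(2.1 * x_rel) - 0.88)
}

#' @param f_hz frequency in Hz, within the cochlear range
#'   \code{[greenwood_frequency(0), greenwood_frequency(1)]}.
#' @return \code{greenwood_position}: relative position from the apex.
#' @rdname greenwood_frequency
#' @export
greenwood_position <- function(f_hz) {
  lo <- greenwood_frequency(0)
  hi <- greenwood_frequency(1)
  if (any(f_hz < lo - 1e-9 | f_hz > hi + 1e-9, na.rm = TRUE))
    stop("frequency outside the cochlear range [", round(lo, 2), ", ",
         round(hi), "] Hz")
  pmin(pmax(log10(f_hz / 165.4 + 0.88) / 2.1, 0), 1)
}

#' CT-measured electrode geometry along the basilar membrane
#'
#' @param cochlea_length_mm length of the cochlear duct from round window to
#'   apex, mm.
#' @param positions_mm per-electrode distance along the basilar membrane,
#'   mm, ordered apex-first (electrode 1 most apical), strictly monotone.
#' @param orientation whether positions are measured
#'   \code{"from_apex"} or \code{"from_round_window"}.
#' @param electrode electrode indices (default sequential).
#' @return an object of class \code{electrode_geometry}.
#' @export
electrode_geometry <- function(cochlea_length_mm, positions_mm,
                               orientation = c("from_apex", "from_round_window"),
                               electrode = seq_along(positions_mm)) {
  orientation <- match.arg(orientation)
  cochlea_length_mm <- as.numeric(cochlea_length_mm)
  positions_mm <- as.numeric(positions_mm)
  if (cochlea_length_mm <= 0) stop("cochlea length must be positive")
  if (any(positions_mm < 0 | positions_mm > cochlea_length_mm))
    stop("electrode positions must lie within [0, cochlea_length_mm]")
  d <- diff(positions_mm)
  # ties allowed: CT measurement rounding can place neighbours at the same mm
  if (length(d) && !(all(d >= 0) || all(d <= 0)))
    stop("electrode positions must be monotone along the array")
  structure(list(cochlea_length_mm = cochlea_length_mm,
                 positions_mm = positions_mm,
                 orientation = orientation,
                 electrode = as.integer(electrode)),
            class = "electrode_geometry")
}

#' Convert a geometry between the two measurement orientations
#'
#' Positions from the apex and from the round window are complementary
#' (\code{x + x' = cochlea_length_mm}); converting twice restores the input.
#'
#' @param geometry an \code{electrode_geometry}.
#' @return the geometry in the opposite orientation.
#' @export
flip_orientation <- function(geometry) {
  geometry$positions_mm <- geometry$cochlea_length_mm - geometry$positions_mm
  geometry$orientation <- if (geometry$orientation == "from_apex")
    "from_round_window" else "from_apex"
  geometry
}

#' Tonotopic (Greenwood) frequency of each electrode
#'
#' Normalizes measured positions by the cochlear length, converts to the
#' apex-origin convention of [greenwood_frequency()], and evaluates the
#' place-frequency function per electrode.
#'
#' @param geometry an \code{electrode_geometry}.
#' @return data.frame with columns \code{electrode}, \code{x_rel} (relative
#'   distance from the apex) and \code{greenwood_hz}; apical electrodes map
#'   to lower frequencies.
#' @export
electrode_tonotopic_map <- function(geometry) {
  g <- if (geometry$orientation == "from_apex") geometry
       else flip_orientation(geometry)
  x <- g$positions_mm / g$cochlea_length_mm
  data.frame(electrode = g$electrode, x_rel = x,
             greenwood_hz = greenwood_frequency(x))
}

#' Read electrode geometry from CSV
#'
#' Expected layout: comment header lines \code{# cochlea_length_mm: <mm>}
#' and \code{# orientation: from_apex|from_round_window}, followed by a CSV
#' body with columns \code{electrode} and \code{distance_mm}.
#'
#' @param path file path.
#' @return an \code{electrode_geometry}.
#' @export
read_geometry_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(name) {
    m <- grep(paste0("^#\\s*", name, "\\s*:"), hdr, value = TRUE)
    if (length(m) != 1L) stop("geometry header missing field '", name, "'")
    trimws(sub("^[^:]*:", "", m))
  }
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  electrode_geometry(
    cochlea_length_mm = as.numeric(get_field("cochlea_length_mm")),
    positions_mm = body$distance_mm,
    orientation = get_field("orientation"),
    electrode = body$electrode
  )
}

#' Compare tonotopic, factory and optimized center frequencies
#'
#' Lines up, per electrode, the Greenwood frequency deduced from imaging
#' with the center frequencies of the factory map and of the optimized map,
#' with pairwise log2 ratios, so the direction of the frequency-place
#' mismatch can be read off directly (a positive
#' \code{log2_greenwood_over_default} means the cochlear place is tuned
#' higher than the band the processor assigns there).
#'
#' @param greenwood_hz per-electrode tonotopic frequencies (a numeric
#'   vector, or the data.frame from [electrode_tonotopic_map()]).
#' @param default_map,ea_map \code{frequency_map}s on the same electrode
#'   set.
#' @param method center-frequency method, see [center_frequency()].
#' @return data.frame with per-electrode center frequencies, log2 ratio
#'   columns, and logical columns \code{greenwood_above_default} /
#'   \code{greenwood_above_ea}.
#' @export
compare_center_frequencies <- function(greenwood_hz, default_map, ea_map,
                                       method = "geometric") {
  if (is.data.frame(greenwood_hz)) greenwood_hz <- greenwood_hz$greenwood_hz
  if (!identical(default_map$electrode, ea_map$electrode))
    stop("maps are on different electrode sets")
  if (length(greenwood_hz) != length(default_map$electrode))
    stop("greenwood_hz length does not match the electrode set")
  fc_def <- center_frequency(default_map$f_low, default_map$f_high, method)
  fc_ea <- center_frequency(ea_map$f_low, ea_map$f_high, method)
  data.frame(
    electrode = default_map$electrode,
    greenwood_hz = greenwood_hz,
    fc_default_hz = fc_def,
    fc_ea_hz = fc_ea,
    log2_greenwood_over_default = log2(greenwood_hz / fc_def),
    log2_greenwood_over_ea = log2(greenwood_hz / fc_ea),
    log2_ea_over_default = log2(fc_ea / fc_def),
    greenwood_above_default = greenwood_hz > fc_def,
    greenwood_above_ea = greenwood_hz > fc_ea
  )
}
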