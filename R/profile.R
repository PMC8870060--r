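#' Device profile: the constraint environment for frequency maps
#'
#' A device profile describes one cochlear implant as seen by the fitting
#' software: the electrode array, the factory ("default") frequency band
#' allocation, the quantization grid of the fitting software, the minimum
#' admissible band width, and any deactivated electrodes.
#'
#' Frequencies are in Hz throughout. Electrodes are indexed apex-first
#' (electrode 1 is the most apical, i.e. lowest-frequency); profiles declared
#' base-first are normalized on construction.
#'
#' The fitting grid is the set of frequencies \code{global_f_min + k *
#' freq_step_hz}, k a non-negative integer. All band edges emitted by the
#' package lie on this grid; factory tables are accepted as given (real
#' fitting software quantizes adjustments, not necessarily the factory map).
#'
#' @param brand label for the implant brand/model family.
#' @param default_bands two-column matrix or data.frame of factory
#'   \code{(f_low, f_high)} pairs in Hz, one row per electrode, contiguous
#'   (each row's \code{f_low} equals the previous row's \code{f_high}) and
#'   strictly increasing.
#' @param freq_step_hz quantization increment of the fitting software (Hz).
#' @param min_band_width_hz minimum admissible band width (Hz).
#' @param deactivated integer vector of deactivated electrode indices
#'   (in the declared indexing convention).
#' @param indexing \code{"apex_first"} (default) or \code{"base_first"};
#'   base-first input is reversed so that stored electrode 1 is most apical.
#' @param global_f_min fixed lower edge of the most apical active band;
#'   defaults to the factory table's lowest edge.
#' @return an object of class \code{device_profile}.
#' @seealso [exploration_domain()], [default_fmap()], [read_device_profile()]
#' @export
device_profile <- function(brand, default_bands, freq_step_hz,
                           min_band_width_hz, deactivated = integer(0),
                           indexing = c("apex_first", "base_first"),
                           global_f_min = NULL) {
  indexing <- match.arg(indexing)
  bands <- as.matrix(default_bands)
  if (ncol(bands) != 2L)
    stop("default_bands must have two columns (f_low, f_high)")
  storage.mode(bands) <- "double"
  n <- nrow(bands)
  deactivated <- as.integer(deactivated)
  if (indexing == "base_first") {
    bands <- bands[n:1, , drop = FALSE]
    deactivated <- if (length(deactivated)) (n + 1L) - deactivated else deactivated
  }
  deactivated <- sort(unique(deactivated))
  if (length(deactivated) && (min(deactivated) < 1L || max(deactivated) > n))
    stop("deactivated indices must lie in 1..n_electrodes")
  if (length(deactivated) >= n)
    stop("all electrodes deactivated: no active array")
  if (any(bands[, 2] <= bands[, 1]))
    stop("each default band must satisfy f_low < f_high")
  if (n > 1L && any(abs(bands[-1L, 1] - bands[-n, 2]) > 1e-9))
    stop("default bands must be contiguous (f_low[i+1] == f_high[i])")
  freq_step_hz <- as.numeric(freq_step_hz)
  min_band_width_hz <- as.numeric(min_band_width_hz)
  stopifnot(freq_step_hz > 0, min_band_width_hz > 0)
  if (is.null(global_f_min)) global_f_min <- bands[1L, 1]

  structure(
    list(
      brand = as.character(brand),
      n_electrodes = n,
      default_bands = data.frame(
        electrode = seq_len(n),
        f_low = bands[, 1],
        f_high = bands[, 2]
      ),
      freq_step_hz = freq_step_hz,
      min_band_width_hz = min_band_width_hz,
      deactivated = deactivated,
      global_f_min = as.numeric(global_f_min)
    ),
    class = "device_profile"
  )
}

#' @export
print.device_profile <- function(x, ...) {
  cat(sprintf(
    "<device_profile> %s: %d electrodes (%d active), %g-%g Hz, step %g Hz, min width %g Hz\n",
    x$brand, x$n_electrodes, length(active_electrodes(x)),
    x$global_f_min, max(x$default_bands$f_high),
    x$freq_step_hz, x$min_band_width_hz
  ))
  if (length(x$deactivated))
    cat("  deactivated:", paste(x$deactivated, collapse = ", "), "\n")
  invisible(x)
}

#' Active electrodes of a profile
#'
#' @param profile a \code{device_profile}.
#' @return integer vector of active (non-deactivated) electrode indices,
#'   apex-first.
#' @export
active_electrodes <- function(profile) {
  setdiff(seq_len(profile$n_electrodes), profile$deactivated)
}

#' Factory band table restricted to active electrodes
#'
#' Deactivated electrodes are excluded as a precondition; their spectral
#' range is absorbed by re-chaining lower edges over the active electrodes
#' only, starting at \code{global_f_min}.
#'
#' @param profile a \code{device_profile}.
#' @return data.frame with columns \code{electrode}, \code{f_low},
#'   \code{f_high}, one row per active electrode.
#' @export
active_default_bands <- function(profile) {
  act <- active_electrodes(profile)
  fh <- profile$default_bands$f_high[act]
  fl <- c(profile$global_f_min, fh[-length(fh)])
  data.frame(electrode = act, f_low = fl, f_high = fh)
}

## grid helpers: the fitting grid is global_f_min + k * step
grid_snap <- function(x, profile, mode = c("nearest", "down", "up")) {
  mode <- match.arg(mode)
  k <- (x - profile$global_f_min) / profile$freq_step_hz
  k <- switch(mode,
    nearest = round(k),
    down = floor(k + 1e-9),
    up = ceiling(k - 1e-9)
  )
  profile$global_f_min + k * profile$freq_step_hz
}

on_grid <- function(x, profile) {
  k <- (x - profile$global_f_min) / profile$freq_step_hz
  abs(k - round(k)) < 1e-6
}

#' Read or write a device profile as JSON
#'
#' The JSON schema has fields \code{brand}, \code{default_bands} (array of
#' \code{[f_low, f_high]} pairs in Hz), \code{freq_step_hz},
#' \code{min_band_width_hz}, \code{deactivated}, \code{indexing}
#' (\code{"apex_first"} or \code{"base_first"}) and optional
#' \code{global_f_min}.
#'
#' @param path file path.
#' @return \code{read_device_profile}: a \code{device_profile}.
#' @export
read_device_profile <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  bands <- if (is.matrix(j$default_bands)) j$default_bands
           else matrix(unlist(j$default_bands), ncol = 2, byrow = TRUE)
  device_profile(
    brand = j$brand,
    default_bands = bands,
    freq_step_hz = j$freq_step_hz,
    min_band_width_hz = j$min_band_width_hz,
    deactivated = if (is.null(j$deactivated)) integer(0) else j$deactivated,
    indexing = if (is.null(j$indexing)) "apex_first" else j$indexing,
    global_f_min = j$global_f_min
  )
}

#' @param profile a \code{device_profile}.
#' @rdname read_device_profile
#' @export
write_device_profile <- function(profile, path) {
  j <- list(
    brand = profile$brand,
    default_bands = mapply(function(l, h) c(l, h),
                           profile$default_bands$f_low,
                           profile$default_bands$f_high,
                           SIMPLIFY = FALSE),
    freq_step_hz = profile$freq_step_hz,
    min_band_width_hz = profile$min_band_width_hz,
    deactivated = profile$deactivated,
    indexing = "apex_first",
    global_f_min = profile$global_f_min
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Shipped representative device profiles
#'
#' Representative factory tables for the four brand families handled by the
#' fitting constraints (quantization step and minimum band width are the
#' brand-specific values; band tables are representative, since factory maps
#' vary by model and coding strategy, and can be replaced by user-supplied
#' JSON profiles):
#' \itemize{
#'   \item \code{"medel12"}: 12 electrodes, 70-8500 Hz logarithmic,
#'     1 Hz step, 1 Hz minimum width.
#'   \item \code{"cochlear22"}: 22 electrodes, 188-7938 Hz filter-bank
#'     table, 1 Hz step, 62 Hz minimum width.
#'   \item \code{"ab16"}: 16 electrodes, 248-8122 Hz on a 62 Hz grid,
#'     62 Hz step and minimum width.
#'   \item \code{"oticon20"}: 20 electrodes, 195-8057 Hz on a 131 Hz grid,
#'     131 Hz step and minimum width.
#' }
#'
#' @param name one of \code{"medel12"}, \code{"cochlear22"}, \code{"ab16"},
#'   \code{"oticon20"}.
#' @param deactivated optional deactivated electrode indices.
#' @return a \code{device_profile}.
#' @export
shipped_profile <- function(name = c("medel12", "cochlear22", "ab16", "oticon20"),
                            deactivated = integer(0)) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".json"), package = "eafit",
                      mustWork = TRUE)
  p <- read_device_profile(path)
  if (length(deactivated)) {
    p <- device_profile(p$brand,
                        cbind(p$default_bands$f_low, p$default_bands$f_high),
                        p$freq_step_hz, p$min_band_width_hz,
                        deactivated = deactivated,
                        global_f_min = p$global_f_min)
  }
  p
}

#' Names of the shipped device profiles
#' @return character vector of profile names accepted by [shipped_profile()].
#' @export
shipped_profile_names <- function() c("medel12", "cochlear22", "ab16", "oticon20")
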