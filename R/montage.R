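#' The 32-channel 10-20 electrode montage
#'
#' Returns the packaged spherical coordinate table for the 32-channel
#' 10-20 montage used by consumer EEG emotion datasets. Coordinates are an
#' idealized equidistant construction on the unit sphere: azimuth is
#' measured from the nasion axis (positive toward the left ear), elevation
#' from the horizontal plane, with the vertex channel Cz at elevation 90.
#' Left/right homologue pairs carry exactly mirrored azimuths.
#'
#' @return A tibble with columns `label`, `azimuth_deg`, `elevation_deg`
#'   (one row per channel, 32 rows) and attribute `vertex = "Cz"`.
#' @examples
#' m <- standard_1020_montage()
#' m[m$label == "Cz", ]
#' @export
standard_1020_montage <- function() {
  path <- system.file("extdata", "montage_deap32.csv",
                      package = "topospectra", mustWork = TRUE)
  read_montage(path)
}

#' Read a montage coordinate table
#'
#' Parses a delimited text file with columns `label`, `azimuth_deg`,
#' `elevation_deg`. Lines starting with `#` are comments.
#'
#' @param path Path to the delimited montage file.
#' @param vertex Label of the vertex (central reference) channel.
#' @return A montage tibble; see [standard_1020_montage()].
#' @export
read_montage <- function(path, vertex = "Cz") {
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  required <- c("label", "azimuth_deg", "elevation_deg")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0("montage file lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tab <- tab[required]
  validate_montage(tab, vertex)
  structure(as_tibble(tab), vertex = vertex,
            class = c("eeg_montage", class(as_tibble(tab))))
}

validate_montage <- function(tab, vertex) {
  if (anyDuplicated(tab$label) > 0) abort("duplicate channel labels in montage")
  if (any(tab$elevation_deg < -90 | tab$elevation_deg > 90)) {
    abort("montage elevations must lie in [-90, 90]")
  }
  if (any(tab$azimuth_deg <= -180 | tab$azimuth_deg > 180)) {
    abort("montage azimuths must lie in (-180, 180]")
  }
  if (!vertex %in% tab$label) {
    abort(paste0("vertex channel '", vertex, "' absent from montage"))
  }
  if (abs(tab$elevation_deg[tab$label == vertex] - 90) > 1e-9) {
    abort(paste0("vertex channel '", vertex, "' must sit at elevation 90"))
  }
  invisible(tab)
}

#' Channel labels of the 32-channel montage
#' @return Character vector of the 32 channel names, montage order.
#' @export
montage_channels <- function() standard_1020_montage()$label

#' Azimuthal equidistant projection of a montage
#'
#' Projects electrode positions from the unit sphere onto the plane so that
#' the arc distance from the vertex (Cz) and the direction from the vertex
#' are both preserved: an electrode at elevation `e` degrees and azimuth `a`
#' lands at planar radius `rho = (90 - e) * pi / 180` (head-radius units)
#' along direction `a`. The vertex maps to the origin.
#'
#' @param montage A montage tibble from [standard_1020_montage()] or
#'   [read_montage()].
#' @return A tibble with columns `label`, `x`, `y` (head-radius units;
#'   `x` toward the nasion, `y` toward the left ear).
#' @examples
#' proj <- aep_project(standard_1020_montage())
#' proj[proj$label == "Cz", ]  # origin
#' @export
aep_project <- function(montage) {
  vertex <- attr(montage, "vertex") %||% "Cz"
  if (!vertex %in% montage$label) {
    abort(paste0("montage has no vertex channel '", vertex, "'"))
  }
  rho <- (90 - montage$elevation_deg) * pi / 180
  az <- montage$azimuth_deg * pi / 180
  tibble(label = montage$label,
         x = rho * cos(az),
         y = rho * sin(az))
}
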