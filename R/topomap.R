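MAP_SIZE <- 227L
BAND_ORDER <- c("pt", "theta", "alpha", "beta", "gamma")

new_scalar_map <- function(values, band, scheme, mask = NULL) {
  stopifnot(is.matrix(values), all(dim(values) == MAP_SIZE))
  rng <- range(if (is.null(mask)) values else values[mask])
  structure(list(values = values, band = band, scheme = scheme,
                 range = rng, mask = mask),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf("<scalar_map> %s / %s, %dx%d, range [%.4g, %.4g]%s\n",
              x$scheme, x$band, nrow(x$values), ncol(x$values),
              x$range[1], x$range[2],
              if (!is.null(x$mask)) ", masked" else ""))
  invisible(x)
}

check_values <- function(values, labels) {
  if (is.null(names(values))) abort("channel values must be named")
  missing <- setdiff(labels, names(values))
  if (length(missing) > 0) {
    abort(paste0("missing channel value(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(values))) abort("channel values must be finite")
  invisible(values)
}

# Cell boundaries tiling `size` pixels into `k` bands. Default: rounded
# equal fractions (heights 25/26 at 227/9, widths 56/57 at 227/4).
# Strict: uniform floor(size/k) with the remainder merged into the last.
cell_edges <- function(size, k, strict = FALSE) {
  if (strict) c(seq(0L, by = size %/% k, length.out = k), size)
  else round((0:k) * size / k)
}

#' Render a band as a direct-matrix-distribution image
#'
#' Paints each cell of the 9x4 layout uniformly with the corresponding
#' channel's value. Cell boundaries tile the full 227 pixels; in strict
#' mode the first 8 rows are exactly 25 px tall (227/4-wide columns
#' likewise uniform) with the remainder merged into the last row/column.
#'
#' @param values Named numeric vector of per-channel band powers (must
#'   cover every label in the layout).
#' @param layout A `dmd_layout`; default [default_dmd_layout()].
#' @param band Band name recorded on the map.
#' @param strict Use uniform 25 px x 56 px cells with remainder merging.
#' @return A `scalar_map`.
#' @export
render_dmd <- function(values, layout = default_dmd_layout(), band = "pt",
                       strict = FALSE) {
  check_values(values, unique(as.vector(layout$grid)))
  re <- cell_edges(MAP_SIZE, 9L, strict)
  ce <- cell_edges(MAP_SIZE, 4L, strict)
  m <- matrix(0, MAP_SIZE, MAP_SIZE)
  for (r in seq_len(9)) for (cc in seq_len(4)) {
    m[(re[r] + 1):re[r + 1], (ce[cc] + 1):ce[cc + 1]] <-
      values[[layout$grid[r, cc]]]
  }
  new_scalar_map(m, band, "DMD")
}

# Integer pixel coordinates of the 36 cell centers of a layout.
dmd_cell_centers <- function(layout) {
  re <- cell_edges(MAP_SIZE, 9L)
  ce <- cell_edges(MAP_SIZE, 4L)
  rows <- integer(0); cols <- integer(0); labs <- character(0)
  for (r in seq_len(9)) for (cc in seq_len(4)) {
    rows <- c(rows, floor((re[r] + 1 + re[r + 1]) / 2))
    cols <- c(cols, floor((ce[cc] + 1 + ce[cc + 1]) / 2))
    labs <- c(labs, layout$grid[r, cc])
  }
  tibble(label = labs, row = rows, col = cols)
}

#' Render a band as an interpolated matrix-distribution image
#'
#' Places each channel's value at the pixel nearest its 9x4 cell center
#' (midline channels occupy two distinct central cells, both carrying the
#' single midline value) and colors the whole 227x227 surface with the
#' biharmonic spline interpolant through those nodes.
#'
#' @inheritParams render_dmd
#' @return A `scalar_map` (no mask; every pixel interpolated).
#' @export
render_dmdi <- function(values, layout = default_dmd_layout(), band = "pt") {
  check_values(values, unique(as.vector(layout$grid)))
  centers <- dmd_cell_centers(layout)
  pts <- data.frame(x = centers$col, y = centers$row,
                    value = unname(values[centers$label]))
  m <- biharmonic_interpolate(pts, grid_x = seq_len(MAP_SIZE),
                              grid_y = seq_len(MAP_SIZE))
  new_scalar_map(m, band, "DMDi")
}

# Snapped pixel positions of projected electrodes. Rounding the axis
# offsets separately keeps left/right homologues exactly mirrored.
aep_pixels <- function(proj, margin = 0.05) {
  center <- (MAP_SIZE + 1) / 2
  r_max <- max(sqrt(proj$x^2 + proj$y^2))
  scale <- (center - 1) / (r_max * (1 + margin))
  tibble(label = proj$label,
         row = center - round(scale * proj$x),
         col = center - round(scale * proj$y))
}

#' Render a band as an azimuthal-equidistant-projection image
#'
#' Maps the projected electrode positions affinely into the 227x227 pixel
#' frame (equal x/y scale, vertex at the image center, 5% margin around
#' the electrode bounding circle), interpolates with the biharmonic spline
#' over every pixel inside the head disc (the circle circumscribing the
#' electrodes), and masks outside-disc pixels to the in-disc minimum.
#'
#' @param values Named numeric vector of per-channel band powers.
#' @param proj Projected coordinates from [aep_project()].
#' @param band Band name recorded on the map.
#' @param margin Fractional margin around the electrode bounding circle.
#' @return A `scalar_map` with a disc mask.
#' @export
render_aep <- function(values, proj = aep_project(standard_1020_montage()),
                       band = "pt", margin = 0.05) {
  check_values(values, proj$label)
  px <- aep_pixels(proj, margin)
  pts <- data.frame(x = px$col, y = px$row,
                    value = unname(values[px$label]))
  center <- (MAP_SIZE + 1) / 2
  disc_r <- max(sqrt((px$row - center)^2 + (px$col - center)^2))
  cols <- matrix(seq_len(MAP_SIZE), MAP_SIZE, MAP_SIZE, byrow = TRUE)
  rows <- matrix(seq_len(MAP_SIZE), MAP_SIZE, MAP_SIZE)
  mask <- (rows - center)^2 + (cols - center)^2 <= disc_r^2 + 1e-9
  fit <- bh_fit(pts$x, pts$y, pts$value)
  m <- matrix(0, MAP_SIZE, MAP_SIZE)
  m[mask] <- bh_eval(fit, cols[mask], rows[mask])
  m[!mask] <- min(m[mask])
  new_scalar_map(m, band, "AEP", mask = mask)
}

#' The 256-level jet palette
#'
#' Classic piecewise-linear jet ramp from dark blue (minimum) through
#' cyan, green and yellow to dark red (maximum), quantized to 256 levels.
#'
#' @return A 256 x 3 integer matrix of 0-255 RGB values.
#' @export
jet_palette <- function() {
  t <- (0:255) / 255
  comp <- function(a, b) pmin(pmax(pmin(4 * t + a, -4 * t + b), 0), 1)
  cbind(r = round(255 * comp(-1.5, 4.5)),
        g = round(255 * comp(-0.5, 3.5)),
        b = round(255 * comp(0.5, 2.5)))
}

#' Quantize a scalar map through the jet colormap
#'
#' Min-max normalizes the map (over its valid pixels), quantizes to 256
#' levels and applies the jet palette: the minimum renders dark blue
#' (0, 0, 128), the maximum dark red (128, 0, 0). A constant map renders
#' uniformly at mid-palette, with a warning.
#'
#' @param map A `scalar_map`.
#' @return An `rgb_image`: 227 x 227 x 3 integer array, values 0-255.
#' @export
jet_quantize <- function(map) {
  v <- map$values
  if (any(!is.finite(v))) abort("map contains non-finite values")
  lo <- map$range[1]; hi <- map$range[2]
  if (hi > lo) {
    k <- round(255 * pmin(pmax((v - lo) / (hi - lo), 0), 1))
  } else {
    warn("constant map: rendered uniformly at mid-palette")
    k <- matrix(128L, nrow(v), ncol(v))
  }
  pal <- jet_palette()
  img <- array(0L, c(MAP_SIZE, MAP_SIZE, 3L))
  for (ch in 1:3) img[, , ch] <- matrix(pal[k + 1L, ch], nrow(v))
  structure(img, class = "rgb_image")
}

#' Stack five band maps into a spectral cube
#'
#' Piles the 2-D maps of `pt`, `theta`, `alpha`, `beta` and `gamma` (in
#' that depth order) into a 227 x 227 x 5 cube, min-max normalizing each
#' slice to [0, 1] independently.
#'
#' @param maps A list of five `scalar_map`s of the same scheme, covering
#'   exactly the five bands.
#' @return A `spectral_cube`: list with `values` (227 x 227 x 5 array),
#'   `bands`, `scheme`.
#' @export
stack_cube <- function(maps) {
  if (length(maps) != 5) abort("exactly five maps are required")
  bands <- vapply(maps, function(m) m$band, character(1))
  if (anyDuplicated(bands) > 0) abort("duplicate band maps supplied")
  if (!setequal(bands, BAND_ORDER)) {
    abort(paste0("bands must be exactly {",
                 paste(BAND_ORDER, collapse = ", "), "}"))
  }
  schemes <- unique(vapply(maps, function(m) m$scheme, character(1)))
  if (length(schemes) != 1) abort("all maps must share one scheme")
  maps <- maps[match(BAND_ORDER, bands)]
  cube <- array(0, c(MAP_SIZE, MAP_SIZE, 5L))
  for (i in seq_len(5)) {
    v <- maps[[i]]$values
    lo <- maps[[i]]$range[1]; hi <- maps[[i]]$range[2]
    cube[, , i] <- if (hi > lo) pmin(pmax((v - lo) / (hi - lo), 0), 1)
    else matrix(0.5, MAP_SIZE, MAP_SIZE)
  }
  structure(list(values = cube, bands = BAND_ORDER, scheme = schemes),
            class = "spectral_cube")
}

band_values <- function(bp_rows, band) {
  setNames(bp_rows[[band]], bp_rows$label)
}

render_map <- function(values, scheme, band, layout, proj, strict = FALSE) {
  switch(scheme,
         dmd = render_dmd(values, layout, band = band, strict = strict),
         dmdi = render_dmdi(values, layout, band = band),
         aep = render_aep(values, proj, band = band),
         abort(paste0("unknown scheme: ", scheme)))
}

#' Render images or cubes for every epoch of a band-power table
#'
#' @param bp Band-power tibble from [batch_band_powers()].
#' @param scheme One of `"dmd"`, `"dmdi"`, `"aep"`.
#' @param band One of `"pt"`, `"theta"`, `"alpha"`, `"beta"`, `"gamma"`
#'   for RGB images, or `"cube"` for 227x227x5 spectral cubes.
#' @param layout,proj Geometry for the matrix and projection schemes.
#' @param out_dir Optional directory; when given, images are written as
#'   PNG (cubes as five grayscale PNG slices) and a manifest CSV.
#' @return A list: `images` (list of `rgb_image` or `spectral_cube`,
#'   epoch order) and `manifest` (tibble: trial_id, epoch_idx, class,
#'   scheme, band, file).
#' @export
image_batch <- function(bp, scheme = "dmd", band = "pt",
                        layout = default_dmd_layout(),
                        proj = aep_project(standard_1020_montage()),
                        out_dir = NULL) {
  if (!scheme %in% c("dmd", "dmdi", "aep")) {
    abort(paste0("unknown scheme: ", scheme))
  }
  if (!band %in% c(BAND_ORDER, "cube")) {
    abort(paste0("unknown band: ", band))
  }
  keys <- dplyr::distinct(bp, .data$trial_id, .data$epoch_idx, .data$class)
  keys <- dplyr::arrange(keys, .data$trial_id, .data$epoch_idx)
  images <- vector("list", nrow(keys))
  files <- rep(NA_character_, nrow(keys))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  for (i in seq_len(nrow(keys))) {
    rows <- bp[bp$trial_id == keys$trial_id[i] &
                 bp$epoch_idx == keys$epoch_idx[i], ]
    if (band == "cube") {
      maps <- lapply(BAND_ORDER, function(b) {
        render_map(band_values(rows, b), scheme, b, layout, proj)
      })
      images[[i]] <- stack_cube(maps)
      if (!is.null(out_dir)) {
        base <- sprintf("t%04d_e%d_%s_cube", keys$trial_id[i],
                        keys$epoch_idx[i], scheme)
        files[i] <- write_cube_png(images[[i]], file.path(out_dir, base))
      }
    } else {
      map <- render_map(band_values(rows, band), scheme, band, layout, proj)
      images[[i]] <- jet_quantize(map)
      if (!is.null(out_dir)) {
        files[i] <- file.path(out_dir,
                              sprintf("t%04d_e%d_%s_%s.png",
                                      keys$trial_id[i], keys$epoch_idx[i],
                                      scheme, band))
        write_map_png(images[[i]], files[i])
      }
    }
  }
  manifest <- dplyr::mutate(keys, scheme = scheme, band = band,
                            file = files)
  if (!is.null(out_dir)) {
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  }
  list(images = images, manifest = manifest)
}

#' Write an RGB image as an 8-bit PNG
#' @param img An `rgb_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_png <- function(img, path) {
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' Write a spectral cube as five grayscale PNG slices plus a manifest
#' @param cube A `spectral_cube`.
#' @param base Output path prefix; slices land at `<base>_<band>.png` and
#'   the slice order at `<base>.json`.
#' @return The JSON manifest path, invisibly.
#' @export
write_cube_png <- function(cube, base) {
  paths <- character(5)
  for (i in seq_len(5)) {
    paths[i] <- paste0(base, "_", cube$bands[i], ".png")
    png::writePNG(cube$values[, , i], paths[i])
  }
  manifest <- paste0(base, ".json")
  jsonlite::write_json(list(bands = cube$bands, scheme = cube$scheme,
                            slices = paths),
                       manifest, auto_unbox = TRUE)
  invisible(manifest)
}
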