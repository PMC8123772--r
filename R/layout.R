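MIDLINE_CHANNELS <- c("Fz", "Cz", "Pz", "Oz")

new_dmd_layout <- function(grid, provenance) {
  stopifnot(is.matrix(grid), nrow(grid) == 9, ncol(grid) == 4)
  structure(list(grid = grid, provenance = provenance),
            class = "dmd_layout")
}

#' Default 9x4 direct-matrix-distribution layout
#'
#' The direct matrix distribution (DMD) places the 32 channels into a 9x4
#' grid whose rows run anterior to posterior and whose columns mirror the
#' left/right hemispheres, leaving no blank cells. The four midline
#' channels (Fz, Cz, Pz, Oz) are duplicated across the two central columns
#' so the representation stays symmetric.
#'
#' @return A `dmd_layout` object holding the 9x4 character grid and a
#'   provenance note.
#' @examples
#' default_dmd_layout()$grid
#' @export
default_dmd_layout <- function() {
  grid <- matrix(c(
    "Fp1", "AF3", "AF4", "Fp2",
    "F7",  "F3",  "F4",  "F8",
    "FC5", "Fz",  "Fz",  "FC6",
    "T7",  "FC1", "FC2", "T8",
    "C3",  "Cz",  "Cz",  "C4",
    "CP5", "CP1", "CP2", "CP6",
    "P3",  "Pz",  "Pz",  "P4",
    "P7",  "PO3", "PO4", "P8",
    "O1",  "Oz",  "Oz",  "O2"), nrow = 9, ncol = 4, byrow = TRUE)
  new_dmd_layout(grid, "package default")
}

#' Read a user-supplied DMD layout
#'
#' @param path Plain-text file: 9 lines of 4 whitespace-separated channel
#'   labels.
#' @return A `dmd_layout` object (not yet validated against a montage; see
#'   [validate_layout()]).
#' @export
read_dmd_layout <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 9) {
    abort(paste0("layout file must have 9 non-empty lines, found ",
                 length(lines)))
  }
  cells <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  if (any(lengths(cells) != 4)) {
    abort("every layout line must contain exactly 4 labels")
  }
  new_dmd_layout(do.call(rbind, cells), paste0("user file: ", path))
}

left_right_pairs <- function() {
  c(Fp1 = "Fp2", AF3 = "AF4", F3 = "F4", F7 = "F8", FC5 = "FC6",
    FC1 = "FC2", C3 = "C4", T7 = "T8", CP5 = "CP6", CP1 = "CP2",
    P3 = "P4", P7 = "P8", PO3 = "PO4", O1 = "O2")
}

homologue <- function(label) {
  pairs <- left_right_pairs()
  rev_pairs <- setNames(names(pairs), pairs)
  ifelse(label %in% MIDLINE_CHANNELS, label,
         ifelse(label %in% names(pairs), unname(pairs[label]),
                ifelse(label %in% names(rev_pairs),
                       unname(rev_pairs[label]), NA_character_)))
}

#' Validate a DMD layout against a montage
#'
#' Checks every structural invariant of the 9x4 direct matrix distribution:
#' all 36 cells filled with known channels; each midline channel (Fz, Cz,
#' Pz, Oz) appearing exactly twice, both occurrences in the central
#' columns; every other montage channel appearing exactly once; and mirror
#' symmetry (the labels at columns `c` and `5 - c` of a row are left/right
#' homologues or the same midline channel). Failures are reported, not
#' raised.
#'
#' @param layout A `dmd_layout`.
#' @param montage A montage tibble; defaults to the packaged 32-channel
#'   montage.
#' @return A tibble with columns `check`, `pass`, `detail`.
#' @export
validate_layout <- function(layout, montage = standard_1020_montage()) {
  g <- layout$grid
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1]] <<- tibble(check = name, pass = pass,
                                            detail = detail)
  }

  filled <- all(nzchar(g)) && !anyNA(g)
  add("all_cells_filled", filled,
      if (!filled) "blank or missing cells" else "")

  unknown <- setdiff(unique(as.vector(g)), montage$label)
  add("labels_known", length(unknown) == 0,
      if (length(unknown) > 0) {
        paste0("unknown label(s): ", paste(unknown, collapse = ", "))
      } else "")

  counts <- table(factor(as.vector(g), levels = montage$label))
  mid_ok <- all(counts[MIDLINE_CHANNELS] == 2)
  mid_central <- all(vapply(MIDLINE_CHANNELS, function(ch) {
    pos <- which(g == ch, arr.ind = TRUE)
    nrow(pos) == 2 && all(pos[, "col"] %in% c(2, 3))
  }, logical(1)))
  add("midline_duplicated_centrally", mid_ok && mid_central,
      if (!(mid_ok && mid_central)) {
        "Fz/Cz/Pz/Oz must each appear exactly twice, in columns 2-3"
      } else "")

  others <- setdiff(montage$label, MIDLINE_CHANNELS)
  singles_ok <- all(counts[others] == 1)
  add("other_channels_once", singles_ok,
      if (!singles_ok) {
        bad <- others[counts[others] != 1]
        paste0("wrong multiplicity: ", paste(bad, collapse = ", "))
      } else "")

  mirror_ok <- TRUE
  for (r in seq_len(9)) for (cc in 1:2) {
    lhs <- g[r, cc]; rhs <- g[r, 5 - cc]
    hom <- homologue(lhs)
    if (is.na(hom) || !identical(hom, rhs)) mirror_ok <- FALSE
  }
  add("mirror_symmetry", mirror_ok,
      if (!mirror_ok) "columns c and 5-c are not homologue pairs" else "")

  dplyr::bind_rows(checks)
}

#' @export
print.dmd_layout <- function(x, ...) {
  cat("<dmd_layout> 9 x 4 grid (", x$provenance, ")\n", sep = "")
  mat <- format(x$grid, width = 4)
  for (r in seq_len(nrow(mat))) cat(" ", paste(mat[r, ], collapse = " "), "\n")
  invisible(x)
}
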