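#' Label a trial from its valence/arousal ratings
#'
#' Self-assessment ratings on the 1-9 scale map to emotional classes:
#' distress when valence < 3 and arousal > 5; calm when valence lies in
#' [4, 6] and arousal < 4; everything else is excluded from analysis.
#' Vectorized over ratings.
#'
#' @param valence,arousal Numeric ratings in [1, 9].
#' @return Character vector in `c("calm", "distress", "excluded")`.
#' @examples
#' label_trial(2, 6)  # distress
#' label_trial(5, 3)  # calm
#' @export
label_trial <- function(valence, arousal) {
  if (length(valence) != length(arousal)) {
    abort("valence and arousal must have equal length")
  }
  if (any(valence < 1 | valence > 9 | arousal < 1 | arousal > 9,
          na.rm = FALSE) || anyNA(valence) || anyNA(arousal)) {
    abort("ratings must lie within [1, 9]")
  }
  dplyr::case_when(
    valence < 3 & arousal > 5 ~ "distress",
    valence >= 4 & valence <= 6 & arousal < 4 ~ "calm",
    TRUE ~ "excluded"
  )
}

#' Label a trial metadata table
#'
#' Adds a `label` column to a metadata table with `valence` and `arousal`
#' columns and reports per-class counts.
#'
#' @param metadata A data frame with `valence` and `arousal` columns.
#' @param drop_excluded Drop excluded rows from the returned manifest
#'   (default `TRUE`); counts always cover all input rows.
#' @return A labeled manifest tibble with attribute `class_counts`, a named
#'   integer vector over calm/distress/excluded.
#' @export
label_manifest <- function(metadata, drop_excluded = TRUE) {
  missing <- setdiff(c("valence", "arousal"), names(metadata))
  if (length(missing) > 0) {
    abort(paste0("metadata lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- as_tibble(metadata)
  out$label <- label_trial(out$valence, out$arousal)
  counts <- table(factor(out$label,
                         levels = c("calm", "distress", "excluded")))
  if (drop_excluded) out <- out[out$label != "excluded", ]
  attr(out, "class_counts") <- setNames(as.integer(counts), names(counts))
  out
}
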