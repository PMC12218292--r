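cell_categories <- c("Simple", "Complex", "Foci", "Nothing")

#' Classify a nucleus crop into the four structure categories
#'
#' `Simple`: exactly one skeleton component without branches (no
#' junctions). `Complex`: two or more components, or any junction.
#' `Foci`: no skeleton but at least one focus. `Nothing`: none of the
#' above. The categories are exhaustive and mutually exclusive.
#'
#' @param features One-row tibble from [skeleton_features()].
#' @param foci List of foci from [segment_structures()] (only its length is
#'   used).
#' @return One of `"Simple"`, `"Complex"`, `"Foci"`, `"Nothing"`.
#' @export
classify_cell <- function(features, foci = list()) {
  nc <- features$n_components
  nj <- features$n_junctions
  if (nc == 1 && nj == 0) return("Simple")
  if (nc >= 2 || nj > 0) return("Complex")
  if (length(foci) >= 1) return("Foci")
  "Nothing"
}

#' Background-subtracted summed intensity over a mask
#'
#' Sum over the mask of (raw - background). Negative residuals are kept so
#' that noise cancels in expectation; nothing is clipped.
#'
#' @param raw 2D raw-channel image (normally a photon-conserving sum
#'   z-projection, see [sum_z_projection()]).
#' @param mask Logical matrix.
#' @param background Scalar from [nuclear_background()] of the same cell.
#' @return Summed background-subtracted intensity.
#' @export
measure_intensity <- function(raw, mask, background) {
  check_finite_image(raw)
  if (!any(mask)) abort("empty mask: nothing to measure")
  sum(raw[mask] - background)
}

#' Select the brightest focus
#'
#' When a cell carries several foci only the brightest (maximal
#' background-subtracted summed intensity) enters the feature table. Exact
#' ties are broken by the lexicographically smallest (row, column) centre.
#'
#' @param foci List of foci, each with `center` and `intensity`.
#' @return The selected focus (single list element).
#' @export
select_brightest_focus <- function(foci) {
  if (!length(foci)) abort("no foci to select from")
  ints <- map_dbl(foci, "intensity")
  best <- which(ints == max(ints))
  if (length(best) > 1) {
    ctrs <- map(foci[best], "center")
    ord <- order(map_dbl(ctrs, 1), map_dbl(ctrs, 2))
    best <- best[ord[1]]
  }
  foci[[best]]
}

new_cell_records <- function(x) {
  x <- as_tibble(x)
  need <- c("cell_id", "strain", "batch", "category", "has_filament",
            "filament_length_px", "filament_intensity", "spot_intensity")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste("cell records missing column(s):",
                                paste(miss, collapse = ", ")))
  class(x) <- c("cell_records", class(x))
  x
}

enforce_record_invariants <- function(x) {
  x <- mutate(x,
    has_filament = if_else(.data$category %in% c("Simple", "Complex"),
                           1L, 0L, missing = NA_integer_),
    filament_length_px = if_else(.data$category == "Simple",
                                 .data$filament_length_px, NA_real_),
    filament_intensity = if_else(.data$category == "Simple",
                                 .data$filament_intensity, NA_real_),
    spot_intensity = if_else(.data$category == "Foci",
                             .data$spot_intensity, NA_real_))
  x
}

#' Assemble the per-cell feature table
#'
#' One row per nucleus crop with the category and the three retained
#' features: filament length and total intensity (Simple cells only —
#' length is overestimated for complex filaments, so Complex cells
#' contribute presence but no measurements) and the brightest-focus
#' intensity (Foci cells only).
#'
#' @param results List of per-cell results, each a list with `category`,
#'   and optionally `filament_length_px`, `filament_intensity`,
#'   `spot_intensity`, `error`.
#' @param metadata Tibble with `cell_id`, `strain`, `batch`, one row per
#'   result.
#' @return A `cell_records` tibble. Cells whose processing errored keep
#'   `NA` category (excluded from statistics downstream); the attrition
#'   count is attached as attribute `n_failed`.
#' @export
build_cell_records <- function(results, metadata) {
  if (is.null(names(results)) || !all(nzchar(names(results))))
    names(results) <- metadata$cell_id[seq_along(results)]
  missing_cells <- setdiff(metadata$cell_id, names(results))
  if (length(missing_cells) || length(results) != nrow(metadata))
    abort(paste("metadata/result mismatch; missing cells:",
                paste(missing_cells, collapse = ", ")))
  results <- results[metadata$cell_id]
  grab <- function(r, f) {
    v <- r[[f]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  x <- tibble(
    cell_id = metadata$cell_id,
    strain = metadata$strain,
    batch = metadata$batch,
    category = map_chr(results, function(r)
      if (!is.null(r$error)) NA_character_ else r$category),
    has_filament = NA_integer_,
    filament_length_px = unname(map_dbl(results, grab, "filament_length_px")),
    filament_intensity = unname(map_dbl(results, grab, "filament_intensity")),
    spot_intensity = unname(map_dbl(results, grab, "spot_intensity")))
  x <- enforce_record_invariants(x)
  n_failed <- sum(is.na(x$category))
  if (n_failed > 0)
    inform(sprintf("%d cell(s) failed processing and carry NA category",
                   n_failed))
  out <- new_cell_records(x)
  attr(out, "n_failed") <- n_failed
  out
}

#' Normalize intensities to the wild-type reference
#'
#' Divides `filament_intensity` and `spot_intensity` by a wild-type mean:
#' either the mean filament intensity of WT Simple cells (the box-plot
#' convention) or the mean brightest-focus intensity of WT Foci cells.
#' Normalisation is scale-invariant: rescaling every raw intensity by a
#' common factor leaves the normalized values unchanged.
#'
#' @param records A `cell_records` tibble.
#' @param wt_strain Label of the reference strain.
#' @param reference `"filament"` (default; WT Simple-cell filament mean) or
#'   `"foci"` (WT Foci-cell brightest-focus mean).
#' @return Records with both intensity columns divided by the reference
#'   mean; the divisor is attached as attribute `wt_reference`.
#' @export
normalize_to_wt <- function(records, wt_strain,
                            reference = c("filament", "foci")) {
  reference <- match.arg(reference)
  wt <- records[records$strain == wt_strain & !is.na(records$category), ]
  ref_vals <- if (reference == "filament") {
    wt$filament_intensity[wt$category == "Simple"]
  } else {
    wt$spot_intensity[wt$category == "Foci"]
  }
  ref_vals <- ref_vals[!is.na(ref_vals)]
  if (!length(ref_vals))
    abort(paste0("no ", wt_strain, " cells available for the '", reference,
                 "' normalisation reference"))
  ref <- mean(ref_vals)
  out <- mutate(records,
                filament_intensity = .data$filament_intensity / ref,
                spot_intensity = .data$spot_intensity / ref)
  attr(out, "wt_reference") <- c(setNames(ref, reference))
  out
}

#' Brightness thresholds for foci classes
#'
#' @param bright_cut Fraction of the WT reference above which a strain's
#'   mean focus intensity counts as bright (default 0.80).
#' @param dim_cut Fraction below which it counts as dim (default 0.20).
#' @param reference Which WT statistic normalisation used, `"foci"` or
#'   `"filament"` (recorded, see [normalize_to_wt()]).
#' @return Object of class `brightness_thresholds`.
#' @export
brightness_thresholds <- function(bright_cut = 0.80, dim_cut = 0.20,
                                  reference = "foci") {
  if (!(0 < dim_cut && dim_cut < bright_cut))
    abort("need 0 < dim_cut < bright_cut")
  structure(list(bright_cut = bright_cut, dim_cut = dim_cut,
                 reference = reference),
            class = "brightness_thresholds")
}

#' Assign bright / intermediate / dim focus classes
#'
#' Bright: mean normalized focus intensity above `bright_cut` (80% of WT);
#' dim: below `dim_cut` (20% of WT); intermediate otherwise. Values exactly
#' on a boundary are intermediate.
#'
#' @param mean_norm_intensity Numeric vector of strain-level mean
#'   normalized focus intensities (>= 0).
#' @param thr A [brightness_thresholds()].
#' @return Character vector over `"bright"`, `"intermediate"`, `"dim"`.
#' @examples
#' brightness_category(c(0.85, 0.5, 0.1))
#' @export
brightness_category <- function(mean_norm_intensity,
                                thr = brightness_thresholds()) {
  stopifnot(all(mean_norm_intensity >= 0, na.rm = TRUE))
  dplyr::case_when(
    mean_norm_intensity > thr$bright_cut ~ "bright",
    mean_norm_intensity < thr$dim_cut ~ "dim",
    TRUE ~ "intermediate")
}
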