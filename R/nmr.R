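#' Random-coil Calpha chemical-shift model
#'
#' Per-residue-type baseline Calpha shifts with a nearest-neighbour
#' correction for residues preceding a proline. The shipped table carries
#' the Wishart et al. (1995) random-coil Calpha values (ppm, DSS-referenced)
#' and the standard -2.0 ppm correction applied to the residue i when
#' residue i+1 is proline; any table with the same two columns can be
#' supplied instead.
#'
#' @param path CSV with columns `aa` (one-letter) and `ca_shift` (ppm);
#'   default = the shipped table.
#' @param pre_proline_correction Correction (ppm) added to the baseline of a
#'   residue that precedes a proline.
#' @return Object of class `random_coil_model`: list with `baseline` (named
#'   numeric), `pre_proline_correction` and a `provenance` string.
#' @examples
#' rc <- random_coil_model()
#' rc$baseline[["G"]]
#' @export
random_coil_model <- function(path = NULL, pre_proline_correction = -2.0) {
  if (is.null(path))
    path <- system.file("extdata", "random_coil_ca.csv", package = "filamentr")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("aa", "ca_shift") %in% names(tab)))
    abort("random-coil table needs columns aa, ca_shift")
  baseline <- setNames(tab$ca_shift, tab$aa)
  need <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(need %in% names(baseline)))
    abort("random-coil table must cover all 20 standard amino acids")
  structure(list(baseline = baseline,
                 pre_proline_correction = pre_proline_correction,
                 provenance = paste("Wishart et al. (1995) random-coil",
                                    "Calpha shifts, DSS-referenced,",
                                    "with -2.0 ppm pre-proline correction")),
            class = "random_coil_model")
}

#' Predict sequence-corrected random-coil Calpha shifts
#'
#' @param sequence One-letter protein sequence.
#' @param rc A [random_coil_model()].
#' @param offset Residue number of the first sequence character.
#' @return Tibble `residue`, `aa`, `ca_shift` (ppm), one row per position
#'   (prolines included; they carry a Calpha even without an amide proton).
#' @export
predict_random_coil <- function(sequence, rc = random_coil_model(),
                                offset = 1L) {
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(aa), names(rc$baseline))
  if (length(bad)) abort(paste("unknown residue type(s):",
                               paste(bad, collapse = ", ")))
  shift <- unname(rc$baseline[aa])
  pre_pro <- c(aa[-1] == "P", FALSE)
  shift[pre_pro] <- shift[pre_pro] + rc$pre_proline_correction
  tibble(residue = seq_along(aa) + as.integer(offset) - 1L,
         aa = aa, ca_shift = shift)
}

new_peak_table <- function(x) {
  x <- as_tibble(x)
  need <- c("residue", "aa", "intensity")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste("peak table missing column(s):",
                                paste(miss, collapse = ", ")))
  if (is.unsorted(x$residue, strictly = TRUE))
    abort("residue numbers must be strictly increasing")
  if (any(x$aa == "P")) abort("peak tables must not contain proline rows")
  if (any(x$intensity < 0)) abort("intensities must be >= 0")
  class(x) <- c("peak_table", class(x))
  x
}

#' Read / write an NMR peak table
#'
#' Tab-separated with columns `residue`, `aa`, `intensity` and optionally
#' `ca_shift`. Residue numbers are 1-based, counted from the first start
#' codon of the coding sequence.
#'
#' @param path TSV file path.
#' @return A validated `peak_table` tibble.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) abort(paste("no such peak table:", path))
  x <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE),
    error = function(e) abort(paste0("malformed TSV '", path, "': ",
                                     conditionMessage(e))))
  new_peak_table(x)
}

#' @rdname read_peak_table
#' @param x Peak table.
#' @export
write_peak_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-residue intensity ratio I/I0
#'
#' Ratio of the amide peak intensity with the binding partner added (I) to
#' the free-state intensity (I0). Attenuated ratios (< 1) mark residues in
#' the binding region. Residues present in only one table yield `NA`.
#'
#' @param bound Peak table with partner added.
#' @param free Free-state peak table.
#' @return Tibble `residue`, `aa`, `intensity_bound`, `intensity_free`,
#'   `ratio`.
#' @examples
#' seq <- simulate_protein_sequence(60, seed = 1)
#' tt <- simulate_nmr_titration(seq, c(20, 40), 0.2, noise_cv = 0, seed = 1)
#' head(intensity_ratio(tt$bound, tt$free))
#' @export
intensity_ratio <- function(bound, free) {
  shared <- intersect(bound$residue, free$residue)
  f0 <- free$intensity[match(shared, free$residue)]
  if (any(f0 <= 0)) {
    bad <- shared[f0 <= 0]
    abort(paste("free intensity must be > 0; offending residue(s):",
                paste(bad, collapse = ", ")))
  }
  out <- full_join(
    tibble(residue = bound$residue, aa = bound$aa,
           intensity_bound = bound$intensity),
    tibble(residue = free$residue, aa_free = free$aa,
           intensity_free = free$intensity),
    by = "residue")
  out <- arrange(out, .data$residue)
  out$aa <- dplyr::coalesce(out$aa, out$aa_free)
  out$aa_free <- NULL
  mutate(out, ratio = .data$intensity_bound / .data$intensity_free)
}

#' Calpha secondary chemical shift (chemical-shift index)
#'
#' Observed Calpha shift minus the sequence-corrected random-coil
#' prediction. Values near zero across a region indicate disorder.
#'
#' @param observed Peak table with a `ca_shift` column.
#' @param sequence One-letter sequence covering the table's numbering.
#' @param rc A [random_coil_model()].
#' @param offset Residue number of the first sequence character.
#' @return Tibble `residue`, `aa`, `delta_ca` (ppm).
#' @export
secondary_shift <- function(observed, sequence, rc = random_coil_model(),
                            offset = 1L) {
  if (!"ca_shift" %in% names(observed))
    abort("observed table has no ca_shift column")
  pred <- predict_random_coil(sequence, rc = rc, offset = offset)
  idx <- match(observed$residue, pred$residue)
  if (anyNA(idx))
    abort("observed residues fall outside the sequence numbering")
  mism <- observed$aa != pred$aa[idx]
  if (any(mism))
    abort(paste("residue type mismatch between table and sequence at:",
                paste(observed$residue[mism], collapse = ", ")))
  tibble(residue = observed$residue, aa = observed$aa,
         delta_ca = observed$ca_shift - pred$ca_shift[idx])
}

#' Flag disordered residues from a secondary-shift profile
#'
#' A residue is flagged disordered when |delta Calpha| falls below the
#' cutoff; the conventional coil-vs-structure scale puts the boundary at
#' 0.5 ppm.
#'
#' @param delta Tibble with columns `residue`, `delta_ca` (from
#'   [secondary_shift()]).
#' @param cutoff ppm threshold.
#' @return List with `profile` (input plus logical `disordered`) and
#'   `fraction` (share of residues flagged).
#' @export
disorder_flag <- function(delta, cutoff = 0.5) {
  if (NROW(delta) == 0) abort("empty secondary-shift profile")
  prof <- mutate(delta, disordered = abs(.data$delta_ca) < cutoff |
                   (cutoff == 0 & .data$delta_ca == 0))
  list(profile = prof, fraction = mean(prof$disordered))
}

#' Call contiguous interaction regions from an intensity-ratio profile
#'
#' Finds maximal runs of residues whose ratio falls below `threshold`,
#' bridging interruptions of at most `max_gap` residues that are missing
#' (e.g. prolines, unassigned) or above threshold, and keeps runs with at
#' least `min_run` observed sub-threshold residues. Reported boundaries are
#' the first and last sub-threshold residues of each run.
#'
#' @param ratio Tibble with `residue` and `ratio` (from
#'   [intensity_ratio()]); `NA` ratios count as missing.
#' @param threshold Attenuation threshold in (0, 1).
#' @param min_run Minimum number of observed sub-threshold residues.
#' @param max_gap Maximum bridged interruption, residues.
#' @return Tibble `start`, `end`, `n_obs`, `mean_ratio`, sorted by `start`;
#'   zero rows when nothing is called.
#' @examples
#' seq <- simulate_protein_sequence(471, seed = 4, no_pro_at = c(310, 395))
#' tt <- simulate_nmr_titration(seq, c(310, 395), 0.2, noise_cv = 0, seed = 1)
#' call_interaction_region(intensity_ratio(tt$bound, tt$free))
#' @export
call_interaction_region <- function(ratio, threshold = 0.5, min_run = 5,
                                    max_gap = 3) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  if (min_run < 1) abort("min_run must be >= 1")
  obs <- ratio[!is.na(ratio$ratio), , drop = FALSE]
  hits <- obs$residue[obs$ratio < threshold]
  if (!length(hits))
    return(tibble(start = integer(0), end = integer(0),
                  n_obs = integer(0), mean_ratio = numeric(0)))
  # group consecutive hits whose interruption is <= max_gap residues
  brk <- c(0, cumsum(diff(hits) > max_gap + 1))
  calls <- map(split(hits, brk), function(h) {
    inside <- obs$residue >= min(h) & obs$residue <= max(h)
    tibble(start = as.integer(min(h)), end = as.integer(max(h)),
           n_obs = length(h),
           mean_ratio = mean(obs$ratio[inside]))
  })
  out <- bind_rows(calls)
  out <- out[out$n_obs >= min_run, , drop = FALSE]
  arrange(out, .data$start)
}
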