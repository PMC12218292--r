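#' Simulate a random protein sequence
#'
#' Uniform draw over the 20 standard amino acids, with optional positions
#' forced to be non-proline (prolines have no backbone amide and therefore
#' drop out of ^1H-^15N peak tables; keeping planted-region boundaries
#' observable requires non-proline residues there).
#'
#' @param n Sequence length.
#' @param seed Integer seed.
#' @param no_pro_at Integer vector of 1-based positions (in sequence
#'   coordinates, i.e. before any numbering offset) that must not be proline.
#' @return One-letter string.
#' @export
simulate_protein_sequence <- function(n, seed = 1L, no_pro_at = integer(0)) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  s <- sample(aa, n, replace = TRUE)
  for (i in no_pro_at) if (s[i] == "P") s[i] <- sample(setdiff(aa, "P"), 1)
  paste(s, collapse = "")
}

#' Simulate an NMR titration peak-table pair
#'
#' Builds per-residue amide peak tables for a free protein and the same
#' protein with a binding partner added. Inside the planted interacting
#' region the bound-state intensity is the free intensity times
#' `attenuation`; outside it is unchanged; multiplicative log-normal noise
#' with coefficient of variation `noise_cv` is then applied to the bound
#' intensities. Prolines are absent from both tables (no backbone amide).
#' Optionally plants Calpha secondary-shift deviations on top of the
#' sequence-corrected random-coil prediction, so that [secondary_shift()]
#' is the exact inverse of the planting at zero noise.
#'
#' @param sequence One-letter protein sequence.
#' @param region Length-2 integer vector, inclusive residue interval of the
#'   attenuated (interacting) segment, in the numbering implied by `offset`.
#' @param attenuation Intensity ratio planted inside the region, in `[0, 1]`.
#' @param noise_cv Coefficient of variation of the multiplicative intensity
#'   noise on the bound table (0 = noise-free).
#' @param seed Integer seed.
#' @param offset Residue number of the first sequence character (numbering
#'   from the first start codon; e.g. 206 for a C-terminal construct).
#' @param free_intensity Mean free-state peak intensity (arbitrary units).
#' @param free_cv Coefficient of variation of per-residue free intensities.
#' @param ca_deviation Optional named plant of Calpha deviations: a numeric
#'   vector of ppm values indexed like the profile, or `NULL` to plant none
#'   (tables then carry pure random-coil shifts).
#' @param rc Random-coil model used to generate Calpha shifts, see
#'   [random_coil_model()].
#' @return List with tibbles `free` and `bound` (columns `residue`, `aa`,
#'   `intensity`, `ca_shift`), `sequence` and `offset`.
#' @examples
#' seq <- simulate_protein_sequence(471, seed = 4, no_pro_at = c(310, 395))
#' tt <- simulate_nmr_titration(seq, region = c(310, 395), attenuation = 0.2,
#'                              noise_cv = 0, seed = 1)
#' head(tt$free)
#' @export
simulate_nmr_titration <- function(sequence, region = c(310, 395),
                                   attenuation = 0.2, noise_cv = 0.1,
                                   seed = 1L, offset = 1L,
                                   free_intensity = 1000, free_cv = 0.15,
                                   ca_deviation = NULL,
                                   rc = random_coil_model()) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    abort("sequence must be a non-empty one-letter string")
  if (attenuation < 0 || attenuation > 1)
    abort("attenuation must lie in [0, 1]")
  n <- nchar(sequence)
  res_num <- seq_len(n) + as.integer(offset) - 1L
  if (region[1] < res_num[1] || region[2] > res_num[n] || region[1] > region[2])
    abort("region must be an interval within the sequence numbering")
  set.seed(as.integer(seed))
  aa <- strsplit(sequence, "")[[1]]
  keep <- aa != "P"

  # log-normal with the requested CV
  rlnorm_cv <- function(k, mean, cv) {
    if (cv <= 0) return(rep(mean, k))
    sdlog <- sqrt(log(1 + cv^2))
    mean * exp(rnorm(k, -sdlog^2 / 2, sdlog))
  }
  free_int <- rlnorm_cv(n, free_intensity, free_cv)
  in_region <- res_num >= region[1] & res_num <= region[2]
  bound_int <- free_int * ifelse(in_region, attenuation, 1)
  bound_int <- bound_int * rlnorm_cv(n, 1, noise_cv)

  ca_rc <- predict_random_coil(sequence, rc = rc, offset = offset)$ca_shift
  dev <- rep(0, n)
  if (!is.null(ca_deviation)) {
    if (length(ca_deviation) != n)
      abort("ca_deviation must have one value per sequence position")
    dev <- ca_deviation
  }
  ca <- ca_rc + dev

  mk <- function(int) tibble(residue = res_num[keep], aa = aa[keep],
                             intensity = int[keep], ca_shift = ca[keep])
  list(free = new_peak_table(mk(free_int)),
       bound = new_peak_table(mk(bound_int)),
       sequence = sequence, offset = as.integer(offset),
       region = as.integer(region), attenuation = attenuation)
}
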