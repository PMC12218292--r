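# bilinear sample of a matrix at fractional (row, col)
bilinear_at <- function(img, r, c) {
  ny <- nrow(img); nx <- ncol(img)
  r <- min(max(r, 1), ny); c <- min(max(c, 1), nx)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- min(r0 + 1, ny); c1 <- min(c0 + 1, nx)
  fr <- r - r0; fc <- c - c0
  img[r0, c0] * (1 - fr) * (1 - fc) + img[r1, c0] * fr * (1 - fc) +
    img[r0, c1] * (1 - fr) * fc + img[r1, c1] * fr * fc
}

# Sub-pixel length of the terminal half-steps: the integer skeleton chain
# ends at the last pixel centre above the half-maximum level, while the
# structure's true end lies up to a pixel further out. Walk along each
# endpoint tangent in quarter-pixel steps until the image drops below the
# half-max level and return the total extra length.
subpixel_end_extension <- function(g, smooth, bg, window = 5, max_px = 2) {
  if (!length(g$pixels)) return(0)
  ny <- g$dim[1]; nx <- g$dim[2]
  to_rc <- function(px) c((px - 1L) %% ny + 1L, (px - 1L) %/% ny + 1L)
  level <- bg + 0.5 * (max(smooth[g$pixels]) - bg)
  extra <- 0
  for (nd in g$nodes$node[g$nodes$type == "endpoint"]) {
    px <- g$nodes$pixels[[match(nd, g$nodes$node)]][1]
    ei <- which(g$edges$from == nd | g$edges$to == nd)[1]
    if (is.na(ei)) next
    path <- g$edges$path[[ei]]
    if (path[1] == px) path <- rev(path)
    k <- min(window, length(path) - 1)
    if (k < 1) next
    endc <- to_rc(px)
    d <- endc - to_rc(path[length(path) - k])
    nrm <- sqrt(sum(d^2))
    if (nrm == 0) next
    d <- d / nrm
    t_out <- 0
    for (t in seq(0.25, max_px, by = 0.25)) {
      pos <- endc + d * t
      if (pos[1] < 1 || pos[1] > ny || pos[2] < 1 || pos[2] > nx) break
      if (bilinear_at(smooth, pos[1], pos[2]) < level) break
      t_out <- t
    }
    extra <- extra + t_out
  }
  extra
}

#' Quantify one nucleus crop
#'
#' The full per-cell chain: maximum z-projection of the segmentation
#' channel, GLoG segmentation, skeletonization with pruning (spur threshold
#' `2 * width_px`) and endpoint elongation, Analyze-Skeleton-style
#' features, four-way classification, and background-subtracted intensity
#' quantification on the photon-conserving sum projection of the raw
#' channel.
#'
#' @param stack An `image_stack`.
#' @param seg_params A [segmentation_params()].
#' @param min_branch_px Pruning threshold; default `2 * width_px`.
#' @param channel Channel segmentation runs on (`"deconv"` unless absent).
#' @param measure_dilate_px Photometry aperture: the detection masks trace
#'   the half-maximum footprint, so for intensity measurement they are
#'   dilated by this radius (px) to capture the Gaussian tails; pixels in
#'   another structure's core mask are not double-counted.
#' @param background_exclude_px Structure masks are dilated by this radius
#'   before taking the nuclear median, so faint structure tails do not
#'   pull the background estimate up.
#' @param mode `"projection"` (default) segments the maximum z-projection;
#'   `"slicewise"` segments every z-slice and unions the filament masks —
#'   an exploratory 3D-aware mode (foci still come from the projection).
#' @return List: `category`, `features`, `masks`, `background`,
#'   `filament_length_px`, `filament_intensity`, `spot_intensity`,
#'   `foci_intensities`.
#' @export
process_cell <- function(stack, seg_params = segmentation_params(),
                         min_branch_px = 2 * seg_params$width_px,
                         channel = "deconv", measure_dilate_px = 4,
                         background_exclude_px = 6,
                         mode = c("projection", "slicewise")) {
  mode <- match.arg(mode)
  working <- max_z_projection(stack, channel)
  masks <- segment_structures(working, seg_params)
  if (mode == "slicewise") {
    arr <- stack_array(stack, channel)
    fm <- masks$filament_mask
    for (k in seq_len(dim(arr)[3]))
      fm <- fm | segment_structures(arr[, , k], seg_params)$filament_mask
    masks$filament_mask <- fm
  }
  if (any(masks$filament_mask)) {
    g <- skeleton_graph(skeletonize_mask(masks$filament_mask))
    g <- prune_skeleton(g, min_branch_px)
    g <- elongate_skeleton(g, masks$filament_mask)
    g <- complete_skeleton(g, masks$filament_mask,
                           max_dist = 1.1 * seg_params$width_px)
    feats <- skeleton_features(g)
  } else {
    feats <- skeleton_features(skeleton_graph(matrix(FALSE, nrow(working),
                                                     ncol(working))))
  }
  category <- classify_cell(feats, masks$foci)

  quant <- sum_z_projection(stack, "raw")
  struct_all <- Reduce(`|`, map(masks$foci, "mask"), masks$filament_mask)
  bg <- nuclear_background(quant,
                           dilate_mask(struct_all, background_exclude_px))
  core_foci <- map(masks$foci, "mask")
  core_union <- Reduce(`|`, core_foci, masks$filament_mask)
  aperture <- function(core, others) {
    ap <- dilate_mask(core, measure_dilate_px)
    ap & !(others & !core)
  }
  fil_int <- spot_int <- len <- NA_real_
  foci_int <- numeric(0)
  if (length(masks$foci)) {
    foci_int <- map_dbl(seq_along(masks$foci), function(i)
      measure_intensity(quant, aperture(core_foci[[i]], core_union), bg))
  }
  if (category == "Simple") {
    len <- feats$total_length_px +
      subpixel_end_extension(
        g, gaussian_smooth(working, seg_params$refine_sigma_px),
        masks$background_estimate)
    fil_int <- measure_intensity(
      quant, aperture(masks$filament_mask, core_union), bg)
  }
  if (category == "Foci") {
    foci <- map2(masks$foci, foci_int, function(f, i)
      list(center = f$center, intensity = i))
    spot_int <- select_brightest_focus(foci)$intensity
  }
  list(category = category, features = feats, masks = masks,
       background = bg, filament_length_px = len,
       filament_intensity = fil_int, spot_intensity = spot_int,
       foci_intensities = foci_int)
}

default_imaging_config <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    simulate = list(n_cells = 50L, n_batches = 3L),
    acquisition = list(),
    segmentation = list(),
    skeleton = list(),
    classification = list(wt_strain = "WT", reference = "filament",
                          bright_cut = 0.80, dim_cut = 0.20),
    statistics = list(pairs = NULL, models = c("M1", "M2", "M3"))
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(user[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the imaging pipeline end to end
#'
#' Either simulates a dataset (config block `simulate`) or reads one
#' (config block `input` with `metadata_csv`/`image_dir`), quantifies every
#' cell fail-soft (a cell-level error is logged with its id and the run
#' continues), assembles the cell-record table, per-strain category
#' proportions and brightness classes, and — when strain pairs are
#' configured — the logistic-regression comparison table with joint FDR
#' adjustment. Deterministic given (inputs, seed).
#'
#' @param config Nested configuration list (or a YAML path readable by
#'   [read_pipeline_config()]); unspecified entries take defaults.
#' @return List: `records`, `proportions`, `brightness`, `tests` (or
#'   `NULL`), `truth` (simulated runs), `log` (character vector),
#'   `n_failed`. When `output_dir` is set, CSVs and `run_log.txt` are also
#'   written there.
#' @export
run_imaging_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- merge_config(default_imaging_config(), config)
  log <- c(sprintf("filamentr %s imaging run, seed %d",
                   as.character(utils::packageVersion("filamentr")),
                   cfg$seed),
           sprintf("config hash %s",
                   rlang::hash(cfg[setdiff(names(cfg), "output_dir")])))
  acq <- do.call(acquisition_params, cfg$acquisition)
  sp <- do.call(segmentation_params, cfg$segmentation)
  min_branch <- cfg$skeleton$min_branch_px %||% (2 * sp$width_px)

  truth <- NULL
  if (!is.null(cfg$input)) {
    ds <- read_image_dataset(cfg$input$metadata_csv,
                             cfg$input$image_dir %||%
                               dirname(cfg$input$metadata_csv), acq)
    cells <- ds$cells; meta <- ds$metadata
    log <- c(log, sprintf("read %d cells from %s", length(cells),
                          cfg$input$metadata_csv))
  } else {
    designs <- cfg$simulate$designs %||%
      default_strain_designs(cfg$simulate$n_batches)
    sim <- simulate_experiment(designs, cfg$simulate$n_cells,
                               cfg$simulate$n_batches, acq,
                               seed = cfg$seed)
    cells <- sim$cells; meta <- sim$metadata; truth <- sim$truth
    log <- c(log, sprintf("simulated %d cells (%d strains x %d)",
                          length(cells), length(designs),
                          cfg$simulate$n_cells))
  }
  # validate statistics block before any heavy computation
  strains <- unique(meta$strain)
  pairs <- cfg$statistics$pairs
  if (!is.null(pairs)) {
    for (pr in pairs) if (!all(unlist(pr) %in% strains))
      abort(paste("statistics pair references unknown strain:",
                  paste(unlist(pr), collapse = " vs ")))
  }
  wt <- cfg$classification$wt_strain
  if (!wt %in% strains)
    abort(paste("classification wt_strain not in dataset:", wt))

  results <- map(seq_along(cells), function(i) {
    tryCatch(process_cell(cells[[i]], sp, min_branch),
             error = function(e) list(error = conditionMessage(e)))
  })
  names(results) <- meta$cell_id
  failed <- keep(results, ~ !is.null(.x$error))
  for (nm in names(failed))
    log <- c(log, sprintf("cell %s failed: %s", nm, failed[[nm]]$error))

  records <- suppressMessages(build_cell_records(results, meta))
  n_failed <- attr(records, "n_failed")
  log <- c(log, sprintf("attrition: %d of %d cells failed", n_failed,
                        nrow(meta)))
  props <- category_proportions(records)

  thr <- brightness_thresholds(cfg$classification$bright_cut,
                               cfg$classification$dim_cut,
                               reference = "foci")
  norm_foci <- tryCatch(normalize_to_wt(records, wt, reference = "foci"),
                        error = function(e) NULL)
  if (is.null(norm_foci)) {
    log <- c(log, paste("no", wt, "foci: brightness classes skipped"))
    bright <- tibble(strain = strains,
                     mean_focus_intensity = NA_real_,
                     class = NA_character_)
  } else {
    bright <- summarise(group_by(norm_foci, .data$strain),
                        mean_focus_intensity = mean(.data$spot_intensity,
                                                    na.rm = TRUE),
                        .groups = "drop")
    bright$class <- brightness_category(
      replace(bright$mean_focus_intensity,
              is.na(bright$mean_focus_intensity), 0), thr)
  }

  norm_records <- normalize_to_wt(records, wt,
                                  reference = cfg$classification$reference)
  tests <- NULL
  if (!is.null(pairs)) {
    tests <- suppressMessages(
      compare_all(norm_records, map(pairs, unlist),
                  models = cfg$statistics$models))
    log <- c(log, sprintf("%d hypotheses tested, %d flagged",
                          sum(!is.na(tests$p)) + attr(tests, "n_flagged"),
                          attr(tests, "n_flagged")))
  }
  if (!is.null(truth)) {
    acc <- mean(category_matches_archetype(records$category,
                                           truth$archetype), na.rm = TRUE)
    log <- c(log, sprintf("category accuracy vs ground truth: %.3f", acc))
  }

  out <- list(records = records, proportions = props, brightness = bright,
              tests = tests, truth = truth, log = log, n_failed = n_failed)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(records, file.path(cfg$output_dir, "cell_records.csv"),
              row.names = FALSE)
    write.csv(props, file.path(cfg$output_dir, "category_proportions.csv"),
              row.names = FALSE)
    write.csv(bright, file.path(cfg$output_dir, "brightness.csv"),
              row.names = FALSE)
    if (!is.null(tests))
      write.csv(tests, file.path(cfg$output_dir, "test_results.csv"),
                row.names = FALSE)
    writeLines(log, file.path(cfg$output_dir, "run_log.txt"))
  }
  out
}

#' Does a called category match a ground-truth archetype?
#'
#' @param category Factor/character of pipeline categories.
#' @param archetype Character of generator archetypes.
#' @return Logical vector (`NA` where the category is missing).
#' @export
category_matches_archetype <- function(category, archetype) {
  map_arch <- c(simple = "Simple", complex = "Complex",
                foci_only = "Foci", nothing = "Nothing")
  as.character(category) == unname(map_arch[archetype])
}

#' Run the NMR mapping pipeline
#'
#' Computes the per-residue intensity-ratio profile (I with partner / I0
#' free), the Calpha secondary-shift profile and disorder fraction when
#' Calpha shifts are available, and contiguous interaction-region calls.
#' With only a free table, the ratio and region outputs are skipped with a
#' logged note.
#'
#' @param config List (or YAML path) with an `nmr` block: `free`, `bound`
#'   (TSV paths or peak tables), `sequence` (string) or `sequence_fasta`,
#'   `offset`, `threshold`, `min_run`, `max_gap`, `disorder_cutoff`,
#'   `rc_table` (optional CSV path), and optional top-level `output_dir`.
#' @return List: `ratio`, `regions`, `secondary_shift`, `disorder`,
#'   `log`.
#' @export
run_nmr_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  nm <- config$nmr %||% config
  get_tab <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) read_peak_table(x) else new_peak_table(x)
  }
  free <- get_tab(nm$free)
  bound <- get_tab(nm$bound)
  if (is.null(free)) abort("nmr config needs at least a free peak table")
  sequence <- nm$sequence %||%
    (if (!is.null(nm$sequence_fasta)) read_fasta_sequence(nm$sequence_fasta)
     else abort("nmr config needs sequence or sequence_fasta"))
  offset <- as.integer(nm$offset %||% 1L)
  if (free$residue[1] < offset ||
      max(free$residue) > offset + nchar(sequence) - 1L)
    abort("peak-table numbering falls outside the sequence numbering")
  rc <- if (!is.null(nm$rc_table)) random_coil_model(nm$rc_table)
        else random_coil_model()
  log <- character(0)

  ratio <- regions <- NULL
  if (!is.null(bound)) {
    ratio <- intensity_ratio(bound, free)
    regions <- call_interaction_region(
      ratio, threshold = nm$threshold %||% 0.5,
      min_run = nm$min_run %||% 5, max_gap = nm$max_gap %||% 3)
    log <- c(log, sprintf("%d interaction region(s) called", nrow(regions)))
  } else {
    log <- c(log, "no bound table: ratio/region outputs skipped")
  }
  delta <- dis <- NULL
  if ("ca_shift" %in% names(free) && !all(is.na(free$ca_shift))) {
    delta <- secondary_shift(free, sequence, rc = rc, offset = offset)
    dis <- disorder_flag(delta, cutoff = nm$disorder_cutoff %||% 0.5)
    log <- c(log, sprintf("disordered fraction: %.3f", dis$fraction))
  }
  out <- list(ratio = ratio, regions = regions, secondary_shift = delta,
              disorder = dis, log = log)
  outdir <- config$output_dir
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(ratio))
      write.csv(ratio, file.path(outdir, "ratio_profile.csv"),
                row.names = FALSE)
    if (!is.null(regions))
      write.csv(regions, file.path(outdir, "interaction_regions.csv"),
                row.names = FALSE)
    if (!is.null(delta))
      write.csv(delta, file.path(outdir, "secondary_shift.csv"),
                row.names = FALSE)
    writeLines(log, file.path(outdir, "nmr_log.txt"))
  }
  out
}
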