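#' Write a simulated experiment to disk
#'
#' One multi-page TIFF per cell (one page per z-slice, 16-bit, photon
#' counts; negative read-noise excursions clip at 0 and counts clip at
#' 65535), a metadata CSV (`cell_id`, `strain`, `batch`, `file`,
#' `file_deconv`), and a ground-truth CSV.
#'
#' @param sim Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Path of the metadata CSV, invisibly.
#' @export
write_image_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack <- function(arr, path) {
    pages <- map(seq_len(dim(arr)[3]), function(k)
      pmin(pmax(round(arr[, , k]), 0), 65535) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
    basename(path)
  }
  files <- map_chr(seq_along(sim$cells), function(i) {
    write_stack(sim$cells[[i]]$raw,
                file.path(dir, paste0(sim$metadata$cell_id[i], ".tif")))
  })
  files_dec <- map_chr(seq_along(sim$cells), function(i) {
    write_stack(sim$cells[[i]]$deconv,
                file.path(dir, paste0(sim$metadata$cell_id[i],
                                      "_deconv.tif")))
  })
  meta <- mutate(sim$metadata, file = files, file_deconv = files_dec)
  meta_path <- file.path(dir, "metadata.csv")
  write.csv(meta, meta_path, row.names = FALSE)
  write.csv(sim$truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(meta_path)
}

#' Read an image dataset from a metadata CSV
#'
#' @param metadata_csv CSV with at least `cell_id`, `strain`, `batch`,
#'   `file` (and optionally `file_deconv`); file paths are relative to
#'   `image_dir`.
#' @param image_dir Directory containing the TIFFs.
#' @param acq An [acquisition_params()]; stacks must match its `crop_px`.
#' @return List with `cells` (list of `image_stack`) and `metadata`, row
#'   order preserved.
#' @export
read_image_dataset <- function(metadata_csv, image_dir = dirname(metadata_csv),
                               acq = acquisition_params()) {
  meta <- as_tibble(read.csv(metadata_csv, stringsAsFactors = FALSE))
  need <- c("cell_id", "strain", "batch", "file")
  miss <- setdiff(need, names(meta))
  if (length(miss)) abort(paste("metadata missing column(s):",
                                paste(miss, collapse = ", ")))
  paths <- file.path(image_dir, meta$file)
  absent <- meta$file[!file.exists(paths)]
  if (length(absent))
    abort(paste("missing image file(s):", paste(absent, collapse = ", ")))
  read_stack <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * 65535
    arr
  }
  bad <- character(0)
  cells <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    raw <- read_stack(paths[i])
    if (any(dim(raw)[1:2] != acq$crop_px)) {
      bad <- c(bad, meta$file[i])
      next
    }
    dec <- raw
    if ("file_deconv" %in% names(meta) && !is.na(meta$file_deconv[i])) {
      dp <- file.path(image_dir, meta$file_deconv[i])
      if (!file.exists(dp)) abort(paste("missing image file(s):",
                                        meta$file_deconv[i]))
      dec <- read_stack(dp)
    }
    cells[[i]] <- new_image_stack(raw, dec, acq)
  }
  if (length(bad))
    abort(paste0("crop size mismatch (expected ", acq$crop_px, " px): ",
                 paste(bad, collapse = ", ")))
  list(cells = cells, metadata = meta[, intersect(
    c("cell_id", "strain", "batch"), names(meta))])
}

#' Read / write a pipeline configuration
#'
#' YAML with blocks `acquisition`, `segmentation`, `skeleton`,
#' `classification`, `statistics`, `nmr`, plus top-level `seed` and
#' `output_dir`. Writing then reading returns an identical configuration
#' object.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste("no such config:", path))
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  for (f in c(cfg$nmr$free, cfg$nmr$bound, cfg$nmr$sequence_fasta,
              cfg$nmr$rc_table, cfg$input$metadata_csv)) {
    if (!is.null(f) && !file.exists(f))
      abort(paste("config references missing file:", f))
  }
  cfg
}

#' @rdname read_pipeline_config
#' @param cfg Configuration list.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a single sequence from a FASTA file
#'
#' @param path FASTA file.
#' @return Upper-case one-letter string (first record).
#' @export
read_fasta_sequence <- function(path) {
  if (!file.exists(path)) abort(paste("no such FASTA:", path))
  s <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  if (!length(s)) abort("FASTA contains no sequences")
  toupper(as.character(s[[1]]))
}
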