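#' Round half away from zero
#'
#' Base `round()` rounds half to even; peak m/z values are conventionally
#' rounded half up, so 3005.45 -> 3005.5 at one decimal.
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded vector
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Construct a raw peak-list spectrum
#'
#' A raw spectrum is the centroided peak list exported from the instrument
#' software: (m/z, intensity) pairs with m/z in Da to one decimal place and
#' nonnegative intensities in arbitrary units, restricted to the 2-20 kDa
#' detection window.
#'
#' @param mz numeric vector of m/z values (Da), strictly increasing after
#'   normalisation
#' @param intensity numeric vector of nonnegative intensities
#' @param strain_id character scalar identifying the isolate
#' @param replicate_id character scalar identifying the replicate
#' @param mz_min,mz_max detection window bounds in Da; peaks outside are
#'   dropped with a message
#' @return an object of class `raw_spectrum` with elements `mz`,
#'   `intensity`, `strain_id`, `replicate_id`
#' @export
raw_spectrum <- function(mz, intensity, strain_id = "unknown",
                         replicate_id = "r1",
                         mz_min = 2000, mz_max = 20000) {
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have equal length")
  }
  if (any(!is.finite(mz)) || any(!is.finite(intensity))) {
    stop("non-finite m/z or intensity value")
  }
  if (any(intensity < 0)) stop("negative intensity")
  mz <- round_half_up(mz, 1)
  keep <- mz >= mz_min & mz <= mz_max
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("dropped %d peak(s) outside [%g, %g] Da",
                    n_dropped, mz_min, mz_max))
  }
  mz <- mz[keep]
  intensity <- intensity[keep]
  o <- order(mz)
  mz <- mz[o]
  intensity <- intensity[o]
  # collisions after rounding: sum intensities (conserves total ion signal)
  if (anyDuplicated(mz)) {
    warning("duplicate m/z after rounding; intensities summed")
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)),
                                   sum))
    mz <- unique(mz)
  }
  structure(
    list(mz = mz, intensity = intensity,
         strain_id = as.character(strain_id),
         replicate_id = as.character(replicate_id),
         n_dropped = n_dropped),
    class = "raw_spectrum"
  )
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("raw_spectrum: %s/%s, %d peaks in [%s, %s] Da\n",
              x$strain_id, x$replicate_id, length(x$mz),
              if (length(x$mz)) format(min(x$mz)) else "-",
              if (length(x$mz)) format(max(x$mz)) else "-"))
  invisible(x)
}

#' Read a two-column peak table
#'
#' Reads an exported peak list (columns `mz`, `intensity`; header optional)
#' and normalises it: m/z rounded to one decimal place, rows outside the
#' 2-20 kDa window dropped with a logged count, intensities at colliding
#' m/z summed.
#'
#' @param path path to a TSV or CSV file
#' @param dialect `"tsv"` or `"csv"`; default guessed from the extension
#' @param strain_id,replicate_id labels attached to the spectrum; default
#'   derived from the file name
#' @inheritParams raw_spectrum
#' @return a [raw_spectrum()]
#' @export
read_peak_table <- function(path, dialect = NULL, strain_id = NULL,
                            replicate_id = "r1",
                            mz_min = 2000, mz_max = 20000) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  dialect <- match.arg(dialect, c("tsv", "csv"))
  sep <- if (dialect == "csv") "," else "\t"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty peak table: ", path)
  # optional header: first line with a non-numeric first field
  first <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[[1]])))
  data_lines <- if (has_header) lines[-1] else lines
  if (length(data_lines) == 0) stop("peak table has a header but no rows: ", path)
  fields <- strsplit(data_lines, sep, fixed = TRUE)
  bad_ncol <- which(vapply(fields, length, 0L) < 2)
  if (length(bad_ncol)) {
    stop(sprintf("line %d of %s: expected two columns",
                 bad_ncol[[1]] + has_header, path))
  }
  mz <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  bad <- which(is.na(mz) | is.na(it))
  if (length(bad)) {
    stop(sprintf("line %d of %s: non-numeric value", bad[[1]] + has_header,
                 path))
  }
  if (is.null(strain_id)) {
    strain_id <- sub("\\.(tsv|csv|txt)$", "", basename(path),
                     ignore.case = TRUE)
  }
  raw_spectrum(mz, it, strain_id = strain_id, replicate_id = replicate_id,
               mz_min = mz_min, mz_max = mz_max)
}

#' Write a peak table
#'
#' Writes a spectrum as a two-column table with m/z formatted to one
#' decimal place. For grid spectra, zero-intensity grid points are omitted
#' so the file is a sparse peak list.
#'
#' @param spectrum a [raw_spectrum()] or [grid_spectrum]
#' @param path output path
#' @param dialect `"tsv"` or `"csv"`
#' @return `path`, invisibly
#' @export
write_peak_table <- function(spectrum, path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  dialect <- match.arg(dialect, c("tsv", "csv"))
  sep <- if (dialect == "csv") "," else "\t"
  if (inherits(spectrum, "grid_spectrum")) {
    mz <- grid_mz(spectrum$grid)
    keep <- spectrum$intensity != 0
    mz <- mz[keep]
    it <- spectrum$intensity[keep]
  } else if (inherits(spectrum, "raw_spectrum")) {
    mz <- spectrum$mz
    it <- spectrum$intensity
  } else {
    stop("spectrum must be a raw_spectrum or grid_spectrum")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("mz", "intensity", sep = sep), con)
  if (length(mz)) {
    writeLines(paste(sprintf("%.1f", mz), format(it, digits = 15, trim = TRUE,
                                                 scientific = FALSE),
                     sep = sep), con)
  }
  invisible(path)
}

#' Read a strain manifest
#'
#' The manifest is a CSV with columns `strain_id,species,genus,file`, one
#' row per spectrum file. A strain may appear on several rows (replicates)
#' but must always carry the same species and genus.
#'
#' @param path manifest CSV path
#' @return data frame with columns `strain_id`, `species`, `genus`, `file`,
#'   `replicate_id`
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("strain_id", "species", "genus", "file")
  miss <- setdiff(req, names(m))
  if (length(miss)) stop("manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(m) == 0) stop("empty manifest: ", path)
  chk <- unique(m[, c("strain_id", "species", "genus")])
  dup <- chk$strain_id[duplicated(chk$strain_id)]
  if (length(dup)) {
    stop("strain(s) with conflicting species/genus labels: ",
         paste(unique(dup), collapse = ", "))
  }
  m$replicate_id <- stats::ave(seq_len(nrow(m)), m$strain_id,
                               FUN = seq_along)
  m$replicate_id <- paste0("r", m$replicate_id)
  m
}

#' Assemble a labeled, preprocessed spectrum set
#'
#' Reads every peak table referenced by the manifest, runs the
#' preprocessing pipeline on each, and returns the labeled set sharing one
#' grid. Missing files are all enumerated in a single error.
#'
#' @param manifest_path manifest CSV (`strain_id,species,genus,file`)
#' @param spectra_dir directory that the manifest's `file` column is
#'   relative to
#' @param grid a [grid_spec()]
#' @param denoise_params a [denoise_params()]
#' @param order preprocessing order, see [preprocess_pipeline()]
#' @return an object of class `spectrum_set`: list with `spectra` (list of
#'   grid spectra), `manifest` (data frame) and `grid`
#' @export
load_spectrum_set <- function(manifest_path, spectra_dir,
                              grid = grid_spec(),
                              denoise_params = msfinger::denoise_params(),
                              order = c("log_then_denoise",
                                        "denoise_then_log")) {
  order <- match.arg(order)
  manifest <- read_manifest(manifest_path)
  paths <- file.path(spectra_dir, manifest$file)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("no spectrum file for strain(s): ",
         paste(sprintf("%s (%s)", manifest$strain_id[missing],
                       manifest$file[missing]), collapse = ", "))
  }
  spectra <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    raw <- read_peak_table(paths[[i]], strain_id = manifest$strain_id[[i]],
                           replicate_id = manifest$replicate_id[[i]],
                           mz_min = grid$start, mz_max = grid$stop)
    spectra[[i]] <- preprocess_pipeline(raw, grid, denoise_params,
                                        order = order)
  }
  spectrum_set(spectra, manifest, grid)
}

#' Build a spectrum set from preprocessed spectra
#'
#' @param spectra list of [grid_spectrum] sharing one grid
#' @param manifest data frame with columns `strain_id`, `species`, `genus`
#'   (one row per spectrum, aligned with `spectra`)
#' @param grid the shared [grid_spec()]
#' @return object of class `spectrum_set`
#' @export
spectrum_set <- function(spectra, manifest, grid) {
  stopifnot(length(spectra) == nrow(manifest))
  for (s in spectra) {
    if (!inherits(s, "grid_spectrum")) stop("all spectra must be grid spectra")
    if (!identical(unclass(s$grid), unclass(grid))) {
      stop("spectrum ", s$strain_id, " is on a different grid")
    }
  }
  structure(list(spectra = spectra, manifest = manifest, grid = grid),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf(
    "spectrum_set: %d spectra, %d strains, %d species, %d genera; grid %g-%g Da step %g\n",
    length(x$spectra), length(unique(x$manifest$strain_id)),
    length(unique(x$manifest$species)), length(unique(x$manifest$genus)),
    x$grid$start, x$grid$stop, x$grid$step))
  invisible(x)
}

#' Intensity matrix of a spectrum set
#'
#' @param set a `spectrum_set`
#' @return numeric matrix, grid points x spectra; columns named
#'   `strain_id.replicate_id`
#' @export
intensity_matrix <- function(set) {
  m <- vapply(set$spectra, function(s) s$intensity,
              numeric(grid_length(set$grid)))
  colnames(m) <- paste(set$manifest$strain_id, set$manifest$replicate_id,
                       sep = ".")
  m
}
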