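# Plain-text dataset serialization: a directory with a JSON metadata
# file and one TSV per array. Text-based on purpose, so datasets are
# portable and diffable; measurements regenerate bit-identically from
# the stored seed in any case.

#' Save / load a synthetic dataset
#'
#' Writes `meta.json` (seed, operator kind, noise spec, shapes) plus
#' `images.tsv` and `measurements.tsv` (one sample per column, full
#' precision). Complex measurements are stored as interleaved
#' real/imaginary rows.
#'
#' @param ds a [synthetic_dataset()].
#' @param dir directory to create/use.
#' @return `load_dataset` returns a list with `images`, `measurements`
#'   and `meta` (the forward model itself is not serialized; rebuild it
#'   from the metadata).
#' @export
save_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "cinnflow-dataset", version = 1L,
               seed = ds$seed, phantom_kind = ds$kind, noise = ds$noise,
               operator_kind = ds$fm$kind,
               domain_shape = ds$fm$domain_shape,
               measurement_dim = dim(ds$measurements) %||% length(ds$measurements),
               complex = is.complex(ds$measurements))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  nb <- batch_size(ds$images)
  im <- matrix(ds$images, ncol = nb)
  utils::write.table(format(im, digits = 17L), file.path(dir, "images.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  y <- ds$measurements
  ym <- matrix(y, ncol = nb)
  if (is.complex(ym)) ym <- rbind(Re(ym), Im(ym))[order(rep(seq_len(nrow(ym)),
                                                            2L)), ]
  utils::write.table(format(ym, digits = 17L),
                     file.path(dir, "measurements.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(dir)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, "cinnflow-dataset"))
    stop("not a cinnflow dataset directory", call. = FALSE)
  im <- as.matrix(utils::read.table(file.path(dir, "images.tsv"), sep = "\t"))
  nb <- ncol(im)
  images <- array(as.numeric(im), c(meta$domain_shape, nb))
  ym <- as.matrix(utils::read.table(file.path(dir, "measurements.tsv"),
                                    sep = "\t"))
  ym <- matrix(as.numeric(ym), nrow = nrow(ym))
  if (isTRUE(meta$complex)) {
    re <- ym[seq(1L, nrow(ym), 2L), , drop = FALSE]
    imp <- ym[seq(2L, nrow(ym), 2L), , drop = FALSE]
    ym <- re + 1i * imp
  }
  mdim <- meta$measurement_dim
  measurements <- if (length(mdim) > 1L) array(ym, mdim) else as.matrix(ym)
  list(images = images, measurements = measurements, meta = meta)
}

#' Export a sampling mask as a text vector
#'
#' One 0/1 value per frequency column.
#'
#' @param mask a [make_mri_mask()].
#' @param path output file.
#' @export
export_mask <- function(mask, path) {
  writeLines(as.character(as.integer(mask$keep)), path)
  invisible(path)
}

#' Export images as PNG files for visual inspection
#'
#' Requires the `png` package; images are min-max scaled per file.
#'
#' @param x image batch.
#' @param prefix file-name prefix; files are `prefix_001.png`, ...
#' @export
export_png <- function(x, prefix) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required for PNG export", call. = FALSE)
  x <- as_image_batch(x)
  for (b in seq_len(batch_size(x))) {
    m <- x[1L, , , b]
    rng <- range(m)
    if (diff(rng) > 0) m <- (m - rng[1L]) / diff(rng)
    png::writePNG(m, sprintf("%s_%03d.png", prefix, b))
  }
  invisible(prefix)
}
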