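#' Write / read a projection stack on disk
#'
#' A stack directory holds `frames.tif` (multi-page 16-bit grayscale TIFF),
#' `metadata.csv` (`frame,time_s,theta_deg`), `geometry.yaml`, `stack.yaml`
#' (background level) and, when present, `truth.csv` (per-frame ground-truth
#' marker positions, 0-based pixels). Pixel data are quantized to 16-bit
#' integers on write; the round trip is lossless for integer-valued frames.
#'
#' @param stack A [projection_stack()].
#' @param dir Directory (created if needed).
#' @return `read_stack()` returns a `projection_stack`; `write_stack()` the
#'   directory, invisibly.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "projection_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pages <- lapply(stack$frames, function(f) {
    pmin(pmax(round(f), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, file.path(dir, "frames.tif"),
                  bits.per.sample = 16, compression = "none")
  utils::write.csv(as.data.frame(stack$meta[, c("frame", "time_s", "theta_deg")]),
                   file.path(dir, "metadata.csv"), row.names = FALSE)
  write_geometry(stack$geom, file.path(dir, "geometry.yaml"))
  yaml::write_yaml(list(background = stack$background),
                   file.path(dir, "stack.yaml"))
  if (!is.null(stack$truth)) {
    utils::write.csv(as.data.frame(stack$truth), file.path(dir, "truth.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("no metadata.csv in ", dir)
  meta <- tibble::as_tibble(utils::read.csv(meta_path))
  if (nrow(meta) > 1 && any(diff(meta$time_s) <= 0)) {
    stop("metadata time column is not strictly increasing")
  }
  pages <- tiff::readTIFF(file.path(dir, "frames.tif"), all = TRUE,
                          as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != nrow(meta)) {
    stop(sprintf("frame count mismatch: %d TIFF pages vs %d metadata rows",
                 length(pages), nrow(meta)))
  }
  frames <- lapply(pages, function(p) round(p * 65535))
  geom <- read_geometry(file.path(dir, "geometry.yaml"))
  extra <- list(background = NULL)
  if (file.exists(file.path(dir, "stack.yaml"))) {
    extra <- yaml::read_yaml(file.path(dir, "stack.yaml"))
  }
  truth <- NULL
  if (file.exists(file.path(dir, "truth.csv"))) {
    truth <- tibble::as_tibble(utils::read.csv(file.path(dir, "truth.csv")))
  }
  projection_stack(frames, meta, geom, background = extra$background,
                   truth = truth)
}
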