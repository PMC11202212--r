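#' Write and read channel stacks as multi-page TIFF
#'
#' One TIFF page per z-slice. Intensities are stored as 32-bit float
#' scaled to [0, 1]; the voxel spacing and the intensity scale are
#' written to a JSON sidecar (\code{<path>.json}) so the stack
#' round-trips exactly.
#'
#' @param stack a \code{\link{channel_stack}}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack)
  mx <- max(stack)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(d[1]), function(z) matrix(stack[z, , ] / scale,
                                                    d[2], d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(spacing_um = spacing_um(stack),
                            intensity_scale = scale),
                       paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- c(length(pages), dim(pages[[1]]))
  arr <- array(0, d)
  for (z in seq_len(d[1])) arr[z, , ] <- pages[[z]]
  channel_stack(arr * meta$intensity_scale, meta$spacing_um)
}

#' Write and read binary masks as 8-bit TIFF
#'
#' @param mask a \code{\link{surface_mask}}.
#' @param path output TIFF path (spacing goes to a JSON sidecar).
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path) {
  d <- dim(mask)
  pages <- lapply(seq_len(d[1]), function(z) matrix(as.numeric(mask[z, , ]),
                                                    d[2], d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(list(spacing_um = spacing_um(mask)),
                       paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- c(length(pages), dim(pages[[1]]))
  arr <- array(FALSE, d)
  for (z in seq_len(d[1])) arr[z, , ] <- pages[[z]] > 0.5
  surface_mask(arr, meta$spacing_um)
}

#' Write and read spot sets as CSV
#'
#' Columns \code{z_um, y_um, x_um, diameter_um, quality}; numeric
#' formatting is fixed so identical spot sets serialize byte-identically.
#'
#' @param spots a \code{\link{spot_set}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_spots <- function(spots, path) {
  df <- as.data.frame(spots)
  df$diameter_um <- attr(spots, "diameter_um")
  df <- df[, c("z_um", "y_um", "x_um", "diameter_um", "quality")]
  for (nm in names(df)) df[[nm]] <- sprintf("%.9g", df[[nm]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spots
#' @export
read_spots <- function(path) {
  df <- utils::read.csv(path)
  dia <- if (nrow(df)) df$diameter_um[1] else 0.723
  spot_set(df[, c("z_um", "y_um", "x_um")], diameter_um = dia,
           quality = if (nrow(df)) df$quality else NULL)
}
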