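#' Construct a volume stack
#'
#' The common currency of all image operations: a single- or multi-channel 3D
#' intensity array with voxel-spacing metadata. Data are stored as
#' `[row (y), col (x), plane (z)]` for a single channel or
#' `[row, col, plane, channel]` for multi-channel stacks. The default voxel
#' size is the light-sheet acquisition geometry 0.54 x 0.54 x 4 um (XYZ),
#' which makes the data strongly anisotropic in Z.
#'
#' @param data 3D (or 4D with trailing channel dimension) numeric array of
#'   finite, non-negative intensities.
#' @param voxel_size_um numeric triple `(x, y, z)` in micrometres, all > 0.
#' @param channel_names optional character vector naming the channels
#'   (e.g. `c("huc", "mbp", "af", "nuclear")`).
#' @return an object of class `volume_stack`.
#' @export
volume_stack <- function(data, voxel_size_um = c(0.54, 0.54, 4),
                         channel_names = NULL) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("`data` must be a 3D or 4D array")
  if (any(dim(data) < 1)) stop("all dimensions must be >= 1")
  if (!all(is.finite(data))) stop("intensities must be finite")
  if (any(data < 0)) stop("intensities must be non-negative")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3 || any(voxel_size_um <= 0))
    stop("`voxel_size_um` must be three strictly positive values (x, y, z)")
  nch <- if (length(dim(data)) == 4L) dim(data)[4] else 1L
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nch))
  if (length(channel_names) != nch)
    stop("length(channel_names) must equal the number of channels")
  structure(list(data = data, voxel_size_um = voxel_size_um,
                 channel_names = channel_names),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("volume_stack:", paste(d[1:3], collapse = " x "),
      "(y x x x z),", length(x$channel_names), "channel(s)\n")
  cat("  voxel size (um, xyz):", paste(x$voxel_size_um, collapse = " x "), "\n")
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one channel of a volume stack as a 3D array
#'
#' @param stack a `volume_stack`.
#' @param channel channel name or index.
#' @export
get_channel <- function(stack, channel = 1L) {
  stopifnot(inherits(stack, "volume_stack"))
  if (is.character(channel)) {
    channel <- match(channel, stack$channel_names)
    if (is.na(channel)) stop("unknown channel name")
  }
  if (length(dim(stack$data)) == 3L) {
    if (channel != 1L) stop("stack has a single channel")
    stack$data
  } else {
    stack$data[, , , channel, drop = TRUE]
  }
}

#' Physical extent of a stack in micrometres
#' @param stack a `volume_stack`.
#' @return numeric triple (x, y, z) extent in um.
#' @export
stack_extent_um <- function(stack) {
  d <- dim(stack$data)
  c(d[2] * stack$voxel_size_um[1],
    d[1] * stack$voxel_size_um[2],
    d[3] * stack$voxel_size_um[3])
}

#' Write a volume stack as a multi-page TIFF with a JSON sidecar
#'
#' Pages are written channel-major (all planes of channel 1, then channel 2,
#' ...), i.e. a channel-first 3D multi-channel TIFF. Intensities are rescaled
#' to \[0, 1\] for 32-bit float storage; the scale factor, voxel size and
#' channel names go into `<path>.json` so that [read_volume_tiff()] restores
#' the stack losslessly.
#'
#' @param stack a `volume_stack`.
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "volume_stack"))
  dat <- stack$data
  if (length(dim(dat)) == 3L) dim(dat) <- c(dim(dat), 1L)
  scale <- max(dat, 1e-12)
  pages <- list()
  for (ch in seq_len(dim(dat)[4]))
    for (z in seq_len(dim(dat)[3]))
      pages[[length(pages) + 1L]] <- dat[, , z, ch] / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(voxel_size_um = stack$voxel_size_um,
               channel_names = stack$channel_names,
               n_planes = dim(dat)[3], n_channels = dim(dat)[4],
               intensity_scale = scale, page_order = "channel_major")
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume stack written by [write_volume_tiff()]
#' @param path TIFF file path; `<path>.json` must exist.
#' @export
read_volume_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- meta$n_planes; nc <- meta$n_channels
  if (length(pages) != nz * nc) stop("page count does not match metadata")
  d <- dim(pages[[1]])
  arr <- array(0, c(d[1], d[2], nz, nc))
  i <- 1L
  for (ch in seq_len(nc)) for (z in seq_len(nz)) {
    arr[, , z, ch] <- pages[[i]]; i <- i + 1L
  }
  arr <- arr * meta$intensity_scale
  if (nc == 1L) dim(arr) <- d <- c(d[1], d[2], nz)
  volume_stack(arr, meta$voxel_size_um, meta$channel_names)
}

#' Assemble a multi-channel 3D stack from 2D plane images
#'
#' Mirrors the preprocessing step that re-saves raw per-plane 2D TIFF series
#' as 3D multi-channel stacks. Input is a list with one element per channel;
#' each element is either a list of 2D matrices or a character vector of
#' single-page TIFF paths, ordered by plane.
#'
#' @param planes list (length = channels) of per-plane matrices or TIFF paths.
#' @param channel_names optional channel names.
#' @param voxel_size_um voxel size, see [volume_stack()].
#' @return a `volume_stack`. Ragged or missing planes raise an error naming
#'   the offending channel/plane.
#' @export
convert_stacks <- function(planes, channel_names = NULL,
                           voxel_size_um = c(0.54, 0.54, 4)) {
  stopifnot(is.list(planes), length(planes) >= 1)
  nz <- length(planes[[1]])
  mats <- vector("list", length(planes))
  for (ch in seq_along(planes)) {
    pl <- planes[[ch]]
    if (length(pl) != nz)
      stop(sprintf("channel %d has %d planes, expected %d", ch, length(pl), nz))
    mats[[ch]] <- lapply(seq_along(pl), function(z) {
      p <- if (is.character(pl)) {
        if (!file.exists(pl[z]))
          stop(sprintf("missing plane file (channel %d, plane %d): %s",
                       ch, z, pl[z]))
        tiff::readTIFF(pl[z])
      } else pl[[z]]
      if (!is.matrix(p))
        stop(sprintf("plane is not a 2D image (channel %d, plane %d)", ch, z))
      p
    })
  }
  d0 <- dim(mats[[1]][[1]])
  for (ch in seq_along(mats)) for (z in seq_len(nz)) {
    d <- dim(mats[[ch]][[z]])
    if (!identical(d, d0))
      stop(sprintf("ragged plane shape %dx%d at channel %d, plane %d (expected %dx%d)",
                   d[1], d[2], ch, z, d0[1], d0[2]))
  }
  arr <- array(0, c(d0[1], d0[2], nz, length(planes)))
  for (ch in seq_along(mats)) for (z in seq_len(nz))
    arr[, , z, ch] <- mats[[ch]][[z]]
  if (length(planes) == 1L) dim(arr) <- c(d0[1], d0[2], nz)
  volume_stack(arr, voxel_size_um, channel_names)
}
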