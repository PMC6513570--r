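#' Labeled 3D segmentation volume
#'
#' Container for an integer-labeled anisotropic voxel grid, the raw input of
#' the morphometry pipeline. Label 0 is background; every positive integer
#' identifies one traced organelle (one label may still split into several
#' connected components, see [extract_organelles()]).
#'
#' The grid is stored as an R array with dimensions `(x, y, z)` where `z` is
#' the section/stack axis. SBF-SEM images transversely to the muscle fiber,
#' so by default the stack axis is also the fiber's longitudinal axis.
#'
#' @param labels 3D array of non-negative integers.
#' @param voxel_size numeric length-3, voxel pitch `(dx, dy, dz)` in nm.
#'   Default `c(10, 10, 30)`: ~10 nm in-plane pixels and 30 nm sections.
#' @param longitudinal_axis which grid axis runs along the muscle fiber;
#'   one of `"x"`, `"y"`, `"z"` (default `"z"`).
#' @return An object of class `labeled_volume`.
#' @examples
#' a <- array(0L, c(4, 4, 3)); a[2:3, 2:3, 2] <- 1L
#' vol <- labeled_volume(a)
#' vol
#' @export
labeled_volume <- function(labels, voxel_size = c(10, 10, 30),
                           longitudinal_axis = "z") {
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  if (anyNA(labels) || any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive numbers (nm)", call. = FALSE)
  longitudinal_axis <- match.arg(longitudinal_axis, c("x", "y", "z"))
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, voxel_size = voxel_size,
         longitudinal_axis = longitudinal_axis),
    class = "labeled_volume"
  )
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  labs <- setdiff(sort(unique(as.integer(x$labels))), 0L)
  cat(sprintf(
    "<labeled_volume> %d x %d x %d voxels @ (%g, %g, %g) nm, %d label(s)\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    length(labs)))
  cat(sprintf("  longitudinal axis: %s\n", x$longitudinal_axis))
  invisible(x)
}

#' Label inventory of a volume
#'
#' @param vol a [labeled_volume()].
#' @return data.frame with one row per positive label and its voxel count.
#' @export
label_inventory <- function(vol) {
  stopifnot(inherits(vol, "labeled_volume"))
  tab <- table(vol$labels[vol$labels > 0L])
  data.frame(label = as.integer(names(tab)),
             voxel_count = as.integer(tab), row.names = NULL)
}

#' Read a labeled segmentation volume
#'
#' Reads an integer-labeled stack from a multi-page TIFF or an MRC file.
#' TIFF carries no physical pixel size for our purposes, so `voxel_size`
#' must be supplied; MRC headers carry a cell spacing which is used unless
#' overridden.
#'
#' @param path file path; format by extension (`.tif`/`.tiff` or `.mrc`).
#' @param voxel_size `(dx, dy, dz)` in nm; overrides any header value.
#' @param longitudinal_axis see [labeled_volume()].
#' @return A [labeled_volume()].
#' @export
read_labeled_volume <- function(path, voxel_size = NULL,
                                longitudinal_axis = "z") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    # undo the [0,1] normalization; true integer labels land back on
    # integers, float imagery does not
    pages <- lapply(pages, function(p) {
      bits <- attr(p, "bits.per.sample") %||% 8L
      p * (2^bits - 1)
    })
    if (any(vapply(pages, function(p)
      any(abs(p - round(p)) > 1e-6), logical(1))))
      stop("TIFF contains non-integer data; expected integer labels",
           call. = FALSE)
    # readTIFF returns row = y, col = x; transpose to (x, y) per page
    arr <- array(0L, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- as.integer(round(t(pages[[k]])))
    if (is.null(voxel_size))
      stop("TIFF stacks carry no voxel size; supply `voxel_size`",
           call. = FALSE)
    labeled_volume(arr, voxel_size, longitudinal_axis)
  } else if (ext == "mrc") {
    m <- read_mrc(path)
    vs <- if (!is.null(voxel_size)) voxel_size else m$voxel_size
    if (is.null(vs))
      stop("MRC header has no voxel size; supply `voxel_size`",
           call. = FALSE)
    labeled_volume(m$data, vs, longitudinal_axis)
  } else {
    stop("unsupported volume format: .", ext, call. = FALSE)
  }
}

#' Write a labeled volume
#'
#' Multi-page 16-bit TIFF or MRC (mode 1, 16-bit signed). Round trips are
#' lossless for labels up to 32767 (TIFF: 65535).
#'
#' @param vol a [labeled_volume()].
#' @param path output path; format chosen from extension.
#' @return `path`, invisibly.
#' @export
write_labeled_volume <- function(vol, path) {
  stopifnot(inherits(vol, "labeled_volume"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (max(vol$labels) > 65535L)
      stop("labels exceed 16-bit TIFF range", call. = FALSE)
    pages <- lapply(seq_len(dim(vol$labels)[3]), function(k)
      t(vol$labels[, , k]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else if (ext == "mrc") {
    write_mrc(vol$labels, path, vol$voxel_size)
  } else {
    stop("unsupported volume format: .", ext, call. = FALSE)
  }
  invisible(path)
}

# Minimal MRC-2014 subset: header words we use are nx/ny/nz, mode,
# mx/my/mz, cella; data modes 0 (int8), 1 (int16), 2 (float32 -- must hold
# integers), 6 (uint16). Voxel size (nm) = 10 * cella / m (cella is in
# Angstrom by convention).
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- h[1]; ny <- h[2]; nz <- h[3]; mode <- h[4]
  mx <- h[8]; my <- h[9]; mz <- h[10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 1024)
  n <- as.double(nx) * ny * nz
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                  endian = "little"),
    stop("unsupported MRC mode: ", mode, call. = FALSE))
  if (length(data) < n) stop("truncated MRC file", call. = FALSE)
  if (any(data != round(data)))
    stop("MRC contains non-integer data; expected integer labels",
         call. = FALSE)
  vs <- NULL
  if (all(c(mx, my, mz) > 0) && all(cella > 0))
    vs <- 10 * cella / c(mx, my, mz)   # Angstrom -> nm
  list(data = array(as.integer(data), c(nx, ny, nz)), voxel_size = vs)
}

write_mrc <- function(labels, path, voxel_size) {
  if (max(labels) > 32767L)
    stop("labels exceed int16 MRC range", call. = FALSE)
  d <- dim(labels)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, 1L, 0L, 0L, 0L, d)), con, size = 4,
           endian = "little")                               # words 1-10
  writeBin(as.numeric(d * voxel_size / 10), con, size = 4,
           endian = "little")                               # cella (A)
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(0, max(labels), mean(labels))), con, size = 4,
           endian = "little")
  # pad header to 1024 bytes (we are at 4*22 = 88)
  writeBin(raw(1024 - 88), con)
  writeBin(as.integer(labels), con, size = 2, endian = "little")
  invisible(path)
}
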