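#' @keywords internal
"_PACKAGE"

# Canonical pixel scale: 5 mm imaged over 640 px.
MYCONET_PIXEL_SIZE_UM <- 5000 / 640  # 7.8125 um/px

#' Construct a network image
#'
#' A `network_image` couples a 2D raster (grayscale intensities in any range,
#' or strictly binary 0/1) with its physical pixel size and a provenance tag.
#' It is the raw input of the quantification pipeline.
#'
#' @param pixels numeric or integer matrix; rows are image rows (top-left
#'   origin). Grayscale intensities or binary 0/1.
#' @param pixel_size_um physical size of one pixel side in micrometers.
#'   Default 7.8125 um (a 5 x 5 mm field imaged at 640 x 640 px).
#' @param provenance free-text source tag (file path, generator call, ...).
#' @param meta optional named list of ground-truth or acquisition metadata.
#' @return an object of class `network_image`.
#' @export
network_image <- function(pixels, pixel_size_um = MYCONET_PIXEL_SIZE_UM,
                          provenance = "", meta = list()) {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("`pixels` must be a non-empty matrix")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         provenance = as.character(provenance), meta = meta),
    class = "network_image"
  )
}

#' @export
print.network_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<network_image> %d x %d px, %.4f um/px (%.2f x %.2f mm)\n",
              d[1], d[2], x$pixel_size_um,
              d[1] * x$pixel_size_um / 1000, d[2] * x$pixel_size_um / 1000))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  if (is_binary_raster(x$pixels))
    cat(sprintf("  binary, coverage %.3f%%\n", 100 * mean(x$pixels > 0)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.network_image <- function(x) dim(x$pixels)

# Accept a network_image, a clean_mask/skeleton_mask, or a bare matrix,
# and return the pixel matrix.
as_pixels <- function(x) {
  if (inherits(x, c("network_image", "clean_mask", "skeleton_mask")))
    return(x$pixels)
  if (is.matrix(x)) return(x)
  stop("expected a matrix, network_image, clean_mask or skeleton_mask, got ",
       paste(class(x), collapse = "/"))
}

# Strictly binary: at most two distinct values, one of which is 0
# (or a single value in {0, 1} / the all-0 / all-max degenerate cases).
is_binary_raster <- function(px) {
  u <- unique(as.vector(px))
  if (length(u) > 2L) return(FALSE)
  all(u %in% c(0, 1)) || (length(u) == 2L && 0 %in% u)
}

# Coerce any binary-valued raster to an integer 0/1 matrix.
as_binary01 <- function(x) {
  px <- as_pixels(x)
  if (!is_binary_raster(px))
    stop("raster is not binary (more than two distinct values)")
  out <- matrix(as.integer(px > 0), nrow(px), ncol(px))
  out
}

#' Read a network image from PNG or TIFF
#'
#' Reads an 8- or 16-bit single-channel (or RGB, converted to luminance)
#' image into a [network_image]. Values are rescaled to 0..255.
#'
#' @param path file path; format inferred from the extension
#'   (`.png`, `.tif`, `.tiff`).
#' @param pixel_size_um physical pixel size to attach (metadata, not read
#'   from the file). Default 7.8125 um.
#' @return a [network_image] with grayscale intensities in 0..255.
#' @export
read_network_image <- function(path, pixel_size_um = MYCONET_PIXEL_SIZE_UM) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (use png/tif/tiff): ", path)
  )
  if (length(dim(arr)) == 3L) {
    # RGB(A) -> luminance
    arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  }
  px <- round(arr * 255)
  storage.mode(px) <- "integer"
  network_image(px, pixel_size_um = pixel_size_um, provenance = path)
}

#' Write a binary or grayscale raster to PNG or TIFF
#'
#' Binary rasters are written with foreground 255, background 0; grayscale
#' rasters are written as 8-bit after clamping to 0..255. If the object
#' carries generator metadata, a sidecar `<path>.json` records it together
#' with the provenance tag.
#'
#' @param x a [network_image], mask object, or matrix.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @param sidecar write the JSON sidecar when metadata is present
#'   (default TRUE).
#' @return `path`, invisibly.
#' @export
write_network_image <- function(x, path, sidecar = TRUE) {
  px <- as_pixels(x)
  if (is_binary_raster(px)) {
    out <- matrix(as.numeric(px > 0), nrow(px), ncol(px))
  } else {
    out <- pmin(pmax(px, 0), 255) / 255
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(out, target = path),
    tif = ,
    tiff = tiff::writeTIFF(out, where = path, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "' (use png/tif/tiff): ", path)
  )
  meta <- if (inherits(x, "network_image")) x$meta else NULL
  if (isTRUE(sidecar) && length(meta)) {
    side <- list(provenance = if (inherits(x, "network_image")) x$provenance else "",
                 pixel_size_um = if (inherits(x, "network_image")) x$pixel_size_um else NA,
                 meta = meta)
    jsonlite::write_json(side, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

# Label connected foreground components under 4- or 8-connectivity.
# Returns an integer matrix of labels (0 = background) and the component
# sizes as an attribute. EBImage::bwlabel is 4-connectivity only, so the
# generic case goes through the pixel adjacency graph.
label_components <- function(mask, connectivity = 8L) {
  mask <- as_binary01(mask)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L))
    stop("`connectivity` must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask > 0L)
  lab <- matrix(0L, nr, nc)
  if (!length(fg)) {
    attr(lab, "sizes") <- integer(0)
    return(lab)
  }
  idx <- seq_along(fg)                 # vertex id per foreground pixel
  pos <- integer(nr * nc); pos[fg] <- idx
  r <- ((fg - 1L) %% nr) + 1L
  co <- ((fg - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))   # down, right (undirected graph)
  if (connectivity == 8L)
    offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    r2 <- r + o[1]; c2 <- co + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- pos[nb] > 0L
    from <- c(from, idx[ok][hit])
    to <- c(to, pos[nb][hit])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  lab[fg] <- comp$membership
  attr(lab, "sizes") <- as.integer(comp$csize)
  lab
}
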