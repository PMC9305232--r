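#' Binarize a grayscale micrograph
#'
#' Thresholds a grayscale network image into a binary mask with the hyphae
#' as foreground. Bright-hyphae-on-dark-background polarity is assumed;
#' set `invert = TRUE` for dark hyphae on a bright background.
#' Already-binary input is returned unchanged (idempotence).
#'
#' @param img a [network_image] or grayscale matrix.
#' @param method `"otsu"` (default; Otsu's threshold via EBImage) or
#'   `"fixed"`.
#' @param fixed_threshold intensity cutoff when `method = "fixed"`; pixels
#'   strictly above it become foreground.
#' @param invert flip polarity before thresholding.
#' @return an integer 0/1 matrix.
#' @export
binarize <- function(img, method = c("otsu", "fixed"),
                     fixed_threshold = NULL, invert = FALSE) {
  method <- match.arg(method)
  px <- as_pixels(img)
  if (is_binary_raster(px)) {
    out <- matrix(as.integer(px > 0), nrow(px), ncol(px))
    if (isTRUE(invert)) out <- 1L - out
    return(out)
  }
  if (isTRUE(invert)) px <- max(px) - px
  rng <- range(px)
  if (method == "otsu") {
    if (rng[1] == rng[2])
      stop("cannot Otsu-threshold a constant image (no threshold exists)")
    scaled <- (px - rng[1]) / (rng[2] - rng[1])
    th01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    thr <- rng[1] + th01 * (rng[2] - rng[1])
  } else {
    if (is.null(fixed_threshold))
      stop("`fixed_threshold` must be supplied when method = \"fixed\"")
    thr <- fixed_threshold
  }
  matrix(as.integer(px > thr), nrow(px), ncol(px))
}

#' Clean a binary mask: smoothing and small-cluster removal
#'
#' Applies morphological closing with a disc of radius `smoothing_radius_px`
#' (0 skips smoothing), then removes every connected foreground component
#' smaller than `min_cluster_px` pixels — the isolated specks that are
#' background noise rather than hyphae.
#'
#' @param mask binary raster (matrix or [network_image]).
#' @param min_cluster_px smallest component size (px) kept. Default 20 at
#'   the canonical 7.8125 um/px scale; a tunable, not a measured constant.
#' @param connectivity 4 or 8 (default 8: diagonal 1-px strands connect).
#' @param smoothing_radius_px disc radius for closing; default 0 (off).
#' @return a `clean_mask` object: `$pixels` (0/1 matrix), `$min_cluster_px`,
#'   `$connectivity`.
#' @export
clean_mask <- function(mask, min_cluster_px = 20L, connectivity = 8L,
                       smoothing_radius_px = 0L) {
  px <- as_binary01(mask)
  min_cluster_px <- as.integer(min_cluster_px)
  if (min_cluster_px < 1L) stop("`min_cluster_px` must be >= 1")
  smoothing_radius_px <- as.integer(smoothing_radius_px)
  if (smoothing_radius_px < 0L) stop("`smoothing_radius_px` must be >= 0")
  if (smoothing_radius_px > 0L && any(px > 0L)) {
    brush <- EBImage::makeBrush(2L * smoothing_radius_px + 1L, shape = "disc")
    closed <- EBImage::closing(EBImage::Image(px), brush)
    px <- matrix(as.integer(EBImage::imageData(closed) > 0),
                 nrow(px), ncol(px))
  }
  if (min_cluster_px > 1L && any(px > 0L)) {
    lab <- label_components(px, connectivity = connectivity)
    sizes <- attr(lab, "sizes")
    small <- which(sizes < min_cluster_px)
    if (length(small)) px[lab %in% small] <- 0L
  }
  structure(list(pixels = px, min_cluster_px = min_cluster_px,
                 connectivity = as.integer(connectivity)),
            class = "clean_mask")
}

#' @export
print.clean_mask <- function(x, ...) {
  cat(sprintf("<clean_mask> %d x %d px, coverage %.3f%%, min_cluster %d px, %d-connectivity\n",
              nrow(x$pixels), ncol(x$pixels), 100 * mean(x$pixels > 0),
              x$min_cluster_px, x$connectivity))
  invisible(x)
}

# One full Zhang-Suen iteration (two subpasses) on a logical matrix.
# Returns the thinned matrix and whether anything changed.
zhang_suen_pass <- function(m) {
  changed <- FALSE
  nr <- nrow(m); nc <- ncol(m)
  for (sub in 1:2) {
    # 8-neighbourhood via shifted copies of the padded image.
    p <- matrix(FALSE, nr + 2L, nc + 2L)
    p[2:(nr + 1L), 2:(nc + 1L)] <- m
    ctr <- p[2:(nr + 1L), 2:(nc + 1L)]
    n2 <- p[1:nr, 2:(nc + 1L)]          # north
    n3 <- p[1:nr, 3:(nc + 2L)]          # north-east
    n4 <- p[2:(nr + 1L), 3:(nc + 2L)]   # east
    n5 <- p[3:(nr + 2L), 3:(nc + 2L)]   # south-east
    n6 <- p[3:(nr + 2L), 2:(nc + 1L)]   # south
    n7 <- p[3:(nr + 2L), 1:nc]          # south-west
    n8 <- p[2:(nr + 1L), 1:nc]          # west
    n9 <- p[1:nr, 1:nc]                 # north-west
    B <- n2 + n3 + n4 + n5 + n6 + n7 + n8 + n9
    A <- (!n2 & n3) + (!n3 & n4) + (!n4 & n5) + (!n5 & n6) +
         (!n6 & n7) + (!n7 & n8) + (!n8 & n9) + (!n9 & n2)
    if (sub == 1L) {
      cond <- ctr & B >= 2 & B <= 6 & A == 1 &
        !(n2 & n4 & n6) & !(n4 & n6 & n8)
    } else {
      cond <- ctr & B >= 2 & B <= 6 & A == 1 &
        !(n2 & n4 & n8) & !(n2 & n6 & n8)
    }
    if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
  }
  list(m = m, changed = changed)
}

#' Extract the 1-px network skeleton
#'
#' Thins a cleaned binary mask to a one-pixel-wide centreline using
#' Zhang-Suen thinning. The skeleton is a subset of the input foreground,
#' and re-thinning a skeleton is a no-op (the algorithm terminates when no
#' pixel is deletable).
#'
#' @param mask a `clean_mask`, binary matrix or binary [network_image].
#' @return a `skeleton_mask` object with `$pixels` (0/1 matrix).
#' @export
skeletonize <- function(mask) {
  px <- as_binary01(mask)
  m <- px > 0L
  repeat {
    res <- zhang_suen_pass(m)
    m <- res$m
    if (!res$changed) break
  }
  structure(list(pixels = matrix(as.integer(m), nrow(px), ncol(px))),
            class = "skeleton_mask")
}

#' @export
print.skeleton_mask <- function(x, ...) {
  cat(sprintf("<skeleton_mask> %d x %d px, %d skeleton px\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' Define a square region of interest
#'
#' @param top_left `(row, col)` of the ROI's top-left corner, 0-based.
#' @param side_px ROI side (>= 64; default 640, i.e. 5 x 5 mm at the
#'   canonical scale).
#' @param label position index along the barrier-to-centre axis.
#' @return a `roi_spec` list.
#' @export
roi_spec <- function(top_left, side_px = 640L, label = 1L) {
  top_left <- as.integer(top_left)
  if (length(top_left) != 2L || any(top_left < 0L))
    stop("`top_left` must be two non-negative integers (row, col), 0-based")
  side_px <- as.integer(side_px)
  if (side_px < 64L) stop("`side_px` must be >= 64")
  structure(list(top_left = top_left, side_px = side_px,
                 label = as.integer(label)),
            class = "roi_spec")
}

#' Crop regions of interest from a network image
#'
#' Crops each ROI (half-open `[top_left, top_left + side)` in 0-based pixel
#' coordinates) into its own [network_image], propagating the pixel scale
#' and attaching the position label. ROIs are returned in the given order,
#' conventionally barrier to centre.
#'
#' @param img a [network_image] (grayscale or binary).
#' @param rois list of [roi_spec()] objects.
#' @return list of cropped [network_image]s.
#' @export
extract_rois <- function(img, rois) {
  stopifnot(inherits(img, "network_image"))
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  d <- dim(img$pixels)
  lapply(rois, function(rs) {
    stopifnot(inherits(rs, "roi_spec"))
    r0 <- rs$top_left[1]; c0 <- rs$top_left[2]; s <- rs$side_px
    if (r0 + s > d[1] || c0 + s > d[2])
      stop(sprintf(
        "ROI label %d at (%d,%d) side %d exceeds image bounds %d x %d",
        rs$label, r0, c0, s, d[1], d[2]))
    crop <- img$pixels[(r0 + 1L):(r0 + s), (c0 + 1L):(c0 + s), drop = FALSE]
    network_image(crop, pixel_size_um = img$pixel_size_um,
                  provenance = img$provenance,
                  meta = c(img$meta[setdiff(names(img$meta), "clean_pixels")],
                           list(roi_label = rs$label,
                                roi_top_left = rs$top_left)))
  })
}
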