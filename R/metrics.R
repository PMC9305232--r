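#' Box-count a binary mask
#'
#' Partitions the raster into an axis-aligned grid of `s` x `s` boxes for
#' each grid size `s` and counts the boxes containing at least one
#' foreground pixel. Edge boxes may be partial when `s` does not divide the
#' image side; they are counted like any other box. The grid can be
#' anchored at any of the four image corners (`anchor`), or offset
#' explicitly; the top-left anchor at offset (0,0) is the default.
#'
#' @param mask binary raster (matrix, mask object or binary
#'   [network_image]).
#' @param grid_sizes_px positive integer grid sizes, each no larger than
#'   the smaller image dimension. Default `c(8, 16, 32, 64)`, geometric
#'   spacing over the standard 8-64 px range for a 640-px field.
#' @param offset `(row, col)` grid-anchor offset in pixels (0-based);
#'   ignored when `anchor != "topleft"`.
#' @param anchor which image corner the grid is aligned to:
#'   `"topleft"` (default), `"topright"`, `"bottomleft"`, `"bottomright"`.
#' @return a `box_count_curve`: `$grid_sizes_px`, `$occupied_counts`
#'   (N(s)), `$roi_side_px`.
#' @export
box_count <- function(mask, grid_sizes_px = c(8L, 16L, 32L, 64L),
                      offset = c(0L, 0L),
                      anchor = c("topleft", "topright",
                                 "bottomleft", "bottomright")) {
  anchor <- match.arg(anchor)
  px <- as_binary01(mask)
  nr <- nrow(px); nc <- ncol(px)
  grid_sizes_px <- as.integer(grid_sizes_px)
  if (!length(grid_sizes_px)) stop("`grid_sizes_px` must be non-empty")
  if (any(grid_sizes_px < 1L)) stop("grid sizes must be positive")
  if (any(grid_sizes_px > min(nr, nc)))
    stop("grid size ", max(grid_sizes_px), " exceeds image dimension ",
         min(nr, nc))
  offset <- as.integer(offset)
  fg <- which(px > 0L)
  r0 <- (fg - 1L) %% nr        # 0-based row
  c0 <- (fg - 1L) %/% nr       # 0-based col
  counts <- vapply(grid_sizes_px, function(s) {
    off <- switch(anchor,
      topleft = offset,
      topright = c(0L, (s - nc %% s) %% s),
      bottomleft = c((s - nr %% s) %% s, 0L),
      bottomright = c((s - nr %% s) %% s, (s - nc %% s) %% s))
    if (!length(fg)) return(0L)
    br <- (r0 + off[1]) %/% s
    bc <- (c0 + off[2]) %/% s
    n_row_boxes <- (nr + off[1] - 1L) %/% s + 1L
    length(unique(br + bc * n_row_boxes))
  }, integer(1))
  structure(list(grid_sizes_px = grid_sizes_px,
                 occupied_counts = counts,
                 roi_side_px = min(nr, nc)),
            class = "box_count_curve")
}

#' @export
print.box_count_curve <- function(x, ...) {
  cat("<box_count_curve>\n")
  print(data.frame(s = x$grid_sizes_px, N = x$occupied_counts),
        row.names = FALSE)
  invisible(x)
}

#' Estimate the mass fractal dimension from a box-count curve
#'
#' Fits log N(s) against log s by unweighted ordinary least squares
#' (natural logarithms) and reports the mass fractal dimension
#' D_m = -slope, following the scaling law N(s) proportional to s^(-D_m).
#' Grid sizes with N(s) = 0 carry no information and are dropped with a
#' warning; at least two usable points are required.
#'
#' @param curve a `box_count_curve` from [box_count()].
#' @return a `fractal_estimate`: `$D_m`, `$intercept` (log-space),
#'   `$r_squared` (NA for a zero-variance fit, e.g. a single pixel where
#'   N(s) is constant), `$curve`, and `$flag` set when D_m falls outside
#'   [-0.1, 2.1].
#' @export
estimate_dimension <- function(curve) {
  stopifnot(inherits(curve, "box_count_curve"))
  s <- curve$grid_sizes_px
  N <- curve$occupied_counts
  usable <- N > 0
  if (any(!usable)) {
    warning(sum(!usable), " grid size(s) with N(s)=0 excluded from the fit")
    s <- s[usable]; N <- N[usable]
  }
  if (length(unique(s)) < 2L)
    stop("need >= 2 distinct grid sizes with N(s) > 0; dimension undefined")
  fit <- stats::lm(log(N) ~ log(s))
  co <- stats::coef(fit)
  ss_tot <- sum((log(N) - mean(log(N)))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(stats::residuals(fit)^2) / ss_tot
  D <- -unname(co[2])
  structure(list(D_m = D, intercept = unname(co[1]), r_squared = r2,
                 curve = curve,
                 flag = if (D < -0.1 || D > 2.1) "dimension outside [-0.1, 2.1]" else NULL),
            class = "fractal_estimate")
}

#' @export
print.fractal_estimate <- function(x, ...) {
  cat(sprintf("<fractal_estimate> D_m = %.4f (r^2 = %s, %d grid sizes)\n",
              x$D_m,
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
              length(x$curve$grid_sizes_px)))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Surface density of a binary mask
#'
#' The density of the network is the ratio between the surface occupied by
#' the network and the total area: exact foreground pixel count over total
#' pixel count.
#'
#' @param mask binary raster.
#' @return a `density_measure`: `$coverage_frac` in [0,1] and
#'   `$coverage_percent` (= 100 x fraction).
#' @export
surface_density <- function(mask) {
  px <- as_binary01(mask)
  frac <- sum(px > 0L) / length(px)
  structure(list(coverage_frac = frac, coverage_percent = 100 * frac),
            class = "density_measure")
}

#' Assemble a barrier-to-centre gradient profile
#'
#' Computes the architecture statistics — mass fractal dimension and surface
#' density — for an ordered series of ROI masks and returns them as a tidy
#' table, one row per location. Density is always measured on the supplied
#' network mask; the box-counting raster is the skeleton (default) or the
#' mask itself, selected by `source`.
#'
#' @param rois list of binary masks (matrices, `clean_mask`es or binary
#'   [network_image]s) in barrier-to-centre order, or a named list where
#'   names give labels.
#' @param grid_sizes_px grid sizes passed to [box_count()].
#' @param source raster fed to box counting: `"skeleton"` (default,
#'   masks are thinned first) or `"clean_mask"`.
#' @param labels optional integer labels, default `seq_along(rois)`.
#' @return a `gradient_profile`: a data.frame with columns `label`, `D_m`,
#'   `r_squared`, `coverage_frac`, `coverage_percent`, plus the per-ROI
#'   estimates in `attr(, "estimates")`.
#' @export
profile_gradient <- function(rois, grid_sizes_px = c(8L, 16L, 32L, 64L),
                             source = c("skeleton", "clean_mask"),
                             labels = NULL) {
  source <- match.arg(source)
  if (!length(rois)) stop("need at least one ROI")
  if (is.null(labels)) labels <- seq_along(rois)
  if (length(labels) != length(rois))
    stop("`labels` must match `rois` in length")
  if (any(diff(as.numeric(labels)) <= 0))
    stop("`labels` must be strictly increasing (barrier to centre)")
  ests <- vector("list", length(rois))
  rows <- lapply(seq_along(rois), function(i) {
    msk <- as_binary01(rois[[i]])
    dens <- surface_density(msk)
    counted <- if (source == "skeleton") skeletonize(msk)$pixels else msk
    est <- estimate_dimension(box_count(counted, grid_sizes_px))
    ests[[i]] <<- est
    data.frame(label = labels[i], D_m = est$D_m, r_squared = est$r_squared,
               coverage_frac = dens$coverage_frac,
               coverage_percent = dens$coverage_percent)
  })
  out <- do.call(rbind, rows)
  attr(out, "estimates") <- ests
  attr(out, "source") <- source
  class(out) <- c("gradient_profile", class(out))
  out
}
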