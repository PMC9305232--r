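#' Parameters for the synthetic hyphal-network generator
#'
#' The generator grows a filamentous binary network by advancing hyphal tips
#' as correlated random walks: each tip steps forward with a jittered heading,
#' may bifurcate (branching), and may terminate when it runs into an existing
#' strand (an anastomosis analogue). Strands are rasterized as Bresenham
#' lines dilated to `strand_width_px`; growth halts when the painted surface
#' coverage reaches `target_coverage_frac` or all tips have terminated.
#' Salt (speckle) noise is applied after growth so that downstream cleaning
#' can be exercised against known ground truth.
#'
#' Defaults emulate sparse extraradical mycorrhizal networks as imaged on a
#' 5 x 5 mm field at 640 x 640 px: a few percent surface coverage,
#' curvilinear strands 1-5 px wide, branching topology.
#'
#' @param image_size_px square image side in pixels (>= 64). Default 640.
#' @param n_seeds number of initial hyphal tips entering the field. Default 10.
#' @param step_len_px tip advance per growth step, px. Default 4.
#' @param angle_jitter_rad s.d. of the per-step heading change, radians.
#'   Default 0.3.
#' @param branch_prob per-step probability that a tip bifurcates. Default 0.05.
#' @param fusion_prob per-contact probability that a tip terminates by joining
#'   an existing strand. Default 0.5.
#' @param strand_width_px rasterized strand thickness, px (>= 1). Default 2.
#' @param target_coverage_frac fraction in (0,1) at which growth halts.
#'   Default 0.06 (the mid-range of the few-percent coverages typical of
#'   sparse extraradical networks).
#' @param noise_speckle_frac fraction of image pixels flipped to foreground
#'   as salt noise after growth. Default 0.002.
#' @param rng_seed integer seed; identical parameters and seed give a
#'   bit-identical image. Default 1.
#' @return a validated list of class `synthetic_network_params`.
#' @seealso [generate_network()], [generate_gradient_series()]
#' @export
synthetic_network_params <- function(image_size_px = 640L,
                                     n_seeds = 10L,
                                     step_len_px = 4,
                                     angle_jitter_rad = 0.3,
                                     branch_prob = 0.05,
                                     fusion_prob = 0.5,
                                     strand_width_px = 2L,
                                     target_coverage_frac = 0.06,
                                     noise_speckle_frac = 0.002,
                                     rng_seed = 1L) {
  p <- list(image_size_px = as.integer(image_size_px),
            n_seeds = as.integer(n_seeds),
            step_len_px = as.numeric(step_len_px),
            angle_jitter_rad = as.numeric(angle_jitter_rad),
            branch_prob = as.numeric(branch_prob),
            fusion_prob = as.numeric(fusion_prob),
            strand_width_px = as.integer(strand_width_px),
            target_coverage_frac = as.numeric(target_coverage_frac),
            noise_speckle_frac = as.numeric(noise_speckle_frac),
            rng_seed = as.integer(rng_seed))
  if (p$image_size_px < 64L) stop("`image_size_px` must be >= 64")
  if (p$n_seeds < 0L) stop("`n_seeds` must be non-negative")
  if (p$step_len_px <= 0) stop("`step_len_px` must be positive")
  if (p$angle_jitter_rad < 0) stop("`angle_jitter_rad` must be non-negative")
  for (nm in c("branch_prob", "fusion_prob", "noise_speckle_frac")) {
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop("`", nm, "` must be in [0, 1]")
  }
  if (p$strand_width_px < 1L) stop("`strand_width_px` must be >= 1")
  if (p$target_coverage_frac <= 0 || p$target_coverage_frac >= 1)
    stop("`target_coverage_frac` must be in (0, 1)")
  class(p) <- "synthetic_network_params"
  p
}

# Pixel offsets of a centered square-ish stamp approximating a disc of
# diameter `width` px, used to thicken the 1-px growth trace.
stamp_offsets <- function(width) {
  if (width <= 1L) return(cbind(dr = 0L, dc = 0L))
  r <- (width - 1) / 2
  span <- seq.int(-floor(r + 0.5), floor(r + 0.5))
  g <- expand.grid(dr = span, dc = span)
  keep <- sqrt(g$dr^2 + g$dc^2) <= r + 0.5
  cbind(dr = as.integer(g$dr[keep]), dc = as.integer(g$dc[keep]))
}

# Integer pixel chain between two points (Bresenham), inclusive of both ends.
bresenham_line <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc) + 1L
  rr <- integer(n); cc <- integer(n)
  err <- dr - dc
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    rr[i] <- r; cc[i] <- c
    if (r == r1 && c == c1) { rr <- rr[1:i]; cc <- cc[1:i]; break }
    e2 <- 2L * err
    if (e2 > -dc) { err <- err - dc; r <- r + sr }
    if (e2 < dr) { err <- err + dr; c <- c + sc }
  }
  cbind(r = rr, c = cc)
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a synthetic hyphal-network image with known ground truth
#'
#' Grows a branching filamentous network (see [synthetic_network_params()]
#' for the growth model) and returns it as a binary [network_image].
#' Ground-truth metadata is attached in `$meta`:
#' \describe{
#'   \item{coverage_frac}{realized noise-free surface coverage}
#'   \item{skeleton_len_px}{total 1-px centreline length drawn}
#'   \item{branch_count}{number of bifurcation events}
#'   \item{fusion_count}{number of tip terminations by contact}
#'   \item{target_reached}{FALSE when all tips died before the coverage
#'     target (a flag, not an error)}
#'   \item{clean_pixels}{the noise-free mask (matrix), for validation}
#' }
#'
#' @param params a [synthetic_network_params()] object.
#' @return a binary [network_image] (0/1 pixels, salt noise included).
#' @export
generate_network <- function(params = synthetic_network_params()) {
  stopifnot(inherits(params, "synthetic_network_params"))
  with_private_seed(params$rng_seed, generate_network_impl(params))
}

generate_network_impl <- function(p) {
  n <- p$image_size_px
  canvas <- matrix(FALSE, n, n)        # thick painted mask
  skel <- matrix(FALSE, n, n)          # 1-px centreline trace
  stamp <- stamp_offsets(p$strand_width_px)
  total_px <- n * n
  target_px <- p$target_coverage_frac * total_px
  painted <- 0L
  skeleton_len <- 0L
  branch_count <- 0L
  fusion_count <- 0L

  # Seeds enter from the four image edges with inward headings, like hyphae
  # crossing a compartment barrier into the imaged field.
  n_tips <- p$n_seeds
  if (n_tips > 0L) {
    edge <- sample.int(4L, n_tips, replace = TRUE)
    along <- runif(n_tips, 1, n)
    tip_r <- ifelse(edge == 1L, 1, ifelse(edge == 2L, n, along))
    tip_c <- ifelse(edge == 3L, 1, ifelse(edge == 4L, n, along))
    inward <- c(0, pi, pi / 2, -pi / 2)[edge]  # heading in (row, col) space
    tip_th <- inward + runif(n_tips, -pi / 3, pi / 3)
    alive <- rep(TRUE, n_tips)
  } else {
    tip_r <- tip_c <- tip_th <- numeric(0)
    alive <- logical(0)
  }

  paint_segment <- function(r0, c0, r1, c1) {
    line <- bresenham_line(round(r0), round(c0), round(r1), round(c1))
    new_sk <- !skel[line]
    skel[line] <<- TRUE
    skeleton_len <<- skeleton_len + sum(new_sk)
    if (nrow(stamp) == 1L) {
      li <- (line[, 2] - 1L) * n + line[, 1]
    } else {
      pr <- rep(line[, 1], each = nrow(stamp)) + stamp[, 1]
      pc <- rep(line[, 2], each = nrow(stamp)) + stamp[, 2]
      ok <- pr >= 1L & pr <= n & pc >= 1L & pc <= n
      li <- unique((pc[ok] - 1L) * n + pr[ok])
    }
    fresh <- !canvas[li]
    canvas[li] <<- TRUE
    painted <<- painted + sum(fresh)
  }

  max_steps <- 500000L
  step <- 0L
  while (any(alive) && painted < target_px && step < max_steps) {
    step <- step + 1L
    i <- which(alive)[((step - 1L) %% sum(alive)) + 1L]
    th <- tip_th[i] + rnorm(1, 0, p$angle_jitter_rad)
    r1 <- tip_r[i] + p$step_len_px * cos(th)
    c1 <- tip_c[i] + p$step_len_px * sin(th)
    # reflect at the field boundary so growth stays in frame
    if (r1 < 1) { r1 <- 2 - r1; th <- pi - th }
    if (r1 > n) { r1 <- 2 * n - r1; th <- pi - th }
    if (c1 < 1) { c1 <- 2 - c1; th <- -th }
    if (c1 > n) { c1 <- 2 * n - c1; th <- -th }
    r1 <- min(max(r1, 1), n); c1 <- min(max(c1, 1), n)

    # anastomosis analogue: landing on an existing strand (not the pixel
    # the tip currently sits on) may terminate the tip
    tr <- round(r1); tc <- round(c1)
    contact <- skel[tr, tc] &&
      !(tr == round(tip_r[i]) && tc == round(tip_c[i]))
    paint_segment(tip_r[i], tip_c[i], r1, c1)
    tip_r[i] <- r1; tip_c[i] <- c1; tip_th[i] <- th
    if (contact && runif(1) < p$fusion_prob) {
      alive[i] <- FALSE
      fusion_count <- fusion_count + 1L
      next
    }
    if (runif(1) < p$branch_prob) {
      branch_count <- branch_count + 1L
      side <- sample(c(-1, 1), 1L)
      tip_r <- c(tip_r, r1); tip_c <- c(tip_c, c1)
      tip_th <- c(tip_th, th + side * (pi / 5 + rnorm(1, 0, p$angle_jitter_rad)))
      alive <- c(alive, TRUE)
    }
  }

  clean <- matrix(as.integer(canvas), n, n)
  pixels <- clean
  if (p$noise_speckle_frac > 0) {
    n_salt <- round(p$noise_speckle_frac * total_px)
    if (n_salt > 0) {
      salt <- sample.int(total_px, n_salt)
      pixels[salt] <- 1L
    }
  }
  network_image(
    pixels,
    provenance = sprintf("generate_network(seed=%d)", p$rng_seed),
    meta = list(
      coverage_frac = painted / total_px,
      skeleton_len_px = skeleton_len,
      branch_count = branch_count,
      fusion_count = fusion_count,
      target_reached = painted >= target_px,
      params = unclass(p),
      clean_pixels = clean
    )
  )
}

#' Generate a barrier-to-centre series of synthetic networks
#'
#' Emulates the spatial sampling scheme in which square regions of interest
#' are placed along the axis from the partner-compartment barrier towards the
#' centre of the fungus-only compartment: one image per location, with
#' ground-truth coverages following `coverage_fracs`. Position labels
#' 1..n run barrier to centre.
#'
#' @param params base [synthetic_network_params()]; `target_coverage_frac`
#'   and `rng_seed` are overridden per location.
#' @param n_locations number of locations (the field default is 3).
#' @param coverage_fracs numeric vector of length `n_locations`, each in
#'   (0,1): the coverage target at each location.
#' @return a list of binary [network_image]s, each with a `location` label
#'   in `$meta`.
#' @export
generate_gradient_series <- function(params = synthetic_network_params(),
                                     n_locations = 3L,
                                     coverage_fracs = c(0.04, 0.06, 0.08)) {
  stopifnot(inherits(params, "synthetic_network_params"))
  n_locations <- as.integer(n_locations)
  if (length(coverage_fracs) != n_locations)
    stop("`coverage_fracs` must have length `n_locations`")
  if (any(coverage_fracs <= 0 | coverage_fracs >= 1))
    stop("each coverage fraction must be in (0, 1)")
  lapply(seq_len(n_locations), function(i) {
    pi_ <- params
    pi_$target_coverage_frac <- coverage_fracs[i]
    # independent, reproducible stream per location
    pi_$rng_seed <- as.integer((params$rng_seed * 131L + i) %% .Machine$integer.max)
    img <- generate_network(pi_)
    img$meta$location <- i
    img
  })
}

#' Analytic fractal fixtures with known dimension
#'
#' Exact binary rasters whose mass fractal dimension and coverage are known
#' in closed form, used to validate the box-counting estimator:
#' \describe{
#'   \item{filled_square}{all foreground; dimension 2, coverage 1}
#'   \item{hline}{a single 1-px row; dimension 1, coverage 1/size}
#'   \item{single_pixel}{one foreground pixel; dimension 0}
#'   \item{sierpinski_carpet}{depth-k carpet (size must be 3^k);
#'     dimension log(8)/log(3) ~ 1.8928, coverage (8/9)^k}
#' }
#'
#' @param name one of `"filled_square"`, `"hline"`, `"single_pixel"`,
#'   `"sierpinski_carpet"`.
#' @param size_px square side in pixels; for the carpet it must be a power
#'   of 3.
#' @return a list of class `analytic_fixture` with fields `name`, `image`
#'   (integer 0/1 matrix), `true_dimension` and `true_coverage_frac`.
#' @export
make_fixture <- function(name, size_px = 640L) {
  supported <- c("filled_square", "hline", "single_pixel", "sierpinski_carpet")
  if (!is.character(name) || length(name) != 1L || !(name %in% supported))
    stop("unsupported fixture '", name, "'; supported: ",
         paste(supported, collapse = ", "))
  size_px <- as.integer(size_px)
  if (size_px < 1L) stop("`size_px` must be positive")
  if (name == "sierpinski_carpet") {
    k <- round(log(size_px) / log(3))
    if (3^k != size_px)
      stop("`size_px` must be a power of 3 for sierpinski_carpet (got ",
           size_px, ")")
    img <- matrix(1L, 1L, 1L)
    cell <- matrix(1L, 3L, 3L); cell[2L, 2L] <- 0L
    for (i in seq_len(k)) img <- kronecker(img, cell)
    dim_true <- log(8) / log(3)
    cov_true <- (8 / 9)^k
  } else if (name == "filled_square") {
    img <- matrix(1L, size_px, size_px)
    dim_true <- 2; cov_true <- 1
  } else if (name == "hline") {
    img <- matrix(0L, size_px, size_px)
    img[ceiling(size_px / 2), ] <- 1L
    dim_true <- 1; cov_true <- 1 / size_px
  } else { # single_pixel
    img <- matrix(0L, size_px, size_px)
    img[ceiling(size_px / 2), ceiling(size_px / 2)] <- 1L
    dim_true <- 0; cov_true <- 1 / size_px^2
  }
  structure(list(name = name, image = img, true_dimension = dim_true,
                 true_coverage_frac = cov_true),
            class = "analytic_fixture")
}
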