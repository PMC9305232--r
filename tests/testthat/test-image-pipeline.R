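test_that("binarization separates a bimodal image and is idempotent", {
  m <- matrix(10L, 20, 20); m[5:10, 5:10] <- 200L
  b <- binarize(network_image(m))
  expect_identical(b, matrix(as.integer(m == 200L), 20, 20))
  # already-binary input passes through unchanged
  expect_identical(binarize(b), b)
  expect_identical(binarize(binarize(network_image(m))), b)
})

test_that("fixed thresholding keeps pixels strictly above the cutoff", {
  ramp <- matrix(rep(0:255, each = 2), nrow = 2)
  b <- binarize(network_image(ramp), method = "fixed", fixed_threshold = 128)
  expect_identical(b, matrix(as.integer(ramp > 128), 2, 256))
  expect_error(binarize(network_image(ramp), method = "fixed"),
               "fixed_threshold")
})

test_that("constant images cannot be Otsu-thresholded", {
  expect_error(binarize(network_image(matrix(7L, 10, 10))), "constant")
})

test_that("polarity inversion flips foreground", {
  m <- matrix(200L, 10, 10); m[3, 3] <- 10L   # dark strand on bright field
  b <- binarize(network_image(m), invert = TRUE)
  expect_equal(sum(b), 1L)
  expect_equal(b[3, 3], 1L)
})

test_that("cleaning removes components below the size threshold", {
  m <- matrix(0L, 40, 40)
  m[5:14, 5:14] <- 1L              # 100-px component
  m[30, 30:32] <- 1L               # 3-px component
  cl <- clean_mask(m, min_cluster_px = 5)
  expect_equal(sum(cl$pixels), 100L)
  expect_equal(sum(cl$pixels[5:14, 5:14]), 100L)
  # threshold 1 is the identity when smoothing is off
  expect_identical(clean_mask(m, min_cluster_px = 1)$pixels, m)
  # empty mask passes through empty
  expect_equal(sum(clean_mask(matrix(0L, 8, 8))$pixels), 0L)
})

test_that("connectivity controls whether diagonal pixels form one cluster", {
  m <- matrix(0L, 6, 6); m[2, 2] <- 1L; m[3, 3] <- 1L
  # brute-force flood fill agrees on the component counts
  expect_equal(brute_component_count(m, 8L), 1L)
  expect_equal(brute_component_count(m, 4L), 2L)
  expect_equal(sum(clean_mask(m, min_cluster_px = 2, connectivity = 8)$pixels), 2L)
  expect_equal(sum(clean_mask(m, min_cluster_px = 2, connectivity = 4)$pixels), 0L)
})

test_that("component labelling matches brute-force flood fill on random masks", {
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(rbinom(24 * 24, 1, 0.25), 24, 24)
    for (conn in c(4L, 8L)) {
      lab <- myconet:::label_components(m, conn)
      expect_equal(max(lab), brute_component_count(m, conn))
      sizes <- attr(lab, "sizes")
      expect_equal(sum(sizes), sum(m))
    }
  }
})

test_that("closing bridges sub-radius gaps before cluster removal", {
  m <- matrix(0L, 20, 20)
  m[10, 2:9] <- 1L; m[10, 11:18] <- 1L     # 1-px gap in a strand
  cl <- clean_mask(m, min_cluster_px = 10, smoothing_radius_px = 1)
  expect_gte(sum(cl$pixels), 16L)          # strand survives as one cluster
  cl0 <- clean_mask(m, min_cluster_px = 10, smoothing_radius_px = 0)
  expect_equal(sum(cl0$pixels), 0L)        # both 8-px halves fall below 10
})

test_that("skeleton of a thick bar is a thin line of about its length", {
  bar <- matrix(0L, 60, 120); bar[30:34, 11:110] <- 1L
  sk <- skeletonize(bar)$pixels
  expect_true(all(sk <= bar))
  expect_gte(sum(sk), 100L - 5L)           # endpoint effects <= width
  expect_lte(sum(sk), 100L)
  # 1-px wide: no 2x2 block fully foreground
  blocks <- sk[-1, -1] + sk[-1, -ncol(sk)] + sk[-nrow(sk), -1] +
    sk[-nrow(sk), -ncol(sk)]
  expect_true(all(blocks < 4))
})

test_that("skeletonization is a no-op on an already-thin mask and on empty", {
  expect_equal(sum(skeletonize(matrix(0L, 10, 10))$pixels), 0L)
  img <- generate_network(small_net_params(3))
  sk <- skeletonize(clean_mask(img)$pixels)$pixels
  expect_identical(skeletonize(sk)$pixels, sk)
})

test_that("filled-disk skeleton agrees with an independent thinning oracle", {
  n <- 51L; ctr <- 26; rad <- 20
  disk <- outer(1:n, 1:n,
                function(r, c) as.integer((r - ctr)^2 + (c - ctr)^2 <= rad^2))
  sk <- skeletonize(disk)$pixels
  expect_lt(sum(sk), sum(disk) / 10)       # skeleton px << disk px
  expect_equal(brute_component_count(sk, 8L), 1L)
  # cross-check against scikit-image's thinning on the same raster
  tmp_in <- tempfile(fileext = ".txt"); tmp_out <- tempfile(fileext = ".txt")
  write.table(disk, tmp_in, row.names = FALSE, col.names = FALSE)
  script <- sprintf(paste0(
    "import numpy as np\nfrom skimage.morphology import skeletonize\n",
    "m = np.loadtxt('%s').astype(bool)\n",
    "s = skeletonize(m)\n",
    "open('%s','w').write(str(int(s.sum())) + '\\n')\n"), tmp_in, tmp_out)
  status <- system2("python", c("-c", shQuote(script)))
  expect_equal(status, 0L)
  oracle_px <- as.integer(readLines(tmp_out))
  expect_lte(abs(sum(sk) - oracle_px), 5L)
})

test_that("preprocessing chain is monotone: skeleton within clean within binary", {
  for (s in 1:5) {
    img <- generate_network(small_net_params(s))
    b <- binarize(img)
    cl <- clean_mask(b, smoothing_radius_px = 0)
    sk <- skeletonize(cl)
    expect_true(all(sk$pixels <= cl$pixels))
    expect_true(all(cl$pixels <= b))
  }
})

test_that("cleaning recovers the noise-free mask from specked images", {
  for (s in 1:10) {
    img <- generate_network(small_net_params(s))
    cl <- clean_mask(img)$pixels
    expect_gte(jaccard(cl, img$meta$clean_pixels), 0.99)
  }
})

test_that("ROI extraction crops exactly and enforces bounds", {
  set.seed(4)
  big <- network_image(matrix(sample(0:255, 2000 * 2000, TRUE), 2000, 2000),
                       pixel_size_um = 7.8125)
  crop <- extract_rois(big, list(roi_spec(c(0, 0), 640, label = 1)))[[1]]
  expect_identical(crop$pixels, big$pixels[1:640, 1:640])
  expect_equal(crop$pixel_size_um, 7.8125)
  expect_error(extract_rois(big, list(roi_spec(c(1500, 1500), 640))),
               "exceeds image bounds")
  three <- extract_rois(big, list(roi_spec(c(0, 0), 640, 1),
                                  roi_spec(c(0, 640), 640, 2),
                                  roi_spec(c(0, 1280), 640, 3)))
  expect_equal(vapply(three, function(x) x$meta$roi_label, integer(1)), 1:3)
})
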