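fixture_cfg <- function(...) {
  # analytic fixtures are noise-free rasters: count the mask itself and
  # keep every component (a single pixel is a valid fixture)
  pipeline_config(source = "clean_mask", min_cluster_px = 1L, ...)
}

test_that("pipeline config round-trips losslessly through YAML", {
  cfg <- pipeline_config(binarize_method = "fixed", fixed_threshold = 99,
                         min_cluster_px = 7L, connectivity = 4L,
                         smoothing_radius_px = 2L,
                         grid_sizes_px = c(4L, 8L, 16L),
                         anchor = "bottomright", source = "clean_mask",
                         roi_side_px = 128L, rng_seed = 12L)
  path <- tempfile(fileext = ".yaml")
  write_pipeline_config(cfg, path)
  expect_equal(read_pipeline_config(path), cfg)
  expect_error(pipeline_config(connectivity = 5), "4 or 8")
})

test_that("fixture preset reproduces the analytic dimensions end to end", {
  tab <- run_architecture_pipeline("fixtures", fixture_cfg())
  expect_equal(nrow(tab), 4L)
  by_img <- setNames(tab$D_m, tab$image)
  expect_equal(unname(by_img["filled_square"]), 2, tolerance = 1e-12)
  expect_equal(unname(by_img["hline"]), 1, tolerance = 1e-12)
  expect_equal(unname(by_img["single_pixel"]), 0, tolerance = 1e-12)
  expect_equal(unname(by_img["sierpinski_carpet"]), log(8) / log(3),
               tolerance = 0.02)   # default 8-64 px grids are not 3-aligned
  expect_true(all(c("N_s8", "N_s64", "config_hash", "version") %in% names(tab)))
  expect_equal(tab$coverage_percent[tab$image == "filled_square"], 100)
})

test_that("pipeline rejects empty input and reports unreadable files", {
  expect_error(run_architecture_pipeline(list(), pipeline_config()),
               "no readable")
  expect_message(
    expect_error(run_architecture_pipeline(c("/nonexistent/a.png"),
                                           pipeline_config()),
                 "no readable"),
    "skipping")
})

test_that("identical config and inputs give identical result tables", {
  cfg <- pipeline_config(rng_seed = 5L)
  t1 <- run_architecture_pipeline("gradient", cfg)
  t2 <- run_architecture_pipeline("gradient", cfg)
  expect_identical(t1, t2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_results_csv(t1, f1); write_results_csv(t2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("images survive a write/read PNG round trip", {
  img <- generate_network(small_net_params(21))
  path <- tempfile(fileext = ".png")
  write_network_image(img, path)
  back <- read_network_image(path)
  expect_identical(matrix(as.integer(back$pixels > 0), 320, 320), img$pixels)
  expect_true(file.exists(paste0(path, ".json")))   # ground-truth sidecar
})

test_that("assay pipeline chains calibration into efficiencies", {
  cal <- data.frame(strain = "A5",
                    copy_number = c(0.5, 1, 2, 3, 5) / 2e-6,
                    biomass_mg = c(0.5, 1, 2, 3, 5))
  assay <- data.frame(replicate_id = c("r1", "r2"),
                      strain = "A5",
                      qd_signal_focal_root = c(100, 90),
                      copies_focal_comp = c(2, 1.5) / 2e-6,
                      copies_focal_in_central = c(3, 1.5) / 2e-6)
  expect_message(res <- run_assay_pipeline(cal, assay),
                 "central-compartment biomass")
  expect_equal(res$calibration$slope, 2e-6, tolerance = 1e-12)
  expect_equal(res$efficiency$efficiency, c(100 / 5, 90 / 3),
               tolerance = 1e-9)
  # the same tables via CSV files
  cal_f <- tempfile(fileext = ".csv"); assay_f <- tempfile(fileext = ".csv")
  write.csv(cal, cal_f, row.names = FALSE)
  write.csv(assay, assay_f, row.names = FALSE)
  res2 <- suppressMessages(run_assay_pipeline(cal_f, assay_f))
  expect_equal(res2$efficiency$efficiency, res$efficiency$efficiency)
})

test_that("assay pipeline names missing columns and skips unfittable strains", {
  cal <- data.frame(strain = c("A5", "A5", "B12"),
                    copy_number = c(1e5, 1e6, 2e5),
                    biomass_mg = c(0.5, 4, 1))
  assay_bad <- data.frame(replicate_id = "r1", strain = "A5",
                          qd_signal_focal_root = 10)
  expect_error(suppressWarnings(run_assay_pipeline(cal, assay_bad)),
               "copies_focal_comp")
  assay_ok <- data.frame(replicate_id = "r1",
                         qd_signal_focal_root = 10,
                         biomass_focal_comp_mg = 1,
                         biomass_focal_in_central_mg = 1)
  expect_warning(res <- run_assay_pipeline(cal, assay_ok), "B12")
  expect_equal(res$calibration$strain, "A5")
  expect_equal(res$efficiency$efficiency, 5)
})

test_that("the myconet CLI writes byte-identical tables for repeat runs", {
  cli <- system.file("cli", "myconet", package = "myconet")
  expect_true(nzchar(cli))
  cfg_f <- tempfile(fileext = ".yaml")
  write_pipeline_config(fixture_cfg(rng_seed = 5L), cfg_f)
  out1 <- tempfile(fileext = ".csv"); out2 <- tempfile(fileext = ".csv")
  libs <- paste0("R_LIBS=", paste(.libPaths(), collapse = ":"))
  s1 <- system2("Rscript", c(cli, "quantify", "--preset", "fixtures",
                             "--config", cfg_f, "--out", out1),
                stdout = FALSE, stderr = FALSE, env = libs)
  s2 <- system2("Rscript", c(cli, "quantify", "--preset", "fixtures",
                             "--config", cfg_f, "--out", out2),
                stdout = FALSE, stderr = FALSE, env = libs)
  expect_equal(s1, 0L)
  expect_equal(s2, 0L)
  expect_identical(readBin(out1, "raw", file.size(out1)),
                   readBin(out2, "raw", file.size(out2)))
  tab <- read.csv(out1)
  expect_equal(nrow(tab), 4L)
})
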