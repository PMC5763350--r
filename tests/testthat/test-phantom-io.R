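test_that("noiseless phantoms reproduce the forward model voxel by voxel", {
  p <- baseline_protocol()
  spec <- phantom_spec(list(list(t1 = 900, t2 = 50, rho = 10)),
                       dim = c(4, 4, 2), kappa_range = c(1, 1))
  ph <- make_phantom(spec, p, noise = NULL, seed = 1)
  y_ref <- jsr_forward(theta_vector(10, 0, 900, 50, 0), p)
  for (v in seq_len(nrow(ph$images)))
    expect_equal(unname(ph$images[v, ]), y_ref, tolerance = 1e-12)
  # background voxels are signal-free
  lm <- array(0L, c(4, 4, 2)); lm[1:2, , ] <- 1L
  spec_bg <- phantom_spec(list(list(t1 = 900, t2 = 50)), dim = c(4, 4, 2),
                          label_map = lm, kappa_range = c(1, 1))
  ph_bg <- make_phantom(spec_bg, p, noise = NULL)
  expect_true(all(ph_bg$images[as.vector(lm) == 0, ] == 0))
  # labels outside the class range are rejected
  bad <- lm; bad[1] <- 3L
  expect_error(phantom_spec(list(list(t1 = 900, t2 = 50)), c(4, 4, 2),
                            label_map = bad), "label_map")
})

test_that("phantom generation is bit-reproducible per seed", {
  p <- baseline_protocol()
  spec <- phantom_spec(list(list(t1 = 2058, t2 = 185), list(t1 = 900, t2 = 50)),
                       dim = c(6, 4, 2))
  a <- make_phantom(spec, p, noise_model(rel = 0.02), seed = 42)
  b <- make_phantom(spec, p, noise_model(rel = 0.02), seed = 42)
  expect_identical(a$images, b$images)
  c <- make_phantom(spec, p, noise_model(rel = 0.02), seed = 43)
  expect_false(identical(a$images, c$images))
})

test_that("voxelwise fitting recovers a noiseless phantom and honours mask and chunking", {
  p <- baseline_protocol()
  spec <- phantom_spec(list(list(t1 = 900, t2 = 50, rho = 10, d_omega = 15)),
                       dim = c(4, 3, 2))
  ph <- make_phantom(spec, p, noise = NULL)
  maps <- voxelwise_fit(ph$images, p, kappa_map = ph$kappa_map,
                        dim = spec$dim)
  expect_equal(dim(maps$t1), c(4L, 3L, 2L))
  expect_true(all(abs(maps$t1 - 900) / 900 < 1e-6))
  expect_true(all(abs(maps$t2 - 50) / 50 < 1e-6))
  expect_true(all(abs(maps$d_omega - 15) / 15 < 1e-6))
  expect_true(all(maps$converged == 1))
  # all-false mask: nothing fitted
  empty <- voxelwise_fit(ph$images, p, kappa_map = ph$kappa_map,
                         mask = array(FALSE, spec$dim), dim = spec$dim)
  expect_true(all(is.na(empty$t1)))
  # chunked and serial execution agree bit-exactly
  m1 <- voxelwise_fit(ph$images, p, ph$kappa_map, chunk_size = 5, dim = spec$dim)
  expect_identical(m1, maps)
  expect_error(voxelwise_fit(ph$images[, 1:7], p), "channels")
})

test_that("a noisy single-class phantom yields an unbiased unimodal T1 distribution", {
  p <- baseline_protocol()
  spec <- phantom_spec(list(list(t1 = 900, t2 = 50, rho = 10)),
                       dim = c(8, 8, 2), kappa_range = c(1, 1))
  ph <- make_phantom(spec, p, noise_model(rel = 0.002), seed = 9)
  maps <- voxelwise_fit(ph$images, p, dim = spec$dim)
  t1s <- maps$t1[is.finite(maps$t1)]
  se <- stats::sd(t1s) / sqrt(length(t1s))
  expect_lt(abs(stats::median(t1s) - 900), 3 * se * sqrt(pi / 2))
  h <- hist(t1s, breaks = "FD", plot = FALSE)
  expect_equal(which.max(h$counts) %in%
                 which(h$counts > 0.5 * max(h$counts)), TRUE)
})

test_that("protocols, maps and tables round-trip losslessly", {
  p <- baseline_protocol(t_rf_ms = 0.6)
  for (ext in c(".yaml", ".json")) {
    tf <- tempfile(fileext = ext)
    write_protocol(p, tf)
    back <- read_protocol(tf)
    expect_equal(unclass(back), unclass(p), tolerance = 1e-12)
    unlink(tf)
  }
  # malformed protocol file names the missing field
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(sequences = list(list(kind = "spgr", tr_ms = 5))), tf)
  expect_error(read_protocol(tf), "flip_deg")
  unlink(tf)
  # NIfTI float32 round trip
  set.seed(5)
  arr <- array(stats::rnorm(4 * 3 * 2, sd = 100), c(4, 3, 2))
  nf <- tempfile(fileext = ".nii.gz")
  write_nifti_map(arr, nf)
  back <- read_nifti_map(nf)
  expect_equal(dim(back), dim(arr))
  expect_lt(max(abs(back - arr) / pmax(abs(arr), 1)), 1e-6)
  unlink(nf)
  # phantom persistence writes readable volumes and sidecar
  spec <- phantom_spec(list(list(t1 = 900, t2 = 50)), dim = c(4, 3, 2))
  od <- tempfile()
  ph <- make_phantom(spec, baseline_protocol(), noise_model(rel = 0.02),
                     seed = 3, out_dir = od)
  expect_true(file.exists(file.path(od, "image_spgr01.nii.gz")))
  expect_true(file.exists(file.path(od, "phantom.json")))
  img1 <- read_nifti_map(file.path(od, "image_spgr01.nii.gz"))
  expect_lt(max(abs(as.vector(img1) - ph$images[, 1])), 1e-5)
  side <- jsonlite::read_json(file.path(od, "phantom.json"))
  expect_equal(side$seed, 3)
  unlink(od, recursive = TRUE)
})
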