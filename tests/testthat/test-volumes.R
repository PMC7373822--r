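# Volume / label / field containers and NIfTI round trips

test_that("volume and label NIfTI round trips are lossless", {
  set.seed(1)
  v <- volume(array(rnorm(4^3)^2, dim = c(4, 4, 4)),
              spacing = c(1.5, 2, 2.5), origin = c(-10, 5, 2))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  back <- read_volume(path)
  expect_identical(back$data, v$data)
  expect_equal(back$spacing, v$spacing)
  expect_equal(back$origin, v$origin)

  zeros <- volume(array(0, dim = c(4, 4, 4)))
  write_volume(zeros, path)
  expect_identical(read_volume(path)$data, zeros$data)

  lab <- label_volume(array(sample(0:4, 4^3, TRUE), dim = c(4, 4, 4)),
                      label_names = c(`1` = "csf", `2` = "gm"))
  lpath <- withr::local_tempfile(fileext = ".nii.gz")
  write_labels(lab, lpath)
  lback <- read_labels(lpath)
  expect_identical(lback$labels, lab$labels)
  expect_true(is.integer(lback$labels))
  expect_equal(unlist(lback$label_names), unlist(lab$label_names))
})

test_that("displacement-field round trips preserve every component", {
  zpath <- withr::local_tempfile(fileext = ".nii.gz")
  z <- zero_field(c(8, 8, 8))
  write_field(z, zpath)
  expect_identical(read_field(zpath)$vectors, z$vectors)

  const <- array(0, dim = c(8, 8, 8, 3))
  const[, , , 1] <- 1.5; const[, , , 2] <- -2
  f <- disp_field(const)
  write_field(f, zpath)
  expect_identical(read_field(zpath)$vectors, f$vectors)

  set.seed(2)
  r <- disp_field(array(rnorm(8^3 * 3), dim = c(8, 8, 8, 3)))
  write_field(r, zpath)
  expect_identical(read_field(zpath)$vectors, r$vectors)
})

test_that("malformed inputs are rejected", {
  expect_error(volume(matrix(1:4, 2)), "3")
  expect_error(volume(array(c(1, NA), dim = c(2, 1, 1))), "finite")
  expect_error(volume(array(1, dim = c(2, 2, 2)), spacing = c(-1, 1, 1)), "spacing")
  expect_error(label_volume(array(-1, dim = c(2, 2, 2))), "non-negative")
  expect_error(label_volume(array(0.5, dim = c(2, 2, 2))), "integer")
  expect_error(disp_field(array(0, dim = c(4, 4, 4, 2))), "3")
  expect_error(read_volume(file.path(tempdir(), "no-such-file.nii")), "not found")
  # a 2D NIfTI is not a 3D volume
  img2d <- RNifti::asNifti(matrix(rnorm(16), 4))
  p <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(img2d, p)
  expect_error(read_volume(p), "3")
  # a 2-component vector file is not a displacement field
  img4d <- RNifti::asNifti(array(0, dim = c(4, 4, 4, 2)))
  RNifti::writeNifti(img4d, p)
  expect_error(read_field(p), "vector")
})

test_that("histogram matching is a monotone quantile map with the right fixed points", {
  set.seed(3)
  ref <- volume(array(rgamma(20^3, 2), dim = c(20, 20, 20)))
  # fixed point: matching an image to itself changes (almost) nothing
  same <- histogram_match(ref, ref)
  expect_lt(max(abs(same$data - ref$data)), 1e-8)
  # a pure intensity shift is undone up to quantization
  shifted <- volume(ref$data + 10)
  matched <- histogram_match(shifted, ref)
  dev <- quantile(matched$data, 1:9 / 10) - quantile(ref$data, 1:9 / 10)
  binw <- diff(range(ref$data)) / 256
  expect_lt(max(abs(dev)), binw)
  # monotone: intensity order is preserved
  ord <- order(shifted$data)
  expect_true(all(diff(matched$data[ord]) >= -1e-12))
  # idempotent up to one quantization bin per decile
  again <- histogram_match(matched, ref)
  dev2 <- quantile(again$data, 1:9 / 10) - quantile(matched$data, 1:9 / 10)
  expect_lt(max(abs(dev2)), binw)
  expect_error(histogram_match(volume(array(1, dim = c(3, 3, 3))), ref), "constant")
})

test_that("default mask falls back to positive intensities", {
  d <- array(0, dim = c(3, 3, 3))
  d[2, 2, 2] <- 5
  expect_equal(sum(default_mask(volume(d))), 1)
  m <- array(TRUE, dim = c(3, 3, 3))
  expect_equal(sum(default_mask(volume(d, mask = m))), 27)
})
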