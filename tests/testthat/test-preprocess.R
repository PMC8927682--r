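test_that("gamma correction obeys the power law and its edge cases", {
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_equal(fv_gamma_correct(img, 1), img)
  expect_equal(fv_gamma_correct(array(0.25, c(4, 4, 3)), 2),
               array(0.0625, c(4, 4, 3)))
  expect_equal(fv_gamma_correct(array(0, c(4, 4, 3)), 3.7),
               array(0, c(4, 4, 3)))
  # order-preserving per pixel for a fixed gamma
  a <- matrix(sort(runif(50)), 5, 10)
  out <- fv_gamma_correct(a, 1.8)
  expect_true(all(diff(as.numeric(out)) >= 0))
  expect_error(fv_gamma_correct(img, 0), "positive")
  expect_error(fv_gamma_correct(img, -2), "positive")
})

test_that("green channel selection returns plane 2 unchanged", {
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  expect_identical(fv_green_channel(img), img[, , 2])
  grey <- array(rep(img[, , 1], 3), c(8, 8, 3))
  expect_identical(fv_green_channel(grey), img[, , 1])
  expect_error(fv_green_channel(img[, , 1:2]), "RGB")
  expect_error(fv_green_channel(matrix(0, 8, 8)), "RGB")
})

test_that("CLAHE keeps range, handles degenerate input, increases contrast", {
  const <- matrix(0.5, 64, 64)
  expect_equal(fv_clahe(const), const)
  set.seed(1)
  noisy <- matrix(runif(96 * 96), 96, 96)
  out <- fv_clahe(noisy)
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(out, fv_clahe(noisy))  # deterministic
  # a low-contrast two-valued plane: the value gap must not shrink
  two <- matrix(0.4, 96, 96)
  two[, 49:96] <- 0.6
  res <- fv_clahe(two)
  gap_before <- 0.2
  gap_after <- mean(res[, 49:96]) - mean(res[, 1:48])
  expect_gte(gap_after, gap_before - 1e-8)
  expect_error(fv_clahe(noisy, clip_limit = 0), "positive")
})

test_that("field-of-view masking zeroes exactly the outside pixels", {
  plane <- matrix(runif(36), 6, 6)
  ones <- matrix(1, 6, 6)
  zeros <- matrix(0, 6, 6)
  expect_equal(fv_apply_field_mask(plane, ones), plane)
  expect_equal(fv_apply_field_mask(plane, zeros), zeros)
  single <- zeros; single[3, 4] <- 1
  out <- fv_apply_field_mask(plane, single)
  expect_equal(sum(out != 0), 1L)
  expect_equal(out[3, 4], plane[3, 4])
  expect_error(fv_apply_field_mask(plane, matrix(1, 5, 6)), "shape")
})

test_that("patch grid enumerates stride origins plus a border-flush origin", {
  g <- fv_patch_grid(c(224, 224))
  expect_equal(nrow(g$origins), 1L)
  g <- fv_patch_grid(c(352, 352))
  expect_equal(sort(unique(g$origins[, "row"])), c(0L, 64L, 128L))
  expect_equal(nrow(g$origins), 9L)
  g <- fv_patch_grid(c(300, 300))
  expect_equal(sort(unique(g$origins[, "row"])), c(0L, 64L, 76L))
  expect_equal(nrow(g$origins), 9L)
  expect_error(fv_patch_grid(c(200, 224)), "smaller")
  # brute-force origin enumeration over assorted extents
  for (n in c(224, 230, 288, 300, 352, 500)) {
    g <- fv_patch_grid(c(n, n))
    expect_equal(sort(unique(g$origins[, "row"])),
                 sort(oracle_origins(n, 224L, 64L)))
  }
})

test_that("every pixel is covered and reassembly round-trips", {
  set.seed(4)
  for (n in c(160L, 300L)) {
    plane <- matrix(runif(n * n), n, n)
    g <- fv_patch_grid(c(n, n), template = 64L, stride = 48L)
    patches <- fv_extract_patches(plane, NULL, g)
    # coverage
    cov <- matrix(0, n, n)
    for (i in seq_along(patches)) {
      o <- g$origins[i, ]
      cov[o[1] + 1:64, o[2] + 1:64] <- cov[o[1] + 1:64, o[2] + 1:64] + 1
    }
    expect_true(all(cov >= 1))
    # round trip within 1e-6
    back <- fv_reassemble(lapply(patches, `[[`, "patch"), g)
    expect_lt(max(abs(back - plane)), 1e-6)
  }
})

test_that("reassembly averages overlapping patches", {
  g <- fv_patch_grid(c(64, 64), template = 64L, stride = 64L)
  one <- fv_reassemble(list(matrix(0.3, 64, 64)), g)
  expect_equal(one, matrix(0.3, 64, 64))
  expect_error(fv_reassemble(list(matrix(0, 64, 64), matrix(0, 64, 64)), g),
               "origins")
})

test_that("patch masks are cropped binary and aligned with their patch", {
  n <- 160L
  plane <- matrix(runif(n * n), n, n)
  mask <- matrix(rbinom(n * n, 1, 0.1), n, n)
  g <- fv_patch_grid(c(n, n), template = 64L, stride = 48L)
  ps <- fv_extract_patches(plane, mask, g)
  i <- 5L
  o <- g$origins[i, ]
  expect_identical(ps[[i]]$mask, mask[o[1] + 1:64, o[2] + 1:64])
  expect_true(all(ps[[i]]$mask %in% c(0, 1)))
})

test_that("patch fixtures round-trip through PNG plus manifest", {
  n <- 96L
  set.seed(8)
  plane <- matrix(runif(n * n), n, n)
  mask <- matrix(rbinom(n * n, 1, 0.15), n, n)
  g <- fv_patch_grid(c(n, n), template = 64L, stride = 32L)
  dir <- file.path(tempdir(), "patch-fixtures")
  man <- fv_write_patches(plane, mask, g, dir, id = "t1")
  tab <- read.csv(file.path(dir, "t1_patches.csv"))
  expect_equal(nrow(tab), nrow(g$origins))
  expect_equal(tab$template[1], 64L)
  expect_equal(tab$stride[1], 32L)
  # binary masks survive the 8-bit PNG round trip exactly
  m1 <- fv_read_mask(file.path(dir, tab$mask_file[1]))
  expect_equal(m1, mask[1:64, 1:64])
})
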