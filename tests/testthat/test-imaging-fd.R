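test_that("auto schedule halves from the smallest dimension down to 1", {
  expect_identical(auto_box_sizes(27), c(27L, 13L, 6L, 3L, 1L))
  expect_identical(auto_box_sizes(64), c(64L, 32L, 16L, 8L, 4L, 2L, 1L))
  expect_identical(auto_box_sizes(2), c(2L, 1L))
})

test_that("box counts are exact on lattice-aligned phantoms", {
  cube <- gen_fractal_phantom("cube", size = 64)
  bc <- box_count(cube, sizes = c(64, 32, 16, 8, 4, 2, 1))
  expect_equal(bc$count, (64 / bc$size)^3)

  line <- gen_fractal_phantom("line", size = 64)
  bl <- box_count(line, sizes = c(64, 32, 16, 8, 4, 2, 1))
  expect_equal(bl$count, 64 / bl$size)

  menger <- gen_fractal_phantom("menger", level = 3)
  bm <- box_count(menger, sizes = c(27, 9, 3, 1))
  expect_equal(bm$count, c(1, 20, 400, 8000))
})

test_that("box_count rejects invalid sizes and empty masks", {
  m <- gen_fractal_phantom("cube", size = 8)
  expect_error(box_count(m, sizes = c(9)), "exceeds")
  expect_error(box_count(m, sizes = c(0)), ">= 1")
  expect_error(box_count(array(0L, c(4, 4, 4))), "empty mask")
})

test_that("box_count matches the brute-force box scanner on random masks", {
  for (seed in 1:10) {
    g <- random_mask(seed, max_dim = 20L)
    if (!any(g != 0)) g[1, 1, 1] <- 1L
    sizes <- auto_box_sizes(min(dim(g)))
    bc <- box_count(g, sizes = sizes)
    oracle <- vapply(sizes, function(s) brute_box_count(g, s), integer(1))
    expect_equal(bc$count, as.numeric(oracle))
  }
})

test_that("box counts never decrease as the box size shrinks", {
  for (seed in 11:16) {
    g <- random_mask(seed, max_dim = 24L)
    if (!any(g != 0)) g[2, 2, 2] <- 1L
    bc <- box_count(g)  # auto: sizes descending
    expect_true(all(diff(bc$count) >= 0))
  }
})

test_that("log-log fit recovers analytic dimensions", {
  menger <- fit_fd(c(27, 9, 3, 1), c(1, 20, 400, 8000))
  expect_equal(menger$fd, log(20) / log(3), tolerance = 1e-10)
  expect_equal(menger$fit_r2, 1.0, tolerance = 1e-12)

  cube <- fit_fd(c(64, 32, 16, 8, 4, 2, 1), (64 / c(64, 32, 16, 8, 4, 2, 1))^3)
  expect_equal(cube$fd, 3.0, tolerance = 1e-10)

  line <- fit_fd(c(64, 32, 16, 8, 4, 2, 1), 64 / c(64, 32, 16, 8, 4, 2, 1))
  expect_equal(line$fd, 1.0, tolerance = 1e-10)
})

test_that("fit_fd enforces its preconditions", {
  expect_error(fit_fd(c(4, 2), c(1, 8)), "at least 3 scales")
  expect_error(fit_fd(c(4, 2, 1), c(0, 2, 4)), "strictly positive")
  expect_error(fit_fd(c(4, 2, 1), c(1, 2)), "equal length")
})

test_that("padding by a common multiple of the box sizes leaves FD exactly unchanged", {
  # lattice-commensurate translation: every box boundary moves with the
  # object, so each per-size count (and hence the slope) is preserved
  phantoms <- list(gen_fractal_phantom("menger", level = 3),
                   gen_fractal_phantom("cube", size = 27),
                   gen_fractal_phantom("line", size = 27))
  sizes <- c(9, 3, 1)
  for (m in phantoms) {
    f0 <- mask_fd(m, "volume", sizes = sizes)
    f1 <- mask_fd(pad_mask(m, 9), "volume", sizes = sizes)
    expect_equal(f1$counts, f0$counts)
    expect_equal(f1$fd, f0$fd, tolerance = 1e-12)
  }
})

test_that("extract_roi_mask selects exactly the requested label", {
  g <- array(0L, c(14, 14, 14))
  g[3:12, 3:12, 3:12] <- 1L
  lm <- roi_labelmap(g, data.frame(label = c(1, 2), region = c("cube", "ghost")))
  m <- extract_roi_mask(lm, 1)
  expect_equal(sum(m$grid), 1000)
  expect_true(all(m$grid[g == 1L] == 1L))
  expect_error(extract_roi_mask(lm, 2), "empty ROI")
  expect_error(extract_roi_mask(lm, 7), "not present")
})

test_that("per-label voxel counts match a brute-force tally on a random phantom", {
  set.seed(21)
  g <- array(sample(0:3, 17^3, replace = TRUE), dim = c(17, 17, 17))
  lm <- roi_labelmap(g, data.frame(label = 1:3, region = paste0("r", 1:3)))
  for (lab in 1:3) {
    tally <- sum(g == lab)  # brute-force tally of the label array
    expect_equal(sum(extract_roi_mask(lm, lab)$grid), tally)
  }
})

test_that("boundary extraction keeps 6-neighbour surface voxels only", {
  cube10 <- pad_mask(gen_fractal_phantom("cube", size = 10), 3)
  b <- extract_boundary(cube10)
  expect_equal(sum(b$grid), 10^3 - 8^3)  # 488
  expect_true(all(b$grid <= cube10$grid))  # boundary is a subset of the mask

  single <- array(0L, c(5, 5, 5)); single[3, 3, 3] <- 1L
  expect_equal(extract_boundary(single)$grid, array(as.integer(single != 0), c(5, 5, 5)))

  shell <- gen_fractal_phantom("shell", size = 12)
  expect_equal(extract_boundary(shell)$grid, shell$grid)  # idempotent on shells

  # second application never grows the voxel count
  for (seed in 31:34) {
    g <- random_mask(seed, max_dim = 16L, density = 0.4)
    if (!any(g != 0)) g[1, 1, 1] <- 1L
    b1 <- extract_boundary(g)
    expect_lte(sum(extract_boundary(b1)$grid), sum(b1$grid))
  }
  expect_error(extract_boundary(array(0L, c(4, 4, 4))), "empty")
})

test_that("regional FD covers every region and records failures", {
  g <- array(1L, c(64, 64, 64))
  lm <- roi_labelmap(g, data.frame(label = c(1, 9), region = c("cube", "missing")))
  fd <- compute_regional_fd(lm, surface_mode = "volume",
                            sizes = c(64, 32, 16, 8, 4, 2, 1))
  expect_equal(unname(fd["cube"]), 3.0, tolerance = 1e-10)
  expect_true(is.na(fd["missing"]))
  expect_match(attr(fd, "failures")[["missing"]], "empty ROI")

  # boundary shell of a solid cube is a 2-D surface; the fit is restricted
  # to the scaling regime (fine scales) where surface scaling dominates
  fdb <- compute_regional_fd(lm, surface_mode = "boundary",
                             sizes = c(8, 4, 2, 1))
  expect_equal(unname(fdb["cube"]), 2.0, tolerance = 0.15)

  empty <- roi_labelmap(array(0L, c(8, 8, 8)),
                        data.frame(label = 1, region = "void"))
  expect_error(compute_regional_fd(empty), "all regions empty")
})

test_that("a 90-region blob labelmap yields 90 finite FD values", {
  lm <- gen_blob_labelmap(n_regions = 90, grid_size = 96, seed = 7)
  fd <- compute_regional_fd(lm)
  expect_length(fd, 90)
  expect_true(all(is.finite(fd)))
  expect_identical(names(fd), aal90_labels()$region)
})

test_that("NIfTI round trip preserves the label grid and spacing", {
  lm <- gen_blob_labelmap(n_regions = 8, grid_size = 32, seed = 3)
  lm$spacing <- c(0.5, 0.5, 1)  # anisotropic voxels occur in practice
  path <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(lm, path)
  back <- read_labelmap(path, label_table = lm$label_table)
  expect_equal(back$grid, lm$grid)
  expect_equal(back$spacing, lm$spacing, tolerance = 1e-6)
  unlink(path)
})

test_that("fd_table binds subjects and enforces a shared region set", {
  maps <- list(s1 = gen_blob_labelmap(8, 32, seed = 1),
               s2 = gen_blob_labelmap(8, 32, seed = 2))
  tab <- fd_table(maps, surface_mode = "volume")
  expect_equal(names(tab)[1], "subject_id")
  expect_equal(nrow(tab), 2)
  expect_equal(ncol(tab), 9)
  path <- tempfile(fileext = ".csv")
  write_fd_table(tab, path)
  expect_equal(read_fd_table(path), tab, tolerance = 1e-12)
  unlink(path)
})
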