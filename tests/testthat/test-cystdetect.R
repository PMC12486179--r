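# The void-extraction chain: binarization window, total/empty partition,
# minimum-diameter size filter (both restore modes), labelling and the
# summary panel.

test_that("binarization window is inclusive at both ends", {
  v <- voxel_volume(array(100L, c(4, 4, 4)), 0.5)
  expect_true(all(binarize_bone(v)$values))
  v89 <- voxel_volume(array(89L, c(4, 4, 4)), 0.5)
  expect_false(any(binarize_bone(v89, lo = 90)$values))
  v90 <- voxel_volume(array(90L, c(4, 4, 4)), 0.5)
  expect_true(all(binarize_bone(v90, lo = 90)$values))
  expect_error(binarize_bone(v, lo = 200, hi = 100), "exceed")
})

test_that("noiseless phantom binarization reproduces the bone truth", {
  spec <- phantom_spec(head_radius = 6, voxel_size = 0.25,
                       cysts = list(list(centre = c(0, 0, 0), diameter = 2)),
                       noise_sd = 0, blur_sigma = 0, seed = 5)
  g <- generate_head(spec)
  expect_identical(binarize_bone(g$volume)$values, g$truth$bone_mask$values)
})

test_that("total region fills the envelope and matches the analytic head volume", {
  solid <- ball_mask(3, 0.25)
  expect_identical(total_region(solid)$values, solid$values)
  shell <- ball_mask(3, 0.25)
  inner <- ball_mask(2.2, 0.25, pad_vox = 4 + round(0.8 / 0.25))
  shell$values <- shell$values & !inner$values
  expect_identical(total_region(shell)$values, ball_mask(3, 0.25)$values)

  spec <- phantom_spec(head_radius = 6, voxel_size = 0.25, seed = 3)
  g <- generate_head(spec)
  tot <- total_region(binarize_bone(g$volume))
  expect_lt(abs(mask_volume(tot) / (4 / 3 * pi * 6^3) - 1), 0.02)
  expect_true(all(tot$values[binarize_bone(g$volume)$values]))
  expect_error(total_region(binary_mask(array(FALSE, c(4, 4, 4)), 1)), "empty")
})

test_that("empty regions partition the total region against bone", {
  b <- ball_mask(2, 0.25)
  tot <- ball_mask(2, 0.25)
  expect_equal(sum(empty_regions(tot, b)$values), 0)
  none <- binary_mask(array(FALSE, dim(tot$values)), 0.25, tot$origin)
  expect_identical(empty_regions(tot, none)$values, tot$values)
  # partition laws on a random bone subset
  set.seed(1)
  sub <- tot
  sub$values <- tot$values & (array(runif(length(tot$values)), dim(tot$values)) < 0.5)
  emp <- empty_regions(tot, sub)
  expect_equal(sum(emp$values & sub$values), 0)
  expect_identical(emp$values | sub$values, tot$values)
  wrong <- binary_mask(array(FALSE, c(3, 3, 3)), 0.25)
  expect_error(empty_regions(tot, wrong), "grid mismatch")
})

test_that("size filter drops sub-threshold voids and restores survivors exactly", {
  small <- ball_mask(0.4, 0.1)      # 0.8 mm diameter
  expect_equal(sum(size_filter(small)$values), 0)
  big <- ball_mask(1.0, 0.1)        # 2.0 mm diameter
  for (mode in c("reconstruction", "opening"))
    expect_identical(size_filter(big, restore = mode)$values, big$values)
  expect_error(size_filter(big, min_diameter = 0.9, step = 0.5), "2 \\* k \\* step")
})

test_that("a thin-necked dumbbell survives whole under reconstruction", {
  h <- 0.1
  n <- c(61, 25, 25)
  ax <- list((seq_len(n[1]) - 31) * h, (seq_len(n[2]) - 13) * h,
             (seq_len(n[3]) - 13) * h)
  D <- function(c0) outer(outer((ax[[1]] - c0)^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  dumb <- D(-1.5) <= 1 | D(1.5) <= 1
  neck <- array(FALSE, n)
  yz2 <- outer(ax[[2]]^2, ax[[3]]^2, `+`)
  for (i in which(abs(ax[[1]]) <= 1.5)) neck[i, , ] <- yz2 <= 0.3^2
  dumb <- binary_mask(dumb | neck, h)
  filt <- size_filter(dumb, restore = "reconstruction")
  expect_identical(filt$values, dumb$values)                   # neck refilled
  expect_equal(max(label_components(filt)$values), 1L)         # one component
})

test_that("size filter is idempotent and equals the brute-force oracle", {
  for (seed in 1:8) {
    m <- random_void_mask(n = 28, h = 0.25, seed = seed)
    got <- size_filter(m, restore = "reconstruction")
    expect_identical(size_filter(got, restore = "reconstruction")$values, got$values)
    want <- oracle_size_filter(m$values, 0.25, 1.0)
    expect_identical(got$values, want)
  }
})

test_that("labelling excludes exterior-touching voids and honours connectivity", {
  h <- 0.25
  tot <- ball_mask(4, h)
  d <- dim(tot$values)
  ax <- (seq_len(d[1]) - (d[1] + 1) / 2) * h
  D <- function(c0) outer(outer((ax - c0[1])^2, (ax - c0[2])^2, `+`),
                          (ax - c0[3])^2, `+`)
  interior <- binary_mask(D(c(0, 0, 0)) <= 1^2, h, tot$origin)  # interior cyst
  notch <- binary_mask(D(c(0, 0, 4)) <= 1^2 & tot$values, h, tot$origin)
  both <- interior
  both$values <- interior$values | notch$values
  lab <- label_cysts(both, tot)
  expect_equal(nrow(lab$records), 1)
  expect_false(lab$records$touches_exterior)
  lab2 <- label_cysts(both, tot, include_surface_voids = TRUE)
  expect_equal(nrow(lab2$records), 2)
  expect_equal(sum(lab2$records$touches_exterior), 1)

  # two cubes sharing one corner: 26-connectivity joins, 6 splits
  arr <- array(FALSE, c(12, 12, 12))
  arr[2:5, 2:5, 2:5] <- TRUE
  arr[6:9, 6:9, 6:9] <- TRUE
  corner <- binary_mask(arr, 1)
  expect_equal(max(label_components(corner, 26)$values), 1L)
  expect_equal(max(label_components(corner, 6)$values), 2L)
})

test_that("summary panel arithmetic and degenerate cases", {
  rec2 <- tibble::tibble(volume_mm3 = c(4.19, 8.00))
  s <- cyst_summary(rec2)
  expect_equal(s$cyst_n, 2)
  expect_equal(s$cyst_v, 12.19)
  expect_equal(s$cystv_ave, 6.095)
  expect_equal(s$cystv_min, 4.19)
  expect_equal(s$cystv_max, 8.00)
  s1 <- cyst_summary(tibble::tibble(volume_mm3 = 3.3))
  expect_equal(s1$cystv_min, s1$cystv_max)
  expect_equal(s1$cystv_min, s1$cystv_ave)
  s0 <- cyst_summary(tibble::tibble(volume_mm3 = double()))
  expect_equal(s0$cyst_n, 0)
  expect_equal(s0$cyst_v, 0)
  expect_true(is.na(s0$cystv_ave) && is.na(s0$cystv_min) && is.na(s0$cystv_max))
})

test_that("mineral map splits bone intensities at within-mask tertiles", {
  set.seed(3)
  b <- ball_mask(2, 0.25)
  v <- voxel_volume(array(0L, dim(b$values)), 0.25, b$origin)
  v$values[b$values] <- as.integer(sample(90:255, sum(b$values), TRUE))
  mm <- mineral_map(v, b)
  counts <- tabulate(mm$values[b$values], 3)
  expect_lt(diff(range(counts)), 0.02 * sum(b$values))
  expect_true(all(mm$values[!b$values] == 0L))
  # two-point distribution in equal halves: ties go to the lower class
  v2 <- v
  half <- which(b$values)
  v2$values[half] <- 100L
  v2$values[half[seq_len(length(half) / 2)]] <- 200L
  mm2 <- mineral_map(v2, b)
  # ties go to the lower class: 100 <= first tertile -> low, 200 <= second
  # tertile -> intermediate; the split is deterministic
  expect_setequal(unique(mm2$values[b$values]), c(1L, 2L))
  expect_equal(unique(mm2$values[v2$values == 100L & b$values]), 1L)
  expect_equal(unique(mm2$values[v2$values == 200L & b$values]), 2L)
  vflat <- v
  vflat$values[b$values] <- 120L
  expect_warning(mmf <- mineral_map(vflat, b), "constant")
  expect_true(all(mmf$values[b$values] == 2L))
})
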