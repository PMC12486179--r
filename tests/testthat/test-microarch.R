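# Trabecular morphometry panel against analytic phantoms, counting
# oracles and invariances.

test_that("Cys-Tb shell matches the analytic spherical shell", {
  cyst <- ball_mask(1, 0.05, pad_vox = 14)
  shell <- cys_tb_shell(cyst, width = 0.5)
  v_analytic <- 4 / 3 * pi * (1.5^3 - 1^3)
  expect_lt(abs(mask_volume(shell) / v_analytic - 1), 0.05)
  expect_equal(sum(shell$values & cyst$values), 0)
  coarse <- ball_mask(1, 0.6)
  expect_error(cys_tb_shell(coarse, width = 0.5), "below one voxel")
  expect_error(cys_tb_shell(cyst, width = 0), "positive")
})

test_that("BV/TV equals the voxel-count oracle", {
  b <- ball_mask(1.5, 0.25)
  roi <- full_roi(b)
  expect_equal(bv_tv(b, roi), 100 * sum(b$values) / length(b$values))
  expect_equal(bv_tv(b, b), 100)
  set.seed(2)
  rnd <- b
  rnd$values <- array(runif(length(b$values)) < 0.3, dim(b$values))
  expect_equal(bv_tv(rnd, roi), 100 * sum(rnd$values) / length(rnd$values))
})

test_that("BS/BV hits analytic values for spheres and slabs and converges", {
  b <- ball_mask(2, 0.1)
  expect_lt(abs(bone_surface(b, full_roi(b))$bs_bv - 1.5), 0.075)  # 3/r, +-5%
  s <- slab_mask(0.4, 0.05, lateral = 61)
  expect_lt(abs(bone_surface(s, full_roi(s))$bs_bv - 5), 0.25)     # 2/t, +-5%
  # halving the voxel changes the sphere area estimate by < 3%
  a1 <- surface_area(ball_mask(2, 0.2))
  a2 <- surface_area(ball_mask(2, 0.1))
  expect_lt(abs(a1 / a2 - 1), 0.03)
})

test_that("local thickness reads slab and cylinder dimensions", {
  s <- slab_mask(0.45, 0.05, lateral = 41)          # odd voxel parity: exact
  expect_lt(abs(local_thickness(s) - 450), 50 + 1e-9)
  s2 <- slab_mask(0.4, 0.1, lateral = 41)
  expect_lt(abs(local_thickness(s2) - 400), 100 + 1e-9)  # one-voxel tolerance
  cyl <- cylinder_mask(0.3, 0.1)
  expect_lt(abs(local_thickness(cyl) - 300), 100 + 1e-9)
  expect_warning(
    th_na <- local_thickness(binary_mask(array(FALSE, c(4, 4, 4)), 1)),
    "undefined")
  expect_true(is.na(th_na))
})

test_that("Tb.N follows the periodicity formula and scale covariance", {
  expect_equal(tb_n(400, 600), 1)
  expect_equal(tb_n(500, 500), 1)
  expect_equal(tb_n(2 * 400, 2 * 600), 0.5)
  expect_error(tb_n(-1, 100), "positive")
})

test_that("SMI separates plate, rod and sphere", {
  expect_lt(abs(smi(slab_mask(0.5, 0.1, lateral = 61)) - 0), 0.3)
  expect_lt(abs(smi(cylinder_mask(1.0, 0.1, length_vox = 61)) - 3), 0.3)
  expect_lt(abs(smi(ball_mask(2, 0.1)) - 4), 0.3)
})

test_that("MIL anisotropy: isotropic near 1, plates strongly anisotropic, rotation-stable", {
  set.seed(10)
  for (seed in c(1, 2, 3)) {
    salt <- binary_mask(array(runif(40^3) < 0.4, c(40, 40, 40)), 0.25)
    da <- mil_tensor(salt, n_directions = 256, seed = seed)$da
    expect_gte(da, 1)
    expect_lte(da, 1.15)
  }
  arr <- array(FALSE, c(41, 41, 60))
  for (k in 1:60) if (k %% 10 < 4) arr[, , k] <- TRUE      # plates normal to z
  pl <- binary_mask(arr, 0.1)
  mt <- mil_tensor(pl, n_directions = 256, seed = 2)
  expect_gt(mt$da, 2)
  # shortest MIL axis is the plate normal (z)
  expect_gt(abs(mt$axes[3, 3]), cos(10 * pi / 180))
  # rotating the volume 90 degrees about x permutes axes, DA unchanged
  arr_r <- aperm(arr, c(1, 3, 2))
  mt_r <- mil_tensor(binary_mask(arr_r, 0.1), n_directions = 256, seed = 2)
  expect_lt(abs(mt_r$da / mt$da - 1), 0.02)
  expect_gt(abs(mt_r$axes[2, 3]), cos(10 * pi / 180))
})

test_that("connectivity density counts handles via the Euler characteristic", {
  b <- ball_mask(1.5, 0.25)
  expect_equal(conn_density(b, full_roi(b)), 0)
  tor <- torus_mask(1.2, 0.4, 0.2)
  roi <- full_roi(tor)
  expect_equal(conn_density(tor, roi), 1 / mask_volume(roi))
  # two disjoint tori in one ROI: the cubical-complex oracle decides
  d <- dim(tor$values)
  two <- array(FALSE, d + c(0, 0, d[3] + 2))
  two[, , seq_len(d[3])] <- tor$values
  two[, , d[3] + 2 + seq_len(d[3])] <- tor$values
  chi_oracle <- oracle_euler(two)
  expect_equal(chi_oracle, 0L)                      # chi = 0 + 0
  roi2 <- binary_mask(array(TRUE, dim(two)), 0.2)
  expect_equal(conn_density(binary_mask(two, 0.2), roi2),
               (1 - chi_oracle) / mask_volume(roi2))
})

test_that("the full panel is translation-invariant", {
  set.seed(4)
  spec <- phantom_spec(head_radius = 5, voxel_size = 0.25,
                       noise_sd = 0, blur_sigma = 0, seed = 6)
  g <- generate_head(spec)
  bone <- g$truth$bone_mask
  d <- dim(bone$values)
  roi <- binary_mask(array(FALSE, d), 0.25, bone$origin)
  roi$values[15:25, 15:25, 15:25] <- TRUE
  p1 <- microarch_panel(bone, roi, n_directions = 128, seed = 1)
  # translate structure and ROI together by 3 voxels
  sh <- function(a) {
    out <- array(FALSE, d)
    out[4:d[1], , ] <- a[1:(d[1] - 3), , ]
    out
  }
  bone2 <- binary_mask(sh(bone$values), 0.25, bone$origin)
  roi2 <- binary_mask(sh(roi$values), 0.25, bone$origin)
  p2 <- microarch_panel(bone2, roi2, n_directions = 128, seed = 1)
  for (nm in c("bv_tv", "tb_th_um", "tb_sp_um", "conn_d_mm3"))
    expect_equal(p1[[nm]], p2[[nm]], tolerance = 1e-8)
  for (nm in c("bs_bv", "smi", "da"))
    expect_equal(p1[[nm]], p2[[nm]], tolerance = 0.05)
})
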