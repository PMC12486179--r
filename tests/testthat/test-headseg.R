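# Landmark geometry: reference plane, MTD estimation, six-region
# labelling, per-cyst region assignment.

test_that("reference plane has closed form and orientation symmetry", {
  lm <- landmark_set(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), side = "right")
  pl <- reference_plane(lm)
  expect_equal(abs(pl$normal), c(0, 1, 0), tolerance = 1e-12)
  # residuals of all three points on the plane
  for (p in list(lm$head_centre, lm$fovea_centre, lm$neck_centre))
    expect_lt(abs(sum((p - pl$point) * pl$normal)), 1e-9)
  lm_l <- landmark_set(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), side = "left")
  expect_equal(reference_plane(lm_l)$normal, -pl$normal)
})

test_that("MTD estimation recovers programmed anisotropy and falls back when isotropic", {
  spec <- phantom_spec(head_radius = 6, voxel_size = 0.25,
                       anisotropy_stretch = 2, noise_sd = 0, blur_sigma = 0,
                       seed = 3)
  g <- generate_head(spec)
  v <- estimate_mtd(g$truth$bone_mask, n_directions = 256)
  expect_lt(acos(abs(v[3])) * 180 / pi, 10)

  # parallel plates normal to x: MTD lies in the plate (y-z) plane
  arr <- array(FALSE, c(60, 41, 41))
  for (i in 1:60) if (i %% 10 < 4) arr[i, , ] <- TRUE
  v2 <- estimate_mtd(binary_mask(arr, 0.1), n_directions = 256)
  expect_lt(abs(v2[1]), 0.2)

  # iid salt noise is isotropic: warning + z-axis default
  set.seed(8)
  salt <- binary_mask(array(runif(40^3) < 0.4, c(40, 40, 40)), 0.25)
  expect_warning(v3 <- estimate_mtd(salt, n_directions = 256), "isotropic")
  expect_equal(v3, c(0, 0, 1))
})

sphere_lm <- function(R) landmark_set(c(0, 0, 0), c(R, 0, 0), c(0, 0, -(R + 4)),
                                      mtd = c(0, 0, 1), side = "right")

test_that("pillar slabs are 30/40/30 of the head width and partition the head", {
  h <- 0.2; R <- 10
  head <- ball_mask(R, h)
  seg <- segment_regions(head, sphere_lm(R))
  labs <- seg$regions$values
  expect_equal(sum(labs > 0), sum(head$values))             # exact partition
  expect_equal(sum(head$values & labs == 0), 0)
  # slab extents along the width axis (x here)
  xs <- which(head$values, arr.ind = TRUE)[, 1]
  width <- diff(range(xs)) + 1
  for (reg in list(c(1, 4), c(2, 5), c(3, 6))) {
    sel <- labs %in% reg & head$values
    w_reg <- diff(range(which(sel, arr.ind = TRUE)[, 1])) + 1
    frac <- c(0.30, 0.40, 0.30)[which(c(1, 2, 3) == reg[1])]
    expect_lt(abs(w_reg - frac * width), 1.5)               # within one voxel
  }
  # central-slab volume against the spherical-slab integral between the
  # reported cut positions; voxels are classified by their centres, so the
  # continuum band carries a half-voxel skirt on each side
  v_central <- sum(labs %in% c(2, 5)) * h^3
  c1 <- seg$geometry$cut_1 - h / 2; c2 <- seg$geometry$cut_2 + h / 2
  slab_int <- pi * (R^2 * (c2 - c1) - (c2^3 - c1^3) / 3)
  expect_lt(abs(v_central / slab_int - 1), 0.02)
})

test_that("six-region labelling is equivariant under 90-degree rotation", {
  h <- 0.5
  n <- 41
  ax <- (seq_len(n) - 21) * h
  # asymmetric head: ellipsoid plus an offset bump
  E <- outer(outer((ax / 7)^2, (ax / 5)^2, `+`), (ax / 6)^2, `+`) <= 1
  B <- outer(outer((ax - 3)^2, (ax - 2)^2, `+`), ax^2, `+`) <= 3^2
  head <- binary_mask(E | B, h, origin = rep(ax[1], 3))
  lm <- landmark_set(c(0, 0, 0), c(7, 0, 0), c(0, 0, -10),
                     mtd = c(0, 0, 1), side = "right")
  seg <- segment_regions(head, lm)

  rot <- function(a) {            # +90 deg about z: (x,y,z) -> (-y,x,z)
    ap <- aperm(a, c(2, 1, 3))
    ap[rev(seq_len(dim(ap)[1])), , ]
  }
  head_r <- binary_mask(rot(head$values), h, origin = rep(ax[1], 3))
  rot_pt <- function(p) c(-p[2], p[1], p[3])
  lm_r <- landmark_set(rot_pt(lm$head_centre), rot_pt(lm$fovea_centre),
                       rot_pt(lm$neck_centre), mtd = c(0, 0, 1), side = "right")
  seg_r <- segment_regions(head_r, lm_r)
  for (reg in 1:6) {
    v1 <- sum(seg$regions$values == reg)
    v2 <- sum(rot(seg$regions$values) == reg & seg_r$regions$values > 0)
    # same label occupies the rotated voxel set up to a boundary layer
    expect_equal(sum(seg_r$regions$values == reg), v1, tolerance = 0.02)
  }
  expect_equal(seg_r$geometry$head_width_mm, seg$geometry$head_width_mm,
               tolerance = 1e-6)
})

test_that("cysts are assigned to the region holding their largest share", {
  h <- 0.25; R <- 8
  head <- ball_mask(R, h)
  seg <- segment_regions(head, sphere_lm(R))
  labs <- seg$regions
  d <- dim(head$values)
  ax <- (seq_len(d[1]) - (d[1] + 1) / 2) * h

  mk_cyst <- function(centre, diam, id = 1L) {
    D <- outer(outer((ax - centre[1])^2, (ax - centre[2])^2, `+`),
               (ax - centre[3])^2, `+`)
    label_volume((D <= (diam / 2)^2) * id, h, head$origin)
  }
  # entirely inside region II (anterior central): x ~ 0, y > 0
  a1 <- assign_cyst_region(mk_cyst(c(0, 4, 0), 2), labs)
  expect_equal(a1$region, "II")
  expect_equal(a1$pillar, "central")
  expect_equal(a1$hemisphere, "anterior")

  # straddling the lateral/central cut with the bigger share lateral
  cut1_x <- -R + 0.3 * 2 * R
  a2 <- assign_cyst_region(mk_cyst(c(cut1_x - 0.4, 3, 0), 2), labs)
  fr <- unlist(a2[paste0("frac_", c("I", "II"))])
  expect_gt(fr[1], fr[2])
  expect_equal(a2$region, "I")

  # exact 50/50 straddle of the reference plane: lower region index + flag
  a3 <- assign_cyst_region(mk_cyst(c(0, 0, 0), 2), labs)
  expect_equal(a3$region, "II")
  expect_true(a3$tie || a3$frac_II != a3$frac_V)   # flagged when exactly equal
  # zero overlap -> unassigned with warning
  far <- label_volume(array(0L, d), h, head$origin)
  far$values[1, 1, 1] <- 1L
  expect_warning(a4 <- assign_cyst_region(far, labs), "unassigned|no overlap")
  expect_equal(a4$region, "unassigned")
})

test_that("pillar counts conserve the number of assigned cysts", {
  rec <- tibble::tibble(
    pillar = c("lateral", "lateral", "lateral", "central", NA),
    hemisphere = c("anterior", "anterior", "anterior", "posterior", NA))
  tab <- pillar_counts(rec)
  expect_equal(tab$anterior[tab$pillar == "lateral"], 3)
  expect_equal(tab$total[tab$pillar == "total"], 4)
  expect_equal(sum(tab$total[tab$pillar != "total"]), 4)
})
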