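# The synthetic femoral-head generator: ground-truth contracts,
# determinism, realized fractions.

three_cysts <- list(list(centre = c(2.5, 1.5, 1.5), diameter = 3),
                    list(centre = c(-3, -1, 0.5), diameter = 2),
                    list(centre = c(0, -2.5, -3), diameter = 1.5))

test_that("truth labels match the cyst specification", {
  spec <- phantom_spec(head_radius = 8, voxel_size = 0.25, cysts = three_cysts,
                       noise_sd = 0, blur_sigma = 0, seed = 4)
  g <- generate_head(spec)
  labs <- g$truth$cyst_labels$values
  expect_equal(sort(unique(labs[labs > 0])), 1:3)
  # label regions pairwise disjoint by construction of a label volume;
  # check each against its analytic sphere volume (one voxel-shell slack)
  for (i in 1:3) {
    d <- three_cysts[[i]]$diameter
    v_analytic <- 4 / 3 * pi * (d / 2)^3
    shell <- 4 * pi * (d / 2)^2 * 0.25      # one voxel layer on the surface
    expect_lt(abs(sum(labs == i) * 0.25^3 - v_analytic), shell)
  }
  # bone truth and cyst voids are disjoint
  expect_equal(sum(g$truth$bone_mask$values & labs > 0), 0)
})

test_that("identical spec and seed give bit-identical volumes", {
  spec <- phantom_spec(head_radius = 6, voxel_size = 0.25,
                       cysts = three_cysts[2], seed = 9)
  g1 <- generate_head(spec)
  g2 <- generate_head(spec)
  expect_identical(g1$volume$values, g2$volume$values)
  expect_identical(g1$truth$bone_mask$values, g2$truth$bone_mask$values)
})

ball_interior <- function(g, r) {
  d <- dim(g$volume$values)
  ax <- (seq_len(d[1]) - (d[1] + 1) / 2) * g$volume$spacing[1]
  outer(outer(ax^2, ax^2, `+`), ax^2, `+`) <= r^2
}

test_that("realized bone fraction hits the target without noise", {
  for (target in c(0.25, 0.45)) {
    spec <- phantom_spec(head_radius = 6, voxel_size = 0.25,
                         bone_fraction_target = target,
                         noise_sd = 0, blur_sigma = 0, seed = 2)
    g <- generate_head(spec)
    interior <- ball_interior(g, 6 - 0.6)
    frac <- sum(g$truth$bone_mask$values & interior) / sum(interior)
    expect_lt(abs(frac - target), 0.02)
  }
})

test_that("invalid cyst layouts are rejected with informative errors", {
  expect_error(phantom_spec(head_radius = 8, voxel_size = 0.25,
                            cysts = list(list(centre = c(7, 0, 0), diameter = 3))),
               "outside the head")
  expect_error(phantom_spec(head_radius = 8, voxel_size = 0.25,
                            cysts = list(list(centre = c(0, 0, 0), diameter = 3),
                                         list(centre = c(1, 0, 0), diameter = 2))),
               "1 and 2 overlap")
})

test_that("histology sections honour the programmed class fractions", {
  s0 <- generate_histo_section(256, 256, osteoid_fraction = 0, seed = 3)
  expect_equal(sum(s0$classes == 2L), 0)
  s1 <- generate_histo_section(512, 512, osteoid_fraction = 0.10, seed = 3)
  expect_lt(abs(s1$truth$realized_osteoid_over_bone - 0.10), 0.01)
  s1b <- generate_histo_section(512, 512, osteoid_fraction = 0.10, seed = 3)
  expect_identical(s1$classes, s1b$classes)
  expect_error(generate_histo_section(64, 64, osteoid_fraction = 0.6,
                                      eroded_surface_fraction = 0.5),
               "must be < 1")
})

test_that("cohorts with identical generators show no systematic difference", {
  n_bad <- 0
  for (seed in 1:200) {
    spec <- cohort_spec(30, 30,
                        continuous = list(x = list(family = "normal",
                                                   a = c(5, 2), b = c(5, 2))),
                        seed = seed)
    co <- generate_cohort(spec)
    a <- co$x[co$group == "A"]; b <- co$x[co$group == "B"]
    se <- sqrt(stats::var(a) / 30 + stats::var(b) / 30)
    if (abs(mean(a) - mean(b)) >= 3 * se) n_bad <- n_bad + 1
  }
  expect_lte(n_bad, 10)    # >= 95% of 200 seeds within 3 pooled SE
})

test_that("a programmed 2-SD shift is detected in essentially every cohort", {
  hits <- 0
  for (seed in 1:200) {
    spec <- cohort_spec(100, 100,
                        continuous = list(x = list(family = "normal",
                                                   a = c(0, 1), b = c(2, 1))),
                        seed = seed)
    co <- generate_cohort(spec)
    cmp <- compare_continuous(co$x[co$group == "A"], co$x[co$group == "B"])
    if (cmp$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 198)
})

test_that("zero event probability produces zero events", {
  spec <- cohort_spec(20, 20, categorical = list(ev = list(p_a = 0, p_b = 0)),
                      seed = 5)
  co <- generate_cohort(spec)
  expect_equal(sum(co$ev == "yes"), 0)
})
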