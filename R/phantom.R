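# Synthetic femoral-head phantoms with known ground truth. The trabecular
# texture is a thresholded Gaussian random field; a cortical shell and
# quasi-spherical cyst voids are added analytically, so every downstream
# stage (binarization, void extraction, region assignment, morphometry)
# can be checked against construction-time truth.

# evaluate `code` under a fixed RNG state without disturbing the caller's
run_seeded <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic femoral-head phantom
#'
#' @param head_radius head radius, mm.
#' @param voxel_size isotropic voxel size, mm (default 0.0736, a typical
#'   specimen micro-CT resolution; coarser grids are fine for testing).
#' @param bone_fraction_target trabecular bone volume fraction in (0,1)
#'   aimed for inside the head (the field is thresholded at the matching
#'   quantile, so the realized fraction is exact up to quantile rounding).
#' @param strut_scale band-pass scale of the trabecular texture, mm
#'   (controls strut thickness; realized mean strut thickness is roughly
#'   2.3 x the quadrature sum of `strut_scale` and half a voxel, so the
#'   default gives ~0.2 mm struts at the default voxel size). Marrow
#'   pore width tracks strut width scaled by the void/bone ratio and
#'   stays well below the 1 mm cyst threshold at the defaults, as in
#'   real trabecular bone.
#' @param anisotropy_stretch >= 1; stretch of the autocorrelation along the
#'   main trabeculae direction (the phantom's MTD is the +z axis).
#' @param cortical_thickness cortical shell thickness, mm.
#' @param cysts list of `list(centre = c(x,y,z) mm, diameter = mm)` voids
#'   carved into the head; centres are relative to the head centre.
#' @param rim_thickness optional sclerotic rim of solid bone around each
#'   cyst, mm (0 disables; mimics the discontinuous bony rim seen around
#'   real lesions).
#' @param noise_sd additive Gaussian intensity noise (8-bit units).
#' @param blur_sigma Gaussian blur of the rendered intensities, mm.
#' @param seed RNG seed; all outputs are bit-reproducible for a fixed seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(head_radius = 12, voxel_size = 0.0736,
                         bone_fraction_target = 0.35, strut_scale = 0.09,
                         anisotropy_stretch = 1.3, cortical_thickness = 0.6,
                         cysts = list(), rim_thickness = 0,
                         noise_sd = 8, blur_sigma = 0.05, seed = 1L) {
  stopifnot(voxel_size > 0, head_radius >= 10 * voxel_size,
            bone_fraction_target > 0, bone_fraction_target < 1,
            strut_scale > 0, anisotropy_stretch >= 1,
            cortical_thickness >= 0, rim_thickness >= 0,
            noise_sd >= 0, blur_sigma >= 0)
  cysts <- lapply(cysts, function(cy) {
    stopifnot(length(cy$centre) == 3L, cy$diameter > 0)
    cy
  })
  if (length(cysts)) {
    # every cyst (plus rim) must stay inside the head sphere
    for (i in seq_along(cysts)) {
      cy <- cysts[[i]]
      if (sqrt(sum(cy$centre^2)) + cy$diameter / 2 + rim_thickness > head_radius)
        stop("cyst ", i, " extends outside the head sphere")
    }
    if (length(cysts) > 1L) {
      for (i in seq_len(length(cysts) - 1L)) for (j in seq(i + 1L, length(cysts))) {
        gap <- sqrt(sum((cysts[[i]]$centre - cysts[[j]]$centre)^2))
        if (gap < (cysts[[i]]$diameter + cysts[[j]]$diameter) / 2 + 2 * rim_thickness)
          stop("cyst specs ", i, " and ", j, " overlap")
      }
    }
  }
  structure(list(head_radius = head_radius, voxel_size = voxel_size,
                 bone_fraction_target = bone_fraction_target,
                 strut_scale = strut_scale, anisotropy_stretch = anisotropy_stretch,
                 cortical_thickness = cortical_thickness, cysts = cysts,
                 rim_thickness = rim_thickness, noise_sd = noise_sd,
                 blur_sigma = blur_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic femoral-head volume with ground truth
#'
#' Renders marrow at intensity 40 and bone at 160 (so the standard 90-255
#' bone window separates the classes before noise), applies the requested
#' blur and noise, and quantizes to 8-bit.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements
#'   * `volume`: [voxel_volume()] (8-bit grayscale),
#'   * `truth`: list with `bone_mask` ([binary_mask()], noiseless bone
#'     truth), `head_mask`, `cyst_labels` ([label_volume()], one label per
#'     specified cyst), `cysts` (tibble: id, centre, diameter, analytic and
#'     voxelized volume), and `landmarks` ([landmark_set()], MTD = +z,
#'     fovea on the medial (+x) surface, neck centre inferior).
#' @export
generate_head <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$voxel_size
  R <- spec$head_radius
  margin <- max(1, 4 * spec$blur_sigma + 2 * h)
  nhalf <- ceiling((R + margin) / h)
  n <- 2L * nhalf + 1L
  ax <- (seq_len(n) - nhalf - 1) * h       # world coords, head centre at 0
  origin <- rep(ax[1], 3)

  x2 <- ax^2
  r2 <- outer(outer(x2, x2, `+`), x2, `+`)
  head <- r2 <= R^2
  interior <- r2 <= (R - spec$cortical_thickness)^2

  run_seeded(spec$seed, {
    noise <- stats::rnorm(n^3)
    sig <- spec$strut_scale / h * c(1, 1, spec$anisotropy_stretch)
    # band-pass (difference-of-Gaussians) texture: the low-pass removal
    # bounds the pore size at a few strut_scale lengths, as in real
    # trabecular bone; a plain smoothed field would keep arbitrarily
    # large low-frequency pores
    field <- array(.gauss3_cpp(noise, c(n, n, n), sig) -
                     .gauss3_cpp(noise, c(n, n, n), 2.5 * sig),
                   c(n, n, n))
    thr <- stats::quantile(field[interior], 1 - spec$bone_fraction_target,
                           names = FALSE)
    bone <- (field > thr) & interior
    bone <- bone | (head & !interior)      # cortical shell is solid bone

    # carve cysts (and optional sclerotic rims)
    labels <- array(0L, c(n, n, n))
    cyst_any <- array(FALSE, c(n, n, n))
    for (i in seq_along(spec$cysts)) {
      cy <- spec$cysts[[i]]
      d2 <- outer(outer((ax - cy$centre[1])^2, (ax - cy$centre[2])^2, `+`),
                  (ax - cy$centre[3])^2, `+`)
      inside <- d2 <= (cy$diameter / 2)^2
      if (spec$rim_thickness > 0) {
        rim <- d2 <= (cy$diameter / 2 + spec$rim_thickness)^2 & !inside
        bone <- bone | (rim & head)
      }
      labels[inside] <- i
      cyst_any <- cyst_any | inside
    }
    bone <- bone & !cyst_any

    vals <- array(0, c(n, n, n))
    vals[head] <- 40
    vals[bone] <- 160
    if (spec$blur_sigma > 0)
      vals <- array(.gauss3_cpp(as.numeric(vals), c(n, n, n),
                                rep(spec$blur_sigma / h, 3)), c(n, n, n))
    if (spec$noise_sd > 0)
      vals <- vals + stats::rnorm(n^3, sd = spec$noise_sd)
    vals <- round(pmin(pmax(vals, 0), 255))
    storage.mode(vals) <- "integer"

    cyst_tbl <- tibble::tibble(
      id = seq_along(spec$cysts),
      diameter_mm = vapply(spec$cysts, function(cy) cy$diameter, 0),
      centre_x = vapply(spec$cysts, function(cy) cy$centre[1], 0),
      centre_y = vapply(spec$cysts, function(cy) cy$centre[2], 0),
      centre_z = vapply(spec$cysts, function(cy) cy$centre[3], 0),
      volume_analytic_mm3 = 4 / 3 * pi * (diameter_mm / 2)^3,
      volume_voxel_mm3 = vapply(seq_along(spec$cysts),
                                function(i) sum(labels == i) * h^3, 0)
    )
    lm <- landmark_set(head_centre = c(0, 0, 0),
                       fovea_centre = c(R, 0, 0),
                       neck_centre = c(0, 0, -(R + 4)),
                       mtd = c(0, 0, 1), side = "right")
    list(
      volume = voxel_volume(vals, h, origin),
      truth = list(
        bone_mask = binary_mask(bone, h, origin),
        head_mask = binary_mask(head, h, origin),
        cyst_labels = label_volume(labels, h, origin),
        cysts = cyst_tbl,
        landmarks = lm
      )
    )
  })
}

#' Generate a labelled 2D histology section
#'
#' Produces a labelled image with classes 0 = marrow, 1 = mineralized
#' bone, 2 = osteoid, 3 = eroded-surface marker. Bone is a thresholded 2D
#' random field; osteoid seams are laid on the bone-marrow interface
#' (nearest marrow pixels first) until the osteoid/bone area ratio hits
#' `osteoid_fraction`; eroded-surface markers are a random subset of the
#' remaining interface pixels covering about `eroded_surface_fraction` of
#' the bone perimeter.
#'
#' @param width,height image size in pixels.
#' @param osteoid_fraction target osteoid-area / bone-area ratio in [0,1).
#' @param eroded_surface_fraction target eroded fraction of the bone
#'   perimeter in [0,1).
#' @param bone_fraction area fraction of mineralized bone.
#' @param texture_scale autocorrelation length of the bone texture, px.
#' @param pixel_size_um pixel size, micrometres.
#' @param seed RNG seed.
#' @return an object of class `histo_section`: list(classes = integer
#'   matrix, pixel_size_um, truth = tibble of realized fractions).
#' @export
generate_histo_section <- function(width = 512, height = 512,
                                   osteoid_fraction = 0.10,
                                   eroded_surface_fraction = 0.15,
                                   bone_fraction = 0.40,
                                   texture_scale = 12,
                                   pixel_size_um = 5, seed = 1L) {
  stopifnot(osteoid_fraction >= 0, osteoid_fraction < 1,
            eroded_surface_fraction >= 0, eroded_surface_fraction < 1,
            bone_fraction > 0, bone_fraction < 1)
  if (osteoid_fraction + eroded_surface_fraction >= 1)
    stop("osteoid_fraction + eroded_surface_fraction must be < 1")
  run_seeded(seed, {
    dims3 <- c(width, height, 1L)
    field <- array(stats::rnorm(width * height), dims3)
    field <- array(.gauss3_cpp(as.numeric(field), dims3,
                               c(texture_scale, texture_scale, 0)), dims3)
    thr <- stats::quantile(field, 1 - bone_fraction, names = FALSE)
    bone <- field[, , 1] > thr
    cls <- matrix(0L, width, height)
    cls[bone] <- 1L

    n_bone <- sum(bone)
    # osteoid: marrow pixels nearest the bone surface, to exact pixel count
    n_ost <- round(osteoid_fraction * n_bone)
    if (n_ost > 0) {
      d2 <- array(.edt_sq_cpp(as.logical(array(!bone, dims3)), dims3, c(1, 1, 1)),
                  dims3)[, , 1]
      # osteoid seams form in patches along the bone surface: candidates
      # are ranked by a coarse random patch field plus their distance to
      # the surface, so seams are contiguous arcs of varying thickness
      # rather than a uniform rind
      patch <- array(stats::rnorm(width * height), dims3)
      patch <- array(.gauss3_cpp(as.numeric(patch), dims3,
                                 c(3 * texture_scale, 3 * texture_scale, 0)), dims3)
      patch <- patch[, , 1] / stats::sd(patch)
      cand <- which(!bone & is.finite(d2) & d2 > 0)
      score <- patch[cand] + 0.8 * sqrt(d2[cand])
      take <- cand[order(score)][seq_len(min(n_ost, length(cand)))]
      cls[take] <- 2L
    }

    # eroded-surface markers: subset of marrow pixels on the solid surface
    solid <- cls == 1L | cls == 2L
    nbr_solid <- neighbors4_any(solid)
    cand_e <- which(!solid & nbr_solid & cls == 0L)
    n_er <- round(eroded_surface_fraction * length(cand_e))
    if (n_er > 0) cls[sample(cand_e, n_er)] <- 3L

    truth <- tibble::tibble(
      bone_px = sum(cls == 1L),
      osteoid_px = sum(cls == 2L),
      realized_osteoid_over_bone = sum(cls == 2L) / max(1, sum(cls == 1L)),
      realized_ov_bv = 100 * sum(cls == 2L) / max(1, sum(cls == 1L) + sum(cls == 2L)),
      realized_es_bs = realized_es_bs(cls)
    )
    structure(list(classes = cls, pixel_size_um = pixel_size_um, truth = truth),
              class = "histo_section")
  })
}

# TRUE where any 4-neighbour is TRUE
neighbors4_any <- function(m) {
  d <- dim(m)
  p <- matrix(FALSE, d[1] + 2, d[2] + 2)
  p[2:(d[1] + 1), 2:(d[2] + 1)] <- m
  (p[1:d[1], 2:(d[2] + 1)] | p[3:(d[1] + 2), 2:(d[2] + 1)] |
     p[2:(d[1] + 1), 1:d[2]] | p[2:(d[1] + 1), 3:(d[2] + 2)])
}

# fraction of solid-surface edges whose non-solid side is the eroded
# marker; shares the edge-count definition with the histomorphometry
realized_es_bs <- function(cls) {
  e <- class_edges(cls)
  tot <- sum(e)
  if (tot == 0) return(0)
  (e[["bone_eroded"]] + e[["osteoid_eroded"]]) / tot
}

#' Specification of a synthetic two-group cohort
#'
#' @param n_group_a,n_group_b group sizes (>= 2).
#' @param continuous named list; each element is
#'   `list(family = "normal"|"lognormal", a = c(location, scale),
#'   b = c(location, scale))` giving the per-group generator.
#' @param categorical named list; each element is `list(p_a =, p_b =)`
#'   event probabilities per group for a binary variable.
#' @param group_labels labels for the two groups.
#' @param seed RNG seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group_a, n_group_b, continuous = list(),
                        categorical = list(),
                        group_labels = c("A", "B"), seed = 1L) {
  stopifnot(n_group_a >= 2, n_group_b >= 2, length(group_labels) == 2L)
  for (v in categorical)
    stopifnot(v$p_a >= 0, v$p_a <= 1, v$p_b >= 0, v$p_b <= 1)
  structure(list(n_group_a = as.integer(n_group_a),
                 n_group_b = as.integer(n_group_b),
                 continuous = continuous, categorical = categorical,
                 group_labels = group_labels, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic subject table
#'
#' @param spec a [cohort_spec()].
#' @return a tibble with `subject`, `group` (factor, two levels), one
#'   numeric column per continuous variable and one factor column
#'   (`"no"`/`"yes"`) per categorical variable.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  run_seeded(spec$seed, {
    n <- c(spec$n_group_a, spec$n_group_b)
    grp <- factor(rep(spec$group_labels, n), levels = spec$group_labels)
    out <- tibble::tibble(
      subject = sprintf("S%04d", seq_len(sum(n))),
      group = grp
    )
    for (nm in names(spec$continuous)) {
      v <- spec$continuous[[nm]]
      gen <- function(par, k) switch(v$family %||% "normal",
        normal = stats::rnorm(k, par[1], par[2]),
        lognormal = stats::rlnorm(k, par[1], par[2]),
        stop("unknown family: ", v$family))
      out[[nm]] <- c(gen(v$a, n[1]), gen(v$b, n[2]))
    }
    for (nm in names(spec$categorical)) {
      v <- spec$categorical[[nm]]
      ev <- c(stats::rbinom(n[1], 1, v$p_a), stats::rbinom(n[2], 1, v$p_b))
      out[[nm]] <- factor(ifelse(ev == 1, "yes", "no"), levels = c("no", "yes"))
    }
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
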