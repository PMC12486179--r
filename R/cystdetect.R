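# Cyst extraction on binarized micro-CT: bone binarization in a fixed
# 8-bit window, envelope ("total region") construction, void derivation by
# set difference, removal of sub-threshold voids by opening-by-
# reconstruction (erosion with a ball of half the minimum diameter, then
# geodesic reconstruction so surviving voids return exactly to their
# original shape), labelling, and the Cyst.N / Cyst.V / CystV.Ave /
# CystV.Min / CystV.Max panel.

#' Binarize bone in an 8-bit intensity window
#'
#' @param volume a [voxel_volume()].
#' @param lo,hi inclusive window bounds (defaults 90 and 255, the standard
#'   global mineralized-tissue window for 8-bit micro-CT).
#' @return a [binary_mask()] of bone.
#' @export
binarize_bone <- function(volume, lo = 90, hi = 255) {
  if (lo > hi) stop("`lo` must not exceed `hi`")
  if (lo < 0 || hi > 255) stop("window bounds must lie in 0-255")
  with_values(volume, volume$values >= lo & volume$values <= hi)
}

#' Total region: the filled envelope of the head
#'
#' Morphological closing with a ball (default radius 1.5 mm, enough to
#' bridge trabecular pores) followed by 3D cavity filling. The result
#' contains every bone voxel.
#'
#' @param bone bone [binary_mask()].
#' @param closing_radius ball radius for the closing, mm.
#' @return a [binary_mask()] of the whole head (bone + marrow spaces).
#' @export
total_region <- function(bone, closing_radius = 1.5) {
  if (!any(bone$values)) stop("bone mask is empty")
  fill_holes(close_ball(bone, closing_radius))
}

#' Empty regions: total region minus bone
#'
#' @param total,bone [binary_mask()]s on the same grid. Bone voxels
#'   outside `total` are clipped with a warning (they violate the
#'   containment contract).
#' @return a [binary_mask()] of non-bone space inside the head.
#' @export
empty_regions <- function(total, bone) {
  check_grid(total, bone, "total/bone")
  stray <- sum(bone$values & !total$values)
  if (stray > 0)
    warning(stray, " bone voxels outside the total region were clipped")
  with_values(total, total$values & !bone$values)
}

#' Remove voids narrower than a minimum inscribed diameter
#'
#' Opening-by-reconstruction: the void mask is eroded with a Euclidean
#' ball of radius `min_diameter / 2` (conceptually in `min_diameter /
#' (2 * step)` increments of `step`; the composition of ball erosions is a
#' single ball erosion, so the increments are algebraic, not approximate),
#' and the surviving voxels seed a geodesic reconstruction inside the
#' original mask. Components whose largest inscribed sphere is smaller
#' than `min_diameter` disappear entirely; all other components are
#' restored voxel-for-voxel to their original extent.
#'
#' @param empty void [binary_mask()] (see [empty_regions()]).
#' @param min_diameter minimum surviving inscribed-sphere diameter, mm
#'   (default 1.0: a cyst is a space more than 1 mm across).
#' @param step erosion/dilation increment, mm; `min_diameter` must equal
#'   `2 * k * step` for an integer k >= 1.
#' @param connectivity foreground connectivity for the reconstruction.
#' @param restore how surviving voids are restored from the eroded seeds:
#'   `"reconstruction"` (default) refills each surviving connected
#'   component completely (geodesic dilation to stability), so a void is
#'   kept or dropped as a whole; `"opening"` dilates the seeds back in
#'   `k` increments of `step`, each clipped to the original mask
#'   (increment-limited geodesic dilation, equal to a ball opening for
#'   k = 1). Use `"opening"` on trabecular volumes whose marrow space is
#'   connected to the cysts: full reconstruction would flood the entire
#'   marrow network through arbitrarily thin connections, while the
#'   incremental dilation restores compact voids (e.g. spherical cysts)
#'   to their exact original shape and nothing more.
#' @return filtered [binary_mask()], a subset of `empty`.
#' @export
size_filter <- function(empty, min_diameter = 1.0, step = 0.5, connectivity = 26,
                        restore = c("reconstruction", "opening")) {
  restore <- match.arg(restore)
  k <- min_diameter / (2 * step)
  if (abs(k - round(k)) > 1e-9 || round(k) < 1)
    stop("`min_diameter` must be 2 * k * step for integer k >= 1 ",
         "(got min_diameter = ", min_diameter, ", step = ", step, ")")
  k <- round(k)
  if (!any(empty$values)) return(empty)
  seeds <- erode_ball(empty, min_diameter / 2)
  if (!any(seeds$values)) return(with_values(empty, array(FALSE, dim(empty$values))))
  if (restore == "reconstruction") {
    reconstruct_mask(seeds, empty, connectivity)
  } else {
    out <- seeds
    for (i in seq_len(k)) {
      out <- dilate_ball(out, step)
      out$values <- out$values & empty$values
    }
    # surface correction: the strict-erosion / inclusive-dilation pair
    # loses about one voxel layer on digitized spheres; a final clipped
    # 1.5-voxel step (reaching in-plane diagonals) restores the original
    # surface position exactly on spheres while the mask clip prevents
    # any restoration beyond the original void
    out <- dilate_ball(out, 1.5 * min(empty$spacing))
    out$values <- out$values & empty$values
    out
  }
}

#' Label cysts and build per-cyst records
#'
#' Connected components of the filtered void mask are labelled; components
#' touching the exterior of the total region (6-adjacent to its
#' complement) are cartilage-/collapse-type surface defects, not interior
#' cysts, and are excluded from the records by default (they stay in the
#' label volume, flagged).
#'
#' @param filtered void mask after [size_filter()].
#' @param total total-region mask ([total_region()]).
#' @param connectivity foreground connectivity (26 default; background
#'   adjacency for the exterior test is always 6).
#' @param include_surface_voids if `TRUE`, exterior-touching voids are kept
#'   in the records (flagged).
#' @return list with `labels` (a [label_volume()]) and `records`, a tibble
#'   with one row per cyst: `id`, `volume_mm3`, `diameter_mm` (largest
#'   inscribed sphere), `centroid_x/y/z` (mm), `touches_exterior`.
#' @export
label_cysts <- function(filtered, total, connectivity = 26,
                        include_surface_voids = FALSE) {
  check_grid(filtered, total, "filtered/total")
  if (any(filtered$values & !total$values))
    stop("filtered voids must lie inside the total region")
  lab <- label_components(filtered, connectivity)
  nlab <- max(lab$values)
  if (nlab == 0L)
    return(list(labels = lab, records = empty_cyst_records()))

  # exterior shell: total-region voxels 6-adjacent to its complement
  ext <- total$values & !erode_ball(total, min(total$spacing) * 1.001)$values

  voxvol <- prod(filtered$spacing)
  th <- array(.local_thickness_cpp(as.logical(filtered$values),
                                   dim(filtered$values), filtered$spacing),
              dim(filtered$values))
  rec <- purrr::map_dfr(seq_len(nlab), function(i) {
    sel <- lab$values == i
    idx <- which(sel, arr.ind = TRUE)
    ctr <- colMeans(sweep(sweep(idx - 1, 2, filtered$spacing, `*`),
                          2, filtered$origin, `+`))
    tibble::tibble(
      id = i,
      volume_mm3 = sum(sel) * voxvol,
      diameter_mm = max(th[sel]),
      centroid_x = ctr[1], centroid_y = ctr[2], centroid_z = ctr[3],
      touches_exterior = any(sel & ext)
    )
  })
  if (!include_surface_voids) {
    rec <- dplyr::filter(rec, !.data$touches_exterior)
  }
  list(labels = lab, records = rec)
}

empty_cyst_records <- function() {
  tibble::tibble(id = integer(), volume_mm3 = double(), diameter_mm = double(),
                 centroid_x = double(), centroid_y = double(),
                 centroid_z = double(), touches_exterior = logical())
}

#' Cyst number/volume summary panel
#'
#' @param records per-cyst tibble from [label_cysts()].
#' @return one-row tibble: `cyst_n`, `cyst_v` (mm^3, 0 when no cysts),
#'   `cystv_ave`, `cystv_min`, `cystv_max` (mm^3; `NA` when no cysts).
#' @export
cyst_summary <- function(records) {
  n <- nrow(records)
  if (n == 0L)
    return(tibble::tibble(cyst_n = 0L, cyst_v = 0,
                          cystv_ave = NA_real_, cystv_min = NA_real_,
                          cystv_max = NA_real_))
  tibble::tibble(
    cyst_n = n,
    cyst_v = sum(records$volume_mm3),
    cystv_ave = mean(records$volume_mm3),
    cystv_min = min(records$volume_mm3),
    cystv_max = max(records$volume_mm3)
  )
}

#' Three-class mineralization map
#'
#' Bone voxels are classified into low/intermediate/high mineral density
#' by the intensity tertiles computed within the bone mask (ties go to the
#' lower class); non-bone voxels are 0.
#'
#' @param volume grayscale [voxel_volume()].
#' @param bone bone [binary_mask()] on the same grid.
#' @return a [label_volume()] with classes 1 (low), 2 (intermediate),
#'   3 (high).
#' @export
mineral_map <- function(volume, bone) {
  check_grid(volume, bone, "volume/bone")
  if (!any(bone$values)) stop("bone mask is empty")
  v <- volume$values[bone$values]
  q <- stats::quantile(v, c(1 / 3, 2 / 3), names = FALSE, type = 1)
  if (q[1] == q[2] && length(unique(v)) == 1L) {
    warning("constant bone intensity; all voxels classed intermediate")
    cls <- rep(2L, length(v))
  } else {
    cls <- 1L + (v > q[1]) + (v > q[2])   # <= tertile -> lower class
  }
  out <- array(0L, dim(volume$values))
  out[bone$values] <- cls
  with_values(volume, out, cls = "label_volume")
}

#' Write PNG slices of a mineralization map
#'
#' Renders axial slices with low/intermediate/high mineral density as
#' red/green/blue.
#' @param mmap a [label_volume()] from [mineral_map()].
#' @param dir output directory.
#' @param slices which z slices to write (default: the middle slice).
#' @return paths written, invisibly.
#' @export
write_mineral_png <- function(mmap, dir, slices = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(mmap$values)
  if (is.null(slices)) slices <- ceiling(d[3] / 2)
  paths <- character()
  for (k in slices) {
    sl <- mmap$values[, , k]
    img <- array(0, c(d[2], d[1], 3))
    for (ch in 1:3) img[, , ch] <- t(sl == ch) * 1
    p <- file.path(dir, sprintf("mineral_z%03d.png", k))
    png::writePNG(img, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
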