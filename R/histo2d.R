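# 2D histomorphometry on labelled undecalcified sections. Class coding:
# 0 marrow/void, 1 mineralized bone, 2 osteoid, 3 eroded-surface marker.
# The bone surface (BS) is the set of pixel edges between the solid phase
# (bone + osteoid) and non-solid pixels inside the image; image-border
# edges are not surface. Surface densities are reported as 2D length per
# area; the standard stereological correction (pi/4 on boundary length,
# converting staircase length to smooth perimeter) is applied when
# `stereology = TRUE`, in which case the densities correspond to the
# conventional mm^2/mm^3 readout.

# count solid/non-solid pixel edges, classified by the solid-side class
# (1 bone, 2 osteoid) and the non-solid-side class (0 marrow, 3 eroded)
class_edges <- function(cls) {
  solid <- cls == 1L | cls == 2L
  out <- c(bone_marrow = 0L, bone_eroded = 0L,
           osteoid_marrow = 0L, osteoid_eroded = 0L)
  tally <- function(a, b) {       # a, b: adjacent pixel class matrices
    sa <- a == 1L | a == 2L
    sb <- b == 1L | b == 2L
    edge <- xor(sa, sb)
    sc <- ifelse(sa, a, b)[edge]  # solid-side class
    nc <- ifelse(sa, b, a)[edge]  # non-solid-side class
    out[["bone_marrow"]] <<- out[["bone_marrow"]] + sum(sc == 1L & nc != 3L)
    out[["bone_eroded"]] <<- out[["bone_eroded"]] + sum(sc == 1L & nc == 3L)
    out[["osteoid_marrow"]] <<- out[["osteoid_marrow"]] + sum(sc == 2L & nc != 3L)
    out[["osteoid_eroded"]] <<- out[["osteoid_eroded"]] + sum(sc == 2L & nc == 3L)
  }
  d <- dim(cls)
  tally(cls[-d[1], ], cls[-1, ])
  tally(cls[, -d[2]], cls[, -1])
  out
}

section_classes <- function(section) {
  stopifnot(inherits(section, "histo_section"))
  section$classes
}

#' Osteoid panel: O.Th, OV/BV, OS/BS, OS/BV
#'
#' * `OV/BV` = osteoid area / (bone + osteoid area), percent.
#' * `OS/BS` = fraction of the bone surface whose solid side is osteoid,
#'   percent.
#' * `OS/BV` = osteoid-covered surface length / bone area (surface
#'   density).
#' * `O.Th` = mean 2D local thickness (inscribed-disc diameter) of the
#'   osteoid seams, micrometres.
#'
#' @param section a `histo_section` ([generate_histo_section()]) or an
#'   integer class matrix plus `pixel_size_um`.
#' @param pixel_size_um pixel size when `section` is a bare matrix.
#' @param stereology apply the pi/4 boundary-length correction to the
#'   surface densities.
#' @return one-row tibble: `o_th_um`, `ov_bv_pct`, `os_bs_pct`,
#'   `os_bv` (mm^2/mm^3 with `stereology`, otherwise raw mm/mm^2).
#' @export
measure_osteoid <- function(section, pixel_size_um = NULL, stereology = FALSE) {
  cls <- if (is.matrix(section)) section else section_classes(section)
  px_um <- if (is.matrix(section)) pixel_size_um else section$pixel_size_um
  if (is.null(px_um)) stop("pixel size required")
  px <- px_um / 1000                      # mm
  lcorr <- if (stereology) pi / 4 else 1

  n_bone <- sum(cls == 1L)
  n_ost <- sum(cls == 2L)
  if (n_bone + n_ost == 0L) {
    warning("no bone in section; osteoid panel undefined")
    return(tibble::tibble(o_th_um = NA_real_, ov_bv_pct = NA_real_,
                          os_bs_pct = NA_real_, os_bv = NA_real_))
  }
  e <- class_edges(cls)
  bs_len <- sum(e) * px * lcorr           # mm
  os_len <- (e[["osteoid_marrow"]] + e[["osteoid_eroded"]]) * px * lcorr
  bv_area <- (n_bone + n_ost) * px^2      # mm^2 (bone incl. osteoid seams)

  o_th <- if (n_ost == 0L) NA_real_ else {
    d3 <- c(dim(cls), 1L)
    th <- array(.local_thickness_cpp(as.logical(array(cls == 2L, d3)), d3,
                                     rep(px, 3)), d3)
    mean(th[, , 1][cls == 2L]) * 1000     # um
  }
  tibble::tibble(
    o_th_um = o_th,
    ov_bv_pct = 100 * n_ost / (n_bone + n_ost),
    os_bs_pct = if (bs_len > 0) 100 * os_len / bs_len else 0,
    os_bv = if (bv_area > 0) os_len / bv_area else NA_real_
  )
}

#' Erosion panel: ES/BS, ES/BV, ES/TV
#'
#' The eroded surface is the part of the bone surface whose non-solid
#' side carries the eroded-surface marker class; it is referred to the
#' total surface (percent), the bone area, and the total tissue area.
#'
#' @inheritParams measure_osteoid
#' @return one-row tibble: `es_bs_pct`, `es_bv`, `es_tv` (densities in
#'   mm^2/mm^3 with `stereology`, raw mm/mm^2 otherwise).
#' @export
measure_erosion <- function(section, pixel_size_um = NULL, stereology = FALSE) {
  cls <- if (is.matrix(section)) section else section_classes(section)
  px_um <- if (is.matrix(section)) pixel_size_um else section$pixel_size_um
  if (is.null(px_um)) stop("pixel size required")
  px <- px_um / 1000
  lcorr <- if (stereology) pi / 4 else 1

  if (sum(cls == 1L | cls == 2L) == 0L) {
    warning("no bone in section; erosion panel undefined")
    return(tibble::tibble(es_bs_pct = NA_real_, es_bv = NA_real_,
                          es_tv = NA_real_))
  }
  e <- class_edges(cls)
  bs_len <- sum(e) * px * lcorr
  es_len <- (e[["bone_eroded"]] + e[["osteoid_eroded"]]) * px * lcorr
  bv_area <- sum(cls == 1L | cls == 2L) * px^2
  tv_area <- length(cls) * px^2
  tibble::tibble(
    es_bs_pct = if (bs_len > 0) 100 * es_len / bs_len else 0,
    es_bv = es_len / bv_area,
    es_tv = es_len / tv_area
  )
}

#' Weidner microvessel density over high-power fields
#'
#' Each field is a binary microvessel mask; any connected cluster of
#' positive pixels (8-connectivity) counts as a single microvessel, so
#' touching endothelial profiles are one vessel. Both the per-field
#' counts and their mean (and total) are reported.
#'
#' @param fields list of logical matrices (conventionally 10 fields at
#'   200x magnification).
#' @return list with `per_field` (tibble: field, n_vessels), `mvd_mean`
#'   and `mvd_total`.
#' @export
microvessel_density <- function(fields) {
  if (length(fields) == 0L) stop("at least one field is required")
  counts <- vapply(fields, function(f) {
    stopifnot(is.matrix(f))
    d3 <- c(dim(f), 1L)
    max(.label_cpp(as.logical(array(f, d3)), d3, 26L))
  }, 0L)
  list(
    per_field = tibble::tibble(field = seq_along(fields), n_vessels = counts),
    mvd_mean = mean(counts),
    mvd_total = sum(counts)
  )
}
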