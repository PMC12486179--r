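# Six-region / three-pillar segmentation of the femoral head from three
# anatomical landmarks. The reference plane passes through the head,
# fovea and neck centres; two cutting planes parallel to the main
# trabeculae direction (MTD) and perpendicular to the reference plane
# split the head into lateral/central/medial pillars of 30/40/30% of the
# head width; the reference plane itself splits anterior from posterior,
# giving regions I-VI (I-III anterior lateral/central/medial, IV-VI the
# posterior counterparts).

unitv <- function(v) v / sqrt(sum(v^2))

# anterior unit vector from the medial and superior axes and the side.
# Truth table: with m = medial (head -> fovea) and s = superior
# (neck -> head), anterior = s x m for a right hip and m x s for a left
# hip (the anteroposterior axis flips between sides in the scanner frame).
anterior_axis <- function(medial, superior, side) {
  a <- if (side == "right") vcross(superior, medial) else vcross(medial, superior)
  unitv(a)
}

#' Reference plane through the three landmark centres
#'
#' @param lm a [landmark_set()].
#' @return list with `point` (the head centre) and `normal` (unit vector,
#'   oriented towards the anterior side for the given `side`).
#' @export
reference_plane <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  n <- vcross(lm$fovea_centre - lm$head_centre, lm$neck_centre - lm$head_centre)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("reference plane undefined: collinear landmarks")
  n <- n / nn
  ant <- anterior_axis(unitv(lm$fovea_centre - lm$head_centre),
                       unitv(lm$head_centre - lm$neck_centre), lm$side)
  if (sum(n * ant) < 0) n <- -n
  list(point = lm$head_centre, normal = n)
}

#' Estimate the main trabeculae direction from the bone mask
#'
#' Stand-in estimator for landmark files that omit the MTD: the principal
#' (longest) axis of the mean-intercept-length tensor of the bone
#' structure. If the structure is nearly isotropic (principal MIL ratio
#' < 1.05) the superoinferior (+z) axis is returned with a warning.
#'
#' @param bone bone [binary_mask()].
#' @param n_directions number of sampling directions.
#' @param seed seed for the direction jitter.
#' @return unit vector with non-negative z component.
#' @export
estimate_mtd <- function(bone, n_directions = 256, seed = 1L) {
  if (!any(bone$values)) stop("bone mask is empty")
  roi <- with_values(bone, array(TRUE, dim(bone$values)))
  mil <- mil_tensor(bone, roi, n_directions = n_directions, seed = seed)
  ratio <- max(mil$principal_mil) / min(mil$principal_mil)
  if (ratio < 1.05) {
    warning("bone structure is nearly isotropic (MIL ratio ",
            round(ratio, 3), "); defaulting MTD to the z axis")
    return(c(0, 0, 1))
  }
  v <- mil$axes[, which.max(mil$principal_mil)]
  if (v[3] < 0) v <- -v
  unitv(v)
}

#' Six-region segmentation of the head mask
#'
#' The width axis `w` is the unit vector perpendicular to the MTD lying in
#' the reference plane, oriented towards the fovea (medial). The head
#' width is the extent of the head-mask voxel centres projected onto `w`;
#' the two MTD-parallel cut planes sit at the cumulative `fractions`
#' quantiles of that extent (default 30/40/30). Anterior/posterior is the
#' signed side of the reference plane. Regions: I/II/III =
#' anterior lateral/central/medial, IV/V/VI = posterior counterparts.
#'
#' @param head head [binary_mask()].
#' @param lm a [landmark_set()]; if `lm$mtd` is `NULL` it is estimated
#'   from `head` via [estimate_mtd()].
#' @param fractions length-3 positive weights summing to 1
#'   (lateral, central, medial).
#' @return list with `regions` (a [label_volume()], labels 1-6 on the head
#'   mask) and `geometry` (list: `w_axis`, `head_width_mm`, `cut_1`,
#'   `cut_2` as signed positions along `w` from the lateral end,
#'   `reference_plane`, `mtd`).
#' @export
segment_regions <- function(head, lm, fractions = c(0.30, 0.40, 0.30)) {
  stopifnot(inherits(head, "binary_mask"), inherits(lm, "landmark_set"))
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions <= 0))
    stop("`fractions` must be positive and sum to 1")
  pl <- reference_plane(lm)
  mtd <- lm$mtd
  if (is.null(mtd)) mtd <- estimate_mtd(head)
  w <- vcross(pl$normal, mtd)
  wn <- sqrt(sum(w^2))
  if (wn < 1e-9) stop("MTD is parallel to the reference-plane normal")
  w <- w / wn
  med <- sum(w * (lm$fovea_centre - lm$head_centre))
  if (abs(med) < 1e-9)
    stop("fovea projects onto the head centre along the width axis; ",
         "medial side undefined")
  if (med < 0) w <- -w                       # w points medial

  co <- mask_coords(head)
  if (nrow(co) == 0L) stop("head mask is empty")
  t_all <- as.numeric(co %*% w - sum(w * lm$head_centre))
  rng <- range(t_all)
  width <- diff(rng)
  cut1 <- rng[1] + fractions[1] * width            # lateral | central
  cut2 <- rng[1] + (fractions[1] + fractions[2]) * width  # central | medial

  pillar <- 1L + (t_all >= cut1) + (t_all > cut2)  # 1 lat, 2 cen, 3 med
  sgn <- as.numeric(sweep(co, 2, pl$point, `-`) %*% pl$normal)
  post <- sgn < 0
  lab6 <- pillar + 3L * post                       # I..III ant, IV..VI post

  out <- array(0L, dim(head$values))
  out[head$values] <- lab6
  list(
    regions = with_values(head, out, cls = "label_volume"),
    geometry = list(w_axis = w, head_width_mm = width,
                    cut_1 = cut1, cut_2 = cut2,
                    reference_plane = pl, mtd = mtd)
  )
}

#' Pillar and hemisphere of each region label
#'
#' @param region integer vector of labels 1-6 (0/NA allowed).
#' @return tibble with `region`, `pillar` (lateral/central/medial) and
#'   `hemisphere` (anterior/posterior).
#' @export
region_lookup <- function(region = 1:6) {
  tibble::tibble(
    region = as.integer(region),
    pillar = c("lateral", "central", "medial")[(region - 1L) %% 3L + 1L],
    hemisphere = ifelse(region <= 3L, "anterior", "posterior")
  )
}

#' Assign each cyst to its distribution region
#'
#' A lesion may straddle several regions; its distribution area is the
#' region containing the highest fraction of its voxels (argmax; exact
#' ties go to the lower region index and are flagged). Cysts with no
#' overlap with the labelled head are `unassigned` with a warning.
#'
#' @param cyst_labels a [label_volume()] of cysts ([label_cysts()]).
#' @param regions a [label_volume()] of regions ([segment_regions()]).
#' @return tibble: `id`, `region` (`"I"`..`"VI"` or `"unassigned"`),
#'   `pillar`, `hemisphere`, `tie` flag, and `frac_I`..`frac_VI` overlap
#'   fractions.
#' @export
assign_cyst_region <- function(cyst_labels, regions) {
  check_grid(cyst_labels, regions, "cysts/regions")
  ids <- sort(unique(cyst_labels$values[cyst_labels$values > 0L]))
  roman <- c("I", "II", "III", "IV", "V", "VI")
  purrr::map_dfr(ids, function(i) {
    reg <- regions$values[cyst_labels$values == i]
    nvox <- length(reg)
    fr <- vapply(1:6, function(r) sum(reg == r) / nvox, 0)
    if (all(fr == 0)) {
      warning("cyst ", i, " has no overlap with the labelled head; unassigned")
      return(tibble::tibble(id = i, region = "unassigned",
                            pillar = NA_character_, hemisphere = NA_character_,
                            tie = FALSE,
                            !!!stats::setNames(as.list(fr), paste0("frac_", roman))))
    }
    best <- which.max(fr)                       # lower index on exact ties
    lk <- region_lookup(best)
    tibble::tibble(id = i, region = roman[best],
                   pillar = lk$pillar, hemisphere = lk$hemisphere,
                   tie = sum(fr == fr[best]) > 1L,
                   !!!stats::setNames(as.list(fr), paste0("frac_", roman)))
  })
}

#' Cyst counts by pillar and hemisphere
#'
#' @param records tibble with `pillar` and `hemisphere` columns (from
#'   [assign_cyst_region()], possibly joined with cyst records).
#' @return 3x2 count tibble (pillar rows, hemisphere columns) with
#'   marginals (`total` row and column).
#' @export
pillar_counts <- function(records) {
  rec <- dplyr::filter(records, !is.na(.data$pillar))
  base <- tidyr::expand_grid(pillar = c("lateral", "central", "medial"),
                             hemisphere = c("anterior", "posterior"))
  counts <- dplyr::count(rec, .data$pillar, .data$hemisphere)
  tab <- dplyr::left_join(base, counts, by = c("pillar", "hemisphere"))
  tab$n[is.na(tab$n)] <- 0L
  wide <- tidyr::pivot_wider(tab, names_from = "hemisphere", values_from = "n")
  wide$total <- wide$anterior + wide$posterior
  tot <- tibble::tibble(pillar = "total",
                        anterior = sum(wide$anterior),
                        posterior = sum(wide$posterior),
                        total = sum(wide$total))
  dplyr::bind_rows(wide, tot)
}
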