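# Trabecular microarchitecture panel on an ROI: BV/TV, BS/BV, Tb.Th,
# Tb.Sp, Tb.N, SMI, DA, Conn.D. The ROI of interest for cysts is the
# Cys-Tb shell, the trabecular region extending 0.5 mm outward from the
# cyst surface.

#' Peri-cyst trabecular shell (Cys-Tb ROI)
#'
#' The region extending `width` mm from the cyst surface into the
#' surrounding tissue: `dilate(cyst, width) \ cyst`, clipped to the total
#' head region.
#'
#' @param cyst [binary_mask()] of one cyst (or several).
#' @param total total-region mask; the shell is clipped to it (`NULL` to
#'   skip clipping).
#' @param width shell width, mm (default 0.5).
#' @return shell [binary_mask()], disjoint from `cyst`.
#' @export
cys_tb_shell <- function(cyst, total = NULL, width = 0.5) {
  if (width <= 0) stop("`width` must be positive")
  if (width < min(cyst$spacing))
    stop("shell width ", width, " mm is below one voxel (",
         min(cyst$spacing), " mm); use a finer grid or a wider shell")
  if (!any(cyst$values)) stop("cyst mask is empty")
  sh <- dilate_ball(cyst, width)
  sh$values <- sh$values & !cyst$values
  if (!is.null(total)) {
    check_grid(cyst, total, "cyst/total")
    sh$values <- sh$values & total$values
  }
  sh
}

#' Bone volume fraction, percent
#'
#' @param bone bone [binary_mask()].
#' @param roi ROI [binary_mask()] on the same grid.
#' @return `100 * |bone & roi| / |roi|`.
#' @export
bv_tv <- function(bone, roi) {
  check_grid(bone, roi, "bone/roi")
  n_roi <- sum(roi$values)
  if (n_roi == 0L) stop("ROI is empty")
  100 * sum(bone$values & roi$values) / n_roi
}

#' Bone surface and surface-to-volume ratio
#'
#' Surface area of the bone interface restricted to the ROI (coarea
#' estimate, see [surface_area()]); BS/BV divides by the bone volume
#' inside the ROI.
#'
#' @param bone,roi [binary_mask()]s on the same grid.
#' @return list with `bs_mm2` and `bs_bv` (1/mm).
#' @export
bone_surface <- function(bone, roi) {
  check_grid(bone, roi, "bone/roi")
  bv <- sum(bone$values & roi$values) * prod(bone$spacing)
  if (bv == 0) stop("no bone inside the ROI")
  s <- surface_area(bone, roi)
  list(bs_mm2 = s, bs_bv = s / bv)
}

#' Mean local thickness of a phase (Tb.Th / Tb.Sp)
#'
#' Sphere-fitting local thickness (distance-ridge): each voxel of the
#' phase carries the diameter of the largest inscribed sphere containing
#' it; the ROI mean of that map is returned. With `mask` = bone this is
#' Tb.Th; with `mask` = void-within-total it is Tb.Sp.
#'
#' @param mask phase [binary_mask()].
#' @param roi ROI [binary_mask()] (`NULL` = whole array).
#' @return mean thickness in micrometres, or `NA` (with a warning) if the
#'   phase does not intersect the ROI.
#' @export
local_thickness <- function(mask, roi = NULL) {
  sel <- mask$values
  if (!is.null(roi)) {
    check_grid(mask, roi, "mask/roi")
    sel <- sel & roi$values
  }
  if (!any(sel)) {
    warning("phase does not intersect the ROI; thickness undefined")
    return(NA_real_)
  }
  th <- array(.local_thickness_cpp(as.logical(mask$values), dim(mask$values),
                                   mask$spacing), dim(mask$values))
  mean(th[sel]) * 1000   # mm -> um
}

#' Trabecular number from thickness and separation
#'
#' Plate-model-free hybrid: `Tb.N = 1 / (Tb.Th + Tb.Sp)`, the number of
#' strut-gap periods per millimetre.
#'
#' @param tb_th,tb_sp thickness and separation, micrometres.
#' @return Tb.N, 1/mm.
#' @export
tb_n <- function(tb_th, tb_sp) {
  if (!isTRUE(tb_th > 0) || !isTRUE(tb_sp > 0))
    stop("tb_th and tb_sp must be positive")
  1 / ((tb_th + tb_sp) / 1000)
}

#' Structure model index
#'
#' `SMI = 6 * V * S' / S^2` where `S'` is the derivative of the surface
#' area under infinitesimal surface dilation. Both `S` and `S'` are taken
#' from the parallel-surface volume expansion: the volume `V(t)` enclosed
#' by the surface offset a signed distance `t` (sublevel sets of the
#' signed Euclidean distance field, with half-voxel surface positioning)
#' is fitted with a quadratic over `t` in `[-span, span]`, giving
#' `S = V'(0)` and `S' = V''(0)`. Ideal plates give ~0, rods ~3, spheres
#' ~4; concave structures can go negative, as is known for this index.
#' Structure cut by the array edge is treated as continuing (no cut-face
#' contribution).
#'
#' @param bone,roi [binary_mask()]s on the same grid.
#' @param span half-width of the offset range used in the fit, mm;
#'   default 3 voxels.
#' @return SMI (unitless), or `NA` if the surface is degenerate.
#' @export
smi <- function(bone, roi = NULL, span = NULL) {
  if (is.null(roi)) roi <- with_values(bone, array(TRUE, dim(bone$values)))
  check_grid(bone, roi, "bone/roi")
  h <- min(bone$spacing)
  if (is.null(span)) span <- 3 * h
  d <- dim(bone$values)
  fg <- bone$values
  if (!any(fg & roi$values)) return(NA_real_)
  # signed distance, negative inside; no padding, so the structure is
  # treated as continuing beyond the array edge
  d_out <- sqrt(array(.edt_sq_cpp(as.logical(!fg), d, bone$spacing), d))
  d_in <- sqrt(array(.edt_sq_cpp(as.logical(fg), d, bone$spacing), d))
  ds <- ifelse(fg, -(pmax(d_in - h / 2, 0)), pmax(d_out - h / 2, 0))
  ds <- ds[roi$values]
  voxvol <- prod(bone$spacing)
  # the quadratic expansion is only valid while the eroded structure
  # persists: clip the fitted range to the deepest interior distance
  span <- max(h, min(span, floor(max(-min(ds), h) / h) * h))
  # anti-aliased sublevel volumes: each voxel contributes the linearly
  # interpolated fraction of its h-slab below the offset t, which removes
  # the voxel-shell staircase from the fitted coefficients. Voxels far
  # below the fitted range only shift the intercept and are dropped.
  ds <- ds[ds <= span + h]
  n_deep <- sum(ds < -(span + h))
  ds <- ds[ds >= -(span + h)]
  ts <- seq(-span, span, by = h)
  vt <- vapply(ts, function(t)
    (n_deep + sum(pmin(pmax((t - ds) / h + 0.5, 0), 1))) * voxvol, 0)
  fit <- stats::lm.fit(cbind(1, ts, ts^2), vt)$coefficients
  s <- fit[2]
  sprime <- 2 * fit[3]
  if (!is.finite(s) || s <= 0) return(NA_real_)
  v <- sum(fg & roi$values) * voxvol
  unname(6 * v * sprime / s^2)
}

# quasi-uniform directions on the half sphere (Fibonacci spiral with a
# seeded random rotation so repeated calls decorrelate)
fib_directions <- function(n, seed = 1L) {
  run_seeded(seed, {
    i <- seq_len(n) - 0.5
    phi <- pi * (1 + sqrt(5)) * i
    z <- 1 - 2 * i / n
    r <- sqrt(pmax(0, 1 - z^2))
    d <- cbind(r * cos(phi), r * sin(phi), z)
    # random rotation
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    Rm <- rbind(
      c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3])),
      c(2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2])),
      c(2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)))
    d %*% t(Rm)
  })
}

#' Mean-intercept-length tensor and degree of anisotropy
#'
#' MIL is sampled over quasi-uniform sphere directions with parallel test
#' lines; an ellipsoid is fitted to `1 / MIL(n)^2` and the degree of
#' anisotropy is the ratio of the longest to the shortest principal MIL
#' axis (>= 1). The CTAn-style alternative `1 - min/max` is available via
#' `da_convention = "one_minus"`.
#'
#' @param bone,roi [binary_mask()]s on the same grid.
#' @param n_directions number of test directions (>= 64 recommended).
#' @param line_spacing spacing of parallel test lines, mm (default 2
#'   voxels).
#' @param seed seed for direction jitter.
#' @param da_convention `"ratio"` (max/min) or `"one_minus"` (1 - min/max).
#' @return list: `tensor` (3x3 fitted quadric), `principal_mil` (mm,
#'   descending), `axes` (columns = principal directions), `da`,
#'   `n_intercepts`.
#' @export
mil_tensor <- function(bone, roi = NULL, n_directions = 512,
                       line_spacing = NULL, seed = 1L,
                       da_convention = c("ratio", "one_minus")) {
  da_convention <- match.arg(da_convention)
  if (is.null(roi)) roi <- with_values(bone, array(TRUE, dim(bone$values)))
  check_grid(bone, roi, "bone/roi")
  if (!any(bone$values & roi$values) || !any(!bone$values & roi$values))
    stop("ROI must contain both bone and void")
  if (is.null(line_spacing)) line_spacing <- 2 * min(bone$spacing)
  dirs <- fib_directions(n_directions, seed = seed)
  res <- .mil_cpp(as.logical(bone$values), as.logical(roi$values),
                  dim(bone$values), bone$spacing, dirs,
                  line_spacing, min(bone$spacing) / 2)
  ok <- res[, 2] > 0
  if (sum(res[, 2]) < 100)
    warning("fewer than 100 intercepts sampled; MIL tensor is unreliable, ",
            "consider a denser line raster")
  mil <- res[ok, 1] / res[ok, 2]
  dd <- dirs[ok, , drop = FALSE]
  # fit n' A n = 1/MIL^2 by least squares on the 6 unique tensor elements
  X <- cbind(dd[, 1]^2, dd[, 2]^2, dd[, 3]^2,
             2 * dd[, 1] * dd[, 2], 2 * dd[, 1] * dd[, 3], 2 * dd[, 2] * dd[, 3])
  beta <- stats::lm.fit(X, 1 / mil^2)$coefficients
  A <- matrix(c(beta[1], beta[4], beta[5],
                beta[4], beta[2], beta[6],
                beta[5], beta[6], beta[3]), 3, 3)
  eig <- eigen(A, symmetric = TRUE)
  ev <- pmax(eig$values, .Machine$double.eps)
  pmil <- 1 / sqrt(ev)                      # descending eigenvalue -> ascending MIL
  ordm <- order(pmil, decreasing = TRUE)
  pmil <- pmil[ordm]
  axes <- eig$vectors[, ordm, drop = FALSE]
  da <- if (da_convention == "ratio") pmil[1] / pmil[3] else 1 - pmil[3] / pmil[1]
  list(tensor = A, principal_mil = pmil, axes = axes, da = da,
       n_intercepts = sum(res[, 2]))
}

#' Connectivity density
#'
#' `Conn.D = (1 - chi) / TV` with `chi` the 3D Euler characteristic of
#' bone within the ROI (cubical complex, 26-connected foreground,
#' zero-padded boundary) and `TV` the ROI volume in mm^3.
#'
#' @param bone,roi [binary_mask()]s on the same grid.
#' @return Conn.D, 1/mm^3.
#' @export
conn_density <- function(bone, roi) {
  check_grid(bone, roi, "bone/roi")
  tv <- mask_volume(roi)
  if (tv == 0) stop("ROI is empty")
  chi <- euler3d(bone$values & roi$values)
  (1 - chi) / tv
}

#' Full trabecular microarchitecture panel on an ROI
#'
#' @param bone bone [binary_mask()].
#' @param roi ROI [binary_mask()] (e.g. a [cys_tb_shell()]).
#' @param total total-region mask used to define the void phase for Tb.Sp
#'   (`NULL`: void = everything non-bone).
#' @param n_directions,seed passed to [mil_tensor()].
#' @param da_convention passed to [mil_tensor()].
#' @return one-row tibble: `bv_tv` (%), `bs_bv` (1/mm), `tb_th_um`,
#'   `tb_sp_um`, `tb_n_mm` (1/mm), `smi`, `da`, `conn_d_mm3` (1/mm^3).
#' @export
microarch_panel <- function(bone, roi, total = NULL, n_directions = 256,
                            seed = 1L, da_convention = "ratio") {
  void_vals <- if (is.null(total)) !bone$values else total$values & !bone$values
  void <- with_values(bone, void_vals)
  th <- local_thickness(bone, roi)
  sp <- local_thickness(void, roi)
  bs <- bone_surface(bone, roi)
  tibble::tibble(
    bv_tv = bv_tv(bone, roi),
    bs_bv = bs$bs_bv,
    tb_th_um = th,
    tb_sp_um = sp,
    tb_n_mm = tb_n(th, sp),
    smi = smi(bone, roi),
    da = mil_tensor(bone, roi, n_directions = n_directions, seed = seed,
                    da_convention = da_convention)$da,
    conn_d_mm3 = conn_density(bone, roi)
  )
}
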