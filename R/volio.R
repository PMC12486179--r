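# File I/O for the pipeline's formats and the shared grid contract.
# Default volume format is NIfTI-1; TIFF stacks are accepted for micro-CT
# exports (spacing must then be given explicitly, TIFF carries none);
# MetaImage (.mhd/.mha) is read and written directly (plain text header +
# raw voxel block).

#' Read a voxel volume
#'
#' @param path file path (`.nii`/`.nii.gz`, `.tif`/`.tiff` multi-page
#'   stack, or `.mhd`/`.mha`).
#' @param format one of `"auto"`, `"nifti"`, `"tiff_stack"`, `"metaimage"`.
#' @param spacing explicit voxel spacing in mm (length 1 or 3); required
#'   for TIFF stacks, optional override otherwise.
#' @param allow_anisotropic if `FALSE` (default), anisotropic spacing is an
#'   error; the morphometry assumes isotropic grids.
#' @return a [voxel_volume()] with 8-bit (0-255) intensities. Sources
#'   exceeding the 8-bit range are linearly rescaled to 0-255 with a
#'   warning.
#' @export
read_volume <- function(path, format = c("auto", "nifti", "tiff_stack", "metaimage"),
                        spacing = NULL, allow_anisotropic = FALSE) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("no such file: ", path)

  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    vals <- as.array(img)
    if (length(dim(vals)) != 3L) stop("expected a 3D NIfTI volume")
    sp <- RNifti::pixdim(img)
    if (is.null(spacing)) {
      spacing <- sp[seq_len(3)]
      if (any(!is.finite(spacing)) || any(spacing <= 0))
        stop("NIfTI pixdim is missing or zero; pass `spacing` explicitly")
    }
  } else if (format == "tiff_stack") {
    if (is.null(spacing))
      stop("TIFF stacks carry no voxel spacing; pass `spacing` explicitly")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    vals <- array(0, c(d[2], d[1], length(pages)))  # pages are row x col = y x x
    for (k in seq_along(pages)) vals[, , k] <- t(pages[[k]])
  } else {
    mi <- read_metaimage(path)
    vals <- mi$values
    if (is.null(spacing)) {
      spacing <- mi$spacing
      if (is.null(spacing)) stop("MetaImage header lacks ElementSpacing; pass `spacing`")
    }
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (!allow_anisotropic && diff(range(spacing)) > 1e-9 * max(spacing))
    stop("anisotropic spacing (", paste(signif(spacing, 5), collapse = ", "),
         " mm); pass allow_anisotropic = TRUE to accept")

  rng <- range(vals)
  if (rng[2] > 255 || rng[1] < 0) {
    warning(sprintf("source intensities span [%g, %g]; rescaling to 0-255", rng[1], rng[2]))
    vals <- (vals - rng[1]) / (rng[2] - rng[1]) * 255
  }
  vals <- array(as.integer(round(vals)), dim(vals))  # strip reader classes
  voxel_volume(vals, spacing)
}

guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.tiff?$", path)) "tiff_stack"
  else if (grepl("\\.mhd?a?$", path)) "metaimage"
  else stop("cannot infer volume format from path: ", path)
}

#' Write a voxel volume
#'
#' @param vol a [voxel_volume()] (or mask/label volume; logicals are
#'   written as 0/1).
#' @param path output path; the extension selects the format
#'   (`.nii`/`.nii.gz`, `.tif`/`.tiff`, `.mhd`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  format <- guess_format(path)
  vals <- vol$values
  if (is.logical(vals)) { vals <- vals * 1L; dim(vals) <- dim(vol$values) }
  if (format == "nifti") {
    img <- RNifti::asNifti(vals, datatype = "auto")
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
  } else if (format == "tiff_stack") {
    pages <- lapply(seq_len(dim(vals)[3]), function(k) t(vals[, , k]) / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else {
    write_metaimage(vals, vol$spacing, path)
  }
  invisible(path)
}

# MetaImage: text header (.mhd or combined .mha) + raw little-endian block
read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("malformed MetaImage header")
    hdr <- c(hdr, line)
    if (grepl("^ElementDataFile", line)) break
  }
  kv <- strsplit(hdr, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  names(vals) <- keys
  dims <- as.integer(strsplit(trimws(vals[["DimSize"]]), "\\s+")[[1]])
  spacing <- if ("ElementSpacing" %in% keys)
    as.numeric(strsplit(trimws(vals[["ElementSpacing"]]), "\\s+")[[1]]) else NULL
  etype <- trimws(vals[["ElementType"]])
  datafile <- trimws(vals[["ElementDataFile"]])
  n <- prod(dims)
  readfun <- function(con) switch(etype,
    MET_UCHAR  = as.integer(readBin(con, "integer", n, size = 1, signed = FALSE)),
    MET_SHORT  = readBin(con, "integer", n, size = 2, signed = TRUE, endian = "little"),
    MET_USHORT = readBin(con, "integer", n, size = 2, signed = FALSE, endian = "little"),
    MET_FLOAT  = readBin(con, "double", n, size = 4, endian = "little"),
    MET_DOUBLE = readBin(con, "double", n, size = 8, endian = "little"),
    stop("unsupported MetaImage ElementType: ", etype))
  if (identical(datafile, "LOCAL")) {
    raw <- readfun(con)
  } else {
    con2 <- file(file.path(dirname(path), datafile), "rb")
    on.exit(close(con2), add = TRUE)
    raw <- readfun(con2)
  }
  list(values = array(raw, dims), spacing = spacing)
}

write_metaimage <- function(vals, spacing, path) {
  dims <- dim(vals)
  rawfile <- sub("\\.mhd$", ".raw", basename(path))
  local_data <- grepl("\\.mha$", path)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %s", paste(dims, collapse = " ")),
    sprintf("ElementSpacing = %s", paste(spacing, collapse = " ")),
    "ElementType = MET_UCHAR",
    sprintf("ElementDataFile = %s", if (local_data) "LOCAL" else rawfile)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  payload <- as.raw(pmax(pmin(as.integer(vals), 255L), 0L))
  if (local_data) {
    writeBin(payload, con)
  } else {
    con2 <- file(file.path(dirname(path), rawfile), "wb")
    on.exit(close(con2), add = TRUE)
    writeBin(payload, con2)
  }
  invisible(path)
}

# landmarks ------------------------------------------------------------------

#' Anatomical landmark set
#'
#' The three centres (femoral head, fovea capitis, femoral neck/calcar)
#' define the reference plane of the six-region segmentation; `mtd` is the
#' main-trabeculae direction. Coordinates are world mm on the volume grid.
#'
#' @param head_centre,fovea_centre,neck_centre numeric length-3, mm.
#' @param mtd main trabeculae direction; normalized to unit length. May be
#'   `NULL`, in which case [estimate_mtd()] is expected downstream.
#' @param side `"left"` or `"right"` hip.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(head_centre, fovea_centre, neck_centre,
                         mtd = NULL, side = c("left", "right")) {
  side <- match.arg(side)
  pts <- rbind(head_centre, fovea_centre, neck_centre)
  if (ncol(pts) != 3L || any(!is.finite(pts))) stop("landmarks must be finite xyz mm")
  cr <- vcross(fovea_centre - head_centre, neck_centre - head_centre)
  if (sqrt(sum(cr^2)) < 1e-9 * max(1, max(abs(pts))))
    stop("reference plane undefined: the three landmark centres are collinear")
  if (!is.null(mtd)) {
    nn <- sqrt(sum(mtd^2))
    if (nn == 0) stop("mtd must be a non-zero vector")
    mtd <- mtd / nn
  }
  structure(list(head_centre = as.numeric(head_centre),
                 fovea_centre = as.numeric(fovea_centre),
                 neck_centre = as.numeric(neck_centre),
                 mtd = mtd, side = side),
            class = "landmark_set")
}

vcross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Read landmarks from JSON
#'
#' Schema: `{"head_centre":[x,y,z], "fovea_centre":[...], "neck_centre":
#' [...], "mtd":[...] (optional), "side":"left"|"right"}`.
#' @param path JSON file.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("head_centre", "fovea_centre", "neck_centre")
  if (!all(need %in% names(j)))
    stop("landmark JSON must contain ", paste(need, collapse = ", "))
  landmark_set(j$head_centre, j$fovea_centre, j$neck_centre,
               mtd = j$mtd, side = if (is.null(j$side)) "left" else j$side)
}

#' Write landmarks to JSON
#' @param lm a [landmark_set()].
#' @param path output path.
#' @export
write_landmarks <- function(lm, path) {
  jsonlite::write_json(
    list(head_centre = lm$head_centre, fovea_centre = lm$fovea_centre,
         neck_centre = lm$neck_centre, mtd = lm$mtd, side = lm$side),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# reports ---------------------------------------------------------------------

#' Write the per-cyst, summary and morphometry reports
#'
#' Writes `cysts.csv` (one row per cyst: id, volume_mm3, diameter_mm,
#' centroid, region, pillar, hemisphere), `summary.json` (the Cyst.N/V/
#' Ave/Min/Max panel plus any extra parameters), and optionally
#' `morphometry.csv` (one row per cyst ROI, 8-parameter panel).
#'
#' @param records tibble of cyst records ([label_cysts()]).
#' @param summary cyst summary tibble ([cyst_summary()]).
#' @param params optional tibble of per-cyst morphometry panels.
#' @param dir output directory (created if needed).
#' @return named list of the paths written, invisibly.
#' @export
write_report <- function(records, summary, params = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(cysts = file.path(dir, "cysts.csv"),
                summary = file.path(dir, "summary.json"))
  readr::write_csv(records, paths$cysts)
  jsonlite::write_json(as.list(summary), paths$summary,
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  if (!is.null(params)) {
    paths$morphometry <- file.path(dir, "morphometry.csv")
    readr::write_csv(params, paths$morphometry)
  }
  invisible(paths)
}
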