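#' Construct a short-axis image stack
#'
#' An `pat_image_stack` holds an ordered set of 2D slices (index 0 = most
#' cranial) together with the geometry needed to turn pixel counts into
#' volumes: in-plane pixel spacing, slice thickness and inter-slice gap.
#' Geometry is mandatory — no spacing is ever assumed.
#'
#' @param slices A 3D numeric array `[row, col, slice]`, or a list of equally
#'   sized numeric matrices (one per slice, cranial to caudal).
#' @param pixel_spacing Numeric length-2, `(dy, dx)` mm per pixel.
#' @param slice_thickness Slice thickness in mm.
#' @param slice_gap Inter-slice gap in mm (default 0); the center-to-center
#'   spacing is `slice_thickness + slice_gap`.
#' @param subject_id Optional free-text subject identifier.
#' @return An object of class `pat_image_stack`.
#' @examples
#' s <- image_stack(array(0, c(8, 8, 3)), pixel_spacing = c(1.5, 1.5),
#'                  slice_thickness = 6)
#' n_slices(s)
#' @export
image_stack <- function(slices, pixel_spacing, slice_thickness = 6,
                        slice_gap = 0, subject_id = NA_character_) {
  if (is.list(slices)) {
    if (length(slices) == 0L) abort("stack must contain at least one slice")
    dims <- unique(lapply(slices, dim))
    if (length(dims) != 1L)
      abort("all slices must share identical row/column dimensions")
    slices <- array(unlist(slices, use.names = FALSE),
                    dim = c(dims[[1]], length(slices)))
  }
  if (!is.array(slices) || length(dim(slices)) != 3L)
    abort("`slices` must be a 3D array or a list of matrices")
  if (dim(slices)[3] < 1L) abort("stack must contain at least one slice")
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) != 2L || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0))
    abort("`pixel_spacing` must be two positive numbers (dy, dx) in mm")
  if (!is.finite(slice_thickness) || slice_thickness <= 0)
    abort("`slice_thickness` must be a positive number of mm")
  if (!is.finite(slice_gap) || slice_gap < 0)
    abort("`slice_gap` must be >= 0 mm")
  structure(
    list(data = slices, pixel_spacing = pixel_spacing,
         slice_thickness = as.numeric(slice_thickness),
         slice_gap = as.numeric(slice_gap),
         subject_id = as.character(subject_id)),
    class = "pat_image_stack")
}

#' @export
print.pat_image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<pat_image_stack> %d slice(s) of %d x %d px; spacing %g x %g mm; thickness %g mm, gap %g mm%s\n",
    d[3], d[1], d[2], x$pixel_spacing[1], x$pixel_spacing[2],
    x$slice_thickness, x$slice_gap,
    if (is.na(x$subject_id)) "" else paste0("; subject ", x$subject_id)))
  invisible(x)
}

#' @rdname image_stack
#' @param stack A `pat_image_stack`.
#' @export
n_slices <- function(stack) dim(stack$data)[3]

#' Center-to-center slice spacing (mm)
#'
#' @param stack A `pat_image_stack`.
#' @return `slice_thickness + slice_gap` in mm.
#' @export
slice_spacing <- function(stack) stack$slice_thickness + stack$slice_gap

#' Axial coordinate of a slice center
#'
#' Slice `i` (0-based, cranial to caudal) is centered at
#' `i * (slice_thickness + slice_gap)` mm from slice 0.
#'
#' @param stack A `pat_image_stack`.
#' @param i 0-based slice index (vectorized).
#' @return z coordinate(s) in mm.
#' @export
slice_z <- function(stack, i) i * slice_spacing(stack)

#' Extract one slice as a matrix
#' @param stack A `pat_image_stack`.
#' @param i 0-based slice index.
#' @return Numeric matrix.
#' @export
get_slice <- function(stack, i) {
  ns <- n_slices(stack)
  if (i < 0 || i >= ns) abort(sprintf("slice index %d out of range [0, %d]", i, ns - 1L))
  stack$data[, , i + 1L]
}

#' Test whether a stack is a binary mask stack
#' @param stack A `pat_image_stack`.
#' @return `TRUE` if every voxel is 0 or 1.
#' @export
is_mask_stack <- function(stack) all(stack$data %in% c(0, 1))

geometry_of <- function(stack) {
  list(pixel_spacing = stack$pixel_spacing,
       slice_thickness = stack$slice_thickness,
       slice_gap = stack$slice_gap)
}

# ---------------------------------------------------------------------------
# Stack readers / writers
# ---------------------------------------------------------------------------

RAW_SCHEMA <- "pat3d-stack"
RAW_VERSION <- 1L

#' Write an image stack to disk
#'
#' Two on-disk dialects are supported. `"nifti"` writes standard NIfTI-1
#' (gzipped if the path ends in `.gz`): pixel spacing and center-to-center
#' slice spacing go into `pixdim`, and the thickness/gap decomposition is
#' recorded in the `descrip` field. `"raw"` writes a lossless pair
#' `<path>.json` (geometry header) + `<path>.bin` (float64 little-endian
#' voxels, slice by slice), which round-trips bit-exactly.
#'
#' @param stack A `pat_image_stack`.
#' @param path Output path. For `"raw"` this is a prefix: `<path>.json` and
#'   `<path>.bin` are written.
#' @param format `"nifti"`, `"raw"`, or `"auto"` (NIfTI iff path ends in
#'   `.nii`/`.nii.gz`).
#' @return `path`, invisibly.
#' @seealso [read_stack()]
#' @export
write_stack <- function(stack, path, format = c("auto", "nifti", "raw")) {
  stopifnot(inherits(stack, "pat_image_stack"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "raw"
  if (format == "nifti") {
    img <- RNifti::asNifti(stack$data)
    RNifti::pixdim(img) <- c(stack$pixel_spacing, slice_spacing(stack))
    img$descrip <- sprintf("pat3d thk=%.17g gap=%.17g", stack$slice_thickness,
                           stack$slice_gap)
    ok <- tryCatch({RNifti::writeNifti(img, path); TRUE},
                   error = function(e) abort(paste0("cannot write ", path, ": ",
                                                    conditionMessage(e))))
  } else {
    header <- list(schema = RAW_SCHEMA, version = RAW_VERSION,
                   dims = dim(stack$data),
                   pixel_spacing = stack$pixel_spacing,
                   slice_thickness = stack$slice_thickness,
                   slice_gap = stack$slice_gap,
                   subject_id = stack$subject_id,
                   dtype = "float64", byte_order = "little")
    hpath <- paste0(path, ".json"); bpath <- paste0(path, ".bin")
    tryCatch({
      # digits = I(17): geometry floats must round-trip bit-exactly
      jsonlite::write_json(header, hpath, auto_unbox = TRUE, digits = I(17))
      con <- file(bpath, "wb"); on.exit(close(con))
      writeBin(as.double(stack$data), con, size = 8L, endian = "little")
    }, error = function(e) abort(paste0("cannot write ", path, ": ",
                                        conditionMessage(e))))
  }
  invisible(path)
}

#' Read an image stack from disk
#'
#' Reads either dialect written by [write_stack()]. Geometry is mandatory:
#' a NIfTI file with non-positive or non-finite `pixdim` entries is rejected
#' with a geometry-missing error rather than silently defaulted. When the
#' NIfTI `descrip` field does not carry the thickness/gap decomposition, the
#' whole center-to-center spacing is taken as slice thickness with zero gap
#' (the decomposition does not affect volumes, which use center-to-center
#' spacing throughout).
#'
#' @param path Path to a `.nii`/`.nii.gz` file or a raw-dialect prefix
#'   (with or without the `.json` suffix).
#' @param format_hint `"auto"`, `"nifti"` or `"raw"`.
#' @return A `pat_image_stack` with slices ordered cranial to caudal.
#' @export
read_stack <- function(path, format_hint = c("auto", "nifti", "raw")) {
  format_hint <- match.arg(format_hint)
  if (format_hint == "auto") {
    format_hint <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "raw"
  }
  if (format_hint == "nifti") {
    if (!file.exists(path)) abort(paste0("no such file: ", path))
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) abort(paste0("unreadable NIfTI file ",
                                                     path, ": ",
                                                     conditionMessage(e))))
    arr <- as.array(img)
    arr <- array(as.numeric(arr), dim(arr))   # drop NIfTI attributes
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3L)
      abort(sprintf("expected a 3D stack, got %d dimensions", length(dim(arr))))
    pd <- RNifti::pixdim(img)
    if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
      abort("geometry missing: NIfTI pixdim must be positive in all three axes")
    descrip <- RNifti::niftiHeader(img)$descrip
    m <- regmatches(descrip,
                    regexec("pat3d thk=([0-9.eE+-]+) gap=([0-9.eE+-]+)", descrip))[[1]]
    if (length(m) == 3L) {
      thk <- as.numeric(m[2]); gap <- as.numeric(m[3])
    } else {
      thk <- pd[3]; gap <- 0
    }
    image_stack(arr, pixel_spacing = pd[1:2], slice_thickness = thk,
                slice_gap = gap)
  } else {
    hpath <- if (grepl("\\.json$", path)) path else paste0(path, ".json")
    bpath <- sub("\\.json$", "", hpath); bpath <- paste0(bpath, ".bin")
    if (!file.exists(hpath)) abort(paste0("no such file: ", hpath))
    header <- tryCatch(jsonlite::read_json(hpath, simplifyVector = TRUE),
                       error = function(e) abort(paste0("unreadable header ",
                                                        hpath, ": ",
                                                        conditionMessage(e))))
    if (!identical(header$schema, RAW_SCHEMA))
      abort(paste0("not a ", RAW_SCHEMA, " header: ", hpath))
    if (!identical(as.integer(header$version), RAW_VERSION))
      abort(sprintf("unsupported %s schema version %s", RAW_SCHEMA,
                    header$version))
    need <- c("dims", "pixel_spacing", "slice_thickness", "slice_gap")
    if (!all(need %in% names(header)))
      abort(paste0("geometry missing from header: ",
                   paste(setdiff(need, names(header)), collapse = ", ")))
    dims <- as.integer(header$dims)
    if (length(dims) != 3L || any(dims < 1L))
      abort("header dims must be three positive integers")
    con <- file(bpath, "rb"); on.exit(close(con))
    vox <- readBin(con, "double", n = prod(dims), size = 8L, endian = "little")
    if (length(vox) != prod(dims))
      abort(sprintf("binary payload truncated: expected %d voxels, read %d",
                    prod(dims), length(vox)))
    image_stack(array(vox, dims), pixel_spacing = header$pixel_spacing,
                slice_thickness = header$slice_thickness,
                slice_gap = header$slice_gap,
                subject_id = header$subject_id %||% NA_character_)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# ROI sets (versioned JSON)
# ---------------------------------------------------------------------------

ROI_SCHEMA <- "pat3d-roi"
ROI_VERSION <- 1L

#' Construct a per-slice ROI annotation set
#'
#' Annotations are applied in order by [apply_roi_set()]: `polygon` and
#' `seed` annotations add fat pixels, `erase_polygon` removes them.
#'
#' @param annotations A list of annotations, each a list with fields
#'   `slice` (0-based index), `type` (`"polygon"`, `"seed"` or
#'   `"erase_polygon"`), and either `vertices` (an n x 2 matrix of 0-based
#'   `(row, col)` pixel coordinates, n >= 3) or `seed` (length-2 `(row, col)`)
#'   plus `tolerance` (intensity units). An optional `label` tags the
#'   annotation as `"atrial"`, `"ventricular"` or `"unassigned"`.
#' @return A `pat_roi_set`.
#' @export
roi_set <- function(annotations = list()) {
  anns <- lapply(annotations, validate_annotation)
  structure(list(annotations = anns, version = ROI_VERSION),
            class = "pat_roi_set")
}

validate_annotation <- function(a) {
  if (is.null(a$slice) || a$slice < 0 || a$slice != round(a$slice))
    abort("annotation `slice` must be a non-negative integer (0-based)")
  a$slice <- as.integer(a$slice)
  if (is.null(a$type) ||
      !a$type %in% c("polygon", "seed", "erase_polygon"))
    abort("annotation `type` must be polygon, seed or erase_polygon")
  a$label <- a$label %||% "unassigned"
  if (!a$label %in% c("atrial", "ventricular", "unassigned"))
    abort("annotation `label` must be atrial, ventricular or unassigned")
  if (a$type %in% c("polygon", "erase_polygon")) {
    v <- a$vertices
    if (is.null(v)) abort("polygon annotation needs `vertices`")
    if (!is.matrix(v)) v <- do.call(rbind, lapply(v, as.numeric))
    if (ncol(v) != 2L || nrow(v) < 3L)
      abort("polygons need >= 3 (row, col) vertices")
    a$vertices <- unname(v * 1.0)
  } else {
    if (is.null(a$seed) || length(a$seed) != 2L)
      abort("seed annotation needs a (row, col) `seed`")
    a$seed <- as.numeric(a$seed)
    if (is.null(a$tolerance) || a$tolerance < 0)
      abort("seed annotation needs `tolerance` >= 0")
    a$tolerance <- as.numeric(a$tolerance)
  }
  a
}

#' @export
print.pat_roi_set <- function(x, ...) {
  cat(sprintf("<pat_roi_set> %d annotation(s) on slice(s) %s\n",
              length(x$annotations),
              paste(sort(unique(vapply(x$annotations, `[[`, 0L, "slice"))),
                    collapse = ", ")))
  invisible(x)
}

#' Write / read an ROI set as versioned JSON
#'
#' The JSON schema is identified by `"schema": "pat3d-roi"` and an integer
#' `"version"`; files with an unknown version are rejected.
#'
#' @param roi A `pat_roi_set`.
#' @param path JSON file path.
#' @return `write_roi_set`: `path` invisibly; `read_roi_set`: a
#'   `pat_roi_set` with annotations in file order.
#' @export
write_roi_set <- function(roi, path) {
  stopifnot(inherits(roi, "pat_roi_set"))
  anns <- lapply(roi$annotations, function(a) {
    out <- list(slice = a$slice, type = a$type, label = a$label)
    if (!is.null(a$vertices))
      out$vertices <- apply(a$vertices, 1L, as.numeric, simplify = FALSE)
    if (!is.null(a$seed)) { out$seed <- a$seed; out$tolerance <- a$tolerance }
    out
  })
  jsonlite::write_json(list(schema = ROI_SCHEMA, version = ROI_VERSION,
                            annotations = anns),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$schema, ROI_SCHEMA))
    abort(paste0("not a ", ROI_SCHEMA, " document: ", path))
  if (!identical(as.integer(doc$version), ROI_VERSION))
    abort(sprintf("unsupported %s schema version %s", ROI_SCHEMA, doc$version))
  anns <- lapply(doc$annotations, function(a) {
    if (!is.null(a$vertices))
      a$vertices <- do.call(rbind, lapply(a$vertices, unlist))
    if (!is.null(a$seed)) a$seed <- unlist(a$seed)
    a
  })
  roi_set(anns)
}

#' Validate that an ROI set binds to a stack
#'
#' Checks that every referenced slice exists and every vertex/seed lies
#' within image bounds; errors otherwise.
#'
#' @param roi A `pat_roi_set`.
#' @param stack A `pat_image_stack`.
#' @return `roi`, invisibly, if valid.
#' @export
validate_roi_binding <- function(roi, stack) {
  d <- dim(stack$data); ns <- d[3]
  for (a in roi$annotations) {
    if (a$slice >= ns)
      abort(sprintf("annotation references slice %d but stack has %d slices",
                    a$slice, ns))
    pts <- if (!is.null(a$vertices)) a$vertices else matrix(a$seed, 1L)
    if (any(pts[, 1] < 0 | pts[, 1] > d[1] - 1 |
            pts[, 2] < 0 | pts[, 2] > d[2] - 1))
      abort(sprintf("annotation on slice %d has coordinates outside the %d x %d image",
                    a$slice, d[1], d[2]))
  }
  invisible(roi)
}

# ---------------------------------------------------------------------------
# Paired measurement tables
# ---------------------------------------------------------------------------

#' Read a paired measurement table (CSV)
#'
#' The table must have a header row with columns `subject`, `quantity` and
#' exactly two numeric method columns (e.g. `autopsy_g`, `cmr_g`); each row
#' is one subject x quantity pair of measurements in grams. The method
#' comparison functions orient differences as second method minus first, so
#' put the reference method first.
#'
#' @param path CSV file path.
#' @return A tibble of class `pat_paired_table` with attribute `methods`
#'   giving the two method column names.
#' @examples
#' tab <- read_paired_table(pat_example("sheep_pat_autopsy_cmr.csv"))
#' dplyr::count(tab, quantity)
#' @export
read_paired_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("subject", "quantity") %in% names(raw)))
    abort("paired table must have `subject` and `quantity` columns")
  methods <- setdiff(names(raw), c("subject", "quantity"))
  if (length(methods) != 2L)
    abort(sprintf("paired table must have exactly two method columns, found %d",
                  length(methods)))
  for (m in methods) {
    vals <- suppressWarnings(as.numeric(raw[[m]]))
    bad <- which(is.na(vals) & !is.na(raw[[m]]))
    if (any(is.na(raw[[m]])))
      abort(sprintf("missing value in column `%s` (row %d)", m,
                    which(is.na(raw[[m]]))[1] + 1L))
    if (length(bad))
      abort(sprintf("non-numeric mass `%s` in column `%s` (row %d)",
                    raw[[m]][bad[1]], m, bad[1] + 1L))
    raw[[m]] <- vals
  }
  out <- tibble::as_tibble(raw)
  attr(out, "methods") <- methods
  class(out) <- c("pat_paired_table", class(out))
  out
}

#' Path to a packaged example file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
pat_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "pat3d")))
  system.file("extdata", file, package = "pat3d", mustWork = TRUE)
}
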