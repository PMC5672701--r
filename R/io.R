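# Volume, mask and seed-file readers/writers.
#
# Internal array convention: `[y, x, z]`, 1-based, z the slice (axial)
# axis.  NIfTI stores `[x, y, z]`; the readers/writers transpose
# accordingly.  Seed files use 1-based (y, x) pixel coordinates with y the
# row and x the column, matching R matrix indexing.

#' Read a volume from NIfTI or an image-stack directory
#'
#' A `.nii`/`.nii.gz` path is read with RNifti; a directory is read as a
#' PNG/TIFF slice stack in lexicographic filename order (slice 1 first).
#' Multi-channel slice images are averaged to grayscale.
#'
#' @param path File or directory path.
#' @return An `rw_volume`: `data` (numeric `[y, x, z]` array), `spacing`
#'   (`c(dy, dx, dz)` in mm; 1 for image stacks), `ref` (NIfTI header
#'   object or `NULL`), `source`.
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L)
      stop("format error: no PNG/TIFF slices found in ", path)
    slices <- lapply(files, function(f) {
      img <- if (grepl("\\.png$", f, ignore.case = TRUE))
        png::readPNG(f) else tiff::readTIFF(f)
      if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
      img
    })
    dims <- unique(lapply(slices, dim))
    if (length(dims) != 1L)
      stop("format error: slice images have mixed sizes in ", path)
    data <- array(unlist(slices), c(dims[[1]], length(slices)))
    structure(list(data = data, spacing = c(1, 1, 1), ref = NULL,
                   source = path),
              class = "rw_volume")
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    nii <- RNifti::readNifti(path)
    arr <- as.array(nii)
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3L)
      stop("format error: expected a 3D NIfTI volume")
    pd <- RNifti::pixdim(nii)
    structure(list(data = aperm(arr, c(2, 1, 3)),
                   spacing = c(pd[2], pd[1], pd[3]),
                   ref = nii, source = path),
              class = "rw_volume")
  } else {
    stop("format error: ", path, " is neither a NIfTI file nor a directory")
  }
}

#' @export
print.rw_volume <- function(x, ...) {
  cat(sprintf("rw_volume: %s voxels, spacing %s mm, from %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), x$source))
  invisible(x)
}

#' Write a mask (or volume) to NIfTI or a PNG stack
#'
#' A `.nii`/`.nii.gz` path writes a NIfTI file (uint8 for logical masks)
#' on the reference grid; a directory path writes one PNG per slice
#' (`slice_0001.png`, ...).
#'
#' @param mask Logical or numeric `[y, x, z]` array (a 2D matrix is
#'   treated as a single slice).
#' @param path Output file or directory.
#' @param ref Optional `rw_volume` whose NIfTI header/geometry is reused.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, ref = NULL) {
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  stopifnot(length(dim(mask)) == 3L)
  if (!is.null(ref)) {
    stopifnot(inherits(ref, "rw_volume"))
    if (!identical(dim(mask), dim(ref$data)))
      stop("mask does not match the reference grid")
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    arr <- aperm(mask, c(2, 1, 3))
    if (is.logical(arr)) storage.mode(arr) <- "integer"
    img <- if (!is.null(ref) && !is.null(ref$ref))
      RNifti::asNifti(arr, reference = ref$ref) else RNifti::asNifti(arr)
    dt <- if (max(arr) <= 255 && min(arr) >= 0 && all(arr == round(arr)))
      "uint8" else "auto"
    RNifti::writeNifti(img, path, datatype = dt)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    nz <- dim(mask)[3]
    mx <- max(mask)
    for (z in seq_len(nz)) {
      sl <- mask[, , z] * 1
      if (mx > 0) sl <- sl / max(mx, 1)
      png::writePNG(sl, file.path(path, sprintf("slice_%04d.png", z)))
    }
  }
  invisible(path)
}

#' Read seed coordinates from a JSON or whitespace text file
#'
#' Two formats are accepted.  JSON:
#' `{"object": [[y, x], ...], "background": [[y, x], ...]}` (entries may
#' also be `[y, x, z]`).  Text: one `label y x` (or `label y x z`) triplet
#' per line, `label` being `1`/`object` or `2`/`background`; blank lines
#' and lines starting with `#` are ignored.  Coordinates are 1-based.
#'
#' @param path Seed file.
#' @param dims Optional grid dimensions for bounds checking.
#' @return A data frame (`label`, `y`, `x`[, `z`]); pass through
#'   [seeds_from_coords()] to obtain linear indices.
#' @export
read_seeds <- function(path, dims = NULL) {
  txt <- readLines(path, warn = FALSE)
  txt <- trimws(txt)
  txt <- txt[nzchar(txt) & !startsWith(txt, "#")]
  if (length(txt) == 0L) stop("seed file ", path, " is empty")
  if (startsWith(txt[1], "{") || grepl("\\.json$", path, ignore.case = TRUE)) {
    js <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                   collapse = "\n"),
                             simplifyMatrix = TRUE)
    parse_class <- function(m, lab) {
      if (is.null(m) || length(m) == 0L) return(NULL)
      m <- if (is.matrix(m)) m else matrix(unlist(m), ncol = length(m[[1]]),
                                           byrow = TRUE)
      df <- data.frame(label = lab, y = m[, 1], x = m[, 2])
      if (ncol(m) >= 3L) df$z <- m[, 3]
      df
    }
    out <- rbind(parse_class(js$object, 1L), parse_class(js$background, 2L))
    if (is.null(out) || nrow(out) == 0L) stop("seed file ", path, " is empty")
  } else {
    fields <- strsplit(txt, "[[:space:],]+")
    nf <- lengths(fields)
    if (any(nf < 3L))
      stop("seed file parse error at line ", which(nf < 3L)[1],
           ": expected `label y x`")
    lab <- vapply(fields, `[[`, "", 1L)
    lab_num <- ifelse(lab %in% c("1", "object"), 1L,
                      ifelse(lab %in% c("2", "background"), 2L, NA_integer_))
    if (anyNA(lab_num))
      stop("seed file parse error at line ", which(is.na(lab_num))[1],
           ": unknown label '", lab[is.na(lab_num)][1], "'")
    out <- data.frame(label = lab_num,
                      y = as.integer(vapply(fields, `[[`, "", 2L)),
                      x = as.integer(vapply(fields, `[[`, "", 3L)))
    if (all(nf >= 4L))
      out$z <- as.integer(vapply(fields, `[[`, "", 4L))
  }
  # conflicting duplicate coordinates are an input error
  key <- do.call(paste, out[setdiff(names(out), "label")])
  for (k in unique(key[duplicated(key)])) {
    if (length(unique(out$label[key == k])) > 1L)
      stop("conflict: seed pixel (", k, ") listed with both labels")
  }
  if (!is.null(dims)) seeds_from_coords(out, dims)  # bounds check only
  out
}

#' Write per-slice provenance records as JSON
#'
#' @param seg An `rw_segmentation`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(seg, path) {
  stopifnot(inherits(seg, "rw_segmentation"))
  keep <- !vapply(seg$provenance, is.null, logical(1))
  jsonlite::write_json(seg$provenance[keep], path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
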