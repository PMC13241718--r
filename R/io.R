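# Slice and cohort I/O. Images travel as NIfTI (spacing from the header) or
# PNG with a JSON geometry sidecar; masks as PNG or NIfTI; cohorts as a
# manifest CSV. Spec JSON round-trips losslessly.

#' Write a slice record to disk
#'
#' @param slice a [slice_record()].
#' @param path base path without extension.
#' @param format "nifti" (image + masks as .nii.gz, spacing in the header;
#'   lossless) or "png" (8-bit min-max rescaled image PNG + mask PNGs +
#'   `<path>_geometry.json` sidecar recording the rescaling; for viewing and
#'   masks).
#' @return invisible character vector of files written.
#' @export
write_slice <- function(slice, path, format = c("nifti", "png")) {
  format <- match.arg(format)
  g <- slice$geometry
  files <- character(0)
  if (format == "nifti") {
    wr <- function(m, suffix) {
      f <- paste0(path, suffix, ".nii.gz")
      img <- RNifti::asNifti(m, reference = NULL)
      RNifti::pixdim(img) <- c(g$row_spacing_mm, g$col_spacing_mm)
      RNifti::writeNifti(img, f)
      f
    }
    files <- wr(slice$image, "")
    if (!is.null(slice$myo_mask)) files <- c(files, wr(slice$myo_mask, "_myo"))
    if (!is.null(slice$scar_mask)) files <- c(files, wr(slice$scar_mask, "_scar"))
    if (!is.null(slice$exclusion_mask)) files <- c(files, wr(slice$exclusion_mask, "_excl"))
    side <- paste0(path, "_geometry.json")
    jsonlite::write_json(list(row_spacing_mm = g$row_spacing_mm,
                              col_spacing_mm = g$col_spacing_mm,
                              thickness_mm = g$thickness_mm),
                         side, auto_unbox = TRUE, digits = NA)
    files <- c(files, side)
  } else {
    rng <- range(slice$image)
    x01 <- if (rng[1] == rng[2]) slice$image * 0 else (slice$image - rng[1]) / (rng[2] - rng[1])
    f <- paste0(path, ".png")
    png::writePNG(x01, f)
    files <- f
    wr_mask <- function(m, suffix) {
      fm <- paste0(path, suffix, ".png")
      png::writePNG(m, fm)
      fm
    }
    if (!is.null(slice$myo_mask)) files <- c(files, wr_mask(slice$myo_mask, "_myo"))
    if (!is.null(slice$scar_mask)) files <- c(files, wr_mask(slice$scar_mask, "_scar"))
    side <- paste0(path, "_geometry.json")
    jsonlite::write_json(list(row_spacing_mm = g$row_spacing_mm,
                              col_spacing_mm = g$col_spacing_mm,
                              thickness_mm = g$thickness_mm,
                              intensity_min = rng[1], intensity_max = rng[2]),
                         side, auto_unbox = TRUE, digits = NA)
    files <- c(files, side)
  }
  invisible(files)
}

#' Read a slice image (NIfTI or PNG + JSON sidecar) into a slice record
#'
#' @param path image path (`.nii`, `.nii.gz` or `.png`); a
#'   `*_geometry.json` sidecar supplies spacing for PNG input and overrides
#'   the NIfTI header when present.
#' @param myo_path,scar_path optional mask files in the same format.
#' @return a [slice_record()].
#' @export
read_slice <- function(path, myo_path = NULL, scar_path = NULL) {
  is_nii <- grepl("\\.nii(\\.gz)?$", path)
  side <- sub("\\.(nii(\\.gz)?|png)$", "_geometry.json", path)
  geo <- NULL
  if (file.exists(side)) {
    j <- jsonlite::fromJSON(side)
    geo <- voxel_geometry(j$row_spacing_mm, j$col_spacing_mm, j$thickness_mm)
  }
  read_one <- function(f) {
    if (grepl("\\.nii(\\.gz)?$", f)) {
      as.matrix(RNifti::readNifti(f)[, ])
    } else {
      a <- png::readPNG(f)
      if (length(dim(a)) == 3) a <- a[, , 1]
      a
    }
  }
  img <- read_one(path)
  if (is.null(geo) && is_nii) {
    pd <- RNifti::pixdim(RNifti::readNifti(path))
    geo <- voxel_geometry(pd[1], if (length(pd) > 1) pd[2] else pd[1],
                          if (length(pd) > 2) pd[3] else 8)
  }
  if (is.null(geo)) {
    stop("no geometry: provide a *_geometry.json sidecar or a NIfTI header",
         call. = FALSE)
  }
  j <- if (file.exists(side)) jsonlite::fromJSON(side) else NULL
  if (!is.null(j$intensity_min) && !is.null(j$intensity_max)) {
    img <- img * (j$intensity_max - j$intensity_min) + j$intensity_min
  }
  slice_record(img, geo,
               myo_mask = if (is.null(myo_path)) NULL else as_binary(read_one(myo_path)),
               scar_mask = if (is.null(scar_path)) NULL else as_binary(read_one(scar_path)))
}

#' Write a cohort to a directory with a manifest CSV
#'
#' @param cohort list of [slice_record()]s, as from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param split optional result of [stratified_split()] recorded per subject.
#' @param format passed to [write_slice()].
#' @return invisible path of the manifest CSV
#'   (columns: subject_id, slice_index, image, scar_mask, myo_mask,
#'   scar_pixels, split).
#' @export
write_cohort <- function(cohort, dir, split = NULL, format = "nifti") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "nifti") ".nii.gz" else ".png"
  rows <- lapply(cohort, function(rec) {
    base <- file.path(dir, sprintf("%s_slice%02d", rec$subject_id, rec$slice_index))
    write_slice(rec, base, format = format)
    sp <- NA_character_
    if (!is.null(split)) {
      for (nm in names(split)) if (rec$subject_id %in% split[[nm]]) sp <- nm
    }
    data.frame(subject_id = rec$subject_id, slice_index = rec$slice_index,
               image = paste0(base, ext),
               scar_mask = paste0(base, "_scar", ext),
               myo_mask = paste0(base, "_myo", ext),
               scar_pixels = sum(rec$scar_mask > 0),
               split = sp, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  f <- file.path(dir, "manifest.csv")
  write.csv(manifest, f, row.names = FALSE)
  invisible(f)
}

#' Serialize / deserialize a phantom spec to JSON (lossless round trip)
#'
#' @param spec a [phantom_spec()].
#' @return JSON string.
#' @export
spec_to_json <- function(spec) {
  jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA)
}

#' @rdname spec_to_json
#' @param json JSON string.
#' @export
spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  do.call(phantom_spec, x)
}
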