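# Image and label I/O (8-bit grayscale PNG, single-slice NIfTI) and YAML
# run configuration. Intensities are rescaled to the 0-255 working scale by
# min-max over the slice on read; coordinates are (row, col), 0-based,
# top-left origin.

#' Read a grayscale slice
#'
#' PNG is read as 8-bit gray (multi-channel images are averaged); NIfTI
#' volumes need `slice` to pick one 2-D slice. Intensities are min-max
#' rescaled to 0-255 (skipped with a warning for constant slices; 16-bit
#' extremes land on 0 and 255 exactly). DICOM is not supported; convert to
#' NIfTI or PNG first.
#'
#' @param path input file; format from the extension
#'   (`.png`, `.nii`, `.nii.gz`).
#' @param slice 1-based slice index along the third axis for 3-D NIfTI.
#' @param rescale rescale to 0-255 (default TRUE); set FALSE for label maps.
#' @return numeric intensity matrix.
#' @export
read_gray_image <- function(path, slice = NULL, rescale = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lp <- tolower(path)
  if (grepl("\\.dcm$|\\.dicom$", lp))
    stop(paste("DICOM input is not supported by this build;",
               "convert the frame to NIfTI or PNG first"), call. = FALSE)
  if (grepl("\\.png$", lp)) {
    a <- png::readPNG(path)
    m <- if (length(dim(a)) == 3) apply(a[, , seq_len(min(3, dim(a)[3])),
                                          drop = FALSE], c(1, 2), mean) else a
    img <- m * 255
  } else if (grepl("\\.nii$|\\.nii\\.gz$", lp)) {
    vol <- RNifti::readNifti(path)
    d <- dim(vol)
    if (length(d) >= 3 && any(d[-(1:2)] > 1)) {
      if (is.null(slice))
        stop("3-D NIfTI input: pass `slice` (--slice) to pick one slice",
             call. = FALSE)
      img <- as.matrix(vol[, , slice])
    } else {
      img <- matrix(as.numeric(vol), d[1], d[2])
    }
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  if (!rescale) return(img)
  rng <- range(img)
  if (diff(rng) == 0) {
    warning("constant-value slice; min-max rescale skipped")
    return(clip255(img))
  }
  (img - rng[1]) / diff(rng) * 255
}

#' Write an 8-bit grayscale PNG
#'
#' @param img numeric matrix, 0-255 scale (rounded and clipped).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gray_png <- function(img, path) {
  assert_gray(img)
  png::writePNG(round(clip255(img)) / 255, path)
  invisible(path)
}

#' Write an integer label map as PNG
#'
#' Labels are stored directly as 8-bit values so that small integer classes
#' survive a round trip.
#'
#' @param labels integer matrix with values 0..255.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_label_png <- function(labels, path) {
  if (any(labels < 0 | labels > 255)) stop("labels must fit 0..255", call. = FALSE)
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' Read an integer label map from PNG
#' @param path input path.
#' @return integer matrix.
#' @export
read_label_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
}

#' Write a matrix as single-slice NIfTI
#' @param img numeric matrix.
#' @param path output `.nii` / `.nii.gz` path.
#' @return the path, invisibly.
#' @export
write_gray_nifti <- function(img, path) {
  RNifti::writeNifti(RNifti::asNifti(img), path)
  invisible(path)
}

#' Load a YAML run configuration
#'
#' Sections `preprocess`, `haris`, `assi`, `learner` mirror the module
#' configs; unknown keys are rejected to catch typos.
#'
#' @param path YAML file.
#' @return a `run_config` list (see [run_config()]).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Assemble a run configuration
#'
#' @param preprocess,haris,assi,learner named lists of arguments passed to
#'   [filter_config()], [haris_config()], [assi_config()]; `learner` holds
#'   `store` (experience-store path or NULL).
#' @param classifier `"assi"` or `"fuzzy"` (the pixel-assignment variant).
#' @param seed integer master seed for the run.
#' @return a `run_config` list.
#' @export
run_config <- function(preprocess = list(), haris = list(k_min = 2, k_max = 8),
                       assi = list(), learner = list(store = NULL),
                       classifier = c("assi", "fuzzy"), seed = 1L) {
  classifier <- match.arg(classifier)
  structure(list(
    preprocess = do.call(filter_config, preprocess),
    haris = do.call(haris_config, haris),
    assi = do.call(assi_config, assi),
    learner = learner,
    classifier = classifier,
    seed = as.integer(seed)), class = "run_config")
}
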