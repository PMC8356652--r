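# End-to-end run: filter -> threshold -> region-count selection ->
# segmentation -> tumor classification -> evaluation -> experience update.
# Deterministic for a fixed config, seed and store state.

#' Geometric brain mask from a segmentation
#'
#' The brain parenchyma class is taken as the most populous intensity class
#' with no pixels on the image border (background touches the border, the
#' skull annulus and any filter transition bands hug the background); the
#' mask is the hole-filled extent of that class, so tumor blobs enclosed by
#' parenchyma are inside while skull, bands and background stay out.
#'
#' @param seg a [haris_segment()] result.
#' @return logical matrix.
#' @export
brain_mask <- function(seg) {
  labels <- seg$labels
  h <- nrow(labels); w <- ncol(labels)
  border_classes <- unique(c(labels[1, ], labels[h, ], labels[, 1], labels[, w]))
  cand <- setdiff(seg$stats$label, border_classes)
  if (length(cand) == 0)
    cand <- seg$stats$label[seg$stats$mean > min(seg$stats$mean)]
  if (length(cand) == 0) return(matrix(TRUE, h, w))
  counts <- seg$stats$pixel_count[match(cand, seg$stats$label)]
  dominant <- cand[which.max(counts)]
  EBImage::fillHull(labels == dominant) > 0
}

#' Run the full segmentation pipeline on one slice
#'
#' Stages: adaptive bilateral filter, fuzzy-entropy threshold, region-count
#' selection, region assembly, tumor classification (`"assi"`: region-level
#' correlation index against a reference patch; `"fuzzy"`: fuzzy-membership
#' reassignment and vertex refinement), evaluation against truth when
#' supplied, and an experience-store append. A warm start (non-empty store)
#' replaces the bootstrap reference patch with the most recent stored one.
#'
#' @param img numeric intensity matrix (0-255 scale).
#' @param truth_labels optional integer truth label map (phantom class ids)
#'   for evaluation.
#' @param cfg a [run_config()].
#' @param store optional experience-store path (overrides the config).
#' @param run_id identifier recorded in the report and store.
#' @param out_dir optional directory; when given, the filtered image, label
#'   map, tumor mask and JSON report are written there.
#' @return a `run_report` list: `k`, `fet_threshold`, `region_stats`,
#'   `classifier`, `tumor_mask`, `metrics` (when truth supplied),
#'   `tumor_burden_truth`, `warm_start`, `store_state`, `version`, `config`.
#' @export
run_pipeline <- function(img, truth_labels = NULL, cfg = run_config(),
                         store = NULL, run_id = "run", out_dir = NULL) {
  assert_gray(img)
  if (is.null(store)) store <- cfg$learner$store

  filtered <- adaptive_bilateral_filter(img, cfg$preprocess)
  hist <- image_histogram(filtered)
  thr <- fet_threshold(hist)
  sel <- select_k(filtered, cfg$haris)
  seg <- haris_segment(filtered, sel$k, cfg$haris)
  bmask <- brain_mask(seg)
  if (!any(bmask)) bmask <- matrix(TRUE, nrow(img), ncol(img))

  prior <- if (!is.null(store)) experience_prior(store) else NULL
  warm <- !is.null(prior)
  acfg <- cfg$assi
  if (is.null(acfg$sigma_e)) acfg$sigma_e <- estimate_noise_sd(filtered)
  usable_prior_patch <- warm && !is.null(prior$reference_patch) &&
    all(dim(prior$reference_patch) == acfg$window) &&
    stats::var(as.numeric(prior$reference_patch)) > 0  # flat references carry
                                                       # no structure signal
  reference <- if (usable_prior_patch) {
    prior$reference_patch
  } else {
    bootstrap_reference(filtered, seg, acfg$window, roi = bmask)$patch
  }

  if (cfg$classifier == "assi") {
    mask <- classify_pixels(filtered, reference, acfg, mode = "region",
                            labels = seg$labels, roi = bmask)
  } else {
    fz <- fuzzy_segment_refine(filtered, seg)
    in_roi <- vapply(seq_along(fz$vertices),
                     function(j) sum(fz$labels == j & bmask), numeric(1))
    cand <- which(in_roi > 0)
    dominant <- fz$vertices[cand[which.max(in_roi[cand])]]
    tumor_lab <- cand[which.max(abs(fz$vertices[cand] - dominant))]
    mask <- fz$labels == tumor_lab & bmask
  }
  attr(mask, "ci") <- NULL

  metrics <- NULL; burden <- NULL
  if (!is.null(truth_labels)) {
    truth_mask <- truth_labels == PHANTOM_CLASSES[["tumor_core"]] |
      truth_labels == PHANTOM_CLASSES[["enhancement_rim"]]
    metrics <- metric_report(confusion(mask, truth_mask))
    metrics$dice <- dice(mask, truth_mask)
    burden <- tumor_burden(truth_labels)
  }

  if (!is.null(store)) {
    experience_update(store, list(
      run_id = run_id, k = sel$k, fet_threshold = thr$threshold,
      class_profile = seg$stats[, c("label", "pixel_count", "mean", "sd")],
      reference_patch = reference))
  }
  store_state <- if (!is.null(store) && file.exists(store)) {
    list(records = length(experience_read(store)), bytes = file.size(store))
  } else list(records = 0L, bytes = 0L)

  report <- list(
    run_id = run_id,
    k = sel$k,
    k_diagnostics = sel$diagnostics,
    fet_threshold = thr$threshold,
    region_stats = seg$stats,
    classifier = cfg$classifier,
    tumor_mask = mask,
    tumor_pixels = sum(mask),
    metrics = metrics,
    tumor_burden_truth = burden,
    warm_start = warm,
    store_state = store_state,
    version = as.character(utils::packageVersion("slns")),
    config = config_echo(cfg))
  class(report) <- "run_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gray_png(filtered, file.path(out_dir, paste0(run_id, "_filtered.png")))
    write_label_png(seg$labels, file.path(out_dir, paste0(run_id, "_labels.png")))
    write_label_png(mask * 255L, file.path(out_dir, paste0(run_id, "_mask.png")))
    write_run_report(report, file.path(out_dir, paste0(run_id, "_report.json")))
  }
  report
}

config_echo <- function(cfg) {
  list(preprocess = unclass(cfg$preprocess),
       haris = unclass(cfg$haris),
       assi = unclass(cfg$assi),
       learner = cfg$learner,
       classifier = cfg$classifier,
       seed = cfg$seed)
}

#' Write a run report as JSON
#'
#' The tumor mask is serialized as a row-major 0/1 vector with dimensions,
#' so the JSON alone reproduces the mask exactly.
#'
#' @param report a `run_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_run_report <- function(report, path) {
  out <- unclass(report)
  out$tumor_mask <- list(dim = dim(report$tumor_mask),
                         values = as.integer(t(report$tumor_mask)))
  out$metrics <- if (!is.null(report$metrics)) unclass(report$metrics) else NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}
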