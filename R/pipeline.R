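#' Pipeline configuration
#'
#' All stage parameters with their defaults: resize policy (1,000 px trigger,
#' 50 ppd trigger, factor 0.5), ISODATA schedule (tolerance 1e-6, 100
#' iterations), segmentation polarity and cleanup area, enhancement method /
#' scales / threshold, closing radii, start-band width delta = 5 px, arc
#' mode, and the Shapiro-Wilk alpha. Serializes round-trip stable to YAML.
#'
#' @param ... Overrides for any default field.
#' @return A `retort_config` list.
#' @export
retort_config <- function(...) {
  cfg <- list(
    fov_deg = 45,
    resize_max_dim = 1000, resize_max_ppd = 50, resize_factor = 0.5,
    isodata_tol = 1e-6, isodata_max_iter = 100L,
    invert_b = FALSE, cleanup_min_area = 20L,
    enhance_method = "vesselness", enhance_scales = c(1, 2, 3),
    enhance_threshold = 0.15,
    restore_close_radius = 2L, av_close_radius = 2L,
    delta = 5, arc_mode = "pixel", geom_step = 5L,
    alpha = 0.05, seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) stop("unknown config field: ",
                                 paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "retort_config")
}

#' @rdname retort_config
#' @param config A `retort_config`.
#' @param path YAML file.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "retort_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname retort_config
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- do.call(retort_config, vals)
  cfg$isodata_max_iter <- as.integer(cfg$isodata_max_iter)
  cfg$cleanup_min_area <- as.integer(cfg$cleanup_min_area)
  cfg$restore_close_radius <- as.integer(cfg$restore_close_radius)
  cfg$av_close_radius <- as.integer(cfg$av_close_radius)
  cfg$geom_step <- as.integer(cfg$geom_step)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# Process one image + label pair through every stage; returns the records
# tibble and writes intermediates under out_dir (if not NULL).
process_image <- function(img, labels, config, image_id,
                          od = NULL, out_dir = NULL) {
  img <- apply_resize_policy(img, config$resize_max_dim,
                             config$resize_max_ppd, config$resize_factor)
  b <- extract_b_channel(img)
  thr <- isodata_threshold(b, tol = config$isodata_tol,
                           max_iter = config$isodata_max_iter)
  seg <- segment_vessels(b, thr, invert = config$invert_b,
                         min_area = config$cleanup_min_area)
  seg <- enhance_vessels(seg, img, method = config$enhance_method,
                         scales = config$enhance_scales,
                         threshold = config$enhance_threshold)
  seg <- restore_with_gt(seg, labels, config$restore_close_radius)
  if (is.null(od)) od <- detect_od(img, seg)
  av <- build_av_masks(seg, labels, config$av_close_radius)
  records <- list()
  for (cls in c("artery", "vein")) {
    skel <- skeletonize(av[[cls]], vessel_class = cls)
    skel <- overlay_od(skel, od)
    traced <- trace_vessels(skel, delta = config$delta)
    records[[cls]] <- tortuosity_records(
      traced, image_id = image_id, arc_mode = config$arc_mode,
      geom_step = config$geom_step
    )
    if (!is.null(out_dir)) {
      write_image(skel, file.path(out_dir, paste0(image_id, "_", cls, "_skel.png")))
    }
  }
  rec <- do.call(rbind, records)
  if (!is.null(out_dir)) {
    write_image(seg, file.path(out_dir, paste0(image_id, "_seg.png")))
    write_od(od, file.path(out_dir, paste0(image_id, "_od.json")))
    write.csv(rec, file.path(out_dir, paste0(image_id, "_records.csv")),
              row.names = FALSE)
  }
  rec
}

#' Run the full tortuosity pipeline over a directory of images
#'
#' Pairs images with ground-truth label maps by filename stem, executes
#' preprocessing, optic-disc detection, artery/vein separation,
#' skeletonization, BFS tracing and tortuosity for each image, writes
#' per-image intermediates plus a consolidated `records.csv`, and emits an
#' artery-versus-vein comparison report (`report.csv`) over per-image mean
#' tortuosities. Deterministic: identical inputs and config give identical
#' outputs.
#'
#' @param image_dir Directory of fundus images (png/tif/jpg).
#' @param gt_dir Directory of RGB label maps with matching stems.
#' @param out_dir Output directory (created if missing).
#' @param config A `retort_config`.
#' @param od_dir Optional directory of per-image `<stem>_od.json` files; when
#'   present the stored disc is used instead of detection.
#' @param dataset Dataset label written into the report.
#' @return List with `records` (tibble) and `report` (tibble), invisibly.
#' @export
run_pipeline <- function(image_dir, gt_dir, out_dir,
                         config = retort_config(), od_dir = NULL,
                         dataset = basename(image_dir)) {
  stopifnot(dir.exists(image_dir), dir.exists(gt_dir))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  imgs <- list.files(image_dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                     ignore.case = TRUE, full.names = TRUE)
  if (length(imgs) == 0L) stop("no inputs: ", image_dir, " has no images")
  gts <- list.files(gt_dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                    ignore.case = TRUE, full.names = TRUE)
  gt_stems <- tools::file_path_sans_ext(basename(gts))
  all_records <- list()
  for (f in imgs) {
    stem <- tools::file_path_sans_ext(basename(f))
    gi <- match(stem, gt_stems)
    if (is.na(gi)) {
      warning("no ground truth for ", stem, "; skipped")
      next
    }
    od <- NULL
    if (!is.null(od_dir)) {
      odf <- file.path(od_dir, paste0(stem, "_od.json"))
      if (file.exists(odf)) od <- read_od(odf)
    }
    img <- read_fundus(f, config$fov_deg)
    labels <- read_labels(gts[gi])
    rec <- tryCatch(
      process_image(img, labels, config, stem, od = od, out_dir = out_dir),
      error = function(e) {
        warning("image ", stem, " skipped: ", conditionMessage(e))
        NULL
      }
    )
    if (!is.null(rec)) all_records[[stem]] <- rec
  }
  if (length(all_records) == 0L) stop("no image produced records")
  records <- do.call(rbind, all_records)
  write.csv(records, file.path(out_dir, "records.csv"), row.names = FALSE)
  agg <- aggregate_tortuosity(records)
  report <- NULL
  pa <- agg$per_image[agg$per_image$vessel_class == "artery", ]
  pv <- agg$per_image[agg$per_image$vessel_class == "vein", ]
  if (nrow(pa) >= 3L && nrow(pv) >= 3L) {
    a <- stats::setNames(pa$mean_t, pa$image_id)
    v <- stats::setNames(pv$mean_t, pv$image_id)
    cmp <- compare_groups(a, v, paired = TRUE, alpha = config$alpha)
    tot <- c(sum(agg$overall$n_segments[agg$overall$vessel_class == "artery"]),
             sum(agg$overall$n_segments[agg$overall$vessel_class == "vein"]))
    report <- build_report(list(cmp), dataset = dataset,
                           fov_deg = config$fov_deg, totals = list(tot))
    write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
  }
  invisible(list(records = records, report = report))
}
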