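#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline with documented
#' defaults. Unknown keys are rejected, so a typo cannot silently fall back
#' to a default.
#'
#' @param ... named overrides of the defaults listed below.
#' @return a `pipeline_config` list with fields:
#' \describe{
#'   \item{enhancement}{`"stretch"`, `"hist_eq"` or `"identity"` (default
#'     `"stretch"`).}
#'   \item{edge_op}{`"roberts"`, `"sobel"`, `"prewitt"` (default `"sobel"`).}
#'   \item{magnitude}{`"euclidean"` or `"abs"` (default `"euclidean"`).}
#'   \item{k, window_sigma}{corner-response constants (0.04, 1.0).}
#'   \item{threshold_rel}{corner threshold as a fraction of the maximum
#'     response (0.02; see [find_corners()]).}
#'   \item{nms_radius}{non-maximum suppression radius in pixels (3).}
#'   \item{patch_radius, min_ncc}{NCC matching patch half-width (4) and
#'     acceptance score (0.8).}
#'   \item{thre, n_hypotheses, n_sample, max_iter, converge_eps}{robust
#'     colour-model fit controls (0.05, 500, 3, 100, 1e-8).}
#'   \item{template_size}{side of the self-template cropped from the centre
#'     of the first image when no template is supplied (16).}
#'   \item{seed}{seed governing all pipeline randomness (0).}
#' }
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    enhancement = "stretch",
    edge_op = "sobel",
    magnitude = "euclidean",
    k = 0.04,
    window_sigma = 1.0,
    threshold_rel = 0.02,
    nms_radius = 3L,
    patch_radius = 4L,
    min_ncc = 0.8,
    thre = 0.05,
    n_hypotheses = 500L,
    n_sample = 3L,
    max_iter = 100L,
    converge_eps = 1e-8,
    template_size = 16L,
    seed = 0L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown pipeline config key(s): ", paste(unknown, collapse = ", ")))
  }
  defaults[names(overrides)] <- overrides
  structure(defaults, class = "pipeline_config")
}

#' Run the full analysis pipeline on an image pair
#'
#' Executes the fixed stage order: enhancement, edge statistics, corner
#' response and selection in both images, NCC matching of corner patches,
#' robust purification of the matched correspondences under the per-channel
#' linear colour model, and SSD template localization. Counts can only
#' shrink through the filtering stages (corners >= matches >= inliers).
#' Colour values fed to the purification stage are read from the original
#' (un-enhanced) images at the matched coordinates. Fully deterministic
#' given `config$seed`; the report carries no timestamps, so two runs with
#' the same inputs are byte-identical once serialized.
#'
#' @param image_a,image_b single-channel or RGB images (matrices/arrays or
#'   file paths).
#' @param config a [pipeline_config()].
#' @param template optional template image for the localization stage; when
#'   omitted, a central `template_size` crop of `image_a` is scanned for in
#'   `image_b`.
#' @param out_dir optional directory; when given, intermediate artifacts
#'   (`corners_a.json`, `matches.json`, `model.json`, `surface.tif`,
#'   `report.json`) are written there.
#' @return a `run_report`: list with `stages` (tibble of stage, n_in,
#'   n_out, note), `params`, and `results` (corner sets, match set, colour
#'   model, match surface).
#' @export
run_pipeline <- function(image_a, image_b, config = pipeline_config(),
                         template = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(image_a)) image_a <- read_image(image_a)
  if (is.character(image_b)) image_b <- read_image(image_b)
  image_a <- as_image(image_a); image_b <- as_image(image_b)
  gray_a <- to_gray(image_a); gray_b <- to_gray(image_b)

  stages <- tibble(stage = character(), n_in = integer(), n_out = integer(),
                   note = character())
  log_stage <- function(stage, n_in, n_out, note = "") {
    stages <<- bind_rows(stages, tibble(stage = stage, n_in = as.integer(n_in),
                                        n_out = as.integer(n_out), note = note))
  }

  enh_a <- enhance(gray_a, config$enhancement)
  enh_b <- enhance(gray_b, config$enhancement)
  log_stage("enhance", length(gray_a), length(enh_a), config$enhancement)

  edges_a <- apply_edge_operator(enh_a, config$edge_op)
  mag <- if (config$magnitude == "abs") gradient_magnitude_abs(edges_a) else edges_a$magnitude
  log_stage("edges", length(enh_a), sum(mag > 0), config$edge_op)

  corners_a <- find_corners(enh_a, k = config$k, window_sigma = config$window_sigma,
                            threshold_rel = config$threshold_rel,
                            nms_radius = config$nms_radius)
  corners_b <- find_corners(enh_b, k = config$k, window_sigma = config$window_sigma,
                            threshold_rel = config$threshold_rel,
                            nms_radius = config$nms_radius)
  log_stage("corners", 2L, nrow(corners_a) + nrow(corners_b),
            paste0("a=", nrow(corners_a), " b=", nrow(corners_b)))

  matches <- ncc_match(enh_a, enh_b, corners_a, corners_b,
                       patch_radius = config$patch_radius, min_ncc = config$min_ncc)
  log_stage("ncc_match", min(nrow(corners_a), nrow(corners_b)), nrow(matches))

  model <- NULL
  if (nrow(matches) >= 4) {
    pairs <- matched_color_pairs(image_a, image_b, matches)
    model <- ransac_fit(pairs, thre = config$thre,
                        n_hypotheses = config$n_hypotheses,
                        n_sample = config$n_sample, max_iter = config$max_iter,
                        converge_eps = config$converge_eps, seed = config$seed)
    log_stage("purify", nrow(matches), sum(model$inlier_mask),
              paste0("E=", format(model$E, digits = 6)))
  } else {
    log_stage("purify", nrow(matches), 0L, "skipped: fewer than 4 matches")
  }

  if (is.null(template)) {
    s <- min(config$template_size, nrow(gray_a), ncol(gray_a))
    r0 <- (nrow(gray_a) - s) %/% 2L + 1L
    c0 <- (ncol(gray_a) - s) %/% 2L + 1L
    template <- gray_a[r0:(r0 + s - 1L), c0:(c0 + s - 1L)]
  } else if (is.character(template)) {
    template <- to_gray(read_image(template))
  }
  surface <- ssd_scan(gray_b, template)
  log_stage("template_match", length(surface$se), 1L,
            paste0("argmin=(", surface$argmin[1], ",", surface$argmin[2], ")"))

  report <- structure(
    list(stages = stages, params = unclass(config),
         results = list(corners_a = corners_a, corners_b = corners_b,
                        matches = matches, model = model, surface = surface)),
    class = "run_report"
  )
  if (!is.null(out_dir)) write_report_artifacts(report, out_dir)
  report
}

# Colour values at matched coordinates, as a_*/b_* columns for ransac_fit().
matched_color_pairs <- function(image_a, image_b, matches) {
  sample_px <- function(img, rows, cols) {
    if (is_rgb(img)) {
      sapply(1:3, function(c) img[cbind(rows, cols, c)])
    } else {
      matrix(img[cbind(rows, cols)], ncol = 1)
    }
  }
  a <- sample_px(image_a, matches$row_a, matches$col_a)
  b <- sample_px(image_b, matches$row_b, matches$col_b)
  list(a = matrix(a, nrow(matches)), b = matrix(b, nrow(matches)))
}

write_report_artifacts <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- report$results
  jsonlite::write_json(as.data.frame(res$corners_a), file.path(out_dir, "corners_a.json"),
                       digits = NA)
  jsonlite::write_json(as.data.frame(res$corners_b), file.path(out_dir, "corners_b.json"),
                       digits = NA)
  jsonlite::write_json(as.data.frame(res$matches), file.path(out_dir, "matches.json"),
                       digits = NA)
  if (!is.null(res$model)) {
    m <- res$model
    jsonlite::write_json(
      list(gain = m$gain, offset = m$offset, inlier_mask = m$inlier_mask,
           E_trajectory = m$E_trajectory, thre = m$thre,
           low_confidence = m$low_confidence),
      file.path(out_dir, "model.json"), digits = NA, auto_unbox = FALSE)
  }
  se <- res$surface$se
  write_image(se / max(se, 1e-12), file.path(out_dir, "surface.tif"))
  jsonlite::write_json(
    list(stages = report$stages, params = report$params),
    file.path(out_dir, "report.json"), digits = NA, auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", nrow(x$stages), " stages\n", sep = "")
  print(as.data.frame(x$stages), row.names = FALSE)
  invisible(x)
}

#' Write ground-truthed fixture bundles to disk
#'
#' Materializes the synthetic generators as files: images as 8-bit PNG,
#' ground truth as sidecar JSON, tabular data as CSV, hierarchies as YAML.
#' A manifest lists every written file with its MD5 checksum; given the same
#' seed the bundle is byte-identical across runs.
#'
#' @param kind `"corners"`, `"correspondence"`, `"template"` or
#'   `"evaluation"`.
#' @param seed integer seed passed to the generators.
#' @param out_dir writable output directory (created if needed).
#' @return the manifest: tibble with `file` and `md5`, invisibly also
#'   written as `manifest.json`.
#' @export
generate_fixtures <- function(kind = c("corners", "correspondence", "template", "evaluation"),
                              seed = 0L, out_dir) {
  kind <- match.arg(kind)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) abort(paste0("out_dir not writable: ", out_dir))
  wj <- function(x, f) jsonlite::write_json(x, file.path(out_dir, f),
                                            digits = NA, auto_unbox = TRUE)
  files <- switch(kind,
    corners = {
      sc <- make_corner_scene(3, c(96L, 96L), noise_sigma = 0, seed = seed)
      write_image(sc$image, file.path(out_dir, "scene.png"))
      wj(list(corner_truth = sc$corner_truth, noise_sigma = sc$noise_sigma,
              seed = sc$seed), "truth.json")
      c("scene.png", "truth.json")
    },
    correspondence = {
      sc <- make_correspondence_scene(200, gain = c(2, 1, 0.5), offset = c(0.1, 0, -0.1),
                                      outlier_fraction = 0.2, noise_sigma = 0.005,
                                      seed = seed)
      utils::write.csv(sc$points, file.path(out_dir, "points.csv"), row.names = FALSE)
      write_image(sc$image_a, file.path(out_dir, "a.png"))
      write_image(sc$image_b, file.path(out_dir, "b.png"))
      wj(list(gain = sc$true_gain, offset = sc$true_offset,
              outlier_indices = sc$outlier_indices, seed = sc$seed), "truth.json")
      c("points.csv", "a.png", "b.png", "truth.json")
    },
    template = {
      sc <- make_corner_scene(2, c(64L, 64L), noise_sigma = 0, seed = seed)
      tpl <- withr::with_seed(as.integer(seed), matrix(runif(64), 8, 8))
      at <- c(11L, 21L)
      img <- embed_template(sc$image, tpl, at)
      write_image(img, file.path(out_dir, "image.png"))
      write_image(tpl, file.path(out_dir, "template.png"))
      wj(list(offset = at, seed = as.integer(seed)), "truth.json")
      c("image.png", "template.png", "truth.json")
    },
    evaluation = {
      withr::with_seed(as.integer(seed), {
        crit_p <- runif(3, 0.5, 2)
        crit <- consistent_judgment(crit_p, perturb = 0.05, seed = seed + 1L,
                                    labels = c("barrier", "healing", "safety"))
        meas <- lapply(1:3, function(i) {
          consistent_judgment(runif(2, 0.5, 2), perturb = 0.05, seed = seed + 10L + i,
                              labels = paste0("m", i, "_", 1:2))
        })
        scores <- matrix(runif(18, 40, 95), 3, 6,
                         dimnames = list(c("chitosan", "absorbable_film",
                                           "sodium_hyaluronate"), NULL))
      })
      utils::write.csv(as.data.frame(unclass(crit)),
                       file.path(out_dir, "criteria.csv"), row.names = FALSE)
      for (i in 1:3) {
        utils::write.csv(as.data.frame(unclass(meas[[i]])),
                         file.path(out_dir, paste0("measures_", i, ".csv")),
                         row.names = FALSE)
      }
      utils::write.csv(data.frame(alternative = rownames(scores), scores),
                       file.path(out_dir, "scores.csv"), row.names = FALSE)
      yaml::write_yaml(
        list(criteria = stats::setNames(
          lapply(1:3, function(i) list(matrix = paste0("measures_", i, ".csv"))),
          colnames(crit))),
        file.path(out_dir, "hierarchy.yaml"))
      c("criteria.csv", paste0("measures_", 1:3, ".csv"), "scores.csv", "hierarchy.yaml")
    }
  )
  md5 <- tools::md5sum(file.path(out_dir, files))
  manifest <- tibble(file = files, md5 = unname(md5))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"), digits = NA)
  manifest
}
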