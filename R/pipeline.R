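# FNV-1a hash over a serialized R object; used for config provenance and
# stage caching (no cryptographic requirement, just change detection)
config_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  h1 <- 17; h2 <- 977
  for (b in raw) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 131 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

#' Pipeline configuration for one case
#'
#' Collects the file paths and per-stage parameter blocks driving
#' [run_case()]. Parameter blocks are validated by their modules'
#' constructors.
#'
#' @param preop_volume,postop_volume paths to the pre-/post-operative
#'   volumes (NIfTI/NRRD).
#' @param landmarks path to the landmark JSON/CSV.
#' @param out_dir output directory (created if needed).
#' @param affected_side `"right"` or `"left"`.
#' @param affected_wall wall carrying the reconstruction (`"floor"` or
#'   `"medial"`); its regions are excluded from the registration ROI.
#' @param segmentation_pre,segmentation_post [segmentation_params()] for
#'   the two modalities (CBCT needs its own threshold: intensities are
#'   uncalibrated).
#' @param registration A [registration_params()].
#' @param deviation list: `max_correspondence_mm`, `clamp_mm`.
#' @param implant list: `threshold`, `projection_distance_mm`.
#' @param smooth_sigma_vox surface-extraction smoothing (voxel units).
#' @param case_id label used in reports.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(preop_volume, postop_volume, landmarks, out_dir,
                            affected_side = "right",
                            affected_wall = "floor",
                            segmentation_pre = segmentation_params(),
                            segmentation_post = segmentation_params(bone_threshold = 240),
                            registration = registration_params(),
                            deviation = list(max_correspondence_mm = 10,
                                             clamp_mm = 1.5),
                            implant = list(threshold = 2000,
                                           projection_distance_mm = 2),
                            smooth_sigma_vox = 1.0,
                            case_id = "case") {
  affected_side <- match.arg(affected_side, c("right", "left"))
  affected_wall <- match.arg(affected_wall, c("floor", "medial"))
  stopifnot(inherits(segmentation_pre, "segmentation_params"),
            inherits(segmentation_post, "segmentation_params"),
            inherits(registration, "registration_params"))
  structure(list(preop_volume = preop_volume, postop_volume = postop_volume,
                 landmarks = landmarks, out_dir = out_dir,
                 affected_side = affected_side, affected_wall = affected_wall,
                 segmentation_pre = segmentation_pre,
                 segmentation_post = segmentation_post,
                 registration = registration, deviation = deviation,
                 implant = implant, smooth_sigma_vox = smooth_sigma_vox,
                 case_id = case_id, schema_version = 1L),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; the
#' `segmentation_pre`/`segmentation_post`/`registration` blocks hold the
#' respective constructor arguments.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (f in c("preop_volume", "postop_volume", "landmarks"))
    if (is.null(y[[f]])) stop("config is missing required path '", f, "'")
  args <- y
  for (blk in c("segmentation_pre", "segmentation_post"))
    if (!is.null(y[[blk]])) args[[blk]] <- do.call(segmentation_params, y[[blk]])
  if (!is.null(y$registration))
    args$registration <- do.call(registration_params, y$registration)
  do.call(pipeline_config, args)
}

log_stage <- function(log_path, stage, ...) {
  msg <- sprintf("[%s] stage=%s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 stage, paste(sprintf("%s=%s", names(list(...)),
                                      unlist(lapply(list(...), format))),
                              collapse = " "))
  cat(msg, "\n", file = log_path, append = TRUE)
  message(msg)
}

# run `fun` under a stage cache: results are stored under out_dir/cache and
# reused when the stage's config hash matches (re-entrancy after interrupts)
with_stage <- function(out_dir, stage, hash, fun, log_path) {
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(cache_dir, paste0(stage, ".rds"))
  if (file.exists(marker)) {
    cached <- readRDS(marker)
    if (identical(cached$hash, hash)) {
      log_stage(log_path, stage, status = "cached")
      return(cached$value)
    }
  }
  value <- tryCatch(fun(), error = function(e)
    stop("pipeline aborted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))
  saveRDS(list(hash = hash, value = value), marker)
  value
}

segment_side_volume <- function(volume, landmarks, side, params, log_path,
                                stage, out_dir, hash) {
  with_stage(out_dir, stage, hash, function() {
    bone <- threshold_bone(volume, params)
    cav <- segment_cavity(volume, bone, params, side = side,
                          landmarks = landmarks, stop_plane = "landmarks")
    s <- side_landmarks(landmarks, side)
    clipped <- clip_anterior(cav, anterior_clip_plane(s$L, s$M))
    vol <- compute_volume(clipped)
    log_stage(log_path, stage, side = side, volume_ml = round(vol, 3),
              voxels = sum(clipped$mask))
    list(mask = clipped, volume_ml = vol)
  }, log_path)
}

#' Run the full per-case analysis
#'
#' Executes the whole workflow: segment the unaffected and affected orbit
#' on the pre-operative scan and the unaffected and reconstructed orbit on
#' the post-operative scan; mirror the unaffected pre-operative cavity
#' surface across the estimated midsagittal plane to build the template;
#' register it rigidly to the reconstructed surface using only unaffected
#' regions (affected-wall labels, rim and unassigned vertices are excluded
#' from the ROI); map signed deviations; summarise them over the nine wall
#' regions; and measure implant coverage. Every stage is logged and cached
#' under `out_dir`; outputs are deterministic given the config.
#'
#' Output files (under `out_dir`): `volumes.json`, `deviation.ply`
#' (color-coded template), `deviation_summary.csv`, `region_labels.csv`,
#' `implant_coverage.csv`, `transform.json`, `case.log`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the volumes, registration result,
#'   deviation summary, coverage table and paths.
#' @export
run_case <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "case.log")
  # hash the analysis-relevant configuration (where outputs go does not
  # change what is computed)
  chash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  aff <- config$affected_side
  una <- setdiff(c("right", "left"), aff)

  for (f in c("preop_volume", "postop_volume", "landmarks"))
    if (!file.exists(config[[f]]))
      stop("pipeline aborted at stage 'landmarks': missing input file ",
           config[[f]], call. = FALSE)
  preop <- read_volume(config$preop_volume)
  postop <- read_volume(config$postop_volume)
  landmarks <- read_landmarks(config$landmarks, require_midline = TRUE)
  validate_landmarks(landmarks, preop)
  log_stage(log_path, "load", preop = config$preop_volume,
            postop = config$postop_volume, hash = chash)

  mirror <- estimate_midsagittal(landmarks)
  log_stage(log_path, "mirror_plane",
            normal = paste(round(mirror$normal, 4), collapse = ","))

  seg_hash <- function(what) config_hash(list(chash, "seg", what))
  una_pre <- segment_side_volume(preop, landmarks, una,
                                 config$segmentation_pre, log_path,
                                 "segment_unaffected_pre", config$out_dir,
                                 seg_hash("una_pre"))
  aff_pre <- segment_side_volume(preop, landmarks, aff,
                                 config$segmentation_pre, log_path,
                                 "segment_affected_pre", config$out_dir,
                                 seg_hash("aff_pre"))
  una_post <- segment_side_volume(postop, landmarks, una,
                                  config$segmentation_post, log_path,
                                  "segment_unaffected_post", config$out_dir,
                                  seg_hash("una_post"))
  rec_post <- segment_side_volume(postop, landmarks, aff,
                                  config$segmentation_post, log_path,
                                  "segment_reconstructed_post", config$out_dir,
                                  seg_hash("rec_post"))

  reg <- with_stage(config$out_dir, "register", config_hash(list(chash, "reg")),
                    function() {
    template0 <- extract_surface(una_pre$mask,
                                 smooth_sigma_vox = config$smooth_sigma_vox)
    template <- reflect_mesh(template0, mirror)
    target <- extract_surface(rec_post$mask,
                              smooth_sigma_vox = config$smooth_sigma_vox)
    s_una <- side_landmarks(landmarks, una)
    s_aff <- side_landmarks(landmarks, aff)
    src <- reflect_points(mirror, rbind(s_una$L, s_una$M,
                                        s_una$apex %||% ((s_una$L + s_una$M) / 2)))
    # reflection maps the unaffected side's lateral/medial rim points onto
    # the affected side's lateral/medial ones (laterality is preserved)
    dst <- rbind(s_aff$L, s_aff$M,
                 s_aff$apex %||% ((s_aff$L + s_aff$M) / 2))
    init <- prealign_landmarks(src, dst)
    mirrored_lm <- landmark_set(
      right = if (aff == "right") list(L = dst[1, ], M = dst[2, ],
                                       apex = dst[3, ]) else NULL,
      left = if (aff == "left") list(L = dst[1, ], M = dst[2, ],
                                     apex = dst[3, ]) else NULL,
      midline = landmarks$midline)
    walls <- label_walls(template, mirrored_lm, mirror, side = aff)
    labels <- split_thirds(walls, template)
    roi <- roi_selector(template, labeling = labels,
                        exclude_labels = c(grep(paste0("^", config$affected_wall),
                                                wall_region_names(), value = TRUE),
                                           "rim", "unassigned"))
    fit <- icp_register(template, roi, target, config$registration, init)
    log_stage(log_path, "register", iterations = fit$iterations,
              rms_mm = round(fit$residuals$rms, 4),
              roi_vertices = sum(roi))
    list(template = template, target = target, labels = labels, fit = fit)
  }, log_path)

  devres <- with_stage(config$out_dir, "deviate",
                       config_hash(list(chash, "dev")), function() {
    moved <- transform_mesh(reg$template, reg$fit$transform)
    map <- signed_distance(moved, reg$target,
                           config$deviation$max_correspondence_mm)
    summ <- deviation_summary(map, reg$labels, regions = wall_region_names())
    log_stage(log_path, "deviate",
              mean_abs_mm = round(mean(abs(map$deviation_mm), na.rm = TRUE), 4))
    list(map = map, summary = summ, moved = moved)
  }, log_path)

  cov <- with_stage(config$out_dir, "implant",
                    config_hash(list(chash, "imp")), function() {
    imp <- withCallingHandlers(
      segment_implant(postop, config$implant$threshold),
      warning = function(w) {
        log_stage(log_path, "implant", note = conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    tab <- implant_coverage(reg$labels, devres$moved, imp,
                            config$implant$projection_distance_mm)
    log_stage(log_path, "implant", voxels = imp$n_voxels,
              components = imp$n_components)
    tab
  }, log_path)

  volumes <- list(case_id = config$case_id, schema_version = config$schema_version,
                  config_hash = chash,
                  affected_side = aff,
                  unaffected_preop_ml = una_pre$volume_ml,
                  affected_preop_ml = aff_pre$volume_ml,
                  unaffected_postop_ml = una_post$volume_ml,
                  reconstructed_postop_ml = rec_post$volume_ml,
                  enlargement_ml = aff_pre$volume_ml - una_pre$volume_ml,
                  residual_ml = rec_post$volume_ml - una_post$volume_ml)
  jsonlite::write_json(volumes, file.path(config$out_dir, "volumes.json"),
                       auto_unbox = TRUE, digits = NA)
  summ <- devres$summary
  summ$config_hash <- chash
  utils::write.csv(summ, file.path(config$out_dir, "deviation_summary.csv"),
                   row.names = FALSE)
  lab_df <- data.frame(vertex = seq_along(reg$labels$label),
                       label = reg$labels$label,
                       deviation_mm = devres$map$deviation_mm,
                       config_hash = chash)
  utils::write.csv(lab_df, file.path(config$out_dir, "region_labels.csv"),
                   row.names = FALSE)
  cov$config_hash <- chash
  utils::write.csv(cov, file.path(config$out_dir, "implant_coverage.csv"),
                   row.names = FALSE)
  colored <- apply_deviation(devres$moved, devres$map, config$deviation$clamp_mm)
  write_mesh(colored, file.path(config$out_dir, "deviation.ply"),
             with_colors = TRUE)
  jsonlite::write_json(list(matrix = as.vector(t(transform_matrix(reg$fit$transform))),
                            order = "row-major", config_hash = chash),
                       file.path(config$out_dir, "transform.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage(log_path, "report", out_dir = config$out_dir)
  invisible(list(volumes = volumes, registration = reg$fit,
                 deviation_summary = devres$summary, implant_coverage = cov,
                 labels = reg$labels, out_dir = config$out_dir))
}

#' Aggregate case reports into cohort statistics
#'
#' Reads every `volumes.json` under `reports` (a directory of per-case
#' output folders, or a list of [run_case()] results / volumes lists) and
#' computes group summaries, the pre/post paired test and CT-vs-CBCT
#' modality agreement. With a single case only the summary is produced and
#' the tests are skipped with a notice.
#'
#' @param reports directory path or list.
#' @param out_dir optional directory for `cohort_summary.csv` and
#'   `cohort_stats.json`.
#' @return List: `records` (data.frame), `tests`, `summary`.
#' @export
run_cohort <- function(reports, out_dir = NULL) {
  vols <- if (is.character(reports)) {
    files <- list.files(reports, pattern = "^volumes\\.json$", recursive = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) stop("no volumes.json found under ", reports)
    lapply(files, jsonlite::read_json)
  } else {
    lapply(reports, function(r) if (!is.null(r$volumes)) r$volumes else r)
  }
  vers <- unique(vapply(vols, function(v) as.integer(v$schema_version %||% NA),
                        integer(1)))
  if (length(vers) != 1L || is.na(vers))
    stop("heterogeneous or missing case report schema versions: ",
         paste(vers, collapse = ", "))
  records <- do.call(rbind, lapply(vols, function(v) data.frame(
    case_id = v$case_id,
    affected_side = v$affected_side,
    unaffected_preop_ml = v$unaffected_preop_ml,
    affected_preop_ml = v$affected_preop_ml,
    unaffected_postop_ml = v$unaffected_postop_ml,
    reconstructed_postop_ml = v$reconstructed_postop_ml)))
  summary_tab <- data.frame(
    quantity = c("unaffected_preop", "affected_preop", "unaffected_postop",
                 "reconstructed_postop"),
    n = nrow(records),
    mean_ml = c(mean(records$unaffected_preop_ml),
                mean(records$affected_preop_ml),
                mean(records$unaffected_postop_ml),
                mean(records$reconstructed_postop_ml)),
    sd_ml = c(stats::sd(records$unaffected_preop_ml),
              stats::sd(records$affected_preop_ml),
              stats::sd(records$unaffected_postop_ml),
              stats::sd(records$reconstructed_postop_ml)))
  tests <- NULL
  if (nrow(records) >= 3L) {
    tests <- list(
      affected_vs_unaffected = paired_volume_test(records$affected_preop_ml,
                                                  records$unaffected_preop_ml),
      reconstructed_vs_unaffected = paired_volume_test(
        records$reconstructed_postop_ml, records$unaffected_postop_ml),
      affected_vs_reconstructed = paired_volume_test(
        records$affected_preop_ml, records$reconstructed_postop_ml),
      modality = modality_agreement(records$unaffected_preop_ml,
                                    records$unaffected_postop_ml))
  } else {
    message("fewer than 3 cases: paired tests skipped, summaries only")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary_tab, file.path(out_dir, "cohort_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(summary = summary_tab, tests = tests,
                              n_cases = nrow(records)),
                         file.path(out_dir, "cohort_stats.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(records = records, tests = tests, summary = summary_tab)
}

#' Write phantom volumes, landmarks and truth to disk
#'
#' Convenience exporter for the CLI: NIfTI images, landmark JSON, truth
#' JSON (volumes, planes, bulge) and the truth template mesh as STL.
#'
#' @param phantom An `orbit_phantom`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$preop, file.path(dir, "preop.nii.gz"))
  write_volume(phantom$postop, file.path(dir, "postop.nii.gz"))
  write_landmarks(phantom$landmarks, file.path(dir, "landmarks.json"))
  tr <- phantom$truth
  jsonlite::write_json(list(volumes_ml = as.list(tr$volumes_ml),
                            affected_side = tr$affected_side,
                            mirror_plane = list(normal = tr$mirror_plane$normal,
                                                point = tr$mirror_plane$point),
                            bulge = tr$bulge, residual = tr$residual,
                            spacing = tr$spacing, dims = tr$dims),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  mesh <- extract_surface(tr$cavity_masks$unaffected, tr$spacing, tr$origin)
  write_mesh(mesh, file.path(dir, "unaffected_surface.stl"))
  invisible(dir)
}
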