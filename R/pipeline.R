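#' Process one slide end to end
#'
#' Runs the full per-slide chain: tissue-class merge, epithelial context
#' assignment, invasive-front estimation, front/center partition, lymphoid
#' aggregate and lymph-node detection, intraepithelial region and IEL
#' flags, then slide scores and distance profiles.
#'
#' @param map a raw [tissue_map()].
#' @param cells a [cell_table()].
#' @param cfg a [pipeline_config()].
#' @return List with `cells` (fully annotated), `front`, `scores` (one-row
#'   data frame), `profiles` (long data frame over both immune groups).
#' @export
process_slide <- function(map, cells, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  map <- merge_tissue_classes(map)
  cells <- assign_epithelial_context(cells, map, cfg)
  front <- estimate_front_line(map, cfg)
  cells <- assign_regions(cells, front, cfg)
  cells <- detect_lymphoid_clusters(cells, cfg)
  region <- build_epithelial_region(cells, cfg, compute_area = FALSE)
  cells <- flag_iels(cells, region)
  scores <- slide_scores(cells, cfg)
  profiles <- rbind(
    cbind(slide_id = scores$slide_id,
          suppressWarnings(distance_profile(cells, "lymphocyte", cfg))),
    cbind(slide_id = scores$slide_id,
          suppressWarnings(distance_profile(cells, "eosinophil", cfg))))
  list(cells = cells, front = front, scores = scores, profiles = profiles)
}

write_scores_csv <- function(df, path) {
  out <- df
  for (col in names(out))
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.12g", out[[col]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline over a set of slides
#'
#' Executes regions, structures, scoring, patient aggregation and (when a
#' cohort table is supplied) per-cohort stage-II normalization and
#' univariate Cox survival analysis, writing all outputs plus a run
#' manifest to `out_dir`. Reruns with identical inputs and configuration
#' reproduce identical score files; the pipeline itself is deterministic
#' and single-threaded.
#'
#' @param slides either a data frame with columns `slide_id`, `cells`
#'   (detection CSV path) and `tissue` (label raster path), or a list of
#'   in-memory slides `list(map =, cells =)`.
#' @param out_dir output directory (created if needed).
#' @param cfg a [pipeline_config()].
#' @param cohort optional per-patient data frame with `patient_id`,
#'   `stage`, `followup_months`, `event` (plus any covariates); triggers
#'   normalization and survival stages.
#' @param scores_for_survival score columns entered (one at a time) into
#'   univariate Cox models.
#' @return The run manifest, invisibly.
#' @export
run_all <- function(slides, out_dir, cfg = pipeline_config(), cohort = NULL,
                    scores_for_survival = c("LymF", "EosF", "IEL")) {
  cfg <- as_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  from_paths <- is.data.frame(slides)
  n_slides <- if (from_paths) nrow(slides) else length(slides)
  if (!n_slides) stop("no slides to process", call. = FALSE)

  slide_rows <- list(); profile_rows <- list(); flags <- list()
  hashes <- list()
  for (i in seq_len(n_slides)) {
    sid <- if (from_paths) slides$slide_id[i] else
      if (!is.null(names(slides))) names(slides)[i] else paste0("slide", i)
    res <- tryCatch({
      if (from_paths) {
        cells <- read_detections(slides$cells[i])
        map <- read_tissue_map(slides$tissue[i])
        hashes[[sid]] <- as.list(tools::md5sum(c(slides$cells[i],
                                                 slides$tissue[i])))
      } else {
        cells <- slides[[i]]$cells
        map <- slides[[i]]$map
      }
      process_slide(map, cells, cfg)
    }, error = function(e) {
      stop(sprintf("slide '%s' failed: %s", sid, conditionMessage(e)),
           call. = FALSE)
    })
    write_detections(res$cells, file.path(out_dir,
                                          paste0("cells_", sid, ".csv")))
    write_front_geojson(res$front,
                        file.path(out_dir, paste0("front_", sid, ".geojson")))
    slide_rows[[sid]] <- res$scores
    profile_rows[[sid]] <- res$profiles
    flags[[sid]] <- list(front_missing = res$scores$front_missing,
                         n_outside = attr(res$cells, "n_outside"))
  }
  slide_df <- do.call(rbind, slide_rows)
  rownames(slide_df) <- NULL
  write_scores_csv(slide_df, file.path(out_dir, "slide_scores.csv"))
  prof_df <- do.call(rbind, profile_rows)
  rownames(prof_df) <- NULL
  write_scores_csv(prof_df, file.path(out_dir, "profiles.csv"))

  patients <- aggregate_patients(slide_df)
  write_scores_csv(patients, file.path(out_dir, "patient_scores.csv"))

  survival_written <- FALSE
  if (!is.null(cohort)) {
    merged <- merge(cohort, patients, by = "patient_id")
    params <- fit_normalization(merged, merged$stage, cfg = cfg)
    normed <- apply_normalization(merged, params)
    write_scores_csv(normed, file.path(out_dir,
                                       "patient_scores_normalized.csv"))
    if (all(c("followup_months", "event") %in% names(normed))) {
      ttr <- build_ttr(normed, cfg)
      ttr <- transform_scores(ttr)
      rows <- list()
      for (sc in intersect(scores_for_survival, names(ttr))) {
        f <- stats::as.formula(paste0("survival::Surv(ttr_months, ttr_event) ~ ",
                                      sc))
        fit <- cox_fit(f, ttr)
        tab <- fit$table
        tab$model <- sc; tab$n <- fit$n; tab$events <- fit$events
        tab$aic <- fit$aic
        rows[[sc]] <- tab
      }
      if (length(rows)) {
        write_scores_csv(do.call(rbind, rows),
                         file.path(out_dir, "survival_univariate.csv"))
        survival_written <- TRUE
      }
    }
  }

  manifest <- list(
    package = "immunofront",
    version = as.character(utils::packageVersion("immunofront")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = cfg$rng_seed,
    config = unclass(cfg),
    n_slides = n_slides,
    input_hashes = hashes,
    slide_flags = flags,
    survival_written = survival_written
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
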