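SCORE_COLS <- c("LymF", "LymC", "LymA", "EosF", "EosC", "EosA", "IEL")

# nearest tumor cell for each non-excluded immune cell of a group;
# returns indices into the cell table plus nn distance and attributed region
nearest_tumor_attribution <- function(cells, group) {
  tum <- which(cells$derived_class == "tumor_epithelial")
  imm <- which(cells$derived_class == group & !cells$excluded)
  if (!length(tum) || !length(imm))
    return(list(tum = tum, imm = imm, dist = numeric(0),
                region = character(0)))
  nn <- .nn_lookup_cpp(cells$x_um[imm], cells$y_um[imm],
                       cells$x_um[tum], cells$y_um[tum])
  list(tum = tum, imm = imm, dist = nn$dist,
       region = cells$region[tum[nn$index]])
}

#' Distance-binned immune profile
#'
#' Bins every non-excluded immune cell of a group once, by the distance to
#' its nearest tumor cell, into `profile_bin_um`-wide bins up to
#' `max_profile_radius_um` (10 micrometre bins to 500 by default). Binning
#' by the nearest tumor cell guarantees no immune cell is counted twice.
#' Counts are also reported per whole-slide tumor cell.
#'
#' @param cells a [cell_table()] with regions and exclusions applied.
#' @param group `"lymphocyte"` or `"eosinophil"`.
#' @param cfg a [pipeline_config()].
#' @return Data frame with columns `group`, `bin_lo_um`, `bin_hi_um`,
#'   `count`, `per_tumor_cell`.
#' @export
distance_profile <- function(cells, group = c("lymphocyte", "eosinophil"),
                             cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  group <- match.arg(group)
  edges <- seq(0, cfg$max_profile_radius_um, by = cfg$profile_bin_um)
  nb <- length(edges) - 1L
  at <- nearest_tumor_attribution(cells, group)
  counts <- integer(nb)
  if (!length(at$tum)) {
    warning("no tumor cells; empty profile", call. = FALSE)
  } else if (length(at$imm)) {
    d <- at$dist[at$dist <= cfg$max_profile_radius_um]
    # half-open bins [lo, hi), last bin closed at the outer limit
    bin <- pmin(findInterval(d, edges), nb)
    counts <- tabulate(bin, nbins = nb)
  }
  n_tum <- length(at$tum)
  data.frame(group = group, bin_lo_um = edges[-length(edges)],
             bin_hi_um = edges[-1], count = counts,
             per_tumor_cell = if (n_tum) counts / n_tum else NA_real_,
             stringsAsFactors = FALSE)
}

#' Unique-count region score
#'
#' The score of an immune group in a region is the number of unique
#' non-excluded immune cells of that group attributed to the region and
#' lying within `count_radius_um` (200 micrometres, ties inclusive) of
#' their nearest tumor cell, divided by the number of tumor cells in the
#' region. Each immune cell is attributed to the region of its nearest
#' tumor cell, so no cell is ever counted twice across front and center.
#'
#' @param cells a [cell_table()] after [assign_regions()] and
#'   [detect_lymphoid_clusters()].
#' @param group `"lymphocyte"` or `"eosinophil"`.
#' @param region `"front"`, `"center"` or `"all"`.
#' @param cfg a [pipeline_config()].
#' @return A single number; `NA` when the region holds no tumor cells or
#'   when `region != "all"` on a slide without a detected front.
#' @export
region_score <- function(cells, group = c("lymphocyte", "eosinophil"),
                         region = c("all", "front", "center"),
                         cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  group <- match.arg(group)
  region <- match.arg(region)
  front_missing <- isTRUE(attr(cells, "front_missing"))
  if (region != "all") {
    if (is.null(attr(cells, "front_missing")) &&
        any(cells$derived_class == "tumor_epithelial" &
            cells$region == "unassigned"))
      stop("regions not assigned; run assign_regions() first", call. = FALSE)
    if (front_missing) return(NA_real_)
  }
  at <- nearest_tumor_attribution(cells, group)
  if (!length(at$tum)) return(NA_real_)
  counted <- at$dist <= cfg$count_radius_um
  if (region == "all") {
    den <- length(at$tum)
    num <- sum(counted)
  } else {
    den <- sum(cells$region[at$tum] == region)
    if (den == 0L) return(NA_real_)
    num <- sum(counted & at$region == region)
  }
  num / den
}

#' Compute all slide-level scores
#'
#' One call per slide: the six lymphocyte/eosinophil region scores, the IEL
#' ratio, tumor-cell counts and the front flag.
#'
#' @param cells a fully processed [cell_table()] (regions, structures and
#'   IEL flags applied).
#' @param cfg a [pipeline_config()].
#' @return One-row data frame with columns `slide_id`, `patient_id`,
#'   `cohort_id`, `LymF`, `LymC`, `LymA`, `EosF`, `EosC`, `EosA`, `IEL`,
#'   `n_tumor_front`, `n_tumor_center`, `n_tumor_total`, `front_missing`.
#' @export
slide_scores <- function(cells, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  stopifnot(inherits(cells, "cell_table"))
  tum <- cells$derived_class == "tumor_epithelial"
  front_missing <- isTRUE(attr(cells, "front_missing"))
  data.frame(
    slide_id = if (nrow(cells)) cells$slide_id[1] else NA_character_,
    patient_id = if (nrow(cells)) cells$patient_id[1] else NA_character_,
    cohort_id = if (nrow(cells)) cells$cohort_id[1] else NA_character_,
    LymF = region_score(cells, "lymphocyte", "front", cfg),
    LymC = region_score(cells, "lymphocyte", "center", cfg),
    LymA = region_score(cells, "lymphocyte", "all", cfg),
    EosF = region_score(cells, "eosinophil", "front", cfg),
    EosC = region_score(cells, "eosinophil", "center", cfg),
    EosA = region_score(cells, "eosinophil", "all", cfg),
    IEL = suppressWarnings(iel_ratio(cells, cfg)),
    n_tumor_front = sum(tum & cells$region == "front"),
    n_tumor_center = sum(tum & cells$region == "center"),
    n_tumor_total = sum(tum),
    front_missing = front_missing,
    stringsAsFactors = FALSE
  )
}

#' Aggregate slide scores to patients
#'
#' Patients with several slides get tumor-cell-weighted averages: region
#' scores are weighted by the slide's tumor-cell count in that region,
#' whole-slide scores (`LymA`, `EosA`, `IEL`) by the slide's total
#' tumor-cell count. Slides missing a score (e.g. `front_missing`) are
#' dropped from that score's average only.
#'
#' @param slide_df data frame of [slide_scores()] rows.
#' @return Data frame with one row per patient, the same score columns, and
#'   provenance columns `n_slides`, `n_tumor_total`.
#' @export
aggregate_patients <- function(slide_df) {
  stopifnot(is.data.frame(slide_df), nrow(slide_df) >= 1L)
  wcol <- c(LymF = "n_tumor_front", LymC = "n_tumor_center",
            LymA = "n_tumor_total", EosF = "n_tumor_front",
            EosC = "n_tumor_center", EosA = "n_tumor_total",
            IEL = "n_tumor_total")
  one <- function(df) {
    out <- data.frame(patient_id = df$patient_id[1],
                      cohort_id = df$cohort_id[1],
                      stringsAsFactors = FALSE)
    for (sc in names(wcol)) {
      v <- df[[sc]]; w <- df[[wcol[[sc]]]]
      ok <- !is.na(v) & !is.na(w) & w > 0
      out[[sc]] <- if (any(ok)) sum(v[ok] * w[ok]) / sum(w[ok]) else NA_real_
    }
    out$n_slides <- nrow(df)
    out$n_tumor_total <- sum(df$n_tumor_total)
    out
  }
  parts <- lapply(split(slide_df, slide_df$patient_id), one)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Fit per-cohort stage-II normalization parameters
#'
#' For each cohort and score, the 5th and 95th percentiles (linear
#' interpolation between order statistics) over stage II patients define the
#' "minimum" and "maximum" of a min-max scaling. Anchoring the range on
#' stage II keeps cohorts comparable while staying robust to outliers,
#' which typically arise in cases with few tumor cells.
#'
#' @param patients patient-level data frame (see [aggregate_patients()])
#'   with a cohort column and the score columns.
#' @param stage per-patient stage labels (vector aligned with `patients`).
#' @param cohort_col name of the cohort column.
#' @param score_cols score columns to fit.
#' @param stage_value label identifying stage II.
#' @param cfg a [pipeline_config()].
#' @return Data frame `cohort`, `score`, `p_lo`, `p_hi`, `n_stage2` of class
#'   `normalization_params`.
#' @export
fit_normalization <- function(patients, stage, cohort_col = "cohort_id",
                              score_cols = SCORE_COLS,
                              stage_value = "II",
                              cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  stopifnot(length(stage) == nrow(patients))
  score_cols <- intersect(score_cols, names(patients))
  is2 <- as.character(stage) %in% as.character(stage_value)
  rows <- list()
  for (ch in unique(as.character(patients[[cohort_col]]))) {
    sel <- patients[[cohort_col]] == ch & is2
    for (sc in score_cols) {
      v <- patients[[sc]][sel]
      v <- v[!is.na(v)]
      if (length(v) < 2L)
        stop(sprintf(
          "cohort '%s' has fewer than 2 stage II patients with non-missing %s",
          ch, sc), call. = FALSE)
      q <- quantile(v, probs = c(cfg$norm_lo_percentile,
                                 cfg$norm_hi_percentile) / 100,
                    type = 7, names = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(cohort = ch, score = sc, p_lo = q[1], p_hi = q[2],
                   n_stage2 = length(v), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("normalization_params", "data.frame")
  out
}

#' Apply per-cohort min-max normalization
#'
#' Maps each score `x` to `(x - p_lo) / (p_hi - p_lo)` using the cohort's
#' fitted stage-II percentiles. Values are deliberately not clipped:
#' outliers above the 95th percentile keep values above 1.0 and stay in the
#' analysis.
#'
#' @param patients patient-level data frame with cohort and score columns.
#' @param params a [fit_normalization()] result.
#' @param cohort_col name of the cohort column.
#' @return `patients` with the fitted score columns replaced by their
#'   normalized values.
#' @export
apply_normalization <- function(patients, params, cohort_col = "cohort_id") {
  stopifnot(inherits(params, "normalization_params"))
  if (any(params$p_hi <= params$p_lo))
    stop("degenerate normalization: p_hi must exceed p_lo (constant scores?)",
         call. = FALSE)
  for (i in seq_len(nrow(params))) {
    sel <- patients[[cohort_col]] == params$cohort[i]
    sc <- params$score[i]
    patients[[sc]][sel] <-
      (patients[[sc]][sel] - params$p_lo[i]) / (params$p_hi[i] - params$p_lo[i])
  }
  patients
}
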