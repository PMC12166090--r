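#' Specification for a synthetic slide
#'
#' Describes the layered tissue geometry and point-process parameters of a
#' simulated slide: a normal-mucosa band at the top of the canvas, a tumor
#' band (or blob) in the middle, a muscle band at the bottom separated from
#' the tumor by a stroma gap (so the true invasive front is the analytic
#' midline of the gap), tumor cells as a homogeneous Poisson process inside
#' tumor epithelium, and immune cells as inhomogeneous Poisson processes
#' whose intensity decays exponentially with distance to the nearest tumor
#' cell, emulating the peaked-near-tumor distance profiles of real slides.
#' Lymphoid aggregates are planted as isotropic Gaussian clusters whose
#' dispersion keeps nearest-neighbour spacing comfortably below the 20
#' micrometre linkage radius. Intraepithelial lymphocytes are planted at a
#' controlled per-tumor-cell rate.
#'
#' @param canvas_um canvas width and height in micrometres.
#' @param mpp raster resolution (micrometres per pixel).
#' @param tumor_geometry `"band"` (horizontal band, the default) or
#'   `"blob"` (disk).
#' @param tumor_band_y,muscle_band_y,normal_band_y y-ranges of the tumor,
#'   muscle and normal-mucosa bands.
#' @param tumor_blob_center,tumor_blob_radius_um blob geometry when
#'   `tumor_geometry = "blob"`.
#' @param tumor_cell_per_mm2 tumor-cell intensity inside tumor epithelium.
#' @param normal_cell_per_mm2 epithelial-cell intensity inside normal
#'   mucosa.
#' @param connective_per_mm2 connective-cell intensity in stroma.
#' @param other_per_mm2 intensity of plasma/neutrophil ("other") cells.
#' @param lym_base_per_mm2,lym_decay_um lymphocyte intensity at distance 0
#'   from tumor cells and exponential decay length.
#' @param eos_base_per_mm2,eos_decay_um same for eosinophils.
#' @param aggregates list of planted clusters, each
#'   `list(center = c(x, y), n = <cells>, sd = <um>)`.
#' @param iel_rate probability that a tumor cell receives an adjacent
#'   planted IEL.
#' @param rng_seed integer seed.
#' @return A `slide_sim_spec` list.
#' @export
slide_sim_spec <- function(canvas_um = c(4000, 4000),
                           mpp = 8,
                           tumor_geometry = c("band", "blob"),
                           tumor_band_y = c(1200, 2800),
                           muscle_band_y = c(3200, 4000),
                           normal_band_y = c(0, 500),
                           tumor_blob_center = c(2000, 2000),
                           tumor_blob_radius_um = 900,
                           tumor_cell_per_mm2 = 1500,
                           normal_cell_per_mm2 = 1200,
                           connective_per_mm2 = 150,
                           other_per_mm2 = 50,
                           lym_base_per_mm2 = 600,
                           lym_decay_um = 100,
                           eos_base_per_mm2 = 60,
                           eos_decay_um = 80,
                           aggregates = list(),
                           iel_rate = 0.15,
                           rng_seed = 1L) {
  spec <- list(canvas_um = canvas_um, mpp = mpp,
               tumor_geometry = match.arg(tumor_geometry),
               tumor_band_y = tumor_band_y, muscle_band_y = muscle_band_y,
               normal_band_y = normal_band_y,
               tumor_blob_center = tumor_blob_center,
               tumor_blob_radius_um = tumor_blob_radius_um,
               tumor_cell_per_mm2 = tumor_cell_per_mm2,
               normal_cell_per_mm2 = normal_cell_per_mm2,
               connective_per_mm2 = connective_per_mm2,
               other_per_mm2 = other_per_mm2,
               lym_base_per_mm2 = lym_base_per_mm2,
               lym_decay_um = lym_decay_um,
               eos_base_per_mm2 = eos_base_per_mm2,
               eos_decay_um = eos_decay_um,
               aggregates = aggregates, iel_rate = iel_rate,
               rng_seed = as.integer(rng_seed))
  stopifnot(all(canvas_um > 0), mpp > 0, iel_rate >= 0, iel_rate <= 1,
            tumor_cell_per_mm2 >= 0, lym_base_per_mm2 >= 0,
            eos_base_per_mm2 >= 0)
  if (spec$tumor_geometry == "blob" &&
      (any(tumor_blob_center - tumor_blob_radius_um < 0) ||
       any(tumor_blob_center + tumor_blob_radius_um > canvas_um)))
    stop("tumor blob extends outside the canvas", call. = FALSE)
  structure(spec, class = "slide_sim_spec")
}

# uniform Poisson sample inside a rectangle, intensity per mm^2
rpois_rect <- function(per_mm2, x0, x1, y0, y1) {
  area_mm2 <- (x1 - x0) * (y1 - y0) / 1e6
  n <- stats::rpois(1, per_mm2 * area_mm2)
  cbind(stats::runif(n, x0, x1), stats::runif(n, y0, y1))
}

#' Simulate one slide
#'
#' Draws the tissue raster and all cell positions from a [slide_sim_spec()]
#' and returns the inputs the pipeline consumes together with the ground
#' truth the generator knows by construction.
#'
#' @param spec a [slide_sim_spec()].
#' @param seed integer seed (defaults to `spec$rng_seed`).
#' @param slide_id,patient_id,cohort_id identifiers stamped on the output.
#' @return List with elements `map` (a raw [tissue_map()]), `cells` (a
#'   [cell_table()]) and `truth` (true front polyline, per-tumor-cell true
#'   region, planted aggregate sizes and centers, expected unique
#'   lymphocyte/eosinophil counts within the count radius per tumor cell,
#'   planted IEL tumor-cell fraction, and the seed).
#' @export
simulate_slide <- function(spec = slide_sim_spec(), seed = spec$rng_seed,
                           slide_id = "S1", patient_id = "P1",
                           cohort_id = "C1") {
  stopifnot(inherits(spec, "slide_sim_spec"))
  set.seed(seed)
  W <- spec$canvas_um[1]; H <- spec$canvas_um[2]; mpp <- spec$mpp
  nr <- ceiling(H / mpp); nc <- ceiling(W / mpp)

  # --- raster: stroma background, then bands/blob painted on top
  px <- (seq_len(nc) - 0.5) * mpp
  py <- (seq_len(nr) - 0.5) * mpp
  lab <- matrix(TISSUE_CLASSES[["stroma"]], nr, nc)
  in_band <- function(y, rng) y >= rng[1] & y < rng[2]
  if (diff(spec$normal_band_y) > 0)
    lab[in_band(py, spec$normal_band_y), ] <-
      TISSUE_CLASSES[["normal_epithelium"]]
  if (diff(spec$muscle_band_y) > 0)
    lab[in_band(py, spec$muscle_band_y), ] <- TISSUE_CLASSES[["muscle"]]
  tumor_mask <- if (spec$tumor_geometry == "band") {
    matrix(in_band(py, spec$tumor_band_y), nr, nc)
  } else {
    outer(py, px, function(y, x)
      (x - spec$tumor_blob_center[1])^2 + (y - spec$tumor_blob_center[2])^2 <=
        spec$tumor_blob_radius_um^2)
  }
  lab[tumor_mask] <- TISSUE_CLASSES[["tumor_epithelium"]]
  map <- tissue_map(lab, mpp)

  # --- tumor and normal epithelial cells
  if (spec$tumor_geometry == "band") {
    tum <- rpois_rect(spec$tumor_cell_per_mm2, 0, W,
                      spec$tumor_band_y[1], spec$tumor_band_y[2])
  } else {
    r <- spec$tumor_blob_radius_um
    cand <- rpois_rect(spec$tumor_cell_per_mm2,
                       spec$tumor_blob_center[1] - r,
                       spec$tumor_blob_center[1] + r,
                       spec$tumor_blob_center[2] - r,
                       spec$tumor_blob_center[2] + r)
    keep <- (cand[, 1] - spec$tumor_blob_center[1])^2 +
      (cand[, 2] - spec$tumor_blob_center[2])^2 <= r^2
    tum <- cand[keep, , drop = FALSE]
  }
  nor <- if (diff(spec$normal_band_y) > 0)
    rpois_rect(spec$normal_cell_per_mm2, 0, W,
               spec$normal_band_y[1], spec$normal_band_y[2])
  else cbind(numeric(0), numeric(0))

  # --- connective and "other" cells in stroma / everywhere
  con <- rpois_rect(spec$connective_per_mm2, 0, W, 0, H)
  oth <- rpois_rect(spec$other_per_mm2, 0, W, 0, H)

  # --- immune cells: homogeneous candidates thinned by exp(-d / decay)
  thin_immune <- function(base, decay) {
    cand <- rpois_rect(base, 0, W, 0, H)
    if (!nrow(cand) || !nrow(tum)) return(cand[0, , drop = FALSE])
    d <- .nn_lookup_cpp(cand[, 1], cand[, 2], tum[, 1], tum[, 2])$dist
    cand[stats::runif(nrow(cand)) < exp(-d / decay), , drop = FALSE]
  }
  lym <- thin_immune(spec$lym_base_per_mm2, spec$lym_decay_um)
  eos <- thin_immune(spec$eos_base_per_mm2, spec$eos_decay_um)

  # --- planted IELs: adjacent lymphocytes for a fraction of tumor cells
  n_iel_tum <- 0L
  iel <- cbind(numeric(0), numeric(0))
  if (spec$iel_rate > 0 && nrow(tum)) {
    pick <- which(stats::runif(nrow(tum)) < spec$iel_rate)
    n_iel_tum <- length(pick)
    if (n_iel_tum) {
      ang <- stats::runif(n_iel_tum, 0, 2 * pi)
      rad <- stats::runif(n_iel_tum, 2, 12)
      iel <- cbind(tum[pick, 1] + rad * cos(ang),
                   tum[pick, 2] + rad * sin(ang))
    }
  }

  # --- planted aggregates: isotropic Gaussian clusters truncated at 1.5 sd
  # (truncation keeps the edge density high enough that nearest-neighbour
  # spacing stays below the 20 um linkage radius, so planting guarantees one
  # connected component)
  agg <- lapply(spec$aggregates, function(a) {
    out <- matrix(numeric(0), 0, 2)
    while (nrow(out) < a$n) {
      m <- cbind(stats::rnorm(a$n, 0, a$sd), stats::rnorm(a$n, 0, a$sd))
      m <- m[m[, 1]^2 + m[, 2]^2 <= (1.5 * a$sd)^2, , drop = FALSE]
      out <- rbind(out, m)
    }
    out <- out[seq_len(a$n), , drop = FALSE]
    cbind(a$center[1] + out[, 1], a$center[2] + out[, 2])
  })
  agg_xy <- if (length(agg)) do.call(rbind, agg) else
    cbind(numeric(0), numeric(0))

  clamp <- function(m) {
    if (!nrow(m)) return(m)
    m[, 1] <- pmin(pmax(m[, 1], 0), W - 1e-6)
    m[, 2] <- pmin(pmax(m[, 2], 0), H - 1e-6)
    m
  }
  pieces <- list(
    list(xy = clamp(tum), class = "epithelial"),
    list(xy = clamp(nor), class = "epithelial"),
    list(xy = clamp(con), class = "connective"),
    list(xy = clamp(oth), class = "plasma"),
    list(xy = clamp(lym), class = "lymphocyte"),
    list(xy = clamp(iel), class = "lymphocyte"),
    list(xy = clamp(agg_xy), class = "lymphocyte"),
    list(xy = clamp(eos), class = "eosinophil")
  )
  df <- do.call(rbind, lapply(pieces, function(p) {
    if (!nrow(p$xy)) return(NULL)
    data.frame(slide_id = slide_id, patient_id = patient_id,
               cohort_id = cohort_id, x_um = p$xy[, 1], y_um = p$xy[, 2],
               class = p$class, stringsAsFactors = FALSE)
  }))
  if (is.null(df))
    df <- data.frame(slide_id = character(), patient_id = character(),
                     cohort_id = character(), x_um = numeric(),
                     y_um = numeric(), class = character())
  cells <- cell_table(df)

  # --- ground truth
  truth <- list(seed = seed)
  if (spec$tumor_geometry == "band" && diff(spec$muscle_band_y) > 0) {
    y_front <- (spec$tumor_band_y[2] + spec$muscle_band_y[1]) / 2
    truth$front_y_um <- y_front
    truth$front_polyline <- cbind(c(0, W), c(y_front, y_front))
    truth$tumor_region <- ifelse(abs(tum[, 2] - y_front) <= 500,
                                 "front", "center")
  }
  truth$tumor_xy <- tum
  truth$n_planted_iel_tumor_cells <- n_iel_tum
  truth$aggregate_sizes <- vapply(spec$aggregates, `[[`, numeric(1), "n")
  # expected unique immune count within the count radius, by quadrature of
  # the thinned intensity over pixels whose centre is within the radius of
  # the nearest (realized) tumor cell
  if (nrow(tum)) {
    grid <- expand.grid(x = px, y = py)
    d <- .nn_lookup_cpp(grid$x, grid$y, tum[, 1], tum[, 2])$dist
    inside <- d <= 200
    pxa <- mpp * mpp / 1e6 # pixel area in mm^2
    truth$expected_lym_200 <- sum(exp(-d[inside] / spec$lym_decay_um)) *
      spec$lym_base_per_mm2 * pxa
    truth$expected_eos_200 <- sum(exp(-d[inside] / spec$eos_decay_um)) *
      spec$eos_base_per_mm2 * pxa
    truth$expected_eos_score <- truth$expected_eos_200 / nrow(tum)
    truth$expected_lym_score <- truth$expected_lym_200 / nrow(tum)
  }
  list(map = map, cells = cells, truth = truth)
}

#' Specification for a synthetic patient cohort
#'
#' Generates clinicopathological covariates, correlated normalized immune
#' scores (Gaussian copula over log-normal margins, front scores of
#' lymphocytes and eosinophils rank-correlated as observed on real slides),
#' and recurrence times under a proportional-hazards model with an
#' exponential baseline whose rate is calibrated so the expected number of
#' observed events matches `events_target`.
#'
#' @param n_patients cohort size.
#' @param events_target expected number of observed events before the
#'   follow-up cutoff.
#' @param cohorts character vector of cohort labels to assign (uniformly).
#' @param stage_probs probabilities of stages I/II/III.
#' @param msi_prevalence probability of MSI.
#' @param chemo_prob probability of adjuvant chemotherapy.
#' @param lymf_eosf_rank_cor target Spearman correlation between LymF and
#'   EosF.
#' @param fc_rank_cor target Spearman correlation between the front and
#'   center score of the same cell type.
#' @param score_meanlog,score_sdlog log-normal margin parameters of the
#'   normalized scores.
#' @param true_hr named vector of true hazard ratios per unit of the
#'   analysis covariate: `log1p`-transformed score for lymphocyte and
#'   eosinophil scores, raw for `IEL` and the clinical covariates.
#' @param censor_range_months administrative censoring drawn uniformly from
#'   this range.
#' @param rng_seed integer seed.
#' @return A `cohort_sim_spec` list.
#' @export
cohort_sim_spec <- function(n_patients = 1122,
                            events_target = 229,
                            cohorts = "C1",
                            stage_probs = c(I = 0.20, II = 0.42, III = 0.38),
                            msi_prevalence = 0.19,
                            chemo_prob = 0.30,
                            lymf_eosf_rank_cor = 0.64,
                            fc_rank_cor = 0.63,
                            score_meanlog = log(0.45),
                            score_sdlog = 0.55,
                            true_hr = c(EosF = 0.70, LymF = 1.0, IEL = 1.0,
                                        age = 1.015, sexM = 1.1,
                                        locationright = 1.0, pT = 1.35,
                                        pN = 1.6, chemo = 0.9,
                                        msiMSI = 0.75),
                            censor_range_months = c(24, 84),
                            rng_seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               events_target = events_target, cohorts = cohorts,
               stage_probs = stage_probs, msi_prevalence = msi_prevalence,
               chemo_prob = chemo_prob,
               lymf_eosf_rank_cor = lymf_eosf_rank_cor,
               fc_rank_cor = fc_rank_cor,
               score_meanlog = score_meanlog, score_sdlog = score_sdlog,
               true_hr = true_hr,
               censor_range_months = censor_range_months,
               rng_seed = as.integer(rng_seed))
  stopifnot(spec$n_patients >= 4L, events_target > 0,
            events_target < n_patients,
            msi_prevalence >= 0, msi_prevalence <= 1,
            chemo_prob >= 0, chemo_prob <= 1,
            abs(lymf_eosf_rank_cor) < 1, abs(fc_rank_cor) < 1,
            all(spec$true_hr > 0))
  structure(spec, class = "cohort_sim_spec")
}

#' Simulate a patient cohort
#'
#' @param spec a [cohort_sim_spec()].
#' @param seed integer seed (defaults to `spec$rng_seed`).
#' @return List with `frame` (per-patient covariates, normalized scores,
#'   `followup_months`, `event`) and `truth` (generating hazard ratios,
#'   calibrated baseline rate, seed).
#' @export
simulate_cohort <- function(spec = cohort_sim_spec(), seed = spec$rng_seed) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(seed)
  n <- spec$n_patients

  # --- scores via Gaussian copula; Pearson correlation on the normal scale
  # chosen so the log-normal margins carry the target Spearman correlation
  r_fe <- 2 * sin(pi * spec$lymf_eosf_rank_cor / 6)
  r_fc <- 2 * sin(pi * spec$fc_rank_cor / 6)
  # explicit latent-factor construction (consistent and positive definite):
  # the center score of each cell type loads on its front score
  e <- matrix(stats::rnorm(n * 5), n, 5)
  z_lymf <- e[, 1]
  z_eosf <- r_fe * z_lymf + sqrt(1 - r_fe^2) * e[, 2]
  z_lymc <- r_fc * z_lymf + sqrt(1 - r_fc^2) * e[, 3]
  z_eosc <- r_fc * z_eosf + sqrt(1 - r_fc^2) * e[, 4]
  z <- cbind(z_lymf, z_eosf, z_lymc, z_eosc, e[, 5])
  q <- stats::pnorm(z)
  s <- stats::qlnorm(q, meanlog = spec$score_meanlog,
                     sdlog = spec$score_sdlog)
  frame <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    cohort_id = sample(spec$cohorts, n, replace = TRUE),
    age = round(pmin(pmax(stats::rnorm(n, 68, 11), 30), 95)),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.45, 0.55)),
    location = sample(c("left", "right"), n, replace = TRUE),
    pT = sample(1:4, n, replace = TRUE, prob = c(0.06, 0.13, 0.56, 0.25)),
    pN = sample(0:2, n, replace = TRUE, prob = c(0.55, 0.25, 0.20)),
    stage = sample(names(spec$stage_probs), n, replace = TRUE,
                   prob = spec$stage_probs),
    grade = sample(1:3, n, replace = TRUE, prob = c(0.15, 0.6, 0.25)),
    msi = sample(c("MSS", "MSI"), n, replace = TRUE,
                 prob = c(1 - spec$msi_prevalence, spec$msi_prevalence)),
    chemo = stats::rbinom(n, 1, spec$chemo_prob),
    LymF = s[, 1], EosF = s[, 2], LymC = s[, 3], EosC = s[, 4],
    IEL = s[, 5],
    stringsAsFactors = FALSE
  )
  frame$LymA <- 0.5 * (frame$LymF + frame$LymC)
  frame$EosA <- 0.5 * (frame$EosF + frame$EosC)

  # --- linear predictor on the analysis scale
  hr <- spec$true_hr
  beta <- log(hr)
  covariate <- function(nm) {
    switch(nm,
           EosF = log1p(frame$EosF), LymF = log1p(frame$LymF),
           EosC = log1p(frame$EosC), LymC = log1p(frame$LymC),
           EosA = log1p(frame$EosA), LymA = log1p(frame$LymA),
           IEL = frame$IEL,
           age = frame$age - mean(frame$age),
           sexM = as.numeric(frame$sex == "M"),
           locationright = as.numeric(frame$location == "right"),
           pT = frame$pT - mean(frame$pT),
           pN = frame$pN - mean(frame$pN),
           chemo = frame$chemo,
           msiMSI = as.numeric(frame$msi == "MSI"),
           stop("unknown covariate in true_hr: ", nm))
  }
  eta <- rep(0, n)
  for (nm in names(beta)) eta <- eta + beta[[nm]] * covariate(nm)

  # --- censoring and baseline-rate calibration to the events target
  cens <- stats::runif(n, spec$censor_range_months[1],
                       spec$censor_range_months[2])
  horizon <- pmin(cens, 60)
  expected_events <- function(lam)
    sum(1 - exp(-lam * exp(eta) * horizon)) - spec$events_target
  lam0 <- stats::uniroot(expected_events, c(1e-8, 10), tol = 1e-12)$root

  # --- inverse-transform sampling under the proportional-hazards model
  u <- stats::runif(n)
  t_event <- -log(u) / (lam0 * exp(eta))
  frame$followup_months <- pmin(t_event, cens)
  frame$event <- as.integer(t_event <= cens)

  list(frame = frame,
       truth = list(true_hr = hr, baseline_rate = lam0, seed = seed,
                    eta = eta))
}
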