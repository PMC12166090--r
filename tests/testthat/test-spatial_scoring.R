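test_that("distance profile bins each immune cell once by nearest tumor cell", {
  cells <- make_scored_cells(c(0, 5, 15, -15, 600),
                             rep(0, 5),
                             c("tumor_epithelial", rep("eosinophil", 4)))
  prof <- distance_profile(cells, "eosinophil")
  expect_equal(nrow(prof), 50L)
  expect_equal(prof$count[1], 1L)  # [0, 10)
  expect_equal(prof$count[2], 2L)  # [10, 20)
  expect_equal(sum(prof$count), 3L) # the 600 um cell is uncounted
  expect_equal(prof$per_tumor_cell, prof$count / 1)

  # two tumor cells 10 um apart, one lymphocyte between them: counted once,
  # in the bin of the nearer tumor cell
  cells2 <- make_scored_cells(c(0, 10, 4), rep(0, 3),
                              c("tumor_epithelial", "tumor_epithelial",
                                "lymphocyte"))
  prof2 <- distance_profile(cells2, "lymphocyte")
  expect_equal(sum(prof2$count), 1L)
  expect_equal(prof2$count[1], 1L) # d = 4 -> [0, 10)
})

test_that("random distance profiles match the exhaustive nearest-neighbour oracle", {
  set.seed(17)
  n_t <- 100; n_i <- 400
  cells <- make_scored_cells(c(runif(n_t, 0, 800), runif(n_i, 0, 800)),
                             c(runif(n_t, 0, 800), runif(n_i, 0, 800)),
                             c(rep("tumor_epithelial", n_t),
                               rep("eosinophil", n_i)))
  prof <- distance_profile(cells, "eosinophil")
  d2 <- outer(cells$x_um[-(1:n_t)], cells$x_um[1:n_t], "-")^2 +
    outer(cells$y_um[-(1:n_t)], cells$y_um[1:n_t], "-")^2
  dmin <- sqrt(apply(d2, 1, min))
  oracle <- tabulate(pmin(findInterval(dmin[dmin <= 500],
                                       seq(0, 500, 10)), 50), nbins = 50)
  expect_equal(prof$count, oracle)
  expect_equal(sum(prof$count), sum(dmin <= 500))
})

test_that("region scores count unique immune cells per regional tumor cell", {
  # 2 front tumor cells, 3 eosinophils within 200 um -> EosF = 1.5
  cells <- make_scored_cells(
    x = c(0, 100, 50, 120, 180),
    y = c(0, 0, 50, 80, 30),
    derived = c("tumor_epithelial", "tumor_epithelial",
                rep("eosinophil", 3)),
    region = c("front", "front", rep("unassigned", 3)),
    front_missing = FALSE)
  expect_equal(region_score(cells, "eosinophil", "front"), 1.5)
  expect_equal(region_score(cells, "eosinophil", "all"), 1.5)
  expect_true(is.na(region_score(cells, "eosinophil", "center"))) # no tumor there

  # an eosinophil 250 um from every tumor cell contributes nothing
  far <- make_scored_cells(c(0, 250), c(0, 0),
                           c("tumor_epithelial", "eosinophil"),
                           region = c("front", "unassigned"))
  expect_equal(region_score(far, "eosinophil", "front"), 0)

  # ties at exactly the count radius are inside
  tie <- make_scored_cells(c(0, 200), c(0, 0),
                           c("tumor_epithelial", "eosinophil"),
                           region = c("front", "unassigned"))
  expect_equal(region_score(tie, "eosinophil", "front"), 1)
})

test_that("front+center counts conserve the unique 200 um eosinophil count", {
  set.seed(23)
  for (rep in 1:20) {
    n_t <- sample(20:100, 1); n_e <- sample(20:150, 1)
    region <- sample(c("front", "center"), n_t, replace = TRUE)
    cells <- make_scored_cells(
      c(runif(n_t, 0, 600), runif(n_e, 0, 600)),
      c(runif(n_t, 0, 600), runif(n_e, 0, 600)),
      c(rep("tumor_epithelial", n_t), rep("eosinophil", n_e)),
      region = c(region, rep("unassigned", n_e)))
    f <- region_score(cells, "eosinophil", "front")
    c_ <- region_score(cells, "eosinophil", "center")
    nf <- sum(region == "front"); nc <- sum(region == "center")
    d2 <- outer(cells$x_um[-(1:n_t)], cells$x_um[1:n_t], "-")^2 +
      outer(cells$y_um[-(1:n_t)], cells$y_um[1:n_t], "-")^2
    unique_200 <- sum(apply(d2, 1, min) <= 200^2)
    total <- (if (nf) f * nf else 0) + (if (nc) c_ * nc else 0)
    expect_equal(total, unique_200, tolerance = 1e-9)
  }
})

test_that("region score is non-decreasing in the count radius", {
  set.seed(29)
  cells <- make_scored_cells(
    c(runif(50, 0, 500), runif(100, 0, 500)),
    c(runif(50, 0, 500), runif(100, 0, 500)),
    c(rep("tumor_epithelial", 50), rep("lymphocyte", 100)),
    region = c(rep("front", 50), rep("unassigned", 100)))
  radii <- c(50, 100, 200, 400)
  s <- vapply(radii, function(r)
    region_score(cells, "lymphocyte", "front",
                 pipeline_config(count_radius_um = r)), numeric(1))
  expect_true(all(diff(s) >= 0))
})

test_that("patients aggregate as tumor-cell-weighted slide averages", {
  slides <- rbind(
    data.frame(slide_id = "A", patient_id = "P1", cohort_id = "C1",
               LymF = 0.2, LymC = 0.1, LymA = 0.15, EosF = 0.10, EosC = 0.05,
               EosA = 0.08, IEL = 0.5, n_tumor_front = 1000,
               n_tumor_center = 500, n_tumor_total = 1500,
               front_missing = FALSE),
    data.frame(slide_id = "B", patient_id = "P1", cohort_id = "C1",
               LymF = 0.6, LymC = 0.3, LymA = 0.45, EosF = 0.40, EosC = 0.15,
               EosA = 0.30, IEL = 0.7, n_tumor_front = 3000,
               n_tumor_center = 1500, n_tumor_total = 4500,
               front_missing = FALSE))
  pat <- aggregate_patients(slides)
  expect_equal(pat$EosF, (0.10 * 1000 + 0.40 * 3000) / 4000) # 0.325
  expect_equal(pat$IEL, (0.5 * 1500 + 0.7 * 4500) / 6000)
  expect_equal(pat$n_slides, 2L)

  # single slide: identity
  one <- aggregate_patients(slides[1, ])
  expect_equal(one$EosF, 0.10)
  expect_equal(one$LymC, 0.1)

  # a front_missing slide contributes only to whole-slide scores
  slides$EosF[2] <- NA; slides$front_missing[2] <- TRUE
  slides$n_tumor_front[2] <- 0
  pat2 <- aggregate_patients(slides)
  expect_equal(pat2$EosF, 0.10)
  expect_equal(pat2$EosA, (0.08 * 1500 + 0.30 * 4500) / 6000)

  # aggregation bound: patient scores inside the slide range
  set.seed(31)
  many <- do.call(rbind, lapply(1:6, function(i) {
    d <- slides[1, ]; d$slide_id <- paste0("S", i)
    d$EosF <- runif(1); d$n_tumor_front <- sample(100:1000, 1); d
  }))
  expect_true(aggregate_patients(many)$EosF >= min(many$EosF) &&
                aggregate_patients(many)$EosF <= max(many$EosF))
})

test_that("stage-II percentile normalization maps p5 to 0 and p95 to 1", {
  pats <- data.frame(patient_id = sprintf("P%03d", 1:101),
                     cohort_id = "C1", EosF = 0:100)
  stage <- rep("II", 101)
  params <- fit_normalization(pats, stage, score_cols = "EosF")
  expect_equal(params$p_lo, 5)
  expect_equal(params$p_hi, 95)
  normed <- apply_normalization(pats, params)
  expect_equal(normed$EosF[pats$EosF == 5], 0)
  expect_equal(normed$EosF[pats$EosF == 95], 1)
  # outliers above p95 exceed 1.0 and are retained, not clipped
  expect_gt(normed$EosF[pats$EosF == 100], 1)

  # percentiles come from stage II only: perturbing stage III changes nothing
  pats2 <- rbind(pats, data.frame(patient_id = "P999", cohort_id = "C1",
                                  EosF = 1e6))
  params2 <- fit_normalization(pats2, c(stage, "III"), score_cols = "EosF")
  expect_equal(params2$p_lo, params$p_lo)
  expect_equal(params2$p_hi, params$p_hi)

  # constant stage II scores degenerate to an error on application
  const <- data.frame(patient_id = c("a", "b", "c"), cohort_id = "C1",
                      EosF = c(2, 2, 2))
  pc <- fit_normalization(const, rep("II", 3), score_cols = "EosF")
  expect_error(apply_normalization(const, pc), "degenerate")

  # too little stage II data names the cohort
  expect_error(fit_normalization(const, c("II", "III", "III"),
                                 score_cols = "EosF"), "C1")
})

test_that("normalization is invariant under affine transforms of the score", {
  set.seed(37)
  x <- rlnorm(40)
  pats <- data.frame(patient_id = as.character(1:40), cohort_id = "C1",
                     EosF = x)
  st <- rep("II", 40)
  n1 <- apply_normalization(pats, fit_normalization(pats, st,
                                                    score_cols = "EosF"))
  pats2 <- pats; pats2$EosF <- 3.5 * x + 2
  n2 <- apply_normalization(pats2, fit_normalization(pats2, st,
                                                     score_cols = "EosF"))
  expect_equal(n1$EosF, n2$EosF, tolerance = 1e-10)
})
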