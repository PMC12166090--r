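# In-code fixtures and independent brute-force oracles used across tests.

# quick cell_table from coordinate vectors
make_cells <- function(x, y, class, slide_id = "S1", patient_id = "P1",
                       cohort_id = "C1") {
  cell_table(data.frame(slide_id = slide_id, patient_id = patient_id,
                        cohort_id = cohort_id, x_um = x, y_um = y,
                        class = class, stringsAsFactors = FALSE))
}

# cells with derived class / region set directly, bypassing context stages
make_scored_cells <- function(x, y, derived, region = "unassigned",
                              front_missing = FALSE) {
  raw <- ifelse(derived %in% c("tumor_epithelial", "normal_epithelial"),
                "epithelial",
                ifelse(derived %in% c("lymphocyte", "eosinophil"),
                       derived, "connective"))
  cells <- make_cells(x, y, raw)
  cells$derived_class <- derived
  cells$region <- region
  attr(cells, "front_missing") <- front_missing
  cells
}

# brute-force O(n^2) nearest-neighbour oracle
bf_nn <- function(qx, qy, rx, ry) {
  d2 <- outer(qx, rx, "-")^2 + outer(qy, ry, "-")^2
  list(index = apply(d2, 1, which.min), dist = sqrt(apply(d2, 1, min)))
}

# brute-force union-find over the explicit <= radius pair list, with the
# same canonical labelling (first-appearance order) as the kernel
bf_components <- function(x, y, radius) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (d2[i, j] <= radius^2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# brute-force point-to-polyline distance (per-segment projection)
bf_dist_polylines <- function(px, py, polylines) {
  best <- rep(Inf, length(px))
  for (p in polylines) {
    for (s in seq_len(nrow(p) - 1L)) {
      vx <- p[s + 1, 1] - p[s, 1]; vy <- p[s + 1, 2] - p[s, 2]
      L2 <- vx^2 + vy^2
      wx <- px - p[s, 1]; wy <- py - p[s, 2]
      t <- if (L2 > 0) pmin(1, pmax(0, (wx * vx + wy * vy) / L2)) else 0
      d <- sqrt((wx - t * vx)^2 + (wy - t * vy)^2)
      best <- pmin(best, d)
    }
  }
  best
}

# independent product-limit (Kaplan-Meier) estimator
bf_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = tt, surv = NA_real_)
  for (k in seq_along(tt)) {
    at_risk <- sum(time >= tt[k])
    d <- sum(time == tt[k] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[k] <- s
  }
  out
}

# write a small detections CSV
write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# layered band map: normal mucosa top, tumor mid, muscle bottom (codes 0-8)
make_band_map <- function(nr = 100, nc = 100, mpp = 10,
                          normal_rows = NULL, tumor_rows = 30:50,
                          muscle_rows = 70:100) {
  lab <- matrix(3L, nr, nc) # stroma
  if (!is.null(normal_rows)) lab[normal_rows, ] <- 6L
  lab[tumor_rows, ] <- 7L
  if (!is.null(muscle_rows)) lab[muscle_rows, ] <- 2L
  tissue_map(lab, mpp)
}
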