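test_that("component size thresholds are strictly exclusive", {
  # 501 lymphocytes on a 10 um chain: one component, > 500 so aggregate
  chain <- make_cells(seq(0, by = 10, length.out = 501), rep(0, 501),
                      rep("lymphocyte", 501))
  out <- detect_lymphoid_clusters(chain)
  comp <- attr(out, "components")
  expect_equal(nrow(comp), 1L)
  expect_equal(comp$size, 501L)
  expect_equal(comp$kind, "aggregate")
  expect_true(all(out$in_aggregate))
  expect_true(all(out$excluded))

  # exactly 500 is not an aggregate
  chain500 <- make_cells(seq(0, by = 10, length.out = 500), rep(0, 500),
                         rep("lymphocyte", 500))
  expect_equal(attr(detect_lymphoid_clusters(chain500),
                    "components")$kind, "none")

  # 21 um apart: two singletons
  pair <- make_cells(c(0, 21), c(0, 0), rep("lymphocyte", 2))
  comp2 <- attr(detect_lymphoid_clusters(pair), "components")
  expect_equal(comp2$size, c(1L, 1L))
  expect_equal(comp2$kind, c("none", "none"))
})

test_that("radius clustering equals brute-force union-find on random instances", {
  set.seed(5)
  for (rep in 1:8) {
    n <- sample(50:400, 1)
    x <- runif(n, 0, 400); y <- runif(n, 0, 400)
    kernel <- immunofront:::.radius_components_cpp(x, y, 20)
    oracle <- bf_components(x, y, 20)
    expect_identical(as.integer(kernel), as.integer(oracle))
  }
})

test_that("component sizes partition the lymphocytes and kinds are monotone", {
  set.seed(9)
  cells <- make_cells(runif(2000, 0, 1500), runif(2000, 0, 1500),
                      sample(c("lymphocyte", "eosinophil"), 2000, TRUE))
  out <- detect_lymphoid_clusters(cells)
  comp <- attr(out, "components")
  expect_equal(sum(comp$size), sum(cells$raw_class == "lymphocyte"))
  rank <- c(none = 0, aggregate = 1, lymph_node = 2)
  expect_true(all(diff(rank[comp$kind[order(comp$size)]]) >= 0))
})

test_that("epithelial region area matches the closed forms for one cell", {
  one <- make_scored_cells(0, 0, "tumor_epithelial")
  reg <- build_epithelial_region(one)
  expect_equal(reg$area_um2, pi * 25^2, tolerance = 1e-3)

  both <- make_scored_cells(c(0, 0), c(0, 0),
                            c("tumor_epithelial", "other"))
  both$raw_class[2] <- "connective"
  reg2 <- build_epithelial_region(both)
  expect_equal(reg2$area_um2, pi * (25^2 - 12.5^2), tolerance = 1e-3)

  none <- make_scored_cells(0, 0, "lymphocyte")
  expect_equal(build_epithelial_region(none)$area_um2, 0)
})

test_that("region area agrees with a Monte-Carlo estimate within 1%", {
  set.seed(21)
  df <- data.frame(x = runif(30, 0, 200), y = runif(30, 0, 200),
                   derived = c(rep("tumor_epithelial", 20), rep("other", 10)))
  cells <- make_scored_cells(df$x, df$y, df$derived)
  cells$raw_class[21:30] <- "connective"
  reg <- build_epithelial_region(cells)
  # Monte-Carlo oracle over the bounding box of the tumor disks
  bb <- c(range(df$x[1:20]) + c(-25, 25), range(df$y[1:20]) + c(-25, 25))
  mx <- runif(4e5, bb[1], bb[2]); my <- runif(4e5, bb[3], bb[4])
  inside <- in_epithelial_region(reg, mx, my)
  mc <- mean(inside) * (bb[2] - bb[1]) * (bb[4] - bb[3])
  expect_equal(reg$area_um2, mc, tolerance = 0.01)
})

test_that("IEL flags follow region membership and exclusions", {
  cells <- make_scored_cells(c(0, 10, 30, 5), c(0, 0, 0, 0),
                             c("tumor_epithelial", "lymphocyte",
                               "lymphocyte", "lymphocyte"))
  cells$excluded[4] <- TRUE # e.g. member of an aggregate
  reg <- build_epithelial_region(cells, compute_area = FALSE)
  out <- flag_iels(cells, reg)
  expect_equal(out$is_iel, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("IEL ratio counts tumor cells with and without adjacent IELs", {
  # 10 tumor cells 100 um apart; IELs planted 10 um from four of them
  tx <- seq(0, 900, by = 100)
  cells <- make_scored_cells(c(tx, tx[1:4] + 10), c(rep(0, 10), rep(0, 4)),
                             c(rep("tumor_epithelial", 10),
                               rep("lymphocyte", 4)))
  reg <- build_epithelial_region(cells, compute_area = FALSE)
  cells <- flag_iels(cells, reg)
  expect_equal(iel_ratio(cells), 4 / 6, tolerance = 1e-12)

  # no IELs at all -> 0
  bare <- make_scored_cells(tx, rep(0, 10), rep("tumor_epithelial", 10))
  expect_equal(iel_ratio(bare), 0)

  # no tumor cells -> missing with warning
  expect_warning(
    r <- iel_ratio(make_scored_cells(0, 0, "lymphocyte")), "no tumor")
  expect_true(is.na(r))
})

test_that("IEL adjacency matches the exhaustive pairwise oracle", {
  set.seed(13)
  n_t <- 120; n_l <- 80
  cells <- make_scored_cells(c(runif(n_t, 0, 500), runif(n_l, 0, 500)),
                             c(runif(n_t, 0, 500), runif(n_l, 0, 500)),
                             c(rep("tumor_epithelial", n_t),
                               rep("lymphocyte", n_l)))
  reg <- build_epithelial_region(cells, compute_area = FALSE)
  cells <- flag_iels(cells, reg)
  # oracle: brute-force adjacency between tumor cells and flagged IELs
  tum <- cells[cells$derived_class == "tumor_epithelial", ]
  iel <- cells[cells$is_iel, ]
  if (nrow(iel)) {
    d2 <- outer(tum$x_um, iel$x_um, "-")^2 + outer(tum$y_um, iel$y_um, "-")^2
    with_iel <- sum(apply(d2, 1, min) <= 25^2)
  } else with_iel <- 0
  expect_equal(iel_ratio(cells), with_iel / (n_t - with_iel),
               tolerance = 1e-12)
})

test_that("everything inside a lymph-node hull is excluded from scoring", {
  set.seed(2)
  # compact planted node (well over the threshold with a tiny config) plus
  # a distant eosinophil and tumor cell that must stay in
  n <- 700
  node <- cbind(rnorm(n, 0, 30), rnorm(n, 0, 30))
  cells <- make_scored_cells(c(node[, 1], 500, 510, 0),
                             c(node[, 2], 500, 510, 0),
                             c(rep("lymphocyte", n), "tumor_epithelial",
                               "eosinophil", "eosinophil"))
  cfg <- pipeline_config(aggregate_min_cells = 50, lymphnode_min_cells = 200)
  out <- detect_lymphoid_clusters(cells, cfg)
  comp <- attr(out, "components")
  expect_true(any(comp$kind == "lymph_node"))
  expect_gt(mean(out$in_lymph_node[1:n]), 0.95) # Gaussian tails may detach
  expect_false(out$excluded[n + 1]) # distant tumor cell kept
  expect_false(out$excluded[n + 2]) # distant eosinophil kept
  expect_true(out$excluded[n + 3])  # eosinophil at the node centre excluded
})
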