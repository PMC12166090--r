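#' Detect lymphoid aggregates and lymph nodes
#'
#' Lymphocytes are clustered by linking every pair at distance at most
#' `cluster_link_radius_um` (20 micrometres) and taking connected
#' components. Components of more than `aggregate_min_cells` (500, strictly
#' exclusive) lymphocytes are lymphoid aggregates; components of more than
#' `lymphnode_min_cells` (50000) are lymph nodes. Member lymphocytes are
#' flagged and excluded from all downstream scoring so dense organized
#' structures do not skew stromal lymphocyte counts. Cells of any class
#' falling inside the convex hull of a lymph-node component are excluded as
#' well: an on-slide lymph node is not tumor microenvironment.
#'
#' @param cells a [cell_table()].
#' @param cfg a [pipeline_config()].
#' @return The `cell_table` with `component_id`, `structure_kind`,
#'   `in_aggregate`, `in_lymph_node` and `excluded` filled in. Component
#'   summary attached as attribute `components` (data frame with
#'   `component_id`, `size`, `kind`).
#' @export
detect_lymphoid_clusters <- function(cells, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  stopifnot(inherits(cells, "cell_table"))
  lym <- which(cells$derived_class == "lymphocyte")
  if (!length(lym)) {
    attr(cells, "components") <-
      data.frame(component_id = integer(), size = integer(),
                 kind = character(), stringsAsFactors = FALSE)
    return(cells)
  }
  comp <- .radius_components_cpp(cells$x_um[lym], cells$y_um[lym],
                                 cfg$cluster_link_radius_um)
  size <- tabulate(comp)
  kind <- ifelse(size > cfg$lymphnode_min_cells, "lymph_node",
                 ifelse(size > cfg$aggregate_min_cells, "aggregate", "none"))
  cells$component_id[lym] <- comp
  cells$structure_kind[lym] <- kind[comp]
  cells$in_aggregate[lym] <- kind[comp] == "aggregate"
  cells$in_lymph_node[lym] <- kind[comp] == "lymph_node"
  cells$excluded <- cells$excluded | cells$in_aggregate | cells$in_lymph_node

  # everything inside a lymph node's convex hull is off-limits for scoring
  for (cid in which(kind == "lymph_node")) {
    member <- lym[comp == cid]
    if (length(member) < 3L) next
    hx <- cells$x_um[member]; hy <- cells$y_um[member]
    h <- grDevices::chull(hx, hy)
    bnd <- cbind(hx[c(h, h[1])], hy[c(h, h[1])])
    cand <- which(!cells$excluded)
    if (length(cand)) {
      inside <- mgcv::in.out(bnd, cbind(cells$x_um[cand], cells$y_um[cand]))
      cells$excluded[cand[inside]] <- TRUE
    }
  }
  attr(cells, "components") <-
    data.frame(component_id = seq_along(size), size = size, kind = kind,
               stringsAsFactors = FALSE)
  cells
}

#' Intraepithelial region
#'
#' The epithelial tissue region used to find intraepithelial lymphocytes:
#' the union of disks of radius `iel_dilation_um` (25 micrometres) around
#' tumor epithelial centroids, minus the union of disks of radius
#' `connective_dilation_um` (12.5 micrometres) around connective-class
#' centroids. Membership tests are exact (nearest-distance tests); the area
#' is computed by scanline integration with exact interval arithmetic in x
#' and step `area_scanline_step_um` in y.
#'
#' @param cells a [cell_table()] with epithelial context assigned.
#' @param cfg a [pipeline_config()].
#' @param compute_area compute `area_um2` (skipped for large slides where
#'   only membership is needed)?
#' @return An `epithelial_region` object with fields `tumor_xy`,
#'   `connective_xy`, `r_tumor`, `r_connective`, `area_um2`.
#' @export
build_epithelial_region <- function(cells, cfg = pipeline_config(),
                                    compute_area = TRUE) {
  cfg <- as_config(cfg)
  stopifnot(inherits(cells, "cell_table"))
  tum <- cells$derived_class == "tumor_epithelial"
  con <- cells$raw_class == "connective"
  reg <- structure(list(
    tumor_xy = cbind(cells$x_um[tum], cells$y_um[tum]),
    connective_xy = cbind(cells$x_um[con], cells$y_um[con]),
    r_tumor = cfg$iel_dilation_um,
    r_connective = cfg$connective_dilation_um,
    area_um2 = 0
  ), class = "epithelial_region")
  if (compute_area && nrow(reg$tumor_xy)) {
    reg$area_um2 <- .disk_region_area_cpp(
      reg$tumor_xy[, 1], reg$tumor_xy[, 2], reg$r_tumor,
      reg$connective_xy[, 1], reg$connective_xy[, 2], reg$r_connective,
      cfg$area_scanline_step_um)
  }
  reg
}

#' @export
print.epithelial_region <- function(x, ...) {
  cat(sprintf(
    "<epithelial_region> %d tumor disks (r=%.1f) - %d connective disks (r=%.1f), area %.1f um^2\n",
    nrow(x$tumor_xy), x$r_tumor, nrow(x$connective_xy), x$r_connective,
    x$area_um2))
  invisible(x)
}

#' Point membership in an epithelial region
#'
#' A point is inside the region iff it lies within `r_tumor` of some tumor
#' centroid and not within `r_connective` of any connective centroid.
#'
#' @param region an [build_epithelial_region()] result.
#' @param x,y coordinates in micrometres.
#' @return Logical vector.
#' @export
in_epithelial_region <- function(region, x, y) {
  stopifnot(inherits(region, "epithelial_region"))
  n <- length(x)
  if (!n) return(logical(0))
  if (!nrow(region$tumor_xy)) return(rep(FALSE, n))
  d_t <- .nn_lookup_cpp(as.numeric(x), as.numeric(y),
                        region$tumor_xy[, 1], region$tumor_xy[, 2])$dist
  inside <- d_t <= region$r_tumor
  if (nrow(region$connective_xy)) {
    d_c <- .nn_lookup_cpp(as.numeric(x), as.numeric(y),
                          region$connective_xy[, 1],
                          region$connective_xy[, 2])$dist
    inside <- inside & d_c > region$r_connective
  }
  inside
}

#' Flag intraepithelial lymphocytes
#'
#' Sets `is_iel` for every non-excluded lymphocyte whose centroid lies
#' inside the intraepithelial region. Lymphocytes already assigned to a
#' lymphoid aggregate or lymph node are never IELs (exclusion precedes
#' flagging).
#'
#' @param cells a [cell_table()] after [detect_lymphoid_clusters()].
#' @param region an [build_epithelial_region()] result.
#' @return The `cell_table` with `is_iel` set.
#' @export
flag_iels <- function(cells, region) {
  stopifnot(inherits(cells, "cell_table"))
  cand <- which(cells$derived_class == "lymphocyte" & !cells$excluded)
  cells$is_iel <- FALSE
  if (length(cand))
    cells$is_iel[cand] <- in_epithelial_region(region, cells$x_um[cand],
                                               cells$y_um[cand])
  cells
}

#' IEL ratio
#'
#' Ratio of tumor cells with at least one adjacent intraepithelial
#' lymphocyte (within `adjacency_radius_um`) to tumor cells with none. This
#' per-tumor-cell formulation is robust to epithelial crypt
#' misclassification, unlike a raw IEL count.
#'
#' @param cells a [cell_table()] after [flag_iels()].
#' @param cfg a [pipeline_config()].
#' @return A single number; `NA` (with a warning) when there are no tumor
#'   cells or every tumor cell has an adjacent IEL (denominator zero).
#' @export
iel_ratio <- function(cells, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  stopifnot(inherits(cells, "cell_table"))
  tum <- which(cells$derived_class == "tumor_epithelial")
  if (!length(tum)) {
    warning("no tumor cells; IEL ratio undefined", call. = FALSE)
    return(NA_real_)
  }
  iel <- which(cells$is_iel)
  if (!length(iel)) return(0)
  d <- .nn_lookup_cpp(cells$x_um[tum], cells$y_um[tum],
                      cells$x_um[iel], cells$y_um[iel])$dist
  with_iel <- sum(d <= cfg$adjacency_radius_um)
  without <- length(tum) - with_iel
  if (without == 0L) {
    warning("all tumor cells have an adjacent IEL; ratio undefined",
            call. = FALSE)
    return(NA_real_)
  }
  with_iel / without
}
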