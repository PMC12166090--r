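#' Front-line object
#'
#' One or more polylines in slide micrometre coordinates separating tumor
#' epithelium from invaded muscle/adipose tissue.
#'
#' @param polylines list of n x 2 matrices (columns x_um, y_um), each with at
#'   least two vertices.
#' @return A `front_line` object with fields `polylines`, `detected` and
#'   `total_length_um`.
#' @export
front_line <- function(polylines = list()) {
  polylines <- Filter(function(p) is.matrix(p) && nrow(p) >= 2L, polylines)
  for (p in polylines)
    if (any(!is.finite(p))) stop("front vertices must be finite", call. = FALSE)
  len <- sum(vapply(polylines, polyline_length, numeric(1)))
  structure(list(polylines = polylines, detected = length(polylines) > 0L,
                 total_length_um = len),
            class = "front_line")
}

#' @export
print.front_line <- function(x, ...) {
  if (x$detected)
    cat(sprintf("<front_line> %d polyline(s), total length %.0f um\n",
                length(x$polylines), x$total_length_um))
  else cat("<front_line> not detected\n")
  invisible(x)
}

polyline_length <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
}

# Ramer-Douglas-Peucker polyline simplification
simplify_polyline <- function(p, tol) {
  n <- nrow(p)
  if (n <= 2L) return(p)
  keep <- logical(n); keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2L) next
    ax <- p[i, 1]; ay <- p[i, 2]; bx <- p[j, 1]; by <- p[j, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    ks <- (i + 1L):(j - 1L)
    wx <- p[ks, 1] - ax; wy <- p[ks, 2] - ay
    t <- if (L2 > 0) pmin(1, pmax(0, (wx * vx + wy * vy) / L2)) else 0
    d2 <- (wx - t * vx)^2 + (wy - t * vy)^2
    kmax <- which.max(d2)
    if (d2[kmax] > tol^2) {
      k <- ks[kmax]
      keep[k] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, k)
      stack[[length(stack) + 1L]] <- c(k, j)
    }
  }
  p[keep, , drop = FALSE]
}

# nearest-pixel sample of a raster field at micrometre coordinates
sample_field <- function(field, mpp, x, y) {
  r <- pmin(pmax(floor(y / mpp) + 1L, 1L), nrow(field))
  c <- pmin(pmax(floor(x / mpp) + 1L, 1L), ncol(field))
  field[cbind(r, c)]
}

#' Estimate the tumor invasive front line
#'
#' Colorectal tumors grow into muscle and adipose tissue; the invasive front
#' is estimated as the line equidistant between the tumor-epithelium mask
#' and the union of the muscle and adipose masks. Concretely, the Euclidean
#' distance transforms to each mask are computed on the raster and the front
#' is the zero contour of their difference, vectorized to polylines and
#' simplified with a one-pixel tolerance. Contour vertices are dropped where
#' the two masks are more than `2 * front_band_halfwidth_um` apart (no
#' tumor/muscle interface there) and where the nearest non-tumor context is
#' normal mucosa rather than muscle/adipose, so no front is drawn along the
#' normal epithelium. Fragments shorter than `min_front_length_um` are
#' discarded as spurious. Absence of a front (no tumor, no muscle/adipose,
#' or nothing survives the filters) is a valid outcome reported via
#' `detected`.
#'
#' @param map a merged [tissue_map()].
#' @param cfg a [pipeline_config()].
#' @return A [front_line()].
#' @export
estimate_front_line <- function(map, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  stopifnot(inherits(map, "tissue_map"))
  lab <- map$labels
  mpp <- map$mpp
  tumor <- lab == TISSUE_CLASSES[["tumor_epithelium"]]
  invaded <- lab == TISSUE_CLASSES[["muscle"]] |
    lab == TISSUE_CLASSES[["adipose"]]
  normal <- lab == TISSUE_CLASSES[["normal_epithelium"]]
  if (!any(tumor) || !any(invaded)) return(front_line())

  d_tum <- EBImage::distmap(matrix(as.numeric(!tumor), nrow(lab))) * mpp
  d_inv <- EBImage::distmap(matrix(as.numeric(!invaded), nrow(lab))) * mpp
  d_nor <- if (any(normal))
    EBImage::distmap(matrix(as.numeric(!normal), nrow(lab))) * mpp
  else NULL

  nr <- nrow(lab); nc <- ncol(lab)
  xs <- (seq_len(nc) - 0.5) * mpp
  ys <- (seq_len(nr) - 0.5) * mpp
  f <- d_tum - d_inv
  contours <- grDevices::contourLines(x = xs, y = ys, z = t(f), levels = 0)
  if (!length(contours)) return(front_line())

  band <- 2 * cfg$front_band_halfwidth_um
  polys <- list()
  for (ct in contours) {
    vx <- ct$x; vy <- ct$y
    ok <- sample_field(d_tum, mpp, vx, vy) +
      sample_field(d_inv, mpp, vx, vy) <= band
    if (!is.null(d_nor)) {
      # omit any stretch bordering the normal mucosa
      ok <- ok & sample_field(d_nor, mpp, vx, vy) >=
        sample_field(d_inv, mpp, vx, vy)
    }
    if (!any(ok)) next
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values & runs$lengths >= 2L)) {
      seg <- cbind(vx[starts[k]:ends[k]], vy[starts[k]:ends[k]])
      seg <- simplify_polyline(seg, tol = mpp)
      if (polyline_length(seg) >= cfg$min_front_length_um)
        polys[[length(polys) + 1L]] <- seg
    }
  }
  front_line(polys)
}

#' Distance from points to a front line
#'
#' Minimum Euclidean distance from each point to any polyline segment of the
#' front.
#'
#' @param front a [front_line()].
#' @param x,y point coordinates in micrometres.
#' @return Numeric vector of distances (`Inf` when no front is detected).
#' @export
dist_to_front <- function(front, x, y) {
  stopifnot(inherits(front, "front_line"))
  if (!front$detected) return(rep(Inf, length(x)))
  segs <- do.call(rbind, lapply(front$polylines, function(p) {
    n <- nrow(p)
    cbind(p[-n, 1], p[-n, 2], p[-1, 1], p[-1, 2])
  }))
  .dist_to_segments_cpp(as.numeric(x), as.numeric(y),
                        segs[, 1], segs[, 2], segs[, 3], segs[, 4])
}

#' Partition tumor cells into front and center
#'
#' Tumor epithelial cells within `front_band_halfwidth_um` (500 micrometres;
#' ties inclusive) of the front line are labelled `front`; all remaining
#' tumor cells are `center`. When no front was detected every tumor cell is
#' `center` and the slide is flagged `front_missing`, which downstream
#' excludes it from region-specific scores.
#'
#' @param cells a [cell_table()] with epithelial context assigned.
#' @param front a [front_line()].
#' @param cfg a [pipeline_config()].
#' @return The `cell_table` with tumor-cell `region` set and attributes
#'   `front_missing`, `n_tumor_front`, `n_tumor_center`.
#' @export
assign_regions <- function(cells, front, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  stopifnot(inherits(cells, "cell_table"), inherits(front, "front_line"))
  tum <- which(cells$derived_class == "tumor_epithelial")
  if (!front$detected) {
    cells$region[tum] <- "center"
    attr(cells, "front_missing") <- TRUE
    attr(cells, "n_tumor_front") <- 0L
    attr(cells, "n_tumor_center") <- length(tum)
    return(cells)
  }
  d <- dist_to_front(front, cells$x_um[tum], cells$y_um[tum])
  cells$region[tum] <- ifelse(d <= cfg$front_band_halfwidth_um,
                              "front", "center")
  attr(cells, "front_missing") <- FALSE
  attr(cells, "n_tumor_front") <- sum(d <= cfg$front_band_halfwidth_um)
  attr(cells, "n_tumor_center") <- sum(d > cfg$front_band_halfwidth_um)
  cells
}

#' Export a front line as GeoJSON
#'
#' Writes a `LineString` (single polyline) or `MultiLineString` geometry in
#' micrometre slide coordinates.
#'
#' @param front a [front_line()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_front_geojson <- function(front, path) {
  stopifnot(inherits(front, "front_line"))
  coords <- lapply(front$polylines, function(p)
    lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2])))
  geom <- if (length(coords) == 1L)
    list(type = "LineString", coordinates = coords[[1]])
  else list(type = "MultiLineString", coordinates = coords)
  obj <- list(type = "Feature",
              properties = list(detected = front$detected,
                                total_length_um = front$total_length_um,
                                crs = "slide micrometres, y down"),
              geometry = geom)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a front line from GeoJSON
#'
#' @param path GeoJSON path written by [write_front_geojson()].
#' @return A [front_line()].
#' @export
read_front_geojson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  geom <- obj$geometry
  if (is.null(geom) || is.null(geom$coordinates)) return(front_line())
  if (identical(geom$type, "LineString")) {
    front_line(list(as.matrix(geom$coordinates)))
  } else {
    coords <- geom$coordinates
    if (is.array(coords) && length(dim(coords)) == 3L) {
      front_line(lapply(seq_len(dim(coords)[1]),
                        function(i) coords[i, , , drop = TRUE]))
    } else {
      front_line(lapply(coords, as.matrix))
    }
  }
}
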