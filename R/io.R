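#' @useDynLib immunofront, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile setNames aggregate
#' @importFrom utils read.csv write.csv head
NULL

# nucleus classes emitted by the upstream nuclei model
RAW_CLASSES <- c("epithelial", "lymphocyte", "neutrophil", "plasma",
                 "eosinophil", "mitosis", "connective")
# semantic classes used by the analysis; neutrophil/plasma/mitosis/connective
# are all grouped as "other"
DERIVED_CLASSES <- c("tumor_epithelial", "normal_epithelial", "lymphocyte",
                     "eosinophil", "other")
OTHER_RAW <- c("neutrophil", "plasma", "mitosis", "connective")

# tissue-type raster codes 0-8
TISSUE_CLASSES <- c(background = 0L, adipose = 1L, muscle = 2L, stroma = 3L,
                    lymphoid_aggregate = 4L, debris = 5L,
                    normal_epithelium = 6L, tumor_epithelium = 7L,
                    mucin = 8L)

derive_default_class <- function(raw_class) {
  out <- rep(NA_character_, length(raw_class))
  out[raw_class %in% OTHER_RAW] <- "other"
  out[raw_class == "lymphocyte"] <- "lymphocyte"
  out[raw_class == "eosinophil"] <- "eosinophil"
  # epithelial stays NA: pending tumor/normal context assignment
  out
}

#' Build a per-slide cell table
#'
#' A `cell_table` is a data frame with one row per detected nucleus and the
#' bookkeeping columns the pipeline fills in as it runs: semantic class,
#' front/center region, lymphoid-structure membership and IEL flags.
#'
#' @param df data frame with at least `slide_id`, `x_um`, `y_um` and `class`
#'   (one of `r paste(RAW_CLASSES, collapse = ", ")`); optional `patient_id`,
#'   `cohort_id`, `prob`.
#' @return A `cell_table` data frame.
#' @export
cell_table <- function(df) {
  req <- c("slide_id", "x_um", "y_um", "class")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!(df$class %in% RAW_CLASSES))
  if (length(bad))
    stop(sprintf("unknown nucleus class '%s' at row %d", df$class[bad[1]],
                 bad[1]), call. = FALSE)
  if (nrow(df) && any(!is.finite(df$x_um) | !is.finite(df$y_um)))
    stop("cell coordinates must be finite", call. = FALSE)
  if (nrow(df) && length(unique(df$slide_id)) > 1L)
    stop("a cell_table holds one slide; got multiple slide_id values",
         call. = FALSE)
  out <- data.frame(
    slide_id = as.character(df$slide_id),
    patient_id = if ("patient_id" %in% names(df))
      as.character(df$patient_id) else rep(NA_character_, nrow(df)),
    cohort_id = if ("cohort_id" %in% names(df))
      as.character(df$cohort_id) else rep(NA_character_, nrow(df)),
    x_um = as.numeric(df$x_um),
    y_um = as.numeric(df$y_um),
    raw_class = as.character(df$class),
    stringsAsFactors = FALSE
  )
  n <- nrow(out)
  out$derived_class <- derive_default_class(out$raw_class)
  out$region <- rep("unassigned", n)
  out$component_id <- rep(NA_integer_, n)
  out$structure_kind <- rep("none", n)
  out$in_aggregate <- rep(FALSE, n)
  out$in_lymph_node <- rep(FALSE, n)
  out$is_iel <- rep(FALSE, n)
  out$excluded <- rep(FALSE, n)
  if ("prob" %in% names(df)) out$prob <- as.numeric(df$prob)
  class(out) <- c("cell_table", "data.frame")
  out
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> slide %s: %d nuclei\n",
              if (nrow(x)) x$slide_id[1] else "?", nrow(x)))
  if (nrow(x)) print(table(x$raw_class))
  invisible(x)
}

#' Read a nuclei detection table
#'
#' Reads a comma-delimited UTF-8 detection table (columns `slide_id`, `x_um`,
#' `y_um`, `class`, optionally `patient_id`, `cohort_id`, `prob`, plus any
#' pipeline columns a previous stage appended) into a [cell_table()].
#' Nucleus classes neutrophil, plasma, mitosis and connective are grouped as
#' "other"; epithelial rows are left pending the tumor/normal tissue-context
#' assignment.
#'
#' @param path CSV file path.
#' @return A `cell_table`.
#' @seealso [write_detections()], [assign_epithelial_context()]
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  tab <- cell_table(df)
  # restore stage columns written by a previous run, if present
  for (col in c("derived_class", "region", "structure_kind")) {
    if (col %in% names(df)) tab[[col]] <- as.character(df[[col]])
  }
  if ("component_id" %in% names(df))
    tab$component_id <- as.integer(df$component_id)
  for (col in c("in_aggregate", "in_lymph_node", "is_iel", "excluded")) {
    if (col %in% names(df)) tab[[col]] <- as.logical(df[[col]])
  }
  tab
}

#' Write a detection table
#'
#' Inverse of [read_detections()]; coordinates are written with full
#' precision so a read/write cycle is bit-exact.
#'
#' @param cells a `cell_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(cells, path) {
  out <- as.data.frame(cells)
  names(out)[names(out) == "raw_class"] <- "class"
  for (col in c("x_um", "y_um", "prob")) {
    if (col %in% names(out)) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Tissue-type label raster
#'
#' @param labels integer matrix of tissue codes 0-8 in the order background,
#'   adipose, muscle, stroma, lymphoid_aggregate, debris, normal_epithelium,
#'   tumor_epithelium, mucin. Row `r`, column `c` covers the half-open pixel
#'   `[ (c-1)*mpp, c*mpp ) x [ (r-1)*mpp, r*mpp )` in slide micrometre
#'   coordinates (origin top-left, x right, y down).
#' @param mpp micrometres per pixel (> 0).
#' @return A `tissue_map` object.
#' @export
tissue_map <- function(labels, mpp) {
  if (!is.numeric(mpp) || length(mpp) != 1L || !is.finite(mpp) || mpp <= 0)
    stop("'mpp' must be a single positive number", call. = FALSE)
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (any(is.na(labels)) || any(labels < 0L) || any(labels > 8L))
    stop("tissue labels must be integer codes 0-8", call. = FALSE)
  structure(list(labels = labels, mpp = mpp, merged = FALSE),
            class = "tissue_map")
}

#' @export
print.tissue_map <- function(x, ...) {
  cat(sprintf("<tissue_map> %d x %d px at %.3g um/px (%s)\n",
              nrow(x$labels), ncol(x$labels), x$mpp,
              if (isTRUE(x$merged)) "merged" else "raw"))
  invisible(x)
}

#' Read a tissue-type label raster
#'
#' Accepts a single-channel indexed PNG (or TIFF when the `tiff` package is
#' installed) whose pixel values are tissue codes 0-8. The physical
#' resolution comes from `mpp` or from a JSON sidecar `<path>.json` with a
#' field `mpp`.
#'
#' @param path image path.
#' @param mpp micrometres per pixel; if `NULL`, read from the sidecar.
#' @return A [tissue_map()].
#' @export
read_tissue_map <- function(path, mpp = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(mpp)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("no 'mpp' given and no sidecar ", sidecar, call. = FALSE)
    mpp <- jsonlite::fromJSON(sidecar)$mpp
  }
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  codes <- round(img * 255)
  if (any(codes > 8))
    stop("tissue raster contains codes > 8", call. = FALSE)
  tissue_map(codes, mpp)
}

#' Write a tissue-type label raster
#'
#' Writes a single-channel PNG with pixel values equal to the tissue codes
#' and a JSON sidecar `<path>.json` carrying the resolution.
#'
#' @param map a [tissue_map()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_tissue_map <- function(map, path) {
  stopifnot(inherits(map, "tissue_map"))
  png::writePNG(map$labels / 255, path)
  jsonlite::write_json(list(mpp = map$mpp), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Merge tissue classes for analysis
#'
#' Prepares a raw tissue raster for the pipeline: lymphoid-aggregate pixels
#' are recoded as stroma so that tissue-level aggregates never act as tumor,
#' muscle/adipose or normal-epithelium context (cell-level clustering in
#' [detect_lymphoid_clusters()] is the single authority on aggregate
#' exclusions), and muscle and stroma are unified into one working class for
#' all nucleus-context queries (see [working_labels()]). The raw muscle and
#' adipose labels remain available to the invasive-front estimator, which
#' relies on the tumor/muscle/adipose topology. Idempotent.
#'
#' @param map a [tissue_map()].
#' @return The merged `tissue_map`.
#' @export
merge_tissue_classes <- function(map) {
  stopifnot(inherits(map, "tissue_map"))
  lab <- map$labels
  lab[lab == TISSUE_CLASSES[["lymphoid_aggregate"]]] <-
    TISSUE_CLASSES[["stroma"]]
  map$labels <- lab
  map$merged <- TRUE
  map
}

#' Working-class view of a tissue map
#'
#' Returns the label grid with muscle and stroma carrying the same working
#' code (the stroma code); used for nucleus-context assignment where the two
#' are analytically equivalent.
#'
#' @param map a [tissue_map()].
#' @return Integer matrix of working codes.
#' @export
working_labels <- function(map) {
  lab <- map$labels
  lab[lab == TISSUE_CLASSES[["muscle"]]] <- TISSUE_CLASSES[["stroma"]]
  lab
}

#' Assign tumor/normal context to epithelial nuclei
#'
#' Each epithelial nucleus is classified as `tumor_epithelial` or
#' `normal_epithelial` by the majority tissue class within a disk of radius
#' `cfg$iel_dilation_um` (25 micrometres by default) around its centroid;
#' any other majority context yields `other`. Ties go to the class of the
#' nearest labelled pixel among the tied classes. Nuclei farther than the
#' disk radius outside the raster extent are classified `other`; their count
#' is attached as attribute `n_outside`.
#'
#' @param cells a [cell_table()].
#' @param map a merged [tissue_map()].
#' @param cfg a [pipeline_config()].
#' @return The `cell_table` with `derived_class` resolved for epithelial
#'   rows.
#' @export
assign_epithelial_context <- function(cells, map, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  stopifnot(inherits(cells, "cell_table"), inherits(map, "tissue_map"))
  idx <- which(cells$raw_class == "epithelial")
  n_outside <- 0L
  if (length(idx)) {
    lab <- working_labels(map)
    mpp <- map$mpp
    nr <- nrow(lab); nc <- ncol(lab)
    r_um <- cfg$iel_dilation_um
    rpix <- ceiling(r_um / mpp) + 1L
    off <- expand.grid(dr = -rpix:rpix, dc = -rpix:rpix)
    tum <- TISSUE_CLASSES[["tumor_epithelium"]]
    nor <- TISSUE_CLASSES[["normal_epithelium"]]
    out <- character(length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      x <- cells$x_um[i]; y <- cells$y_um[i]
      c0 <- floor(x / mpp) + 1L
      r0 <- floor(y / mpp) + 1L
      if (r0 < 1L - rpix || r0 > nr + rpix || c0 < 1L - rpix ||
          c0 > nc + rpix) {
        n_outside <- n_outside + 1L
        out[k] <- "other"
        next
      }
      rr <- r0 + off$dr; cc <- c0 + off$dc
      keep <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      rr <- rr[keep]; cc <- cc[keep]
      px <- (cc - 0.5) * mpp; py <- (rr - 0.5) * mpp
      d2 <- (px - x)^2 + (py - y)^2
      inside <- d2 <= r_um^2
      if (!any(inside)) { out[k] <- "other"; next }
      cls <- lab[cbind(rr[inside], cc[inside])]
      tabulated <- table(cls)
      top <- as.integer(names(tabulated)[tabulated == max(tabulated)])
      ctx <- if (length(top) == 1L) top else {
        dd <- d2[inside]
        cand <- which(cls %in% top)
        cls[cand[which.min(dd[cand])]]
      }
      out[k] <- if (ctx == tum) "tumor_epithelial"
        else if (ctx == nor) "normal_epithelial" else "other"
    }
    cells$derived_class[idx] <- out
  }
  if (n_outside)
    warning(n_outside, " epithelial nuclei outside the tissue-map extent ",
            "were classified 'other'", call. = FALSE)
  attr(cells, "n_outside") <- n_outside
  cells
}
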