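#' Pipeline configuration
#'
#' Bundles every tunable constant of the spatial immune-scoring pipeline.
#' Defaults reproduce the standard analysis: unique immune-cell counting in a
#' 200 micrometre radius around tumor cells, distance profiles in 10
#' micrometre bins up to 500, a 1000 micrometre-diameter invasive-front band
#' (half-width 500), the 25/12.5 micrometre epithelial dilation/subtraction
#' radii, 20 micrometre radius linkage for lymphocyte clustering with the
#' strictly exclusive >500 (aggregate) and >50000 (lymph node) component
#' thresholds, 5th/95th stage-II percentile min-max normalization, and a
#' 60-month follow-up cutoff for time to recurrence.
#'
#' @param count_radius_um radius (micrometres) for the unique-count region
#'   scores.
#' @param max_profile_radius_um outer limit of the distance profile.
#' @param profile_bin_um width of one profile distance bin; must divide
#'   `max_profile_radius_um` evenly.
#' @param front_band_halfwidth_um half-width of the invasive-front band:
#'   tumor cells within this distance of the front line are "front".
#' @param iel_dilation_um dilation radius around tumor epithelial cells
#'   defining the intraepithelial region.
#' @param connective_dilation_um dilation radius around connective cells
#'   subtracted from the intraepithelial region.
#' @param cluster_link_radius_um linkage radius for lymphocyte clustering.
#' @param aggregate_min_cells exclusive component-size threshold above which
#'   a lymphocyte cluster is a lymphoid aggregate.
#' @param lymphnode_min_cells exclusive threshold above which a cluster is a
#'   lymph node.
#' @param norm_lo_percentile,norm_hi_percentile stage-II percentiles used as
#'   minimum/maximum for per-cohort min-max scaling (in percent).
#' @param followup_cutoff_months follow-up cutoff; later events are censored.
#' @param adjacency_radius_um radius within which an intraepithelial
#'   lymphocyte counts as adjacent to a tumor cell for the IEL ratio. The
#'   epithelial dilation radius is reused by default.
#' @param min_front_length_um minimum length of a surviving front polyline
#'   fragment; shorter fragments are discarded as spurious.
#' @param area_scanline_step_um integration step for region-area computation.
#' @param rng_seed integer seed recorded in run manifests.
#' @return An object of class `pipeline_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$count_radius_um
#' @export
pipeline_config <- function(count_radius_um = 200,
                            max_profile_radius_um = 500,
                            profile_bin_um = 10,
                            front_band_halfwidth_um = 500,
                            iel_dilation_um = 25,
                            connective_dilation_um = 12.5,
                            cluster_link_radius_um = 20,
                            aggregate_min_cells = 500,
                            lymphnode_min_cells = 50000,
                            norm_lo_percentile = 5,
                            norm_hi_percentile = 95,
                            followup_cutoff_months = 60,
                            adjacency_radius_um = 25,
                            min_front_length_um = 500,
                            area_scanline_step_um = 0.05,
                            rng_seed = 1L) {
  cfg <- list(
    count_radius_um = count_radius_um,
    max_profile_radius_um = max_profile_radius_um,
    profile_bin_um = profile_bin_um,
    front_band_halfwidth_um = front_band_halfwidth_um,
    iel_dilation_um = iel_dilation_um,
    connective_dilation_um = connective_dilation_um,
    cluster_link_radius_um = cluster_link_radius_um,
    aggregate_min_cells = aggregate_min_cells,
    lymphnode_min_cells = lymphnode_min_cells,
    norm_lo_percentile = norm_lo_percentile,
    norm_hi_percentile = norm_hi_percentile,
    followup_cutoff_months = followup_cutoff_months,
    adjacency_radius_um = adjacency_radius_um,
    min_front_length_um = min_front_length_um,
    area_scanline_step_um = area_scanline_step_um,
    rng_seed = as.integer(rng_seed)
  )
  lengths <- c("count_radius_um", "max_profile_radius_um", "profile_bin_um",
               "front_band_halfwidth_um", "iel_dilation_um",
               "connective_dilation_um", "cluster_link_radius_um",
               "followup_cutoff_months", "adjacency_radius_um",
               "area_scanline_step_um")
  for (nm in lengths) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
  }
  nbins <- cfg$max_profile_radius_um / cfg$profile_bin_um
  if (abs(nbins - round(nbins)) > 1e-9)
    stop("'profile_bin_um' must divide 'max_profile_radius_um' evenly",
         call. = FALSE)
  if (cfg$aggregate_min_cells >= cfg$lymphnode_min_cells)
    stop("'aggregate_min_cells' must be below 'lymphnode_min_cells'",
         call. = FALSE)
  if (cfg$norm_lo_percentile >= cfg$norm_hi_percentile)
    stop("'norm_lo_percentile' must be below 'norm_hi_percentile'",
         call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_config <- function(cfg) {
  if (is.null(cfg)) return(pipeline_config())
  if (inherits(cfg, "pipeline_config")) return(cfg)
  if (is.list(cfg)) return(do.call(pipeline_config, cfg))
  stop("'cfg' must be a pipeline_config or a named list", call. = FALSE)
}
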