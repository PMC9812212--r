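#' Read a run configuration from YAML
#'
#' A run configuration bundles the detector geometry, rotation series and
#' crystal orientation of a simulation:
#'
#' ```yaml
#' detector:
#'   wavelength: 1.54
#'   distance: 45
#'   pixel_mm: 0.3
#'   raster: [487, 407]
#'   beam_center: [243, 203]
#' series:
#'   start: 0
#'   frame_width: 1
#'   substep: 0.1
#'   total_range: 180
#' orientation:              # optional, row-major 3x3; identity if absent
#'   - [1, 0, 0]
#'   - [0, 1, 0]
#'   - [0, 0, 1]
#' ```
#'
#' @param path YAML file.
#' @return list with `detector` ([detector_geometry()]), `series`
#'   ([rotation_series()]) and `orientation` ([orientation_matrix()]).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$detector) || is.null(cfg$series))
    stop("read_run_config: need `detector` and `series` sections")
  d <- cfg$detector
  geom <- detector_geometry(
    wavelength = d$wavelength, distance = d$distance, pixel_mm = d$pixel_mm,
    raster = unlist(d$raster),
    beam_center = if (is.null(d$beam_center)) (unlist(d$raster) - 1) / 2
                  else unlist(d$beam_center))
  s <- cfg$series
  series <- rotation_series(
    start = if (is.null(s$start)) 0 else s$start,
    frame_width = s$frame_width, substep = s$substep,
    total_range = s$total_range)
  ori <- if (is.null(cfg$orientation)) orientation_matrix()
         else orientation_matrix(do.call(rbind, cfg$orientation))
  list(detector = geom, series = series, orientation = ori)
}
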