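#' Scan simulation configuration
#'
#' Parameters of the line-scan SMLM simulator. The artificial space is a
#' sub-lattice of `s_px * s_im` cells per side; the scanner rasterizes it in
#' horizontal lines of height `s_px` (one camera-pixel row), advancing the
#' clock by `dt_line_ms` per line. Emitters appear with Poisson rate
#' `lambda_on` per line, wait through a Poisson-distributed switch-ON
#' countdown, stay ON for a Poisson-distributed lifetime and are rendered
#' only in lines scanned while they are ON -- producing the top/bottom
#' truncated Airy patterns characteristic of line-scanned dSTORM.
#'
#' @param s_px sub-lattice cells per camera pixel (100 gives 1 nm cells at a
#'   100 nm pixel).
#' @param s_im image size in camera pixels.
#' @param pixel_size_nm physical pixel size in nm.
#' @param dt_line_ms time step per scanned line (ms).
#' @param lambda_on Poisson rate of new emitters per line. The default gives
#'   on average 2-3 emitters in the ON state inside a 9x9 field.
#' @param mean_lifetime,mean_countdown Poisson means (ms) of the ON lifetime
#'   and the switch-ON countdown.
#' @param photon_range integer range the per-emitter base brightness is drawn
#'   from (detector units).
#' @param photon_sigma_frac per-frame brightness jitter as a fraction of the
#'   base brightness.
#' @param airy_radius_range range of the Airy first-zero radius, in
#'   sub-lattice units.
#' @param noise_sigma_range range of the Gaussian read-noise standard
#'   deviation (detector units).
#' @param min_on_fraction minimum fraction of an emitter's ON lines that must
#'   be captured by the scanner for the emitter to count as ground truth.
#' @param shot_noise,read_noise toggles for the two noise stages.
#' @param kernel_window_zeros extent of the rendered PSF window, in units of
#'   the Airy first-zero radius.
#' @param seed RNG seed used by the simulation entry points.
#' @return a `scan_config` list.
#' @export
scan_config <- function(s_px = 100L, s_im = 9L, pixel_size_nm = 100,
                        dt_line_ms = 6, lambda_on = 0.17,
                        mean_lifetime = 90, mean_countdown = 90,
                        photon_range = c(800L, 1500L),
                        photon_sigma_frac = 0.2,
                        airy_radius_range = c(525, 555),
                        noise_sigma_range = c(175, 185),
                        min_on_fraction = 0.4,
                        shot_noise = TRUE, read_noise = TRUE,
                        kernel_window_zeros = 2.2,
                        seed = 1L) {
  cfg <- list(s_px = as.integer(s_px), s_im = as.integer(s_im),
              pixel_size_nm = pixel_size_nm, dt_line_ms = dt_line_ms,
              lambda_on = lambda_on, mean_lifetime = mean_lifetime,
              mean_countdown = mean_countdown,
              photon_range = as.integer(photon_range),
              photon_sigma_frac = photon_sigma_frac,
              airy_radius_range = airy_radius_range,
              noise_sigma_range = noise_sigma_range,
              min_on_fraction = min_on_fraction,
              shot_noise = isTRUE(shot_noise), read_noise = isTRUE(read_noise),
              kernel_window_zeros = kernel_window_zeros,
              seed = as.integer(seed))
  class(cfg) <- "scan_config"
  validate_scan_config(cfg)
  cfg
}

validate_scan_config <- function(cfg) {
  stopifnot(cfg$s_px >= 1L, cfg$s_im >= 9L,
            cfg$photon_range[1] < cfg$photon_range[2],
            cfg$min_on_fraction > 0, cfg$min_on_fraction <= 1,
            cfg$lambda_on >= 0, cfg$mean_lifetime > 0,
            cfg$mean_countdown > 0, cfg$dt_line_ms > 0,
            cfg$airy_radius_range[1] > 0,
            diff(cfg$airy_radius_range) >= 0,
            diff(cfg$noise_sigma_range) >= 0)
  invisible(cfg)
}

#' Read / write a scan configuration as YAML
#'
#' Field names in the YAML file mirror the arguments of [scan_config()].
#'
#' @param path file path.
#' @param cfg a `scan_config`.
#' @return `read_scan_config` returns a `scan_config`.
#' @export
read_scan_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(scan_config, vals)
}

#' @rdname read_scan_config
#' @export
write_scan_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
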