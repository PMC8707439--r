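# Packing generation by particle growth, packing-fraction bookkeeping and
# plain-text snapshot I/O.

#' Control settings for the packing generator
#'
#' @param grow_rate Multiplicative radius inflation per growth step.
#' @param relax_cap Relaxation step cap per growth increment.
#' @param final_cap Relaxation step cap for the final (full-size) stage.
#' @param mean_overlap_tol Required residual mean contact overlap divided
#'   by the mean radius after final relaxation.
#' @return A list of class `mcdem_pack_control`.
#' @export
pack_control <- function(grow_rate = 1.02, relax_cap = 400,
                         final_cap = 40000, mean_overlap_tol = 1e-3) {
  structure(list(grow_rate = grow_rate, relax_cap = relax_cap,
                 final_cap = final_cap, mean_overlap_tol = mean_overlap_tol),
            class = "mcdem_pack_control")
}

#' Generate a random packing by particle growth
#'
#' Radii are sampled from the fitted size distribution until their total
#' volume meets `target_fraction` of the box volume (then rescaled by a
#' factor <= 1 so the final solid fraction is exact), seeded without
#' overlap at reduced size at random positions, and inflated in small
#' multiplicative steps with interleaved overlap relaxation (friction
#' off, strong damping) until full size — so the relative radii, and
#' hence the PSD shape, are preserved throughout growth. The box is
#' periodic in x and y and bounded by flat plates at the z faces; gravity
#' is off. Velocities are zeroed on return, giving a quasi-stress-free
#' initial state.
#'
#' @param box Box edge length (m), or a 3-vector `(Lx, Ly, Lz)`.
#' @param fit An [fit_psd()] result (or an [psd_spec()], fitted on the fly).
#' @param target_fraction Solid fraction to reach, in (0, 0.64).
#' @param material [material_params()] for the particles.
#' @param seed Optional integer; `set.seed()` is called when given, and
#'   identical seeds give bitwise-identical packings.
#' @param control [pack_control()] settings.
#' @return An object of class `mcdem_packing`: `radius`, `position`
#'   (n x 3), `box = c(Lx, Ly)`, `z_lo`, `z_hi`, `material`, `fraction`,
#'   `fraction_history` (per growth step), `n`.
#' @export
generate_packing <- function(box, fit, target_fraction = 0.59, material,
                             seed = NULL, control = pack_control()) {
  if (inherits(fit, "mcdem_psd")) fit <- fit_psd(fit)
  stopifnot(inherits(fit, "mcdem_psd_fit"),
            inherits(material, "mcdem_material"))
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(length(box) == 3, all(box > 0))
  if (target_fraction <= 0 || target_fraction >= 0.64)
    stop("target_fraction must lie in (0, 0.64): random close packing bounds the growth method")
  if (!is.null(seed)) set.seed(seed)

  vbox <- prod(box)
  rad <- sample_radii(fit, target_volume = target_fraction * vbox)
  dmax <- 2 * max(rad)
  if (dmax >= 0.95 * min(box))
    stop("largest sampled particle does not fit the box")
  if (min(box) < 4 * dmax)
    warning("box edge < 4 x largest particle diameter; ",
            "the packing may not be statistically representative")
  # the sampler overshoots the target volume by part of one particle;
  # drop the last particle when that lands closer to the target
  vtgt <- target_fraction * vbox
  v <- 4 / 3 * pi * rad^3
  if (length(rad) > 1 &&
      (sum(v) - vtgt) > (vtgt - (sum(v) - v[length(v)])))
    rad <- rad[-length(rad)]
  # fine adjustment so the terminal solid fraction is exact; a large
  # correction would distort the PSD, meaning the box holds too few
  # particles to meet the fraction at this granularity
  fscale <- (vtgt / sum(4 / 3 * pi * rad^3))^(1 / 3)
  if (abs(fscale - 1) > 0.05)
    stop("particle volume granularity too coarse to meet the target ",
         "fraction in this box; use a larger box or a finer distribution")
  rad <- rad * fscale

  res <- cpp_pack(rad, box[1], box[2], 0, box[3],
                  unclass(material), unclass(control))
  if (!isTRUE(res$converged)) {
    ach <- if (length(res$fraction_history)) max(res$fraction_history) else 0
    stop(sprintf(paste0("packing generation failed (%s); achieved fraction ",
                        "%.3f of target %.3f"),
                 if (nzchar(res$reason)) res$reason else "relaxation cap",
                 ach, target_fraction))
  }
  structure(list(
    radius = as.numeric(res$radius), position = res$position,
    box = box[1:2], z_lo = 0, z_hi = box[3],
    material = material, fraction = res$fraction,
    fraction_history = as.numeric(res$fraction_history),
    mean_overlap_ratio = res$mean_overlap_ratio,
    n = length(res$radius)
  ), class = "mcdem_packing")
}

#' Solid packing fraction of a particle bed
#'
#' Total sphere volume over the bed volume
#' `Lx * Ly * (z_top - z_bottom)`. Overlap volume is not subtracted
#' (after relaxation residual overlaps are below 1e-3 of a radius, the
#' standard DEM bookkeeping).
#'
#' @param p An `mcdem_packing` (or any list with `radius`, `box`, `z_lo`,
#'   `z_hi`).
#' @return Dimensionless solid fraction.
#' @export
packing_fraction <- function(p) {
  gap <- p$z_hi - p$z_lo
  if (gap <= 0) stop("plate gap must be > 0")
  sum(4 / 3 * pi * p$radius^3) / (p$box[1] * p$box[2] * gap)
}

#' @export
print.mcdem_packing <- function(x, ...) {
  cat(sprintf("<mcdem_packing> %d particles, box %.3g x %.3g x %.3g mm, fraction %.3f\n",
              x$n, x$box[1] * 1e3, x$box[2] * 1e3, (x$z_hi - x$z_lo) * 1e3,
              packing_fraction(x)))
  invisible(x)
}

#' Write / read a packing snapshot as columnar text
#'
#' The format is a `#`-prefixed metadata header (box dimensions, plate
#' positions) followed by whitespace-separated columns
#' `id radius x y z`, written at full double precision so a round trip
#' is lossless.
#'
#' @param p An `mcdem_packing`.
#' @param file Path to write to / read from.
#' @return `write_packing` returns `file` invisibly; `read_packing`
#'   returns an `mcdem_packing` (without material attached).
#' @export
write_packing <- function(p, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# mcdem packing snapshot"),
    sprintf("# box %.17g %.17g", p$box[1], p$box[2]),
    sprintf("# plates %.17g %.17g", p$z_lo, p$z_hi),
    "# columns: id radius x y z"), con)
  df <- data.frame(id = seq_along(p$radius), radius = p$radius,
                   x = p$position[, 1], y = p$position[, 2],
                   z = p$position[, 3])
  write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_packing
#' @export
read_packing <- function(file) {
  hdr <- readLines(file, n = 4)
  box <- as.numeric(strsplit(sub("^# box ", "", hdr[2]), " ")[[1]])
  plates <- as.numeric(strsplit(sub("^# plates ", "", hdr[3]), " ")[[1]])
  df <- read.table(file, comment.char = "#")
  names(df) <- c("id", "radius", "x", "y", "z")
  structure(list(
    radius = df$radius,
    position = as.matrix(df[, c("x", "y", "z")]),
    box = box, z_lo = plates[1], z_hi = plates[2],
    material = NULL, fraction = NA_real_,
    n = nrow(df)
  ), class = "mcdem_packing")
}
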