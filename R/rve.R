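# Representative-volume-element size series: regenerate a packing per box
# size at fixed PSD and solid fraction, compact each with the same
# protocol, and quantify mutual consistency of the responses.

#' Run an RVE size series
#'
#' One packing and one compaction per box size, identical PSD, target
#' fraction and loading protocol throughout (a fresh packing is generated
#' per size; seeds are derived from `seed` so members are independent but
#' reproducible). The deviation metric between two curves is the
#' coefficient of determination of one against the other on the common
#' loading leg; a size is declared representative when its curve reaches
#' `r2_threshold` against the largest box.
#'
#' @param sizes Strictly increasing box edge lengths (m), at least 2.
#' @param fit [fit_psd()] result (or [psd_spec()]).
#' @param material [material_params()].
#' @param params [contact_model_params()].
#' @param protocol [loading_protocol()].
#' @param target_fraction Solid fraction for every member.
#' @param seed Base seed.
#' @param control [sim_control()] shared by all members.
#' @param pack_ctl [pack_control()].
#' @param r2_threshold Consistency threshold (default 0.95).
#' @return An object of class `mcdem_rve_series`: `sizes`, `curves`
#'   (list), `n_particles`, `r2_vs_largest`, `pairwise_r2` (matrix),
#'   `representative` (logical), `failed` (logical, per member).
#' @export
run_rve_series <- function(sizes, fit, material, params, protocol,
                           target_fraction = 0.59, seed = 1,
                           control = sim_control(), pack_ctl = pack_control(),
                           r2_threshold = 0.95) {
  stopifnot(length(sizes) >= 2, all(diff(sizes) > 0))
  if (inherits(fit, "mcdem_psd")) fit <- fit_psd(fit)
  ns <- length(sizes)
  curves <- vector("list", ns)
  npart <- integer(ns)
  failed <- logical(ns)
  for (k in seq_len(ns)) {
    res <- tryCatch({
      pk <- generate_packing(sizes[k], fit, target_fraction, material,
                             seed = seed + k, control = pack_ctl)
      npart[k] <- pk$n
      run_uniaxial(pk, params, protocol, control)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[k] <- TRUE
      warning("RVE member ", k, " failed: ", conditionMessage(res))
    } else curves[[k]] <- res$curve
  }
  ok <- which(!failed)
  pair <- matrix(NA_real_, ns, ns,
                 dimnames = list(paste0("L", sizes), paste0("L", sizes)))
  for (a in ok) for (b in ok) {
    pair[a, b] <- if (a == b) 1 else
      suppressWarnings(r_squared(curves[[b]], curves[[a]]))
  }
  largest <- max(ok)
  r2v <- pair[, largest]
  structure(list(
    sizes = sizes, curves = curves, n_particles = npart,
    r2_vs_largest = r2v, pairwise_r2 = pair,
    representative = !is.na(r2v) & r2v >= r2_threshold,
    failed = failed
  ), class = "mcdem_rve_series")
}

#' @export
print.mcdem_rve_series <- function(x, ...) {
  cat("<mcdem_rve_series>\n")
  print(data.frame(size_mm = x$sizes * 1e3, n = x$n_particles,
                   r2_vs_largest = round(x$r2_vs_largest, 4),
                   representative = x$representative))
  invisible(x)
}
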