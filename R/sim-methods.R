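#' @export
print.gi_sim <- function(x, ...) {
  cat("Quasi-1D antroduodenal digestion run\n")
  cat(sprintf("  scenario %d, T = %g s, %d cells (dx = %g mm), %d substeps\n",
              x$scenario$id, x$T, x$geom$n, x$geom$dx * 1000, x$substeps))
  cat(sprintf("  particle density %g kg/m^3; functionality: acid F21 = %g, alkaline F(3..5)1 = %g\n",
              x$scenario$particle_density, x$scenario$F["2", "secretion"],
              x$scenario$F["3", "secretion"]))
  last <- x$series[nrow(x$series), ]
  cat(sprintf("  final stomach pH (volume mean / min): %.2f / %.2f\n",
              last$ph_stomach_mean, last$ph_stomach_min))
  cat(sprintf("  final duodenal pH (volume mean / min): %.2f / %.2f\n",
              last$ph_duodenum_mean, last$ph_duodenum_min))
  cat("  particle bin mass change (dissolution + cascade, % of initial):\n")
  pc <- x$phase_change_pct[2:6]
  cat(sprintf("    j=%d (%.1f mm): %+.2f%%\n", 2:6,
              x$config$particle$diameters * 1000, pc), sep = "")
  ev <- x$ledgers$evac_phase[2:6] / x$init_phase_mass[2:6] * 100
  cat(sprintf("  evacuated into the bowel (%% of initial bin mass): j6 %.1f%%, j5 %.1f%%\n",
              ev[5], ev[4]))
  cat(sprintf("  global mass closure error: %.2e (relative)\n", x$closure))
  invisible(x)
}

#' @export
summary.gi_sim <- function(object, ...) {
  out <- list(
    scenario = object$scenario$id,
    T = object$T,
    phase_table = data.frame(
      phase = 2:6,
      diameter_mm = object$config$particle$diameters * 1000,
      initial_mass_kg = object$init_phase_mass[2:6],
      change_pct = object$phase_change_pct[2:6],
      evacuated_pct = 100 * object$ledgers$evac_phase[2:6] /
        object$init_phase_mass[2:6]
    ),
    ph = unlist(object$series[nrow(object$series),
                              c("ph_stomach_mean", "ph_stomach_min",
                                "ph_duodenum_mean", "ph_duodenum_min")]),
    absorbed_kg = object$ledgers$absorbed,
    secreted_kg = sum(object$ledgers$secreted),
    closure = object$closure
  )
  class(out) <- "summary.gi_sim"
  out
}

#' @export
print.summary.gi_sim <- function(x, ...) {
  cat(sprintf("scenario %d, T = %g s\n", x$scenario, x$T))
  print(x$phase_table, row.names = FALSE, digits = 4)
  cat("pH:", paste(names(x$ph), sprintf("%.2f", x$ph), collapse = ", "), "\n")
  cat(sprintf("secreted %.3e kg, absorbed %.3e kg, closure %.1e\n",
              x$secreted_kg, x$absorbed_kg, x$closure))
  invisible(x)
}

#' Plot a digestion run
#'
#' Two panels: particle bin masses in the stomach over time, and the final
#' pH profile along the tract with the wall-region boundaries marked.
#'
#' @param x a `gi_sim`.
#' @param which subset of c("mass", "ph").
#' @param ... ignored.
#' @export
plot.gi_sim <- function(x, which = c("mass", "ph"), ...) {
  op <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if ("mass" %in% which) {
    m <- as.matrix(x$series[, paste0("stomach_p", 2:6)]) * 1000
    graphics::matplot(x$series$time, m, type = "l", lty = 1, lwd = 2,
                      xlab = "time (s)", ylab = "stomach bin mass (g)",
                      main = sprintf("scenario %d", x$scenario$id))
    graphics::legend("topright", sprintf("%.1f mm",
                                         x$config$particle$diameters * 1000),
                     col = 1:5, lty = 1, lwd = 2, cex = 0.8)
  }
  if ("ph" %in% which) {
    graphics::plot(x$geom$x * 100, x$final$ph, type = "l", lwd = 2,
                   xlab = "centerline position (cm)", ylab = "pH",
                   main = sprintf("pH profile at t = %g s", x$T))
    gx <- x$geom$xf[x$geom$gate_face] * 100
    graphics::abline(v = gx, lty = 2)
    graphics::mtext("pylorus", at = gx, side = 3, cex = 0.7)
  }
  invisible(x)
}

#' Write run outputs as plain-text tables
#'
#' Writes `series.csv` (the recorded time series), `ph_profiles.csv`
#' (per-cell pH snapshots), `summary.txt`, the configuration (`config.yaml`)
#' and the geometry table (`geometry.tsv`) into a directory.
#'
#' @param sim a `gi_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
gi_write_outputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$series, file.path(dir, "series.csv"),
                   row.names = FALSE)
  if (!is.null(sim$ph_profiles)) {
    utils::write.csv(as.data.frame(sim$ph_profiles),
                     file.path(dir, "ph_profiles.csv"), row.names = FALSE)
  }
  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con)
  print(summary(sim))
  sink()
  close(con)
  write_config(sim$config, file.path(dir, "config.yaml"))
  write_geometry(sim$geom, file.path(dir, "geometry.tsv"))
  invisible(dir)
}
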