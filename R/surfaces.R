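#' Barycentric grid over the lipid simplex
#'
#' All blends with denominators equal to `resolution`: `choose(resolution + 2,
#' 2)` points.
#'
#' @param resolution integer at least 2.
#' @return data frame with columns `cw`, `gb`, `gds`.
#' @export
barycentric_grid <- function(resolution) {
  if (resolution < 2) stop_config("resolution must be at least 2")
  .barycentric_grid(as.integer(resolution))
}

.slice_values <- function(object, cond) {
  if (inherits(object, "sln_fit") || inherits(object, "sln_desirability"))
    predict(object, cond)
  else stop_config("expected an sln_fit or an sln_desirability surface")
}

#' Ternary slice of a fitted model or desirability surface
#'
#' Evaluates predictions (or global desirability) on a barycentric grid over
#' the lipid simplex at one fixed process setting, the numeric content of an
#' isoresponse ternary plot.
#'
#' @param object an `sln_fit` or [desirability_surface()].
#' @param setting length-2 numeric: `p80_pct`, `us_time_min`.
#' @param resolution barycentric denominator (at least 2).
#' @return an `sln_ternary_grid` data frame with columns `cw`, `gb`, `gds`,
#'   `p80_pct`, `us_time_min`, `value`.
#' @export
ternary_slice <- function(object, setting, resolution = 60) {
  code_process(setting[[1]], setting[[2]]) # domain check
  blend <- barycentric_grid(resolution)
  cond <- data.frame(p80_pct = setting[[1]], us_time_min = setting[[2]],
                     cw = blend$cw, gb = blend$gb, gds = blend$gds)
  out <- cbind(blend, p80_pct = setting[[1]], us_time_min = setting[[2]],
               value = .slice_values(object, cond))
  structure(out, class = c("sln_ternary_grid", "data.frame"),
            resolution = as.integer(resolution))
}

#' Process-plane slice of a fitted model or desirability surface
#'
#' Evaluates predictions (or global desirability) on a uniform grid over the
#' surfactant-ratio and ultrasound-time box at one fixed lipid blend, the
#' numeric content of a process-plane surface plot.
#'
#' @param object an `sln_fit` or [desirability_surface()].
#' @param blend length-3 numeric lipid proportions `(cw, gb, gds)`.
#' @param resolution points per axis (recycled to length 2, each at least 2).
#' @return an `sln_process_grid`: list with `p80_pct`, `us_time_min` axis
#'   vectors, `blend`, and the `values` matrix (rows indexed by `p80_pct`).
#' @export
process_slice <- function(object, blend, resolution = 50) {
  blend <- as.numeric(blend)
  if (length(blend) != 3 || any(blend < 0) || abs(sum(blend) - 1) > 1e-9)
    stop_config("blend must be three non-negative proportions summing to 1")
  resolution <- rep_len(as.integer(resolution), 2)
  if (any(resolution < 2)) stop_config("resolution must be at least 2 per axis")
  p80s <- seq(0, 100, length.out = resolution[1])
  uss <- seq(1, 10, length.out = resolution[2])
  g <- expand.grid(p80_pct = p80s, us_time_min = uss, KEEP.OUT.ATTRS = FALSE)
  cond <- data.frame(g, cw = blend[1], gb = blend[2], gds = blend[3])
  vals <- matrix(.slice_values(object, cond), nrow = resolution[1],
                 dimnames = list(format(p80s, trim = TRUE),
                                 format(uss, trim = TRUE)))
  structure(list(p80_pct = p80s, us_time_min = uss, blend = blend,
                 values = vals),
            class = "sln_process_grid")
}

#' Export a slice grid to long-form CSV
#'
#' Columns `cw,gb,gds,p80_pct,us_time_min,value`.
#'
#' @param grid an `sln_ternary_grid` or `sln_process_grid`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  if (inherits(grid, "sln_ternary_grid")) {
    long <- as.data.frame(grid)[, c("cw", "gb", "gds", "p80_pct", "us_time_min", "value")]
  } else if (inherits(grid, "sln_process_grid")) {
    g <- expand.grid(p80_pct = grid$p80_pct, us_time_min = grid$us_time_min,
                     KEEP.OUT.ATTRS = FALSE)
    long <- data.frame(cw = grid$blend[1], gb = grid$blend[2], gds = grid$blend[3],
                       p80_pct = g$p80_pct, us_time_min = g$us_time_min,
                       value = as.vector(grid$values))
  } else stop_config("not a slice grid")
  utils::write.csv(long, path, quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @export
plot.sln_process_grid <- function(x, main = NULL, ...) {
  graphics::filled.contour(x$p80_pct, x$us_time_min, x$values,
                           xlab = "% polysorbate 80 in P80/SO",
                           ylab = "ultrasound time (min)",
                           main = main %||% sprintf("blend (%.2f, %.2f, %.2f)",
                                                    x$blend[1], x$blend[2], x$blend[3]),
                           ...)
  invisible(x)
}

#' @export
plot.sln_ternary_grid <- function(x, pch = 15, cex = 0.8, ...) {
  # equilateral projection: cw at the top vertex, gb lower-left, gds lower-right
  px <- x$gds + x$cw / 2
  py <- x$cw * sqrt(3) / 2
  pal <- grDevices::hcl.colors(64, "viridis")
  col <- pal[cut(x$value, 64, labels = FALSE, include.lowest = TRUE)]
  graphics::plot(px, py, col = col, pch = pch, cex = cex, asp = 1,
                 axes = FALSE, xlab = "", ylab = "", ...)
  graphics::polygon(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2))
  graphics::text(c(0.5, -0.03, 1.03), c(sqrt(3) / 2 + 0.04, -0.03, -0.03),
                 c("CW", "GB", "GDS"))
  invisible(x)
}
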