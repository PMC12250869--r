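# Derringer-Suich desirability: piecewise-linear ramps onto [0,1] per
# response, aggregated as a weighted geometric mean. Weights act only in the
# aggregation; the ramps themselves are linear (exponent 1).

#' Desirability specification for one response
#'
#' @param shape `"bilateral"` (target between min and max, zero outside),
#'   `"left_unilateral"` (larger is better: zero below min, one at and above
#'   target) or `"right_unilateral"` (smaller is better: one at and below
#'   target, zero at and above max).
#' @param min,max,target response-scale break points; only those the shape
#'   uses are required.
#' @param weight positive aggregation weight.
#' @return an `sln_dspec`.
#' @export
desirability_spec <- function(shape = c("bilateral", "left_unilateral", "right_unilateral"),
                              min = NULL, max = NULL, target = NULL, weight = 1) {
  shape <- match.arg(shape)
  need <- switch(shape, bilateral = c("min", "target", "max"),
                 left_unilateral = c("min", "target"),
                 right_unilateral = c("target", "max"))
  vals <- list(min = min, max = max, target = target)
  miss <- need[vapply(vals[need], is.null, TRUE)]
  if (length(miss)) stop_config(paste(shape, "spec needs", paste(miss, collapse = ", ")))
  ordered_ok <- switch(shape,
    bilateral = min < target && target < max,
    left_unilateral = min < target,
    right_unilateral = target < max)
  if (!ordered_ok) stop_config("desirability break points out of order")
  if (!is.numeric(weight) || weight <= 0) stop_config("weight must be positive")
  structure(list(shape = shape, min = min, max = max, target = target,
                 weight = weight), class = "sln_dspec")
}

#' The packaged study's desirability specifications
#'
#' Particle size: bilateral, 50/100/200 nm (a 100 nm target inside hard 50 and
#' 200 nm limits). PDI: smaller-is-better with target 0 and cutoff 0.4. Zeta
#' potential magnitude: larger-is-better, worthless below 25 mV, fully
#' desirable at and above 40 mV. All weights 1.
#'
#' @return named list of [desirability_spec()]s keyed by response column.
#' @export
sln_desirability_specs <- function() {
  list(ps_nm = desirability_spec("bilateral", min = 50, target = 100, max = 200),
       pdi = desirability_spec("right_unilateral", target = 0, max = 0.4),
       zp_abs_mv = desirability_spec("left_unilateral", min = 25, target = 40))
}

#' Partial desirability of response values
#'
#' @param y response values.
#' @param spec an `sln_dspec`.
#' @return desirabilities in \[0, 1\], same length as `y`.
#' @export
partial_desirability <- function(y, spec) {
  d <- switch(spec$shape,
    bilateral = pmin((y - spec$min) / (spec$target - spec$min),
                     (spec$max - y) / (spec$max - spec$target)),
    left_unilateral = (y - spec$min) / (spec$target - spec$min),
    right_unilateral = (spec$max - y) / (spec$max - spec$target))
  pmin(pmax(d, 0), 1)
}

#' Global desirability
#'
#' Weighted geometric mean `(prod d_i^w_i)^(1/sum w_i)`; zero whenever any
#' partial desirability is zero, and invariant under uniform scaling of the
#' weights.
#'
#' @param ds partial desirabilities in \[0, 1\]: a vector (one point) or a
#'   matrix with one column per response.
#' @param ws positive weights, one per response.
#' @return global desirability value(s).
#' @export
global_desirability <- function(ds, ws = NULL) {
  if (is.null(dim(ds))) ds <- matrix(ds, nrow = 1)
  if (is.null(ws)) ws <- rep(1, ncol(ds))
  if (length(ws) != ncol(ds)) stop_config("one weight per response is required")
  if (any(ws <= 0)) stop_config("weights must be positive")
  if (any(ds < 0 | ds > 1)) stop_config("partial desirabilities must lie in [0, 1]")
  # geometric mean via logs, with explicit zero-annihilation
  lg <- sweep(log(pmax(ds, .Machine$double.xmin)), 2, ws, `*`)
  out <- exp(rowSums(lg) / sum(ws))
  out[apply(ds == 0, 1, any)] <- 0
  drop(out)
}

#' Bundle fitted models and desirability specs into one surface
#'
#' The resulting object predicts global desirability at run conditions, for
#' grid slicing and optimization.
#'
#' @param fits named list of `sln_fit`s.
#' @param specs named list of `sln_dspec`s; names must match `fits`.
#' @return an `sln_desirability`.
#' @export
desirability_surface <- function(fits, specs) {
  if (!setequal(names(fits), names(specs)) || is.null(names(fits)))
    stop_config("fits and specs must be named lists over the same responses")
  specs <- specs[names(fits)]
  structure(list(fits = fits, specs = specs,
                 weights = vapply(specs, `[[`, 1, "weight")),
            class = "sln_desirability")
}

#' @export
predict.sln_desirability <- function(object, newdata, extrapolate = FALSE, ...) {
  pred <- vapply(object$fits, predict, numeric(nrow(newdata)),
                 newdata = newdata, extrapolate = extrapolate)
  pred <- matrix(pred, nrow = nrow(newdata), dimnames = list(NULL, names(object$fits)))
  ds <- vapply(names(object$fits),
               function(r) partial_desirability(pred[, r], object$specs[[r]]),
               numeric(nrow(newdata)))
  ds <- matrix(ds, nrow = nrow(newdata), dimnames = list(NULL, names(object$fits)))
  global_desirability(ds, object$weights)
}

# --- fast separable grid evaluation -----------------------------------------
# A crossed-model prediction over a (blend grid) x (process grid) product
# factorizes: group terms by their (x1, x2) exponent pattern, precompute the
# blend part of each group as one matrix, the process part as another, and
# take a single blends-by-process matrix product per response.

.blend_part <- function(terms, blend) {
  vapply(terms, function(e) {
    col <- rep(1, nrow(blend))
    for (k in which(e[3:5] > 0L)) col <- col * blend[[k]]^e[k + 2L]
    col
  }, numeric(nrow(blend)))
}

# precompute, per response, the blend-side matrix A (blends x exponent groups)
# and the process-exponent pattern of each group
.grid_engine <- function(surface, blend) {
  lapply(surface$fits, function(fit) {
    e12 <- vapply(fit$spec$terms, function(e) paste(e[1:2], collapse = ","), "")
    groups <- split(seq_along(e12), e12)
    A <- vapply(groups, function(idx) {
      Bg <- matrix(.blend_part(fit$spec$terms[idx], blend), nrow = nrow(blend))
      drop(Bg %*% fit$coeffs[idx])
    }, numeric(nrow(blend)))
    pat <- t(vapply(groups, function(idx) fit$spec$terms[[idx[1]]][1:2], numeric(2)))
    list(A = matrix(A, nrow = nrow(blend)), pat = pat, coding = fit$process_coding)
  })
}

.grid_predict_engine <- function(eng, proc) {
  xp <- .code_for(eng$coding)(proc$p80_pct, proc$us_time_min)
  P <- xp[, 1]^matrix(eng$pat[, 1], nrow(proc), nrow(eng$pat), byrow = TRUE) *
       xp[, 2]^matrix(eng$pat[, 2], nrow(proc), nrow(eng$pat), byrow = TRUE)
  eng$A %*% t(P) # blends x process points
}

.grid_desirability <- function(surface, engine, proc) {
  D <- NULL
  w <- surface$weights
  wsum <- sum(w)
  for (r in names(surface$fits)) {
    d <- partial_desirability(.grid_predict_engine(engine[[r]], proc),
                              surface$specs[[r]])
    term <- d^(w[[r]] / wsum) # 0^positive = 0: annihilation is automatic
    D <- if (is.null(D)) term else D * term
  }
  D
}

.barycentric_grid <- function(k) {
  ij <- expand.grid(i = 0:k, j = 0:k)
  ij <- ij[ij$i + ij$j <= k, , drop = FALSE]
  data.frame(cw = ij$i / k, gb = ij$j / k, gds = (k - ij$i - ij$j) / k)
}

# --- optimization ------------------------------------------------------------

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.project_simplex <- function(b) {
  b <- pmax(b, 0)
  s <- sum(b)
  if (s <= 0) rep(1 / 3, 3) else b / s
}

.point_desirability <- function(surface, cond) {
  predict(surface, cond, extrapolate = FALSE)
}

.refine_moves <- function(x, step) {
  # candidate neighbours of x = c(p80, us, cw, gb, gds) at the current step:
  # +/- moves on each process axis (relative step) and along each pairwise
  # simplex exchange direction, clamped to the domain
  out <- list()
  for (s in c(-1, 1)) {
    v <- x; v[1] <- .clamp(v[1] + s * step * 100, 0, 100); out <- c(out, list(v))
    v <- x; v[2] <- .clamp(v[2] + s * step * 9, 1, 10); out <- c(out, list(v))
    for (pr in list(c(3, 4), c(3, 5), c(4, 5))) {
      give <- if (s > 0) pr[2] else pr[1] # component the step is taken from
      d <- min(step, x[give])
      if (d <= 0) next
      v <- x
      v[pr] <- v[pr] + s * c(d, -d)
      v[3:5] <- .project_simplex(v[3:5])
      out <- c(out, list(v))
    }
  }
  out
}

.refine_point <- function(surface, start, step0, tol = 1e-4) {
  x <- start
  f <- function(v)
    .point_desirability(surface, data.frame(p80_pct = v[1], us_time_min = v[2],
                                            cw = v[3], gb = v[4], gds = v[5]))
  best <- f(x)
  step <- step0
  while (step >= tol) {
    improved <- FALSE
    for (cand in .refine_moves(x, step)) {
      val <- f(cand)
      if (val > best + 1e-15) {
        x <- cand
        best <- val
        improved <- TRUE
      }
    }
    if (!improved) step <- step / 2
  }
  list(x = x, d = best)
}

#' Maximize global desirability over the design domain
#'
#' Dense scan of the lipid simplex (barycentric step `grid_step`) crossed with
#' the process box (the same relative step on each axis), followed by
#' multi-start local refinement: projected coordinate descent from the best
#' grid cell plus `n_starts - 1` seeded jitters of the top grid cells, with
#' step halving down to `1e-4` relative. Deterministic given `seed` and
#' `grid_step`; never returns a point below the best grid value.
#'
#' @param fits named list of `sln_fit`s (one per response).
#' @param specs named list of [desirability_spec()]s over the same responses.
#' @param seed integer seed for the jittered starts.
#' @param grid_step relative grid step in (0, 0.25].
#' @param n_starts number of local starts.
#' @return an `sln_optimum`: `condition`, `global_d`, `partial_ds`,
#'   `predicted`, `feasible`, plus grid diagnostics. If the entire grid has
#'   zero desirability the result is flagged `feasible = FALSE`.
#' @examples
#' \donttest{
#' study <- design_runs(sln_runs())
#' fits <- lapply(c(ps_nm = "ps_nm", pdi = "pdi", zp_abs_mv = "zp_abs_mv"),
#'                function(r) fit_response(study, model_spec(), r))
#' opt <- optimize_desirability(fits, sln_desirability_specs(), grid_step = 0.05)
#' opt$condition
#' }
#' @export
optimize_desirability <- function(fits, specs, seed = 1, grid_step = 0.01,
                                  n_starts = 10) {
  if (!is.numeric(grid_step) || grid_step <= 0 || grid_step > 0.25)
    stop_config("grid_step must lie in (0, 0.25]")
  surface <- desirability_surface(fits, specs)
  k <- max(2L, round(1 / grid_step))
  blend <- .barycentric_grid(k)
  p80s <- seq(0, 100, length.out = k + 1)
  uss <- seq(1, 10, length.out = k + 1)
  proc <- expand.grid(p80_pct = p80s, us_time_min = uss, KEEP.OUT.ATTRS = FALSE)

  # chunked scan, keeping the top cells for refinement starts
  engine <- .grid_engine(surface, blend)
  top_vals <- numeric(0)
  top_cond <- NULL
  chunk <- max(1L, floor(4e6 / nrow(blend)))
  for (lo in seq(1, nrow(proc), by = chunk)) {
    hi <- min(lo + chunk - 1L, nrow(proc))
    pr <- proc[lo:hi, , drop = FALSE]
    D <- .grid_desirability(surface, engine, pr)
    ord <- order(D, decreasing = TRUE)[seq_len(min(n_starts, length(D)))]
    bi <- (ord - 1L) %% nrow(blend) + 1L
    pi <- (ord - 1L) %/% nrow(blend) + 1L
    cond <- cbind(pr[pi, , drop = FALSE], blend[bi, , drop = FALSE])
    top_vals <- c(top_vals, D[ord])
    top_cond <- rbind(top_cond, cond)
  }
  ord <- order(top_vals, decreasing = TRUE)[seq_len(min(n_starts, length(top_vals)))]
  top_vals <- top_vals[ord]
  top_cond <- top_cond[ord, , drop = FALSE]

  if (top_vals[1] <= 0) {
    return(structure(list(condition = top_cond[1, , drop = FALSE],
                          global_d = 0, partial_ds = NULL, predicted = NULL,
                          feasible = FALSE, grid_step = grid_step,
                          grid_best = 0, seed = seed),
                     class = "sln_optimum"))
  }

  keep <- .preserve_seed()
  on.exit(.restore_seed(keep))
  set.seed(as.integer(seed))
  best <- list(x = as.numeric(top_cond[1, c("p80_pct", "us_time_min", "cw", "gb", "gds")]),
               d = top_vals[1])
  for (s in seq_len(nrow(top_cond))) {
    x0 <- as.numeric(top_cond[s, c("p80_pct", "us_time_min", "cw", "gb", "gds")])
    if (s > 1) { # seeded jitter within half a grid cell; start 1 is exact
      x0[1] <- .clamp(x0[1] + stats::runif(1, -50, 50) * grid_step, 0, 100)
      x0[2] <- .clamp(x0[2] + stats::runif(1, -4.5, 4.5) * grid_step, 1, 10)
      x0[3:5] <- .project_simplex(x0[3:5] + stats::runif(3, -0.5, 0.5) * grid_step)
    }
    res <- .refine_point(surface, x0, step0 = grid_step)
    if (res$d > best$d) best <- res
  }

  cond <- data.frame(p80_pct = best$x[1], us_time_min = best$x[2],
                     cw = best$x[3], gb = best$x[4], gds = best$x[5])
  pred <- vapply(surface$fits, predict, numeric(1), newdata = cond)
  ds <- vapply(names(surface$fits),
               function(r) partial_desirability(pred[[r]], surface$specs[[r]]), 1)
  structure(list(condition = cond,
                 global_d = global_desirability(ds, surface$weights),
                 partial_ds = ds, predicted = pred, feasible = TRUE,
                 grid_step = grid_step, grid_best = top_vals[1], seed = seed),
            class = "sln_optimum")
}

#' @export
print.sln_optimum <- function(x, ...) {
  if (!x$feasible) {
    cat("<sln_optimum: no feasible region (desirability zero everywhere on the grid)>\n")
    return(invisible(x))
  }
  cat(sprintf("<sln_optimum: D = %.4f>\n", x$global_d))
  cat(sprintf("  p80 = %.2f%%  us = %.2f min  blend = (%.3f, %.3f, %.3f)\n",
              x$condition$p80_pct, x$condition$us_time_min,
              x$condition$cw, x$condition$gb, x$condition$gds))
  for (r in names(x$predicted))
    cat(sprintf("  %-10s predicted %.4g  d = %.3f\n", r, x$predicted[[r]], x$partial_ds[[r]]))
  invisible(x)
}
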