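# D-optimal subset selection by a greedy Fedorov-style exchange.

.logdet_xtx <- function(X) {
  d <- determinant(crossprod(X), logarithm = TRUE)
  if (d$sign <= 0) -Inf else as.numeric(d$modulus)
}

# one greedy pass from a random full-rank start: first improving swap in
# candidate order, log-scale relative threshold against float-noise cycling
.exchange_once <- function(X, n_runs, max_iter) {
  N <- nrow(X)
  p <- ncol(X)
  sel <- NULL
  for (draw in seq_len(100)) {
    cand <- sort(sample.int(N, n_runs))
    if (qr(X[cand, , drop = FALSE])$rank == p) { sel <- cand; break }
  }
  if (is.null(sel))
    stop_numeric("no full-rank starting subset found in 100 seeded draws")
  ld <- .logdet_xtx(X[sel, , drop = FALSE])
  iter <- 0L
  repeat {
    improved <- FALSE
    for (i in seq_along(sel)) {
      for (j in setdiff(seq_len(N), sel)) {
        trial <- sel
        trial[i] <- j
        ld_new <- .logdet_xtx(X[trial, , drop = FALSE])
        if (ld_new > ld + 1e-10 * max(1, abs(ld))) {
          sel <- trial
          ld <- ld_new
          improved <- TRUE
          iter <- iter + 1L
          break
        }
      }
      if (improved) break
    }
    if (!improved || iter >= max_iter) break
  }
  list(sel = sel, ld = ld)
}

#' D-optimal run selection by exchange
#'
#' Selects `n_runs` rows of a candidate set maximizing `det(X'X)` of the model
#' matrix: starting from a seeded random full-rank subset, repeatedly swaps an
#' in-design point for an out-of-design candidate whenever the swap increases
#' the determinant (first improving swap in candidate order, log-scale
#' relative improvement threshold `1e-10`), until a full pass finds no
#' improvement or `max_iter` accepted swaps.
#'
#' The returned design's log-determinant is never below the starting
#' subset's. Greedy exchange reaches the global optimum on well-separated
#' candidate sets but is not guaranteed to in general.
#'
#' @param candidates candidate run conditions.
#' @param spec a [model_spec()].
#' @param n_runs number of runs to select; at least the spec's term count.
#' @param seed integer seed for the starting subsets.
#' @param max_iter cap on accepted swaps per restart.
#' @param n_restarts independent seeded starts; the best final design wins.
#' @return an `sln_design` with attributes `logdet` (final log det(X'X)),
#'   `candidate_rows` (selected indices) and `seed`.
#' @export
d_optimal_exchange <- function(candidates, spec, n_runs, seed = 1, max_iter = 1000,
                               n_restarts = 5) {
  X <- model_matrix(candidates, spec)
  p <- ncol(X)
  N <- nrow(X)
  if (n_runs < p)
    stop_config(sprintf("n_runs (%d) below the '%s' term count (%d)", n_runs, spec$name, p))
  if (n_runs > N) stop_config("n_runs exceeds the candidate count")
  if (qr(X)$rank < p)
    stop_numeric("candidate set is rank-deficient for this model spec")

  if (n_runs == N) {
    sel <- seq_len(N)
  } else {
    keep <- .preserve_seed()
    on.exit(.restore_seed(keep))
    sel <- NULL
    best_ld <- -Inf
    for (restart in seq_len(n_restarts)) {
      set.seed(as.integer(seed) + restart - 1L)
      res <- .exchange_once(X, n_runs, max_iter)
      if (res$ld > best_ld + if (is.finite(best_ld)) 1e-10 * max(1, abs(best_ld)) else 0) {
        best_ld <- res$ld
        sel <- res$sel
      }
    }
    sel <- sort(sel)
  }

  out <- candidates[sel, , drop = FALSE]
  rownames(out) <- NULL
  structure(.as_study(out),
            class = c("sln_design", "sln_study", "data.frame"),
            provenance = "d_optimal", seed = seed,
            candidate_rows = sel,
            logdet = .logdet_xtx(X[sel, , drop = FALSE]))
}
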