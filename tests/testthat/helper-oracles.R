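# Independent oracles and small builders shared across tests.

# a model spec built directly from exponent vectors (the documented
# representation), for tiny instances the named specs do not cover
custom_spec <- function(terms, name = "custom") {
  terms <- lapply(terms, function(e) {
    v <- integer(5)
    names(v) <- c("x1", "x2", "x3", "x4", "x5")
    v[names(e)] <- e
    v
  })
  labels <- vapply(seq_along(terms), function(i) paste0("t", i), character(1))
  structure(list(name = name, terms = terms, labels = labels),
            class = "sln_model_spec")
}

# brute-force least squares by the normal equations (independent of the
# package's QR path)
ols_normal_equations <- function(X, y) {
  unname(drop(solve(crossprod(X), crossprod(X, y))))
}

# exhaustive D-optimal subset search
best_subset_logdet <- function(X, n_runs) {
  subsets <- utils::combn(nrow(X), n_runs)
  vals <- apply(subsets, 2, function(idx) {
    d <- determinant(crossprod(X[idx, , drop = FALSE]), logarithm = TRUE)
    if (d$sign <= 0) -Inf else as.numeric(d$modulus)
  })
  max(vals)
}

# random interior run conditions under a local seed
random_conditions <- function(n, seed) {
  set.seed(seed)
  b <- matrix(stats::rexp(3 * n), ncol = 3)
  b <- b / rowSums(b)
  data.frame(run_id = as.character(seq_len(n)),
             p80_pct = stats::runif(n, 0, 100),
             us_time_min = stats::runif(n, 1, 10),
             cw = b[, 1], gb = b[, 2], gds = b[, 3])
}

all_fits <- function(data = design_runs(sln_runs()), spec = model_spec()) {
  lapply(c(ps_nm = "ps_nm", pdi = "pdi", zp_abs_mv = "zp_abs_mv"),
         function(r) fit_response(data, spec, r))
}

table4_condition <- function() {
  data.frame(p80_pct = 40.8, us_time_min = 7.5, cw = 0.59, gb = 0.22, gds = 0.19)
}
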