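# Term representation: a 5-row integer exponent matrix over (x1, x2, x3, x4, x5),
# one column per monomial. x1, x2 are the coded process factors; x3, x4, x5 the
# raw lipid proportions cw, gb, gds. Scheffe-type specs carry no intercept and
# no pure process terms: both are absorbed by the mixture sum constraint.

.factor_names <- c("x1", "x2", "x3", "x4", "x5")

.term <- function(...) {
  e <- integer(5)
  names(e) <- .factor_names
  dots <- c(...)
  e[names(dots)] <- dots
  e
}

.term_label <- function(e) {
  if (!any(e > 0)) return("(Intercept)")
  parts <- mapply(function(f, k) {
    if (k == 0) "" else if (k == 1) f else paste0(f, "^", k)
  }, .factor_names, e)
  paste(parts[nzchar(parts)], collapse = ":")
}

.mix_monomials <- function(cubic = TRUE) {
  m <- list(.term(x3 = 1), .term(x4 = 1), .term(x5 = 1),
            .term(x3 = 1, x4 = 1), .term(x3 = 1, x5 = 1), .term(x4 = 1, x5 = 1))
  if (cubic) m <- c(m, list(.term(x3 = 1, x4 = 1, x5 = 1)))
  m
}

#' Response model specifications
#'
#' Three named term structures:
#' \describe{
#'   \item{`process_quadratic`}{full quadratic in the two coded process
#'     factors: intercept, x1, x2, x1^2, x2^2, x1 x2 (6 terms).}
#'   \item{`scheffe_reduced_cubic`}{reduced cubic Scheffe polynomial in the
#'     three lipid proportions: the three linear blending terms, three binary
#'     and one ternary nonlinear blending term (7 terms, no intercept).}
#'   \item{`multiplicative_deg3`}{the crossed mixture-process model, the
#'     Scheffe part multiplied into the process quadratic and truncated at
#'     degree-3 coefficients: the 7 Scheffe terms, the 6 degree-2 mixture
#'     monomials crossed with x1 and with x2, and the 3 linear blending terms
#'     crossed with x1^2, x2^2 and x1 x2 (28 terms, no intercept, every term
#'     contains a mixture factor).}
#' }
#'
#' @param name one of the three spec names.
#' @return an `sln_model_spec` with elements `name`, `terms` (list of exponent
#'   vectors) and `labels`.
#' @export
model_spec <- function(name = c("multiplicative_deg3", "scheffe_reduced_cubic",
                                "process_quadratic")) {
  name <- match.arg(name)
  terms <- switch(name,
    process_quadratic = list(
      .term(), .term(x1 = 1), .term(x2 = 1),
      .term(x1 = 2), .term(x2 = 2), .term(x1 = 1, x2 = 1)),
    scheffe_reduced_cubic = .mix_monomials(cubic = TRUE),
    multiplicative_deg3 = c(
      .mix_monomials(cubic = TRUE),
      lapply(.mix_monomials(cubic = FALSE), function(e) { e["x1"] <- 1L; e }),
      lapply(.mix_monomials(cubic = FALSE), function(e) { e["x2"] <- 1L; e }),
      lapply(.mix_monomials(cubic = FALSE)[1:3], function(e) { e["x1"] <- 2L; e }),
      lapply(.mix_monomials(cubic = FALSE)[1:3], function(e) { e["x2"] <- 2L; e }),
      lapply(.mix_monomials(cubic = FALSE)[1:3], function(e) { e["x1"] <- 1L; e["x2"] <- 1L; e })))
  structure(list(name = name, terms = terms,
                 labels = vapply(terms, .term_label, character(1))),
            class = "sln_model_spec")
}

#' @export
print.sln_model_spec <- function(x, ...) {
  cat(sprintf("<sln_model_spec '%s': %d terms>\n", x$name, length(x$terms)))
  cat(" ", paste(x$labels, collapse = " + "), "\n")
  invisible(x)
}

.code_for <- function(process_coding) {
  switch(process_coding,
         centered = function(p, u) cbind((p - 50) / 50, (u - 5.5) / 4.5),
         unit = function(p, u) cbind(p / 100, (u - 1) / 9),
         stop_config(paste("unknown process coding:", process_coding)))
}

#' Model matrix for a run set
#'
#' Expands run conditions into the numeric design matrix of a spec: entry
#' (i, j) is the product over factors of the coded/raw factor value raised to
#' the term's exponent. Process factors are coded before monomial evaluation;
#' mixture proportions enter raw.
#'
#' @param runs run conditions (design or study data frame).
#' @param spec a [model_spec()].
#' @param process_coding `"centered"` maps the process domains to \[-1, 1\]
#'   (the conventional coding); `"unit"` maps them to \[0, 1\]. Predictions
#'   from a fit are invariant to this choice.
#' @return numeric matrix, one column per term, labelled.
#' @export
model_matrix <- function(runs, spec, process_coding = "centered") {
  stopifnot(inherits(spec, "sln_model_spec"))
  xp <- .code_for(process_coding)(runs$p80_pct, runs$us_time_min)
  vals <- cbind(xp, runs$cw, runs$gb, runs$gds)
  X <- vapply(spec$terms, function(e) {
    col <- rep(1, nrow(vals))
    for (k in which(e > 0L)) col <- col * vals[, k]^e[k]
    col
  }, numeric(nrow(vals)))
  X <- matrix(X, nrow = nrow(vals), dimnames = list(NULL, spec$labels))
  X
}
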