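#' slnopt: mixture-process designed experiments for SLN formulation
#'
#' Crossed simplex-centroid x factorial designs, D-optimal exchange selection,
#' Scheffe-by-quadratic multiplicative response models, Derringer-Suich
#' desirability optimization, and isoresponse grid evaluation, built around a
#' packaged 66-run solid lipid nanoparticle (SLN) study.
#'
#' @section Factors:
#' Every run condition carries five factors: `p80_pct`, the percentage of
#' polysorbate 80 in the polysorbate 80 / sorbitan oleate surfactant couple
#' (0--100); `us_time_min`, ultrasound treatment time in minutes (1--10); and
#' the lipid blend proportions `cw` (carnauba wax), `gb` (glyceryl behenate)
#' and `gds` (glyceryl distearate), each in \[0, 1\] and summing to 1.
#'
#' @name slnopt-package
#' @keywords internal
"_PACKAGE"

# canonical column order of the run CSV dialect
.run_cols <- c("run_id", "p80_pct", "us_time_min", "cw", "gb", "gds")
.response_cols <- c("ps_nm", "pdi", "zp_abs_mv")
.study_cols <- c(.run_cols, .response_cols)

# md5 of the packaged fixture; a mismatch means the installation is corrupted
.fixture_md5 <- "7a5d7488ecc73d81339fc918b50d820a"

.domain <- list(p80_pct = c(0, 100), us_time_min = c(1, 10))

stop_config <- function(msg) stop(errorCondition(msg, class = c("sln_config_error", "error")))
stop_data <- function(msg) stop(errorCondition(msg, class = c("sln_data_error", "error")))
stop_numeric <- function(msg) stop(errorCondition(msg, class = c("sln_numeric_error", "error")))

#' Validate run conditions
#'
#' Checks that process factors lie inside their variation domains and that the
#' lipid proportions are a point of the 2-simplex (non-negative, summing to 1
#' within `tol`).
#'
#' @param x data frame with columns `p80_pct`, `us_time_min`, `cw`, `gb`, `gds`.
#' @param tol tolerance on the mixture sum constraint.
#' @return `x`, invisibly, after validation.
#' @export
validate_conditions <- function(x, tol = 1e-9) {
  need <- setdiff(.run_cols[-1], names(x))
  if (length(need)) stop_data(paste("missing condition columns:", paste(need, collapse = ", ")))
  if (any(x$p80_pct < 0 | x$p80_pct > 100))
    stop_data("p80_pct outside its 0-100 variation domain")
  if (any(x$us_time_min < 1 | x$us_time_min > 10))
    stop_data("us_time_min outside its 1-10 min variation domain")
  b <- as.matrix(x[, c("cw", "gb", "gds")])
  if (any(b < -tol)) stop_data("negative mixture proportion")
  if (any(abs(rowSums(b) - 1) > tol))
    stop_data("mixture proportions cw + gb + gds must sum to 1")
  invisible(x)
}

.validate_responses <- function(x) {
  if (!is.null(x$ps_nm) && any(x$ps_nm <= 0, na.rm = TRUE))
    stop_data("ps_nm must be positive where present")
  if (!is.null(x$pdi) && any(x$pdi < 0, na.rm = TRUE))
    stop_data("pdi must be non-negative where present")
  if (!is.null(x$zp_abs_mv) && any(x$zp_abs_mv < 0, na.rm = TRUE))
    stop_data("zp_abs_mv is a magnitude and must be non-negative where present")
  invisible(x)
}

.as_study <- function(x) {
  x <- as.data.frame(x)
  if (is.null(x$run_id)) x$run_id <- as.character(seq_len(nrow(x)))
  x <- x[, intersect(.study_cols, names(x)), drop = FALSE]
  x$run_id <- as.character(x$run_id)
  for (col in setdiff(.study_cols, c("run_id", setdiff(.study_cols, names(x)))))
    x[[col]] <- as.numeric(x[[col]])
  class(x) <- c("sln_study", "data.frame")
  x
}

#' The packaged 66-run SLN formulation study
#'
#' Loads the packaged dataset of 66 experimental points (a 63-run crossed
#' mixture-process design plus repeats of runs 51, 52 and 55, labelled
#' `"51r"`, `"52r"`, `"55r"`), with the measured responses: particle size
#' `ps_nm` (z-average, nm), polydispersity index `pdi`, and zeta potential
#' magnitude `zp_abs_mv` (mV; measured values are negative, stored in absolute
#' value).
#'
#' The lipid ternary centroid is stored at full precision (1/3 to 15 digits);
#' printed study tables round it to 0.33.
#'
#' @return an `sln_study` data frame with 66 rows.
#' @examples
#' study <- sln_runs()
#' nrow(study)                 # 66
#' nrow(design_runs(study))    # 63
#' @export
sln_runs <- function() {
  path <- system.file("extdata", "sln_runs.csv", package = "slnopt", mustWork = TRUE)
  if (!identical(unname(tools::md5sum(path)), .fixture_md5))
    stop_data("packaged study fixture is corrupted (checksum mismatch)")
  read_run_csv(path)
}

#' Read and write run tables in the package CSV dialect
#'
#' The dialect is comma-separated UTF-8 with decimal points and the fixed
#' header `run_id,p80_pct,us_time_min,cw,gb,gds,ps_nm,pdi,zp_abs_mv`; response
#' columns may be empty. Repeat runs are labelled by a trailing `r` on the run
#' id (a plain-file-safe encoding of a prime mark).
#'
#' @param path file path.
#' @param check validate factor domains and response signs on read.
#' @return `read_run_csv()`: an `sln_study` data frame. `write_run_csv()`:
#'   `path`, invisibly.
#' @export
read_run_csv <- function(path, check = TRUE) {
  if (is.null(path) || !file.exists(path))
    stop_data(paste("no such file:", path %||% "(none given)"))
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  if (!all(.run_cols %in% header))
    stop_data(paste("CSV header must contain", paste(.run_cols, collapse = ",")))
  x <- utils::read.csv(path, colClasses = c(run_id = "character"),
                       check.names = FALSE, fileEncoding = "UTF-8")
  x <- .as_study(x)
  if (check) {
    validate_conditions(x)
    .validate_responses(x)
  }
  x
}

#' @param x run table (`sln_study` or plain data frame in the dialect).
#' @rdname read_run_csv
#' @export
write_run_csv <- function(x, path) {
  x <- as.data.frame(x)
  for (col in setdiff(.study_cols, names(x))) x[[col]] <- NA_real_
  utils::write.csv(x[, .study_cols], path, quote = FALSE, row.names = FALSE,
                   eol = "\n", fileEncoding = "UTF-8", na = "")
  invisible(path)
}

.is_repeat_id <- function(run_id) grepl("(r|′)$", run_id)

#' Split a study into design runs and repeat runs
#'
#' Repeat runs (run id ending in `r` or a prime mark) duplicate the condition
#' of an existing design run; they estimate pure experimental error and are
#' excluded from the default model fit, mirroring how the packaged study was
#' analysed.
#'
#' @param study an `sln_study` data frame.
#' @return the subset of rows, same class.
#' @export
design_runs <- function(study) study[!.is_repeat_id(study$run_id), , drop = FALSE]

#' @rdname design_runs
#' @export
replicate_runs <- function(study) study[.is_repeat_id(study$run_id), , drop = FALSE]

#' Pairs of condition-identical runs
#'
#' @param study an `sln_study` data frame.
#' @return data frame with one row per condition replicated at least twice,
#'   columns `key` (condition fingerprint) and `n` (number of runs).
#' @export
replicate_pairs <- function(study) {
  key <- apply(signif(as.matrix(study[, .run_cols[-1]]), 10), 1, paste, collapse = "|")
  tab <- table(key)
  data.frame(key = names(tab)[tab >= 2], n = as.integer(tab[tab >= 2]),
             row.names = NULL)
}

#' Simulate responses from known model coefficients
#'
#' Stands in for wet-lab measurement: each response is the noise-free model
#' evaluation (model-matrix row times the true coefficients) plus independent
#' Gaussian error. The same seed always reproduces the same dataset; the
#' caller's RNG state is left untouched.
#'
#' @param design run conditions (design or study data frame).
#' @param spec a [model_spec()].
#' @param true_coeffs numeric vector (one response) or matrix with one column
#'   per response; rows must match the spec's terms.
#' @param noise_sd non-negative error standard deviation, recycled across
#'   responses.
#' @param seed integer seed.
#' @param responses response column names to fill; defaults to the coefficient
#'   matrix column names, else `ps_nm`, `pdi`, `zp_abs_mv`.
#' @return an `sln_study` data frame with simulated response columns.
#' @export
simulate_responses <- function(design, spec, true_coeffs, noise_sd = 0, seed = 1,
                               responses = NULL) {
  true_coeffs <- as.matrix(true_coeffs)
  if (nrow(true_coeffs) != length(spec$terms))
    stop_config(sprintf("true_coeffs has %d rows but the '%s' spec has %d terms",
                        nrow(true_coeffs), spec$name, length(spec$terms)))
  if (any(noise_sd < 0)) stop_config("noise_sd must be non-negative")
  if (is.null(responses))
    responses <- colnames(true_coeffs)
  if (is.null(responses))
    responses <- .response_cols[seq_len(ncol(true_coeffs))]
  noise_sd <- rep_len(noise_sd, ncol(true_coeffs))
  X <- model_matrix(design, spec)
  mu <- X %*% true_coeffs
  out <- .as_study(design)
  if (is.null(out$run_id)) out$run_id <- as.character(seq_len(nrow(out)))
  withr_seed <- .preserve_seed()
  on.exit(.restore_seed(withr_seed))
  set.seed(as.integer(seed))
  for (j in seq_along(responses))
    out[[responses[j]]] <- mu[, j] + stats::rnorm(nrow(mu), 0, noise_sd[j])
  .as_study(out)
}

.preserve_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
  invisible()
}
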