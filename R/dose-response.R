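#' Dose-response table of single-cell outputs
#'
#' The shared container for simulated and (synthetic-)experimental data:
#' a long-format data frame with one row per cell per dose.
#'
#' @param dose_nM Numeric vector of doses (nM), one per row.
#' @param cell_id Cell identifier within each dose.
#' @param output Single-cell output (reporter units).
#' @return A `dose_response_table` (data frame with columns
#'   `dose_nM`, `cell_id`, `output`).
#' @export
dose_response_table <- function(dose_nM, cell_id, output) {
  stopifnot(length(dose_nM) == length(output))
  if (missing(cell_id)) cell_id <- stats::ave(dose_nM, dose_nM, FUN = seq_along)
  d <- data.frame(dose_nM = dose_nM, cell_id = cell_id, output = output)
  if (any(d$dose_nM < 0)) stop("doses must be >= 0")
  class(d) <- c("dose_response_table", "data.frame")
  d
}

#' @rdname dose_response_table
#' @param res An `ensemble_result` from [run_ensemble()].
#' @param output Which endpoint column to use as the channel output.
#' @export
as_dose_response <- function(res, output = c("Rep_end", "Fpp_end")) {
  output <- match.arg(output)
  dose_response_table(res$cells$dose_nM, res$cells$cell_id,
                      res$cells[[output]])
}

#' Per-dose summary statistics
#'
#' @param table A `dose_response_table`.
#' @return Data frame with per-dose `n`, `mean`, `sd` (n-1 denominator)
#'   and `cv`, ordered by dose.
#' @export
summarize_doses <- function(table) {
  s <- do.call(rbind, lapply(split(table, table$dose_nM), function(d) {
    data.frame(dose_nM = d$dose_nM[1], n = nrow(d), mean = mean(d$output),
               sd = if (nrow(d) >= 2) stats::sd(d$output) else NA_real_)
  }))
  s <- s[order(s$dose_nM), ]
  s$cv <- noise_cv(s$mean, s$sd)
  rownames(s) <- NULL
  s
}

#' Total noise: coefficient of variation
#'
#' CV = sample standard deviation (n-1 denominator) divided by the mean.
#' Undefined (NA, with a warning) where the mean is not positive.
#'
#' @param mean,sd Per-dose mean and standard deviation, or a numeric vector
#'   of samples if `sd` is missing.
#' @return Numeric CV vector (or scalar for a sample vector).
#' @export
noise_cv <- function(mean, sd) {
  if (missing(sd)) {
    x <- mean
    return(noise_cv(base::mean(x), stats::sd(x)))
  }
  bad <- !is.na(mean) & mean <= 0
  if (any(bad)) warning("CV undefined for non-positive mean; returning NA")
  ifelse(mean > 0, sd / mean, NA_real_)
}

#' Read / write dose-response tables as delimited text
#'
#' @param file Path to a tab-separated file with header
#'   `dose_nM, cell_id, output`.
#' @return `read_dose_response()` returns a `dose_response_table`.
#' @export
read_dose_response <- function(file) {
  d <- utils::read.delim(file)
  need <- c("dose_nM", "cell_id", "output")
  if (!all(need %in% names(d)))
    stop("expected columns ", paste(need, collapse = ", "))
  dose_response_table(d$dose_nM, d$cell_id, d$output)
}

#' @rdname read_dose_response
#' @param table A `dose_response_table`.
#' @export
write_dose_response <- function(table, file) {
  utils::write.table(as.data.frame(table), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
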