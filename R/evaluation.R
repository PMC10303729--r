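# Validation statistics and experiment harnesses. Pearson's r is the sole
# correlation measure; degenerate (zero-variance) inputs yield an explicit
# "undefined" result rather than a silent NaN, so degenerate cohorts stay
# visible in reports.

#' Pearson correlation with explicit undefined status
#'
#' Sample Pearson correlation coefficient of two paired vectors. If either
#' vector has zero variance the correlation is undefined: the return value
#' is `NA` carrying attribute `undefined = TRUE` (test with
#' [is_undefined_r]), never a silent `NaN`.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return scalar r in \[-1,1\], or undefined-`NA`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y))
  if (length(x) < 2) stop("need n >= 2 for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, undefined = TRUE))
  stats::cor(x, y, method = "pearson")
}

#' @rdname pearson_r
#' @param r a value returned by [pearson_r].
#' @export
is_undefined_r <- function(r) isTRUE(attr(r, "undefined"))

#' Parameter-recovery report
#'
#' Compares estimated fractions against ground truth: root-mean-square
#' error, bias (mean signed error, estimate minus truth), Pearson r, and a
#' per-sample error table. A constant offset shows up as bias = rmse with
#' r = 1 -- the signature of systematic over-/under-estimation.
#'
#' @param truth,estimates paired numeric vectors (fraction %), n >= 2.
#' @return list of class `recovery_report`: `n`, `rmse`, `bias`,
#'   `pearson_r`, `table` (truth, estimate, error).
#' @export
recovery_report <- function(truth, estimates) {
  if (length(truth) != length(estimates))
    stop("length mismatch: ", length(truth), " vs ", length(estimates))
  if (length(truth) < 2) stop("need n >= 2")
  err <- estimates - truth
  structure(list(n = length(truth),
                 rmse = sqrt(mean(err^2)),
                 bias = mean(err),
                 pearson_r = pearson_r(truth, estimates),
                 table = data.frame(truth = truth, estimate = estimates,
                                    error = err)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  r <- if (is_undefined_r(x$pearson_r)) "undefined" else format(round(x$pearson_r, 4))
  cat("recovery_report: n =", x$n, " rmse =", format(round(x$rmse, 4)),
      " bias =", format(round(x$bias, 4)), " r =", r, "\n")
  invisible(x)
}

#' Total-vs-summed-fractions consistency check
#'
#' Compares, per sample, the calibration model's total HSPC estimate with
#' the sum of the NNLS-deconvolved progenitor subset fractions. Both are
#' estimates of the same quantity from different panels and models; their
#' agreement is the pipeline's internal consistency check.
#'
#' @param total_estimates named numeric vector (sample -> total fraction,
#'   %), e.g. the `predicted` column of [batch_predict].
#' @param subset_results list of `deconvolution_result`s, or a
#'   [batch_deconvolve] data.frame; fractions on the \[0,1\] scale are
#'   converted to % by `scale`.
#' @param progenitor_types cell types summed as "progenitors" (default
#'   HSC, LMPP, CMP).
#' @param scale multiplier applied to summed subset fractions to put them
#'   on the % scale of `total_estimates` (default 100: NNLS coefficients
#'   are per-unit fractions).
#' @return list of class `consistency_check`: `table` (sample_id, total,
#'   summed, difference), `max_abs_difference`, `pearson_r`.
#' @export
consistency_check <- function(total_estimates, subset_results,
                              progenitor_types = c("HSC", "LMPP", "CMP"),
                              scale = 100) {
  if (is.data.frame(subset_results)) {
    unknown <- setdiff(progenitor_types, names(subset_results))
    if (length(unknown)) stop("unknown cell type(s): ",
                              paste(unknown, collapse = ", "))
    summed <- stats::setNames(
      rowSums(subset_results[, progenitor_types, drop = FALSE]) * scale,
      subset_results$sample_id)
  } else {
    summed <- vapply(subset_results, function(r)
      sum_progenitor_fractions(r, progenitor_types) * scale, numeric(1))
    names(summed) <- vapply(subset_results, function(r) r$sample_id, character(1))
  }
  only_total <- setdiff(names(total_estimates), names(summed))
  only_sub <- setdiff(names(summed), names(total_estimates))
  if (length(only_total) || length(only_sub))
    stop("sample sets differ; only in totals: {",
         paste(only_total, collapse = ", "), "}, only in subsets: {",
         paste(only_sub, collapse = ", "), "}")
  ids <- names(total_estimates)
  tab <- data.frame(sample_id = ids,
                    total = unname(total_estimates[ids]),
                    summed = unname(summed[ids]),
                    difference = unname(summed[ids] - total_estimates[ids]),
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 max_abs_difference = max(abs(tab$difference)),
                 pearson_r = pearson_r(tab$total, tab$summed)),
            class = "consistency_check")
}

#' Correlate a panel CpG's methylation with a sample covariate
#'
#' Pearson correlation between a CpG's percent methylation and a per-sample
#' covariate (e.g. flow-cytometric CD34 counts, manual blast counts) over
#' all samples where both are present (complete-case pairing, no
#' imputation). Optionally reports the leave-one-out range of r, which
#' exposes correlations driven by a single leverage point.
#'
#' @param measurements a `measurement_table`.
#' @param cpg_id CpG to correlate.
#' @param covariate_name name of the covariate column.
#' @param loo also compute the leave-one-out r range (default `FALSE`).
#' @return list: `r` (possibly undefined, see [pearson_r]), `n`, and if
#'   requested `loo_range` (min/max r over single-sample deletions).
#' @export
correlate_with_covariate <- function(measurements, cpg_id, covariate_name,
                                     loo = FALSE) {
  if (!covariate_name %in% names(measurements))
    stop("covariate '", covariate_name, "' absent from measurement table")
  m <- measurements[measurements$cpg_id == cpg_id, , drop = FALSE]
  ok <- !is.na(m$percent_methylation) & !is.na(m[[covariate_name]])
  m <- m[ok, , drop = FALSE]
  if (nrow(m) < 2)
    stop("need >=2 samples with both CpG '", cpg_id, "' and covariate '",
         covariate_name, "'; got ", nrow(m))
  x <- m$percent_methylation
  y <- m[[covariate_name]]
  out <- list(r = pearson_r(x, y), n = nrow(m))
  if (loo && nrow(m) >= 3) {
    rs <- vapply(seq_len(nrow(m)), function(i) {
      r <- pearson_r(x[-i], y[-i])
      if (is_undefined_r(r)) NA_real_ else r
    }, numeric(1))
    out$loo_range <- range(rs, na.rm = TRUE)
  }
  out
}
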