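# Dilution-series calibration of the total-HSPC fraction.
#
# Graded mixtures of sorted CD34+ and CD34- cells with flow-cytometry-
# verified fractions serve as training data: the known CD34+ fraction (%)
# is regressed on the panel beta values by ordinary least squares with an
# intercept. Separate models per sample source (mPB vs CB) are first-class
# because panel methylation differs between adult mobilized and cord blood
# CD34+ cells; no cross-source correction is attempted.

#' Construct a dilution series
#'
#' Paired records of a known mixture fraction (CD34+ cells, %, as measured
#' by flow cytometry) and the measured panel beta values for that mixture.
#'
#' @param data data.frame with columns `sample_id`, `known_fraction`
#'   (0--100) and one numeric beta column (\[0,1\]) per panel CpG.
#' @param panel a `marker_panel`; every panel CpG must have a column.
#' @param source source label, e.g. `"mPB"` or `"CB"`.
#' @return object of class `dilution_series`.
#' @export
dilution_series <- function(data, panel, source = NA_character_) {
  cpgs <- panel_cpgs(panel)
  miss <- setdiff(cpgs, names(data))
  if (length(miss))
    stop("dilution data lacks panel CpG column(s): ", paste(miss, collapse = ", "))
  if (is.null(data$known_fraction)) stop("dilution data lacks known_fraction")
  kf <- data$known_fraction
  if (any(is.na(kf)) || any(kf < 0 | kf > 100))
    stop("known_fraction must be in [0,100] with no missing values")
  if (any(is.na(as.matrix(data[cpgs]))))
    stop("every dilution record must cover the full panel (missing beta found)")
  structure(list(data = as.data.frame(data), panel = panel, source = source),
            class = "dilution_series")
}

#' Fit the multivariable dilution model
#'
#' Ordinary least squares of the known mixture fraction (%) on the panel
#' beta values, with intercept: `fraction ~ b_0 + sum_j b_j beta_j`.
#' Deterministic; requires at least one more record than panel CpGs. A
#' constant beta column is an error (the slope is unidentifiable); an
#' exactly collinear design -- which every idealized noise-free
#' multi-CpG series produces, since each beta is then the same linear
#' function of the fraction -- falls back to the minimum-norm
#' least-squares solution with a warning, preserving the fitted values.
#'
#' @param series a [dilution_series].
#' @param panel optional panel override (default: the series' panel).
#' @return object of class `calibration_model` with fields `panel`,
#'   `intercept`, `coefficients` (named per CpG, in fraction-% per unit
#'   beta), `training_source` and `diagnostics` (r_squared, residual_sd, n).
#' @export
fit_dilution_model <- function(series, panel = series$panel) {
  cpgs <- panel_cpgs(panel)
  df <- series$data
  miss <- setdiff(cpgs, names(df))
  if (length(miss)) stop("series lacks panel CpG(s): ", paste(miss, collapse = ", "))
  n <- nrow(df)
  if (n < length(cpgs) + 1)
    stop("need at least ", length(cpgs) + 1, " dilution records for a ",
         length(cpgs), "-CpG panel; got ", n)
  X <- cbind(`(Intercept)` = 1, as.matrix(df[cpgs]))
  y <- df$known_fraction
  const <- cpgs[apply(df[cpgs], 2, function(v) stats::sd(v) == 0)]
  if (length(const))
    stop("rank-deficient design: constant beta column(s): ",
         paste(const, collapse = ", "))
  qrX <- qr(X)
  rank_deficient <- qrX$rank < ncol(X)
  if (rank_deficient) {
    # exactly collinear CpGs (e.g. an idealized noise-free series, where
    # every panel beta is the same linear function of the fraction): take
    # the minimum-norm least-squares solution, which still reproduces the
    # fitted values, and say so
    warning("collinear panel design (rank ", qrX$rank, " of ", ncol(X),
            "); using the minimum-norm least-squares solution")
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
    cf <- drop(sv$v[, pos, drop = FALSE] %*%
                 ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos]))
    fitted <- drop(X %*% cf)
    resid <- y - fitted
    p_eff <- qrX$rank
  } else {
    fml <- stats::as.formula(paste("known_fraction ~",
                                   paste(sprintf("`%s`", cpgs), collapse = " + ")))
    fit <- stats::lm(fml, data = df)
    cf <- unname(stats::coef(fit))
    resid <- stats::residuals(fit)
    p_eff <- length(cf)
  }
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  structure(list(
    panel = panel,
    intercept = cf[1],
    coefficients = stats::setNames(cf[-1], cpgs),
    training_source = series$source,
    diagnostics = list(r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                       residual_sd = sqrt(rss / max(1, n - p_eff)),
                       n = n,
                       rank_deficient = rank_deficient)),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("calibration_model (", x$panel$name, " panel, source ",
      x$training_source, ")\n  intercept: ", format(x$intercept),
      "\n  coefficients (%-fraction per unit beta):\n", sep = "")
  print(x$coefficients)
  cat("  R^2 =", format(x$diagnostics$r_squared),
      " residual sd =", format(x$diagnostics$residual_sd),
      " n =", x$diagnostics$n, "\n")
  invisible(x)
}

#' Predict a cell fraction from panel methylation
#'
#' Linear prediction `intercept + sum coef * beta`, reported both raw
#' (`unclamped`) and clamped to \[0,100\] (`fraction`). Clamping keeps
#' reported fractions physical without hiding systematic bias -- near-zero
#' true fractions can legitimately predict slightly negative.
#'
#' @param model a `calibration_model`.
#' @param beta_by_cpg named numeric vector (or single-row data.frame/list)
#'   of beta values covering the model's panel.
#' @return list with `fraction` (clamped %, \[0,100\]) and `unclamped` (raw
#'   linear prediction, %).
#' @export
predict_fraction <- function(model, beta_by_cpg) {
  beta_by_cpg <- unlist(beta_by_cpg)
  cpgs <- names(model$coefficients)
  miss <- cpgs[!cpgs %in% names(beta_by_cpg) |
                 is.na(beta_by_cpg[cpgs])]
  if (length(miss)) stop("missing panel CpG value(s): ", paste(miss, collapse = ", "))
  raw <- model$intercept + sum(model$coefficients * beta_by_cpg[cpgs])
  list(fraction = min(100, max(0, raw)), unclamped = raw)
}

#' Predict fractions for every sample of a measurement table
#'
#' Applies [predict_fraction] per sample after pivoting the long-format
#' percent-methylation records to beta. Samples missing a panel CpG get a
#' row-level error entry instead of aborting the batch.
#'
#' @param model a `calibration_model`.
#' @param measurements a `measurement_table`.
#' @return data.frame (sample order preserved) with columns `sample_id`,
#'   `predicted` (clamped %), `unclamped` (%), `error` (NA or message).
#' @export
batch_predict <- function(model, measurements) {
  samples <- unique(measurements$sample_id)
  if (!length(samples))
    return(data.frame(sample_id = character(0), predicted = numeric(0),
                      unclamped = numeric(0), error = character(0),
                      stringsAsFactors = FALSE))
  bm <- measurements_to_beta(measurements)
  rows <- lapply(samples, function(s) {
    res <- tryCatch(predict_fraction(model, unclass(bm)[, s]),
                    error = function(e) e)
    if (inherits(res, "error"))
      data.frame(sample_id = s, predicted = NA_real_, unclamped = NA_real_,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    else
      data.frame(sample_id = s, predicted = res$fraction,
                 unclamped = res$unclamped, error = NA_character_,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
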