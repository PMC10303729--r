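# Reference-based NNLS deconvolution of HSPC subsets.
#
# The design matrix A holds the mean beta value of each panel CpG (rows) in
# each reference cell type (columns: HSC, LMPP, CMP, leukocytes). A sample's
# panel beta vector b is decomposed as b ~ A x with x >= 0; no sum-to-one
# constraint is imposed, and normalization to proportions is a reporting
# option with the raw coefficients always retained.

#' Build a reference atlas of mean beta values
#'
#' Entry (c, t) is the mean beta over the samples annotated as cell type t
#' at panel CpG c. A `"leukocytes"` pseudo-type may be requested: it is the
#' equal-weight mean of the per-group means over `leukocyte_groups`, so that
#' arbitrary group sizes in the reference set do not bias the aggregate.
#'
#' @param beta a [beta_matrix] of reference profiles.
#' @param ann a `sample_annotation`.
#' @param cell_types ordered cell-type labels wanted as atlas columns; the
#'   label `"leukocytes"` triggers pseudo-type aggregation.
#' @param panel a `marker_panel`; its CpGs become the atlas rows.
#' @param leukocyte_groups group labels pooled into the `"leukocytes"`
#'   pseudo-type (default: all annotated groups not named in `cell_types`).
#' @return numeric matrix of class `reference_atlas` (panel CpGs x cell
#'   types), all entries in \[0,1\].
#' @export
build_reference <- function(beta, ann, cell_types, panel,
                            leukocyte_groups = setdiff(unique(ann$group),
                                                       cell_types)) {
  cpgs <- panel_cpgs(panel)
  miss <- setdiff(cpgs, rownames(beta))
  if (length(miss)) stop("panel CpG(s) absent from beta matrix: ",
                         paste(miss, collapse = ", "))
  vals <- unclass(beta)[cpgs, , drop = FALSE]
  group_mean <- function(groups) {
    per_group <- vapply(groups, function(g) {
      idx <- match(intersect(colnames(vals), ann$sample_id[ann$group == g]),
                   colnames(vals))
      if (!length(idx)) stop("no samples annotated as cell type '", g, "'")
      rowMeans(vals[, idx, drop = FALSE], na.rm = TRUE)
    }, numeric(length(cpgs)))
    # equal weight per group, whatever the group sizes
    rowMeans(matrix(per_group, nrow = length(cpgs)))
  }
  A <- vapply(cell_types, function(ct) {
    if (ct == "leukocytes") {
      if (!length(leukocyte_groups))
        stop("no leukocyte groups available for the pseudo-type")
      group_mean(leukocyte_groups)
    } else group_mean(ct)
  }, numeric(length(cpgs)))
  A <- matrix(A, nrow = length(cpgs), dimnames = list(cpgs, cell_types))
  if (anyNA(A)) stop("reference atlas contains missing means")
  structure(A, class = c("reference_atlas", class(A)))
}

#' Write / read a reference atlas (CpG rows x cell-type columns, TSV/CSV)
#' @param atlas a `reference_atlas`.
#' @param path file path.
#' @param delim field delimiter (default tab).
#' @export
write_atlas <- function(atlas, path, delim = "\t") {
  df <- data.frame(cpg_id = rownames(atlas), unclass(atlas),
                   check.names = FALSE, row.names = NULL)
  data.table::fwrite(df, path, sep = delim, quote = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- .detect_delim(path)
  df <- data.table::fread(path, sep = delim, header = TRUE,
                          colClasses = list(character = 1), data.table = FALSE)
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- df[[1]]
  if (anyNA(A) || any(A < 0 | A > 1)) stop("atlas values must be in [0,1]")
  structure(A, class = c("reference_atlas", class(A)))
}

#' Non-negative least squares (Lawson--Hanson active set)
#'
#' Minimizes `||A x - b||_2` subject to `x >= 0` by the Lawson--Hanson
#' active-set algorithm: variables enter the passive set by the largest
#' positive gradient of the dual `w = A'(b - A x)`, inner least-squares
#' steps on the passive set are clipped back to the feasible boundary, and
#' the loop terminates when every zero variable has `w <= tol`. At the
#' solution the Karush--Kuhn--Tucker conditions hold: `x_i > 0` implies the
#' gradient component is (numerically) zero, `x_i = 0` implies it is
#' non-positive up to `tol`. Deterministic for fixed inputs.
#'
#' @param A numeric matrix (m x n), finite entries.
#' @param b numeric vector of length m.
#' @param tol dual-feasibility tolerance (default 1e-10).
#' @param max_iter iteration cap (default `30 * n`, ample for panel-sized
#'   problems).
#' @return list with `x` (nonnegative solution, named by `colnames(A)`) and
#'   `residual_norm` (`||A x - b||_2`).
#' @export
nnls_solve <- function(A, b, tol = 1e-10, max_iter = 30L * ncol(A)) {
  A <- as.matrix(A)
  if (!ncol(A)) stop("A must have at least one column")
  if (length(b) != nrow(A))
    stop("dimension mismatch: length(b) = ", length(b), ", nrow(A) = ", nrow(A))
  if (!all(is.finite(A)) || !all(is.finite(b)))
    stop("non-finite entries in A or b")
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter) {
    iter <- iter + 1L
    # candidate with the steepest improving gradient among the active set
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(n)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) { x <- z; break }
      # step toward z only as far as feasibility allows, then prune
      neg <- P[z[P] <= tol]
      ratio <- x[neg] / (x[neg] - z[neg])
      ratio[!is.finite(ratio)] <- 0
      alpha <- min(ratio)
      x <- x + alpha * (z - x)
      passive[P][x[P] <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x <- pmax(x, 0)
  names(x) <- colnames(A)
  list(x = x, residual_norm = sqrt(sum((A %*% x - b)^2)))
}

#' Deconvolve one sample against a reference atlas
#'
#' Solves [nnls_solve] with the atlas as design matrix and the sample's
#' panel beta vector as observation. With `normalize = TRUE` the raw NNLS
#' coefficients are rescaled to sum to one (raw values retained); an
#' all-zero fit sets the `degenerate` flag instead of dividing by zero.
#'
#' @param atlas a `reference_atlas`.
#' @param beta_by_cpg named numeric vector of beta values covering the
#'   atlas CpGs.
#' @param normalize report proportions summing to 1 (default `FALSE`).
#' @param sample_id optional identifier carried into the result.
#' @return object of class `deconvolution_result`: `fractions` (named),
#'   `raw_fractions`, `residual_norm`, `normalized`, `degenerate`.
#' @export
deconvolve_sample <- function(atlas, beta_by_cpg, normalize = FALSE,
                              sample_id = NA_character_) {
  beta_by_cpg <- unlist(beta_by_cpg)
  cpgs <- rownames(atlas)
  miss <- cpgs[!cpgs %in% names(beta_by_cpg) | is.na(beta_by_cpg[cpgs])]
  if (length(miss)) stop("missing atlas CpG value(s): ", paste(miss, collapse = ", "))
  sol <- nnls_solve(unclass(atlas), beta_by_cpg[cpgs])
  raw <- sol$x
  tot <- sum(raw)
  degenerate <- FALSE
  if (normalize) {
    if (tot > 0) fr <- raw / tot else { fr <- raw * 0; degenerate <- TRUE }
  } else fr <- raw
  structure(list(sample_id = sample_id, fractions = fr, raw_fractions = raw,
                 residual_norm = sol$residual_norm, normalized = normalize,
                 degenerate = degenerate),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat("deconvolution_result", if (!is.na(x$sample_id)) paste0("[", x$sample_id, "]"),
      if (x$normalized) "(normalized)", "\n")
  print(round(x$fractions, 4))
  cat("residual norm:", format(x$residual_norm), "\n")
  invisible(x)
}

#' Deconvolve every sample of a measurement table
#'
#' @param atlas a `reference_atlas`.
#' @param measurements a `measurement_table` covering the atlas CpGs.
#' @param normalize see [deconvolve_sample].
#' @return data.frame with one row per sample: `sample_id`, one column per
#'   cell type (fractions), `residual_norm`, `degenerate`.
#' @export
batch_deconvolve <- function(atlas, measurements, normalize = FALSE) {
  bm <- measurements_to_beta(measurements)
  samples <- colnames(bm)
  rows <- lapply(samples, function(s) {
    r <- deconvolve_sample(atlas, unclass(bm)[, s], normalize = normalize,
                           sample_id = s)
    cbind(data.frame(sample_id = s, stringsAsFactors = FALSE),
          as.data.frame(as.list(r$fractions), check.names = FALSE),
          data.frame(residual_norm = r$residual_norm, degenerate = r$degenerate))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sum selected progenitor fractions
#'
#' Arithmetic sum of the named cell-type fractions of a deconvolution
#' result, e.g. HSC + LMPP + CMP as the deconvolution-side estimate of the
#' total HSPC fraction.
#'
#' @param result a `deconvolution_result`.
#' @param progenitor_types cell-type labels to sum (subset of the result's
#'   types); an empty set sums to 0.
#' @return scalar sum.
#' @export
sum_progenitor_fractions <- function(result, progenitor_types) {
  unknown <- setdiff(progenitor_types, names(result$fractions))
  if (length(unknown)) stop("unknown cell type(s): ",
                            paste(unknown, collapse = ", "))
  if (!length(progenitor_types)) return(0)
  sum(result$fractions[progenitor_types])
}
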