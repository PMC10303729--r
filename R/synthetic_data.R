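# Synthetic methylation data with the statistical structure the pipeline
# assumes: per-cell-type reference profiles carrying planted marker CpGs
# (large delta-beta toward the target type, low within-type variance) over a
# bimodal background, linear mixing of reference profiles by known
# proportions, and additive Gaussian technical noise on beta clamped to
# [0,1]. Everything is seeded and bit-reproducible.

#' Specification for the synthetic-data generators
#'
#' Defaults emulate the structure of a sorted-cell-type 450k reference
#' compendium around a small HSPC-subset panel: three progenitor subsets
#' (HSC, LMPP, CMP) plus three mature leukocyte groups, three hyper- and
#' three hypomethylated planted markers per cell type with a target
#' separation of delta-beta 0.6, replicate jitter of sd 0.02 on the beta
#' scale, technical measurement noise of sd 0.02, and an 8-point dilution
#' grid spanning 0--100% (an artifact default; graded two-component
#' mixtures with flow-verified fractions).
#'
#' @param cell_types character vector of cell-type labels.
#' @param n_background_cpgs count of non-marker background CpGs.
#' @param markers_per_type named integer vector `c(hyper=, hypo=)`.
#' @param marker_delta target |delta beta| of planted markers, in (0,1].
#' @param within_type_sd beta-scale sd of replicate samples about the type
#'   mean.
#' @param noise_sd technical measurement noise sd (additive Gaussian on
#'   beta).
#' @param samples_per_type replicate samples generated per cell type.
#' @param dilution_grid known CD34+ fractions (%) for dilution series.
#' @param pan_groups cell types jointly covered by pan markers -- CpGs
#'   methylated (or unmethylated) in *all* of these types at once and at
#'   the opposite level everywhere else, emulating markers of the whole
#'   HSPC compartment that are erased during hematopoietic differentiation.
#'   Default: the three progenitor subsets. Set `n_pan_hyper = 0` (and
#'   hypo) to disable.
#' @param n_pan_hyper,n_pan_hypo counts of planted pan markers per
#'   direction (default 3 hyper, 0 hypo: the total-HSPC panel is
#'   hypermethylated in progenitors).
#' @param seed integer seed; fixed seed gives bit-identical outputs.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(cell_types = c("HSC", "LMPP", "CMP",
                                          "granulocytes", "CD4T", "monocytes"),
                           n_background_cpgs = 1000L,
                           markers_per_type = c(hyper = 3L, hypo = 3L),
                           marker_delta = 0.6,
                           within_type_sd = 0.02,
                           noise_sd = 0.02,
                           samples_per_type = 4L,
                           dilution_grid = c(0, 1, 2.5, 5, 10, 25, 50, 100),
                           pan_groups = intersect(c("HSC", "LMPP", "CMP"),
                                                  cell_types),
                           n_pan_hyper = 3L, n_pan_hypo = 0L,
                           seed = 1L) {
  stopifnot(marker_delta > 0, marker_delta <= 1,
            within_type_sd >= 0, noise_sd >= 0,
            all(dilution_grid >= 0 & dilution_grid <= 100),
            samples_per_type >= 1, n_background_cpgs >= 0)
  structure(list(cell_types = cell_types,
                 n_background_cpgs = as.integer(n_background_cpgs),
                 markers_per_type = markers_per_type,
                 marker_delta = marker_delta,
                 within_type_sd = within_type_sd,
                 noise_sd = noise_sd,
                 samples_per_type = as.integer(samples_per_type),
                 dilution_grid = dilution_grid,
                 pan_groups = pan_groups,
                 n_pan_hyper = as.integer(n_pan_hyper),
                 n_pan_hypo = as.integer(n_pan_hypo),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.clamp01 <- function(x) pmin(1, pmax(0, x))

# count clamping events before applying them (reported, not silently lost)
.clamp_count <- function(x) sum(x < 0 | x > 1)

#' Generate synthetic reference methylomes with planted markers
#'
#' Background CpGs draw a shared baseline from a bimodal beta distribution
#' (modes near 0.1 and 0.9, equal mixing weight -- the genome-wide beta
#' shape) with small non-specific between-type wobble. Planted markers
#' offset the target type from a common non-target level by
#' `+/- marker_delta` (hyper: target high, hypo: target low); offsets that
#' would leave \[0,1\] are shrunk to fit and the realized delta recorded.
#' Replicate samples jitter about their type mean with `within_type_sd`,
#' clamped to \[0,1\].
#'
#' @param spec a [synthetic_spec].
#' @return list with `beta` ([beta_matrix]), `annotation`
#'   (`sample_annotation`), and `truth` (data.frame: cpg_id, cell_type,
#'   direction, planted_delta).
#' @export
make_reference_profiles <- function(spec) {
  set.seed(derive_seed(spec$seed, "reference"))
  types <- spec$cell_types
  n_bg <- spec$n_background_cpgs
  n_hyper <- spec$markers_per_type[["hyper"]]
  n_hypo <- spec$markers_per_type[["hypo"]]
  n_mark <- (n_hyper + n_hypo) * length(types)
  n_pan <- spec$n_pan_hyper + spec$n_pan_hypo

  marker_ids <- sprintf("cgM%05d", seq_len(n_mark))
  pan_ids <- if (n_pan) sprintf("cgP%05d", seq_len(n_pan)) else character(0)
  bg_ids <- sprintf("cgB%05d", seq_len(n_bg))
  cpgs <- c(marker_ids, pan_ids, bg_ids)

  # type-mean matrix
  mu <- matrix(NA_real_, length(cpgs), length(types),
               dimnames = list(cpgs, types))
  truth <- data.frame(cpg_id = character(0), cell_type = character(0),
                      direction = character(0), planted_delta = numeric(0),
                      stringsAsFactors = FALSE)
  k <- 0L
  for (t in types) {
    for (d in c(rep("hyper", n_hyper), rep("hypo", n_hypo))) {
      k <- k + 1L
      cg <- marker_ids[k]
      if (d == "hyper") {
        base <- stats::runif(1, 0.05, 0.25)
        target <- base + spec$marker_delta
      } else {
        base <- stats::runif(1, 0.75, 0.95)
        target <- base - spec$marker_delta
      }
      # offsets that would leave [0,1] are shrunk to fit; realized delta
      # lands in the truth table either way
      target <- .clamp01(target)
      mu[cg, ] <- base
      mu[cg, t] <- target
      truth <- rbind(truth, data.frame(cpg_id = cg, cell_type = t,
                                       direction = d,
                                       planted_delta = target - base,
                                       stringsAsFactors = FALSE))
    }
  }
  # pan markers: one level shared by every pan group, the opposite level
  # in every other type (the total-HSPC panel regime)
  if (n_pan) {
    pan_dirs <- c(rep("hyper", spec$n_pan_hyper), rep("hypo", spec$n_pan_hypo))
    for (k in seq_len(n_pan)) {
      cg <- pan_ids[k]
      if (pan_dirs[k] == "hyper") {
        base <- stats::runif(1, 0.05, 0.25)
        target <- .clamp01(base + spec$marker_delta)
      } else {
        base <- stats::runif(1, 0.75, 0.95)
        target <- .clamp01(base - spec$marker_delta)
      }
      mu[cg, ] <- base
      mu[cg, spec$pan_groups] <- target
      truth <- rbind(truth, data.frame(
        cpg_id = cg, cell_type = paste(spec$pan_groups, collapse = "+"),
        direction = pan_dirs[k], planted_delta = target - base,
        stringsAsFactors = FALSE))
    }
  }
  if (n_bg) {
    mode <- stats::rbinom(n_bg, 1, 0.5)
    base <- .clamp01(ifelse(mode == 1, stats::rnorm(n_bg, 0.9, 0.04),
                            stats::rnorm(n_bg, 0.1, 0.04)))
    # small non-specific between-type wobble keeps background |delta| small
    wob <- matrix(stats::rnorm(n_bg * length(types), 0, 0.01),
                  n_bg, length(types))
    mu[bg_ids, ] <- .clamp01(base + wob)
  }

  n_s <- spec$samples_per_type
  sample_ids <- as.vector(vapply(types, function(t) paste0(t, "_", seq_len(n_s)),
                                 character(n_s)))
  vals <- matrix(NA_real_, length(cpgs), length(sample_ids),
                 dimnames = list(cpgs, sample_ids))
  col <- 0L
  for (t in types) for (i in seq_len(n_s)) {
    col <- col + 1L
    jit <- stats::rnorm(length(cpgs), 0, spec$within_type_sd)
    vals[, col] <- .clamp01(mu[, t] + jit)
  }
  ann <- sample_annotation(data.frame(
    sample_id = sample_ids,
    group = rep(types, each = n_s),
    source = "synthetic", stringsAsFactors = FALSE))
  list(beta = beta_matrix(vals), annotation = ann, truth = truth)
}

#' Simulate a noisy mixture of reference profiles
#'
#' `b = A p + eps`, with `eps` i.i.d. Gaussian(0, `noise_sd`), clamped to
#' \[0,1\]. The count of clamping events is attached as attribute
#' `"n_clamped"`.
#'
#' @param atlas a `reference_atlas` (CpGs x cell types).
#' @param proportions nonnegative vector over the atlas cell types summing
#'   to 1 (tolerance 1e-9).
#' @param noise_sd technical noise sd.
#' @param seed integer seed.
#' @return named beta vector over the atlas CpGs.
#' @export
simulate_mixture <- function(atlas, proportions, noise_sd = 0, seed = 1L) {
  if (length(proportions) != ncol(atlas))
    stop("proportions length ", length(proportions), " != ", ncol(atlas),
         " cell types")
  if (any(proportions < 0)) stop("negative proportion")
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  set.seed(seed)
  b <- drop(unclass(atlas) %*% proportions) +
    stats::rnorm(nrow(atlas), 0, noise_sd)
  out <- .clamp01(b)
  attr(out, "n_clamped") <- .clamp_count(b)
  names(out) <- rownames(atlas)
  out
}

#' Simulate a two-component dilution series
#'
#' For every grid fraction f (%), mixes the two atlas columns at
#' `p = (f/100, 1 - f/100)` with measurement noise; `known_fraction = f`.
#' Emulates graded mixtures of sorted CD34+ and CD34- cells whose mixing
#' fraction was verified by flow cytometry.
#'
#' @param atlas a two-column `reference_atlas`; the first column is the
#'   CD34+ (diluted) component.
#' @param grid known fractions in \[0,100\]; default from `spec`.
#' @param noise_sd measurement noise sd on beta.
#' @param seed integer seed.
#' @param source source label carried on the series (e.g. `"mPB"`).
#' @param panel optional `marker_panel` (default: a nameless panel over
#'   the atlas CpGs, directions `"hyper"`).
#' @return list with `series` (a [dilution_series]) and `measurements`
#'   (the same data as a long-format `measurement_table`).
#' @export
simulate_dilution_series <- function(atlas, grid = c(0, 1, 2.5, 5, 10, 25, 50, 100),
                                     noise_sd = 0, seed = 1L, source = "mPB",
                                     panel = NULL) {
  if (ncol(atlas) != 2)
    stop("dilution simulation needs exactly the two mixing types; atlas has ",
         ncol(atlas))
  if (any(grid < 0 | grid > 100)) stop("dilution grid outside [0,100]")
  if (is.null(panel))
    panel <- marker_panel("panel", data.frame(
      cpg_id = rownames(atlas), gene = NA_character_, direction = "hyper",
      stringsAsFactors = FALSE))
  rows <- lapply(seq_along(grid), function(i) {
    f <- grid[i]
    b <- simulate_mixture(atlas, c(f / 100, 1 - f / 100), noise_sd,
                          seed = derive_seed(seed, i))
    c(known_fraction = f, b)
  })
  mat <- do.call(rbind, rows)
  df <- data.frame(sample_id = sprintf("dil_%02d", seq_along(grid)),
                   mat, check.names = FALSE, stringsAsFactors = FALSE)
  series <- dilution_series(df, panel, source = source)
  long <- do.call(rbind, lapply(seq_along(grid), function(i) {
    data.frame(sample_id = df$sample_id[i],
               cpg_id = rownames(atlas),
               percent_methylation = 100 * unlist(df[i, rownames(atlas)]),
               known_fraction = grid[i],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(series = series, measurements = measurement_table(long))
}

#' Simulate a leukemia cohort with known blast counts
#'
#' Per sample, a blast fraction is drawn uniformly in `blast_range` and the
#' panel beta is the blast-weighted mix of an HSPC-like and a leukocyte
#' reference column plus noise; the drawn blast percentage is stored as the
#' covariate `blast_count_percent`. Emulates the setting where panel
#' methylation is correlated against manual blast counts.
#'
#' @param atlas a two-column `reference_atlas`: first column the HSPC-like
#'   (blast) profile, second the leukocyte profile.
#' @param n_samples cohort size (>= 2, or downstream correlation is
#'   undefined).
#' @param blast_range blast percentage range, within \[0,100\].
#' @param noise_sd measurement noise sd on beta.
#' @param seed integer seed.
#' @return a `measurement_table` with covariate `blast_count_percent`.
#' @export
make_leukemia_cohort <- function(atlas, n_samples = 39L,
                                 blast_range = c(0, 100), noise_sd = 0.03,
                                 seed = 1L) {
  if (n_samples < 2) stop("need n_samples >= 2 for a correlation cohort")
  if (any(blast_range < 0 | blast_range > 100))
    stop("blast_range outside [0,100]")
  if (ncol(atlas) != 2)
    stop("leukemia simulation needs a (blast-like, leukocyte) atlas")
  set.seed(derive_seed(seed, "leukemia"))
  blast <- stats::runif(n_samples, blast_range[1], blast_range[2])
  rows <- lapply(seq_len(n_samples), function(i) {
    b <- simulate_mixture(atlas, c(blast[i] / 100, 1 - blast[i] / 100),
                          noise_sd, seed = derive_seed(seed, 1000L + i))
    data.frame(sample_id = sprintf("leuk_%02d", i),
               cpg_id = rownames(atlas),
               percent_methylation = 100 * unname(b),
               blast_count_percent = blast[i],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  measurement_table(do.call(rbind, rows))
}
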