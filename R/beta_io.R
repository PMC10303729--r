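# Tabular IO and packaged marker panels.
#
# Canonical internal scale is beta in [0,1]; targeted pyrosequencing percent
# values are divided by 100 on ingest so that arrays and targeted assays share
# one algebra. CpG identifiers are opaque strings throughout -- no genomic
# coordinates are needed anywhere in the pipeline.

#' Construct a validated beta-value matrix
#'
#' A beta matrix is a numeric CpG-by-sample matrix of DNA methylation
#' beta values (methylation fraction in \[0,1\]). Rows are CpG sites
#' (Illumina "cg" probe identifiers or any opaque string), columns are
#' samples. Missing entries (`NA`) are allowed; every non-missing value
#' must lie in \[0,1\] and both identifier sets must be unique.
#'
#' @param values numeric matrix with CpG rownames and sample colnames,
#'   or any object coercible to one.
#' @param cpg_ids,sample_ids optional identifier vectors overriding the
#'   dimnames of `values`.
#' @return a numeric matrix of class `beta_matrix`.
#' @export
beta_matrix <- function(values, cpg_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cpg_ids) || is.null(sample_ids))
    stop("beta_matrix requires CpG row identifiers and sample column identifiers")
  if (length(cpg_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match the matrix shape")
  rownames(values) <- as.character(cpg_ids)
  colnames(values) <- as.character(sample_ids)
  validate_beta_matrix(values)
  class(values) <- c("beta_matrix", class(values))
  values
}

validate_beta_matrix <- function(values) {
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate CpG identifier(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicate sample identifier(s): ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("beta value out of [0,1] at CpG '", rownames(values)[bad[1, 1]],
         "', sample '", colnames(values)[bad[1, 2]], "' (value ",
         format(values[bad[1, , drop = FALSE]]), ")")
  }
  invisible(values)
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("beta_matrix:", nrow(x), "CpGs x", ncol(x), "samples;",
      sum(is.na(x)), "missing\n")
  invisible(x)
}

.detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a beta-value matrix from a TSV/CSV file
#'
#' Expects a header row of sample identifiers with a first column of CpG
#' identifiers (conventionally named `cpg_id`). The delimiter is
#' auto-detected between tab and comma unless given. Values on the percent
#' scale (0--100, as exported by pyrosequencing software) are converted to
#' the canonical \[0,1\] scale by dividing by 100.
#'
#' @param path file path.
#' @param scale `"unit"` for beta in \[0,1\] (default) or `"percent"` for
#'   0--100 inputs.
#' @param delim field delimiter; `NULL` (default) auto-detects tab vs comma.
#' @param missing token denoting a missing value (default `"NA"`).
#' @return a [beta_matrix].
#' @export
read_beta_matrix <- function(path, scale = c("unit", "percent"),
                             delim = NULL, missing = "NA") {
  scale <- match.arg(scale)
  if (is.null(delim)) delim <- .detect_delim(path)
  dt <- data.table::fread(path, sep = delim, header = TRUE,
                          na.strings = missing, colClasses = list(character = 1),
                          data.table = FALSE)
  if (ncol(dt) < 2) stop("beta matrix file needs a CpG column plus >=1 sample column")
  ids <- dt[[1]]
  vals <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!is.na(dt[, -1, drop = FALSE]) & is.na(suppressWarnings(
      matrix(as.numeric(as.matrix(dt[, -1, drop = FALSE])), nrow = nrow(dt)))),
      arr.ind = TRUE)
    stop("non-numeric cell in beta matrix at row '", ids[bad[1, 1]], "'")
  }
  hi <- if (scale == "percent") 100 else 1
  bad <- which(!is.na(vals) & (vals < 0 | vals > hi), arr.ind = TRUE)
  if (nrow(bad))
    stop("value outside [0,", hi, "] (scale=", scale, ") at CpG '",
         ids[bad[1, 1]], "', sample '", colnames(vals)[bad[1, 2]], "'")
  if (scale == "percent") vals <- vals / 100
  beta_matrix(vals, cpg_ids = ids, sample_ids = colnames(vals))
}

#' Write a beta-value matrix to a TSV/CSV file
#'
#' First column is `cpg_id`, remaining columns are sample identifiers.
#' Round-trips through [read_beta_matrix] at full stored precision.
#'
#' @param beta a [beta_matrix].
#' @param path output path.
#' @param delim field delimiter (default tab).
#' @export
write_beta_matrix <- function(beta, path, delim = "\t") {
  df <- data.frame(cpg_id = rownames(beta), unclass(beta),
                   check.names = FALSE, row.names = NULL)
  data.table::fwrite(df, path, sep = delim, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read sample annotations
#'
#' Long-format table with columns `sample_id`, `group` and optionally
#' `source` (e.g. mPB, CB, PB, BM). Every annotated sample resolves to
#' exactly one group.
#'
#' @param path file path; delimiter auto-detected between tab and comma.
#' @param delim optional delimiter override.
#' @return data.frame with columns sample_id, group, source.
#' @export
read_annotations <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- .detect_delim(path)
  df <- data.table::fread(path, sep = delim, header = TRUE, data.table = FALSE)
  sample_annotation(df)
}

#' Construct a validated sample-annotation table
#'
#' @param df data.frame with columns `sample_id`, `group` and optional
#'   `source`.
#' @return validated data.frame of class `sample_annotation`.
#' @export
sample_annotation <- function(df) {
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  if (is.null(df$source)) df$source <- NA_character_
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("sample annotated more than once: ", paste(unique(dup), collapse = ", "))
  class(df) <- c("sample_annotation", "data.frame")
  df
}

#' Read a targeted measurement table
#'
#' Long-format table of pyrosequencing-style measurements with columns
#' `sample_id`, `cpg_id`, `percent_methylation` (0--100) and optional
#' `known_fraction` plus arbitrary covariate columns (e.g.
#' `cd34_flow_percent`, `blast_count_percent`), all preserved by name.
#'
#' @param path file path; delimiter auto-detected.
#' @param delim optional delimiter override.
#' @return a `measurement_table` data.frame.
#' @export
read_measurements <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- .detect_delim(path)
  df <- data.table::fread(path, sep = delim, header = TRUE, data.table = FALSE)
  measurement_table(df)
}

#' Construct a validated measurement table
#'
#' @param df data.frame with at least `sample_id`, `cpg_id`,
#'   `percent_methylation`; `(sample_id, cpg_id)` pairs must be unique and
#'   percent values must lie in \[0,100\].
#' @return data.frame of class `measurement_table`.
#' @export
measurement_table <- function(df) {
  need <- c("sample_id", "cpg_id", "percent_methylation")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("measurement table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$cpg_id <- as.character(df$cpg_id)
  key <- paste(df$sample_id, df$cpg_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (sample, CpG) pair: (", df$sample_id[dup[1]], ", ",
         df$cpg_id[dup[1]], ")")
  pm <- df$percent_methylation
  bad <- which(!is.na(pm) & (pm < 0 | pm > 100))
  if (length(bad))
    stop("percent_methylation outside [0,100] for (", df$sample_id[bad[1]],
         ", ", df$cpg_id[bad[1]], "): ", pm[bad[1]])
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' Write a measurement table
#' @param m a `measurement_table`.
#' @param path output path.
#' @param delim field delimiter (default tab).
#' @export
write_measurements <- function(m, path, delim = "\t") {
  data.table::fwrite(as.data.frame(m), path, sep = delim, na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' Convert a measurement table to per-sample beta vectors
#'
#' Pivots the long-format percent-methylation records to a beta matrix on
#' the canonical \[0,1\] scale (percent / 100).
#'
#' @param m a `measurement_table`.
#' @param cpg_ids optional CpG subset/order; default all CpGs present.
#' @return a [beta_matrix] (CpGs x samples); combinations absent from the
#'   table are `NA`.
#' @export
measurements_to_beta <- function(m, cpg_ids = NULL) {
  if (is.null(cpg_ids)) cpg_ids <- unique(m$cpg_id)
  samples <- unique(m$sample_id)
  vals <- matrix(NA_real_, length(cpg_ids), length(samples),
                 dimnames = list(cpg_ids, samples))
  keep <- m$cpg_id %in% cpg_ids
  vals[cbind(match(m$cpg_id[keep], cpg_ids),
             match(m$sample_id[keep], samples))] <- m$percent_methylation[keep] / 100
  beta_matrix(vals)
}

# ---- marker panels ---------------------------------------------------------

#' Construct a marker panel
#'
#' @param name panel name.
#' @param markers data.frame with columns `cpg_id`, `gene`, `direction`
#'   (`"hyper"` = methylated in the target type, `"hypo"` = unmethylated).
#' @return object of class `marker_panel`.
#' @export
marker_panel <- function(name, markers) {
  need <- c("cpg_id", "gene", "direction")
  miss <- setdiff(need, names(markers))
  if (length(miss)) stop("panel markers lack column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(markers$cpg_id))
    stop("duplicate CpG in panel: ",
         markers$cpg_id[duplicated(markers$cpg_id)][1])
  bad <- setdiff(unique(markers$direction), c("hyper", "hypo"))
  if (length(bad)) stop("unknown marker direction: ", paste(bad, collapse = ", "))
  structure(list(name = name,
                 markers = as.data.frame(markers)[need]),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("marker_panel '", x$name, "': ", nrow(x$markers), " CpGs\n", sep = "")
  print(x$markers, row.names = FALSE)
  invisible(x)
}

#' Panel CpG identifiers
#' @param panel a `marker_panel`.
#' @return character vector of CpG ids in panel order.
#' @export
panel_cpgs <- function(panel) panel$markers$cpg_id

.builtin_panels <- list(
  # 3-CpG total-HSPC panel: all three CpGs are methylated in HSPCs and
  # demethylated during hematopoietic differentiation.
  hspc3 = data.frame(
    cpg_id = c("cg17707057", "cg00164282", "cg17607231"),
    gene = c("STK17A", "MYO1D", "SP140"),
    direction = c("hyper", "hyper", "hyper"),
    stringsAsFactors = FALSE),
  # 6-CpG subset panel (one hypo- and one hypermethylated CpG per HSPC
  # subtype); STK17A, FTO and MYO1D are the hypermethylated three.
  subset6 = data.frame(
    cpg_id = c("cg08865625", "cg17707057", "cg09749364",
               "cg01986630", "cg06768361", "cg00164282"),
    gene = c("HLF", "STK17A", "BMF", "FTO", "TESC", "MYO1D"),
    direction = c("hypo", "hyper", "hypo", "hyper", "hypo", "hyper"),
    stringsAsFactors = FALSE)
)

#' Packaged marker panels
#'
#' Returns one of the two built-in HSPC marker panels:
#' \describe{
#'   \item{`hspc3`}{the 3-CpG total-HSPC panel (STK17A cg17707057,
#'     MYO1D cg00164282, SP140 cg17607231; all hypermethylated in HSPCs),
#'     used for dilution-series calibration of total HSPC fractions.}
#'   \item{`subset6`}{the 6-CpG subset panel (HLF cg08865625,
#'     STK17A cg17707057, BMF cg09749364, FTO cg01986630, TESC cg06768361,
#'     MYO1D cg00164282; one hypo- and one hypermethylated CpG per HSPC
#'     subtype), used for NNLS deconvolution of HSC/LMPP/CMP/leukocyte
#'     fractions.}
#' }
#'
#' @param name `"hspc3"` or `"subset6"`.
#' @return a [marker_panel].
#' @export
builtin_panel <- function(name) {
  if (!name %in% names(.builtin_panels))
    stop("unknown panel '", name, "'; available: ",
         paste(names(.builtin_panels), collapse = ", "))
  marker_panel(name, .builtin_panels[[name]])
}

#' Read / write a marker panel as JSON
#'
#' Panels serialize as `{name, markers: [{cpg_id, gene, direction}, ...]}`.
#'
#' @param path file path.
#' @return [marker_panel] (for `read_panel`); the path, invisibly (for
#'   `write_panel`).
#' @export
read_panel <- function(path) {
  obj <- jsonlite::fromJSON(path)
  marker_panel(obj$name, as.data.frame(obj$markers))
}

#' @rdname read_panel
#' @param panel a `marker_panel` to serialize.
#' @export
write_panel <- function(panel, path) {
  jsonlite::write_json(list(name = panel$name, markers = panel$markers),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Per-stage seed derivation: one user seed governs every stochastic stage of
# a run; stages get distinct deterministic offsets (kept below 2^31).
#' Derive a per-stage seed from a master seed
#' @param seed master integer seed.
#' @param stage stage label (character) or integer offset.
#' @return integer seed, deterministic in (seed, stage).
#' @export
derive_seed <- function(seed, stage) {
  off <- if (is.character(stage)) sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) else as.integer(stage)
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647L)
}
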