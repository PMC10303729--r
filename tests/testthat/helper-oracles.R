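# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's own solver paths.

# Brute-force NNLS oracle: best objective over scaled simplex directions.
# Enumerates weight vectors w on the unit simplex at the given step; for
# each direction the optimal nonnegative scale s has the closed form
# max(0, <Aw, b> / ||Aw||^2). Every grid point is feasible for NNLS, so the
# true NNLS objective can never exceed the best grid objective.
grid_nnls_objective <- function(A, b, step = 0.01) {
  n <- ncol(A)
  m <- round(1 / step)
  combos <- if (n == 1) matrix(m, 1, 1) else {
    grid <- expand.grid(rep(list(0:m), n - 1))
    last <- m - rowSums(grid)
    keep <- last >= 0
    as.matrix(cbind(grid[keep, , drop = FALSE], last[keep]))
  }
  best <- sqrt(sum(b^2))  # x = 0
  for (i in seq_len(nrow(combos))) {
    w <- combos[i, ] / m
    Aw <- drop(A %*% w)
    den <- sum(Aw^2)
    if (den == 0) next
    s <- max(0, sum(Aw * b) / den)
    obj <- sqrt(sum((s * Aw - b)^2))
    if (obj < best) best <- obj
  }
  best
}

# Normal-equations OLS oracle: explicit matrix inversion, independent of lm.
normal_equations <- function(X, y) {
  drop(solve(t(X) %*% X) %*% (t(X) %*% y))
}

# KKT conditions for min ||Ax - b|| s.t. x >= 0 at a candidate x.
kkt_holds <- function(A, b, x, tol = 1e-8) {
  g <- drop(crossprod(A, b - A %*% x))  # negative gradient
  all(ifelse(x > tol, abs(g) < 1e-6, g <= tol))
}

# Random NNLS instance on the scale of panel deconvolution problems.
random_nnls_instance <- function(seed, max_types = 3, max_cpgs = 8) {
  set.seed(seed)
  k <- sample(1:max_types, 1)
  m <- sample(k:max_cpgs, 1)
  A <- matrix(runif(m * k), m, k)
  p <- runif(k); p <- p / sum(p)
  b <- pmin(1, pmax(0, drop(A %*% p) + rnorm(m, 0, 0.01)))
  list(A = A, b = b, p = p)
}

# Minimal two-group beta fixture used by IO/selection unit tests.
tiny_beta <- function() {
  vals <- rbind(
    cg_sep  = c(0.8, 0.9, 0.1, 0.2),
    cg_flat = c(0.5, 0.5, 0.5, 0.5))
  colnames(vals) <- c("t1", "t2", "r1", "r2")
  list(beta = beta_matrix(vals),
       ann = sample_annotation(data.frame(
         sample_id = c("t1", "t2", "r1", "r2"),
         group = c("HSPC", "HSPC", "leuko", "leuko"))))
}

# Rename chosen generated CpG rows (and truth entries) to real probe ids,
# so panel-facing tests can exercise the packaged panels on synthetic data.
rename_cpgs <- function(ref, from, to) {
  idx <- match(from, rownames(ref$beta))
  stopifnot(!anyNA(idx))
  rn <- rownames(ref$beta)
  rn[idx] <- to
  ref$beta <- beta_matrix(unclass(ref$beta), cpg_ids = rn,
                          sample_ids = colnames(ref$beta))
  ref$truth$cpg_id[match(from, ref$truth$cpg_id)] <- to
  ref
}

# Shared end-to-end cohort builder: reference -> panels -> atlas ->
# dilution-calibrated total model + NNLS subset deconvolution on one
# simulated cohort with known total and subset fractions.
build_consistency_cohort <- function(seed, n_cohort = 30, noise_sd = 0.02,
                                     n_dilution_series = 3) {
  spec <- synthetic_spec(noise_sd = noise_sd, seed = derive_seed(seed, "ref"))
  ref <- make_reference_profiles(spec)
  subsets <- c("HSC", "LMPP", "CMP")

  sel <- select_subset_markers(ref$beta, ref$annotation, subsets,
                               n_hypo = 1, n_hyper = 1)
  panel6 <- marker_panel("subset6-synthetic", data.frame(
    cpg_id = unlist(lapply(sel, `[[`, "cpg_id")),
    gene = NA_character_,
    direction = unlist(lapply(sel, `[[`, "direction")),
    stringsAsFactors = FALSE))
  atlas4 <- build_reference(ref$beta, ref$annotation,
                            c(subsets, "leukocytes"), panel6)

  pan_ids <- ref$truth$cpg_id[grepl("^cgP", ref$truth$cpg_id)]
  panel3 <- marker_panel("hspc3-synthetic", data.frame(
    cpg_id = pan_ids, gene = NA_character_, direction = "hyper",
    stringsAsFactors = FALSE))
  atlas3 <- build_reference(ref$beta, ref$annotation,
                            c(subsets, "leukocytes"), panel3)
  # two-component mixing atlas: CD34+ = equal mix of the subsets
  atlas2 <- cbind(CD34pos = rowMeans(atlas3[, subsets]),
                  CD34neg = atlas3[, "leukocytes"])

  # several replicate dilution series (multiple donors) stabilize the fit
  dil <- lapply(seq_len(n_dilution_series), function(i) {
    simulate_dilution_series(atlas2, grid = spec$dilution_grid,
                             noise_sd = noise_sd,
                             seed = derive_seed(seed, paste0("dil", i)),
                             panel = panel3)$series$data
  })
  dil <- do.call(rbind, dil)
  dil$sample_id <- sprintf("dil_%02d", seq_len(nrow(dil)))
  model <- fit_dilution_model(dilution_series(dil, panel3, "mPB"))

  # cohort with known totals and random subset splits
  set.seed(derive_seed(seed, "cohort"))
  total <- runif(n_cohort, 0, 100)
  splitw <- matrix(rexp(n_cohort * 3), n_cohort, 3)
  splitw <- splitw / rowSums(splitw)
  all_cpgs <- union(panel_cpgs(panel3), panel_cpgs(panel6))
  atlas_all <- build_reference(ref$beta, ref$annotation,
                               c(subsets, "leukocytes"),
                               marker_panel("all", data.frame(
                                 cpg_id = all_cpgs, gene = NA_character_,
                                 direction = "hyper", stringsAsFactors = FALSE)))
  truth_sub <- splitw * total / 100   # per-subset fractions in [0,1]
  samples <- lapply(seq_len(n_cohort), function(i) {
    p <- c(truth_sub[i, ], 1 - total[i] / 100)
    simulate_mixture(atlas_all, p, noise_sd,
                     seed = derive_seed(seed, 2000L + i))
  })
  b_mat <- do.call(cbind, samples)
  colnames(b_mat) <- sprintf("s%02d", seq_len(n_cohort))

  totals_hat <- sapply(seq_len(n_cohort), function(i)
    predict_fraction(model, b_mat[panel_cpgs(panel3), i])$fraction)
  names(totals_hat) <- colnames(b_mat)
  dec <- lapply(seq_len(n_cohort), function(i)
    deconvolve_sample(atlas4, b_mat[panel_cpgs(panel6), i],
                      sample_id = colnames(b_mat)[i]))
  list(model = model, atlas4 = atlas4, panel3 = panel3, panel6 = panel6,
       totals_hat = totals_hat, deconv = dec,
       truth_total = stats::setNames(total, colnames(b_mat)),
       truth_subsets = truth_sub, ref = ref)
}
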