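ref_fixture <- function(seed = 2, n_bg = 100) {
  spec <- synthetic_spec(n_background_cpgs = n_bg, seed = seed)
  ref <- make_reference_profiles(spec)
  sel <- select_subset_markers(ref$beta, ref$annotation,
                               c("HSC", "LMPP", "CMP"),
                               n_hypo = 1, n_hyper = 1)
  panel <- marker_panel("p6", data.frame(
    cpg_id = unlist(lapply(sel, `[[`, "cpg_id")), gene = NA_character_,
    direction = unlist(lapply(sel, `[[`, "direction"))))
  list(ref = ref, panel = panel)
}

test_that("reference atlas entries are per-type means; leukocytes pool with equal group weight", {
  vals <- rbind(cg1 = c(0.2, 0.4, 0.1, 0.2, 0.3, 0.3, 0.3),
                cg2 = c(0.9, 0.9, 0.5, 0.6, 0.1, 0.1, 0.1))
  colnames(vals) <- paste0("s", 1:7)
  ann <- sample_annotation(data.frame(
    sample_id = colnames(vals),
    group = c("HSC", "HSC", "gran", "gran", "gran", "CD4T", "CD4T")))
  panel <- marker_panel("p", data.frame(cpg_id = c("cg1", "cg2"),
                                        gene = NA, direction = "hyper"))
  A <- build_reference(beta_matrix(vals), ann, c("HSC", "leukocytes"), panel)
  expect_equal(unclass(A)["cg1", "HSC"], 0.3)
  # equal weight per group, regardless of group size:
  # gran mean cg1 = 0.2, CD4T mean = 0.3 -> 0.25 (pooled mean would be 0.24)
  expect_equal(unclass(A)["cg1", "leukocytes"], 0.25)
  # cg2: gran mean 0.4, CD4T mean 0.1 -> 0.25 (pooled would be 0.28)
  expect_equal(unclass(A)["cg2", "leukocytes"], 0.25)

  one <- build_reference(beta_matrix(vals), ann, "HSC",
                         marker_panel("p1", data.frame(cpg_id = "cg2",
                                                       gene = NA,
                                                       direction = "hyper")))
  expect_equal(unclass(one)["cg2", "HSC"], 0.9)
  expect_error(build_reference(beta_matrix(vals), ann, c("HSC", "NKT"), panel),
               "NKT")
  bad_panel <- marker_panel("p", data.frame(cpg_id = "cg9", gene = NA,
                                            direction = "hyper"))
  expect_error(build_reference(beta_matrix(vals), ann, "HSC", bad_panel),
               "cg9")
})

test_that("NNLS solves identity and exact-membership cases", {
  sol <- nnls_solve(diag(2), c(0.3, 0.7))
  expect_equal(unname(sol$x), c(0.3, 0.7), tolerance = 1e-12)
  expect_equal(sol$residual_norm, 0, tolerance = 1e-12)

  set.seed(8)
  A <- matrix(runif(18), 6, 3)
  sol <- nnls_solve(A, A[, 2])
  expect_equal(unname(sol$x), c(0, 1, 0), tolerance = 1e-8)
  expect_lt(sol$residual_norm, 1e-10)
})

test_that("NNLS validates inputs", {
  expect_error(nnls_solve(diag(2), c(1, 2, 3)), "dimension mismatch")
  expect_error(nnls_solve(matrix(c(1, NA, 0, 1), 2), c(1, 1)), "non-finite")
})

test_that("NNLS satisfies KKT conditions and matches an independent solver", {
  skip_if_not_installed("pracma")
  for (seed in 1:25) {
    inst <- random_nnls_instance(seed)
    sol <- nnls_solve(inst$A, inst$b)
    expect_true(kkt_holds(inst$A, inst$b, sol$x))
    ref <- pracma::lsqnonneg(inst$A, inst$b)
    expect_equal(unname(sol$x), unname(ref$x), tolerance = 1e-6)
  }
})

test_that("NNLS objective never exceeds the simplex grid-search oracle", {
  for (seed in 1:30) {
    inst <- random_nnls_instance(seed)
    sol <- nnls_solve(inst$A, inst$b)
    expect_lte(sol$residual_norm,
               grid_nnls_objective(inst$A, inst$b, step = 0.01) + 1e-8)
  }
})

test_that("noise-free mixtures of reference columns are recovered exactly", {
  fx <- ref_fixture(seed = 4)
  A <- build_reference(fx$ref$beta, fx$ref$annotation,
                       c("HSC", "LMPP", "CMP", "leukocytes"), fx$panel)
  # pure HSC sample
  r <- deconvolve_sample(A, unclass(A)[, "HSC"])
  expect_equal(unname(r$fractions),
               c(1, 0, 0, 0), tolerance = 1e-8)
  expect_lt(r$residual_norm, 1e-10)
  # two-column 50/50 mix against the closed-form two-column solution
  A2 <- unclass(A)[, c("HSC", "leukocytes")]
  b <- drop(A2 %*% c(0.5, 0.5))
  closed <- drop(solve(crossprod(A2)) %*% crossprod(A2, b))
  r2 <- nnls_solve(A2, b)
  expect_equal(unname(r2$x), unname(closed), tolerance = 1e-10)
  expect_equal(unname(r2$x), c(0.5, 0.5), tolerance = 1e-10)
})

test_that("arbitrary nonnegative compositions are recovered to 1e-8", {
  fx <- ref_fixture(seed = 6)
  A <- build_reference(fx$ref$beta, fx$ref$annotation,
                       c("HSC", "LMPP", "CMP", "leukocytes"), fx$panel)
  set.seed(10)
  for (i in 1:20) {
    p <- runif(4); p <- p / sum(p)
    r <- deconvolve_sample(A, drop(unclass(A) %*% p))
    expect_equal(unname(r$raw_fractions), p, tolerance = 1e-8)
  }
})

test_that("normalization returns proportions summing to 1, raw retained", {
  A <- structure(matrix(c(0.9, 0.1, 0.1, 0.9), 2,
                        dimnames = list(c("cg1", "cg2"), c("X", "Y"))),
                 class = c("reference_atlas", "matrix"))
  b <- c(cg1 = 0.55, cg2 = 0.50)
  r <- deconvolve_sample(A, b, normalize = TRUE)
  expect_equal(sum(r$fractions), 1, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(sum(r$raw_fractions), 1)))
  expect_false(r$degenerate)
  # an observation orthogonal-ish to the atlas with zero fit
  r0 <- deconvolve_sample(A, c(cg1 = 0, cg2 = 0), normalize = TRUE)
  expect_true(all(r0$fractions == 0))
  expect_true(r0$degenerate)
  expect_error(deconvolve_sample(A, c(cg1 = 0.5)), "cg2")
})

test_that("progenitor sums add the named fractions only", {
  r <- structure(list(sample_id = "s", normalized = TRUE,
                      fractions = c(HSC = 0.1, LMPP = 0.2, CMP = 0.3,
                                    leukocytes = 0.4),
                      raw_fractions = NULL, residual_norm = 0,
                      degenerate = FALSE),
                 class = "deconvolution_result")
  expect_equal(sum_progenitor_fractions(r, c("HSC", "LMPP", "CMP")), 0.6)
  expect_equal(sum_progenitor_fractions(r, character(0)), 0)
  expect_equal(sum_progenitor_fractions(r, names(r$fractions)), 1)
  expect_error(sum_progenitor_fractions(r, "MEP"), "MEP")
})

test_that("noisy mixture recovery stays within the frozen error bound", {
  # mean absolute error over seeded mixtures at beta-noise sd 0.02;
  # threshold frozen from the grid-oracle pipeline at < 0.05
  fx <- ref_fixture(seed = 12)
  A <- build_reference(fx$ref$beta, fx$ref$annotation,
                       c("HSC", "LMPP", "CMP", "leukocytes"), fx$panel)
  set.seed(99)
  props <- t(sapply(1:100, function(i) { p <- runif(4); p / sum(p) }))
  mae <- mean(sapply(1:100, function(i) {
    b <- simulate_mixture(A, props[i, ], noise_sd = 0.02, seed = 300 + i)
    r <- deconvolve_sample(A, b)
    mean(abs(r$raw_fractions - props[i, ]))
  }))
  expect_lt(mae, 0.05)
})

test_that("atlas round-trips through its tabular serialization", {
  fx <- ref_fixture(seed = 20, n_bg = 20)
  A <- build_reference(fx$ref$beta, fx$ref$annotation,
                       c("HSC", "LMPP", "CMP", "leukocytes"), fx$panel)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_atlas(A, path)
  back <- read_atlas(path)
  expect_equal(unclass(back), unclass(A)[, , drop = FALSE],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(rownames(back), rownames(A))
})

test_that("batch deconvolution matches per-sample calls", {
  fx <- ref_fixture(seed = 14, n_bg = 20)
  A <- build_reference(fx$ref$beta, fx$ref$annotation,
                       c("HSC", "LMPP", "CMP", "leukocytes"), fx$panel)
  b1 <- simulate_mixture(A, c(0.2, 0.2, 0.2, 0.4), 0.01, seed = 1)
  b2 <- simulate_mixture(A, c(0, 0.1, 0.1, 0.8), 0.01, seed = 2)
  m <- measurement_table(data.frame(
    sample_id = rep(c("a", "b"), each = nrow(A)),
    cpg_id = rep(rownames(A), 2),
    percent_methylation = 100 * c(b1, b2)))
  out <- batch_deconvolve(A, m)
  single <- deconvolve_sample(A, b1)
  expect_equal(unlist(out[1, c("HSC", "LMPP", "CMP", "leukocytes")]),
               single$fractions, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(out$residual_norm[1], single$residual_norm)
})
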