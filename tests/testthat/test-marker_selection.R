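test_that("group statistics match hand-computed means, sds, and delta", {
  fx <- tiny_beta()
  st <- group_stats(fx$beta, fx$ann, "HSPC")
  sep <- st[st$cpg_id == "cg_sep", ]
  expect_equal(sep$mean_target, 0.85)
  expect_equal(sep$mean_rest, 0.15)
  expect_equal(sep$delta, 0.70)
  # sample sd with n-1 denominator: sd(c(0.8, 0.9)) = 0.1/sqrt(2)
  expect_equal(sep$sd_target, 0.1 / sqrt(2), tolerance = 1e-12)
  expect_equal(sep$sd_rest, 0.1 / sqrt(2), tolerance = 1e-12)
  expect_equal(st[st$cpg_id == "cg_flat", "delta"], 0)
})

test_that("extreme separation and identical groups give the boundary stats", {
  vals <- rbind(cg_x = c(1, 1, 0, 0))
  colnames(vals) <- c("t1", "t2", "r1", "r2")
  ann <- sample_annotation(data.frame(sample_id = colnames(vals),
                                      group = c("A", "A", "B", "B")))
  st <- group_stats(beta_matrix(vals), ann, "A")
  expect_equal(st$delta, 1)
  expect_equal(st$sd_target, 0)
  expect_equal(st$sd_rest, 0)
})

test_that("group_stats rejects degenerate group definitions", {
  fx <- tiny_beta()
  expect_error(group_stats(fx$beta, fx$ann, "HSPC", rest_groups = "HSPC"),
               "overlap")
  expect_error(group_stats(fx$beta, fx$ann, "absent"), ">=2")
})

test_that("missing-value policy: complete-case, drop CpGs >20% missing", {
  vals <- rbind(cg_ok = c(0.8, 0.9, NA, 0.1, 0.2, 0.1),
                cg_gone = c(0.8, NA, NA, 0.1, 0.2, 0.3))
  colnames(vals) <- paste0("s", 1:6)
  ann <- sample_annotation(data.frame(
    sample_id = colnames(vals),
    group = rep(c("A", "B"), each = 3)))
  st <- group_stats(beta_matrix(vals), ann, "A", max_missing = 1/3)
  expect_true("cg_ok" %in% st$cpg_id)      # 1/3 missing: kept, complete-case
  expect_false("cg_gone" %in% st$cpg_id)   # 2/3 missing in target: dropped
  expect_equal(st$n_target[st$cpg_id == "cg_ok"], 2)
  expect_equal(st$mean_target[st$cpg_id == "cg_ok"], 0.85)
})

test_that("candidate scores and ordering follow |delta| - w*max(sd)", {
  st <- data.frame(cpg_id = c("cgA", "cgB", "cgC"),
                   mean_target = c(0.95, 0.97, 0.55),
                   mean_rest = c(0.05, 0.02, 0.05),
                   delta = c(0.9, 0.95, 0.5),
                   sd_target = c(0.05, 0.30, 0.01),
                   sd_rest = c(0.02, 0.10, 0.005),
                   n_target = 4, n_rest = 4)
  out <- rank_candidates(st, "hyper", n_top = 3, w = 1)
  expect_equal(out$cpg_id, c("cgA", "cgB", "cgC"))
  expect_equal(out$score, c(0.85, 0.65, 0.49))
  # single-CpG input ranks first whatever its score
  one <- rank_candidates(st[3, ], "both", n_top = 1)
  expect_equal(one$cpg_id, "cgC")
  # over-asking warns and returns everything
  expect_warning(all3 <- rank_candidates(st, "both", n_top = 10), "only 3")
  expect_equal(nrow(all3), 3)
})

test_that("ties break by larger |delta| then lexicographic id", {
  st <- data.frame(cpg_id = c("cgZ", "cgA", "cgB"),
                   mean_target = c(0.9, 0.8, 0.9),
                   mean_rest = c(0.1, 0.1, 0.1),
                   delta = c(0.8, 0.7, 0.8),
                   sd_target = c(0.10, 0.00, 0.10),
                   sd_rest = 0, n_target = 3, n_rest = 3)
  out <- rank_candidates(st, "both", n_top = 3)  # scores: .7, .7, .7
  expect_equal(out$cpg_id, c("cgB", "cgZ", "cgA"))
})

test_that("swapping target and rest negates delta and preserves scores", {
  spec <- synthetic_spec(n_background_cpgs = 50, seed = 7)
  ref <- make_reference_profiles(spec)
  a <- group_stats(ref$beta, ref$annotation, "HSC")
  b <- group_stats(ref$beta, ref$annotation,
                   setdiff(unique(ref$annotation$group), "HSC"),
                   rest_groups = "HSC")
  b <- b[match(a$cpg_id, b$cpg_id), ]
  expect_equal(b$delta, -a$delta, tolerance = 1e-12)
  expect_equal(marker_score(a), marker_score(b), tolerance = 1e-12)
  expect_true(all(abs(a$delta) <= 1))
  expect_true(all(marker_score(a) <= 1))
})

test_that("scores are invariant to sample and CpG row permutations", {
  spec <- synthetic_spec(n_background_cpgs = 30, seed = 11)
  ref <- make_reference_profiles(spec)
  st1 <- group_stats(ref$beta, ref$annotation, "LMPP")
  set.seed(1)
  perm_beta <- beta_matrix(unclass(ref$beta)[sample(nrow(ref$beta)),
                                             sample(ncol(ref$beta))])
  st2 <- group_stats(perm_beta, ref$annotation, "LMPP")
  st2 <- st2[match(st1$cpg_id, st2$cpg_id), ]
  expect_equal(st2$delta, st1$delta, tolerance = 1e-12)
  expect_equal(marker_score(st2), marker_score(st1), tolerance = 1e-12)
})

test_that("planted pan-HSPC markers take the top hypermethylated ranks", {
  # fixture emulating CD34+ HSPCs vs mature leukocyte references, with the
  # packaged 3-CpG panel ids planted as the pan markers
  spec <- synthetic_spec(cell_types = c("HSPC", "granulocytes", "CD4T",
                                        "monocytes"),
                         markers_per_type = c(hyper = 0L, hypo = 0L),
                         pan_groups = "HSPC", n_pan_hyper = 3,
                         n_background_cpgs = 300, seed = 5)
  ref <- make_reference_profiles(spec)
  ref <- rename_cpgs(ref, c("cgP00001", "cgP00002", "cgP00003"),
                     c("cg17707057", "cg00164282", "cg17607231"))
  st <- group_stats(ref$beta, ref$annotation, "HSPC")
  top <- rank_candidates(st, "hyper", n_top = 3)
  expect_setequal(top$cpg_id, c("cg17707057", "cg00164282", "cg17607231"))
})

test_that("subset selection recovers exactly the planted markers per subset", {
  spec <- synthetic_spec(n_background_cpgs = 200, seed = 3)
  ref <- make_reference_profiles(spec)
  subsets <- c("HSC", "LMPP", "CMP")
  sel <- select_subset_markers(ref$beta, ref$annotation, subsets,
                               n_hypo = 3, n_hyper = 3)
  for (s in subsets) {
    planted <- ref$truth$cpg_id[ref$truth$cell_type == s]
    expect_setequal(sel[[s]]$cpg_id, planted)
    expect_equal(sum(sel[[s]]$direction == "hyper"), 3)
    expect_equal(sum(sel[[s]]$direction == "hypo"), 3)
  }
  # 18-CpG design: all distinct across subsets
  all_ids <- unlist(lapply(sel, `[[`, "cpg_id"))
  expect_equal(length(all_ids), 18)
  expect_equal(anyDuplicated(all_ids), 0)
})

test_that("single-subset selection reduces to rank_candidates", {
  spec <- synthetic_spec(n_background_cpgs = 50, seed = 9)
  ref <- make_reference_profiles(spec)
  sel <- select_subset_markers(ref$beta, ref$annotation, "HSC",
                               n_hypo = 2, n_hyper = 2)
  st <- group_stats(ref$beta, ref$annotation, "HSC")
  expect_setequal(sel$HSC$cpg_id[sel$HSC$direction == "hyper"],
                  rank_candidates(st, "hyper", 2)$cpg_id)
  expect_setequal(sel$HSC$cpg_id[sel$HSC$direction == "hypo"],
                  rank_candidates(st, "hypo", 2)$cpg_id)
})

test_that("pareto front is the non-dominated set in (|delta|, max sd)", {
  st <- data.frame(cpg_id = paste0("cg", 1:4),
                   mean_target = 0.5, mean_rest = 0.1,
                   delta = c(0.9, 0.8, 0.7, 0.6),
                   sd_target = c(0.30, 0.10, 0.20, 0.05),
                   sd_rest = 0, n_target = 3, n_rest = 3)
  pf <- pareto_front(st)
  # cg3 dominated by cg2 (lower |delta|, higher sd); others survive
  expect_setequal(pf$cpg_id, c("cg1", "cg2", "cg4"))
})
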