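# Cell-type-specific CpG marker selection.
#
# A candidate marker separates a target cell population from a comparison
# population along two axes: a large difference of group mean beta values and
# a low within-group variation. Selection is made reproducible by the scalar
# score |delta| - w * max(sd_target, sd_rest); the worst-case (larger) group
# sd is used because a marker is unusable if either group is noisy.

.group_idx <- function(beta, ann, groups) {
  ids <- ann$sample_id[ann$group %in% groups]
  match(intersect(colnames(beta), ids), colnames(beta))
}

#' Per-CpG two-group summary statistics
#'
#' For every CpG, computes the mean and sample standard deviation of beta
#' within a target group and within a comparison ("rest") group, plus the
#' difference of means `delta = mean_target - mean_rest`. Hypermethylated
#' markers of the target type have `delta > 0`, hypomethylated ones
#' `delta < 0`.
#'
#' Missing values are handled complete-case per CpG within each group; CpGs
#' missing in more than `max_missing` of either group's samples are dropped
#' before analysis.
#'
#' @param beta a [beta_matrix].
#' @param ann a `sample_annotation`.
#' @param target_group group label(s) forming the target population.
#' @param rest_groups group labels forming the comparison population;
#'   default: every annotated group not in `target_group`.
#' @param max_missing maximum tolerated fraction of missing values per CpG
#'   in either group (default 0.2).
#' @return data.frame with columns cpg_id, mean_target, mean_rest, delta,
#'   sd_target, sd_rest, n_target, n_rest.
#' @export
group_stats <- function(beta, ann, target_group,
                        rest_groups = setdiff(unique(ann$group), target_group),
                        max_missing = 0.2) {
  ti <- .group_idx(beta, ann, target_group)
  ri <- .group_idx(beta, ann, rest_groups)
  if (length(ti) < 2) stop("target group needs >=2 annotated samples in the matrix")
  if (length(ri) < 2) stop("rest group needs >=2 annotated samples in the matrix")
  if (length(intersect(ti, ri)))
    stop("target and rest sample sets overlap: ",
         paste(colnames(beta)[intersect(ti, ri)], collapse = ", "))

  tg <- unclass(beta)[, ti, drop = FALSE]
  rg <- unclass(beta)[, ri, drop = FALSE]
  n_t <- rowSums(!is.na(tg)); n_r <- rowSums(!is.na(rg))
  keep <- (rowMeans(is.na(tg)) <= max_missing) &
          (rowMeans(is.na(rg)) <= max_missing) & n_t >= 2 & n_r >= 2
  tg <- tg[keep, , drop = FALSE]; rg <- rg[keep, , drop = FALSE]
  mt <- rowMeans(tg, na.rm = TRUE); mr <- rowMeans(rg, na.rm = TRUE)
  st <- apply(tg, 1, stats::sd, na.rm = TRUE)
  sr <- apply(rg, 1, stats::sd, na.rm = TRUE)
  data.frame(cpg_id = rownames(tg),
             mean_target = unname(mt), mean_rest = unname(mr),
             delta = unname(mt - mr),
             sd_target = unname(st), sd_rest = unname(sr),
             n_target = unname(n_t[keep]), n_rest = unname(n_r[keep]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Marker score: separation minus worst-case noise
#'
#' `score = |delta| - w * max(sd_target, sd_rest)`. Monotone increasing in
#' the mean difference and decreasing in either group's variation; bounded
#' above by 1 since |delta| <= 1.
#'
#' @param stats data.frame from [group_stats].
#' @param w nonnegative weight on the variation axis (default 1).
#' @return numeric vector of scores.
#' @export
marker_score <- function(stats, w = 1) {
  abs(stats$delta) - w * pmax(stats$sd_target, stats$sd_rest)
}

#' Rank candidate marker CpGs
#'
#' Scores every CpG with [marker_score], filters to the requested direction
#' (hyper: `delta > 0`; hypo: `delta < 0`), sorts by score descending with
#' ties broken by larger |delta| then lexicographic CpG id, and truncates
#' to the top `n_top`. Requesting more candidates than exist returns all
#' of them with a warning.
#'
#' @param stats data.frame from [group_stats].
#' @param direction `"hyper"`, `"hypo"` or `"both"`.
#' @param n_top number of candidates to return.
#' @param w weight on the variation axis (default 1).
#' @return data.frame of candidates: cpg_id, direction, score, plus all
#'   [group_stats] columns, ordered best-first.
#' @export
rank_candidates <- function(stats, direction = c("both", "hyper", "hypo"),
                            n_top = 3L, w = 1) {
  direction <- match.arg(direction)
  if (!nrow(stats)) stop("no CpG statistics supplied")
  if (n_top < 1) stop("n_top must be >= 1")
  cand <- stats
  cand$direction <- ifelse(cand$delta > 0, "hyper", "hypo")
  cand$score <- marker_score(cand, w)
  if (direction != "both") cand <- cand[cand$direction == direction, , drop = FALSE]
  ord <- order(-cand$score, -abs(cand$delta), cand$cpg_id)
  cand <- cand[ord, , drop = FALSE]
  if (n_top > nrow(cand)) {
    warning("requested ", n_top, " candidates but only ", nrow(cand),
            " available; returning all")
    n_top <- nrow(cand)
  }
  out <- cand[seq_len(n_top), c("cpg_id", "direction", "score",
                                setdiff(names(stats), "cpg_id")), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pareto front of candidate CpGs
#'
#' The non-dominated set under (maximize |delta|, minimize
#' max(sd_target, sd_rest)) -- the two selection axes without
#' scalarization, emitted for inspection alongside the scored ranking.
#'
#' @param stats data.frame from [group_stats].
#' @return subset of `stats` on the Pareto front, with columns `abs_delta`
#'   and `max_sd` added, sorted by decreasing |delta|.
#' @export
pareto_front <- function(stats) {
  ad <- abs(stats$delta)
  ms <- pmax(stats$sd_target, stats$sd_rest)
  ord <- order(-ad, ms)
  keep <- logical(length(ord))
  best_sd <- Inf
  for (i in ord) {
    if (ms[i] < best_sd) { keep[i] <- TRUE; best_sd <- ms[i] }
  }
  out <- stats[keep, , drop = FALSE]
  out$abs_delta <- ad[keep]
  out$max_sd <- ms[keep]
  out[order(-out$abs_delta), , drop = FALSE]
}

#' Select subset-specific marker CpGs
#'
#' For each progenitor subset, candidates are scored against the union of
#' all other subsets and all non-subset (leukocyte) groups, and the top
#' `n_hypo` hypomethylated and `n_hyper` hypermethylated CpGs are chosen.
#' A CpG may serve at most one subset: claims are resolved greedily by
#' best score across subsets. Defaults of three CpGs per direction per
#' subset give the 18-CpG design over three subsets.
#'
#' @param beta a [beta_matrix].
#' @param ann a `sample_annotation`.
#' @param subsets character vector of subset group labels (e.g. HSC, LMPP,
#'   CMP).
#' @param n_hypo,n_hyper candidates per direction per subset (default 3).
#' @param w score weight (default 1).
#' @param max_missing per-CpG missingness threshold, see [group_stats].
#' @return named list (one element per subset) of candidate data.frames as
#'   returned by [rank_candidates].
#' @export
select_subset_markers <- function(beta, ann, subsets, n_hypo = 3L, n_hyper = 3L,
                                  w = 1, max_missing = 0.2) {
  all_groups <- unique(ann$group)
  scored <- lapply(subsets, function(s) {
    st <- group_stats(beta, ann, target_group = s,
                      rest_groups = setdiff(all_groups, s),
                      max_missing = max_missing)
    st$direction <- ifelse(st$delta > 0, "hyper", "hypo")
    st$score <- marker_score(st, w)
    st$subset <- s
    st
  })
  pool <- do.call(rbind, scored)
  pool <- pool[order(-pool$score, -abs(pool$delta), pool$cpg_id), , drop = FALSE]

  want <- c(hypo = as.integer(n_hypo), hyper = as.integer(n_hyper))
  taken_cpg <- character(0)
  got <- stats::setNames(
    rep(list(c(hypo = 0L, hyper = 0L)), length(subsets)), subsets)
  keep_rows <- integer(0)
  for (i in seq_len(nrow(pool))) {
    s <- pool$subset[i]; d <- pool$direction[i]; cg <- pool$cpg_id[i]
    if (cg %in% taken_cpg) next
    if (got[[s]][d] >= want[d]) next
    taken_cpg <- c(taken_cpg, cg)
    got[[s]][d] <- got[[s]][d] + 1L
    keep_rows <- c(keep_rows, i)
  }
  sel <- pool[keep_rows, , drop = FALSE]
  out <- lapply(subsets, function(s) {
    x <- sel[sel$subset == s, , drop = FALSE]
    x <- x[order(-x$score), setdiff(names(x), "subset"), drop = FALSE]
    rownames(x) <- NULL
    for (d in c("hypo", "hyper")) {
      n_d <- sum(x$direction == d)
      if (n_d < want[d])
        warning("subset '", s, "': only ", n_d, " ", d,
                "methylated candidate(s) available of ", want[d], " requested")
    }
    x
  })
  stats::setNames(out, subsets)
}
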