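#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Tie-aware rank-based AUROC: the probability that a random positive scores
#' above a random negative, with ties counted half.
#'
#' @param scores numeric scores, higher = more positive.
#' @param positive logical vector.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("auroc: both classes required")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Build a scored-pose table
#'
#' The evaluation container: one row per pose with its complex id, score,
#' RMSD, near-native label and docking rank. Crystal poses are excluded when
#' `drop_crystal = TRUE` (the test-set convention: all evaluated poses come
#' from the docking program).
#'
#' @param table dataset table carrying complex_id, pose_id, rmsd, is_crystal,
#'   dock_rank.
#' @param scores numeric scores aligned with rows.
#' @param cutoff near-native cutoff in Angstrom.
#' @param drop_crystal exclude crystal poses.
#' @return data.frame of class `scored_poses`.
#' @export
scored_poses <- function(table, scores, cutoff = 2.0, drop_crystal = TRUE) {
  stopifnot(nrow(table) == length(scores))
  out <- data.frame(complex_id = table$complex_id, pose_id = table$pose_id,
                    dock_rank = table$dock_rank, is_crystal = table$is_crystal,
                    rmsd = table$rmsd, score = as.numeric(scores),
                    stringsAsFactors = FALSE)
  if (drop_crystal) out <- out[!out$is_crystal, , drop = FALSE]
  if (any(!is.finite(out$score))) stop("scored_poses: non-finite scores")
  out$label <- label_pose(out$rmsd, cutoff)
  class(out) <- c("scored_poses", "data.frame")
  out
}

#' Inter-target metrics: pooled AUROC and Spearman Rs
#'
#' Computed directly over all tested complexes and poses pooled together:
#' AUROC of score against the near-native label, and the Spearman rank
#' correlation between score and RMSD. By the reported sign convention a
#' good method has strongly negative Rs (high scores at low RMSD).
#'
#' @param sets `scored_poses` table.
#' @return named vector (inter_auroc, inter_rs).
#' @export
inter_metrics <- function(sets) {
  pos <- sets$label == "positive"
  if (length(unique(pos)) < 2)
    stop("inter_metrics: pooled poses contain a single class")
  c(inter_auroc = auroc(sets$score, pos),
    inter_rs = stats::cor(sets$score, sets$rmsd, method = "spearman"))
}

#' Intra-target metrics: per-complex AUROC and Rs, averaged
#'
#' The statistic is computed within each complex's pose set and averaged
#' over complexes. Complexes where it is undefined (single class for AUROC;
#' fewer than 3 poses or zero rank variation for Rs) are skipped; their
#' counts are returned as attributes.
#'
#' @param sets `scored_poses` table.
#' @return named vector (intra_auroc, intra_rs) with attributes
#'   `n_skipped_auroc`, `n_skipped_rs`.
#' @export
intra_metrics <- function(sets) {
  by_cx <- split(sets, sets$complex_id)
  aucs <- vapply(by_cx, function(s) {
    pos <- s$label == "positive"
    if (sum(pos) == 0 || sum(!pos) == 0) NA_real_ else auroc(s$score, pos)
  }, numeric(1))
  rss <- vapply(by_cx, function(s) {
    if (nrow(s) < 3 || stats::sd(s$rmsd) == 0 || stats::sd(s$score) == 0)
      return(NA_real_)
    stats::cor(s$score, s$rmsd, method = "spearman")
  }, numeric(1))
  if (all(is.na(aucs))) stop("intra_metrics: no evaluable complex for AUROC")
  out <- c(intra_auroc = mean(aucs, na.rm = TRUE),
           intra_rs = mean(rss, na.rm = TRUE))
  attr(out, "n_skipped_auroc") <- sum(is.na(aucs))
  attr(out, "n_skipped_rs") <- sum(is.na(rss))
  out
}

# deterministic pose order for top-k selection:
# score desc, then dock_rank asc (NA last), then table order
top_k_order <- function(s) {
  dr <- s$dock_rank
  dr[is.na(dr)] <- Inf
  order(-s$score, dr, seq_len(nrow(s)))
}

#' Top-k success rate
#'
#' Fraction of complexes whose k top-scored poses contain at least one pose
#' with RMSD strictly below the cutoff. Score ties are broken by docking
#' rank, then pose order.
#'
#' @param sets `scored_poses` table.
#' @param k number of top poses considered (SR1, SR3, ...).
#' @param cutoff near-native cutoff in Angstrom.
#' @return success rate in [0, 1].
#' @export
success_rate <- function(sets, k = 1, cutoff = 2.0) {
  if (k < 1) stop("success_rate: k must be >= 1")
  ok <- vapply(split(sets, sets$complex_id), function(s) {
    top <- utils::head(top_k_order(s), k)
    any(s$rmsd[top] < cutoff)
  }, logical(1))
  mean(ok)
}

#' Success-rate ceiling
#'
#' Fraction of complexes possessing at least one near-native pose; the upper
#' bound of any top-k success rate.
#'
#' @param sets `scored_poses` table.
#' @param cutoff near-native cutoff in Angstrom.
#' @return fraction in [0, 1].
#' @export
ceiling_rate <- function(sets, cutoff = 2.0) {
  mean(vapply(split(sets, sets$complex_id),
              function(s) any(s$rmsd < cutoff), logical(1)))
}

#' Binding-funnel analysis
#'
#' For each RMSD window [0, w] the Spearman correlation between RMSD and
#' score is computed per complex over the poses falling inside the window
#' and averaged over evaluable complexes (at least 3 poses with rank
#' variation). Windows with no evaluable complex yield NA.
#'
#' @param sets `scored_poses` table.
#' @param windows upper window edges in Angstrom (default 2:10).
#' @return named numeric vector of mean Rs per window.
#' @export
funnel_analysis <- function(sets, windows = 2:10) {
  by_cx <- split(sets, sets$complex_id)
  out <- vapply(windows, function(w) {
    vals <- vapply(by_cx, function(s) {
      s <- s[s$rmsd <= w, , drop = FALSE]
      if (nrow(s) < 3 || stats::sd(s$rmsd) == 0 || stats::sd(s$score) == 0)
        return(NA_real_)
      stats::cor(s$score, s$rmsd, method = "spearman")
    }, numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
  names(out) <- sprintf("rs_0_%d", windows)
  out
}

#' Pool pose sets of one ligand across receptors (ensemble strategy)
#'
#' All docked poses of a ligand across multiple crystal structures are
#' considered as a single set; each pose keeps the RMSD computed in its own
#' receptor, so success is judged on the selected pose's own RMSD.
#' Downstream metrics apply unchanged to the pooled table.
#'
#' @param sets `scored_poses` table.
#' @param ligand_of named map complex_id -> ligand id.
#' @return `scored_poses` table with complex_id replaced by the ligand id.
#' @export
ensemble_pool <- function(sets, ligand_of) {
  miss <- setdiff(unique(sets$complex_id), names(ligand_of))
  if (length(miss) > 0)
    stop("ensemble_pool: no ligand id for complex(es): ",
         paste(utils::head(miss, 5), collapse = ", "))
  sets$complex_id <- unname(ligand_of[sets$complex_id])
  sets
}

#' Bootstrap mean and sd of a docking-power statistic
#'
#' Resamples complexes (never poses) with replacement `n_boot` times,
#' recomputes the statistic on each replicate and returns its mean and
#' standard deviation.
#'
#' @param statistic function taking a `scored_poses` table.
#' @param sets `scored_poses` table (>= 2 complexes).
#' @param n_boot number of replicates (default 1000).
#' @param seed RNG seed.
#' @return named vector (mean, sd).
#' @export
bootstrap_metric <- function(statistic, sets, n_boot = 1000L, seed = 1L) {
  by_cx <- split(sets, sets$complex_id)
  if (length(by_cx) < 2) stop("bootstrap_metric: need >= 2 complexes")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vals <- vapply(seq_len(n_boot), function(b) {
    pick <- sample(length(by_cx), replace = TRUE)
    rep_sets <- do.call(rbind, lapply(seq_along(pick), function(q) {
      s <- by_cx[[pick[q]]]
      s$complex_id <- sprintf("%s_b%d", s$complex_id, q)  # keep copies distinct
      s
    }))
    class(rep_sets) <- class(sets)
    statistic(rep_sets)
  }, numeric(1))
  c(mean = mean(vals), sd = stats::sd(vals))
}

#' Paired comparison of two methods (Wilcoxon signed-rank)
#'
#' Two-sided Wilcoxon signed-rank test on paired per-complex values of two
#' methods; significant at p < 0.05. When every difference is zero the test
#' is degenerate and p = 1 is reported.
#'
#' @param values_a,values_b paired per-complex values (same complexes, same
#'   order).
#' @return list (statistic, p_value, significant).
#' @export
compare_methods <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b))
  d <- values_a - values_b
  if (length(d) < 3)
    warning("compare_methods: only ", length(d),
            " pairs; the test is underpowered")
  if (all(d == 0))
    return(list(statistic = NA_real_, p_value = 1, significant = FALSE))
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b, paired = TRUE,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       significant = wt$p.value < 0.05)
}

#' Full docking-power evaluation report
#'
#' Computes the pooled and per-complex AUROC/Rs, top-k success rates with
#' ceiling, the binding-funnel profile, and bootstrap mean/sd for each
#' success rate.
#'
#' @param sets `scored_poses` table.
#' @param top_k success-rate depths (default 1 and 3).
#' @param cutoff near-native cutoff in Angstrom.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed bootstrap seed.
#' @return list of class `eval_report`.
#' @export
evaluate_report <- function(sets, top_k = c(1, 3), cutoff = 2.0,
                            n_boot = 1000L, seed = 1L) {
  inter <- tryCatch(inter_metrics(sets), error = function(e) c(
    inter_auroc = NA_real_, inter_rs = NA_real_))
  intra <- tryCatch(intra_metrics(sets), error = function(e) c(
    intra_auroc = NA_real_, intra_rs = NA_real_))
  srs <- vapply(top_k, function(k) success_rate(sets, k, cutoff), numeric(1))
  names(srs) <- sprintf("sr%d", top_k)
  boots <- lapply(top_k, function(k)
    bootstrap_metric(function(s) success_rate(s, k, cutoff), sets,
                     n_boot = n_boot, seed = seed))
  names(boots) <- sprintf("sr%d", top_k)
  structure(list(
    n_complexes = length(unique(sets$complex_id)), n_poses = nrow(sets),
    inter = inter, intra = as.numeric(intra) |> stats::setNames(names(intra)),
    n_skipped_auroc = attr(intra, "n_skipped_auroc"),
    n_skipped_rs = attr(intra, "n_skipped_rs"),
    success_rates = srs, ceiling = ceiling_rate(sets, cutoff),
    bootstrap = boots, funnel = funnel_analysis(sets),
    top_k = top_k, cutoff = cutoff, n_boot = n_boot, seed = seed),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d complexes, %d poses\n", x$n_complexes, x$n_poses))
  cat(sprintf("  inter AUROC %.3f, inter Rs %+.3f | intra AUROC %.3f, intra Rs %+.3f\n",
              x$inter["inter_auroc"], x$inter["inter_rs"],
              x$intra["intra_auroc"], x$intra["intra_rs"]))
  for (k in seq_along(x$success_rates))
    cat(sprintf("  %s = %.3f (bootstrap %.3f +/- %.3f)\n",
                names(x$success_rates)[k], x$success_rates[k],
                x$bootstrap[[k]]["mean"], x$bootstrap[[k]]["sd"]))
  cat(sprintf("  ceiling = %.3f\n", x$ceiling))
  invisible(x)
}

#' Write an evaluation report as JSON
#' @param report `eval_report`.
#' @param path output JSON file.
#' @export
write_eval_report <- function(report, path) {
  obj <- list(n_complexes = report$n_complexes, n_poses = report$n_poses,
              inter = as.list(report$inter), intra = as.list(report$intra),
              n_skipped_auroc = report$n_skipped_auroc,
              n_skipped_rs = report$n_skipped_rs,
              success_rates = as.list(report$success_rates),
              ceiling = report$ceiling,
              bootstrap = lapply(report$bootstrap, as.list),
              funnel = as.list(report$funnel),
              cutoff = report$cutoff, n_boot = report$n_boot, seed = report$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
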