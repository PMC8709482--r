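# Modulation statistics: per-participant cell means vs the 20-response
# resting baseline, normality-routed paired tests, Bonferroni correction
# within each muscle x movement x condition family, and R2/R1 ratios.

#' Control baseline from pre- and post-block resting responses
#'
#' Pools the resting control responses recorded before and after a movement
#' block (nominally 10 + 10 = 20), applies the outlier rule
#' ([exclude_outliers()]) to the pooled set, and returns the mean.
#'
#' @param pre_values,post_values Numeric vectors of control R1 amplitudes (mV).
#' @return Baseline mean (mV).
#' @export
control_baseline <- function(pre_values, post_values) {
  if (length(pre_values) == 0 || length(post_values) == 0) {
    stop("both control sets must be non-empty", call. = FALSE)
  }
  pool <- c(pre_values, post_values)
  keep <- exclude_outliers(pool)
  if (!any(keep)) stop("empty control pool after outlier exclusion", call. = FALSE)
  mean(pool[keep])
}

#' Normalize a cell mean to its control baseline
#'
#' @param cell_mean Conditioned-cell mean amplitude (mV).
#' @param baseline Control baseline (mV), must be > 0.
#' @return Percent of control: `100 * cell_mean / baseline` (100 = no
#'   modulation).
#' @export
normalize_to_control <- function(cell_mean, baseline) {
  if (any(baseline <= 0)) stop("baseline must be > 0", call. = FALSE)
  100 * cell_mean / baseline
}

#' Filter second responses
#'
#' R2 is removed (set to `NA`, R1 kept) when the paired R1 peak-to-peak is
#' below the response floor or when R2 > R1, either of which suggests
#' contamination by volitional muscle activation. Adds a logical
#' `r2_retained` column.
#'
#' @param doublets Doublet table with `r1_pp`, `r2_pp`.
#' @param floor_mv Response floor (mV), default 0.02.
#' @return The table with filtered `r2_pp` and `r2_retained` bookkeeping.
#' @export
filter_r2 <- function(doublets, floor_mv = 0.02) {
  drop <- doublets$r1_pp < floor_mv | doublets$r2_pp > doublets$r1_pp
  drop[is.na(drop)] <- TRUE
  doublets$r2_retained <- !drop
  doublets$r2_pp[!doublets$r2_retained] <- NA_real_
  doublets
}

#' Per-pair R2/R1 ratio
#'
#' @param doublet One row of a [filter_r2()]-processed table (vectorized over
#'   rows).
#' @return Ratio in percent: `100 * r2_pp / r1_pp`.
#' @export
r2_r1_ratio <- function(doublet) {
  if (any(!doublet$r2_retained)) {
    stop("r2_r1_ratio called on a doublet removed by filter_r2", call. = FALSE)
  }
  100 * doublet$r2_pp / doublet$r1_pp
}

#' Paired comparison with normality routing
#'
#' Tests per-participant conditioned-cell means against the paired control
#' baselines: the Shapiro-Wilk test is applied to the paired differences; if
#' normality is not rejected (p > 0.05) a two-tailed paired Student's t-test
#' is used, otherwise a two-sided Wilcoxon signed-rank test (exact for small
#' samples without ties, normal approximation with correction otherwise).
#' Constant non-zero differences cannot be assessed for normality and are
#' routed to the Wilcoxon branch; all-zero differences are degenerate with
#' p = 1.
#'
#' @param cell_means Per-participant conditioned means (mV).
#' @param baselines Per-participant control baselines (mV), same order.
#' @param alpha_normality Shapiro-Wilk routing level (default 0.05).
#' @return List: `test_used` (`"t_paired"`, `"wilcoxon"`, `"degenerate"`),
#'   `p_raw`, `shapiro_p`.
#' @export
compare_to_control <- function(cell_means, baselines, alpha_normality = 0.05) {
  stopifnot(length(cell_means) == length(baselines))
  if (length(cell_means) < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- cell_means - baselines
  if (all(d == 0)) {
    return(list(test_used = "degenerate", p_raw = 1, shapiro_p = NA_real_))
  }
  if (stats::sd(d) == 0) {
    w <- suppressWarnings(stats::wilcox.test(cell_means, baselines, paired = TRUE))
    return(list(test_used = "wilcoxon", p_raw = w$p.value, shapiro_p = NA_real_))
  }
  sw <- stats::shapiro.test(d)
  if (sw$p.value > alpha_normality) {
    tt <- stats::t.test(cell_means, baselines, paired = TRUE)
    list(test_used = "t_paired", p_raw = tt$p.value, shapiro_p = sw$p.value)
  } else {
    w <- suppressWarnings(stats::wilcox.test(cell_means, baselines, paired = TRUE))
    list(test_used = "wilcoxon", p_raw = w$p.value, shapiro_p = sw$p.value)
  }
}

#' Bonferroni adjustment
#'
#' @param p_raw Raw p-values in `[0, 1]`.
#' @param m Family size (default: number of p-values supplied).
#' @return `pmin(1, m * p_raw)`.
#' @export
bonferroni_adjust <- function(p_raw, m = length(p_raw)) {
  stopifnot(all(p_raw >= 0 & p_raw <= 1, na.rm = TRUE), m >= 1)
  pmin(1, m * p_raw)
}

cell_mean_after_outliers <- function(x) {
  mean(x[exclude_outliers(x)])
}

#' Full modulation analysis of a multi-participant doublet table
#'
#' Implements the statistical pipeline end-to-end. Per participant and
#' analysis cell (muscle x movement x condition x CTI, or the isometric
#' cell): the cell mean is the average of that participant's conditioned R1
#' responses after outlier exclusion; the paired baseline is
#' [control_baseline()] over the participant's pooled pre/post resting
#' controls of the same block. Cells are then compared across participants
#' with [compare_to_control()], Bonferroni-corrected within each muscle x
#' movement x condition family (the CTIs of that family), and classified as
#' facilitation (significant, > 100% of control) or inhibition (significant,
#' < 100%). R2/R1 ratios are computed per retained pair ([filter_r2()]),
#' averaged per participant and cell, and reported alongside the
#' corresponding control ratio.
#'
#' @param doublets Doublet table with a `participant` column (from
#'   [simulate_experiment()], or [measure_session()] results bound over
#'   participants).
#' @param alpha Significance level after correction (default 0.05).
#' @param floor_mv Response floor for R2 filtering (mV).
#' @param family_size Bonferroni family size; default is the number of cells
#'   in each muscle x movement x condition family.
#' @return Object of class `semp_modulation`: one row per cell with
#'   `normalized_pct`, `r2_r1_pct`, `control_r2_r1_pct`, `test_used`,
#'   `p_raw`, `p_adjusted`, `significant`, `direction`, `n_participants`.
#' @export
analyze_modulation <- function(doublets, alpha = 0.05, floor_mv = 0.02,
                               family_size = NULL) {
  if (is.null(doublets$participant)) doublets$participant <- 1L
  fd <- filter_r2(doublets, floor_mv)
  fd$ratio_pct <- ifelse(fd$r2_retained, 100 * fd$r2_pp / fd$r1_pp, NA_real_)

  cond <- fd[fd$phase %in% c("conditioned", "isometric"), , drop = FALSE]
  ctrl <- fd[fd$phase %in% c("control_pre", "control_post"), , drop = FALSE]
  if (nrow(cond) == 0 || nrow(ctrl) == 0) {
    stop("doublet table needs conditioned and control phases", call. = FALSE)
  }

  cond$cell <- paste(cond$muscle, cond$movement, cond$condition, cond$cti_ms, sep = "|")
  ctrl$block <- paste(ctrl$muscle, ctrl$movement, ctrl$condition, sep = "|")

  # per participant x block baseline (mean of pooled 20 controls after
  # outlier exclusion) and control R2/R1 ratio
  ctrl_key <- paste(ctrl$participant, ctrl$block, sep = "@")
  base_map <- tapply(seq_len(nrow(ctrl)), ctrl_key, function(ii) {
    control_baseline(ctrl$r1_pp[ii][ctrl$phase[ii] == "control_pre"],
                     ctrl$r1_pp[ii][ctrl$phase[ii] == "control_post"])
  })
  ctrl_ratio_map <- tapply(ctrl$ratio_pct, ctrl_key,
                           function(r) mean(r, na.rm = TRUE))

  cells <- unique(cond$cell)
  rows <- lapply(cells, function(cl) {
    cc <- cond[cond$cell == cl, , drop = FALSE]
    parts <- sort(unique(cc$participant))
    cm <- vapply(parts, function(pp)
      cell_mean_after_outliers(cc$r1_pp[cc$participant == pp]), numeric(1))
    block <- paste(cc$muscle[1], cc$movement[1], cc$condition[1], sep = "|")
    bl <- unname(base_map[paste(parts, block, sep = "@")])
    if (any(is.na(bl))) {
      stop("cell ", cl, " lacks control responses for some participants",
           call. = FALSE)
    }
    cmp <- compare_to_control(cm, bl)
    rr <- vapply(parts, function(pp) {
      r <- cc$ratio_pct[cc$participant == pp]
      if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
    }, numeric(1))
    ctrl_rr <- unname(ctrl_ratio_map[paste(parts, block, sep = "@")])
    data.frame(
      muscle = cc$muscle[1], movement = cc$movement[1],
      condition = cc$condition[1], cti_ms = cc$cti_ms[1],
      n_participants = length(parts),
      normalized_pct = normalize_to_control(mean(cm), mean(bl)),
      r2_r1_pct = if (all(is.na(rr))) NA_real_ else mean(rr, na.rm = TRUE),
      control_r2_r1_pct = mean(ctrl_rr, na.rm = TRUE),
      test_used = cmp$test_used, p_raw = cmp$p_raw, shapiro_p = cmp$shapiro_p
    )
  })
  res <- do.call(rbind, rows)

  fam <- paste(res$muscle, res$movement, res$condition, sep = "|")
  res$p_adjusted <- NA_real_
  for (f in unique(fam)) {
    ii <- fam == f
    m <- if (is.null(family_size)) sum(ii) else family_size
    res$p_adjusted[ii] <- bonferroni_adjust(res$p_raw[ii], m)
  }
  res$significant <- res$p_adjusted < alpha
  res$direction <- ifelse(!res$significant, "none",
                          ifelse(res$normalized_pct > 100, "facilitation",
                                 ifelse(res$normalized_pct < 100, "inhibition", "none")))
  ord <- order(res$movement, res$condition, res$muscle, res$cti_ms)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("semp_modulation", "data.frame"))
}
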