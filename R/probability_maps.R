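# Exceedance-probability maps: per muscle x CTI probability that a
# conditioned response exceeds (facilitation) or falls below (inhibition) the
# resting control responses.

exceedance_counts <- function(conditioned, control, mode = c("pairwise", "exceeds_all")) {
  mode <- match.arg(mode)
  if (length(conditioned) == 0 || length(control) == 0) {
    stop("conditioned and control sets must be non-empty", call. = FALSE)
  }
  if (mode == "pairwise") {
    cmp <- outer(conditioned, control, ">")
    n_fac <- sum(cmp)
    n_inh <- sum(outer(conditioned, control, "<"))
    total <- length(conditioned) * length(control)
  } else {
    n_fac <- sum(vapply(conditioned, function(c) all(c > control), logical(1)))
    n_inh <- sum(vapply(conditioned, function(c) all(c < control), logical(1)))
    total <- length(conditioned)
  }
  c(fac = n_fac, inh = n_inh, total = total)
}

#' Exceedance probability of conditioned responses over controls
#'
#' In the default pairwise mode this is the fraction of all (conditioned,
#' control) pairs in which the conditioned response is strictly higher
#' (facilitation) or strictly lower (inhibition) -- the Mann-Whitney U count
#' over the total number of comparisons. The alternative `"exceeds_all"`
#' interpretation counts the conditioned responses that exceed (fall below)
#' every control, over the number of conditioned responses. Ties are counted
#' in neither direction, so facilitation, inhibition, and tie probabilities
#' sum to 1 exactly.
#'
#' @param conditioned,control Non-empty numeric vectors of R1 amplitudes.
#' @param direction `"facilitation"` or `"inhibition"`.
#' @param mode Comparison interpretation.
#' @return A probability in `[0, 1]`.
#' @export
exceedance_probability <- function(conditioned, control,
                                   direction = c("facilitation", "inhibition"),
                                   mode = c("pairwise", "exceeds_all")) {
  direction <- match.arg(direction)
  cnt <- exceedance_counts(conditioned, control, mode)
  unname(cnt[if (direction == "facilitation") "fac" else "inh"] / cnt["total"])
}

#' Build a facilitation/inhibition probability map
#'
#' For one movement x condition block, computes per muscle and CTI (or the
#' single isometric column) the probability that a conditioned R1 response
#' exceeds / falls below the block's resting control responses. Outlier
#' exclusion ([exclude_outliers()]) is applied to each conditioned cell and
#' control pool per participant before comparison; with several participants,
#' comparisons are made within participant and pooled
#' (summed counts over summed comparisons).
#'
#' @param doublets Doublet table (see [analyze_modulation()] for the schema).
#' @param movement,condition Block selectors.
#' @param mode Comparison interpretation, see [exceedance_probability()].
#' @return Object of class `semp_probability_map`: data frame with `muscle`,
#'   `cti_ms` (`NA` for the isometric column), `p_facilitation`,
#'   `p_inhibition`, `p_tie`, `n_comparisons`, and attributes `movement`,
#'   `condition`, `mode`.
#' @export
build_probability_map <- function(doublets, movement, condition,
                                  mode = c("pairwise", "exceeds_all")) {
  mode <- match.arg(mode)
  if (is.null(doublets$participant)) doublets$participant <- 1L
  blk <- doublets[doublets$movement == movement & doublets$condition == condition, , drop = FALSE]
  if (nrow(blk) == 0) stop("no doublets for ", movement, " / ", condition, call. = FALSE)
  cond <- blk[blk$phase %in% c("conditioned", "isometric"), , drop = FALSE]
  ctrl <- blk[blk$phase %in% c("control_pre", "control_post"), , drop = FALSE]

  muscles <- intersect(EMG_CHANNELS, unique(blk$muscle))
  ctis <- sort(unique(cond$cti_ms), na.last = TRUE)
  rows <- list()
  for (mus in muscles) {
    for (cti in ctis) {
      sel <- cond$muscle == mus &
        (if (is.na(cti)) is.na(cond$cti_ms) else !is.na(cond$cti_ms) & cond$cti_ms == cti)
      cc <- cond[sel, , drop = FALSE]
      if (nrow(cc) == 0) next
      n_fac <- n_inh <- n_tot <- 0
      for (pp in sort(unique(cc$participant))) {
        cv <- cc$r1_pp[cc$participant == pp]
        kv <- ctrl$r1_pp[ctrl$muscle == mus & ctrl$participant == pp]
        if (length(kv) == 0) {
          stop(sprintf("cell (%s, %s, %s, cti %s) lacks control responses",
                       mus, movement, condition, cti), call. = FALSE)
        }
        cv <- cv[exclude_outliers(cv)]
        kv <- kv[exclude_outliers(kv)]
        cnt <- exceedance_counts(cv, kv, mode)
        n_fac <- n_fac + cnt["fac"]; n_inh <- n_inh + cnt["inh"]
        n_tot <- n_tot + cnt["total"]
      }
      p_fac <- unname(n_fac / n_tot)
      p_inh <- unname(n_inh / n_tot)
      rows[[length(rows) + 1L]] <- data.frame(
        muscle = mus, cti_ms = cti,
        p_facilitation = p_fac,
        p_inhibition = p_inh,
        # complement form keeps p_fac + p_inh + p_tie == 1 exactly in floats
        p_tie = 1 - (p_fac + p_inh),
        n_comparisons = unname(n_tot)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("semp_probability_map", "data.frame"),
            movement = movement, condition = condition, mode = mode)
}

#' Classify the dominant modulation of a map cell
#'
#' @param p_facilitation,p_inhibition Probabilities (vectorized).
#' @return `"facilitation"`, `"inhibition"`, or `"balanced"` on an exact tie.
#' @export
classify_modulation <- function(p_facilitation, p_inhibition) {
  ifelse(p_facilitation > p_inhibition, "facilitation",
         ifelse(p_inhibition > p_facilitation, "inhibition", "balanced"))
}

#' Write analysis outputs: tables and heatmaps
#'
#' Writes `modulation.csv` (the per-cell test results), `probability_map.csv`
#' (all maps, long format), `significance_summary.csv` (significant cells
#' only, with a `connection_width` column equal to `|normalized_pct - 100|`,
#' the amount of facilitation or inhibition), and a PNG heatmap per map
#' (fill: `p_facilitation - p_inhibition`).
#'
#' @param modulation A [analyze_modulation()] result (or `NULL`).
#' @param maps List of [build_probability_map()] results (or `NULL`).
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
render_outputs <- function(modulation, maps, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir, call. = FALSE)
  written <- character()

  if (!is.null(modulation)) {
    f <- file.path(out_dir, "modulation.csv")
    readr::write_csv(as.data.frame(modulation), f, progress = FALSE, na = "")
    written <- c(written, f)

    sig <- as.data.frame(modulation)[which(modulation$significant), , drop = FALSE]
    sig$connection_width <- abs(sig$normalized_pct - 100)
    f <- file.path(out_dir, "significance_summary.csv")
    readr::write_csv(sig[, c("muscle", "movement", "condition", "cti_ms",
                             "normalized_pct", "direction", "connection_width")],
                     f, progress = FALSE, na = "")
    written <- c(written, f)
  }

  if (!is.null(maps) && length(maps) > 0) {
    long <- do.call(rbind, lapply(maps, function(m) {
      df <- as.data.frame(m)
      df$movement <- attr(m, "movement")
      df$condition <- attr(m, "condition")
      df
    }))
    f <- file.path(out_dir, "probability_map.csv")
    readr::write_csv(long, f, progress = FALSE, na = "")
    written <- c(written, f)

    for (m in maps) {
      df <- as.data.frame(m)
      df$column <- ifelse(is.na(df$cti_ms), "isometric", paste0(df$cti_ms, " ms"))
      df$column <- factor(df$column, levels = unique(df$column))
      df$muscle <- factor(df$muscle, levels = rev(EMG_CHANNELS))
      gg <- ggplot2::ggplot(df, ggplot2::aes(
        x = .data$column, y = .data$muscle,
        fill = .data$p_facilitation - .data$p_inhibition)) +
        ggplot2::geom_tile(color = "grey30") +
        ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                      high = "#b2182b", limits = c(-1, 1),
                                      name = "P(fac) - P(inh)") +
        ggplot2::labs(
          title = sprintf("%s / %s", attr(m, "movement"), attr(m, "condition")),
          x = NULL, y = NULL) +
        ggplot2::theme_minimal()
      f <- file.path(out_dir, sprintf("map_%s_%s.png", attr(m, "movement"),
                                      attr(m, "condition")))
      ggplot2::ggsave(f, gg, width = 5, height = 3.2, dpi = 120)
      written <- c(written, f)
    }
  }
  invisible(written)
}
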