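# Reliability, efficiency, construct validity and reference values.

#' Reliability summary of a scored application
#'
#' Mean SE(theta) and the percentage of persons measured reliably
#' (SE <= `se_threshold`), for the total sample or the subgroup excluding
#' persons at the best-possible-functioning raw-score extreme (the
#' ceiling). The ceiling raw sum is the minimum possible total for
#' symptom-coded measures (higher theta = worse) and the maximum possible
#' total for function-coded measures.
#'
#' @param scores a `score_table` from [eap_score()] or a data frame with
#'   `se_theta` and `raw_sum`.
#' @param n_items item count of the application (carried into the output;
#'   for CAT pass the mean administered).
#' @param exclude_ceiling drop best-functioning-extreme raw sums?
#' @param direction `"symptom"` or `"function"` (sets which raw extreme is
#'   the ceiling).
#' @param max_raw maximum attainable raw sum (needed for
#'   direction = "function"; defaults to the observed maximum).
#' @param se_threshold reliable-measurement bound (default 0.32).
#' @return list with `mean_se`, `pct_reliable`, `n`, `n_items`,
#'   `subgroup` ("total" or "ceiling_excluded").
#' @export
reliability_summary <- function(scores, n_items = NA_real_,
                                exclude_ceiling = FALSE,
                                direction = c("symptom", "function"),
                                max_raw = NULL,
                                se_threshold = 0.32) {
  direction <- match.arg(direction)
  df <- as.data.frame(scores)
  if (exclude_ceiling) {
    ceiling_raw <- if (direction == "symptom") 0 else {
      if (is.null(max_raw)) max(df$raw_sum) else max_raw
    }
    df <- df[df$raw_sum != ceiling_raw, , drop = FALSE]
    if (nrow(df) == 0L) stop("no persons left after ceiling exclusion")
  }
  list(mean_se = mean(df$se_theta),
       pct_reliable = 100 * mean(df$se_theta <= se_threshold),
       n = nrow(df), n_items = n_items,
       subgroup = if (exclude_ceiling) "ceiling_excluded" else "total")
}

#' Per-person measurement efficiency
#'
#' Information delivered per administered item:
#' `E = (1 - SE(theta)^2) / n_items`. An SE above 1 (prior-dominated
#' scores) is floored at zero efficiency with a warning.
#'
#' @param se per-person SE(theta), in (0, 1].
#' @param n_items items administered (scalar or per-person vector, >= 1).
#' @return numeric vector of efficiencies.
#' @export
#' @examples
#' efficiency(0.32, 8)   # 0.1122
efficiency <- function(se, n_items) {
  stopifnot(all(se > 0), all(n_items >= 1))
  if (any(se > 1)) {
    warning(sum(se > 1), " SE value(s) > 1; efficiency floored at 0")
  }
  pmax(1 - se^2, 0) / n_items
}

#' Relative efficiency of two applications with bootstrap CI
#'
#' Ratio of mean per-person efficiencies (application B over A) with a
#' percentile bootstrap over persons. A ratio above 1 means B extracts
#' more information per item than A.
#'
#' @param se_a,se_b per-person SE(theta) of the two applications (same
#'   persons, same order).
#' @param items_a,items_b item counts (scalar or per-person).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for the resampling.
#' @param conf confidence level (default 0.95).
#' @return list with `ratio`, `ci_low`, `ci_high`, `theta_range_a/b`
#'   slots left NA unless supplied via `scores_a/b`, `n`.
#' @export
relative_efficiency <- function(se_a, se_b, items_a, items_b,
                                n_boot = 1000L, seed = 1L, conf = 0.95) {
  if (length(se_a) != length(se_b)) stop("applications must cover the same persons")
  ea <- efficiency(se_a, items_a)
  eb <- efficiency(se_b, items_b)
  ratio <- mean(eb) / mean(ea)
  set.seed(child_seed(seed, "boot"))
  n <- length(ea)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
  boots <- colMeans(matrix(eb[idx], n, n_boot)) /
    colMeans(matrix(ea[idx], n, n_boot))
  qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  list(ratio = ratio, ci_low = qs[1], ci_high = qs[2], n = n,
       n_boot = n_boot)
}

#' Construct-validity hypothesis ledger
#'
#' Checks hypothesized Pearson correlations between instrument scores and
#' legacy-scale scores: a hypothesis is met when |r| exceeds its expected
#' bound (e.g. strong > 0.50, moderate > 0.30). Mismatches are marked in
#' the returned table.
#'
#' @param hypotheses data frame with columns `measure`,
#'   `expected_threshold` (numeric |r| bound) and optionally
#'   `expected_strength`.
#' @param score_list named list (by measure) of paired numeric score
#'   vectors: each element a list/data frame with components `x` and `y`.
#' @return the hypothesis data frame with `observed_r` (|r|), `met`, and
#'   `marked` ("*" where expectation and observation disagree).
#' @export
construct_validity <- function(hypotheses, score_list) {
  out <- hypotheses
  out$observed_r <- NA_real_
  for (i in seq_len(nrow(out))) {
    sc <- score_list[[out$measure[i]]]
    if (is.null(sc)) next
    x <- sc$x; y <- sc$y
    if (length(x) < 3L) stop("need n >= 3 paired scores for ", out$measure[i])
    if (sd(x) == 0 || sd(y) == 0) {
      warning("zero-variance series for ", out$measure[i], "; r undefined")
      next
    }
    out$observed_r[i] <- abs(cor(x, y))
  }
  out$met <- !is.na(out$observed_r) &
    out$observed_r > out$expected_threshold
  out$marked <- ifelse(is.na(out$observed_r) | out$met, "", "*")
  out
}

#' Reference-value table by demographic subgroup
#'
#' Mean (SD) T-scores with subgroup sizes, for the total reference sample
#' and any requested covariate splits. Single-item measures scored
#' without an IRT model can be summarized by passing their raw scores
#' through `t_scores` with `label_prefix` describing the scale.
#'
#' @param t_scores numeric vector of T-scores (or raw single-item
#'   scores).
#' @param covariates data frame aligned with `t_scores`.
#' @param grouping character vector of covariate columns to split by
#'   (besides the total row).
#' @param mean_se_theta optional mean SE(theta) to attach to the total
#'   row (reported in T units, 10 x SE(theta), in formatted output).
#' @return data frame with `group`, `level`, `n`, `mean_t`, `sd_t`.
#' @export
reference_values <- function(t_scores, covariates = NULL, grouping = character(),
                             mean_se_theta = NA_real_) {
  rows <- list(data.frame(group = "total", level = "all",
                          n = length(t_scores), mean_t = mean(t_scores),
                          sd_t = sd(t_scores), stringsAsFactors = FALSE))
  for (g in grouping) {
    f <- as.factor(covariates[[g]])
    for (lv in levels(f)) {
      sel <- f == lv
      if (!any(sel)) next            # empty subgroup omitted
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, level = lv, n = sum(sel), mean_t = mean(t_scores[sel]),
        sd_t = sd(t_scores[sel]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "mean_se_theta") <- mean_se_theta
  attr(out, "mean_se_t_display") <- 10 * mean_se_theta
  out
}

#' Score the same responses under two calibration versions
#'
#' Scores identical response data under two anchor parameter sets /
#' item subsets (e.g. a current and a legacy instrument version) and
#' compares the resulting score distributions and precisions. When a
#' subset omits administered items the output is flagged provisional.
#'
#' @param responses persons x items matrix for the full administered bank.
#' @param anchor_a,anchor_b lists with components `params`
#'   ([item_parameters()] for the full bank on that version's metric) and
#'   `items` (column indices scored under that version).
#' @param grid a [quadrature_grid()].
#' @return list with `scores_a`, `scores_b` (score tables), `summary`
#'   (data frame per version: n_items, mean_t, sd_t, mean_se_theta),
#'   `provisional` flags (TRUE when a version drops items).
#' @export
version_crosswalk <- function(responses, anchor_a, anchor_b,
                              grid = quadrature_grid()) {
  responses <- as.matrix(responses)
  score_version <- function(anchor) {
    items <- anchor$items
    if (length(items) == 0L) stop("empty item subset")
    stopifnot(all(items >= 1L), all(items <= ncol(responses)))
    eap_score(responses[, items, drop = FALSE],
              subset_items(anchor$params, items), grid)
  }
  sa <- score_version(anchor_a)
  sb <- score_version(anchor_b)
  summ <- data.frame(
    version = c("a", "b"),
    n_items = c(length(anchor_a$items), length(anchor_b$items)),
    mean_t = c(mean(sa$t_score), mean(sb$t_score)),
    sd_t = c(sd(sa$t_score), sd(sb$t_score)),
    mean_se_theta = c(mean(sa$se_theta), mean(sb$se_theta)),
    stringsAsFactors = FALSE)
  list(scores_a = sa, scores_b = sb, summary = summ,
       provisional = c(a = length(anchor_a$items) < ncol(responses),
                       b = length(anchor_b$items) < ncol(responses)))
}
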