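# Post-hoc computerized adaptive testing: each person's stored full-bank
# responses are replayed through an adaptive administration with maximum
# posterior weighted information (MPWI) item selection and EAP scoring.

#' CAT configuration
#'
#' @param se_stop SE(theta) stopping threshold (default 0.32,
#'   corresponding to reliability >= 0.90).
#' @param min_items minimum items before the SE rule can stop the test
#'   (default 4).
#' @param max_items maximum items administered (typically the short-form
#'   length).
#' @param selection item selection rule; only `"MPWI"` is implemented.
#' @param estimator trait estimator; only `"EAP"` is implemented.
#' @return a `cat_config` list.
#' @export
cat_config <- function(se_stop = 0.32, min_items = 4L, max_items,
                       selection = "MPWI", estimator = "EAP") {
  stopifnot(se_stop >= 0, min_items >= 1L, max_items >= min_items)
  selection <- match.arg(selection, "MPWI")
  estimator <- match.arg(estimator, "EAP")
  structure(list(se_stop = se_stop, min_items = as.integer(min_items),
                 max_items = as.integer(max_items), selection = selection,
                 estimator = estimator), class = "cat_config")
}

#' Replay one response pattern through a post-hoc CAT
#'
#' The first item maximizes item information at theta = 0; each subsequent
#' item maximizes the posterior-weighted information
#' `integral I_j(theta) posterior(theta) d theta` over unadministered
#' items (ties broken by lowest item index, so replays are
#' deterministic). Responses are read from the stored row. The test stops
#' when SE(theta) <= `se_stop` once at least `min_items` have been given,
#' or at `max_items`.
#'
#' @param response_row integer vector of the person's full-bank responses
#'   (0..K-1).
#' @param params [item_parameters()] for the bank.
#' @param config a [cat_config()].
#' @param grid a [quadrature_grid()] (shared by selection and scoring).
#' @return a `cat_trace` list: `administered` (ordered item indices),
#'   `interim` (data frame step, item, theta_hat, se), `final_theta`,
#'   `final_se`, `n_items`, `stop_reason` ("se_met" or "max_items").
#' @export
run_cat <- function(response_row, params, config, grid = quadrature_grid()) {
  J <- n_items(params)
  if (J < config$min_items) stop("bank smaller than min_items")
  response_row <- as.integer(response_row)
  stopifnot(length(response_row) == J)
  nodes <- grid$nodes
  info <- vapply(seq_len(J), function(j) {
    item_information(params$alpha[j], params$betas[[j]], nodes)
  }, numeric(length(nodes)))             # Q x J
  logp <- .log_prob_tables(params, nodes)
  log_post <- log(grid$weights)
  administered <- integer(0)
  interim <- data.frame(step = integer(0), item = integer(0),
                        theta_hat = numeric(0), se = numeric(0))
  # first item: most information at theta = 0
  i0 <- which.min(abs(nodes))
  repeat {
    remaining <- setdiff(seq_len(J), administered)
    if (length(administered) == 0L) {
      crit <- info[i0, remaining]
    } else {
      post <- exp(log_post - max(log_post))
      post <- post / sum(post)
      crit <- as.numeric(post %*% info[, remaining, drop = FALSE])
    }
    nxt <- remaining[which.max(crit)]   # which.max takes the first maximum
    administered <- c(administered, nxt)
    log_post <- log_post + logp[[nxt]][, response_row[nxt] + 1L]
    post <- exp(log_post - max(log_post)); post <- post / sum(post)
    th <- sum(post * nodes)
    se <- sqrt(max(sum(post * nodes^2) - th^2, 0))
    interim <- rbind(interim, data.frame(step = length(administered),
                                         item = nxt, theta_hat = th, se = se))
    if (length(administered) >= config$min_items && se <= config$se_stop) {
      stop_reason <- "se_met"; break
    }
    if (length(administered) >= config$max_items) {
      stop_reason <- "max_items"; break
    }
  }
  structure(list(administered = administered, interim = interim,
                 final_theta = th, final_se = se,
                 n_items = length(administered), stop_reason = stop_reason),
            class = "cat_trace")
}

#' Batch post-hoc CAT over a response matrix
#'
#' Runs [run_cat()] for every person and summarizes the administration:
#' the per-person table carries items used, final trait estimate and SE;
#' the summary reports mean SE(theta), the percentage of reliable
#' measurements (SE <= `se_stop`), and the mean number of items. The
#' replay is fully deterministic.
#'
#' @param responses persons x items matrix (0..K-1).
#' @param params [item_parameters()] for the bank.
#' @param config a [cat_config()].
#' @param grid a [quadrature_grid()].
#' @return list with `table` (data frame person_id, n_items, final_theta,
#'   final_se, t_score, stop_reason), `summary` (mean_se, pct_reliable,
#'   mean_items), `traces` (list of `cat_trace`).
#' @export
batch_cat <- function(responses, params, config, grid = quadrature_grid()) {
  responses <- as.matrix(responses)
  traces <- lapply(seq_len(nrow(responses)), function(i) {
    run_cat(responses[i, ], params, config, grid)
  })
  ids <- rownames(responses)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(responses)))
  tab <- data.frame(
    person_id = ids,
    n_items = vapply(traces, function(tr) tr$n_items, 0L),
    final_theta = vapply(traces, function(tr) tr$final_theta, 0),
    final_se = vapply(traces, function(tr) tr$final_se, 0),
    stop_reason = vapply(traces, function(tr) tr$stop_reason, ""),
    stringsAsFactors = FALSE)
  tab$t_score <- 50 + 10 * tab$final_theta
  list(table = tab,
       summary = list(mean_se = mean(tab$final_se),
                      pct_reliable = 100 * mean(tab$final_se <= config$se_stop),
                      mean_items = mean(tab$n_items)),
       traces = traces)
}

#' Write CAT traces as JSON lines
#' @param traces list of `cat_trace` objects.
#' @param path output file (one JSON object per person per line).
#' @return the path, invisibly.
#' @export
write_cat_traces <- function(traces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in traces) {
    writeLines(jsonlite::toJSON(list(
      administered = tr$administered,
      theta = tr$interim$theta_hat, se = tr$interim$se,
      final_theta = tr$final_theta, final_se = tr$final_se,
      n_items = tr$n_items, stop_reason = tr$stop_reason
    ), auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
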