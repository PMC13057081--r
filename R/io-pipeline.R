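# File I/O and the stage-per-stage evaluation pipeline: assumptions ->
# GRM calibration -> item fit -> construct validity -> reliability / CAT /
# efficiency -> DIF -> reference values, per measure.

#' Read a response matrix from CSV
#'
#' Expects a header row with `person_id`, the item columns, and optional
#' covariate columns. Categories may be stored 0-based or 1-based
#' (`category_base`); they are re-based to 0..K-1 on read. Out-of-range
#' or non-integer categories are rejected with the offending cell named.
#'
#' @param path CSV path (UTF-8, comma-separated).
#' @param item_columns character vector naming the item columns; defaults
#'   to every column except `person_id` and `covariate_columns`.
#' @param covariate_columns character vector of covariate columns.
#' @param category_base 0 or 1 (default 0).
#' @param n_categories optional per-item (or scalar) category count for
#'   range validation.
#' @return list with `responses` (integer matrix, 0-based),
#'   `covariates` (data frame), `person_id`.
#' @export
read_responses <- function(path, item_columns = NULL,
                           covariate_columns = character(),
                           category_base = 0L, n_categories = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"person_id" %in% names(df)) stop("missing person_id column")
  if (is.null(item_columns)) {
    item_columns <- setdiff(names(df), c("person_id", covariate_columns))
  }
  miss <- setdiff(item_columns, names(df))
  if (length(miss)) stop("item column(s) not found: ", paste(miss, collapse = ", "))
  X <- as.matrix(df[item_columns])
  storage.mode(X) <- "numeric"
  X <- X - category_base
  for (j in seq_along(item_columns)) {
    x <- X[, j]
    kmax <- if (is.null(n_categories)) Inf else
      (if (length(n_categories) == 1L) n_categories else n_categories[j]) - 1
    bad <- which(!is.na(x) & (x < 0 | x > kmax | x != floor(x)))
    if (length(bad)) {
      stop("invalid category at row ", bad[1], ", column '",
           item_columns[j], "' (value ", x[bad[1]] + category_base, ")")
    }
  }
  storage.mode(X) <- "integer"
  list(responses = X, covariates = df[covariate_columns],
       person_id = as.character(df$person_id))
}

#' Write a response matrix (plus covariates) to CSV
#'
#' @param responses integer matrix (0-based categories).
#' @param path output path.
#' @param covariates optional aligned data frame.
#' @param person_id optional id vector.
#' @param category_base base used on disk (default 0).
#' @return the path, invisibly.
#' @export
write_responses <- function(responses, path, covariates = NULL,
                            person_id = NULL, category_base = 0L) {
  responses <- as.matrix(responses)
  if (is.null(person_id)) person_id <- as.character(seq_len(nrow(responses)))
  df <- data.frame(person_id = person_id, responses + category_base,
                   check.names = FALSE)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    df <- cbind(df, as.data.frame(covariates))
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Evaluate one measure end to end
#'
#' Runs the evaluation stages in order for a single measure:
#' assumption checks, GRM calibration, S-X2 item fit, reliability (total
#' and ceiling-excluded), post-hoc CAT, efficiency comparisons, the DIF
#' scan (with impact re-estimation when items are flagged), and — when a
#' legacy scale or hypothesis is supplied — construct validity.
#' Single-item measures are routed to descriptive summaries only.
#'
#' @param responses persons x items matrix (0..K-1).
#' @param covariates data frame of grouping covariates (for DIF).
#' @param direction `"symptom"` or `"function"`.
#' @param short_form integer indices of the short-form subset (also the
#'   CAT maximum length); default: all items.
#' @param dif_covariates covariate names to scan (default: all columns).
#' @param anchor optional [item_parameters()] used for T-scores in
#'   construct validity / reference values (locally fitted parameters are
#'   used for everything else).
#' @param legacy optional list with `scores` (0-100 legacy scale scores)
#'   and `expected_threshold` for the construct-validity check.
#' @param grid quadrature grid.
#' @param seed seed for the efficiency bootstrap.
#' @param se_threshold reliable-measurement bound (default 0.32).
#' @param dif_threshold McFadden R2 flag threshold (default 0.02).
#' @param n_boot bootstrap resamples (default 1000).
#' @return an `evaluation_report` list with one element per stage.
#' @export
evaluate_measure <- function(responses, covariates = NULL,
                             direction = "symptom", short_form = NULL,
                             dif_covariates = NULL, anchor = NULL,
                             legacy = NULL, grid = quadrature_grid(),
                             seed = 1L, se_threshold = 0.32,
                             dif_threshold = 0.02, n_boot = 1000L) {
  responses <- as.matrix(responses)
  J <- ncol(responses)
  report <- list(n_persons = nrow(responses), n_items = J,
                 direction = direction)
  if (J == 1L) {
    report$descriptive <- list(mean = mean(responses), sd = sd(responses))
    if (!is.null(legacy)) {
      hyp <- data.frame(measure = "measure",
                        expected_threshold = legacy$expected_threshold)
      report$construct_validity <- construct_validity(
        hyp, list(measure = list(x = as.numeric(responses), y = legacy$scores)))
    }
    class(report) <- "evaluation_report"
    return(report)
  }
  if (is.null(short_form)) short_form <- seq_len(J)

  # stage 1: assumptions
  poly <- polychoric_matrix(responses)
  sf <- single_factor_fit(poly$rho, nrow(responses))
  report$assumptions <- list(
    single_factor = sf,
    residuals = residual_correlations(poly$rho, sf$loadings),
    bifactor = if (J >= 6L) bifactor_indices(poly$rho) else NULL,
    mokken = mokken_coefficients(responses),
    monotonicity = monotonicity_check(responses),
    iio = iio_ht(responses))

  # stage 2: GRM calibration (local parameters); downstream stages use the
  # calibration's category coding
  fit <- fit_grm(responses, grid)
  responses <- apply_category_maps(responses, fit$category_maps)
  report$grm <- list(params = fit$params, log_lik = fit$log_lik,
                     converged = fit$converged,
                     category_maps = fit$category_maps)

  # stage 3: item fit
  report$item_fit <- sx2_item_fit(fit$params, responses, grid)

  # stage 4: scoring and reliability
  scores <- eap_score(responses, fit$params, grid)
  max_raw <- sum(n_categories(fit$params) - 1L)
  report$scores <- scores
  report$reliability <- list(
    bank_total = reliability_summary(scores, J, FALSE, direction,
                                     max_raw, se_threshold),
    bank_no_ceiling = reliability_summary(scores, J, TRUE, direction,
                                          max_raw, se_threshold))
  report$marginal_reliability <- marginal_reliabilities(fit$params, scores, grid)
  report$information <- information_profile(fit$params)

  # short form
  sf_params <- subset_items(fit$params, short_form)
  sf_scores <- eap_score(responses[, short_form, drop = FALSE], sf_params, grid)
  report$short_form <- list(
    items = short_form,
    reliability = reliability_summary(sf_scores, length(short_form),
                                      FALSE, direction,
                                      se_threshold = se_threshold))

  # stage 5: post-hoc CAT
  cat_res <- batch_cat(responses, fit$params,
                       cat_config(se_stop = se_threshold,
                                  max_items = length(short_form)), grid)
  report$cat <- cat_res[c("table", "summary")]

  # efficiency: CAT vs full bank, short form vs full bank
  report$efficiency <- list(
    cat_vs_bank = relative_efficiency(scores$se_theta, cat_res$table$final_se,
                                      J, cat_res$table$n_items,
                                      n_boot = n_boot, seed = seed),
    short_vs_bank = relative_efficiency(scores$se_theta, sf_scores$se_theta,
                                        J, length(short_form),
                                        n_boot = n_boot,
                                        seed = child_seed(seed, "sf")),
    theta_range = range(scores$theta_hat))

  # stage 6: DIF
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    if (is.null(dif_covariates)) dif_covariates <- names(covariates)
    difs <- list()
    flagged <- integer(0)
    for (cv in dif_covariates) {
      res <- tryCatch(
        dif_scan(responses, scores$theta_hat, covariates[[cv]],
                 threshold = dif_threshold),
        error = function(e) e)
      if (inherits(res, "error")) next
      difs[[cv]] <- res
      flagged <- union(flagged,
                       which(report$grm$params$item_names %in%
                               res$by_item$item[res$by_item$flag_any_pairwise]))
    }
    report$dif <- list(scans = difs, flagged_items = sort(flagged))
    if (length(flagged) && J - length(flagged) >= 3L) {
      report$dif$impact <- dif_impact(responses, sort(flagged), grid,
                                      se_threshold)
      report$dif$cat_exposure <- dif_cat_exposure(cat_res$traces, fit$params,
                                                  sort(flagged))
    }
  }

  # construct validity against a legacy scale
  if (!is.null(legacy)) {
    t_for_validity <- if (!is.null(anchor)) {
      eap_score(responses, anchor, grid)$t_score
    } else scores$t_score
    hyp <- data.frame(measure = "measure",
                      expected_threshold = legacy$expected_threshold)
    report$construct_validity <- construct_validity(
      hyp, list(measure = list(x = t_for_validity, y = legacy$scores)))
  }
  class(report) <- "evaluation_report"
  report
}

#' Run the full evaluation pipeline for a study
#'
#' Applies [evaluate_measure()] to each measure of a study configuration
#' and, when a reference-sample definition is present, computes reference
#' values from the anchored T-scores. Artifacts (parameter JSON, score
#' CSVs, report JSON) are written under `out_dir` when given. Stage
#' failures abort the dependent stages for that measure but not the other
#' measures.
#'
#' @param config list with elements `measures` (named list; each measure a
#'   list with `responses`, plus optional `covariates`, `direction`,
#'   `short_form`, `anchor`, `legacy`), optional `reference` (list with
#'   `margins`, `n_target`, `max_deviation`, `grouping`), `seed`,
#'   `se_threshold`, `dif_threshold`, `n_boot`.
#' @param out_dir optional output directory.
#' @return named list of `evaluation_report`s, plus `reference_values`
#'   when configured.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  seed <- if (is.null(config$seed)) 1L else config$seed
  se_thr <- if (is.null(config$se_threshold)) 0.32 else config$se_threshold
  dif_thr <- if (is.null(config$dif_threshold)) 0.02 else config$dif_threshold
  n_boot <- if (is.null(config$n_boot)) 1000L else config$n_boot
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  reports <- list()
  for (nm in names(config$measures)) {
    m <- config$measures[[nm]]
    rep_m <- tryCatch(
      evaluate_measure(
        m$responses, covariates = m$covariates,
        direction = if (is.null(m$direction)) "symptom" else m$direction,
        short_form = m$short_form, anchor = m$anchor, legacy = m$legacy,
        seed = child_seed(seed, nm), se_threshold = se_thr,
        dif_threshold = dif_thr, n_boot = n_boot),
      error = function(e) {
        warning("measure '", nm, "' failed: ", conditionMessage(e))
        structure(list(error = conditionMessage(e)),
                  class = "evaluation_report")
      })
    reports[[nm]] <- rep_m
    if (!is.null(out_dir) && is.null(rep_m$error)) {
      if (!is.null(rep_m$grm)) {
        write_item_parameters(rep_m$grm$params,
                              file.path(out_dir, paste0(nm, "_params.json")))
        write_scores(rep_m$scores, file.path(out_dir, paste0(nm, "_scores.csv")))
        write.csv(rep_m$item_fit, file.path(out_dir, paste0(nm, "_itemfit.csv")),
                  row.names = FALSE)
      }
    }
  }
  out <- list(measures = reports)
  if (!is.null(config$reference)) {
    rf <- config$reference
    pool <- rf$persons
    drawn <- draw_reference_sample(pool, rf$margins,
                                   n_target = rf$n_target,
                                   max_deviation = if (is.null(rf$max_deviation))
                                     0.025 else rf$max_deviation)
    out$reference_sample <- drawn
    refvals <- list()
    for (nm in names(config$measures)) {
      m <- config$measures[[nm]]
      if (is.null(reports[[nm]]$scores)) next
      sel <- rownames(pool) %in% rownames(drawn$sample)
      t_ref <- if (!is.null(m$anchor)) {
        eap_score(m$responses[sel, , drop = FALSE], m$anchor)$t_score
      } else reports[[nm]]$scores$t_score[sel]
      refvals[[nm]] <- reference_values(
        t_ref, covariates = m$covariates[sel, , drop = FALSE],
        grouping = if (is.null(rf$grouping)) character() else rf$grouping,
        mean_se_theta = mean(reports[[nm]]$scores$se_theta[sel]))
    }
    out$reference_values <- refvals
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(.report_summary(out),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}

# compact, JSON-friendly view of the pipeline output
.report_summary <- function(out) {
  lapply(out$measures, function(r) {
    if (!is.null(r$error)) return(list(error = r$error))
    s <- list(n_persons = r$n_persons, n_items = r$n_items)
    if (!is.null(r$assumptions)) {
      a <- r$assumptions
      s$assumptions <- list(
        cfi = a$single_factor$cfi, tli = a$single_factor$tli,
        rmsea = a$single_factor$rmsea, srmr = a$single_factor$srmr,
        residual_flags = a$residuals$label,
        ecv = if (!is.null(a$bifactor)) a$bifactor$ecv else NA,
        omega_h = if (!is.null(a$bifactor)) a$bifactor$omega_h else NA,
        H = a$mokken$H, HT = a$iio$HT, ht_band = a$iio$band)
    }
    if (!is.null(r$reliability)) {
      s$reliability <- list(
        mean_se = r$reliability$bank_total$mean_se,
        pct_reliable = r$reliability$bank_total$pct_reliable,
        pct_reliable_no_ceiling = r$reliability$bank_no_ceiling$pct_reliable)
    }
    if (!is.null(r$cat)) s$cat <- r$cat$summary
    if (!is.null(r$dif)) s$dif_flagged <- r$dif$flagged_items
    if (!is.null(r$item_fit)) s$items_misfit <- sum(r$item_fit$misfit, na.rm = TRUE)
    s
  })
}
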