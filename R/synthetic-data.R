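# Synthetic-data generator: item banks, latent traits with a ceiling
# component, GRM responses with injectable DIF, a correlated 0-100 legacy
# instrument, and a demographically stratified reference subsample. Every
# generated object carries known ground truth so the evaluation pipeline
# can be tested against it.

#' Specification of a synthetic item bank
#'
#' @param n_items number of items (>= 1).
#' @param n_categories response categories per item (>= 2; 5 for typical
#'   never/almost-never/sometimes/often/almost-always scales).
#' @param alpha_range range (strictly positive pair) that discriminations
#'   are drawn from uniformly.
#' @param threshold_span pair giving the lowest and highest threshold in
#'   the bank; item threshold sets are spread across this span.
#' @param short_form_items 1-based indices of the short-form subset.
#' @param version_subsets named list of 1-based index vectors (e.g. a
#'   `"v2.0"` subset of the administered bank).
#' @param direction `"symptom"` (higher theta = worse functioning) or
#'   `"function"` (higher theta = better functioning).
#' @return a `bank_spec` list.
#' @export
bank_spec <- function(n_items, n_categories = 5L,
                      alpha_range = c(1.2, 2.8),
                      threshold_span = c(-2.2, 2.8),
                      short_form_items = NULL, version_subsets = list(),
                      direction = c("symptom", "function")) {
  direction <- match.arg(direction)
  stopifnot(n_items >= 1L, n_categories >= 2L,
            length(alpha_range) == 2L, all(alpha_range > 0),
            alpha_range[2] >= alpha_range[1],
            length(threshold_span) == 2L,
            threshold_span[2] >= threshold_span[1])
  subsets <- c(list(short_form = short_form_items), version_subsets)
  for (s in subsets) {
    if (!is.null(s) && (any(s < 1L) || any(s > n_items))) {
      stop("item subsets must index items 1..", n_items)
    }
  }
  structure(list(n_items = as.integer(n_items),
                 n_categories = as.integer(n_categories),
                 alpha_range = alpha_range, threshold_span = threshold_span,
                 short_form_items = short_form_items,
                 version_subsets = version_subsets, direction = direction),
            class = "bank_spec")
}

#' Generate an item bank with known parameters
#'
#' Discriminations are drawn uniformly from `alpha_range`; each item's
#' K-1 thresholds are centred at item locations spread evenly over
#' `threshold_span` with jittered, strictly increasing spacings.
#'
#' @param spec a [bank_spec()].
#' @param seed integer seed; identical spec + seed reproduce the bank.
#' @return an [item_parameters()] object with attribute `"spec"`.
#' @export
generate_item_bank <- function(spec, seed) {
  stopifnot(inherits(spec, "bank_spec"))
  set.seed(child_seed(seed, "bank"))
  J <- spec$n_items; K <- spec$n_categories
  alpha <- runif(J, spec$alpha_range[1], spec$alpha_range[2])
  span <- spec$threshold_span
  centers <- if (J == 1L) mean(span) else seq(span[1], span[2], length.out = J)
  # random-but-ordered spacings around each center; degenerate span
  # collapses every threshold to the center
  width <- (span[2] - span[1]) / 2
  betas <- lapply(seq_len(J), function(j) {
    if (K == 2L) return(centers[j])
    off <- seq(-0.45, 0.45, length.out = K - 1L) * min(width, 2.4)
    jit <- runif(K - 1L, -0.08, 0.08) * min(width, 1)
    b <- sort(centers[j] + off + jit)
    b + cumsum(c(0, pmax(0, 1e-3 - diff(b))))
  })
  # rescale the bank so the extreme thresholds sit exactly on the span
  # (threshold_span is a contract: lowest/highest beta in the bank)
  if (width > 0) {
    lo <- min(unlist(betas)); hi <- max(unlist(betas))
    betas <- lapply(betas, function(b) {
      span[1] + (b - lo) * (span[2] - span[1]) / (hi - lo)
    })
  }
  # permute item order so bank position does not encode difficulty
  ord <- sample.int(J)
  params <- item_parameters(alpha[ord], betas[ord],
                            paste0("syn", seq_len(J)))
  attr(params, "spec") <- spec
  params
}

#' Specification of a synthetic respondent population
#'
#' @param n_persons number of respondents.
#' @param theta_distribution `list(kind = "normal", mean, sd)` or
#'   `list(kind = "skewed", shape)` (skew-normal, standardized to mean 0 /
#'   SD 1 before the ceiling component is added).
#' @param ceiling_mass proportion of persons relocated to a narrow
#'   best-possible-functioning component (mean 2.5 prior SDs toward the
#'   best-functioning extreme, SD 0.25), emulating the raw-score ceiling
#'   seen in general-population samples.
#' @param best_direction `"low"` if low theta is best functioning (symptom
#'   coded measures) or `"high"` (function coded).
#' @param covariate_margins named list; each element a named numeric vector
#'   of category proportions summing to 1 (e.g.
#'   `list(child_sex = c(male = .51, female = .49))`).
#' @return a `population_spec` list.
#' @export
population_spec <- function(n_persons,
                            theta_distribution = list(kind = "normal",
                                                      mean = 0, sd = 1),
                            ceiling_mass = 0,
                            best_direction = c("low", "high"),
                            covariate_margins = list()) {
  best_direction <- match.arg(best_direction)
  stopifnot(n_persons >= 1L, ceiling_mass >= 0, ceiling_mass <= 1)
  for (nm in names(covariate_margins)) {
    m <- covariate_margins[[nm]]
    if (any(m < 0) || any(m > 1) || abs(sum(m) - 1) > 1e-8) {
      stop("margins for covariate '", nm, "' must lie in [0,1] and sum to 1")
    }
  }
  structure(list(n_persons = as.integer(n_persons),
                 theta_distribution = theta_distribution,
                 ceiling_mass = ceiling_mass,
                 best_direction = best_direction,
                 covariate_margins = covariate_margins),
            class = "population_spec")
}

#' Simulate latent traits and covariates
#'
#' Draws theta from the specified distribution, relocates a `ceiling_mass`
#' fraction to the best-functioning extreme (a narrow normal component
#' centred 2.5 prior SDs beyond the mean in the best-functioning
#' direction), and draws covariates independently from their margins.
#'
#' @param pop a [population_spec()].
#' @param seed integer seed.
#' @return data frame with `person_id`, `theta`, `is_ceiling`, and one
#'   column per covariate (factors).
#' @export
simulate_thetas <- function(pop, seed) {
  stopifnot(inherits(pop, "population_spec"))
  set.seed(child_seed(seed, "thetas"))
  n <- pop$n_persons
  td <- pop$theta_distribution
  if (identical(td$kind, "normal")) {
    mu <- td$mean; sdv <- td$sd
    theta <- rnorm(n, mu, sdv)
  } else if (identical(td$kind, "skewed")) {
    # skew-normal via the delta representation, standardized
    a <- td$shape
    d <- a / sqrt(1 + a^2)
    z <- d * abs(rnorm(n)) + sqrt(1 - d^2) * rnorm(n)
    ez <- d * sqrt(2 / pi)
    theta <- (z - ez) / sqrt(1 - ez^2)
    mu <- 0; sdv <- 1
  } else stop("unknown theta distribution kind: ", td$kind)
  is_ceiling <- runif(n) < pop$ceiling_mass
  sign_best <- if (pop$best_direction == "low") -1 else 1
  mu_extreme <- mu + sign_best * 2.5 * sdv
  theta[is_ceiling] <- rnorm(sum(is_ceiling), mu_extreme, 0.25)
  out <- data.frame(person_id = as.character(seq_len(n)), theta = theta,
                    is_ceiling = is_ceiling, stringsAsFactors = FALSE)
  for (nm in names(pop$covariate_margins)) {
    m <- pop$covariate_margins[[nm]]
    out[[nm]] <- factor(sample(names(m), n, replace = TRUE, prob = m),
                        levels = names(m))
  }
  out
}

#' Differential-functioning injection for one item
#'
#' For persons in `affected_level` of `group_covariate`, the item's
#' thresholds are shifted by `uniform_shift` (uniform DIF) and its
#' discrimination multiplied by `alpha_multiplier` (non-uniform DIF).
#'
#' @param item_index 1-based index of the affected item.
#' @param group_covariate covariate column name.
#' @param affected_level the focal category label.
#' @param uniform_shift real added to every threshold for the focal group.
#' @param alpha_multiplier positive multiplier on the focal group's
#'   discrimination.
#' @return a `dif_spec` list.
#' @export
dif_spec <- function(item_index, group_covariate, affected_level,
                     uniform_shift = 0, alpha_multiplier = 1) {
  stopifnot(item_index >= 1L, alpha_multiplier > 0)
  structure(list(item_index = as.integer(item_index),
                 group_covariate = group_covariate,
                 affected_level = affected_level,
                 uniform_shift = uniform_shift,
                 alpha_multiplier = alpha_multiplier),
            class = "dif_spec")
}

#' Simulate GRM responses, optionally with injected DIF
#'
#' Each cell is drawn from the graded-model category distribution at the
#' person's theta; where a [dif_spec()] applies, the focal group's
#' parameters are modified before sampling. Categories are coded 0..K-1
#' and no cells are missing (forced completion).
#'
#' @param params an [item_parameters()] object.
#' @param persons data frame from [simulate_thetas()] (needs `theta` plus
#'   any covariates referenced by `dif`), or a bare numeric theta vector.
#' @param dif optional list of [dif_spec()] objects.
#' @param seed integer seed.
#' @return integer matrix (persons x items) with item-name columns.
#' @export
simulate_responses <- function(params, persons, dif = NULL, seed = 1L) {
  if (is.numeric(persons)) {
    persons <- data.frame(theta = persons)
  }
  theta <- persons$theta
  if (any(!is.finite(theta))) stop("theta must be finite")
  if (inherits(dif, "dif_spec")) dif <- list(dif)
  for (d in dif) {
    if (d$item_index > n_items(params)) stop("DIF item index out of range")
    if (!d$group_covariate %in% names(persons)) {
      stop("DIF covariate '", d$group_covariate, "' not found")
    }
  }
  set.seed(child_seed(seed, "responses"))
  n <- length(theta); J <- n_items(params)
  out <- matrix(0L, n, J, dimnames = list(NULL, params$item_names))
  u <- matrix(runif(n * J), n, J)
  for (j in seq_len(J)) {
    alpha_j <- rep(params$alpha[j], n)
    shift_j <- rep(0, n)
    for (d in dif) {
      if (d$item_index == j) {
        focal <- persons[[d$group_covariate]] == d$affected_level
        alpha_j[focal] <- alpha_j[focal] * d$alpha_multiplier
        shift_j[focal] <- shift_j[focal] + d$uniform_shift
      }
    }
    # inverse-CDF draw: count how many cumulative probs P(X >= k) exceed u
    K <- length(params$betas[[j]]) + 1L
    x <- integer(n)
    for (k in seq_len(K - 1L)) {
      pk <- plogis(alpha_j * (theta - (params$betas[[j]][k] + shift_j)))
      x <- x + as.integer(u[, j] < pk)
    }
    out[, j] <- x
  }
  out
}

#' Simulate a correlated 0-100 legacy instrument
#'
#' A second latent trait is drawn jointly (bivariate) normal with the
#' supplied theta at correlation `target_r`; 5-category graded items are
#' generated from it, then reverse-scored and linearly transformed so that
#' category 0 ("never a problem") maps to 100 and the worst category to 0:
#' `item score = (K-1 - response) * 100/(K-1)`. The scale score is the
#' item-score mean.
#'
#' @param thetas numeric vector of primary latent traits (standardized
#'   internally for the joint draw).
#' @param target_r desired latent correlation, in \[-1, 1\].
#' @param n_items number of legacy items (default 5).
#' @param seed integer seed.
#' @param params optional [item_parameters()] for the legacy items; a
#'   default 5-category bank is generated when omitted.
#' @return list with `latent` (legacy trait), `items` (response matrix,
#'   0..K-1), `item_scores` (0-100), `scale_scores` (0-100 means), and
#'   `params`.
#' @export
simulate_legacy_scale <- function(thetas, target_r, n_items = 5L, seed = 1L,
                                  params = NULL) {
  stopifnot(abs(target_r) <= 1)
  set.seed(child_seed(seed, "legacy"))
  z <- (thetas - mean(thetas)) / sd(thetas)
  eps <- rnorm(length(thetas))
  latent <- target_r * z + sqrt(1 - target_r^2) * eps
  if (is.null(params)) {
    params <- generate_item_bank(
      bank_spec(n_items, 5L, alpha_range = c(1.3, 2.2),
                threshold_span = c(-1.8, 2.0)),
      seed = child_seed(seed, "legacy-bank"))
  }
  items <- simulate_responses(params, latent, seed = child_seed(seed, "legacy-items"))
  K <- n_categories(params)
  item_scores <- sweep(-items, 2L, K - 1L, "+") * (100 / (K[1] - 1L))
  list(latent = latent, items = items, item_scores = item_scores,
       scale_scores = rowMeans(item_scores), params = params)
}

#' Draw a demographically stratified reference subsample
#'
#' Two-phase selection against target population margins: phase 1 walks the
#' pool and admits persons while any of their covariate categories is still
#' under its target count; phase 2 tops the sample up to `n_target` from
#' the remaining pool (lowest index first). Covariates whose final
#' proportions deviate from the margins by more than `max_deviation` are
#' flagged — infeasible strata (e.g. an empty category in the pool) stay
#' flagged rather than failing.
#'
#' @param persons data frame of candidates (factor covariate columns).
#' @param population_margins named list of named proportion vectors, as in
#'   [population_spec()].
#' @param n_target subsample size (default: pool size, i.e. selection only
#'   reorders/flags).
#' @param max_deviation tolerated absolute deviation per category
#'   (default 0.025, i.e. 2.5%).
#' @return list with `sample` (selected rows), `deviations` (data frame:
#'   covariate, level, target, achieved, deviation, flagged), `phase_sizes`.
#' @export
draw_reference_sample <- function(persons, population_margins,
                                  n_target = NULL, max_deviation = 0.025) {
  if (nrow(persons) == 0L) stop("empty candidate pool")
  if (is.null(n_target)) n_target <- nrow(persons)
  stopifnot(n_target >= 1L, n_target <= nrow(persons))
  for (nm in names(population_margins)) {
    if (!nm %in% names(persons)) stop("covariate '", nm, "' not in pool")
  }
  target_counts <- lapply(population_margins, function(m) {
    stats::setNames(m * n_target, names(m))
  })
  filled <- lapply(target_counts, function(tc) stats::setNames(rep(0, length(tc)), names(tc)))
  selected <- logical(nrow(persons))
  n_sel <- 0L
  # phase 1: repeatedly admit the candidate whose covariate categories
  # carry the largest remaining deficit (ties: lowest pool index), so
  # under-represented strata fill first
  lev_of <- lapply(names(target_counts), function(nm) {
    as.character(persons[[nm]])
  })
  names(lev_of) <- names(target_counts)
  repeat {
    if (n_sel >= n_target) break
    score <- rep(0, nrow(persons))
    for (nm in names(target_counts)) {
      deficit <- pmax(target_counts[[nm]] - filled[[nm]], 0)
      sc <- deficit[lev_of[[nm]]]
      sc[is.na(sc)] <- 0
      score <- score + sc
    }
    score[selected] <- -Inf
    if (max(score) <= 0) break
    i <- which.max(score)
    selected[i] <- TRUE
    n_sel <- n_sel + 1L
    for (nm in names(target_counts)) {
      lev <- lev_of[[nm]][i]
      if (!is.na(lev) && lev %in% names(filled[[nm]])) {
        filled[[nm]][lev] <- filled[[nm]][lev] + 1
      }
    }
  }
  phase1 <- n_sel
  # phase 2: fill remaining slots from the residual pool in order
  if (n_sel < n_target) {
    pool <- which(!selected)
    extra <- pool[seq_len(n_target - n_sel)]
    selected[extra] <- TRUE
    n_sel <- n_target
  }
  samp <- persons[selected, , drop = FALSE]
  dev <- do.call(rbind, lapply(names(population_margins), function(nm) {
    m <- population_margins[[nm]]
    ach <- vapply(names(m), function(lev) {
      mean(as.character(samp[[nm]]) == lev, na.rm = TRUE)
    }, 0)
    data.frame(covariate = nm, level = names(m), target = as.numeric(m),
               achieved = as.numeric(ach),
               deviation = abs(as.numeric(ach) - as.numeric(m)),
               stringsAsFactors = FALSE)
  }))
  dev$flagged <- dev$deviation > max_deviation
  rownames(dev) <- NULL
  list(sample = samp, deviations = dev,
       phase_sizes = c(phase1 = phase1, phase2 = n_target - phase1))
}
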