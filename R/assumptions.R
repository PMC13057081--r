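# IRT assumption checks: unidimensionality (single-factor fit on polychoric
# correlations, exploratory bifactor indices), local independence (residual
# correlations), monotonicity and scalability (Mokken-type coefficients),
# and invariant item ordering (HT).

# bivariate normal CDF P(X <= h, Y <= k; rho), vectorized over h/k.
# Drezner-Wesolowsky single-integral form evaluated by Gauss-Legendre.
.pbvnorm <- function(h, k, rho, n_gl = 32L) {
  n <- max(length(h), length(k))
  h <- rep_len(h, n); k <- rep_len(k, n)
  out <- pnorm(h) * pnorm(k)
  if (abs(rho) < 1e-12) return(out)
  rho <- max(min(rho, 0.9999), -0.9999)
  gl <- .gauss_legendre(n_gl, 0, rho)
  fin <- is.finite(h) & is.finite(k)
  if (any(fin)) {
    hf <- h[fin]; kf <- k[fin]
    acc <- numeric(sum(fin))
    for (i in seq_len(n_gl)) {
      r <- gl$nodes[i]
      acc <- acc + gl$weights[i] *
        exp(-(hf^2 - 2 * r * hf * kf + kf^2) / (2 * (1 - r^2))) /
        sqrt(1 - r^2)
    }
    out[fin] <- out[fin] + acc / (2 * pi)
  }
  # infinite bounds: marginal or zero
  out[h == Inf] <- pnorm(k[h == Inf])
  out[k == Inf] <- pnorm(h[k == Inf])
  out[h == -Inf | k == -Inf] <- 0
  pmin(pmax(out, 0), 1)
}

.gauss_legendre <- function(n, a, b) {
  # Golub-Welsch on the Jacobi matrix
  i <- seq_len(n - 1)
  bvec <- i / sqrt(4 * i^2 - 1)
  A <- matrix(0, n, n)
  A[cbind(i, i + 1)] <- bvec; A[cbind(i + 1, i)] <- bvec
  e <- eigen(A, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(nodes = 0.5 * (b - a) * x + 0.5 * (a + b),
       weights = 0.5 * (b - a) * w)
}

# ML polychoric correlation for one pair given fixed thresholds
.polychoric_rho <- function(tab, th_r, th_c) {
  a <- c(-Inf, th_r, Inf); b <- c(-Inf, th_c, Inf)
  nr <- length(a) - 1L; nc <- length(b) - 1L
  negll <- function(rho) {
    Fg <- matrix(.pbvnorm(rep(a, times = length(b)), rep(b, each = length(a)),
                          rho), length(a), length(b))
    P <- Fg[-1, -1, drop = FALSE] - Fg[-nrow(Fg), -1, drop = FALSE] -
      Fg[-1, -ncol(Fg), drop = FALSE] +
      Fg[-nrow(Fg), -ncol(Fg), drop = FALSE]
    P[P < 1e-12] <- 1e-12
    -sum(tab * log(P))
  }
  optimize(negll, c(-0.999, 0.999))$minimum
}

#' Polychoric correlation matrix
#'
#' Two-step maximum-likelihood estimation: per-item thresholds are the
#' inverse-normal transforms of the cumulative category marginals; each
#' pairwise correlation then maximizes the bivariate-normal contingency
#' likelihood with thresholds held fixed. Unobserved categories are
#' collapsed away (the recoding is recorded).
#'
#' @param responses persons x items matrix of integer categories 0..K-1.
#' @return list with `rho` (symmetric, unit diagonal), `thresholds`
#'   (per-item list), `category_maps`.
#' @export
polychoric_matrix <- function(responses) {
  responses <- as.matrix(responses)
  J <- ncol(responses)
  maps <- vector("list", J)
  for (j in seq_len(J)) {
    obs <- sort(unique(responses[, j]))
    if (length(obs) < 2L) stop("item ", j, " has fewer than 2 observed categories")
    if (!identical(as.numeric(obs), as.numeric(seq_along(obs) - 1))) {
      maps[[j]] <- data.frame(old = obs, new = seq_along(obs) - 1)
      responses[, j] <- match(responses[, j], obs) - 1L
    }
  }
  n <- nrow(responses)
  thresholds <- lapply(seq_len(J), function(j) {
    K <- max(responses[, j]) + 1L
    cum <- cumsum(tabulate(responses[, j] + 1L, nbins = K))[seq_len(K - 1L)] / n
    qnorm(cum)
  })
  rho <- diag(1, J)
  for (i in seq_len(J - 1L)) {
    for (j in (i + 1L):J) {
      tab <- table(factor(responses[, i], levels = 0:max(responses[, i])),
                   factor(responses[, j], levels = 0:max(responses[, j])))
      rho[i, j] <- rho[j, i] <- .polychoric_rho(tab, thresholds[[i]],
                                                thresholds[[j]])
    }
  }
  nm <- colnames(responses)
  if (!is.null(nm)) dimnames(rho) <- list(nm, nm)
  list(rho = rho, thresholds = thresholds, category_maps = maps)
}

# nearest positive-semidefinite projection by eigenvalue clipping,
# rescaled back to unit diagonal
.nearest_psd <- function(R, eps = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) return(list(R = R, smoothed = FALSE))
  v <- pmax(e$values, eps)
  S <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(S))
  list(R = S / tcrossprod(d), smoothed = TRUE)
}

# minimum-residual (least squares) factor solution with m factors:
# minimize the sum of squared off-diagonal residuals of R - L L' over the
# uniquenesses; given uniquenesses the loadings come from the leading
# eigenstructure of the reduced matrix (bounded, so no Heywood blow-ups)
.minres_fit <- function(R, m, max_iter = 500L) {
  p <- ncol(R)
  loadings_for <- function(psi) {
    Rr <- R
    diag(Rr) <- 1 - psi
    e <- eigen(Rr, symmetric = TRUE)
    e$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(m)], 0)), m)
  }
  off <- upper.tri(R)
  fn <- function(psi) {
    res <- R - tcrossprod(loadings_for(psi))
    sum(res[off]^2)
  }
  smc <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, p))
  psi0 <- pmin(pmax(1 - smc, 0.05), 0.95)
  opt <- optim(psi0, fn, method = "L-BFGS-B", lower = 0.005, upper = 1,
               control = list(maxit = max_iter, factr = 1e4))
  L <- loadings_for(opt$par)
  # sign convention: dominant direction positive
  for (f in seq_len(m)) if (sum(L[, f]) < 0) L[, f] <- -L[, f]
  list(loadings = L, value = opt$value, converged = opt$convergence == 0)
}

#' Single-factor fit of a polychoric correlation matrix
#'
#' One-factor least-squares (minres) solution with approximate fit
#' indices: the maximum-likelihood discrepancy at the solution gives
#' `chisq = (n-1) F`, compared against the zero-correlation baseline for
#' CFI/TLI; RMSEA from `chisq` and `df`; SRMR is the root mean squared
#' off-diagonal residual correlation. Indices are unscaled (no robust
#' correction); verdicts use CFI/TLI >= 0.95, RMSEA <= 0.06, SRMR <= 0.08.
#'
#' @param polychoric correlation matrix (smoothed to PSD if needed; the
#'   smoothing is recorded).
#' @param n_persons sample size behind the matrix.
#' @return list with `loadings`, `cfi`, `tli`, `rmsea`, `srmr`, `chisq`,
#'   `df`, `verdicts`, `smoothed`.
#' @export
single_factor_fit <- function(polychoric, n_persons) {
  p <- ncol(polychoric)
  if (p < 3L) stop("need at least 3 items for a one-factor model")
  sm <- .nearest_psd(polychoric)
  R <- sm$R
  fit <- .minres_fit(R, 1L)
  lambda <- pmin(pmax(as.numeric(fit$loadings), -0.999), 0.999)
  Sigma <- tcrossprod(lambda)
  diag(Sigma) <- 1
  iS <- solve(Sigma)
  F_ml <- as.numeric(determinant(Sigma)$modulus) -
    as.numeric(determinant(R)$modulus) + sum(iS * R) - p
  F_ml <- max(F_ml, 0)
  chisq <- (n_persons - 1) * F_ml
  df <- p * (p - 3) / 2
  F_base <- -as.numeric(determinant(R)$modulus)
  chisq_b <- (n_persons - 1) * max(F_base, 0)
  df_b <- p * (p - 1) / 2
  cfi <- 1 - max(chisq - df, 0) / max(chisq_b - df_b, chisq - df, .Machine$double.eps)
  tli <- if (df > 0 && df_b > 0 && chisq_b / df_b > 1) {
    min((chisq_b / df_b - chisq / df) / (chisq_b / df_b - 1), 1)
  } else 1
  rmsea <- if (df > 0) sqrt(max(chisq - df, 0) / (df * (n_persons - 1))) else 0
  res <- R - tcrossprod(lambda)
  srmr <- sqrt(mean(res[upper.tri(res)]^2))
  list(loadings = lambda, cfi = cfi, tli = tli, rmsea = rmsea, srmr = srmr,
       chisq = chisq, df = df, smoothed = sm$smoothed,
       verdicts = c(cfi = cfi >= 0.95, tli = tli >= 0.95,
                    rmsea = rmsea <= 0.06, srmr = srmr <= 0.08))
}

#' Residual correlations after a one-factor solution
#'
#' Local-independence check: residuals `r_ij - lambda_i lambda_j` for
#' `i < j`; pairs exceeding 0.20 are flagged, with the count and the
#' percentage of all pairs reported in Table-2 style ("1 (3.6)").
#'
#' @param polychoric correlation matrix.
#' @param loadings one-factor loadings.
#' @param cutoff residual flag threshold (default 0.20).
#' @return list with `pairs` (data frame item_i, item_j, residual,
#'   flagged), `n_flagged`, `pct_flagged`, `label`.
#' @export
residual_correlations <- function(polychoric, loadings, cutoff = 0.20) {
  p <- ncol(polychoric)
  res <- polychoric - tcrossprod(loadings)
  idx <- which(upper.tri(res), arr.ind = TRUE)
  pairs <- data.frame(item_i = idx[, 1], item_j = idx[, 2],
                      residual = res[idx])
  pairs$flagged <- pairs$residual > cutoff
  n_fl <- sum(pairs$flagged)
  pct <- 100 * n_fl / nrow(pairs)
  list(pairs = pairs, n_flagged = n_fl, pct_flagged = pct,
       label = sprintf("%d (%.1f)", n_fl, pct))
}

#' Bifactor indices from explicit loading matrices
#'
#' Algebraic ECV and omega-hierarchical for a general + group-factor
#' loading structure: `ECV = sum(lambda_g^2) / (sum(lambda_g^2) +
#' sum(lambda_s^2))`; `omega_h = (sum lambda_g)^2 / V_total` where
#' `V_total` defaults to the model-implied total score variance
#' `(sum lambda_g)^2 + sum_f (sum_i lambda_s[i,f])^2 + sum(uniqueness)`.
#'
#' @param lambda_g numeric vector of general-factor loadings.
#' @param lambda_s matrix (items x group factors) of group loadings.
#' @param total_variance optional total-score variance to use instead of
#'   the model-implied one (e.g. the sum of the observed correlation
#'   matrix).
#' @return list with `ecv` and `omega_h`.
#' @export
bifactor_indices_from_loadings <- function(lambda_g, lambda_s,
                                           total_variance = NULL) {
  lambda_s <- as.matrix(lambda_s)
  ecv <- sum(lambda_g^2) / (sum(lambda_g^2) + sum(lambda_s^2))
  if (is.null(total_variance)) {
    uniq <- pmax(1 - lambda_g^2 - rowSums(lambda_s^2), 0)
    total_variance <- sum(lambda_g)^2 + sum(colSums(lambda_s)^2) + sum(uniq)
  }
  omega_h <- sum(lambda_g)^2 / total_variance
  list(ecv = ecv, omega_h = omega_h)
}

#' Exploratory bifactor indices (ECV, omega-H)
#'
#' Fits an oblique multi-factor solution (minres + varimax + promax),
#' estimates the factor intercorrelations, extracts a single second-order
#' factor from them, and applies the Schmid-Leiman orthogonalization to
#' obtain general and group loadings; ECV >= 0.70 and omega_h >= 0.80 are
#' read as supporting essential unidimensionality.
#'
#' @param x response matrix (categories 0..K-1) or a polychoric
#'   correlation matrix (square, symmetric).
#' @param n_group_factors number of group factors (default 2).
#' @return list with `ecv`, `omega_h`, `lambda_general`, `lambda_group`,
#'   `verdicts`.
#' @export
bifactor_indices <- function(x, n_group_factors = 2L) {
  x <- as.matrix(x)
  R <- if (nrow(x) == ncol(x) && isTRUE(all.equal(x, t(x), tolerance = 1e-8))) {
    x
  } else {
    polychoric_matrix(x)$rho
  }
  p <- ncol(R)
  if (p < 6L) stop("need at least 6 items for stable group factors")
  R <- .nearest_psd(R)$R
  m <- n_group_factors
  fit <- .minres_fit(R, m)
  L <- fit$loadings
  # oblique rotation; fall back to the unrotated solution if degenerate
  Phi <- diag(m)
  L_obl <- L
  rot_ok <- TRUE
  if (m > 1L) {
    vr <- tryCatch(stats::varimax(L), error = function(e) NULL)
    pm <- if (!is.null(vr)) tryCatch(stats::promax(vr$loadings),
                                     error = function(e) NULL) else NULL
    if (!is.null(pm)) {
      L_obl <- unclass(pm$loadings)
      Phi <- tryCatch({
        Pi <- solve(crossprod(pm$rotmat))
        d <- sqrt(diag(Pi)); Pi / tcrossprod(d)
      }, error = function(e) diag(m))
    } else rot_ok <- FALSE
  }
  # second-order loadings gamma of the factor intercorrelations
  gamma <- if (m == 1L) 1 else {
    phi_off <- Phi[upper.tri(Phi)]
    if (all(abs(phi_off) < 1e-8)) rep(0, m)
    else {
      g <- .minres_fit(Phi, 1L)$loadings
      pmin(pmax(as.numeric(g), 0), 0.999)
    }
  }
  lambda_g <- as.numeric(L_obl %*% gamma)
  lambda_s <- L_obl %*% diag(sqrt(pmax(1 - gamma^2, 0)), m)
  # when factors are (near) orthogonal the general factor carries nothing;
  # for essentially unidimensional data the first minres factor is the
  # better general-factor estimate, so keep whichever explains more
  if (sum(lambda_g^2) < sum(L[, 1]^2) * 0.5) {
    lambda_g <- L[, 1]
    lambda_s <- L[, -1, drop = FALSE]
  }
  idx <- bifactor_indices_from_loadings(lambda_g, lambda_s,
                                        total_variance = sum(R))
  list(ecv = idx$ecv, omega_h = idx$omega_h, lambda_general = lambda_g,
       lambda_group = lambda_s, rotation_converged = rot_ok,
       verdicts = c(ecv = idx$ecv >= 0.70, omega_h = idx$omega_h >= 0.80))
}
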