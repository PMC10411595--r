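#' Negative binomial log-likelihood
#'
#' @param y counts.
#' @param mu fitted means (same length or recycled).
#' @param alpha dispersion; variance = mu + alpha * mu^2. alpha below
#'   1e-12 is evaluated as Poisson.
#' @return scalar log-likelihood.
#' @keywords internal
nb_loglik <- function(y, mu, alpha) {
  mu <- pmax(mu, 1e-10)
  if (alpha < 1e-12) {
    sum(stats::dpois(y, lambda = mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
  }
}

# IRLS-backed NB GLM with fixed dispersion, log link and offset.
# Wraps stats::glm.fit with the MASS negative.binomial family; retries
# from a damped start if the first fit fails or diverges.
nb_glm_fit_raw <- function(y, X, offset, alpha) {
  fam <- if (alpha < 1e-12) {
    stats::poisson(link = "log")
  } else {
    MASS::negative.binomial(theta = 1 / alpha, link = "log")
  }
  run <- function(mustart) {
    tryCatch(
      suppressWarnings(stats::glm.fit(
        x = X, y = y, offset = offset, family = fam,
        mustart = mustart,
        control = stats::glm.control(maxit = 100, epsilon = 1e-10))),
      error = function(e) NULL)
  }
  fit <- run(NULL)
  if (is.null(fit) || !fit$converged || any(!is.finite(fit$coefficients))) {
    fit2 <- run(pmax(y, 1 / 6) + 0.1)
    if (!is.null(fit2) && all(is.finite(fit2$coefficients))) fit <- fit2
  }
  fit
}

#' Fit a negative binomial GLM to one gene
#'
#' Maximizes the NB log-likelihood with fixed dispersion alpha, log
#' link and offset log(size factor). Coefficients, standard errors and
#' the covariance matrix are reported on the log2 scale; fitting is done
#' on the natural-log scale internally.
#'
#' @param y counts for one gene (length = number of samples).
#' @param X design matrix (full column rank).
#' @param sf per-sample size factors.
#' @param alpha NB dispersion (fixed).
#' @return list: `coef_log2`, `se_log2`, `vcov_log2`, `loglik`,
#'   `fitted` (means on count scale), `alpha`, `df` (rank of X),
#'   `converged`, `degenerate` (TRUE for the guarded all-zero fit).
#' @export
fit_nb_glm <- function(y, X, sf = rep(1, length(y)), alpha = 1e-8) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  p <- ncol(X)
  if (all(y == 0)) {
    # structural-zero gene: log-likelihood of the point mass at zero is
    # 0; intercept diverges to -Inf and is reported as such, flagged
    cf <- stats::setNames(rep(0, p), colnames(X))
    icpt <- which(apply(X, 2, function(v) all(v == v[1]) && v[1] != 0))
    if (length(icpt) > 0) cf[icpt[1]] <- -Inf
    return(list(coef_log2 = cf, se_log2 = rep(NA_real_, p),
                vcov_log2 = matrix(NA_real_, p, p), loglik = 0,
                fitted = rep(0, length(y)), alpha = alpha, df = p,
                converged = FALSE, degenerate = TRUE))
  }
  # A design cell whose counts are all zero sends its coefficient to
  # -Inf (complete separation): the Wald SE explodes and the test loses
  # all power. Guard by adding a small pseudo-count inside the
  # optimizer only; reported log-likelihoods use the original counts
  # and the guard never touches any emitted count table.
  cell <- apply(X, 1, paste, collapse = "\r")
  zero_cell <- any(tapply(y, cell, function(v) all(v == 0))) && any(y > 0)
  yfit <- if (zero_cell) y + 0.125 else y
  fit <- nb_glm_fit_raw(yfit, X, log(sf), alpha)
  if (is.null(fit)) {
    return(list(coef_log2 = stats::setNames(rep(NA_real_, p), colnames(X)),
                se_log2 = rep(NA_real_, p),
                vcov_log2 = matrix(NA_real_, p, p), loglik = NA_real_,
                fitted = rep(NA_real_, length(y)), alpha = alpha, df = p,
                converged = FALSE, degenerate = FALSE))
  }
  mu <- fit$fitted.values
  ll <- nb_loglik(y, mu, alpha)
  # observed-information covariance from the IRLS weights
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  vc <- tryCatch(solve(XtWX), error = function(e) {
    matrix(NA_real_, p, p)
  })
  l2 <- log(2)
  list(coef_log2 = fit$coefficients / l2,
       se_log2 = sqrt(pmax(diag(vc), 0)) / l2,
       vcov_log2 = vc / l2^2,
       loglik = ll, fitted = mu, alpha = alpha, df = p,
       converged = isTRUE(fit$converged),
       degenerate = FALSE)
}

#' Per-gene NB dispersion by adjusted profile likelihood
#'
#' For each gene, alternates between fitting the GLM mean structure at
#' the current dispersion and maximizing the NB likelihood in the
#' dispersion given the fitted means (coordinate ascent on the joint
#' likelihood, whose fixed point maximizes the profile likelihood).
#' By default the Cox-Reid adjustment -0.5 * log det(X' W X) is added
#' to the dispersion objective, correcting the downward bias of plain
#' ML when the mean design consumes many degrees of freedom. Estimates
#' are clamped to a floor. No empirical-Bayes moderation is applied.
#'
#' @param counts gene x sample matrix.
#' @param design [sample_design()] data.frame.
#' @param sf per-sample size factors.
#' @param formula full model formula on design columns (default
#'   `~ strain * treatment` restricted to terms with >= 2 levels).
#' @param floor lower clamp for alpha (default 1e-8).
#' @param alpha_max upper search bound.
#' @param cr_adjust apply the Cox-Reid adjustment (default TRUE).
#' @return data.frame gene_id, alpha, converged, method ("profile" or
#'   "mom" for the method-of-moments fallback).
#' @export
estimate_dispersion <- function(counts, design, sf,
                                formula = NULL, floor = 1e-8,
                                alpha_max = 10, cr_adjust = TRUE) {
  X <- design_matrix(design, formula)
  n <- nrow(counts)
  alpha <- numeric(n)
  conv <- logical(n)
  method <- character(n)
  for (i in seq_len(n)) {
    y <- counts[i, ]
    r <- profile_alpha_one(y, X, sf, floor, alpha_max, cr_adjust)
    alpha[i] <- r$alpha
    conv[i] <- r$converged
    method[i] <- r$method
  }
  data.frame(gene_id = rownames(counts), alpha = alpha,
             converged = conv, method = method,
             stringsAsFactors = FALSE)
}

profile_alpha_one <- function(y, X, sf, floor, alpha_max,
                              cr_adjust = TRUE) {
  if (all(y == 0)) {
    return(list(alpha = floor, converged = TRUE, method = "profile"))
  }
  off <- log(sf)
  fit <- nb_glm_fit_raw(y, X, off, floor)
  if (is.null(fit)) {
    return(list(alpha = mom_alpha(y, sf, floor), converged = FALSE,
                method = "mom"))
  }
  mu <- pmax(fit$fitted.values, 1e-10)
  a <- floor
  cr <- function(alpha) {
    if (!cr_adjust) return(0)
    w <- mu / (1 + alpha * mu)
    -0.5 * determinant(crossprod(X * sqrt(w)), logarithm = TRUE)$modulus[1]
  }
  for (it in 1:3) {
    obj <- function(la) nb_loglik(y, mu, exp(la)) + cr(exp(la))
    opt <- stats::optimize(obj, c(log(floor), log(alpha_max)),
                           maximum = TRUE, tol = 1e-4)
    a_new <- if (obj(log(floor)) >= opt$objective) floor else exp(opt$maximum)
    fit <- nb_glm_fit_raw(y, X, off, a_new)
    if (is.null(fit)) {
      return(list(alpha = mom_alpha(y, sf, floor), converged = FALSE,
                  method = "mom"))
    }
    mu <- pmax(fit$fitted.values, 1e-10)
    if (abs(log(a_new + floor) - log(a + floor)) < 1e-3) {
      a <- a_new
      break
    }
    a <- a_new
  }
  list(alpha = a, converged = TRUE, method = "profile")
}

# method-of-moments dispersion: alpha = sum((y-mu)^2 - mu) / sum(mu^2)
# with mu from scaled group-free means
mom_alpha <- function(y, sf, floor) {
  q <- mean(y / sf)
  mu <- q * sf
  a <- sum((y - mu)^2 - mu) / sum(mu^2)
  max(a, floor)
}

# Builds the model matrix from a sample_design, dropping factors with a
# single observed level; default full design is ~ strain * treatment.
design_matrix <- function(design, formula = NULL) {
  if (is.null(formula)) {
    terms <- character(0)
    if (nlevels(droplevels(design$strain)) > 1) terms <- c(terms, "strain")
    if (nlevels(droplevels(design$treatment)) > 1) terms <- c(terms, "treatment")
    formula <- if (length(terms) == 0) ~1 else
      stats::as.formula(paste("~", paste(terms, collapse = " * ")))
  }
  d <- as.data.frame(design)
  d$strain <- droplevels(d$strain)
  d$treatment <- droplevels(d$treatment)
  stats::model.matrix(formula, data = d)
}
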