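#' Squeeze a proportion vector away from the boundary
#'
#' Beta regression requires responses strictly inside (0, 1). Observed
#' proportions containing exact zeros are compressed with the standard
#' transform `y* = (y * (n - 1) + 0.5) / n`, where `n` is the sample size.
#' The transform is applied to the whole vector (not only the zeros): it is
#' affine and order-preserving, with fixed point 0.5.
#'
#' @param y numeric vector in `[0, 1]`.
#' @param n sample size (default `length(y)`).
#' @return vector strictly inside (0, 1).
#' @export
#' @examples
#' squeeze_transform(c(0, 0.5, 0.07), n = 533)
squeeze_transform <- function(y, n = length(y)) {
  if (any(!is.finite(y)) || any(y < 0) || any(y > 1))
    stop("y must lie in [0, 1]")
  if (n < 2) stop("n must be >= 2")
  (y * (n - 1) + 0.5) / n
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a zero-variance variable")
  (x - mean(x)) / s
}

# Covariate set per the analysis rule: age, sex and hypertension are
# controlled for, except when one of them is the outcome of interest.
covariates_for <- function(outcome,
                           base = c("age", "sex", "hypertension")) {
  setdiff(base, outcome)
}

new_model_result <- function(family, coefs, effect_term, n, loglik, k,
                             extra = list()) {
  ci <- coefs[coefs$term == effect_term, ]
  if (nrow(ci) != 1L) stop("effect term not found in fit")
  res <- list(family = family,
              coefficients = coefs,
              effect = ci,
              n = n,
              logLik = loglik,
              k = k,
              AIC = 2 * k - 2 * loglik,
              BIC = k * log(n) - 2 * loglik)
  structure(c(res, extra), class = "pvs_model")
}

#' @export
print.pvs_model <- function(x, ...) {
  cat(sprintf("<pvs_model:%s> n=%d logLik=%.2f AIC=%.2f BIC=%.2f\n",
              x$family, x$n, x$logLik, x$AIC, x$BIC))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

model_frame <- function(data, outcome, predictor, covariates, z_predictor) {
  vars <- c(outcome, predictor, covariates)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  if (z_predictor) df[[predictor]] <- zscore(df[[predictor]])
  df
}

#' Linear model with standardized effect
#'
#' Ordinary least squares with the predictor of interest z-scored; the
#' outcome is z-scored too by default so the reported effect is a
#' standardized beta comparable across measures.
#'
#' @param data data frame.
#' @param outcome,predictor,covariates column names.
#' @param z_outcome z-score the outcome (default `TRUE`).
#' @param conf_level confidence level for Wald intervals.
#' @return a `pvs_model` with the standardized coefficient and CI of
#'   `predictor`.
#' @export
fit_linear <- function(data, outcome, predictor,
                       covariates = covariates_for(outcome),
                       z_outcome = TRUE, conf_level = 0.95) {
  df <- model_frame(data, outcome, predictor, covariates, z_predictor = TRUE)
  if (z_outcome) df[[outcome]] <- zscore(df[[outcome]])
  form <- stats::reformulate(c(predictor, covariates), response = outcome)
  fit <- stats::lm(form, data = df)
  if (fit$rank < length(stats::coef(fit)))
    stop("rank-deficient design in linear model")
  sm <- summary(fit)$coefficients
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      ci_lo = sm[, 1] - zq * sm[, 2],
                      ci_hi = sm[, 1] + zq * sm[, 2], row.names = NULL)
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  new_model_result("linear", coefs, predictor, nrow(df), ll, k,
                   extra = list(fit = fit))
}

#' Binary logistic regression with odds ratio
#'
#' Maximum-likelihood logistic fit with the predictor of interest z-scored;
#' reports the odds ratio per SD with a Wald confidence interval. Degenerate
#' outcomes (all 0 or all 1) and perfect separation raise errors.
#'
#' @inheritParams fit_linear
#' @return a `pvs_model`; the `effect` row is on the log-odds scale, with
#'   `or`, `or_lo`, `or_hi` added.
#' @export
fit_logistic <- function(data, outcome, predictor,
                         covariates = covariates_for(outcome),
                         conf_level = 0.95) {
  df <- model_frame(data, outcome, predictor, covariates, z_predictor = TRUE)
  y <- df[[outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("degenerate outcome: all observations are ", y[1])
  form <- stats::reformulate(c(predictor, covariates), response = outcome)
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        stop("perfect (or quasi-perfect) separation in logistic model", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) stop("logistic fit did not converge")
  sm <- summary(fit)$coefficients
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      ci_lo = sm[, 1] - zq * sm[, 2],
                      ci_hi = sm[, 1] + zq * sm[, 2], row.names = NULL)
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  res <- new_model_result("logistic", coefs, predictor, nrow(df), ll, k,
                          extra = list(fit = fit))
  res$effect$or <- exp(res$effect$estimate)
  res$effect$or_lo <- exp(res$effect$ci_lo)
  res$effect$or_hi <- exp(res$effect$ci_hi)
  res
}

# Negative log-likelihood of the beta regression (logit link), parameter
# vector c(beta, log_phi).
betareg_nll <- function(par, y, X) {
  p <- ncol(X)
  mu <- stats::plogis(drop(X %*% par[seq_len(p)]))
  phi <- exp(par[p + 1L])
  -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

#' Beta regression with logit link
#'
#' Maximum-likelihood fit of y ~ Beta(mu * phi, (1 - mu) * phi) with
#' logit(mu) = X beta, estimating beta and the precision phi jointly by
#' BFGS on (beta, log phi). Standard errors come from the observed
#' information (numerical Hessian at the optimum). Responses touching 0 or
#' 1 raise an error pointing at [squeeze_transform].
#'
#' @inheritParams fit_linear
#' @return a `pvs_model`; `phi` holds the precision estimate.
#' @export
fit_beta_regression <- function(data, outcome, predictor,
                                covariates = covariates_for(outcome),
                                conf_level = 0.95) {
  df <- model_frame(data, outcome, predictor, covariates, z_predictor = TRUE)
  y <- df[[outcome]]
  if (any(y <= 0 | y >= 1))
    stop("beta regression needs y strictly in (0,1); apply squeeze_transform() first")
  X <- stats::model.matrix(stats::reformulate(c(predictor, covariates)),
                           data = df)
  p <- ncol(X)
  # starting values: OLS on the logit scale; method-of-moments phi
  eta0 <- stats::qlogis(y)
  b0 <- stats::coef(stats::lm.fit(X, eta0))
  mu0 <- stats::plogis(drop(X %*% b0))
  v0 <- max(stats::var(y - mu0), 1e-8)
  phi0 <- max(mean(mu0 * (1 - mu0)) / v0 - 1, 1)
  opt <- stats::optim(c(b0, log(phi0)), betareg_nll, y = y, X = X,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("beta regression did not converge (optim code ", opt$convergence,
         "): ", paste(opt$message, collapse = " "))
  H <- opt$hessian
  cov <- tryCatch(solve(H), error = function(e)
    stop("singular information matrix in beta regression"))
  se <- sqrt(pmax(diag(cov), 0))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- opt$par
  terms <- c(colnames(X), "log_phi")
  coefs <- data.frame(term = terms, estimate = est, se = se,
                      ci_lo = est - zq * se, ci_hi = est + zq * se,
                      row.names = NULL)
  ll <- -opt$value
  k <- p + 1L
  res <- new_model_result("beta", coefs, predictor, nrow(df), ll, k,
                          extra = list(phi = exp(est[p + 1L]),
                                       convergence = opt$convergence))
  res
}

#' Polyserial correlation between an ordinal and a continuous variable
#'
#' Two-step estimator under the latent bivariate-normal model: thresholds
#' are fixed at the inverse-normal cumulative category proportions, then
#' the latent correlation rho is estimated by maximum likelihood of the
#' conditional ordinal categories given the standardized continuous
#' variable. The Wald CI uses the observed information (numerical second
#' derivative of the profile log-likelihood).
#'
#' @param ordinal integer-valued ordinal vector with >= 2 observed levels.
#' @param continuous numeric vector, same length.
#' @param conf_level confidence level.
#' @return list with `rho`, `se`, `ci`, `thresholds`, `n`.
#' @export
polyserial_corr <- function(ordinal, continuous, conf_level = 0.95) {
  ok <- stats::complete.cases(ordinal, continuous)
  o <- ordinal[ok]; x <- continuous[ok]
  lev <- sort(unique(o))
  if (length(lev) < 2L) stop("ordinal variable has fewer than 2 observed levels")
  oi <- match(o, lev)
  n <- length(oi)
  cum <- cumsum(tabulate(oi, length(lev)))[-length(lev)] / n
  tau <- stats::qnorm(cum)                        # interior thresholds
  lo <- c(-Inf, tau); hi <- c(tau, Inf)
  z <- (x - mean(x)) / stats::sd(x)
  ll <- function(rho) {
    s <- sqrt(1 - rho^2)
    pr <- stats::pnorm((hi[oi] - rho * z) / s) -
          stats::pnorm((lo[oi] - rho * z) / s)
    sum(log(pmax(pr, 1e-300)))
  }
  opt <- stats::optimize(ll, c(-0.999, 0.999), maximum = TRUE, tol = 1e-9)
  rho <- opt$maximum
  h <- 1e-4
  d2 <- (ll(rho + h) - 2 * ll(rho) + ll(rho - h)) / h^2
  se <- if (is.finite(d2) && d2 < 0) 1 / sqrt(-d2) else NA_real_
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(rho = rho, se = se,
       ci = c(rho - zq * se, rho + zq * se),
       thresholds = tau, n = n)
}

#' Pearson correlation with confidence interval
#'
#' @param x,y numeric vectors.
#' @param conf_level confidence level.
#' @return list with `r`, `ci`, `p`, `n`.
#' @export
pearson_corr <- function(x, y, conf_level = 0.95) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input to correlation")
  ct <- stats::cor.test(x, y, conf.level = conf_level)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       p = ct$p.value, n = length(x))
}

#' Welch two-sample t test
#'
#' @param x,y numeric vectors (the two groups).
#' @param conf_level confidence level.
#' @return list with `t`, `df` (Welch-Satterthwaite), `p`, `ci` (difference
#'   of means).
#' @export
welch_t <- function(x, y, conf_level = 0.95) {
  tt <- stats::t.test(x, y, var.equal = FALSE, conf.level = conf_level)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       ci = as.numeric(tt$conf.int))
}

#' Chi-squared test on a contingency table
#'
#' Without continuity correction by default; for 2 x 2 tables a Wald
#' confidence interval on the difference of proportions is added.
#'
#' @param tab matrix (contingency table).
#' @param correct apply Yates continuity correction.
#' @param conf_level confidence level for the proportion-difference CI.
#' @return list with `chisq`, `df`, `p`, and `prop_diff_ci` for 2 x 2.
#' @export
chi_sq <- function(tab, correct = FALSE, conf_level = 0.95) {
  tab <- as.matrix(tab)
  ct <- stats::chisq.test(tab, correct = correct)
  out <- list(chisq = unname(ct$statistic), df = unname(ct$parameter),
              p = ct$p.value)
  if (all(dim(tab) == c(2L, 2L))) {
    n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ])
    p1 <- tab[1, 2] / n1; p2 <- tab[2, 2] / n2
    se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    out$prop_diff_ci <- c(p1 - p2 - zq * se, p1 - p2 + zq * se)
  }
  out
}

#' Compare fitted models against a visual-rating reference
#'
#' Computes AIC/BIC differences of each candidate model against the
#' reference (conventionally the model using the ordinal visual rating) for
#' the same outcome and sample. A candidate is flagged as a practical
#' improvement when its BIC is at least `bic_margin` (default 10) lower
#' than the reference's and its AIC is smaller too; non-overlapping effect
#' CIs are flagged as a significant difference in effects.
#'
#' @param results named list of `pvs_model` objects.
#' @param reference name or index of the reference model.
#' @param bic_margin BIC difference taken as practically meaningful.
#' @return data frame, one row per model: `dAIC`, `dBIC` (model minus
#'   reference), `practical_improvement`, `effect_differs`.
#' @export
compare_models <- function(results, reference = 1L, bic_margin = 10) {
  stopifnot(length(results) >= 1L)
  ref <- results[[reference]]
  ns <- vapply(results, `[[`, 0L, "n")
  if (length(unique(ns)) != 1L)
    stop("models fitted on different sample sizes cannot be compared")
  rows <- lapply(seq_along(results), function(i) {
    m <- results[[i]]
    ov <- !(m$effect$ci_lo > ref$effect$ci_hi ||
            m$effect$ci_hi < ref$effect$ci_lo)
    data.frame(model = if (!is.null(names(results))) names(results)[i] else i,
               AIC = m$AIC, BIC = m$BIC,
               dAIC = m$AIC - ref$AIC, dBIC = m$BIC - ref$BIC,
               practical_improvement = (ref$BIC - m$BIC >= bic_margin) &&
                 (m$AIC < ref$AIC),
               effect_differs = !ov)
  })
  do.call(rbind, rows)
}

#' Fit the association battery of one PVS measure across outcomes
#'
#' Chooses the model family per outcome the way the cohort analysis does:
#' linear for continuous/ordinal-as-continuous outcomes (age, Fazekas
#' total), logistic for binary risk factors, and beta regression (with the
#' squeeze transform) for the WMH proportion of ICV.
#'
#' @param data cohort data frame.
#' @param pvs_measure predictor column name.
#' @param outcomes character vector of outcome columns.
#' @param binary_outcomes which outcomes are binary.
#' @param proportion_outcomes which outcomes are proportions in [0,1).
#' @return named list of `pvs_model` objects.
#' @export
pvs_associations <- function(data, pvs_measure,
                             outcomes = c("fazekas_total", "wmh_pct_icv",
                                          "hypertension", "cholesterol",
                                          "diabetes", "cvd", "stroke", "age"),
                             binary_outcomes = c("hypertension", "cholesterol",
                                                 "diabetes", "cvd", "stroke",
                                                 "sex"),
                             proportion_outcomes = "wmh_pct_icv") {
  res <- list()
  for (oc in outcomes) {
    res[[oc]] <- if (oc %in% binary_outcomes) {
      fit_logistic(data, oc, pvs_measure)
    } else if (oc %in% proportion_outcomes) {
      d2 <- data
      d2[[oc]] <- squeeze_transform(d2[[oc]], n = nrow(d2))
      fit_beta_regression(d2, oc, pvs_measure)
    } else {
      fit_linear(data, oc, pvs_measure)
    }
  }
  res
}
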