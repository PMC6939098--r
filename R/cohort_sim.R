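#' Specification for a simulated cohort
#'
#' Simulates per-subject rows with the statistical structure of an older-age
#' community cohort: a latent PVS-burden score drives continuous PVS
#' morphometry, binary vascular risk factors through logistic models, WMH
#' volume (as a proportion of intracranial volume) through a beta model with
#' logit-linked mean, and an ordinal 0-4 visual rating through cutpoints on
#' the latent score. Default marginals follow the target cohort: binary
#' prevalences (hypertension 47.65%, diabetes 9.57%, hypercholesterolemia
#' 39.21%, CVD history 28.33%, stroke 17.64%), age 72.5 (SD 0.69) years,
#' 46.7% female, WMH about 1% of ICV, and the PVS metric means/SDs of the
#' same regime (count 258 +/- 95, etc.).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param prevalences named probabilities in (0,1) for the binary outcomes.
#' @param effect_log_odds named per-SD log-odds effects of the latent burden
#'   on each binary outcome (default all 0).
#' @param beta_reg_coefs (intercept, slope) on the logit scale for the mean
#'   WMH proportion as a function of latent burden; the default intercept
#'   -4.6 puts the mean at plogis(-4.6) ~ 0.01.
#' @param beta_precision beta-distribution precision phi (> 0).
#' @param rating_cutpoints 4 strictly ascending cutpoints on the latent
#'   scale for the 0-4 rating.
#' @param rating_misclass probability of +/-1 category misclassification.
#' @param age_mean,age_sd,sex_prop_female covariate marginals.
#' @param seed integer RNG seed.
#' @return a `cohort_sim_spec` list.
#' @export
cohort_sim_spec <- function(n_subjects = 533L,
                            prevalences = c(hypertension = 0.4765,
                                            diabetes = 0.0957,
                                            cholesterol = 0.3921,
                                            cvd = 0.2833,
                                            stroke = 0.1764),
                            effect_log_odds = NULL,
                            beta_reg_coefs = c(-4.6, 0),
                            beta_precision = 50,
                            rating_cutpoints = c(-2.5, -1.0, 0.8, 2.2),
                            rating_misclass = 0,
                            age_mean = 72.5, age_sd = 0.69,
                            sex_prop_female = 0.467,
                            seed = 1L) {
  if (is.null(effect_log_odds))
    effect_log_odds <- setNames(rep(0, length(prevalences)), names(prevalences))
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  if (any(prevalences <= 0) || any(prevalences >= 1))
    stop("prevalences must be strictly inside (0,1)")
  if (beta_precision <= 0) stop("beta_precision must be positive")
  if (length(rating_cutpoints) != 4L || is.unsorted(rating_cutpoints, strictly = TRUE))
    stop("rating_cutpoints must be 4 strictly ascending values")
  if (!all(names(prevalences) %in% names(effect_log_odds)))
    stop("effect_log_odds must name every outcome in prevalences")
  structure(list(n_subjects = as.integer(n_subjects),
                 prevalences = prevalences,
                 effect_log_odds = effect_log_odds,
                 beta_reg_coefs = beta_reg_coefs,
                 beta_precision = beta_precision,
                 rating_cutpoints = rating_cutpoints,
                 rating_misclass = rating_misclass,
                 age_mean = age_mean, age_sd = age_sd,
                 sex_prop_female = sex_prop_female,
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

# marginal mean/SD and latent loading of each continuous PVS metric in the
# target regime (loadings chosen to reproduce the observed correlation
# pattern: volume/size track burden closely, count more noisily)
.pvs_metric_params <- data.frame(
  metric = c("pvs_count", "pvs_volume", "pvs_mean_length",
             "pvs_mean_width", "pvs_mean_size"),
  mean = c(258.07, 3274.78, 3.94, 2.01, 13.76),
  sd = c(94.81, 1464.42, 0.54, 0.36, 4.85),
  loading = c(0.70, 0.90, 0.85, 0.85, 0.80))

#' Simulate a cohort table with known effect structure
#'
#' @param spec a [cohort_sim_spec].
#' @return data frame with one row per subject: demographics, binary risk
#'   factors, `fazekas_total` (0-6), `wmh_pct_icv` (proportion in [0,1)),
#'   `pvs_visual` (0-4), the five continuous PVS metrics, and the hidden
#'   generating score `latent_burden` (kept for parameter-recovery tests;
#'   drop it to mimic real data).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    L <- rnorm(n)
    df <- data.frame(latent_burden = L,
                     age = rnorm(n, spec$age_mean, spec$age_sd),
                     sex = rbinom(n, 1, spec$sex_prop_female))
    for (i in seq_len(nrow(.pvs_metric_params))) {
      p <- .pvs_metric_params[i, ]
      z <- p$loading * L + sqrt(1 - p$loading^2) * rnorm(n)
      df[[p$metric]] <- p$mean + p$sd * z
    }
    df$pvs_count <- pmax(round(df$pvs_count), 0)
    df$pvs_volume <- pmax(df$pvs_volume, 0)
    for (oc in names(spec$prevalences)) {
      eta <- qlogis(spec$prevalences[[oc]]) + spec$effect_log_odds[[oc]] * L
      df[[oc]] <- rbinom(n, 1, plogis(eta))
    }
    mu <- plogis(spec$beta_reg_coefs[1] + spec$beta_reg_coefs[2] * L)
    df$wmh_pct_icv <- rbeta(n, mu * spec$beta_precision,
                            (1 - mu) * spec$beta_precision)
    fz <- round(2.47 + 1.14 * (0.6 * L + 0.8 * rnorm(n)))
    df$fazekas_total <- pmin(pmax(fz, 0), 6)
    rating <- findInterval(L, spec$rating_cutpoints)
    if (spec$rating_misclass > 0) {
      flip <- runif(n) < spec$rating_misclass
      rating[flip] <- pmin(pmax(rating[flip] +
                                  sample(c(-1L, 1L), sum(flip), TRUE), 0L), 4L)
    }
    df$pvs_visual <- rating
    df
  })
}
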