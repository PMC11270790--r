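#' Simulated-cohort specification
#'
#' Describes a synthetic DLBCL-like cohort: clinical covariates drawn to
#' match a realistic baseline mix, a log-normal MTA distribution, and
#' progression-free and overall survival times generated from a Weibull
#' proportional-hazards model with user-chosen true log-hazard-ratios and
#' administrative censoring.
#'
#' Covariate defaults emulate a typical first-line R-CHOP cohort: median
#' MTA near 2.4 cm^2 with quartiles near 0.95/5.0, about a quarter of
#' patients over 75, 45% with elevated LDH, 59% advanced Ann Arbor stage,
#' 30% ECOG >= 2 and 41% multi-site extranodal disease. Event times follow
#' hazard h_0(t) exp(sum beta x) with Weibull baseline (shape 1 =
#' exponential, so Kaplan-Meier curves have closed forms in tests).
#'
#' @param n number of patients, >= 1.
#' @param seed RNG seed; fixes the whole cohort.
#' @param mta_meanlog,mta_sdlog log-normal parameters of the MTA (cm^2).
#' @param sex_male_p probability of male sex.
#' @param age_probs probabilities of the four age bands <=40 / 41-60 /
#'   61-75 / >75 (must sum to 1).
#' @param ldh_probs probabilities of LDH ratio bands <=1 / (1,3] / >3.
#' @param ecog2_p probability of ECOG performance status >= 2.
#' @param ann_arbor_adv_p probability of Ann Arbor stage III/IV.
#' @param lugano_extra_p probability that a stage-I/II patient is
#'   nevertheless Lugano III/IV (stages are otherwise concordant).
#' @param en_multi_p probability of more than one extranodal site.
#' @param en_major_p_multi,en_major_p_single probability of major-organ
#'   extranodal involvement given multi-/single-site disease.
#' @param beta_pfs,beta_os named numeric vectors of true log-hazard-ratios;
#'   names must be numeric columns of the generated table (e.g.
#'   `mta_high_pfs`, `nccn_high`, `log_mta`, or any extra covariate).
#' @param shape_pfs,scale_pfs,shape_os,scale_os Weibull baseline parameters
#'   (shape dimensionless, scale in months), all > 0.
#' @param censor_months administrative censoring window in months (>= 0).
#' @param mta_cut_pfs,mta_cut_os cut-offs (cm^2) defining the dichotomised
#'   MTA columns used by the default effects.
#' @param extra_covariates named list of additional generators, each
#'   `list(dist = "binary", p = ...)` or `list(dist = "normal", mean, sd)`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, seed = 1L,
                        mta_meanlog = log(2.37), mta_sdlog = 1.23,
                        sex_male_p = 0.518,
                        age_probs = c(0.075, 0.243, 0.479, 0.204),
                        ldh_probs = c(0.546, 0.386, 0.068),
                        ecog2_p = 0.304,
                        ann_arbor_adv_p = 0.589,
                        lugano_extra_p = 0.088,
                        en_multi_p = 0.407,
                        en_major_p_multi = 0.6,
                        en_major_p_single = 0.275,
                        beta_pfs = c(mta_high_pfs = log(2.617),
                                     nccn_high = log(2.633)),
                        beta_os = c(mta_high_os = log(2.021),
                                    nccn_high = log(3.869)),
                        shape_pfs = 1, scale_pfs = 280,
                        shape_os = 1, scale_os = 380,
                        censor_months = 88,
                        mta_cut_pfs = 1.36, mta_cut_os = 5.73,
                        extra_covariates = list()) {
  stopifnot(n >= 1, mta_sdlog > 0,
            shape_pfs > 0, scale_pfs > 0, shape_os > 0, scale_os > 0,
            censor_months >= 0)
  # percentages quoted from baseline tables carry rounding; allow it and
  # renormalise
  for (p in list(age_probs, ldh_probs)) {
    if (abs(sum(p) - 1) > 0.01)
      stop("covariate category probabilities must sum to 1", call. = FALSE)
  }
  age_probs <- age_probs / sum(age_probs)
  ldh_probs <- ldh_probs / sum(ldh_probs)
  if ((length(beta_pfs) && is.null(names(beta_pfs))) ||
      (length(beta_os) && is.null(names(beta_os))))
    stop("'beta_pfs'/'beta_os' must be named by covariate column",
         call. = FALSE)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 mta_meanlog = mta_meanlog, mta_sdlog = mta_sdlog,
                 sex_male_p = sex_male_p, age_probs = age_probs,
                 ldh_probs = ldh_probs, ecog2_p = ecog2_p,
                 ann_arbor_adv_p = ann_arbor_adv_p,
                 lugano_extra_p = lugano_extra_p,
                 en_multi_p = en_multi_p,
                 en_major_p_multi = en_major_p_multi,
                 en_major_p_single = en_major_p_single,
                 beta_pfs = beta_pfs, beta_os = beta_os,
                 shape_pfs = shape_pfs, scale_pfs = scale_pfs,
                 shape_os = shape_os, scale_os = scale_os,
                 censor_months = censor_months,
                 mta_cut_pfs = mta_cut_pfs, mta_cut_os = mta_cut_os,
                 extra_covariates = extra_covariates),
            class = "cohort_spec")
}

# Weibull proportional-hazards event time: S(t | x) =
# exp(-(t/scale)^shape * exp(lp)), inverted at a uniform draw.
.ph_weibull_time <- function(u, lp, shape, scale) {
  scale * (-log(u) / exp(lp))^(1 / shape)
}

.linear_predictor <- function(df, beta) {
  if (!length(beta)) return(rep(0, nrow(df)))
  missing <- setdiff(names(beta), names(df))
  if (length(missing))
    stop("unknown covariates in beta: ", paste(missing, collapse = ", "),
         call. = FALSE)
  lp <- rep(0, nrow(df))
  for (nm in names(beta)) lp <- lp + beta[[nm]] * as.numeric(df[[nm]])
  lp
}

#' Simulate a survival cohort
#'
#' Draws a clinical/metabolic covariate table per the generators in a
#' [cohort_spec], scores it with [nccn_ipi()], and generates PFS and OS
#' times from the Weibull proportional-hazards model with administrative
#' censoring at `censor_months`. Deterministic given the spec's seed.
#'
#' @param spec a [cohort_spec].
#' @return A data frame with clinical columns (`age`, `sex`, `ldh_ratio`,
#'   `ecog`, `ann_arbor`, `lugano`, `en_sites`, `en_major_organ`), the MTA
#'   and its derived columns (`log_mta`, `mta_high_pfs`, `mta_high_os`),
#'   NCCN-IPI columns (`nccn_score`, `nccn_group`, `nccn_high`), any extra
#'   covariates, and survival columns `pfs_months`, `pfs_event`,
#'   `os_months`, `os_event`.
#' @examples
#' coh <- simulate_cohort(cohort_spec(n = 100, seed = 7))
#' mean(coh$pfs_event)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  set.seed(spec$seed)
  n <- spec$n

  age_band <- sample.int(4L, n, replace = TRUE, prob = spec$age_probs)
  age <- c(18, 41, 61, 76)[age_band] +
    floor(stats::runif(n) * c(23, 20, 15, 15)[age_band])
  sex <- ifelse(stats::runif(n) < spec$sex_male_p, "male", "female")

  ldh_band <- sample.int(3L, n, replace = TRUE, prob = spec$ldh_probs)
  ldh_ratio <- c(stats::runif(n, 0.4, 1.0),
                 stats::runif(n, 1.01, 3.0),
                 stats::runif(n, 3.01, 6.0))[(ldh_band - 1L) * n + seq_len(n)]

  ecog_high <- stats::runif(n) < spec$ecog2_p
  ecog <- ifelse(ecog_high,
                 sample(2:4, n, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
                 sample(0:1, n, replace = TRUE))

  ann_adv <- stats::runif(n) < spec$ann_arbor_adv_p
  ann_arbor <- ifelse(ann_adv, sample(c("III", "IV"), n, replace = TRUE),
                      sample(c("I", "II"), n, replace = TRUE))
  lugano <- ifelse(ann_adv | stats::runif(n) < spec$lugano_extra_p,
                   sample(c("III", "IV"), n, replace = TRUE),
                   sample(c("I", "II"), n, replace = TRUE))

  en_multi <- stats::runif(n) < spec$en_multi_p
  en_sites <- ifelse(en_multi, sample(2:4, n, replace = TRUE),
                     sample(0:1, n, replace = TRUE))
  en_major <- stats::runif(n) < ifelse(en_multi, spec$en_major_p_multi,
                                       spec$en_major_p_single)

  mta <- stats::rlnorm(n, spec$mta_meanlog, spec$mta_sdlog)

  df <- data.frame(
    patient_id = seq_len(n), age = age, sex = sex,
    ldh_ratio = ldh_ratio, ecog = ecog,
    ann_arbor = ann_arbor, lugano = lugano,
    en_sites = en_sites, en_major_organ = en_major,
    mta = mta, log_mta = log(mta),
    mta_high_pfs = as.integer(mta >= spec$mta_cut_pfs),
    mta_high_os = as.integer(mta >= spec$mta_cut_os),
    stringsAsFactors = FALSE)

  ipi <- nccn_ipi(df)
  df$nccn_score <- ipi$total
  df$nccn_group <- ipi$group
  df$nccn_high <- as.integer(ipi$total >= 4L)

  for (nm in names(spec$extra_covariates)) {
    g <- spec$extra_covariates[[nm]]
    df[[nm]] <- switch(g$dist,
      binary = as.integer(stats::runif(n) < g$p),
      normal = stats::rnorm(n, g$mean %||% 0, g$sd %||% 1),
      stop("unknown covariate generator: ", g$dist, call. = FALSE))
  }

  t_pfs <- .ph_weibull_time(stats::runif(n),
                            .linear_predictor(df, spec$beta_pfs),
                            spec$shape_pfs, spec$scale_pfs)
  t_os <- .ph_weibull_time(stats::runif(n),
                           .linear_predictor(df, spec$beta_os),
                           spec$shape_os, spec$scale_os)
  df$pfs_months <- pmin(t_pfs, spec$censor_months)
  df$pfs_event <- as.integer(t_pfs <= spec$censor_months)
  df$os_months <- pmin(t_os, spec$censor_months)
  df$os_event <- as.integer(t_os <= spec$censor_months)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
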