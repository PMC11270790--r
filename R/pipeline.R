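#' Analysis-plan configuration
#'
#' Controls the staged prognostic analysis of [run_analysis_plan()]:
#' which endpoints and metabolic metrics are analysed, how metrics enter
#' the Cox models, the significance level gating entry into the
#' multivariate model, and optional pre-specified cut-offs (when absent,
#' cut-offs are recomputed from the cohort by ROC/Youden).
#'
#' @param endpoints subset of `c("pfs", "os")`.
#' @param metrics metabolic metric columns to analyse (used where present
#'   in the cohort).
#' @param metric_form `"dichotomized"` (metrics enter Cox models as
#'   high/low at their cut-off) or `"continuous"` (log-transformed for the
#'   skewed volume/area metrics).
#' @param alpha univariate significance level required to enter the
#'   multivariate model.
#' @param cutoffs optional named list per endpoint of named numeric
#'   cut-offs per metric, e.g.
#'   `list(pfs = c(mta = 1.36, tmtv = 215.78), os = c(mta = 5.73))`;
#'   metrics without a supplied value get an ROC/Youden cut-off.
#' @param three_year_months evaluation time of the "3-year" survival rate,
#'   in months.
#' @return An object of class `plan_config`.
#' @export
plan_config <- function(endpoints = c("pfs", "os"),
                        metrics = c("mta", "tmtv", "suvmax", "suvmean"),
                        metric_form = c("dichotomized", "continuous"),
                        alpha = 0.05, cutoffs = NULL,
                        three_year_months = 36) {
  metric_form <- match.arg(metric_form)
  endpoints <- match.arg(endpoints, several.ok = TRUE)
  stopifnot(alpha > 0, alpha < 1, three_year_months > 0)
  structure(list(endpoints = endpoints, metrics = metrics,
                 metric_form = metric_form, alpha = alpha,
                 cutoffs = cutoffs, three_year_months = three_year_months),
            class = "plan_config")
}

# Binary clinical parameters of the univariate screen, derived from cohort
# columns where available.
.clinical_binaries <- function(cohort) {
  out <- list()
  if ("lugano" %in% names(cohort))
    out$lugano_stage <- as.integer(cohort$lugano %in% c("III", "IV"))
  if ("age" %in% names(cohort))
    out$age <- as.integer(cohort$age > 60)
  if ("ann_arbor" %in% names(cohort))
    out$ann_arbor_stage <- as.integer(cohort$ann_arbor %in% c("III", "IV"))
  if ("en_sites" %in% names(cohort))
    out$en <- as.integer(cohort$en_sites > 1)
  if ("ldh_ratio" %in% names(cohort))
    out$ldh <- as.integer(cohort$ldh_ratio > 1)
  if ("ecog" %in% names(cohort))
    out$ecog_ps <- as.integer(cohort$ecog >= 2)
  out
}

.cox_row <- function(fit, parameter) {
  data.frame(parameter = parameter,
             hr = fit$hr, ci_lower = fit$ci_lower, ci_upper = fit$ci_upper,
             p = fit$p, converged = fit$converged, row.names = NULL)
}

.km_row <- function(label, time, event, t36) {
  km <- km_estimate(time, event)
  data.frame(group = label, n = length(time), events = sum(event),
             rate_3yr = 100 * survival_at(km, t36))
}

#' Run the staged prognostic analysis
#'
#' Executes, per endpoint: (1) ROC/Youden cut-off selection for each
#' metabolic metric; (2) univariate Cox regression of every metabolic and
#' clinical parameter; (3) a multivariate Cox model over the parameters
#' with univariate p below `alpha`; (4) a bivariate Cox model of
#' dichotomised MTA together with the NCCN-IPI high-risk indicator; and
#' (5) Kaplan-Meier curves with log-rank tests for the MTA split, the
#' NCCN-IPI split, and the MTA split within the NCCN-IPI >= 4 subgroup,
#' reporting 3-year rates. Every decision (cut-off source, parameters
#' entered, strata skipped for lack of events) is appended to a run log.
#'
#' @param cohort data frame with survival columns (`pfs_months`,
#'   `pfs_event`, `os_months`, `os_event` as applicable), metabolic metric
#'   columns, and clinical columns (as produced by [simulate_cohort()] or
#'   an equivalent CSV).
#' @param config a [plan_config].
#' @return An object of class `mta_report`: per-endpoint lists with
#'   `roc` (cut-off table), `univariate`, `multivariate`, `bivariate`
#'   (Cox tables), `km` (3-year rate table) and `logrank` (test table),
#'   plus `log` (character vector of run decisions).
#' @export
run_analysis_plan <- function(cohort, config = plan_config()) {
  cohort <- as.data.frame(cohort)
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  stopifnot(inherits(config, "plan_config"))
  runlog <- character()
  note <- function(...) runlog <<- c(runlog, sprintf(...))
  out <- list()

  for (ep in config$endpoints) {
    tcol <- paste0(ep, "_months"); ecol <- paste0(ep, "_event")
    if (!all(c(tcol, ecol) %in% names(cohort)))
      stop("cohort lacks ", ep, " endpoint columns", call. = FALSE)
    time <- cohort[[tcol]]; event <- as.integer(cohort[[ecol]])
    metrics <- intersect(config$metrics, names(cohort))

    # --- stage 1: cut-offs -------------------------------------------------
    roc_tab <- data.frame()
    cutoffs <- numeric(0)
    for (m in metrics) {
      supplied <- if (is.null(config$cutoffs)) NULL
                  else config$cutoffs[[ep]][m]
      rr <- tryCatch(roc_youden(cohort[[m]], event), error = function(e) e)
      if (inherits(rr, "error")) {
        note("[%s] ROC for %s skipped: %s", ep, m, conditionMessage(rr))
        next
      }
      if (length(supplied) == 1L && !is.na(supplied)) {
        cutoffs[m] <- as.numeric(supplied)
        note("[%s] cut-off for %s supplied: %.4g", ep, m, cutoffs[m])
      } else {
        cutoffs[m] <- rr$cutoff
        note("[%s] cut-off for %s computed by ROC/Youden: %.4g",
             ep, m, cutoffs[m])
      }
      roc_tab <- rbind(roc_tab, data.frame(
        parameter = m, auc = rr$auc, cutoff = cutoffs[m],
        sensitivity = rr$sensitivity, specificity = rr$specificity))
    }

    # --- stage 2: univariate Cox ------------------------------------------
    params <- list()
    for (m in names(cutoffs)) {
      params[[m]] <- if (config$metric_form == "dichotomized")
        as.integer(cohort[[m]] >= cutoffs[m])
      else if (all(cohort[[m]] > 0)) log(cohort[[m]]) else cohort[[m]]
    }
    params <- c(params, .clinical_binaries(cohort))
    uni <- data.frame()
    for (nm in names(params)) {
      fit <- tryCatch(
        cox_fit(matrix(params[[nm]], ncol = 1L,
                       dimnames = list(NULL, nm)), time, event),
        error = function(e) e)
      if (inherits(fit, "error")) {
        note("[%s] univariate Cox for %s skipped: %s", ep, nm,
             conditionMessage(fit))
        next
      }
      uni <- rbind(uni, .cox_row(fit, nm))
    }

    # --- stage 3: multivariate Cox ----------------------------------------
    sel <- uni$parameter[uni$p < config$alpha & uni$converged]
    multi <- NULL
    if (length(sel) >= 1L) {
      note("[%s] multivariate model over: %s", ep,
           paste(sel, collapse = ", "))
      X <- do.call(cbind, params[sel])
      colnames(X) <- sel
      mfit <- tryCatch(cox_fit(X, time, event), error = function(e) e)
      if (inherits(mfit, "error")) {
        note("[%s] multivariate Cox failed: %s", ep, conditionMessage(mfit))
      } else {
        multi <- .cox_row(mfit, sel)
      }
    } else {
      note("[%s] no parameter reached univariate p < %.3g; %s", ep,
           config$alpha, "multivariate model not fitted")
    }

    # --- stage 4: bivariate MTA + NCCN-IPI --------------------------------
    bi <- NULL
    if ("mta" %in% names(cutoffs) && "nccn_high" %in% names(cohort)) {
      X <- cbind(mta = as.integer(cohort$mta >= cutoffs["mta"]),
                 nccn_ipi = as.integer(cohort$nccn_high))
      bfit <- tryCatch(cox_fit(X, time, event), error = function(e) e)
      if (inherits(bfit, "error")) {
        note("[%s] bivariate MTA + NCCN-IPI model failed: %s", ep,
             conditionMessage(bfit))
      } else {
        bi <- .cox_row(bfit, c("mta", "nccn_ipi"))
      }
    }

    # --- stage 5: KM / log-rank strata ------------------------------------
    km_tab <- data.frame(); lr_tab <- data.frame()
    strata <- list()
    if ("mta" %in% names(cutoffs)) {
      hi <- cohort$mta >= cutoffs["mta"]
      strata[["MTA"]] <- list(low = !hi, high = hi)
    }
    if ("nccn_high" %in% names(cohort)) {
      hi <- cohort$nccn_high == 1L
      strata[["NCCN-IPI"]] <- list(low = !hi, high = hi)
      if ("mta" %in% names(cutoffs)) {
        sub <- cohort$nccn_high == 1L
        mh <- cohort$mta >= cutoffs["mta"]
        strata[["MTA within NCCN-IPI >= 4"]] <-
          list(low = sub & !mh, high = sub & mh)
      }
    }
    for (sn in names(strata)) {
      lo <- strata[[sn]]$low; hi <- strata[[sn]]$high
      for (side in c("low", "high")) {
        idx <- if (side == "low") lo else hi
        if (!any(idx)) {
          note("[%s] stratum '%s %s' empty; Kaplan-Meier skipped", ep, sn,
               side)
          next
        }
        km_tab <- rbind(km_tab, cbind(
          stratification = sn,
          .km_row(side, time[idx], event[idx], config$three_year_months)))
      }
      if (!any(lo) || !any(hi) ||
          sum(event[lo | hi]) == 0L) {
        note("[%s] log-rank for '%s' skipped: %s", ep, sn,
             if (!any(lo) || !any(hi)) "an arm is empty"
             else "no events in either arm")
        next
      }
      lr <- logrank(time[lo], event[lo], time[hi], event[hi])
      lr_tab <- rbind(lr_tab, data.frame(
        stratification = sn, chisq = lr$chisq, p = lr$p))
    }

    out[[ep]] <- list(roc = roc_tab, univariate = uni, multivariate = multi,
                      bivariate = bi, km = km_tab, logrank = lr_tab)
  }
  out$log <- runlog
  class(out) <- "mta_report"
  out
}

#' @export
print.mta_report <- function(x, digits = 3, ...) {
  for (ep in setdiff(names(x), "log")) {
    cat(sprintf("== Endpoint: %s ==\n", toupper(ep)))
    r <- x[[ep]]
    if (nrow(r$roc)) {
      cat("ROC / Youden cut-offs:\n")
      print(transform(r$roc, auc = round(auc, digits),
                      sensitivity = round(sensitivity, digits),
                      specificity = round(specificity, digits)),
            row.names = FALSE)
    }
    cat("Univariate Cox:\n")
    print(.round_cox_tab(r$univariate, digits), row.names = FALSE)
    if (!is.null(r$multivariate)) {
      cat("Multivariate Cox:\n")
      print(.round_cox_tab(r$multivariate, digits), row.names = FALSE)
    }
    if (!is.null(r$bivariate)) {
      cat("Bivariate MTA + NCCN-IPI:\n")
      print(.round_cox_tab(r$bivariate, digits), row.names = FALSE)
    }
    if (nrow(r$km)) {
      cat("Kaplan-Meier 3-year rates (%):\n")
      print(transform(r$km, rate_3yr = round(rate_3yr, 1)),
            row.names = FALSE)
    }
    if (nrow(r$logrank)) {
      cat("Log-rank tests:\n")
      print(transform(r$logrank, chisq = round(chisq, digits),
                      p = format_p(p)), row.names = FALSE)
    }
    cat("\n")
  }
  invisible(x)
}

.round_cox_tab <- function(tab, digits) {
  data.frame(parameter = tab$parameter, hr = round(tab$hr, digits),
             ci_lower = round(tab$ci_lower, digits),
             ci_upper = round(tab$ci_upper, digits),
             p = format_p(tab$p))
}

#' Baseline-characteristics summary table
#'
#' Summarises a cohort the way baseline tables are reported: categorical
#' variables as "n (percent)" with one decimal, continuous metabolic
#' metrics as mean (SD) and median (range).
#'
#' @param cohort cohort data frame (see [simulate_cohort()]); must be
#'   non-empty.
#' @return A data frame with columns `variable`, `level`, `value`.
#' @examples
#' cohort_table(simulate_cohort(cohort_spec(50, seed = 2)))
#' @export
cohort_table <- function(cohort) {
  cohort <- as.data.frame(cohort)
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  N <- nrow(cohort)
  fmt_n <- function(k) sprintf("%d (%.1f)", k, 100 * k / N)
  rows <- list()
  add_cat <- function(variable, labels, counts) {
    keep <- !is.na(counts)
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = labels[keep],
      value = vapply(counts[keep], fmt_n, character(1L)))
  }
  if ("sex" %in% names(cohort))
    add_cat("Gender", c("Male", "Female"),
            c(sum(cohort$sex == "male"), sum(cohort$sex != "male")))
  if ("age" %in% names(cohort))
    add_cat("Age (years)", c("<=40", "41-<=60", "61-<=75", ">75"),
            c(sum(cohort$age <= 40), sum(cohort$age > 40 & cohort$age <= 60),
              sum(cohort$age > 60 & cohort$age <= 75), sum(cohort$age > 75)))
  if ("en_sites" %in% names(cohort))
    add_cat("EN", c("0-1", ">1"),
            c(sum(cohort$en_sites <= 1), sum(cohort$en_sites > 1)))
  if ("ann_arbor" %in% names(cohort))
    add_cat("Ann Arbor Stage", c("Stage I/II", "Stage III/IV"),
            c(sum(cohort$ann_arbor %in% c("I", "II")),
              sum(cohort$ann_arbor %in% c("III", "IV"))))
  if ("lugano" %in% names(cohort))
    add_cat("Lugano Stage", c("Stage I/II", "Stage III/IV"),
            c(sum(cohort$lugano %in% c("I", "II")),
              sum(cohort$lugano %in% c("III", "IV"))))
  if ("ldh_ratio" %in% names(cohort))
    add_cat("LDH", c("Normal", "High"),
            c(sum(cohort$ldh_ratio <= 1), sum(cohort$ldh_ratio > 1)))
  if ("ecog" %in% names(cohort))
    add_cat("ECOG PS", c("0-1", ">1"),
            c(sum(cohort$ecog <= 1), sum(cohort$ecog > 1)))
  if ("nccn_score" %in% names(cohort))
    add_cat("NCCN-IPI",
            c("Low (0/1)", "Low-intermediate (2/3)",
              "High-intermediate (4-5)", "High (6-8)"),
            c(sum(cohort$nccn_score <= 1),
              sum(cohort$nccn_score %in% 2:3),
              sum(cohort$nccn_score %in% 4:5),
              sum(cohort$nccn_score >= 6)))
  for (m in intersect(c("mta", "tmtv", "suvmax", "suvmean"),
                      names(cohort))) {
    v <- cohort[[m]]
    lab <- unname(c(mta = "MTA (cm^2)", tmtv = "TMTV (cm^3)",
                    suvmax = "SUVmax (g/ml)", suvmean = "SUVmean (g/ml)")[m])
    rows[[length(rows) + 1L]] <- data.frame(
      variable = lab, level = c("Mean (SD)", "Median (range)"),
      value = c(sprintf("%.2f (%.2f)", mean(v), stats::sd(v)),
                sprintf("%.2f (%.2f-%.2f)", stats::median(v),
                        min(v), max(v))))
  }
  do.call(rbind, rows)
}
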