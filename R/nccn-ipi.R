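#' NCCN-IPI risk score
#'
#' Scores each clinical record on the enhanced International Prognostic
#' Index used for DLBCL. Points: age <= 40 scores 0, 41-60 scores 1,
#' 61-75 scores 2, > 75 scores 3; LDH ratio (serum LDH / upper limit of
#' normal) <= 1 scores 0, > 1 to <= 3 scores 1, > 3 scores 2; Ann Arbor
#' stage III/IV scores 1; ECOG performance status >= 2 scores 1; and
#' extranodal involvement of a major organ (bone marrow, CNS, liver,
#' gastrointestinal tract or lung) scores 1 — a total of 0 to 8. Risk
#' groups: low 0-1, low-intermediate 2-3, high-intermediate 4-5, high 6-8;
#' the common binary split is low risk < 4 vs high risk >= 4.
#'
#' @param records data frame with columns `age` (years, > 0), `ldh_ratio`
#'   (>= 0), `ann_arbor` ("I".."IV"), `ecog` (0-4) and `en_major_organ`
#'   (logical or 0/1). Extra columns are ignored.
#' @return A data frame with one row per record: component points
#'   (`age_points`, `ldh_points`, `stage_points`, `ecog_points`,
#'   `en_points`), `total`, `group` (factor low / low-intermediate /
#'   high-intermediate / high) and `high_risk` (total >= 4).
#' @examples
#' nccn_ipi(data.frame(age = 69, ldh_ratio = 1.2, ann_arbor = "III",
#'                     ecog = 1, en_major_organ = FALSE))  # total 4
#' @export
nccn_ipi <- function(records) {
  records <- as.data.frame(records)
  need <- c("age", "ldh_ratio", "ann_arbor", "ecog", "en_major_organ")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing clinical columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  age <- as.numeric(records$age)
  ldh <- as.numeric(records$ldh_ratio)
  stage <- as.character(records$ann_arbor)
  ecog <- as.numeric(records$ecog)
  en <- as.logical(records$en_major_organ)
  if (anyNA(age) || any(age <= 0))
    stop("'age' must be positive", call. = FALSE)
  if (anyNA(ldh) || any(ldh < 0))
    stop("'ldh_ratio' must be non-negative", call. = FALSE)
  if (!all(stage %in% c("I", "II", "III", "IV")))
    stop("'ann_arbor' must be one of I, II, III, IV", call. = FALSE)
  if (anyNA(ecog) || any(ecog < 0 | ecog > 4))
    stop("'ecog' must lie in 0..4", call. = FALSE)
  if (anyNA(en)) stop("'en_major_organ' must be logical", call. = FALSE)

  age_points <- ifelse(age <= 40, 0L,
                ifelse(age <= 60, 1L,
                ifelse(age <= 75, 2L, 3L)))
  ldh_points <- ifelse(ldh <= 1, 0L, ifelse(ldh <= 3, 1L, 2L))
  stage_points <- as.integer(stage %in% c("III", "IV"))
  ecog_points <- as.integer(ecog >= 2)
  en_points <- as.integer(en)
  total <- age_points + ldh_points + stage_points + ecog_points + en_points
  group <- cut(total, breaks = c(-1, 1, 3, 5, 8),
               labels = c("low", "low-intermediate",
                          "high-intermediate", "high"))
  data.frame(age_points = age_points, ldh_points = ldh_points,
             stage_points = stage_points, ecog_points = ecog_points,
             en_points = en_points, total = as.integer(total),
             group = group, high_risk = total >= 4L)
}

#' Dichotomize a marker at a cut-off
#'
#' High risk is called when the value is greater than or equal to the
#' cut-off (the boundary itself is high, matching ">= cut-off" reporting of
#' biomarker splits).
#'
#' @param values numeric marker values.
#' @param cutoff single finite number.
#' @return Factor with levels `low`, `high`.
#' @examples
#' dichotomize(c(0.9, 1.36, 5.8), 1.36)
#' @export
dichotomize <- function(values, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff))
    stop("'cutoff' must be a single finite number", call. = FALSE)
  factor(ifelse(as.numeric(values) >= cutoff, "high", "low"),
         levels = c("low", "high"))
}
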