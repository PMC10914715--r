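#' Disease state labels, ordered from no disorder to full syndrome
#'
#' `FMD` (free of metabolic disorder), `MMD` (mild, 1 abnormal
#' component), `SMD` (severe, 2), `MetS` (3 or more).
#' @export
mets_states <- c("FMD", "MMD", "SMD", "MetS")

#' Joint Interim Statement component classification
#'
#' Flags the five abnormal metabolic components for each subject record
#' from one survey wave, using the harmonized (Joint Interim Statement)
#' cutoffs for an Asian population:
#'
#' * central obesity: waist circumference >= 85 cm (men) / >= 80 cm (women)
#' * elevated blood pressure: SBP >= 130 mmHg or DBP >= 85 mmHg, or treated
#' * elevated fasting glucose: FBG >= 5.6 mmol/L, or treated
#' * hypertriglyceridemia: TG >= 1.7 mmol/L
#' * low HDL cholesterol: HDL < 1.03 mmol/L (men) / < 1.29 mmol/L (women),
#'   or treated
#'
#' Boundary values equal to a `>=` cutoff qualify; the HDL comparison is
#' strict `<`. A criterion whose measurement is missing and whose
#' treatment flag does not already decide it cannot be evaluated:
#' by default this raises an error naming the criterion
#' (`na_action = "error"`); `na_action = "keep"` returns `NA` flags so a
#' caller can apply complete-case exclusion.
#'
#' @param data Data frame with columns `sex` ("male"/"female"),
#'   `waist_cm`, `sbp_mmhg`, `dbp_mmhg`, `fbg_mmol_l`, `tg_mmol_l`,
#'   `hdl_mmol_l` and logical `treated_htn`, `treated_glu`, `treated_hdl`
#'   (missing treatment columns are taken as all-`FALSE`).
#' @param na_action `"error"` or `"keep"`.
#' @return The input tibble with logical columns `central_obesity`,
#'   `hypertension`, `high_fbg`, `high_tg`, `low_hdl`, plus `n_abnormal`
#'   and `state` (factor FMD < MMD < SMD < MetS).
#' @export
classify_components <- function(data, na_action = c("error", "keep")) {
  na_action <- match.arg(na_action)
  data <- as_tibble(data)
  if (!"sex" %in% colnames(data) || anyNA(data$sex)) {
    abort("`sex` is required for every subject (cutoffs are sex-specific)")
  }
  if (!all(data$sex %in% c("male", "female"))) {
    abort("`sex` must be 'male' or 'female'")
  }
  flag_col <- function(nm) {
    if (nm %in% colnames(data)) {
      tidyr::replace_na(as.logical(data[[nm]]), FALSE)
    } else rep(FALSE, nrow(data))
  }
  thtn <- flag_col("treated_htn")
  tglu <- flag_col("treated_glu")
  thdl <- flag_col("treated_hdl")
  male <- data$sex == "male"

  # OR with a treatment flag: TRUE wins over a missing measurement
  or_flag <- function(value_flag, treated) ifelse(treated, TRUE, value_flag)

  res <- data |>
    mutate(
      central_obesity = data$waist_cm >= ifelse(male, 85, 80),
      hypertension = or_flag(data$sbp_mmhg >= 130 | data$dbp_mmhg >= 85, thtn),
      high_fbg = or_flag(data$fbg_mmol_l >= 5.6, tglu),
      high_tg = data$tg_mmol_l >= 1.7,
      low_hdl = or_flag(data$hdl_mmol_l < ifelse(male, 1.03, 1.29), thdl)
    )
  flags <- c("central_obesity", "hypertension", "high_fbg", "high_tg", "low_hdl")
  if (na_action == "error") {
    for (f in flags) {
      if (anyNA(res[[f]])) {
        abort(paste0("criterion '", f, "' cannot be evaluated for row ",
                     which(is.na(res[[f]]))[1],
                     ": measurement missing and no treatment flag"))
      }
    }
  }
  res |>
    mutate(
      n_abnormal = rowSums(across(all_of(flags))),
      state = classify_state(.data$n_abnormal)
    )
}

#' Four-state metabolic disease staging
#'
#' Maps the abnormal-component count to the ordered disease states
#' FMD (0 components), MMD (1), SMD (2) and MetS (3 or more).
#'
#' @param n_abnormal Integer vector of abnormal-component counts (0-5).
#' @return Ordered factor with levels `FMD < MMD < SMD < MetS` (`NA` in,
#'   `NA` out).
#' @export
classify_state <- function(n_abnormal) {
  stopifnot(all(is.na(n_abnormal) | (n_abnormal >= 0 & n_abnormal <= 5)))
  idx <- pmin(n_abnormal, 3) + 1
  factor(mets_states[idx], levels = mets_states, ordered = TRUE)
}

#' Label a between-wave disease transition
#'
#' `forward` if the follow-up state is strictly worse than baseline,
#' `reverse` if strictly better, `unchanged` if equal, under the ordering
#' FMD < MMD < SMD < MetS. Any jump counts (e.g. FMD to MetS is a single
#' forward transition).
#'
#' @param baseline,followup Vectors coercible to the ordered state factor
#'   (see [classify_state()]).
#' @return Factor with levels `unchanged`, `forward`, `reverse`.
#' @export
label_transition <- function(baseline, followup) {
  as_state <- function(x) {
    if (is.factor(x)) x <- as.character(x)
    bad <- setdiff(unique(x[!is.na(x)]), mets_states)
    if (length(bad) > 0) abort(paste0("unknown state(s): ", paste(bad, collapse = ", ")))
    factor(x, levels = mets_states, ordered = TRUE)
  }
  b <- as_state(baseline)
  f <- as_state(followup)
  out <- dplyr::case_when(
    is.na(b) | is.na(f) ~ NA_character_,
    f > b ~ "forward",
    f < b ~ "reverse",
    TRUE ~ "unchanged"
  )
  factor(out, levels = c("unchanged", "forward", "reverse"))
}

#' Stage a two-wave cohort
#'
#' Classifies both waves of a longitudinal cohort (columns suffixed `_bl`
#' for baseline and `_fu` for follow-up), adds the five component flags,
#' the abnormal-component count and disease state per wave, and the
#' transition label. Subjects with an unevaluable criterion in either wave
#' are dropped (complete-case staging) with a message.
#'
#' @param cohort Data frame with `sex` plus the biomarker/treatment
#'   columns of [classify_components()] suffixed `_bl` and `_fu`.
#' @return The staged tibble with per-wave flag columns (same suffixes),
#'   `state_bl`, `state_fu` and `transition`.
#' @export
add_mets_staging <- function(cohort) {
  cohort <- as_tibble(cohort)
  stage_wave <- function(suffix) {
    cols <- c("waist_cm", "sbp_mmhg", "dbp_mmhg", "fbg_mmol_l", "tg_mmol_l",
              "hdl_mmol_l", "treated_htn", "treated_glu", "treated_hdl")
    have <- paste0(cols, suffix)[paste0(cols, suffix) %in% colnames(cohort)]
    wave <- cohort[, c("sex", have)]
    colnames(wave) <- sub(paste0(suffix, "$"), "", colnames(wave))
    out <- classify_components(wave, na_action = "keep")
    flags <- c("central_obesity", "hypertension", "high_fbg", "high_tg",
               "low_hdl", "n_abnormal", "state")
    out <- out[, flags]
    colnames(out) <- paste0(flags, suffix)
    out
  }
  staged <- bind_cols(cohort, stage_wave("_bl"), stage_wave("_fu"))
  keep <- !is.na(staged$state_bl) & !is.na(staged$state_fu)
  if (any(!keep)) {
    message(sum(!keep), " subject(s) excluded: missing criterion in at least one wave")
    staged <- staged[keep, ]
  }
  staged |>
    mutate(transition = label_transition(.data$state_bl, .data$state_fu))
}

#' Cohort transition accounting
#'
#' Summarizes the dynamic progression of a staged two-wave cohort: sample
#' size, MetS counts per wave, new MetS cases among subjects free of MetS
#' at baseline, cumulative incidence, and the split of all state changes
#' into forward progressions and reverse recoveries.
#'
#' @param staged Data frame with columns `state_bl` and `state_fu` (as
#'   produced by [add_mets_staging()]); a `transition` column is recomputed
#'   if absent.
#' @return One-row tibble: `n`, `baseline_mets`, `followup_mets`,
#'   `new_mets`, `cumulative_incidence_pct`, `unchanged_n`,
#'   `unchanged_pct`, `changes_n`, `forward_n`, `forward_pct_of_changes`,
#'   `reverse_n`, `reverse_pct_of_changes`. Percentages are unrounded;
#'   the change shares are `NA` when no subject changed state.
#' @export
cohort_summary <- function(staged) {
  staged <- as_tibble(staged)
  stopifnot(all(c("state_bl", "state_fu") %in% colnames(staged)))
  tr <- label_transition(staged$state_bl, staged$state_fu)
  n <- nrow(staged)
  bl_mets <- sum(staged$state_bl == "MetS")
  fu_mets <- sum(staged$state_fu == "MetS")
  at_risk <- staged$state_bl != "MetS"
  new_mets <- sum(at_risk & staged$state_fu == "MetS")
  changes <- sum(tr != "unchanged")
  tibble(
    n = n,
    baseline_mets = bl_mets,
    followup_mets = fu_mets,
    new_mets = new_mets,
    cumulative_incidence_pct = 100 * new_mets / sum(at_risk),
    unchanged_n = sum(tr == "unchanged"),
    unchanged_pct = 100 * sum(tr == "unchanged") / n,
    changes_n = changes,
    forward_n = sum(tr == "forward"),
    forward_pct_of_changes = if (changes > 0) 100 * sum(tr == "forward") / changes else NA_real_,
    reverse_n = sum(tr == "reverse"),
    reverse_pct_of_changes = if (changes > 0) 100 * sum(tr == "reverse") / changes else NA_real_
  )
}
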