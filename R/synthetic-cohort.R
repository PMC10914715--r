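#' Forward sampling from a Bayesian network
#'
#' Draws `n` independent complete records by ancestral (topological-order)
#' sampling. Reproducible: the same seed yields the same table.
#'
#' @param net A valid `bnet`.
#' @param n Number of rows (`n = 0` returns an empty table with the full
#'   header).
#' @param seed Integer seed.
#' @return A tibble with one factor column per node, levels as declared.
#' @export
sample_from_network <- function(net, n, seed) {
  stopifnot(n >= 0)
  set.seed(as.integer(seed))
  parents <- lapply(net$cpts, function(cp) cp$parents)
  ord <- topo_order(parents)
  if (is.null(ord)) abort("network graph is cyclic")
  codes <- matrix(NA_integer_, nrow = n, ncol = length(ord),
                  dimnames = list(NULL, ord))
  for (v in ord) {
    cp <- net$cpts[[v]]
    r <- length(bn_levels(net, v))
    probmat <- matrix(cp$prob, nrow = r)
    sizes <- vapply(cp$parents, function(p) length(bn_levels(net, p)), integer(1))
    combo <- if (length(cp$parents) == 0) rep(1L, n) else {
      combo_lin(codes[, cp$parents, drop = FALSE], sizes)
    }
    if (n > 0) {
      pm <- probmat[, combo, drop = FALSE] # r x n
      u <- runif(n)
      acc <- rep(0, n)
      drawn <- rep(r, n) # fall through to last level
      assigned <- rep(FALSE, n)
      for (k in seq_len(r - 1)) {
        acc <- acc + pm[k, ]
        hit <- !assigned & u < acc
        drawn[hit] <- k
        assigned <- assigned | hit
      }
      codes[, v] <- drawn
    }
  }
  out <- lapply(bn_nodes(net), function(v) {
    factor(bn_levels(net, v)[codes[, v]], levels = bn_levels(net, v))
  })
  names(out) <- bn_nodes(net)
  as_tibble(out)
}

#' Configuration for the synthetic longitudinal cohort generator
#'
#' Defaults encode the study conditions: covariate marginals from the
#' published probability-distribution columns, the follow-up transition
#' CPTs from the published conditional probability tables, and invented
#' (clearly synthetic) sex-specific log-normal biomarker distributions
#' whose parameters are chosen so every component's marginal prevalence
#' lands in a plausible 10-50% band. The analysis layer never depends on
#' the biomarker parameters themselves; they only have to produce the
#' right discrete structure after classification.
#'
#' @param ... Named overrides of any default element (`covariates`,
#'   `progression_cpt`, `recovery_cpt`, `biomarkers`, `treated`).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    covariates = list(
      gender = prog_marginals$gender,
      age = prog_marginals$age,
      exercise = prog_marginals$exercise,
      smoke = c(no = 0.62, yes = 0.38),
      drink = c(no = 0.67, yes = 0.33),
      functional_loss = c(no = 0.84, yes = 0.16),
      hyperuricemia = prog_marginals$hyperuricemia,
      hba1c = recov_marginals$hba1c,
      bmi = prog_marginals$bmi
    ),
    # P(move | risk flag, bmi): risk flag rows (no, yes), bmi columns
    progression_cpt = matrix(prog_outcome_cpt[, 2], nrow = 2, byrow = TRUE,
                             dimnames = list(c("no", "yes"),
                                             c("normal", "thin", "overweight"))),
    recovery_cpt = matrix(recov_outcome_cpt[, 2], nrow = 2, byrow = TRUE,
                          dimnames = list(c("no", "yes"),
                                          c("normal", "thin", "overweight"))),
    biomarkers = list(
      waist = list(median_male = 84, median_female = 79, sdlog = 0.08,
                   bmi_mult = c(normal = 1, thin = 0.92, overweight = 1.08)),
      sbp = list(median = 125, sdlog = 0.10),
      dbp = list(median = 76, sdlog = 0.10),
      fbg = list(median = 5.2, sdlog = 0.12,
                 bmi_mult = c(normal = 1, thin = 0.98, overweight = 1.05)),
      tg = list(median = 1.35, sdlog = 0.35,
                bmi_mult = c(normal = 1, thin = 0.90, overweight = 1.15)),
      hdl = list(median_male = 1.15, median_female = 1.40, sdlog = 0.18,
                 bmi_mult = c(normal = 1, thin = 1.05, overweight = 0.92))
    ),
    treated = c(htn = 0.15, glu = 0.12, hdl = 0.05) # among abnormal at baseline
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) abort(paste0("unknown config field '", nm, "'"))
    cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- "cohort_config"
  cfg
}

# value strictly on the requested side of a threshold ("above" means
# >= threshold); optionally a nudge of `base` that is pushed back if it
# crossed; all arguments vectorized
draw_side <- function(n, threshold, above, base = NULL) {
  sgn <- ifelse(above, 1, -1)
  fresh <- threshold * exp((0.02 + abs(rnorm(n, 0, 0.08))) * sgn)
  if (is.null(base)) return(fresh)
  val <- base * exp(rnorm(n, 0, 0.03))
  crossed <- (val >= threshold) != above
  val[crossed] <- fresh[crossed]
  val
}

comp_names <- c("central_obesity", "hypertension", "high_fbg", "high_tg", "low_hdl")

# draw all biomarker values for one wave given sex and bmi level;
# returns a tibble of raw values
draw_biomarkers <- function(sex, bmi, cfg) {
  b <- cfg$biomarkers
  n <- length(sex)
  male <- sex == "male"
  ml <- function(spec) {
    med <- if (!is.null(spec$median)) rep(spec$median, n) else
      ifelse(male, spec$median_male, spec$median_female)
    if (!is.null(spec$bmi_mult)) med <- med * spec$bmi_mult[as.character(bmi)]
    med * exp(rnorm(n, 0, spec$sdlog))
  }
  tibble(
    waist_cm = ml(b$waist),
    sbp_mmhg = ml(b$sbp),
    dbp_mmhg = ml(b$dbp),
    fbg_mmol_l = ml(b$fbg),
    tg_mmol_l = ml(b$tg),
    hdl_mmol_l = ml(b$hdl)
  )
}

# realize one wave's biomarkers so the component flags equal `target`
# (n x 5 logical matrix, columns comp_names); treatment flags are kept only
# where the component stays abnormal
realize_wave <- function(target, sex, treated, base = NULL) {
  n <- nrow(target)
  male <- sex == "male"
  waist_thr <- ifelse(male, 85, 80)
  hdl_thr <- ifelse(male, 1.03, 1.29)
  pick <- function(col) if (is.null(base)) NULL else base[[col]]
  out <- tibble(
    waist_cm = draw_side(n, waist_thr, target[, "central_obesity"], pick("waist_cm")),
    tg_mmol_l = draw_side(n, 1.7, target[, "high_tg"], pick("tg_mmol_l"))
  )
  # hypertension: treated flag alone keeps it abnormal; else push SBP
  t_htn <- treated[, "htn"] & target[, "hypertension"]
  sbp_ab <- target[, "hypertension"] & !t_htn
  out$sbp_mmhg <- draw_side(n, 130, sbp_ab, pick("sbp_mmhg"))
  # diastolic pressure is kept below its cutoff so the hypertension flag is
  # carried by SBP (or the treatment flag) alone and toggles stay exact
  out$dbp_mmhg <- draw_side(n, 85, FALSE, pick("dbp_mmhg"))
  t_glu <- treated[, "glu"] & target[, "high_fbg"]
  out$fbg_mmol_l <- draw_side(n, 5.6, target[, "high_fbg"] & !t_glu, pick("fbg_mmol_l"))
  t_hdl <- treated[, "hdl"] & target[, "low_hdl"]
  # low HDL is abnormal *below* the threshold
  out$hdl_mmol_l <- draw_side(n, hdl_thr, !(target[, "low_hdl"] & !t_hdl), pick("hdl_mmol_l"))
  out$treated_htn <- t_htn
  out$treated_glu <- t_glu
  out$treated_hdl <- t_hdl
  out
}

flags_matrix <- function(classified) {
  as.matrix(classified[, comp_names]) == TRUE
}

#' Generate a synthetic two-wave MetS cohort
#'
#' Emulates the discrete structure of the longitudinal survey the analysis
#' assumes, without any real data: covariates are drawn from configured
#' marginals, baseline biomarkers from sex-specific log-normal
#' distributions shifted by BMI level, the baseline disease state follows
#' by component classification, the between-wave transition is drawn from
#' the configured transition CPT given the model's two direct parents
#' (hyperuricemia and BMI level for progression; high HbA1c and BMI level
#' for recovery), and follow-up biomarkers are perturbed so that
#' reclassification realizes exactly the drawn transition.
#'
#' The cohort is the at-risk population of the requested outcome model:
#' for `outcome = "progression"` every subject starts below MetS and moves
#' forward or stays; for `outcome = "recovery"` every subject starts above
#' FMD and recovers or stays. Baseline draws incompatible with the at-risk
#' condition are resolved by re-realizing the baseline component profile
#' at an admissible abnormal-component count.
#'
#' @param n Number of subjects.
#' @param seed Integer seed; the output is bit-reproducible given the seed.
#' @param outcome `"progression"` or `"recovery"`.
#' @param config A [cohort_config()].
#' @return A tibble with one row per subject: covariate factors,
#'   baseline/follow-up biomarkers and treatment flags (`_bl` / `_fu`
#'   suffixes) and the drawn transition in `sim_transition`.
#' @export
generate_cohort <- function(n, seed, outcome = c("progression", "recovery"),
                            config = cohort_config()) {
  outcome <- match.arg(outcome)
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  cv <- config$covariates
  draw_cov <- function(m) factor(sample(names(m), n, replace = TRUE, prob = m),
                                 levels = names(m))
  covs <- tibble(
    id = seq_len(n),
    sex = factor(as.character(draw_cov(cv$gender)),
                 levels = c("female", "male")),
    age_group = draw_cov(cv$age),
    exercise = draw_cov(cv$exercise),
    smoke = draw_cov(cv$smoke),
    drink = draw_cov(cv$drink),
    functional_loss = draw_cov(cv$functional_loss),
    hyperuricemia = draw_cov(cv$hyperuricemia),
    high_hba1c = draw_cov(cv$hba1c),
    bmi_level = draw_cov(cv$bmi)
  )
  sex_chr <- ifelse(covs$sex == "male", "male", "female")

  bl <- draw_biomarkers(sex_chr, covs$bmi_level, config)
  cls <- classify_components(bind_cols(tibble(sex = sex_chr), bl),
                             na_action = "keep")
  flags <- flags_matrix(cls)
  # treatment at baseline only among subjects abnormal by value
  treated <- cbind(
    htn = flags[, "hypertension"] & runif(n) < config$treated[["htn"]],
    glu = flags[, "high_fbg"] & runif(n) < config$treated[["glu"]],
    hdl = flags[, "low_hdl"] & runif(n) < config$treated[["hdl"]]
  )

  # enforce the at-risk baseline state by re-realizing offenders' profiles
  count <- rowSums(flags)
  offenders <- if (outcome == "progression") which(count >= 3) else which(count == 0)
  if (length(offenders) > 0) {
    t_new <- if (outcome == "progression") {
      sample(0:2, length(offenders), replace = TRUE, prob = c(0.2, 0.4, 0.4))
    } else {
      sample(1:2, length(offenders), replace = TRUE)
    }
    target <- flags[offenders, , drop = FALSE]
    for (i in seq_along(offenders)) {
      target[i, ] <- FALSE
      if (t_new[i] > 0) target[i, sample(5, t_new[i])] <- TRUE
    }
    treated[offenders, ] <- treated[offenders, , drop = FALSE] &
      target[, c("hypertension", "high_fbg", "low_hdl")]
    redo <- realize_wave(target, sex_chr[offenders],
                         treated[offenders, , drop = FALSE])
    bl[offenders, colnames(bl)] <- redo[, colnames(bl)]
    flags[offenders, ] <- target
    count <- rowSums(flags)
  }
  bl$treated_htn <- treated[, "htn"]
  bl$treated_glu <- treated[, "glu"]
  bl$treated_hdl <- treated[, "hdl"]

  # transition draw from the configured CPT given the two direct parents
  cpt <- if (outcome == "progression") config$progression_cpt else config$recovery_cpt
  risk <- if (outcome == "progression") covs$hyperuricemia else covs$high_hba1c
  p_move <- cpt[cbind(as.character(risk), as.character(covs$bmi_level))]
  move <- runif(n) < p_move

  # follow-up component targets
  target <- flags
  state_idx <- pmin(count, 3) # 0..3
  for (i in which(move)) {
    if (outcome == "progression") {
      normals <- which(!flags[i, ])
      target[i, normals[sample.int(length(normals), 1)]] <- TRUE
    } else {
      goal <- c(0, 0, 1, 2)[state_idx[i] + 1] # next state down
      drop_k <- count[i] - goal
      abn <- which(flags[i, ])
      untreated <- setdiff(abn, c(2, 3, 5)[treated[i, ]])
      take <- if (length(untreated) >= drop_k) {
        untreated[sample.int(length(untreated), drop_k)]
      } else {
        c(untreated, setdiff(abn, untreated)[sample.int(length(abn) - length(untreated),
                                                        drop_k - length(untreated))])
      }
      target[i, take] <- FALSE
    }
  }
  fu <- realize_wave(target, sex_chr, treated, base = bl)

  out <- bind_cols(
    covs,
    rename_with(bl, ~ paste0(.x, "_bl")),
    rename_with(fu, ~ paste0(.x, "_fu"))
  )
  out$sim_transition <- factor(
    ifelse(move, if (outcome == "progression") "forward" else "reverse",
           "unchanged"),
    levels = c("unchanged", "forward", "reverse")
  )
  out
}
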