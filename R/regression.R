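#' Model specification for the downstream regressions
#'
#' @param outcome One of `"OS"` (Cox proportional hazards on survival),
#'   `"BIOPSY_ONLY"`, `"RADIOCHEMO"` (binomial logistic) or `"RTV_BIN"`
#'   (proportional-odds ordered logistic on the 5-mL RTV bins, resected
#'   patients only).
#' @param candidate_covariates Character vector of registry columns to
#'   screen. Defaults per outcome to the clinically eligible set.
#' @param interaction_terms Character vector of interactions (`"a:b"`)
#'   tested in the multivariable model; default `age_years:tvtb_cm` for OS,
#'   none otherwise.
#' @param screening_alpha Univariable inclusion threshold (default 0.1).
#' @param interaction_alpha Multivariable inclusion threshold for
#'   interaction terms (default 0.01, stricter due to multiple testing).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(outcome = c("OS", "BIOPSY_ONLY", "RADIOCHEMO", "RTV_BIN"),
                       candidate_covariates = NULL,
                       interaction_terms = NULL,
                       screening_alpha = 0.1,
                       interaction_alpha = 0.01) {
  outcome <- match.arg(outcome)
  if (is.null(candidate_covariates)) {
    candidate_covariates <- switch(outcome,
      OS = c("age_years", "sex", "kps_at_least_70", "preop_volume_ml",
             "tvtb_cm", "biopsy_only", "rtv_ml", "radiochemo"),
      BIOPSY_ONLY = c("age_years", "sex", "kps_at_least_70",
                      "preop_volume_ml", "tvtb_cm"),
      RADIOCHEMO = c("age_years", "sex", "kps_at_least_70",
                     "preop_volume_ml", "tvtb_cm", "biopsy_only", "rtv_ml"),
      RTV_BIN = c("age_years", "sex", "kps_at_least_70",
                  "preop_volume_ml", "tvtb_cm"))
  }
  if (is.null(interaction_terms))
    interaction_terms <- if (outcome == "OS") "age_years:tvtb_cm" else character(0)
  outcome_col <- switch(outcome, OS = "survival_days",
                        BIOPSY_ONLY = "biopsy_only",
                        RADIOCHEMO = "radiochemo", RTV_BIN = "rtv_bin")
  if (outcome_col %in% candidate_covariates)
    stop("the outcome cannot also be a covariate")
  structure(list(outcome = outcome,
                 candidate_covariates = candidate_covariates,
                 interaction_terms = interaction_terms,
                 screening_alpha = screening_alpha,
                 interaction_alpha = interaction_alpha),
            class = "model_spec")
}

# complete-case rows for the given covariates, with per-model exclusions
# recorded (missing RTV mirrors patients without post-operative imaging)
model_frame <- function(registry, spec, covariates) {
  df <- as.data.frame(registry)
  excluded <- list()
  if ("rtv_ml" %in% c(covariates, if (spec$outcome == "RTV_BIN") "rtv_ml")) {
    drop <- df$rtv_excluded | is.na(df$rtv_ml)
    if (any(drop)) excluded$missing_rtv <- df$patient_id[drop]
    df <- df[!drop, , drop = FALSE]
  }
  if (spec$outcome == "RTV_BIN") {
    drop <- df$biopsy_only == 1
    if (any(drop)) excluded$biopsy_only <- df$patient_id[drop]
    df <- df[!drop, , drop = FALSE]
  }
  if (spec$outcome == "OS") {
    drop <- df$survival_days <= 0
    if (any(drop)) excluded$zero_followup <- df$patient_id[drop]
    df <- df[!drop, , drop = FALSE]
  }
  cc <- stats::complete.cases(df[, covariates, drop = FALSE])
  if (any(!cc)) excluded$incomplete_covariates <- df$patient_id[!cc]
  df <- df[cc, , drop = FALSE]
  if (is.character(df$sex)) df$sex <- factor(df$sex, levels = c("female", "male"))
  list(data = df, excluded = excluded)
}

check_nonconstant <- function(df, covariates) {
  for (v in covariates) {
    vals <- df[[v]]
    if (length(unique(vals[!is.na(vals)])) < 2L)
      stop(sprintf("covariate '%s' is constant in the model frame", v))
  }
}

fit_one <- function(df, spec, rhs) {
  fmla <- switch(spec$outcome,
    OS = stats::as.formula(paste("survival::Surv(survival_days, event) ~", rhs)),
    BIOPSY_ONLY = stats::as.formula(paste("biopsy_only ~", rhs)),
    RADIOCHEMO = stats::as.formula(paste("radiochemo ~", rhs)),
    RTV_BIN = stats::as.formula(paste("rtv_bin ~", rhs)))
  switch(spec$outcome,
    OS = survival::coxph(fmla, data = df, ties = "efron"),
    RTV_BIN = MASS::polr(fmla, data = df, Hess = TRUE),
    stats::glm(fmla, data = df, family = stats::binomial()))
}

# Wald coefficient table on the log scale; polr drops its intercepts
coef_table <- function(fit, spec) {
  if (inherits(fit, "polr")) {
    sm <- summary(fit)$coefficients
    keep <- setdiff(rownames(sm), names(fit$zeta))
    est <- sm[keep, "Value"]; se <- sm[keep, "Std. Error"]
    p <- 2 * stats::pnorm(-abs(est / se))
    terms <- keep
  } else if (inherits(fit, "coxph")) {
    sm <- summary(fit)$coefficients
    est <- sm[, "coef"]; se <- sm[, "se(coef)"]; p <- sm[, "Pr(>|z|)"]
    terms <- rownames(sm)
  } else {
    sm <- summary(fit)$coefficients
    keep <- setdiff(rownames(sm), "(Intercept)")
    est <- sm[keep, "Estimate"]; se <- sm[keep, "Std. Error"]
    p <- sm[keep, "Pr(>|z|)"]
    terms <- keep
  }
  z <- stats::qnorm(0.975)
  data.frame(term = terms, coef = unname(est), se = unname(se),
             hr = exp(unname(est)),
             ci_low = exp(unname(est) - z * unname(se)),
             ci_high = exp(unname(est) + z * unname(se)),
             p = unname(p), row.names = NULL, stringsAsFactors = FALSE)
}

check_separation <- function(fit) {
  if (inherits(fit, "glm")) {
    mu <- stats::fitted(fit)
    if (all(mu > 1 - 1e-8) || all(mu < 1e-8) ||
        any(abs(stats::coef(fit)) > 15, na.rm = TRUE))
      stop(sprintf("logistic model shows (quasi-)separation or a degenerate outcome; condition indicators: max|coef| = %.3g",
                   max(abs(stats::coef(fit)), na.rm = TRUE)))
  }
  invisible(fit)
}

#' Univariable covariate screening
#'
#' Fits one single-covariate model per candidate (Cox, binomial-logistic or
#' ordered-logistic depending on the outcome) and retains candidates whose
#' Wald p-value is at or below `spec$screening_alpha`.
#'
#' @param registry A `cohort_registry` (with `tvtb_cm` filled where needed).
#' @param spec A [model_spec].
#' @return A list with `retained` (character vector), `table` (per-candidate
#'   estimate and p) and `failed` (candidates whose fit did not converge,
#'   flagged rather than silently dropped).
#' @export
univariable_screen <- function(registry, spec) {
  retained <- character(0); failed <- character(0); rows <- list()
  for (v in spec$candidate_covariates) {
    mf <- model_frame(registry, spec, v)
    res <- tryCatch({
      check_nonconstant(mf$data, v)
      fit <- fit_one(mf$data, spec, v)
      check_separation(fit)
      coef_table(fit, spec)
    }, error = function(e) e, warning = function(w) {
      if (grepl("did not converge", conditionMessage(w))) w else invokeRestart("muffleWarning")
    })
    if (inherits(res, "condition")) {
      failed <- c(failed, v)
      next
    }
    pmin_v <- min(res$p)
    rows[[v]] <- data.frame(candidate = v, p = pmin_v)
    if (pmin_v <= spec$screening_alpha) retained <- c(retained, v)
  }
  list(retained = retained,
       table = if (length(rows)) do.call(rbind, rows) else
         data.frame(candidate = character(0), p = numeric(0)),
       failed = failed)
}

finish_result <- function(fit, tab, mf, spec, screen = NULL, class2 = "model_result") {
  structure(list(outcome = spec$outcome, terms = tab,
                 n_used = nrow(mf$data), excluded = mf$excluded,
                 screening = screen, fit = fit),
            class = c(class2, "model_result"))
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<%s model> n = %d\n", x$outcome, x$n_used))
  tab <- x$terms
  tab$hr <- sprintf("%.3f (%.3f-%.3f)", tab$hr, tab$ci_low, tab$ci_high)
  print(tab[, c("term", "hr", "p")], row.names = FALSE)
  invisible(x)
}

#' Cox proportional-hazards model for overall survival
#'
#' Screens the candidate covariates univariably at `screening_alpha`, fits
#' the multivariable Cox model (Efron ties) on the retained set, then tests
#' each interaction term in the multivariable model and keeps it when its
#' Wald p-value is at or below `interaction_alpha`. Patients with missing
#' RTV are excluded whenever `rtv_ml` is in the model.
#'
#' @param registry A `cohort_registry` with `tvtb_cm` filled.
#' @param spec A [model_spec] with `outcome = "OS"`.
#' @param screen Run the univariable screen (default `TRUE`); otherwise all
#'   candidates enter the multivariable model.
#' @return A `hazard_model_result` with a per-term table (`coef`, `hr`,
#'   `ci_low`, `ci_high`, `p`), `n_used`, `excluded` and the screening trail.
#' @export
fit_cox_os <- function(registry, spec = model_spec("OS"), screen = TRUE) {
  stopifnot(spec$outcome == "OS")
  scr <- if (screen) univariable_screen(registry, spec) else NULL
  covs <- if (screen) scr$retained else spec$candidate_covariates
  if (!length(covs)) stop("no covariates retained for the multivariable model")
  mf <- model_frame(registry, spec, covs)
  check_nonconstant(mf$data, covs)
  rhs <- paste(covs, collapse = " + ")
  fit <- fit_one(mf$data, spec, rhs)
  kept_int <- character(0)
  for (it in spec$interaction_terms) {
    parts <- strsplit(it, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% covs)) next
    fit_i <- fit_one(mf$data, spec, paste(rhs, "+", it))
    tab_i <- coef_table(fit_i, spec)
    p_i <- tab_i$p[tab_i$term == it]
    if (length(p_i) == 1L && is.finite(p_i) && p_i <= spec$interaction_alpha)
      kept_int <- c(kept_int, it)
  }
  if (length(kept_int)) {
    rhs <- paste(c(covs, kept_int), collapse = " + ")
    fit <- fit_one(mf$data, spec, rhs)
  }
  if (!is.null(fit$info) || any(!is.finite(stats::coef(fit))))
    stop("Cox model did not converge")
  finish_result(fit, coef_table(fit, spec), mf, spec, scr, "hazard_model_result")
}

#' Build a hazard-model result from published hazard ratios
#'
#' Wraps externally reported Cox hazard ratios (e.g. a published
#' multivariable table) in the same structure [fit_cox_os()] returns, so
#' derived quantities like [combined_hr_tvtb()] can be evaluated on them.
#'
#' @param hr Named numeric vector of hazard ratios, e.g.
#'   `c(tvtb_cm = 2.406, "age_years:tvtb_cm" = 0.983)`.
#' @param n_used Optional cohort size for provenance.
#' @return A `hazard_model_result` (without standard errors).
#' @export
hazard_result_from_estimates <- function(hr, n_used = NA_integer_) {
  stopifnot(is.numeric(hr), !is.null(names(hr)), all(hr > 0))
  tab <- data.frame(term = names(hr), coef = log(unname(hr)), se = NA_real_,
                    hr = unname(hr), ci_low = NA_real_, ci_high = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  structure(list(outcome = "OS", terms = tab, n_used = n_used,
                 excluded = list(), screening = NULL, fit = NULL),
            class = c("hazard_model_result", "model_result"))
}

#' Age-conditional combined hazard ratio of the centrality metric
#'
#' With an age-by-TVTB interaction in the Cox model, the per-cm hazard
#' ratio of TVTB depends on age:
#' `HR(age) = HR_tvtb * HR_interaction ^ age`. With an interaction HR below
#' 1 the protective effect of distance from the reference point grows with
#' age.
#'
#' @param result A `hazard_model_result` containing a TVTB main effect and
#'   an age-by-TVTB interaction term.
#' @param age_years Age (or vector of ages) at which to evaluate.
#' @param tvtb_term,interaction_term Term names in the result table.
#' @return Hazard ratio per cm of TVTB at the given age(s).
#' @export
combined_hr_tvtb <- function(result, age_years,
                             tvtb_term = "tvtb_cm",
                             interaction_term = "age_years:tvtb_cm") {
  tab <- result$terms
  hr_main <- tab$hr[tab$term == tvtb_term]
  hr_int <- tab$hr[tab$term == interaction_term]
  if (length(hr_main) != 1L)
    stop(sprintf("result has no '%s' main effect", tvtb_term))
  if (length(hr_int) != 1L)
    stop(sprintf("result has no '%s' interaction term", interaction_term))
  hr_main * hr_int^age_years
}

#' Binomial logistic model for a binary treatment outcome
#'
#' @param registry A `cohort_registry`.
#' @param spec A [model_spec] with outcome `"BIOPSY_ONLY"` or `"RADIOCHEMO"`.
#' @param screen Run the univariable screen first (default `TRUE`).
#' @return A `model_result` with per-term odds ratios and Wald CIs.
#' @export
fit_binomial <- function(registry, spec = model_spec("BIOPSY_ONLY"), screen = TRUE) {
  stopifnot(spec$outcome %in% c("BIOPSY_ONLY", "RADIOCHEMO"))
  outcome_col <- if (spec$outcome == "BIOPSY_ONLY") "biopsy_only" else "radiochemo"
  y <- registry[[outcome_col]]
  if (length(unique(y[!is.na(y)])) < 2L)
    stop(sprintf("outcome '%s' is constant; logistic model is degenerate (separation)", outcome_col))
  scr <- if (screen) univariable_screen(registry, spec) else NULL
  covs <- if (screen) scr$retained else spec$candidate_covariates
  if (!length(covs)) stop("no covariates retained for the multivariable model")
  mf <- model_frame(registry, spec, covs)
  check_nonconstant(mf$data, covs)
  fit <- fit_one(mf$data, spec, paste(covs, collapse = " + "))
  check_separation(fit)
  finish_result(fit, coef_table(fit, spec), mf, spec, scr)
}

#' Ordered logistic (proportional-odds) model on RTV bins
#'
#' Models the five ordered 5-mL RTV bins on resected patients only
#' (biopsy-only patients are excluded since their RTV equals the
#' preoperative volume by construction).
#'
#' @param registry A `cohort_registry` with `rtv_bin` derived.
#' @param spec A [model_spec] with `outcome = "RTV_BIN"`.
#' @param screen Run the univariable screen first (default `TRUE`).
#' @return A `model_result` with per-term odds ratios and Wald CIs.
#' @export
fit_ordered <- function(registry, spec = model_spec("RTV_BIN"), screen = TRUE) {
  stopifnot(spec$outcome == "RTV_BIN")
  mf0 <- model_frame(registry, spec, character(0))
  occupied <- table(droplevels(mf0$data$rtv_bin))
  if (length(occupied) < 2L)
    stop("fewer than 2 occupied RTV bins; ordered model is not identifiable")
  empty <- setdiff(RTV_BINS, names(occupied))
  if (length(empty))
    warning(sprintf("RTV bin(s) with no members: %s", paste(empty, collapse = ", ")))
  scr <- if (screen) univariable_screen(registry, spec) else NULL
  covs <- if (screen) scr$retained else spec$candidate_covariates
  if (!length(covs)) stop("no covariates retained for the multivariable model")
  mf <- model_frame(registry, spec, covs)
  mf$data$rtv_bin <- droplevels(mf$data$rtv_bin)
  check_nonconstant(mf$data, covs)
  fit <- fit_one(mf$data, spec, paste(covs, collapse = " + "))
  finish_result(fit, coef_table(fit, spec), mf, spec, scr)
}

#' Write a fitted model as a tidy CSV plus a JSON model card
#'
#' @param result A `model_result`.
#' @param path Output CSV path; the model card is written to `<path>.json`.
#' @return The path, invisibly.
#' @export
write_model_result <- function(result, path) {
  utils::write.csv(result$terms, path, row.names = FALSE)
  card <- list(outcome = result$outcome, n_used = result$n_used,
               excluded = result$excluded,
               screening = if (!is.null(result$screening))
                 list(retained = result$screening$retained,
                      failed = result$screening$failed))
  jsonlite::write_json(card, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
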