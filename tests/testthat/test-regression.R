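# simulated registry with known effects, bypassing mask generation
sim_registry <- function(n, seed = 1, b_age = 0, b_tvtb = 0, b_int = 0,
                         base_rate = log(2) / 374) {
  set.seed(seed)
  age <- round(pmin(95, pmax(18, rnorm(n, 65, 12))))
  tvtb <- round(runif(n, 0, 5), 2)
  lp <- b_age * (age - 65) + b_tvtb * (tvtb - 2.5) + b_int * (age * tvtb - 65 * 2.5)
  t_death <- pmax(1, round(rexp(n, rate = base_rate * exp(lp))))
  fup <- round(runif(n, 750, 2924))
  df <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    survival_days = pmin(t_death, fup),
    event = as.integer(t_death <= fup),
    age_years = age,
    sex = sample(c("female", "male"), n, replace = TRUE),
    kps_at_least_70 = rbinom(n, 1, 0.7),
    biopsy_only = rbinom(n, 1, 0.18),
    radiochemo = rbinom(n, 1, 0.77),
    preop_volume_ml = round(runif(n, 5, 80), 1),
    residual_ce_volume_ml = round(runif(n, 0, 30), 2),
    stringsAsFactors = FALSE
  )
  reg <- suppressWarnings(validate_registry(df))
  reg$tvtb_cm <- tvtb
  reg
}

test_that("combined TVTB hazard ratio reproduces the age-conditional values", {
  res <- hazard_result_from_estimates(
    c(tvtb_cm = 2.406, "age_years:tvtb_cm" = 0.983), n_used = 206L)
  expect_equal(round(combined_hr_tvtb(res, 60), 2), 0.86)
  expect_equal(round(combined_hr_tvtb(res, 80), 2), 0.61)
  # at age zero the interaction vanishes
  expect_identical(combined_hr_tvtb(res, 0), 2.406)
  # monotone decreasing in age when the interaction HR < 1
  ages <- seq(20, 90, by = 5)
  expect_true(all(diff(combined_hr_tvtb(res, ages)) < 0))
  no_int <- hazard_result_from_estimates(c(tvtb_cm = 2.406))
  expect_error(combined_hr_tvtb(no_int, 60), "interaction")
})

test_that("Cox fit recovers planted coefficients and keeps the interaction", {
  reg <- sim_registry(2000, seed = 11, b_age = 0.079, b_tvtb = 0.878, b_int = -0.0171)
  spec <- model_spec("OS", candidate_covariates = c("age_years", "tvtb_cm"))
  fit <- fit_cox_os(reg, spec, screen = FALSE)
  tab <- fit$terms
  expect_true("age_years:tvtb_cm" %in% tab$term)
  truth <- c(age_years = 0.079, tvtb_cm = 0.878, "age_years:tvtb_cm" = -0.0171)
  for (nm in names(truth)) {
    row <- tab[tab$term == nm, ]
    expect_lt(abs(row$coef - truth[[nm]]), 4 * row$se)
    expect_equal(row$hr, exp(row$coef), tolerance = 1e-10)
    expect_true(row$ci_low < row$ci_high)
  }
})

test_that("Cox fit on a tiny untied cohort matches the closed-form partial likelihood", {
  # one binary covariate, no ties: beta solves the score equation, which for
  # n <= 6 can be maximised directly on the enumerated risk sets
  df <- registry_df(6,
    survival_days = c(30L, 60L, 100L, 200L, 400L, 800L),
    event = rep(1L, 6),
    kps_at_least_70 = c(0L, 0L, 1L, 0L, 1L, 1L))
  reg <- suppressWarnings(validate_registry(df))
  loglik <- function(b) {
    ord <- order(reg$survival_days)
    x <- reg$kps_at_least_70[ord]
    ll <- 0
    for (i in seq_along(x)) {
      risk <- i:length(x)
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }
  b_hat <- stats::optimize(loglik, c(-5, 5), maximum = TRUE)$maximum
  fit <- fit_cox_os(reg, model_spec("OS", candidate_covariates = "kps_at_least_70",
                                    interaction_terms = character(0)),
                    screen = FALSE)
  expect_equal(fit$terms$coef[1], b_hat, tolerance = 1e-4)
})

test_that("an insignificant interaction is dropped and constants are rejected", {
  reg <- sim_registry(600, seed = 21, b_age = 0.05)   # no tvtb effect at all
  spec <- model_spec("OS", candidate_covariates = c("age_years", "tvtb_cm"))
  fit <- fit_cox_os(reg, spec, screen = FALSE)
  expect_false("age_years:tvtb_cm" %in% fit$terms$term)

  reg$kps_at_least_70 <- 1L
  expect_error(
    fit_cox_os(reg, model_spec("OS", candidate_covariates = "kps_at_least_70"),
               screen = FALSE),
    "kps_at_least_70")
})

test_that("univariable screening retains strong effects and flags failures", {
  reg <- sim_registry(800, seed = 31, b_age = 0.08)
  spec <- model_spec("OS", candidate_covariates = c("age_years", "sex"))
  scr <- univariable_screen(reg, spec)
  expect_true("age_years" %in% scr$retained)
  expect_true(all(scr$table$p >= 0 & scr$table$p <= 1))
  # empty candidate set -> empty retention
  empty <- univariable_screen(reg, model_spec("OS", candidate_covariates = character(0)))
  expect_length(empty$retained, 0)
  # a constant candidate is flagged, not silently dropped
  reg$kps_at_least_70 <- 1L
  scr2 <- univariable_screen(reg, model_spec("OS",
    candidate_covariates = c("age_years", "kps_at_least_70")))
  expect_true("kps_at_least_70" %in% scr2$failed)
})

test_that("screening retains a null covariate at roughly the nominal rate", {
  # with p <= 0.1 screening, an independent covariate is kept ~10% of the time
  hits <- 0L
  n_rep <- 60L
  for (r in seq_len(n_rep)) {
    reg <- sim_registry(400, seed = 1000 + r)
    scr <- univariable_screen(reg, model_spec("OS", candidate_covariates = "tvtb_cm"))
    hits <- hits + ("tvtb_cm" %in% scr$retained)
  }
  ci <- stats::binom.test(hits, n_rep, p = 0.1)$conf.int
  expect_true(ci[1] <= 0.1 && 0.1 <= ci[2])
})

test_that("binomial logistic model recovers a planted odds ratio", {
  set.seed(41)
  n <- 2000
  reg <- sim_registry(n, seed = 41)
  lp <- -2 + log(2) * reg$kps_at_least_70   # OR 2 for KPS
  reg$biopsy_only <- rbinom(n, 1, plogis(lp))
  fit <- fit_binomial(reg, model_spec("BIOPSY_ONLY",
    candidate_covariates = "kps_at_least_70"), screen = FALSE)
  row <- fit$terms[fit$terms$term == "kps_at_least_70", ]
  expect_true(row$ci_low < 2 && 2 < row$ci_high)
  # degenerate outcome errors out
  reg$biopsy_only <- 1L
  expect_error(fit_binomial(reg, model_spec("BIOPSY_ONLY",
    candidate_covariates = "kps_at_least_70"), screen = FALSE), "separation|degenerate")
})

test_that("ordered RTV model excludes biopsy-only patients and finds direction", {
  set.seed(51)
  n <- 1200
  reg <- sim_registry(n, seed = 51)
  # plant: larger preoperative volume pushes RTV upward
  lat <- 0.1 * (reg$preop_volume_ml - 40) + rlogis(n) * 3
  reg$rtv_ml <- pmax(0, 5 + lat)
  reg$rtv_bin <- bin_rtv(reg$rtv_ml)
  n_biopsy <- sum(reg$biopsy_only == 1)
  fit <- fit_ordered(reg, model_spec("RTV_BIN",
    candidate_covariates = "preop_volume_ml"), screen = FALSE)
  expect_equal(fit$n_used, n - n_biopsy)
  row <- fit$terms[fit$terms$term == "preop_volume_ml", ]
  expect_gt(row$hr, 1)   # direction recovered (proportional odds > 1)
  expect_lt(row$p, 0.01)
  # fewer than two occupied bins is not identifiable
  reg2 <- reg
  reg2$rtv_ml <- 1; reg2$rtv_bin <- bin_rtv(reg2$rtv_ml)
  expect_error(fit_ordered(reg2, model_spec("RTV_BIN",
    candidate_covariates = "preop_volume_ml"), screen = FALSE), "occupied")
})

test_that("model results serialise to tidy CSV with a JSON model card", {
  reg <- sim_registry(500, seed = 61, b_age = 0.06)
  fit <- fit_cox_os(reg, model_spec("OS",
    candidate_covariates = c("age_years", "tvtb_cm")), screen = TRUE)
  path <- tempfile(fileext = ".csv")
  write_model_result(fit, path)
  tab <- utils::read.csv(path)
  expect_true(all(c("term", "coef", "hr", "ci_low", "ci_high", "p") %in% names(tab)))
  card <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(card$outcome, "OS")
  expect_equal(card$n_used, fit$n_used)
})
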