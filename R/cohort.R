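#' Overall-survival group thresholds
#'
#' The cohort is split into short (< 6 months), medium (6--24 months) and
#' long (> 24 months) overall survival. Calendar months are converted to
#' days as `round(365.25 * k / 12)`, giving 183 days for 6 months and 731
#' days for 24 months; both thresholds are configurable.
#'
#' @param t6_days Days corresponding to 6 months (default 183).
#' @param t24_days Days corresponding to 24 months (default 731).
#' @return A named list of thresholds.
#' @export
os_thresholds <- function(t6_days = 183L, t24_days = 731L) {
  stopifnot(t6_days > 0, t24_days > t6_days)
  list(t6_days = as.integer(t6_days), t24_days = as.integer(t24_days))
}

OS_GROUPS <- c("SHORT", "MEDIUM", "LONG", "UNASSIGNABLE")

#' Assign a patient to an overall-survival group
#'
#' Deceased patients (`event = 1`) are SHORT below the 6-month threshold,
#' MEDIUM between 6 and 24 months inclusive, and LONG above 24 months.
#' Censored patients can only be classified when their follow-up already
#' exceeds 24 months (LONG); a censored patient with shorter follow-up is
#' UNASSIGNABLE and excluded from the maps.
#'
#' @param survival_days Non-negative integer vector, days from surgery to
#'   death or censoring.
#' @param event Binary vector, 1 = died, 0 = censored.
#' @param thresholds See [os_thresholds()].
#' @return Factor with levels SHORT, MEDIUM, LONG, UNASSIGNABLE.
#' @export
assign_os_group <- function(survival_days, event, thresholds = os_thresholds()) {
  stopifnot(length(survival_days) == length(event))
  if (any(survival_days < 0)) stop("survival_days must be non-negative")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  out <- ifelse(
    event == 1,
    ifelse(survival_days < thresholds$t6_days, "SHORT",
           ifelse(survival_days <= thresholds$t24_days, "MEDIUM", "LONG")),
    ifelse(survival_days > thresholds$t24_days, "LONG", "UNASSIGNABLE")
  )
  factor(out, levels = OS_GROUPS)
}

#' Derive residual tumor volume (RTV)
#'
#' RTV is the post-operative contrast-enhancing volume in resected patients,
#' and is set equal to the full preoperative volume (CE rim plus necrotic
#' core) in biopsy-only patients. A resected patient with a missing residual
#' volume cannot be given an RTV and is flagged for exclusion from RTV-using
#' models.
#'
#' @param biopsy_only Binary vector.
#' @param preop_volume_ml Positive numeric vector.
#' @param residual_ce_volume_ml Non-negative numeric vector, `NA` if missing.
#' @return Numeric vector of RTV in mL; `NA` where excluded.
#' @export
derive_rtv <- function(biopsy_only, preop_volume_ml, residual_ce_volume_ml) {
  stopifnot(length(biopsy_only) == length(preop_volume_ml),
            length(biopsy_only) == length(residual_ce_volume_ml))
  ifelse(biopsy_only == 1, preop_volume_ml, residual_ce_volume_ml)
}

RTV_BINS <- c("B0_5", "B5_10", "B10_15", "B15_20", "B20PLUS")

#' Bin residual tumor volume into 5-mL groups
#'
#' Bins are half-open on the right: (0,5], (5,10], (10,15], (15,20],
#' (20, Inf), with 0 mL included in the first bin (gross total resection).
#'
#' @param rtv_ml Non-negative numeric vector; `NA` passes through.
#' @return Ordered factor with levels `B0_5 < B5_10 < B10_15 < B15_20 < B20PLUS`.
#' @export
bin_rtv <- function(rtv_ml) {
  if (any(rtv_ml < 0, na.rm = TRUE)) stop("rtv_ml must be non-negative")
  cut(rtv_ml, breaks = c(-Inf, 5, 10, 15, 20, Inf),
      labels = RTV_BINS, right = TRUE, ordered_result = TRUE)
}

REGISTRY_COLUMNS <- c("patient_id", "survival_days", "event", "age_years",
                      "sex", "kps_at_least_70", "biopsy_only", "radiochemo",
                      "preop_volume_ml", "residual_ce_volume_ml")

#' Load and validate a clinical registry
#'
#' Reads a CSV with one row per patient, optionally renaming columns through
#' a mapping (canonical name -> file column name), validates the per-row
#' invariants, and derives the OS group, RTV and RTV bin columns. Rows
#' violating an invariant are reported with their row numbers.
#'
#' @param path CSV file with a header row; missing values as empty cells.
#' @param schema_config Optional named character vector or list mapping
#'   canonical column names to the file's column names, or the path of a
#'   YAML file holding such a mapping under the key `columns`.
#' @param thresholds OS-group thresholds, see [os_thresholds()].
#' @return A `data.frame` of class `cohort_registry` with the canonical
#'   columns plus `os_group`, `rtv_ml`, `rtv_bin`, `rtv_excluded` and a
#'   placeholder `tvtb_cm` column (filled by [append_tvtb()]).
#' @export
load_registry <- function(path, schema_config = NULL, thresholds = os_thresholds()) {
  if (!file.exists(path)) stop(sprintf("registry file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (is.character(schema_config) && length(schema_config) == 1L &&
      file.exists(schema_config)) {
    cfg <- yaml::read_yaml(schema_config)
    schema_config <- if (!is.null(cfg$columns)) cfg$columns else cfg
  }
  if (!is.null(schema_config)) {
    mapping <- unlist(schema_config)
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      if (!src %in% names(df))
        stop(sprintf("schema error: mapped column '%s' (for '%s') not in file", src, canon))
      names(df)[names(df) == src] <- canon
    }
  }
  missing_cols <- setdiff(REGISTRY_COLUMNS, names(df))
  if (length(missing_cols))
    stop(sprintf("schema error: missing column(s) %s",
                 paste(sQuote(missing_cols), collapse = ", ")))
  df <- df[REGISTRY_COLUMNS]
  validate_registry(df, thresholds = thresholds)
}

#' Validate a registry data frame and derive grouping columns
#'
#' @param df Data frame with the canonical registry columns.
#' @inheritParams load_registry
#' @return A validated `cohort_registry` (see [load_registry()]).
#' @export
validate_registry <- function(df, thresholds = os_thresholds()) {
  problems <- character(0)
  row_problem <- function(rows, msg) {
    if (length(rows))
      problems <<- c(problems, sprintf("row %d: %s", rows, msg))
  }
  num_cols <- c("survival_days", "event", "age_years", "kps_at_least_70",
                "biopsy_only", "radiochemo", "preop_volume_ml",
                "residual_ce_volume_ml")
  for (col in num_cols) {
    vals <- df[[col]]
    if (!is.numeric(vals)) {
      suppressWarnings(conv <- as.numeric(vals))
      row_problem(which(!is.na(vals) & is.na(conv)), sprintf("non-numeric %s", col))
      df[[col]] <- conv
    }
  }
  dup <- duplicated(df$patient_id)
  if (any(dup))
    problems <- c(problems, sprintf("duplicate patient_id '%s'",
                                    unique(df$patient_id[dup])))
  row_problem(which(is.na(df$survival_days) | df$survival_days < 0),
              "survival_days must be a non-negative number")
  row_problem(which(!df$event %in% c(0, 1)), "event must be 0/1")
  row_problem(which(!is.na(df$sex) & !df$sex %in% c("female", "male")),
              "sex must be 'female' or 'male'")
  row_problem(which(is.na(df$preop_volume_ml) | df$preop_volume_ml <= 0),
              "preop_volume_ml must be positive")
  row_problem(which(df$biopsy_only == 0 & !is.na(df$residual_ce_volume_ml) &
                      df$residual_ce_volume_ml < 0),
              "residual_ce_volume_ml must be non-negative")
  if (length(problems))
    stop(paste(c("invalid registry:", problems), collapse = "\n  "))

  df$os_group <- assign_os_group(df$survival_days, df$event, thresholds)
  n_unassign <- sum(df$os_group == "UNASSIGNABLE")
  if (n_unassign > 0)
    warning(sprintf(
      "%d censored patient(s) with follow-up <= 24 months are UNASSIGNABLE and excluded from maps",
      n_unassign))
  df$rtv_ml <- derive_rtv(df$biopsy_only, df$preop_volume_ml, df$residual_ce_volume_ml)
  df$rtv_excluded <- df$biopsy_only == 0 & is.na(df$residual_ce_volume_ml)
  df$rtv_bin <- bin_rtv(df$rtv_ml)
  if (!"tvtb_cm" %in% names(df)) df$tvtb_cm <- NA_real_
  class(df) <- c("cohort_registry", "data.frame")
  df
}

#' Write a derived registry to CSV
#'
#' @param registry A `cohort_registry`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Cohort descriptive statistics
#'
#' Summarises the derived registry the way a clinical descriptives table
#' does: group sizes and percentages for the OS groups, resection and
#' treatment rates, and medians/ranges of the continuous variables.
#'
#' @param registry A `cohort_registry`.
#' @return A list with `n`, `os_groups` (count and percent per group),
#'   `resection_percent`, `radiochemo_percent`, `kps70_percent`, and
#'   median/range summaries.
#' @export
cohort_descriptives <- function(registry) {
  n <- nrow(registry)
  grp <- table(factor(registry$os_group, levels = OS_GROUPS))
  med_range <- function(x) {
    x <- x[!is.na(x)]
    c(median = stats::median(x), min = min(x), max = max(x))
  }
  list(
    n = n,
    os_groups = data.frame(
      group = names(grp),
      n = as.integer(grp),
      percent = round(100 * as.integer(grp) / n, 1)
    ),
    resection_percent = round(100 * sum(registry$biopsy_only == 0) / n, 1),
    radiochemo_percent = round(100 * sum(registry$radiochemo == 1) / n, 1),
    kps70_percent = round(100 * sum(registry$kps_at_least_70 == 1) / n, 1),
    survival_days = med_range(registry$survival_days),
    preop_volume_ml = med_range(registry$preop_volume_ml)
  )
}
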