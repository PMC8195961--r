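#' Simulation configuration for synthetic glioblastoma cohorts
#'
#' Defaults describe a compact stand-in for a population-based glioblastoma
#' cohort: 215 patients with ellipsoidal contrast-enhancing tumors on a
#' 32x32x32 grid at 4 mm (a coarse common reference space centred on the
#' world origin), a brain ellipsoid bounding the anatomy, a central planted
#' effect region whose overlap raises the probability of short survival,
#' covariates correlated with tumor centrality, and administrative
#' censoring that can only affect long survivors.
#'
#' @param n_patients Cohort size (default 215).
#' @param grid A [grid_spec]; default 32^3 voxels at 4 mm, origin-centred.
#' @param brain_semi_axes_mm Semi-axes of the brain ellipsoid (tumors are
#'   clipped to it).
#' @param center_semi_axes_mm Semi-axes of the ellipsoid tumor centres are
#'   drawn from (inside the brain, so tumors rarely touch the grid edge).
#' @param radii_range_mm Per-axis tumor semi-axis range, drawn uniformly.
#' @param effect List: `center_mm`, `radius_mm` of the planted spherical
#'   region R; `p_short_base` and `p_short_in`, the probability of
#'   SHORT-group membership for tumors not overlapping / overlapping R.
#'   Patients not assigned SHORT split between MEDIUM and LONG at the
#'   cohort's marginal ratio.
#' @param survival `"group"` (default): survival days drawn uniformly
#'   inside the assigned group's interval. `"exponential"`: exponential
#'   survival with log-hazard `b_age*(age-65) + b_tvtb*(tvtb-2.5) +
#'   b_age_tvtb*(age*tvtb - 65*2.5)` around a 374-day baseline median;
#'   groups are then derived from the realised survival.
#' @param hazard_coefs Named list of the log-hazard coefficients used by the
#'   exponential model (defaults of the magnitude seen in glioblastoma
#'   cohorts: `b_age = 0.079` per year, `b_tvtb = 0.878` per cm,
#'   `b_age_tvtb = -0.0171`).
#' @param ref Reference point for the centrality metric (default the world
#'   origin, standing in for the centre of the third ventricle).
#' @param censor_range_days Administrative follow-up horizon, drawn
#'   uniformly per patient; the lower end exceeds 24 months so every
#'   censored patient is still classifiable as a long survivor.
#' @param resected_fraction_missing_rtv Probability a resected patient has
#'   no post-operative volume (excluded from RTV models).
#' @param seed Integer seed; all generation is deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 215L,
                       grid = grid_spec(c(32L, 32L, 32L), spacing_mm = c(4, 4, 4)),
                       brain_semi_axes_mm = c(56, 60, 52),
                       center_semi_axes_mm = c(42, 46, 38),
                       radii_range_mm = c(14, 30),
                       effect = list(center_mm = c(28, 24, -14), radius_mm = 4,
                                     p_short_base = 0.15, p_short_in = 0.6),
                       survival = c("group", "exponential"),
                       hazard_coefs = list(b_age = 0.079, b_tvtb = 0.878,
                                           b_age_tvtb = -0.0171),
                       ref = reference_point(c(0, 0, 0), "center of third ventricle (synthetic)"),
                       censor_range_days = c(750, 2924),
                       resected_fraction_missing_rtv = 0.05,
                       seed = 1L) {
  survival <- match.arg(survival)
  stopifnot(n_patients >= 3L, all(radii_range_mm > 0),
            radii_range_mm[1] <= radii_range_mm[2],
            effect$p_short_base >= 0, effect$p_short_base <= 1,
            effect$p_short_in >= 0, effect$p_short_in <= 1,
            censor_range_days[1] > 731)
  if (any(center_semi_axes_mm > brain_semi_axes_mm))
    stop("tumor centre domain must lie inside the brain ellipsoid")
  world_half_extent <- grid$spacing_mm * (grid$shape - 1) / 2
  if (any(brain_semi_axes_mm > world_half_extent + grid$spacing_mm / 2))
    stop("brain ellipsoid does not fit the grid; tumors cannot fit")
  if (sqrt(sum(effect$center_mm^2)) + effect$radius_mm >
      min(brain_semi_axes_mm))
    stop("planted effect region must lie inside the brain ellipsoid")
  structure(list(n_patients = as.integer(n_patients), grid = grid,
                 brain_semi_axes_mm = brain_semi_axes_mm,
                 center_semi_axes_mm = center_semi_axes_mm,
                 radii_range_mm = radii_range_mm, effect = effect,
                 survival = survival, hazard_coefs = hazard_coefs, ref = ref,
                 censor_range_days = censor_range_days,
                 resected_fraction_missing_rtv = resected_fraction_missing_rtv,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Full-resolution template grid profile
#'
#' A 91 x 109 x 91 grid at 2 mm spacing, the dimensions of the common
#' 2 mm adult template. Pass as `sim_config(grid = fullres_grid())` for
#' production-scale runs; the default 32^3 / 4 mm grid keeps test suites
#' fast.
#'
#' @return A [grid_spec].
#' @export
fullres_grid <- function() grid_spec(c(91L, 109L, 91L), spacing_mm = c(2, 2, 2))

# world coordinates of every voxel centre, as three arrays (computed once)
grid_world_coords <- function(grid) {
  sh <- grid$shape
  i <- array(rep(0:(sh[1] - 1L), times = sh[2] * sh[3]), dim = sh)
  j <- array(rep(rep(0:(sh[2] - 1L), each = sh[1]), times = sh[3]), dim = sh)
  k <- array(rep(0:(sh[3] - 1L), each = sh[1] * sh[2]), dim = sh)
  A <- grid$affine
  list(x = A[1, 1] * i + A[1, 2] * j + A[1, 3] * k + A[1, 4],
       y = A[2, 1] * i + A[2, 2] * j + A[2, 3] * k + A[2, 4],
       z = A[3, 1] * i + A[3, 2] * j + A[3, 3] * k + A[3, 4])
}

ellipsoid_mask <- function(coords, center, semi_axes) {
  ((coords$x - center[1]) / semi_axes[1])^2 +
    ((coords$y - center[2]) / semi_axes[2])^2 +
    ((coords$z - center[3]) / semi_axes[3])^2 <= 1
}

# uniform point inside an axis-aligned ellipsoid (rejection from the box)
runif_ellipsoid <- function(semi_axes) {
  repeat {
    p <- stats::runif(3, -1, 1)
    if (sum(p^2) <= 1) return(p * semi_axes)
  }
}

# voxelize one tumor: ellipsoid at `center` with `radii`, clipped to the
# brain; evaluated on the tumor's bounding box only for speed
voxelize_tumor <- function(grid, center, radii, brain, coords) {
  A <- grid$affine
  ctr_vox <- world_to_voxel(grid, center)
  half <- ceiling(radii / grid$spacing_mm) + 1L
  lo <- pmax(0L, floor(ctr_vox - half)); hi <- pmin(grid$shape - 1L, ceiling(ctr_vox + half))
  ii <- (lo[1]:hi[1]) + 1L; jj <- (lo[2]:hi[2]) + 1L; kk <- (lo[3]:hi[3]) + 1L
  vox <- array(0L, dim = grid$shape)
  inside <- ((coords$x[ii, jj, kk] - center[1]) / radii[1])^2 +
            ((coords$y[ii, jj, kk] - center[2]) / radii[2])^2 +
            ((coords$z[ii, jj, kk] - center[3]) / radii[3])^2 <= 1
  vox[ii, jj, kk] <- as.integer(inside & brain[ii, jj, kk])
  if (sum(vox) == 0L) {
    # degenerate clip: keep at least the voxel nearest the centre
    v <- pmin(pmax(round(ctr_vox), 0L), grid$shape - 1L)
    vox[v[1] + 1L, v[2] + 1L, v[3] + 1L] <- 1L
  }
  vox
}

draw_covariates <- function(n) {
  age <- round(stats::rnorm(n, 65, 12))
  while (any(bad <- age < 18 | age > 95)) age[bad] <- round(stats::rnorm(sum(bad), 65, 12))
  sex <- ifelse(stats::runif(n) < 0.609, "male", "female")
  kps <- as.integer(stats::runif(n) < stats::plogis(1.0 - 0.06 * (age - 65)))
  list(age = age, sex = sex, kps = kps)
}

group_survival_days <- function(group, censor_range) {
  n <- length(group)
  days <- integer(n); event <- integer(n)
  s <- group == "SHORT"; m <- group == "MEDIUM"; l <- group == "LONG"
  days[s] <- sample(8:182, sum(s), replace = TRUE); event[s] <- 1L
  days[m] <- sample(183:731, sum(m), replace = TRUE); event[m] <- 1L
  if (any(l)) {
    t_death <- round(stats::runif(sum(l), 732, 3300))
    fup <- round(stats::runif(sum(l), censor_range[1], censor_range[2]))
    days[l] <- pmin(t_death, fup)
    event[l] <- as.integer(t_death <= fup)
  }
  list(days = days, event = event)
}

build_registry_frame <- function(ids, cov, days, event, tvtb, preop, config) {
  n <- length(ids)
  biopsy <- as.integer(stats::runif(n) < stats::plogis(-0.9 - 0.45 * tvtb))
  residual <- ifelse(biopsy == 1, NA_real_,
                     round(preop * stats::rbeta(n, 0.6, 7), 2))
  miss <- biopsy == 0 & stats::runif(n) < config$resected_fraction_missing_rtv
  residual[miss] <- NA_real_
  radio <- as.integer(stats::runif(n) < stats::plogis(
    0.6 - 0.06 * (cov$age - 65) + 0.6 * cov$kps - 0.3 * biopsy))
  data.frame(patient_id = ids, survival_days = days, event = event,
             age_years = cov$age, sex = cov$sex, kps_at_least_70 = cov$kps,
             biopsy_only = biopsy, radiochemo = radio,
             preop_volume_ml = preop, residual_ce_volume_ml = residual,
             stringsAsFactors = FALSE)
}

generate_masks <- function(config) {
  coords <- grid_world_coords(config$grid)
  brain <- ellipsoid_mask(coords, c(0, 0, 0), config$brain_semi_axes_mm)
  n <- config$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  masks <- vector("list", n)
  centers <- matrix(0, n, 3); radii <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    centers[i, ] <- runif_ellipsoid(config$center_semi_axes_mm)
    radii[i, ] <- stats::runif(3, config$radii_range_mm[1], config$radii_range_mm[2])
    masks[[i]] <- tumor_mask(ids[i],
                             voxelize_tumor(config$grid, centers[i, ], radii[i, ],
                                            brain, coords),
                             config$grid)
  }
  list(masks = masks, ids = ids, centers = centers, radii = radii,
       coords = coords, brain = brain)
}

# does the mask overlap the planted spherical region R?
overlaps_region <- function(mask, coords, effect) {
  idx <- mask$voxels == 1L
  any((coords$x[idx] - effect$center_mm[1])^2 +
      (coords$y[idx] - effect$center_mm[2])^2 +
      (coords$z[idx] - effect$center_mm[3])^2 <= effect$radius_mm^2)
}

#' Generate a synthetic cohort with a planted location effect
#'
#' Generates ellipsoidal tumor masks, assigns OS groups with a higher
#' SHORT-survival probability for tumors overlapping the planted region
#' (or, under the exponential survival model, draws survival from a
#' proportional-hazards model in age and centrality), derives all clinical
#' covariates, and returns the registry already validated and with the
#' centrality metric appended.
#'
#' @param config A [sim_config].
#' @return A list with `masks` (list of [tumor_mask]), `registry` (a
#'   `cohort_registry` with `tvtb_cm` filled), and `truth` (planted region,
#'   probabilities, hazard coefficients, per-patient overlap flags, seed).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- generate_masks(config)
  n <- config$n_patients
  # overlap with R only drives the group-based effect model
  overlap <- if (config$survival == "group")
    vapply(g$masks, overlaps_region, logical(1),
           coords = g$coords, effect = config$effect)
  else rep(NA, n)
  cov <- draw_covariates(n)
  tvtb <- vapply(g$masks, tvtb_cm, numeric(1), ref = config$ref)
  vox_ml <- prod(config$grid$spacing_mm) / 1000
  preop <- round(vapply(g$masks, function(m) sum(m$voxels), numeric(1)) * vox_ml, 3)

  if (config$survival == "group") {
    # balanced (stratified) assignment: within each overlap stratum a random
    # subset of the planted size is assigned SHORT, so every tumor has
    # exactly the planted marginal probability while the realised
    # conditional fractions are pinned to it (removes composition noise
    # between replicates); non-SHORT patients then split MEDIUM : LONG at
    # the cohort's marginal ratio, again within stratum
    p_med_rel <- 122 / (122 + 41)
    group <- character(n)
    for (ov in c(TRUE, FALSE)) {
      idx <- which(overlap == ov)
      p_s <- if (ov) config$effect$p_short_in else config$effect$p_short_base
      n_s <- round(p_s * length(idx))
      s_idx <- if (n_s > 0) sample(idx, n_s) else integer(0)
      rest <- setdiff(idx, s_idx)
      m_idx <- if (length(rest)) sample(rest, round(p_med_rel * length(rest))) else integer(0)
      group[s_idx] <- "SHORT"
      group[m_idx] <- "MEDIUM"
      group[setdiff(rest, m_idx)] <- "LONG"
    }
    sv <- group_survival_days(group, config$censor_range_days)
  } else {
    hc <- config$hazard_coefs
    lp <- hc$b_age * (cov$age - 65) + hc$b_tvtb * (tvtb - 2.5) +
      hc$b_age_tvtb * (cov$age * tvtb - 65 * 2.5)
    t_death <- pmax(1, round(stats::rexp(n, rate = log(2) / 374 * exp(lp))))
    fup <- round(stats::runif(n, config$censor_range_days[1], config$censor_range_days[2]))
    sv <- list(days = pmin(t_death, fup), event = as.integer(t_death <= fup))
  }
  df <- build_registry_frame(g$ids, cov, sv$days, sv$event, tvtb, preop, config)
  registry <- suppressWarnings(validate_registry(df))
  registry$tvtb_cm <- tvtb
  list(masks = g$masks, registry = registry,
       truth = list(effect = config$effect, overlap = overlap,
                    survival_model = config$survival,
                    hazard_coefs = config$hazard_coefs,
                    centers_mm = g$centers, radii_mm = g$radii,
                    seed = config$seed))
}

#' Generate a null cohort with no location-outcome coupling
#'
#' Masks are generated exactly as in [generate_cohort()], but OS-group
#' labels come from a random permutation of a fixed label vector (default
#' split 52/122/41 at n = 215, scaled proportionally otherwise), so tumor
#' location is independent of outcome by construction. Used for
#' type-I-error suites.
#'
#' @param config A [sim_config].
#' @param group_sizes Integer vector of SHORT/MEDIUM/LONG sizes; default
#'   the 52/122/41 split scaled to `config$n_patients`.
#' @return Same structure as [generate_cohort()].
#' @export
generate_null_cohort <- function(config = sim_config(), group_sizes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  if (is.null(group_sizes)) {
    if (n == 215L) group_sizes <- c(52L, 122L, 41L)
    else {
      group_sizes <- round(n * c(52, 122, 41) / 215)
      group_sizes[1] <- n - sum(group_sizes[-1])
    }
  }
  stopifnot(sum(group_sizes) == n, all(group_sizes >= 1L))
  set.seed(config$seed)
  g <- generate_masks(config)
  cov <- draw_covariates(n)
  tvtb <- vapply(g$masks, tvtb_cm, numeric(1), ref = config$ref)
  vox_ml <- prod(config$grid$spacing_mm) / 1000
  preop <- round(vapply(g$masks, function(m) sum(m$voxels), numeric(1)) * vox_ml, 3)
  group <- sample(rep(c("SHORT", "MEDIUM", "LONG"), times = group_sizes))
  sv <- group_survival_days(group, config$censor_range_days)
  df <- build_registry_frame(g$ids, cov, sv$days, sv$event, tvtb, preop, config)
  registry <- suppressWarnings(validate_registry(df))
  registry$tvtb_cm <- tvtb
  list(masks = g$masks, registry = registry,
       truth = list(effect = NULL, group_sizes = group_sizes,
                    survival_model = "null-permuted", seed = config$seed))
}
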