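#' Group a set of tumor masks under an OS-group label
#'
#' @param group_label Label of the overall-survival group (e.g. `"SHORT"`).
#' @param masks List of [tumor_mask] objects sharing one grid.
#' @return An object of class `grouped_masks` with fields `group_label`,
#'   `masks`, `n` and the shared `grid`.
#' @export
grouped_masks <- function(group_label, masks) {
  if (length(masks) < 1L) stop("a group needs at least one mask")
  stopifnot(all(vapply(masks, inherits, logical(1), "tumor_mask")))
  grid <- masks[[1L]]$grid
  for (m in masks) assert_same_grid(m$grid, grid, sprintf("mask '%s' and the group", m$patient_id))
  structure(
    list(group_label = as.character(group_label), masks = masks,
         n = length(masks), grid = grid),
    class = "grouped_masks"
  )
}

#' Split cohort masks into OS-group mask collections
#'
#' @param masks List of [tumor_mask], named or ordered to match the registry.
#' @param registry A `cohort_registry` whose `patient_id` column matches the
#'   masks' patient ids. UNASSIGNABLE patients are dropped.
#' @return Named list of [grouped_masks] for SHORT, MEDIUM, LONG.
#' @export
group_masks_by_os <- function(masks, registry) {
  ids <- vapply(masks, function(m) m$patient_id, character(1))
  if (!all(registry$patient_id %in% ids))
    stop("registry contains patients without a mask")
  by_id <- stats::setNames(masks, ids)
  out <- list()
  for (g in c("SHORT", "MEDIUM", "LONG")) {
    pid <- registry$patient_id[registry$os_group == g]
    if (length(pid)) out[[g]] <- grouped_masks(g, unname(by_id[pid]))
  }
  out
}

#' Epsilon policy for zero-count voxels
#'
#' At voxels where every patient of a group, or none, has tumor, the raw
#' odds are 0/ n or n/0. The count is then replaced by a small epsilon
#' (default 1e-6), so the odds become `eps / (n - eps)` when no patient has
#' tumor there and `(n - eps) / eps` when all do. Applying the substitution
#' to the count (so the "without tumor" denominator becomes `n - eps`)
#' keeps the log-odds-ratio map antisymmetric under group exchange. Set
#' `denominator = "n"` to keep the group size as the denominator instead.
#'
#' @param epsilon Positive real in (0, 1).
#' @param denominator `"n_minus_eps"` (default) or `"n"`.
#' @return An object of class `epsilon_policy`.
#' @export
epsilon_policy <- function(epsilon = 1e-6, denominator = c("n_minus_eps", "n")) {
  stopifnot(epsilon > 0, epsilon < 1)
  structure(list(epsilon = epsilon, denominator = match.arg(denominator)),
            class = "epsilon_policy")
}

# n_masks x n_voxels 0/1 matrix restricted to the voxels in `domain_idx`
# (linear indices); the workhorse layout for counting and permutation.
mask_matrix <- function(masks, domain_idx) {
  n <- length(masks)
  M <- matrix(0L, nrow = n, ncol = length(domain_idx))
  for (i in seq_len(n)) M[i, ] <- masks[[i]]$voxels[domain_idx]
  M
}

count_array <- function(masks, grid) {
  counts <- array(0L, dim = grid$shape)
  for (m in masks) counts <- counts + m$voxels
  counts
}

#' Tumor distribution map
#'
#' The number of patients with tumor at each voxel, across all supplied
#' masks.
#'
#' @param masks List of [tumor_mask] on one grid (or a [grouped_masks]).
#' @return A [voxel_map] with label `COUNT`.
#' @export
distribution_map <- function(masks) {
  if (inherits(masks, "grouped_masks")) masks <- masks$masks
  if (length(masks) == 0L) stop("no masks supplied")
  grid <- masks[[1L]]$grid
  for (m in masks) assert_same_grid(m$grid, grid, sprintf("mask '%s' and the cohort", m$patient_id))
  voxel_map("COUNT", count_array(masks, grid), grid,
            metadata = list(n = length(masks)))
}

#' Analysis domain: voxels with a minimum tumor coverage
#'
#' Odds, log-odds-ratios and voxel-wise tests are only meaningful where the
#' cohort has lesions; all maps are `NaN` outside this domain. The default
#' requires at least 10 patients (about 5% of a 215-patient cohort) with
#' tumor at a voxel, in line with the minimum-lesion-count convention of
#' voxel-based lesion-symptom mapping: at thinly covered voxels the
#' per-voxel Fisher null is so discrete that the strict permutation
#' adjustment flags voxels whose observed p-value equals its own null
#' minimum, regardless of the significance level. Set `min_coverage = 1`
#' to test every covered voxel.
#'
#' @param masks List of [tumor_mask] for the whole mapped cohort.
#' @param min_coverage Minimum number of patients with tumor at a voxel.
#' @return Logical 3D array, `TRUE` inside the domain.
#' @export
analysis_domain <- function(masks, min_coverage = 10L) {
  if (inherits(masks, "grouped_masks")) masks <- masks$masks
  dist <- distribution_map(masks)
  dist$values >= min_coverage
}

# eps-substituted odds for tumor counts k out of n
odds_from_counts <- function(k, n, policy = epsilon_policy()) {
  eps <- policy$epsilon
  num <- ifelse(k == 0, eps, ifelse(k == n, n - eps, k))
  den <- if (policy$denominator == "n_minus_eps") n - num else n - k
  den[den == 0] <- eps   # only reachable with denominator = "n" at k = n
  num / den
}

#' Tumor odds map for one OS group
#'
#' Per voxel: (number of patients in the group with tumor there) divided by
#' (number without), with the epsilon substitution at all-zero and all-one
#' voxels (see [epsilon_policy()]).
#'
#' @param group A [grouped_masks].
#' @param policy An [epsilon_policy].
#' @param domain Optional logical array restricting computation; defaults to
#'   the group's own covered voxels being unrestricted (the whole grid).
#' @return A [voxel_map] with label `ODDS`.
#' @export
odds_map <- function(group, policy = epsilon_policy(), domain = NULL) {
  stopifnot(inherits(group, "grouped_masks"))
  counts <- count_array(group$masks, group$grid)
  if (any(counts == group$n))
    warning(sprintf("group %s: %d voxel(s) where every patient has tumor; mirrored epsilon substitution applied",
                    group$group_label, sum(counts == group$n)))
  odds <- odds_from_counts(counts, group$n, policy)
  if (!is.null(domain)) odds[!domain] <- NaN
  voxel_map("ODDS", odds, group$grid,
            metadata = list(group = group$group_label, n = group$n,
                            epsilon = policy$epsilon))
}

#' Log-odds-ratio map between two OS groups
#'
#' Per voxel, the natural log of the ratio of group A's tumor odds to group
#' B's. Positive values mean higher tumor odds in group A. The epsilon
#' substitution keeps every in-domain value finite.
#'
#' @param groupA,groupB [grouped_masks] on the same grid, disjoint patients.
#' @param policy An [epsilon_policy].
#' @param domain Optional logical array; voxels outside are `NaN`.
#' @return A [voxel_map] with label `LOG_OR`.
#' @export
log_odds_ratio_map <- function(groupA, groupB, policy = epsilon_policy(),
                               domain = NULL) {
  assert_same_grid(groupA$grid, groupB$grid, "the two groups")
  idsA <- vapply(groupA$masks, function(m) m$patient_id, character(1))
  idsB <- vapply(groupB$masks, function(m) m$patient_id, character(1))
  if (length(intersect(idsA, idsB)))
    stop("groups share patients; pairwise comparisons need disjoint groups")
  oA <- suppressWarnings(odds_map(groupA, policy))
  oB <- suppressWarnings(odds_map(groupB, policy))
  lor <- log(oA$values) - log(oB$values)
  if (!is.null(domain)) lor[!domain] <- NaN
  voxel_map("LOG_OR", lor, groupA$grid,
            metadata = list(groupA = groupA$group_label, groupB = groupB$group_label,
                            nA = groupA$n, nB = groupB$n, epsilon = policy$epsilon))
}

#' Mask a log-odds-ratio map by a significance map
#'
#' Voxels that are not significant are set to `NaN`, so only voxels whose
#' adjusted p-value passed the threshold remain visible.
#'
#' @param log_or A [voxel_map] with label `LOG_OR`.
#' @param significance A [voxel_map] with label `SIGNIFICANCE` on the same grid.
#' @return A masked `LOG_OR` [voxel_map].
#' @export
mask_log_or <- function(log_or, significance) {
  stopifnot(log_or$label == "LOG_OR", significance$label == "SIGNIFICANCE")
  assert_same_grid(log_or$grid, significance$grid, "log-OR and significance maps")
  vals <- log_or$values
  keep <- is.finite(significance$values) & significance$values == 1
  vals[!keep] <- NaN
  voxel_map("LOG_OR", vals, log_or$grid,
            metadata = c(log_or$metadata, list(masked = TRUE)))
}
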