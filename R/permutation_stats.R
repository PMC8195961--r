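#' Permutation test configuration
#'
#' @param n_perm Number of random label permutations for the null
#'   distribution (default 2000).
#' @param alpha Significance level for the adjusted p-values (default 0.01;
#'   voxels with adjusted p <= alpha are flagged).
#' @param seed Integer master seed for the permutation stream.
#' @param smooth If `TRUE`, use the add-one adjusted p-value
#'   `(b + 1) / (n_perm + 1)` instead of the literal proportion
#'   `b / n_perm`, where `b` counts null p-values strictly below the
#'   observed one. The literal rule can return adjusted p = 0.
#' @param scheme `"pairwise"` (default): labels are shuffled among the two
#'   groups being compared only. `"global"`: all cohort labels are shuffled
#'   jointly across the three OS groups (requires the full cohort, see
#'   [run_atlas()]).
#' @return An object of class `perm_config`.
#' @export
perm_config <- function(n_perm = 2000L, alpha = 0.01, seed = 1L,
                        smooth = FALSE, scheme = c("pairwise", "global")) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  stopifnot(alpha > 0, alpha < 1)
  structure(list(n_perm = as.integer(n_perm), alpha = alpha,
                 seed = as.integer(seed), smooth = isTRUE(smooth),
                 scheme = match.arg(scheme)),
            class = "perm_config")
}

# two-sided mid-free Fisher p for a support of hypergeometric probabilities:
# sum of P(tables) whose probability <= observed, with a relative tie
# tolerance so floating-point noise cannot drop exactly-tied tables
fisher_p_from_probs <- function(d, obs_index, tie_tol = 1e-7) {
  sum(d[d <= d[obs_index] * (1 + tie_tol)])
}

#' Two-sided Fisher exact p-value for a 2x2 tumor-by-group table
#'
#' The table has the OS group as one variable and tumor presence at a voxel
#' as the other: `kA` of `nA` group-A patients and `kB` of `nB` group-B
#' patients have tumor. The two-sided p-value sums the hypergeometric
#' probabilities of all tables with the same margins whose probability does
#' not exceed the observed table's (with a 1e-7 relative tie tolerance).
#'
#' @param kA,nA Tumor-present count and size of group A.
#' @param kB,nB Tumor-present count and size of group B.
#' @return p-value in (0, 1].
#' @export
fisher_p <- function(kA, nA, kB, nB) {
  stopifnot(kA >= 0, kB >= 0, kA <= nA, kB <= nB)
  K <- kA + kB
  x <- max(0, K - nB):min(K, nA)
  d <- stats::dhyper(x, nA, nB, K)
  min(1, fisher_p_from_probs(d, match(kA, x)))
}

#' Precompute Fisher p-values for fixed group sizes
#'
#' With fixed group sizes the per-voxel test depends only on the pair of
#' tumor-present counts, so a single `(nA+1) x (nB+1)` lookup makes the
#' observed pass and every permutation an O(voxels) table lookup.
#'
#' @param nA,nB Group sizes.
#' @return Numeric matrix `L` with `L[kA + 1, kB + 1] = fisher_p(kA, nA, kB, nB)`.
#' @export
build_p_lookup <- function(nA, nB) {
  stopifnot(nA >= 1, nB >= 1)
  L <- matrix(NA_real_, nrow = nA + 1L, ncol = nB + 1L)
  for (K in 0:(nA + nB)) {
    x <- max(0, K - nB):min(K, nA)
    d <- stats::dhyper(x, nA, nB, K)
    thr <- d * (1 + 1e-7)
    # p[i] = sum of probabilities <= d[i] (tie-tolerant), for every support point
    p <- vapply(seq_along(x), function(i) sum(d[d <= thr[i]]), numeric(1))
    L[cbind(x + 1L, K - x + 1L)] <- pmin(1, p)
  }
  L
}

#' Observed Fisher p-value map for a pairwise group comparison
#'
#' @param groupA,groupB Disjoint [grouped_masks] on a shared grid.
#' @param domain Logical array marking the analysis domain (voxels covered
#'   by at least one patient of the mapped cohort); defaults to the union of
#'   the two groups' coverage. Voxels outside are `NaN`.
#' @return A [voxel_map] with label `PVALUE`.
#' @export
observed_p_map <- function(groupA, groupB, domain = NULL) {
  assert_same_grid(groupA$grid, groupB$grid, "the two groups")
  if (is.null(domain)) domain <- analysis_domain(c(groupA$masks, groupB$masks))
  kA <- count_array(groupA$masks, groupA$grid)
  kB <- count_array(groupB$masks, groupB$grid)
  L <- build_p_lookup(groupA$n, groupB$n)
  vals <- array(NaN, dim = groupA$grid$shape)
  idx <- which(domain)
  vals[idx] <- L[cbind(kA[idx] + 1L, kB[idx] + 1L)]
  voxel_map("PVALUE", vals, groupA$grid,
            metadata = list(groupA = groupA$group_label, groupB = groupB$group_label,
                            nA = groupA$n, nB = groupB$n))
}

# one permutation pass: given the 0/1 membership vector z over the pooled
# patients, per-voxel group-A counts via a BLAS matrix-vector product
perm_counts <- function(M, z) as.vector(crossprod(M, z))

#' Permutation-adjusted p-value map
#'
#' Builds a per-voxel null distribution by randomly reassigning the pooled
#' patients (and their tumors) to the two groups, preserving group sizes,
#' and recomputing the Fisher p-value at every voxel; this respects the
#' spatial dependency between neighbouring voxels because whole tumors move
#' between groups. The adjusted p-value at a voxel is the proportion of its
#' null p-values that are strictly smaller than the observed one.
#'
#' @param groupA,groupB The compared [grouped_masks] (same objects used for
#'   `observed`).
#' @param observed The observed `PVALUE` [voxel_map] from [observed_p_map()].
#' @param config A [perm_config]; results are reproducible given its seed.
#' @param all_masks,all_labels For `scheme = "global"`: every mapped
#'   cohort mask and its OS-group label; permutations then shuffle the full
#'   label list and the null counts come from the reassigned A/B groups.
#' @return A [voxel_map] with label `ADJ_PVALUE` (`NaN` outside the domain).
#' @export
permutation_adjust <- function(groupA, groupB, observed, config = perm_config(),
                               all_masks = NULL, all_labels = NULL) {
  stopifnot(inherits(config, "perm_config"), observed$label == "PVALUE")
  domain_idx <- which(is.finite(observed$values))
  pobs <- observed$values[domain_idx]
  nA <- groupA$n; nB <- groupB$n
  L <- build_p_lookup(nA, nB)

  global <- config$scheme == "global" && !is.null(all_masks)
  if (global) {
    stopifnot(length(all_labels) == length(all_masks))
    M <- matrix(0, nrow = length(all_masks), ncol = length(domain_idx))
    for (i in seq_along(all_masks)) M[i, ] <- all_masks[[i]]$voxels[domain_idx]
    labels0 <- as.character(all_labels)
    lab_a <- groupA$group_label; lab_b <- groupB$group_label
  } else {
    pooled <- c(groupA$masks, groupB$masks)
    M <- matrix(0, nrow = nA + nB, ncol = length(domain_idx))
    for (i in seq_along(pooled)) M[i, ] <- pooled[[i]]$voxels[domain_idx]
  }

  below <- integer(length(domain_idx))
  set.seed(config$seed)
  for (j in seq_len(config$n_perm)) {
    if (global) {
      lab <- sample(labels0)
      kA <- perm_counts(M, as.numeric(lab == lab_a))
      kB <- perm_counts(M, as.numeric(lab == lab_b))
    } else {
      z <- numeric(nA + nB)
      z[sample.int(nA + nB, nA)] <- 1
      kA <- perm_counts(M, z)
      kB <- perm_counts(M, 1 - z)
    }
    pnull <- L[cbind(kA + 1L, kB + 1L)]
    below <- below + (pnull < pobs)
  }
  adj <- if (config$smooth) (below + 1) / (config$n_perm + 1) else below / config$n_perm
  vals <- array(NaN, dim = groupA$grid$shape)
  vals[domain_idx] <- adj
  voxel_map("ADJ_PVALUE", vals, groupA$grid,
            metadata = list(groupA = groupA$group_label, groupB = groupB$group_label,
                            nA = nA, nB = nB, n_perm = config$n_perm,
                            seed = config$seed, scheme = config$scheme,
                            smooth = config$smooth,
                            n_domain_voxels = length(domain_idx)))
}

#' Threshold an adjusted p-value map into a 0/1 significance mask
#'
#' @param adj_p An `ADJ_PVALUE` [voxel_map].
#' @param alpha Significance level; voxels with adjusted p <= alpha become 1
#'   (the boundary is included). `NaN` voxels become 0.
#' @return A [voxel_map] with label `SIGNIFICANCE`.
#' @export
significance_mask <- function(adj_p, alpha = 0.01) {
  stopifnot(adj_p$label == "ADJ_PVALUE", alpha > 0, alpha < 1)
  vals <- array(0, dim = adj_p$grid$shape)
  vals[is.finite(adj_p$values) & adj_p$values <= alpha] <- 1
  voxel_map("SIGNIFICANCE", vals, adj_p$grid,
            metadata = c(adj_p$metadata, list(alpha = alpha)))
}

#' Run one full pairwise OS-group comparison
#'
#' Computes the observed Fisher p-value map, the permutation-adjusted
#' p-value map, the significance mask at `config$alpha`, and the
#' significance-masked log-odds-ratio map for two disjoint OS groups.
#'
#' @inheritParams permutation_adjust
#' @param policy An [epsilon_policy] for the odds maps.
#' @param domain Optional logical analysis-domain array (voxels covered by
#'   at least one mapped patient); defaults to the two groups' coverage.
#' @return An object of class `comparison_result` with fields
#'   `groupA_label`, `groupB_label`, `n_included`, `p_map`, `adj_p_map`,
#'   `significance`, `log_or`, `masked_log_or`.
#' @export
run_comparison <- function(groupA, groupB, policy = epsilon_policy(),
                           config = perm_config(), domain = NULL,
                           all_masks = NULL, all_labels = NULL) {
  if (is.null(domain)) domain <- analysis_domain(c(groupA$masks, groupB$masks))
  p_map <- observed_p_map(groupA, groupB, domain)
  adj <- permutation_adjust(groupA, groupB, p_map, config,
                            all_masks = all_masks, all_labels = all_labels)
  sig <- significance_mask(adj, config$alpha)
  lor <- log_odds_ratio_map(groupA, groupB, policy, domain)
  structure(
    list(groupA_label = groupA$group_label, groupB_label = groupB$group_label,
         n_included = groupA$n + groupB$n,
         p_map = p_map, adj_p_map = adj, significance = sig,
         log_or = lor, masked_log_or = mask_log_or(lor, sig)),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  nsig <- sum(x$significance$values == 1)
  cat(sprintf("<comparison_result> %s vs %s (n = %d): %d significant voxel(s)\n",
              x$groupA_label, x$groupB_label, x$n_included, nsig))
  invisible(x)
}

#' Run the full statistical tumor atlas for a cohort
#'
#' Builds the cohort tumor distribution map and the three pairwise
#' OS-group comparisons (MEDIUM vs SHORT, LONG vs MEDIUM, LONG vs SHORT),
#' all restricted to the analysis domain of voxels covered by at least one
#' mapped patient.
#'
#' @param masks List of [tumor_mask] for the cohort.
#' @param registry A `cohort_registry`; UNASSIGNABLE patients are dropped
#'   from the maps.
#' @param policy An [epsilon_policy].
#' @param config A [perm_config]; each comparison derives its own seed from
#'   `config$seed` so the three null streams are independent.
#' @param min_coverage Analysis-domain threshold, see [analysis_domain()].
#' @return A list with `distribution` (COUNT map), `domain`, and
#'   `comparisons` (named list of [run_comparison()] results).
#' @export
run_atlas <- function(masks, registry, policy = epsilon_policy(),
                      config = perm_config(), min_coverage = 10L) {
  mapped <- registry[registry$os_group != "UNASSIGNABLE", , drop = FALSE]
  groups <- group_masks_by_os(masks, mapped)
  if (!all(c("SHORT", "MEDIUM", "LONG") %in% names(groups)))
    stop("all three OS groups must be non-empty for the atlas")
  mapped_masks <- unlist(lapply(groups, function(g) g$masks), recursive = FALSE)
  dist <- distribution_map(mapped_masks)
  domain <- dist$values >= min_coverage
  pairs <- list(MEDIUM_vs_SHORT = c("MEDIUM", "SHORT"),
                LONG_vs_MEDIUM  = c("LONG", "MEDIUM"),
                LONG_vs_SHORT   = c("LONG", "SHORT"))
  all_args <- if (config$scheme == "global") {
    labs <- unlist(lapply(groups, function(g) rep(g$group_label, g$n)))
    list(masks = mapped_masks, labels = labs)
  } else list(masks = NULL, labels = NULL)
  comparisons <- list()
  for (i in seq_along(pairs)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    comparisons[[names(pairs)[i]]] <- run_comparison(
      groups[[pairs[[i]][1]]], groups[[pairs[[i]][2]]],
      policy = policy, config = cfg, domain = domain,
      all_masks = all_args$masks, all_labels = all_args$labels)
  }
  list(distribution = dist, domain = domain, comparisons = comparisons)
}
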