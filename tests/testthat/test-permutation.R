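test_that("fisher_p matches the enumeration oracle on sampled small tables", {
  set.seed(1)
  for (i in 1:200) {
    nA <- sample(1:15, 1); nB <- sample(1:15, 1)
    kA <- sample(0:nA, 1); kB <- sample(0:nB, 1)
    expect_equal(fisher_p(kA, nA, kB, nB), fisher_oracle(kA, nA, kB, nB),
                 tolerance = 1e-12,
                 label = sprintf("table (%d/%d, %d/%d)", kA, nA, kB, nB))
  }
})

test_that("fisher_p agrees with stats::fisher.test", {
  set.seed(2)
  for (i in 1:50) {
    nA <- sample(2:40, 1); nB <- sample(2:40, 1)
    kA <- sample(0:nA, 1); kB <- sample(0:nB, 1)
    ref <- stats::fisher.test(matrix(c(kA, nA - kA, kB, nB - kB), 2))$p.value
    expect_equal(fisher_p(kA, nA, kB, nB), ref, tolerance = 1e-9)
  }
})

test_that("fisher_p handles degenerate and symmetric tables", {
  expect_equal(fisher_p(0, 5, 0, 5), 1)
  expect_equal(fisher_p(5, 5, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_p(2, 4, 2, 4), 1)
  # symmetry under swapping groups together with present/absent labels
  set.seed(3)
  for (i in 1:50) {
    nA <- sample(1:20, 1); nB <- sample(1:20, 1)
    kA <- sample(0:nA, 1); kB <- sample(0:nB, 1)
    expect_equal(fisher_p(kA, nA, kB, nB), fisher_p(nA - kA, nA, nB - kB, nB),
                 tolerance = 1e-12)
    expect_equal(fisher_p(kA, nA, kB, nB), fisher_p(kB, nB, kA, nA),
                 tolerance = 1e-12)
  }
})

test_that("the p-value lookup reproduces fisher_p over its whole index range", {
  L <- build_p_lookup(5, 5)
  expect_equal(dim(L), c(6L, 6L))
  for (kA in 0:5) for (kB in 0:5)
    expect_equal(L[kA + 1, kB + 1], fisher_p(kA, 5, kB, 5), tolerance = 1e-12)
  expect_true(all(L >= 0 & L <= 1))
  L2 <- build_p_lookup(52, 122)
  expect_equal(dim(L2), c(53L, 123L))
  expect_true(all(L2 >= 0 & L2 <= 1))
})

test_that("observed p-value maps place lookup values on the analysis domain", {
  g <- tiny_grid()
  mk <- function(id, vox) mask_at(vox, g, id)
  # 8 patients: voxel (1,1,1) covered by all 4 of group A, none of B
  gA <- grouped_masks("SHORT", lapply(1:4, function(i)
    mk(sprintf("A%d", i), rbind(c(1, 1, 1), c(2, 2, 2)))))
  gB <- grouped_masks("MEDIUM", lapply(1:4, function(i)
    mk(sprintf("B%d", i), rbind(c(2, 2, 2), c(3, 3, 3)))))
  domain <- analysis_domain(c(gA$masks, gB$masks), min_coverage = 1)
  pm <- observed_p_map(gA, gB, domain)
  expect_equal(pm$values[1, 1, 1], 2 / 70, tolerance = 1e-12)
  expect_equal(pm$values[2, 2, 2], 1)   # equal proportions
  expect_true(is.nan(pm$values[4, 4, 4]))  # outside the domain
})

test_that("permutation adjustment is reproducible and respects strict counting", {
  g <- tiny_grid()
  mk <- function(id, vox) mask_at(vox, g, id)
  gA <- grouped_masks("SHORT", lapply(1:4, function(i)
    mk(sprintf("A%d", i), rbind(c(1, 1, 1), c(2, 2, 2)))))
  gB <- grouped_masks("MEDIUM", lapply(1:4, function(i)
    mk(sprintf("B%d", i), rbind(c(2, 2, 2), c(3, 3, 3)))))
  domain <- analysis_domain(c(gA$masks, gB$masks), min_coverage = 1)
  pm <- observed_p_map(gA, gB, domain)
  cfg <- perm_config(n_perm = 300, seed = 99)
  a1 <- permutation_adjust(gA, gB, pm, cfg)
  a2 <- permutation_adjust(gA, gB, pm, cfg)
  expect_identical(a1$values, a2$values)
  # voxel (2,2,2) has equal coverage in every permutation: p always 1,
  # nothing strictly below -> adjusted p = 0 under the literal rule ...
  expect_equal(a1$values[2, 2, 2], 0)
  # ... and (0 + 1) / (n_perm + 1) under the add-one variant
  sm <- permutation_adjust(gA, gB, pm, perm_config(300, seed = 99, smooth = TRUE))
  expect_equal(sm$values[2, 2, 2], 1 / 301)
  expect_error(perm_config(n_perm = 0), "at least 1")
})

test_that("Monte-Carlo adjusted p-values converge to the exhaustive permutation law", {
  # 8 patients, 4 informative voxels; enumerate all C(8,4) = 70 assignments
  g <- tiny_grid()
  vox_sets <- list(A1 = rbind(c(1,1,1), c(2,2,2)), A2 = rbind(c(1,1,1), c(3,3,3)),
                   A3 = rbind(c(1,1,1), c(2,2,2)), A4 = c(4,4,4),
                   B1 = rbind(c(2,2,2), c(3,3,3)), B2 = c(3,3,3),
                   B3 = c(2,2,2), B4 = rbind(c(4,4,4), c(1,1,1)))
  masks <- lapply(names(vox_sets), function(id) mask_at(vox_sets[[id]], g, id))
  gA <- grouped_masks("SHORT", masks[1:4])
  gB <- grouped_masks("MEDIUM", masks[5:8])
  domain <- analysis_domain(masks, min_coverage = 1)
  pm <- observed_p_map(gA, gB, domain)
  dom_idx <- which(is.finite(pm$values))

  # exhaustive oracle: per voxel, proportion of assignments with p < observed
  M <- sapply(masks, function(m) m$voxels[dom_idx])
  L <- build_p_lookup(4, 4)
  combs <- utils::combn(8, 4)
  null_p <- apply(combs, 2, function(idx) {
    kA <- as.vector(M[, idx, drop = FALSE] %*% rep(1, 4))
    kB <- as.vector(M %*% rep(1, 8)) - kA
    L[cbind(kA + 1, kB + 1)]
  })
  exact <- rowMeans(null_p < pm$values[dom_idx] - 1e-12)

  adj <- permutation_adjust(gA, gB, pm, perm_config(n_perm = 2000, seed = 7))
  mc <- adj$values[dom_idx]
  se <- sqrt(pmax(exact * (1 - exact), 1e-12) / 2000)
  expect_true(all(abs(mc - exact) <= pmax(3 * se, 1e-9)))
})

test_that("the strict adjustment rule is anti-conservative on thin-coverage nulls", {
  # exact (no Monte Carlo) probability that a voxel is flagged at alpha=0.01
  # under the null, for margins 122/52 and total coverage K: the observed
  # table equals the minimum atom of its own discrete null and gets
  # adjusted p = 0
  flag_prob <- function(nA, nB, K) {
    L <- build_p_lookup(nA, nB)
    x <- max(0, K - nB):min(K, nA)
    w <- stats::dhyper(x, nA, nB, K)
    p <- L[cbind(x + 1L, K - x + 1L)]
    Fm <- vapply(p, function(pi) sum(w[p < pi * (1 - 1e-9)]), numeric(1))
    sum(w * (Fm <= 0.01))
  }
  # a single covered patient: flagged whenever it falls in the smaller group
  expect_equal(flag_prob(122, 52, 1), 52 / 174, tolerance = 1e-12)
  # the inflation persists at high coverage but shrinks below 2%
  expect_lt(flag_prob(122, 52, 50), 0.02)
  expect_gt(flag_prob(122, 52, 50), 0.01)
  # which is why analysis_domain() requires a minimum lesion count
  expect_gt(flag_prob(122, 52, 3), flag_prob(122, 52, 30))
})

test_that("significance masks threshold adjusted p at alpha inclusively", {
  g <- tiny_grid()
  vals <- array(NaN, dim = g$shape)
  vals[1, 1, 1] <- 0.01; vals[2, 2, 2] <- 0.011; vals[3, 3, 3] <- 0
  adj <- voxel_map("ADJ_PVALUE", vals, g)
  sig <- significance_mask(adj, alpha = 0.01)
  expect_equal(sig$values[1, 1, 1], 1)   # boundary included
  expect_equal(sig$values[2, 2, 2], 0)
  expect_equal(sig$values[3, 3, 3], 1)
  expect_equal(sig$values[4, 4, 4], 0)   # NaN domain -> 0
  all_nan <- voxel_map("ADJ_PVALUE", array(NaN, dim = g$shape), g)
  expect_true(all(significance_mask(all_nan)$values == 0))
})

test_that("run_comparison reports the pooled group size and coherent maps", {
  set.seed(21)
  g <- tiny_grid(c(6L, 6L, 6L))
  rand_masks <- function(n, pre) lapply(seq_len(n), function(i) {
    vox <- array(as.integer(runif(216) < 0.35), dim = g$shape)
    if (sum(vox) == 0) vox[1, 1, 1] <- 1L
    tumor_mask(sprintf("%s%d", pre, i), vox, g)
  })
  gA <- grouped_masks("MEDIUM", rand_masks(9, "A"))
  gB <- grouped_masks("SHORT", rand_masks(7, "B"))
  res <- suppressWarnings(run_comparison(gA, gB, config = perm_config(100, seed = 1),
                                         domain = analysis_domain(c(gA$masks, gB$masks),
                                                                  min_coverage = 2)))
  expect_equal(res$n_included, 16)
  dom <- is.finite(res$p_map$values)
  expect_identical(dom, is.finite(res$adj_p_map$values))
  # significance is exactly the alpha-thresholded adjusted map on the domain
  expect_equal(res$significance$values[dom] == 1,
               res$adj_p_map$values[dom] <= 0.01)
  # masked log-OR finite exactly on significant voxels
  expect_identical(is.finite(res$masked_log_or$values),
                   res$significance$values == 1)
  # a different permutation seed yields a different null realisation
  res2 <- suppressWarnings(run_comparison(gA, gB, config = perm_config(100, seed = 2),
                                          domain = analysis_domain(c(gA$masks, gB$masks),
                                                                   min_coverage = 2)))
  expect_false(identical(res$adj_p_map$values, res2$adj_p_map$values))
})

test_that("the global permutation scheme shuffles all three group labels", {
  set.seed(31)
  g <- tiny_grid(c(5L, 5L, 5L))
  rand_masks <- function(n, pre) lapply(seq_len(n), function(i) {
    vox <- array(as.integer(runif(125) < 0.4), dim = g$shape)
    if (sum(vox) == 0) vox[1, 1, 1] <- 1L
    tumor_mask(sprintf("%s%d", pre, i), vox, g)
  })
  all_masks <- rand_masks(12, "P")
  labels <- rep(c("SHORT", "MEDIUM", "LONG"), each = 4)
  gA <- grouped_masks("MEDIUM", all_masks[labels == "MEDIUM"])
  gB <- grouped_masks("SHORT", all_masks[labels == "SHORT"])
  dom <- analysis_domain(all_masks, min_coverage = 1)
  pm <- observed_p_map(gA, gB, dom)
  cfg <- perm_config(200, seed = 5, scheme = "global")
  adj <- permutation_adjust(gA, gB, pm, cfg, all_masks = all_masks, all_labels = labels)
  expect_true(all(adj$values[dom] >= 0 & adj$values[dom] <= 1))
  expect_equal(adj$metadata$scheme, "global")
})
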