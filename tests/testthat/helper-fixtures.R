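# small in-code fixtures shared across test files

tiny_grid <- function(shape = c(4L, 4L, 4L), spacing = c(1, 1, 1)) {
  grid_spec(shape, spacing_mm = spacing)
}

# mask with 1s at the given voxel index rows (1-based matrix or vector)
mask_at <- function(idx, grid = tiny_grid(), patient_id = "P1") {
  vox <- array(0L, dim = grid$shape)
  idx <- matrix(idx, ncol = 3)
  vox[idx] <- 1L
  tumor_mask(patient_id, vox, grid)
}

# n single-voxel masks at positions cycling through the grid diagonal
diag_masks <- function(n, grid = tiny_grid(), prefix = "P") {
  lapply(seq_len(n), function(i) {
    d <- ((i - 1) %% grid$shape[1]) + 1
    mask_at(c(d, d, d), grid, sprintf("%s%02d", prefix, i))
  })
}

# registry data frame with valid defaults, overridable per column
registry_df <- function(n = 4, ...) {
  df <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    survival_days = rep(400L, n),
    event = rep(1L, n),
    age_years = rep(65, n),
    sex = rep(c("female", "male"), length.out = n),
    kps_at_least_70 = rep(1L, n),
    biopsy_only = rep(0L, n),
    radiochemo = rep(1L, n),
    preop_volume_ml = rep(30, n),
    residual_ce_volume_ml = rep(1.5, n),
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

write_registry_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# exhaustive two-sided Fisher oracle from binomial coefficients only
fisher_oracle <- function(kA, nA, kB, nB) {
  K <- kA + kB
  xs <- max(0, K - nB):min(K, nA)
  probs <- choose(nA, xs) * choose(nB, K - xs) / choose(nA + nB, K)
  obs <- probs[match(kA, xs)]
  sum(probs[probs <= obs * (1 + 1e-7)])
}
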