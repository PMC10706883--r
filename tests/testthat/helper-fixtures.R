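# Shared fixtures, generated in code at test time.

small_phantom <- function(noise_sd = 0, grid = c(24, 24, 8), seed = 7, ...) {
  make_phantom(phantom_spec(grid = grid, noise_sd = noise_sd, seed = seed, ...))
}

# A phantom-like object with hand-specified voxelwise truth arrays (all-TRUE
# kidney mask), for driving the simulators over arbitrary parameter grids.
truth_phantom <- function(truth, voxel_mm = c(3, 3, 5), noise_sd = 0,
                          noise_model = "gaussian") {
  dims <- dim(truth[[1]])
  masks <- list(kidney = array(TRUE, dims))
  structure(list(truth = truth, masks = masks,
                 spec = list(grid = dims, voxel_mm = voxel_mm,
                             noise_sd = noise_sd, noise_model = noise_model)),
            class = "kidney_phantom")
}

# Column of voxels, one per row of the parameter table.
voxel_column <- function(n, values) array(values, c(n, 1, 1))

# Explicit normal-equations OLS oracle for y ~ a + b x.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}

# Brute-force AUC: fraction of correctly ordered positive/negative pairs,
# ties counting one half.
auc_pairs_oracle <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}
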