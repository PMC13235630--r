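# Shared fixtures (built once per test run) and independent brute-force
# oracles used to check the package's statistics.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

small_params <- function(seed = 1L) phantom_params_small(seed = seed)

small_atlas <- function() cached("small_atlas", make_atlas(small_params()))

canonical_atlas <- function() cached("canonical_atlas", make_atlas(phantom_params()))

# a hand-painted 12x12x4 atlas with exactly 4 voxels per region, giving full
# control over region values in metric tests
toy_atlas <- function() {
  cached("toy_atlas", {
    labels <- array(0L, dim = c(12, 12, 4))
    # GM ids 1..10 and paired WM ids 11..20 as 2x2 blocks on slices 2-3;
    # reference region on slice 1
    id <- 0L
    for (g in 0:4) {
      for (h in 0:1) {
        id <- id + 1L
        r <- 2 * g + 1
        c <- 2 * h + 1
        labels[r:(r + 1), c:(c + 1), 2] <- id        # GM
        labels[r:(r + 1), c + 4 + 0:1, 3] <- id + 10L  # WM
      }
    }
    labels[1:2, 1:2, 1] <- 21L
    groups <- c("frontal_insular", "temporal", "parietal", "pcc_precuneus",
                "striatum")
    hemi <- rep(c("L", "R"), times = 5)
    grp <- rep(groups, each = 2)
    regions <- tibble::tibble(
      region_id = c(1:10, 11:20, 21L, 99L),
      name = c(paste0(grp, "_", hemi, "_GM"), paste0(grp, "_", hemi, "_WM"),
               "reference", "wholebrain"),
      tissue = c(rep("GM", 10), rep("WM", 10), "reference", "wholebrain"),
      hemisphere = c(hemi, hemi, NA, NA),
      group = c(grp, grp, "reference", "other")
    )
    label_atlas(labels, regions, spacing = c(1, 1, 1))
  })
}

toy_volume <- function(data) pet_volume(data, spacing = c(1, 1, 1))

random_toy_volume <- function() {
  toy_volume(array(runif(12 * 12 * 4, 0.5, 3), dim = c(12, 12, 4)))
}

# a small simulated cohort reused across tests
small_cohort <- function() {
  cached("small_cohort",
         simulate_cohort(3, 3, small_params(seed = 42L), atlas = small_atlas()))
}

# ---- independent oracles -------------------------------------------------

# exact one-sided rank-sum p-value by enumerating all choose(m+n, m) rank
# assignments (no ties)
bf_wilcoxon_exact <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  n <- length(pooled)
  combos <- utils::combn(n, length(a))
  ranks <- rank(pooled)
  w_all <- apply(combos, 2, function(ix) {
    sum(ranks[ix]) - length(a) * (length(a) + 1) / 2
  })
  mean(w_all >= w_obs)
}

# AUC as the Mann-Whitney concordant-pair probability with ties counted half
bf_auc <- function(labels, scores) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# OLS by the normal equations
bf_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# brute-force ROI scan: mean over voxels found by scanning the label map
bf_region_mean <- function(vol, atlas, region_id) {
  vals <- c()
  d <- dim(atlas$labels)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (atlas$labels[x, y, z] == region_id) {
      vals <- c(vals, vol$data[x, y, z])
    }
  }
  mean(vals)
}

# brute-force contrast from raw voxel lists
bf_contrast <- function(vol, atlas, gid, wid) {
  g <- vol$data[atlas$labels == gid]
  w <- vol$data[atlas$labels == wid]
  sdp <- function(v) sqrt(mean((v - mean(v))^2))
  (mean(w) - mean(g)) / (sdp(w) + sdp(g))
}

# deterministic fixture pair for the SSIM reference-implementation check;
# the frozen expected value was computed with scikit-image
# (gaussian_weights, sigma 1.5, population covariance, data_range = range(x))
ssim_fixture <- function() {
  i <- matrix(rep(0:39, 40), 40, 40)
  j <- t(i)
  x <- sin(i / 3) * cos(j / 5) + 0.1 * (((i * 7 + j * 13) %% 11) / 11)
  y <- 0.9 * x + 0.05 * cos((i * j) / 50) + 0.02 * sin(i - j)
  list(x = x, y = y, expected = 0.930368931285)
}

# light stand-in slice samples for batching tests
fake_samples <- function(n_pos, n_neg) {
  c(
    lapply(seq_len(n_pos), function(i) list(status = "positive", id = i)),
    lapply(seq_len(n_neg), function(i) list(status = "negative", id = i))
  )
}
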