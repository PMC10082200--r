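# Shared fixtures, built in code.  The full-size phantom and the demo
# pipeline run are expensive, so they are memoized across test files.

fixture_env <- new.env(parent = emptyenv())

# one full-size (43 x 512 x 512) noise-free phantom for projection tests
get_clean_phantom <- function() {
  if (is.null(fixture_env$clean_phantom)) {
    spec <- phantom_spec(noise_sigma = 0, texture_scale = 0, seed = 11)
    fixture_env$clean_phantom <- make_phantom(spec)
  }
  fixture_env$clean_phantom
}

# small noisy phantom spec for micro pipeline tests (16 x 64 x 64 grid)
micro_spec <- function(seed = 1L) {
  phantom_spec(shape = c(16, 64, 64),
               organs = list(list(label = "kidney_right",
                                  center = c(8, 30, 16),
                                  semi = c(4, 10, 8), intensity = 0.65)),
               distractors = list(list(type = "sphere",
                                       center = c(8, 12, 48),
                                       radius = 5, intensity = 0.8)),
               noise_sigma = 0.03, texture_scale = 0.03, seed = seed)
}

micro_run_config <- function(seed = 5L) {
  run_config(organ = "kidney_right", seed = seed,
             n_train = 2L, n_eval = 2L,
             shape = c(16, 64, 64), target_z = 16L,
             preset = "fast",
             sampling = sampling_config(grid_spacing = 10,
                                        dilation_radius = 12, strip_pad = 4,
                                        slice_stride = 1, z_stride = 1,
                                        bc_max = 8),
             search = search_config(scan_step = 4, merge_distance = 4,
                                    dilate_size = 6),
             base_spec = micro_spec())
}

# the seeded demo pipeline run shared by the acceptance criteria
get_demo_run <- function() {
  if (is.null(fixture_env$demo_run)) {
    fixture_env$demo_cfg <- run_config(seed = 7L)
    fixture_env$demo_run <- suppressWarnings(
      run_pipeline(fixture_env$demo_cfg, quiet = TRUE))
  }
  list(cfg = fixture_env$demo_cfg, res = fixture_env$demo_run)
}

# reference Lloyd iteration, written independently of cluster_roi: plain
# loops, same quantile initialization contract.
reference_lloyd <- function(v, k, max_iter = 100, tol = 1e-4) {
  centers <- unique(unname(quantile(v, probs = seq(0, 1, length.out = k))))
  k <- length(centers)
  lab <- integer(length(v))
  for (it in seq_len(max_iter)) {
    for (i in seq_along(v)) {
      best <- 1
      for (j in seq_len(k))
        if (abs(v[i] - centers[j]) < abs(v[i] - centers[best])) best <- j
      lab[i] <- best
    }
    newc <- centers
    for (j in seq_len(k)) if (any(lab == j)) newc[j] <- mean(v[lab == j])
    mv <- max(abs(newc - centers))
    centers <- newc
    if (mv < tol) break
  }
  for (i in seq_along(v)) {
    best <- 1
    for (j in seq_len(k))
      if (abs(v[i] - centers[j]) < abs(v[i] - centers[best])) best <- j
    lab[i] <- best
  }
  list(labels = lab, centers = centers)
}

# all-pairs brute-force surface distances (oracle for surface_metrics)
brute_surface_metrics <- function(p, r, spacing = 1) {
  sp_vox <- which(ctroi:::surface_voxels(p), arr.ind = TRUE)
  sr_vox <- which(ctroi:::surface_voxels(r), arr.ind = TRUE)
  spc <- rep(spacing, length.out = ncol(sp_vox))
  dmat <- matrix(0, nrow(sp_vox), nrow(sr_vox))
  for (a in seq_len(nrow(sp_vox)))
    for (b in seq_len(nrow(sr_vox)))
      dmat[a, b] <- sqrt(sum(((sp_vox[a, ] - sr_vox[b, ]) * spc)^2))
  d_pr <- apply(dmat, 1, min)
  d_rp <- apply(dmat, 2, min)
  c(ASSD = mean(c(d_pr, d_rp)), MSSD = max(c(d_pr, d_rp)))
}

# random blobby logical array for metric property tests
random_mask <- function(dim, density = 0.3) {
  arr <- array(runif(prod(dim)) < density, dim = dim)
  arr
}
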