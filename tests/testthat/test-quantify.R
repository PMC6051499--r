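test_that("window_mean is the duration-weighted mean over the closed window", {
  expect_equal(window_mean(const_tac(3), time_window(30, 60)), 3)
  t1 <- tac(c(35, 45, 55), c(10, 10, 10), c(1, 2, 3))
  expect_equal(window_mean(t1, time_window(30, 60)), 2)
  t2 <- tac(c(40, 50), c(5, 15), c(1, 3))
  expect_equal(window_mean(t2, time_window(30, 60)), (5 * 1 + 15 * 3) / 20)
  # closed-interval membership: a frame exactly on the edge counts
  expect_equal(window_mean(t1, time_window(55, 60)), 3)
  expect_error(window_mean(t1, time_window(60, 70)), "\\[60, 70\\]")
})

test_that("suvr is a windowed ratio with domain checks", {
  ref <- const_tac(1)
  expect_equal(suvr(ref, ref, time_window(30, 60)), 1)
  expect_equal(suvr(const_tac(2), ref, time_window(30, 60)), 2)
  # invariance under common positive rescaling
  tt <- gen_srtm_tacs(srtm_params(bp_true = 0.5))
  w <- time_window(50, 70)
  s1 <- suvr(tt$target, tt$reference, w)
  scaled <- function(x, f) tac(x$frame_mid_times, x$frame_durations,
                               f * x$activity)
  expect_equal(suvr(scaled(tt$target, 7.3), scaled(tt$reference, 7.3), w), s1)
  # transient bias: close to DVR but not equal
  expect_lt(abs(s1 - 1.5) / 1.5, 0.10)
  expect_gt(abs(s1 - 1.5), 1e-3)
  expect_error(suvr(const_tac(1), const_tac(0), time_window(30, 60)),
               "positive reference")
  short <- tac(c(35, 45), c(10, 10), c(1, 1))
  expect_error(suvr(const_tac(1), short, time_window(30, 60)), "frame grid")
})

test_that("logan_bp matches closed forms and the SRTM ground truth", {
  # identical curves give slope 1, BP 0 (to 1e-10), for arbitrary TACs
  set.seed(42)
  for (i in 1:5) {
    x <- tac(seq(5, 90, 5), rep(5, 18), exp(rnorm(18, 1, 0.2)))
    expect_lt(abs(logan_bp(x, x, 10)), 1e-10)
  }
  # constant activities: integrals are linear in t and the slope is exactly
  # the activity ratio
  mid <- seq(10, 90, 10)
  tgt <- tac(mid, rep(10, 9), rep(2, 9))
  ref <- tac(mid, rep(10, 9), rep(1, 9))
  expect_equal(logan_bp(tgt, ref, 10), 1, tolerance = 1e-12)
  # SRTM recovery within 2% across binding levels
  for (bp in c(0, 0.25, 0.5, 1, 2)) {
    tt <- gen_srtm_tacs(srtm_params(bp_true = bp))
    est <- logan_bp(tt$target, tt$reference, 30)
    if (bp == 0) expect_lt(abs(est), 0.02)
    else expect_lt(abs(est - bp) / bp, 0.02)
  }
  expect_error(logan_bp(tgt, ref, 80), ">= 3 frames")
  neg <- tac(mid, rep(10, 9), c(rep(2, 8), -1))
  expect_error(logan_bp(neg, ref, 10), "positive")
})

test_that("pvc_correct inverts the mixing model", {
  M <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE)
  expect_equal(pvc_correct(c(3.4, 1.9), M), c(4, 1))
  expect_equal(pvc_correct(c(5, 7), diag(2)), c(5, 7))
  # regional_values container round-trips through correction
  rv <- regional_values(c("frontal", "precuneus"), c(3.4, 1.9), "SUVr")
  out <- pvc_correct(rv, M)
  expect_s3_class(out, "regional_values")
  expect_equal(out$values, c(4, 1))
  # forward-then-inverse is the identity on noiseless phantoms
  set.seed(3)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    W <- diag(k) * 3 + matrix(runif(k * k), k)
    W <- W / rowSums(W)
    tm <- runif(k, 1, 5)
    expect_equal(pvc_correct(gen_pvc_phantom(phantom_spec(tm, W)), W), tm,
                 tolerance = 1e-8)
  }
  expect_error(pvc_correct(c(1, 2), matrix(c(0.9, 0.2, 0.3, 0.7), 2,
                                           byrow = TRUE)), "sum to 1")
  sing <- matrix(0.5, 2, 2)
  expect_error(pvc_correct(c(1, 2), sing), "ill-conditioned")
})

test_that("noisy correction error grows with matrix conditioning", {
  # two-region mixing with increasing off-diagonal weight: condition number
  # rises and so does the corrected error at fixed noise
  errs <- sapply(c(0.05, 0.2, 0.35, 0.45), function(w) {
    M <- matrix(c(1 - w, w, w, 1 - w), 2, byrow = TRUE)
    err <- replicate(200, {
      spec <- phantom_spec(c(4, 1), M, noise_sd = 0.1,
                           seed = sample.int(1e6, 1))
      sqrt(mean((pvc_correct(gen_pvc_phantom(spec), M) - c(4, 1))^2))
    })
    mean(err)
  })
  expect_true(all(diff(errs) > 0))
})

test_that("mean_cortical_index aggregates regions correctly", {
  rv <- regional_values(c("frontal", "parietal", "temporal"), c(1, 2, 3),
                        "BP")
  expect_equal(mean_cortical_index(rv, "parietal"), 2)
  expect_equal(mean_cortical_index(rv), 2)
  rv2 <- regional_values(c("a", "b"), c(1, 3))
  expect_equal(mean_cortical_index(rv2, c("a", "b"), weights = c(1, 3)), 2.5)
  expect_error(mean_cortical_index(rv, c("frontal", "occipital")),
               "occipital")
  expect_error(mean_cortical_index(rv2, c("a", "b"), weights = c(0, 0)),
               "weights")
  # index always lies between the regional extremes
  set.seed(12)
  for (i in 1:10) {
    k <- sample(2:8, 1)
    vals <- rnorm(k)
    w <- runif(k)
    rvk <- regional_values(paste0("r", 1:k), vals)
    idx <- mean_cortical_index(rvk, weights = w)
    expect_gte(idx, min(vals))
    expect_lte(idx, max(vals))
  }
})

test_that("regional means from labelled volumes are exact", {
  img <- array(5, c(4, 4, 2))
  lab <- array(1L, c(4, 4, 2))
  expect_equal(regional_mean_from_volume(img, lab, 1), 5)
  img2 <- array(0, c(2, 2, 1)); lab2 <- array(0L, c(2, 2, 1))
  img2[1, 1, 1] <- 2; img2[2, 1, 1] <- 4
  lab2[1, 1, 1] <- 3L; lab2[2, 1, 1] <- 3L
  expect_equal(regional_mean_from_volume(img2, lab2, 3), 3)
  # checkerboard phantom with known per-label means
  lab3 <- array((outer(1:4, 1:4, "+") %% 2L), c(4, 4, 1))
  img3 <- array(0, c(4, 4, 1))
  img3[lab3 == 0] <- 7
  img3[lab3 == 1] <- 11
  expect_equal(regional_mean_from_volume(img3, lab3, 0), 7)
  expect_equal(regional_mean_from_volume(img3, lab3, 1), 11)
  expect_error(regional_mean_from_volume(img, array(1L, c(2, 2, 2)), 1),
               "grid")
  expect_error(regional_mean_from_volume(img, lab, 9), "label 9")
})

test_that("NIfTI round trip preserves volumes", {
  set.seed(5)
  a <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  p <- file.path(tempdir(), "vol.nii")
  write_nifti(a, p)
  expect_equal(read_nifti(p), a)
  write_nifti(a, p, datatype = "float32")
  expect_equal(read_nifti(p), a, tolerance = 1e-6)
  # volume + labels flow into regional means
  lab <- array(0L, dim(a)); lab[1:2, , ] <- 1L
  pl <- file.path(tempdir(), "lab.nii")
  write_nifti(lab, pl)
  expect_equal(regional_mean_from_volume(read_nifti(p), read_nifti(pl), 1),
               mean(a[1:2, , ]), tolerance = 1e-6)
  unlink(c(p, pl))
})
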