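test_that("angular_error applies the wraparound rule", {
  expect_equal(angular_error(170, -170), 20)
  expect_equal(angular_error(-170, 170), 20)
  expect_equal(angular_error(180, 0), 180)
  xs <- c(-179.5, -90, 0, 45, 180)
  expect_equal(angular_error(xs, xs), rep(0, 5))
  expect_error(angular_error(-180, 0), "\\(-180, 180\\]")
  expect_error(angular_error(0, 200), "\\(-180, 180\\]")
})

test_that("angular_error is symmetric and bounded by 180", {
  set.seed(501)
  a <- runif(200, -179.999, 180)
  b <- runif(200, -179.999, 180)
  ea <- angular_error(a, b)
  expect_equal(ea, angular_error(b, a))
  expect_true(all(ea >= 0 & ea <= 180))
})

test_that("evaluate_mae recovers planted uniform errors and handles cutoffs", {
  set.seed(502)
  L <- 60
  ref <- data.frame(position = 1:L,
                    phi = runif(L, -160, 160), psi = runif(L, -160, 160))
  perfect <- data.frame(position = 1:L, phi = ref$phi, psi = ref$psi,
                        confidence = runif(L, 0, 1.5))
  r <- evaluate_mae(perfect, ref)
  expect_equal(r$mae_phi, 0)
  expect_equal(r$mae_psi, 0)
  expect_equal(r$n_phi, L)

  shifted <- perfect
  shifted$phi <- ref$phi + 10 * sample(c(-1, 1), L, replace = TRUE)
  shifted$psi <- ref$psi + 10
  r10 <- evaluate_mae(shifted, ref)
  expect_equal(r10$mae_phi, 10, tolerance = 1e-9)
  expect_equal(r10$mae_psi, 10, tolerance = 1e-9)

  # cutoff above every confidence: empty set
  r_empty <- evaluate_mae(perfect, ref, cutoff = 2.0)
  expect_equal(r_empty$n, 0)
  expect_true(is.na(r_empty$mae_phi))

  # undefined native angles drop out of the denominator
  ref2 <- ref
  ref2$phi[1:5] <- NA
  r2 <- evaluate_mae(perfect, ref2)
  expect_equal(r2$n_phi, L - 5)
  expect_equal(r2$n_psi, L)
})

test_that("cutoff_curve rows match evaluate_mae and counts never increase", {
  set.seed(503)
  L <- 80
  ref <- data.frame(position = 1:L, phi = runif(L, -150, 150),
                    psi = runif(L, -150, 150))
  conf <- runif(L, 0, 1.5)
  err <- (1.6 - conf) * 8  # noisier where confidence is low
  pred <- data.frame(position = 1:L, phi = ref$phi + err,
                     psi = ref$psi - err, confidence = conf)
  cuts <- seq(0, 1.4, by = 0.2)
  curve <- cutoff_curve(pred, ref, cuts)
  expect_equal(nrow(curve), length(cuts))
  one <- evaluate_mae(pred, ref, cutoff = 0)
  expect_equal(curve$mae_phi[1], one$mae_phi)
  expect_true(all(diff(curve$n_phi) <= 0))
  # confidence-correlated noise: MAE non-increasing with cutoff
  expect_true(all(diff(curve$mae_phi) <= 1e-9))
  expect_true(all(diff(curve$mae_psi) <= 1e-9))
  # duplicate cutoffs give identical rows
  dup <- cutoff_curve(pred, ref, c(0.5, 0.5))
  expect_equal(dup[1, -1], dup[2, -1], ignore_attr = TRUE)
  expect_error(cutoff_curve(pred, ref, c(1, 0.5)))
})

test_that("fragments excised from the native give precision 1 everywhere", {
  sp <- scenario_spec(trace_noise_sd = 0, outlier_rate = 0, seed = 9,
                      recurrence = c(15L, 0L, 15L))
  sc <- generate_scenario(sp)
  pc <- local_precision_coverage(sc$library, sc$native$ca)
  covered <- !is.na(pc$precision)
  expect_true(any(covered))
  expect_true(all(pc$precision[covered] == 1))
  expect_equal(pc$coverage, mean(covered))
  expect_true(all(pc$compatible))
})

test_that("decoy-only libraries have near-zero precision on a helical native", {
  sp <- scenario_spec(regions = data.frame(kind = c("helix", "coil"),
                                           length = c(12L, 10L)),
                      recurrence = c(12L, 12L), seed = 10)
  nat <- generate_native(sp)
  lib <- generate_library(sp, nat)
  decoys <- Filter(function(f) attr(f, "planted") == "outlier", lib)
  pc <- local_precision_coverage(decoys, nat$ca)
  covered <- !is.na(pc$precision)
  expect_true(mean(pc$precision[covered]) < 0.2)
})

test_that("per-position precision counts equal a brute-force recount", {
  sc <- generate_scenario(scenario_spec(seed = 12))
  pc <- local_precision_coverage(sc$library, sc$native$ca)
  L <- nrow(sc$native$ca)
  for (pos in c(3, 7, 15, 20, 31)) {
    cov <- Filter(function(f) fragment_covers(f, pos), sc$library)
    compat <- vapply(cov, function(f) {
      kabsch(f$ca_trace,
             sc$native$ca[f$query_start:f$query_end, ])$rmsd < 1.5
    }, logical(1))
    if (length(cov)) {
      expect_equal(pc$precision[pos], mean(compat), tolerance = 1e-12)
    } else {
      expect_true(is.na(pc$precision[pos]))
    }
  }
})

test_that("precision and coverage are invariant under rigid motion of the native", {
  set.seed(504)
  sc <- generate_scenario(scenario_spec(seed = 13))
  pc1 <- local_precision_coverage(sc$library, sc$native$ca)
  pc2 <- local_precision_coverage(sc$library, rigid_transform(sc$native$ca))
  expect_equal(pc1$precision, pc2$precision, tolerance = 1e-9)
  expect_equal(pc1$coverage, pc2$coverage)
})

test_that("optimal_centroid_baseline picks the best-fitting fragment", {
  sp <- scenario_spec(seed = 14)
  sc <- generate_scenario(sp)
  base <- optimal_centroid_baseline(sc$library, sc$native$ca)
  rms <- vapply(sc$library, function(f) {
    kabsch(f$ca_trace, sc$native$ca[f$query_start:f$query_end, ])$rmsd
  }, numeric(1))
  ids <- vapply(sc$library, `[[`, "", "id")
  for (pos in c(7, 19, 31)) {
    cov <- which(vapply(sc$library, fragment_covers, logical(1),
                        position = pos))
    expect_identical(base$centroid_id[pos], ids[cov[which.min(rms[cov])]])
  }
  # a native-excised fragment always beats a jittered one
  ca <- sc$native$ca
  exact <- make_frag("exact", 1, ca[1:8, ])
  noisy <- make_frag("noisy", 1, ca[1:8, ] + 0.3)
  b2 <- optimal_centroid_baseline(list(noisy, exact), ca)
  expect_identical(b2$centroid_id[4], "exact")
  # single covering fragment: that fragment
  b1 <- optimal_centroid_baseline(list(noisy), ca)
  expect_identical(b1$centroid_id[2], "noisy")
})

test_that("the optimal baseline lower-bounds the method's centroid fit", {
  # The baseline picks the minimum-native-RMSD fragment, so at every position
  # its fragment fits the native at least as well as the method's centroid;
  # in reliable regions (confidence >= 0.8) its torsion MAE lower-bounds the
  # method's as well.
  sc <- generate_scenario(scenario_spec(seed = 15))
  pred <- predict_target(sc$library, sc$spec$target_length)
  base <- optimal_centroid_baseline(sc$library, sc$native$ca)
  ids <- vapply(sc$library, `[[`, "", "id")
  nat_rmsd <- function(id) {
    f <- sc$library[[match(id, ids)]]
    kabsch(f$ca_trace, sc$native$ca[f$query_start:f$query_end, ])$rmsd
  }
  both <- which(!is.na(pred$centroid_id) & !is.na(base$centroid_id))
  expect_gt(length(both), 10)
  for (i in both) {
    expect_lte(nat_rmsd(base$centroid_id[i]),
               nat_rmsd(pred$centroid_id[i]) + 1e-9)
  }
  ref <- data.frame(position = seq_len(nrow(sc$native$torsions)),
                    phi = sc$native$torsions[, "phi"],
                    psi = sc$native$torsions[, "psi"])
  keep <- which(!is.na(pred$phi) & pred$confidence >= 0.8)
  m <- evaluate_mae(pred[keep, ], ref)
  b <- evaluate_mae(base[keep, ], ref)
  expect_lte(b$mae_phi, m$mae_phi + 1e-9)
  expect_lte(b$mae_psi, m$mae_psi + 1e-9)
})

test_that("evaluate_predictions assembles curve, positions and coverage", {
  sc <- generate_scenario(scenario_spec(seed = 16))
  pred <- predict_target(sc$library, sc$spec$target_length)
  rep <- evaluate_predictions(pred, sc$native, cutoffs = c(0, 0.8),
                              library = sc$library, native_ca = sc$native$ca)
  expect_s3_class(rep, "evaluation_report")
  expect_equal(nrow(rep$per_cutoff), 2L)
  expect_equal(nrow(rep$per_position), sc$spec$target_length)
  expect_true(all(rep$per_position$err_phi >= 0 &
                    rep$per_position$err_phi <= 180, na.rm = TRUE))
  expect_true(rep$coverage >= 0 && rep$coverage <= 1)
})

test_that("pooled and per-protein MAE aggregation both work", {
  ref1 <- data.frame(position = 1:10, phi = rep(0.5, 10), psi = rep(0.5, 10))
  ref2 <- data.frame(position = 1:5, phi = rep(0.5, 5), psi = rep(0.5, 5))
  p1 <- data.frame(position = 1:10, phi = ref1$phi + 10, psi = ref1$psi,
                   confidence = 1)
  p2 <- data.frame(position = 1:5, phi = ref2$phi + 40, psi = ref2$psi,
                   confidence = 1)
  pooled <- evaluate_mae_multi(list(p1, p2), list(ref1, ref2))
  expect_equal(pooled$mae_phi, (10 * 10 + 40 * 5) / 15)
  per <- evaluate_mae_multi(list(p1, p2), list(ref1, ref2),
                            aggregate = "per_protein")
  expect_equal(per$mae_phi, 25)
})
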