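test_that("confidence reproduces the published worked examples exactly", {
  expect_equal(confidence(0.75, 100), 1.5, tolerance = 1e-12)
  expect_equal(confidence(1.0, 10), 1.0, tolerance = 1e-12)
  expect_equal(confidence(0.5, 100), 1.0, tolerance = 1e-12)
  expect_equal(confidence(0.8, 10), 0.8, tolerance = 1e-12)
  expect_equal(confidence(0.4, 100), 0.8, tolerance = 1e-12)
})

test_that("the recurrence weighting factor is exactly 1 at r = 10", {
  for (c_val in c(0.1, 0.33, 0.5, 0.75, 1.0)) {
    expect_equal(confidence(c_val, 10), c_val, tolerance = 1e-12)
  }
  expect_equal(confidence(1, 1), 0)   # log10(1) = 0
  expect_equal(confidence(0.9, 0), 0) # unassignable position
})

test_that("confidence is monotone non-decreasing in c and r", {
  cs <- seq(0, 1, by = 0.05)
  rs <- c(1:15, 20, 50, 100, 500)
  for (r in rs) expect_true(all(diff(confidence(cs, r)) >= 0))
  for (c_val in cs) expect_true(all(diff(confidence(c_val, rs)) >= 0))
  expect_error(confidence(1.2, 10), "\\[0, 1\\]")
  expect_error(confidence(0.5, -1), ">= 0")
})

test_that("consistency is the fraction of edges at or below threshold", {
  w <- matrix(NA_real_, 5, 5)
  w[upper.tri(w)] <- c(0.5, 1.0, 1.2, 1.5, 0.9, 1.49, 1.1, 0.7, 1.3, 0.2)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  g <- cluster_graph(w)
  expect_equal(consistency(g), 1.0)  # boundary 1.5 counts as similar

  w2 <- matrix(NA_real_, 4, 4)
  w2[upper.tri(w2)] <- c(1.0, 1.2, 2.0, 3.0, 0.5, 2.5)
  w2[lower.tri(w2)] <- t(w2)[lower.tri(w2)]
  expect_equal(consistency(cluster_graph(w2)), 0.5)  # 3 of 6

  expect_error(consistency(cluster_graph(matrix(NA_real_, 3, 3))),
               "edgeless")

  set.seed(301)
  w3 <- random_graph_weights(12)
  g3 <- cluster_graph(w3)
  ut <- w3[upper.tri(w3)]
  expect_equal(consistency(g3),
               sum(ut <= 1.5, na.rm = TRUE) / sum(!is.na(ut)),
               tolerance = 1e-12)
})

test_that("recurrence counts vertices and survives filtering arithmetic", {
  expect_equal(recurrence(cluster_graph(matrix(NA_real_, 0, 0))), 0L)
  set.seed(302)
  w <- random_graph_weights(20, wmin = 1.6, wmax = 4)
  res <- shrink_cluster(cluster_graph(w))
  expect_equal(recurrence(res$graph), 20L - nrow(res$removed))
})

test_that("centroid minimizes average incident weight among eligible vertices", {
  # hand-built: clique abc (low weights) + peripheral d attached to a
  w <- matrix(NA_real_, 4, 4,
              dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  w["a", "b"] <- w["b", "a"] <- 0.4
  w["a", "c"] <- w["c", "a"] <- 0.6
  w["b", "c"] <- w["c", "b"] <- 0.5
  w["a", "d"] <- w["d", "a"] <- 1.4
  g <- cluster_graph(w)
  # eligible: degree >= ceiling(0.5 * 3) = 2 -> a, b, c
  # averages: a = 2.4/3 = 0.8, b = 0.45, c = 0.55 -> b
  expect_identical(attr(centroid(g), "centroid_id"), "b")
  expect_identical(centroid_oracle(w), "b")

  # all-zero weights: deterministic lexicographic winner
  w0 <- matrix(0, 5, 5)
  diag(w0) <- NA
  rownames(w0) <- colnames(w0) <- c("m", "k", "z", "b", "q")
  expect_identical(attr(centroid(cluster_graph(w0)), "centroid_id"), "b")

  # random stable graphs vs exhaustive scan
  set.seed(303)
  for (rep in 1:40) {
    n <- sample(3:12, 1)
    wr <- random_graph_weights(n, wmin = 0.2, wmax = 1.4)
    gr <- cluster_graph(wr)
    cen <- centroid(gr)
    orc <- centroid_oracle(wr)
    if (is.null(orc)) {
      expect_null(cen)
    } else {
      expect_identical(attr(cen, "centroid_id"), orc)
      # minimality: no eligible vertex has a strictly smaller average
      deg <- rowSums(!is.na(wr))
      elig <- deg >= max(1, ceiling(0.5 * (n - 1)))
      avg_w <- rowSums(wr, na.rm = TRUE)[elig] / deg[elig]
      i <- which(rownames(wr) == orc)
      expect_lte(sum(wr[i, ], na.rm = TRUE) / deg[i], min(avg_w) + 1e-12)
    }
  }
})

test_that("isolated vertices are never centroid-eligible", {
  w <- matrix(NA_real_, 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  w["a", "b"] <- w["b", "a"] <- 0.5
  g <- cluster_graph(w)  # c is isolated
  expect_true(attr(centroid(g, min_degree_fraction = 0), "centroid_id")
              %in% c("a", "b"))
  lone <- cluster_graph(matrix(NA_real_, 1, 1, dimnames = list("a", "a")))
  expect_null(centroid(lone))
})

test_that("predict_position handles uncovered positions", {
  ca <- helix_ca(10)
  lib <- list(make_frag("f1", 1, ca))
  a <- predict_position(lib, 50)
  expect_identical(a$status, "empty")
  expect_equal(a$confidence, 0)
  expect_true(is.na(a$centroid_id))
  expect_true(is.na(a$phi))
  expect_false(a$reliable)
})

test_that("predict_position equals running the stage operations individually", {
  set.seed(304)
  sc <- generate_scenario(scenario_spec(seed = 21))
  cfg <- frag_config()
  for (pos in c(4, 7, 19, 31, 38)) {
    a <- predict_position(sc$library, pos, cfg)
    g <- build_cluster(sc$library, pos, overlap_min = cfg$overlap_min)
    res <- shrink_cluster(g, threshold = cfg$threshold)
    expect_identical(a$status, res$status)
    expect_equal(a$recurrence, n_vertices(res$graph))
    if (res$status == "stable") {
      c_val <- consistency(res$graph, cfg$threshold)
      expect_equal(a$consistency, c_val, tolerance = 1e-12)
      expect_equal(a$confidence,
                   confidence(c_val, recurrence(res$graph)),
                   tolerance = 1e-12)
      cen <- centroid(res$graph, cfg$min_degree_fraction)
      if (!is.null(cen)) {
        expect_identical(a$centroid_id, attr(cen, "centroid_id"))
        off <- pos - cen$query_start + 1
        expect_equal(a$phi, unname(cen$torsions[off, "phi"]))
        expect_equal(a$psi, unname(cen$torsions[off, "psi"]))
      }
    } else {
      expect_equal(a$confidence, 0)
      expect_true(is.na(a$phi))
    }
  }
})

test_that("predict_target recovers a planted consensus motif", {
  sc <- generate_scenario(scenario_spec(seed = 5))
  pred <- predict_target(sc$library, sc$spec$target_length)
  expect_equal(nrow(pred), sc$spec$target_length)
  expect_identical(pred$position, seq_len(sc$spec$target_length))
  labels <- setNames(vapply(sc$library, attr, "", "planted"),
                     vapply(sc$library, `[[`, "", "id"))
  # helix region center (position 7): reliable, centroid is a true fragment,
  # predicted torsions match the planted helix angles
  a <- pred[pred$position == 7, ]
  expect_identical(a$status, "stable")
  expect_gte(a$confidence, 0.8)
  expect_identical(unname(labels[a$centroid_id]), "true")
  expect_equal(a$phi, -57, tolerance = 2)
  expect_equal(a$psi, -47, tolerance = 2)
  # coil linker center: not reliable
  expect_lt(pred$confidence[pred$position == 19], 0.8)
  # singleton composition
  one <- predict_position(sc$library, 7)
  expect_equal(a$confidence, one$confidence, tolerance = 1e-12)
  expect_identical(a$centroid_id, one$centroid_id)
})

test_that("an empty library leaves every position unassigned", {
  pred <- predict_target(list(), 12)
  expect_true(all(pred$status == "empty"))
  expect_true(all(pred$confidence == 0))
  expect_true(all(is.na(pred$phi)))
})
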