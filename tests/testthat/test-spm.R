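make_static_ensemble <- function(coords, n_frames = 3) {
  # identical coordinates every frame, with an infinitesimal jitter pattern
  # added where a test needs nonzero fluctuations
  frames <- array(0, c(n_frames, nrow(coords), 3))
  for (f in seq_len(n_frames)) frames[f, , ] <- coords
  frames
}

test_that("the cross-correlation matrix captures duplicated, mirrored and independent motion", {
  set.seed(2)
  nf <- 400
  base <- rnorm(nf)
  frames <- array(0, c(nf, 3, 3))
  frames[, 1, ] <- base          # residue 1: reference motion
  frames[, 2, ] <- base          # residue 2: duplicated -> C = +1
  frames[, 3, ] <- -base         # residue 3: mirrored -> C = -1
  cm <- dccm(coordinate_ensemble(frames))
  expect_equal(diag(cm), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cm[1, 2], 1)
  expect_equal(cm[1, 3], -1)
  expect_equal(cm, t(cm))
})

test_that("zero-fluctuation residues are refused by name", {
  frames <- make_static_ensemble(matrix(1:12, 4, 3))
  frames[, 1:3, ] <- frames[, 1:3, ] + rnorm(length(frames[, 1:3, ])) * 0.1
  expect_error(dccm(coordinate_ensemble(frames, paste0("RES", 1:4))),
               regexp = "RES4", class = "halocat_degenerate_residue")
})

test_that("mean distances average frame-wise Euclidean separations", {
  # static pair 4 A apart
  frames <- make_static_ensemble(rbind(c(0, 0, 0), c(4, 0, 0)))
  frames[, 1, 2] <- frames[, 1, 2] + c(-1e-9, 0, 1e-9)  # break degeneracy
  frames[, 2, 2] <- frames[, 2, 2] + c(1e-9, 0, -1e-9)
  m <- mean_distance_matrix(coordinate_ensemble(frames))
  expect_equal(m[1, 2], 4, tolerance = 1e-6)
  expect_equal(diag(m), c(0, 0), ignore_attr = TRUE)
  # oscillation of +/-1 A along the separation axis around 5 A averages to 5
  frames2 <- array(0, c(2, 2, 3))
  frames2[1, 2, 1] <- 4; frames2[2, 2, 1] <- 6
  m2 <- mean_distance_matrix(coordinate_ensemble(frames2))
  expect_equal(m2[1, 2], 5)
})

test_that("graph construction applies the distance cutoff and the -ln|C| weight", {
  m <- matrix(c(0, 4, 7, 4, 0, 5, 7, 5, 0), 3, 3)
  cm <- matrix(c(1, 1, 0.5, 1, 1, 0.5, 0.5, 0.5, 1), 3, 3)
  g <- build_spm_graph(m, cm)
  # pair (1,3) at 7 A is excluded regardless of correlation
  expect_equal(nrow(g$edges), 2)
  expect_false(any(g$edges$i == 1 & g$edges$j == 3))
  w12 <- g$edges$weight[g$edges$i == 1 & g$edges$j == 2]
  w23 <- g$edges$weight[g$edges$i == 2 & g$edges$j == 3]
  expect_equal(w12, 0)               # |C| = 1 gives a zero-length edge
  expect_equal(w23, -log(0.5))       # 0.6931
  expect_error(build_spm_graph(m, cm[1:2, 1:2]),
               class = "halocat_invalid_parameter")
})

test_that("shortest paths and usages match hand enumeration on small graphs", {
  # 3-node path: 1-2 (|c|=0.9), 2-3 (|c|=0.5), no 1-3 edge
  m <- matrix(10, 3, 3); diag(m) <- 0
  m[1, 2] <- m[2, 1] <- 4; m[2, 3] <- m[3, 2] <- 4
  cm <- diag(3); cm[1, 2] <- cm[2, 1] <- 0.9; cm[2, 3] <- cm[3, 2] <- 0.5
  g <- shortest_path_map(build_spm_graph(m, cm))
  expect_equal(g$path_lengths[1, 3], -log(0.9) - log(0.5), tolerance = 1e-12)
  # every pair's path uses an edge incident to the middle node
  expect_equal(g$edges$usage, c(2L, 2L))
  # star graph: hub edges carry all leaf-to-leaf paths
  n <- 5
  ms <- matrix(10, n, n); diag(ms) <- 0
  cs <- diag(n)
  for (l in 2:n) { ms[1, l] <- ms[l, 1] <- 3; cs[1, l] <- cs[l, 1] <- 0.8 }
  gs <- shortest_path_map(build_spm_graph(ms, cs))
  expect_equal(sort(gs$edges$usage), rep(4L, 4))  # 1 spoke + 3 leaf pairs
  expect_true(all(gs$edges$in_map))
  # single edge: usage 1 and in the map
  m1 <- matrix(c(0, 4, 4, 0), 2, 2); c1 <- matrix(c(1, .7, .7, 1), 2, 2)
  g1 <- shortest_path_map(build_spm_graph(m1, c1))
  expect_equal(g1$edges$usage, 1L)
  expect_true(g1$edges$in_map)
})

test_that("Dijkstra agrees exactly with brute-force enumeration on random graphs", {
  for (seed in 1:25) {
    n <- sample(4:8, 1)
    g <- random_spm_graph(n, p_edge = 0.5, seed = seed)
    if (!nrow(g$edges)) next
    g <- shortest_path_map(g)
    adj <- halocat:::spm_adjacency(g)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      expect_equal(g$path_lengths[i, j], brute_force_shortest(adj, i, j),
                   tolerance = 1e-12,
                   info = sprintf("seed %d pair %d-%d", seed, i, j))
    }
  }
})

test_that("strengthening a correlation never lengthens any shortest path", {
  g <- random_spm_graph(7, p_edge = 0.6, seed = 99)
  g <- shortest_path_map(g)
  for (k in seq_len(min(5, nrow(g$edges)))) {
    g2 <- g
    g2$edges$weight[k] <- g2$edges$weight[k] * 0.5  # larger |c|
    g2 <- shortest_path_map(g2)
    expect_true(all(g2$path_lengths <= g$path_lengths + 1e-12))
  }
})

test_that("disconnected components are scored per component", {
  m <- matrix(10, 4, 4); diag(m) <- 0
  m[1, 2] <- m[2, 1] <- 3; m[3, 4] <- m[4, 3] <- 3
  cm <- diag(4); cm[1, 2] <- cm[2, 1] <- 0.9; cm[3, 4] <- cm[4, 3] <- 0.8
  g <- shortest_path_map(build_spm_graph(m, cm))
  expect_equal(g$edges$usage, c(1L, 1L))
  expect_true(all(!is.finite(g$path_lengths[1, 3:4])))
})

test_that("relabeling residues permutes the outputs consistently", {
  pl <- planted_chain_spec(5, n_frames = 300)
  ens <- simulate_ensemble(pl$spec)
  perm <- sample(13)
  ens_p <- coordinate_ensemble(ens$frames[, perm, , drop = FALSE],
                               ens$residue_labels[perm])
  cm <- dccm(ens); cm_p <- dccm(ens_p)
  expect_equal(unname(cm_p), unname(cm[perm, perm]))
  m <- mean_distance_matrix(ens); m_p <- mean_distance_matrix(ens_p)
  expect_equal(unname(m_p), unname(m[perm, perm]), tolerance = 1e-12)
})

test_that("a planted correlated chain surfaces among the top-usage edges", {
  expect_true(chain_edges_recovered(seed = 1))
  expect_true(chain_edges_recovered(seed = 2))
})

test_that("per-residue usage aggregates incident edges", {
  m1 <- matrix(c(0, 4, 4, 0), 2, 2); c1 <- matrix(c(1, .7, .7, 1), 2, 2)
  g1 <- shortest_path_map(build_spm_graph(m1, c1))
  ru <- residue_usage(g1)
  expect_equal(ru$usage, c(1L, 1L))
  expect_true(all(ru$in_map))
  expect_error(residue_usage(build_spm_graph(m1, c1)),
               class = "halocat_invalid_parameter")
})
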