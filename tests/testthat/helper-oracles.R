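# Independent oracles and fixture builders shared across the suite.

# Brute-force shortest path by enumeration over all simple paths.
# Independent of the package's Dijkstra implementation.
brute_force_shortest <- function(adj_w, from, to) {
  n <- nrow(adj_w)
  best <- Inf
  walk <- function(v, visited, len) {
    if (len >= best) return()
    if (v == to) { best <<- len; return() }
    for (u in seq_len(n)) {
      if (!visited[u] && is.finite(adj_w[v, u]))
        walk(u, `[<-`(visited, u, TRUE), len + adj_w[v, u])
    }
  }
  walk(from, `[<-`(rep(FALSE, n), from, TRUE), 0)
  best
}

# Random connected-ish weighted graph as an spm_graph, built through the
# exported constructor from fabricated distance/correlation matrices.
random_spm_graph <- function(n, p_edge = 0.5, seed = 1) {
  set.seed(seed)
  cmat <- diag(n)
  m <- matrix(10, n, n); diag(m) <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    if (stats::runif(1) < p_edge) {
      cmat[i, j] <- cmat[j, i] <- stats::runif(1, 0.05, 0.99)
      m[i, j] <- m[j, i] <- stats::runif(1, 2, 5.9)
    }
  }
  build_spm_graph(m, cmat)
}

# Planted communication pathway: a closed chain of 12 residues along the
# boundary of a 4x4 grid (4.5 A spacing) with ring-stationary AR(1)
# correlations (rho^ring-distance, positive semidefinite by construction),
# plus one uncorrelated bystander residue at an interior grid cell. A closed
# chain avoids the usage asymmetry of terminal edges, so recovery can demand
# strict dominance: every planted edge out-used by every background edge.
planted_chain_spec <- function(seed, n_frames = 1500, rho = 0.9) {
  grid <- expand.grid(x = 0:3, y = 0:3)
  ring_cells <- c(1, 2, 3, 4, 8, 12, 16, 15, 14, 13, 9, 5)  # boundary walk
  coords <- rbind(cbind(grid$x[ring_cells] * 4.5, grid$y[ring_cells] * 4.5, 0),
                  c(4.5, 4.5, 0))
  n <- 13
  ct <- diag(n)
  for (a in 1:12) for (b in 1:12)
    ct[a, b] <- rho^min(abs(a - b), 12 - abs(a - b))
  list(spec = ensemble_spec(coords, ct, fluctuation_scale = 0.8,
                            n_frames = n_frames, seed = seed),
       chain_pairs = t(apply(cbind(1:12, c(2:12, 1)), 1, sort)))
}

chain_edges_recovered <- function(seed) {
  pl <- planted_chain_spec(seed)
  ens <- simulate_ensemble(pl$spec)
  g <- build_spm_graph(mean_distance_matrix(ens), dccm(ens))
  g <- shortest_path_map(g)
  is_chain <- apply(g$edges, 1, function(e)
    any(pl$chain_pairs[, 1] == e[["i"]] & pl$chain_pairs[, 2] == e[["j"]]))
  sum(is_chain) == nrow(pl$chain_pairs) &&
    (!any(!is_chain) ||
       min(g$edges$usage[is_chain]) > max(g$edges$usage[!is_chain]))
}

# Random assay scenario with a safely in-range product curve, for
# round-trip testing of the plate-read generator and quantifier.
random_roundtrip_case <- function(seed) {
  set.seed(seed)
  cal <- indicator_calibration(pka_apparent = stats::runif(1, 6.9, 7.3),
                               ratio_acid = stats::runif(1, 0.0, 0.3),
                               ratio_base = stats::runif(1, 1.5, 3.0))
  buf <- buffer_spec(total_conc = stats::runif(1, 0.5, 3),
                     pka_apparent = stats::runif(1, 6.9, 7.5),
                     initial_ph = stats::runif(1, 6.8, 7.2))
  scen <- assay_scenario(buf, cal, substrate0 = 10)
  pmax_safe <- 0.15 * buf$total_conc * scen$dilution_factor
  prod <- c(0, sort(stats::runif(5, 0, pmax_safe)))
  list(scenario = scen,
       curve = progress_curve(c(0, 30, 60, 180, 270, 360), prod,
                              substrate0 = 10))
}

# Closed-form logistic melt curve (duplicated here so the extractor is
# checked against an expression written independently of the generator).
logistic_melt <- function(t, tm, k, low, high) {
  low + (high - low) / (1 + exp((tm - t) / k))
}

table1 <- list(
  f12y_1f    = list(kcat = 6.30, km = 0.98, eff = 6.43),
  f12y_epox  = list(kmax = 60.2, k50 = 14.2, nh = 2.32),
  g14a_epox  = list(kmax = 0.78, k50 = 49.5, nh = 4.58),
  wt_azide   = list(kmax = 27.0, k50 = 17.3, nh = 1.61),
  f12y_azide = list(kmax = 137, k50 = 49.6, nh = 2.44),
  t7s_epox   = list(kmax = 25.4, k50 = 40.3, nh = 1.14)
)

table3 <- data.frame(
  variant = c("WT", "F12Y", "T7S", "F12A", "F12Q", "G14A"),
  conversion = c(0.465, 0.453, 0.336, 0.509, 0.524, 0.0534),
  ee_p = c(0.826, 0.938, 0.945, 0.625, 0.510, 0.164),
  e_printed = c(22, 74, 57, 8.3, 5.3, 1.4)
)
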