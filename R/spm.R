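#' Dynamic cross-correlation matrix of residue fluctuations
#'
#' Scalar cross-correlation of positional displacements:
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`, with dr the
#' displacement of a residue's reference point from its ensemble mean.
#' Values near +1/-1 flag correlated/anticorrelated motions.
#'
#' @param ensemble A [coordinate_ensemble()].
#' @return n x n matrix of class `dccm_matrix`, symmetric with unit diagonal.
#' @export
dccm <- function(ensemble) {
  x <- ensemble$frames
  n <- dim(x)[2]
  cov <- matrix(0, n, n)
  for (a in 1:3) {
    da <- sweep(x[, , a, drop = TRUE], 2, colMeans(x[, , a, drop = TRUE]))
    cov <- cov + crossprod(da) / dim(x)[1]
  }
  d <- diag(cov)
  zero <- which(d <= .Machine$double.eps * max(d, 1))
  if (length(zero))
    halocat_error(sprintf("residue(s) with zero fluctuation: %s",
                          paste(ensemble$residue_labels[zero], collapse = ", ")),
                  "halocat_degenerate_residue")
  cm <- cov / sqrt(outer(d, d))
  diag(cm) <- 1
  dimnames(cm) <- list(ensemble$residue_labels, ensemble$residue_labels)
  structure(cm, class = c("dccm_matrix", "matrix", "array"))
}

#' Mean inter-residue distance matrix over an ensemble
#'
#' `m_ij` = mean over frames of the Euclidean distance between residue
#' reference points i and j.
#'
#' @param ensemble A [coordinate_ensemble()].
#' @return n x n symmetric nonnegative matrix (Angstrom) with zero diagonal.
#' @export
mean_distance_matrix <- function(ensemble) {
  x <- ensemble$frames
  nf <- dim(x)[1]; n <- dim(x)[2]
  m <- matrix(0, n, n)
  for (f in seq_len(nf))
    m <- m + as.matrix(stats::dist(x[f, , ]))
  m <- m / nf
  dimnames(m) <- list(ensemble$residue_labels, ensemble$residue_labels)
  m
}

#' Build the residue-communication graph
#'
#' Residue pairs closer on average than `distance_cutoff` and with absolute
#' motion correlation of at least `min_abs_corr` are connected; each edge is
#' weighted `-ln|C_ij|`, so strongly correlated neighbors are joined by
#' short edges. (The log base only rescales all weights uniformly and cannot
#' change which paths are shortest.)
#'
#' @param m Mean-distance matrix from [mean_distance_matrix()].
#' @param c Correlation matrix from [dccm()].
#' @param distance_cutoff Edge distance cutoff (Angstrom, default 6).
#' @param min_abs_corr Minimum `|C_ij|` for an edge (default 0.01; weaker
#'   correlations would get near-infinite weights and never carry paths).
#' @return An object of class `spm_graph`: residue `nodes` plus an `edges`
#'   data frame (`i`, `j`, `weight`, `usage`, `in_map`); usage columns are
#'   populated by [shortest_path_map()].
#' @export
build_spm_graph <- function(m, c, distance_cutoff = 6.0, min_abs_corr = 0.01) {
  if (!all(dim(m) == dim(c)))
    halocat_error("distance and correlation matrices disagree in dimension",
                  "halocat_invalid_parameter")
  n <- nrow(m)
  idx <- which(upper.tri(m) & m < distance_cutoff &
                 abs(c) >= min_abs_corr, arr.ind = TRUE)
  w <- pmax(-log(pmin(abs(c[idx]), 1)), 0)
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  structure(list(nodes = labels,
                 edges = data.frame(i = idx[, 1], j = idx[, 2], weight = w,
                                    usage = NA_integer_, in_map = NA)),
            class = "spm_graph")
}

# Dijkstra over the weighted adjacency of an spm_graph from one source.
# Deterministic: the frontier picks the lowest node index among equal
# distances, and equal-length alternative paths keep the lowest-index
# predecessor.
dijkstra_tree <- function(adj_w, source, eps = 1e-12) {
  n <- nrow(adj_w)
  dist <- rep(Inf, n); dist[source] <- 0
  pred <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]  # which.min takes the first = lowest index
    done[u] <- TRUE
    nb <- which(is.finite(adj_w[u, ]) & !done)
    for (v in nb) {
      nd <- dist[u] + adj_w[u, v]
      if (nd < dist[v] - eps) {
        dist[v] <- nd; pred[v] <- u
      } else if (abs(nd - dist[v]) <= eps &&
                 (is.na(pred[v]) || u < pred[v])) {
        pred[v] <- u
      }
    }
  }
  list(dist = dist, pred = pred)
}

spm_adjacency <- function(graph) {
  n <- length(graph$nodes)
  adj <- matrix(Inf, n, n)
  e <- graph$edges
  adj[cbind(e$i, e$j)] <- e$weight
  adj[cbind(e$j, e$i)] <- e$weight
  adj
}

#' Score edges by shortest-path usage and prune to the shortest path map
#'
#' Runs all-pairs shortest paths (Dijkstra with deterministic tie-breaking:
#' lowest node index preferred) over the weighted graph and counts, for each
#' edge, the number of unordered source-target residue pairs whose shortest
#' path traverses it. Edges whose usage reaches the `usage_quantile`
#' quantile of the positive usages form the map (`in_map`). Disconnected
#' components are handled per component.
#'
#' @param graph An [build_spm_graph()] result with at least one edge.
#' @param usage_quantile Quantile of positive edge usages above which an
#'   edge enters the map (default 0.8).
#' @return The graph with `usage` and `in_map` populated, plus a
#'   `path_lengths` matrix of all-pairs shortest path lengths.
#' @export
shortest_path_map <- function(graph, usage_quantile = 0.8) {
  if (nrow(graph$edges) == 0L)
    halocat_error("graph has no edges", "halocat_invalid_parameter")
  stopifnot_number(usage_quantile, "usage_quantile", 0, 1)
  n <- length(graph$nodes)
  adj <- spm_adjacency(graph)
  ekey <- paste(graph$edges$i, graph$edges$j)
  usage <- integer(nrow(graph$edges))
  plen <- matrix(Inf, n, n, dimnames = list(graph$nodes, graph$nodes))
  diag(plen) <- 0
  for (s in seq_len(n - 1L)) {
    tr <- dijkstra_tree(adj, s)
    plen[s, ] <- pmin(plen[s, ], tr$dist)
    for (t in seq.int(s + 1L, n)) {
      if (!is.finite(tr$dist[t])) next
      v <- t
      while (v != s) {
        u <- tr$pred[v]
        key <- paste(min(u, v), max(u, v))
        pos <- match(key, ekey)
        usage[pos] <- usage[pos] + 1L
        v <- u
      }
    }
  }
  plen <- pmin(plen, t(plen))
  graph$edges$usage <- usage
  pos_use <- usage[usage > 0]
  thr <- if (length(pos_use)) stats::quantile(pos_use, usage_quantile) else Inf
  graph$edges$in_map <- usage >= thr & usage > 0
  graph$path_lengths <- plen
  graph
}

#' Per-residue usage scores for structure coloring
#'
#' Sums the usage of all edges incident to each residue; `in_map` marks
#' residues touched by at least one map edge.
#'
#' @param graph A [shortest_path_map()] result.
#' @return Data frame with `residue`, `usage`, `in_map`.
#' @export
residue_usage <- function(graph) {
  if (all(is.na(graph$edges$usage)))
    halocat_error("run shortest_path_map() first", "halocat_invalid_parameter")
  n <- length(graph$nodes)
  usage <- integer(n); inmap <- logical(n)
  for (r in seq_len(nrow(graph$edges))) {
    e <- graph$edges[r, ]
    usage[e$i] <- usage[e$i] + e$usage
    usage[e$j] <- usage[e$j] + e$usage
    if (isTRUE(e$in_map)) inmap[c(e$i, e$j)] <- TRUE
  }
  data.frame(residue = graph$nodes, usage = usage, in_map = inmap)
}

#' @export
print.spm_graph <- function(x, ...) {
  cat(sprintf("shortest-path-map graph: %d residues, %d edges",
              length(x$nodes), nrow(x$edges)))
  if (!all(is.na(x$edges$in_map)))
    cat(sprintf(", %d map edges", sum(x$edges$in_map)))
  cat("\n")
  invisible(x)
}
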