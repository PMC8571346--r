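#' Bilateral health-effect network from export mortality
#'
#' Decomposes each economy's export-related premature deaths over its
#' consuming partners in proportion to the embodied-emission flows:
#' q_ij = deaths_i x T_ij / EEE_i for j != i, so each row sums back to the
#' economy's export mortality exactly. q_ij is read as "deaths suffered in
#' producing economy i attributable to consumption in economy j".
#'
#' @param export_mortality named per-economy deaths (a-1), names matching
#'   the rows of `T`.
#' @param T country-level embodied flow matrix (Gg).
#' @param accounts matching [trade_accounts()] output.
#' @return a `health_network`: list with the directed weight matrix `q`
#'   (zero diagonal) and node labels.
#' @export
bilateral_health_flows <- function(export_mortality, T, accounts) {
  if (any(export_mortality < 0)) stop("export mortality must be non-negative")
  labels <- rownames(T)
  m <- export_mortality[labels]
  eee <- accounts$EEE[match(labels, accounts$region)]
  if (any(m > 0 & eee <= 0))
    stop("inconsistent inputs: export mortality without embodied exports")
  off <- T
  diag(off) <- 0
  q <- matrix(0, nrow(T), ncol(T), dimnames = dimnames(T))
  pos <- which(m > 0)
  for (i in pos) q[i, ] <- m[i] * off[i, ] / eee[i]
  structure(list(q = q, labels = labels), class = "health_network")
}

#' @export
print.health_network <- function(x, ...) {
  cat(sprintf("<health_network> %d economies, %d edges, %.2f deaths a-1 total flow\n",
              length(x$labels), sum(x$q > 0), sum(x$q)))
  invisible(x)
}

# symmetrized weights w_ij = q_ij + q_ji (zero diagonal)
symmetrized_weights <- function(net) {
  w <- net$q + t(net$q)
  diag(w) <- 0
  w
}

#' Degrees and strengths of the health-effect network
#'
#' Out-degree counts the consuming partners an economy bears health loss
#' for; in-degree counts the producing partners it draws health loss from
#' (edges are flows above `threshold`). Strengths are the corresponding
#' weighted sums and do not depend on the threshold.
#'
#' @param net a `health_network`.
#' @param threshold edge-existence threshold in deaths a-1 (default 0:
#'   any positive flow is an edge).
#' @return data frame per node: k_out, k_in, s_out, s_in.
#' @export
degrees_strengths <- function(net, threshold = 0) {
  if (threshold < 0) stop("threshold must be >= 0")
  a <- net$q > threshold
  diag(a) <- FALSE
  data.frame(region = net$labels,
             k_out = rowSums(a), k_in = colSums(a),
             s_out = rowSums(net$q), s_in = colSums(net$q),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Brandes shortest-path accumulation on an undirected weighted graph.
# lengths: matrix of edge lengths (Inf = no edge). Returns node and edge
# betweenness over ordered source-target pairs, endpoints excluded.
brandes_betweenness <- function(lengths) {
  n <- nrow(lengths)
  node_b <- numeric(n)
  edge_b <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    preds <- vector("list", n)
    visited <- logical(n)
    order_out <- integer(0)
    repeat {
      cand <- which(!visited & is.finite(dist))
      if (length(cand) == 0) break
      u <- cand[which.min(dist[cand])]
      visited[u] <- TRUE
      order_out <- c(order_out, u)
      nb <- which(is.finite(lengths[u, ]) & !visited)
      for (v in nb) {
        alt <- dist[u] + lengths[u, v]
        if (alt < dist[v] - 1e-12) {
          dist[v] <- alt; sigma[v] <- sigma[u]; preds[[v]] <- u
        } else if (abs(alt - dist[v]) <= 1e-12) {
          sigma[v] <- sigma[v] + sigma[u]
          preds[[v]] <- c(preds[[v]], u)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_out)) {
      for (u in preds[[w]]) {
        share <- sigma[u] / sigma[w] * (1 + delta[w])
        edge_b[u, w] <- edge_b[u, w] + share
        edge_b[w, u] <- edge_b[w, u] + share
        delta[u] <- delta[u] + share
      }
      if (w != s) node_b[w] <- node_b[w] + delta[w]
    }
  }
  list(node = node_b, edge = edge_b)
}

#' Betweenness centrality
#'
#' b_k = sum over ordered pairs (i, j), i != j != k, of the share of
#' shortest i-j paths passing through k. The unweighted variant uses the
#' binary symmetrized graph with unit edge lengths; the weighted variant
#' uses edge length 1 / w_ij on the symmetrized weights, so larger health
#' flows mean shorter paths. Pairs with no connecting path contribute 0.
#'
#' @param net a `health_network`.
#' @param weighted logical.
#' @param threshold edge-existence threshold for the binary graph.
#' @return named per-node betweenness.
#' @export
betweenness_centrality <- function(net, weighted = FALSE, threshold = 0) {
  w <- symmetrized_weights(net)
  adj <- w > threshold
  lengths <- matrix(Inf, nrow(w), ncol(w))
  if (weighted) lengths[adj] <- 1 / w[adj] else lengths[adj] <- 1
  b <- brandes_betweenness(lengths)$node
  names(b) <- net$labels
  b
}

#' Eigenvector centrality of the binary symmetrized network
#'
#' Power iteration for the principal eigenpair of the undirected binary
#' adjacency; the returned vector is non-negative with unit Euclidean
#' norm.
#'
#' @param net a `health_network`.
#' @param threshold edge-existence threshold.
#' @param tol residual tolerance.
#' @param max_iter iteration cap.
#' @return list `vector` (named), `value` (largest eigenvalue).
#' @export
eigenvector_centrality <- function(net, threshold = 0, tol = 1e-10,
                                   max_iter = 10000) {
  a <- symmetrized_weights(net) > threshold
  if (!any(a)) stop("network has no edges")
  A <- a * 1
  # shifted iteration (A + I) shares the principal eigenvector and cannot
  # oscillate on bipartite graphs
  M <- A + diag(nrow(A))
  v <- rep(1 / sqrt(nrow(A)), nrow(A))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mv <- as.numeric(M %*% v)
    v <- mv / sqrt(sum(mv^2))
    lambda <- as.numeric(t(v) %*% A %*% v)
    if (max(abs(A %*% v - lambda * v)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) stop("power iteration did not converge")
  names(v) <- net$labels
  list(vector = v, value = lambda)
}

#' Weighted nearest-neighbour degree
#'
#' omega_i = sum_j (q_ij + q_ji)(k_j_out + k_j_in) / (s_i_out + s_i_in):
#' the strength-weighted mean total degree of i's neighbours. omega(k)
#' averages omega_i over nodes of total degree k; a decreasing omega(k)
#' marks a disassortative (hub-periphery) network. Isolated nodes get
#' omega = 0 by convention.
#'
#' @param net a `health_network`.
#' @param threshold edge-existence threshold.
#' @return list `omega_i` (named per node), `omega_k` (data frame k,
#'   omega).
#' @export
weighted_nn_degree <- function(net, threshold = 0) {
  ds <- degrees_strengths(net, threshold)
  w <- symmetrized_weights(net)
  ktot <- ds$k_out + ds$k_in
  stot <- ds$s_out + ds$s_in
  omega <- numeric(length(ktot))
  for (i in seq_along(omega)) {
    if (stot[i] <= 0) next
    omega[i] <- sum(w[i, ] * ktot) / stot[i]
  }
  if (any(stot <= 0 & ktot > 0))
    message("isolated-strength nodes assigned omega = 0")
  names(omega) <- net$labels
  ks <- sort(unique(ktot[ktot > 0]))
  omega_k <- data.frame(
    k = ks,
    omega = vapply(ks, function(k) mean(omega[ktot == k]), numeric(1)))
  list(omega_i = omega, omega_k = omega_k)
}

#' Weighted modularity of a partition
#'
#' Q = (1/2m) sum_ij \[w_ij - p_i p_j / 2m\] delta(c_i, c_j) on the
#' symmetrized weights w = q + q', with p_i the node's total attached
#' weight and m half the total weight; diagonal terms enter as written
#' (with w_ii = 0).
#'
#' @param net a `health_network`.
#' @param membership integer or character community label per node.
#' @return modularity Q in \[-1, 1\].
#' @export
modularity_q <- function(net, membership) {
  w <- symmetrized_weights(net)
  if (length(membership) != nrow(w))
    stop("membership must label every node")
  p <- rowSums(w)
  m2 <- sum(w)                      # 2m
  if (m2 <= 0) stop("network has no weight")
  same <- outer(membership, membership, `==`)
  sum((w - outer(p, p) / m2) * same) / m2
}

# connected components of a boolean adjacency matrix (labels 1..k,
# ordered by smallest member index for determinism)
components_of <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which(adj[u, ] & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Girvan-Newman community detection
#'
#' Divisive algorithm on the symmetrized weighted graph: repeatedly
#' removes the edge with the highest weighted edge betweenness (edge
#' length 1 / w_ij, ties broken by lexicographic edge order), and returns
#' the partition along the resulting dendrogram that maximizes the
#' weighted modularity of the original network. Fully deterministic.
#'
#' @param net a `health_network`.
#' @return a `partition`: list with `membership` (integer labels),
#'   `modularity`, and the number of communities.
#' @export
detect_communities <- function(net) {
  w0 <- symmetrized_weights(net)
  n <- nrow(w0)
  if (n < 2) stop("need at least 2 nodes")
  w <- w0
  best_membership <- rep(1L, n)
  best_q <- modularity_q(net, best_membership)
  while (any(w > 0)) {
    lengths <- matrix(Inf, n, n)
    lengths[w > 0] <- 1 / w[w > 0]
    eb <- brandes_betweenness(lengths)$edge
    eb[w <= 0] <- -Inf
    eb[lower.tri(eb, diag = TRUE)] <- -Inf
    # lexicographic tie-break: first max in column-major order of the
    # upper triangle, i.e. smallest (j, i) pair
    target <- which(eb == max(eb))[1]
    i <- row(eb)[target]; j <- col(eb)[target]
    w[i, j] <- 0; w[j, i] <- 0
    comp <- components_of(w > 0 | diag(TRUE, n))
    q <- modularity_q(net, comp)
    if (q > best_q + 1e-12) {
      best_q <- q
      best_membership <- comp
    }
  }
  structure(list(membership = stats::setNames(best_membership, net$labels),
                 modularity = best_q,
                 n_communities = length(unique(best_membership))),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d communities, Q = %.4f\n",
              x$n_communities, x$modularity))
  print(split(names(x$membership), x$membership))
  invisible(x)
}

#' Intra- and inter-community health-effect flows
#'
#' Block sums of the directed flows q over community pairs; the intra
#' share is the fraction of all flow carried inside communities.
#'
#' @param net a `health_network`.
#' @param partition a `partition` (or a membership vector).
#' @return list `flow_matrix` (communities x communities, deaths a-1),
#'   `intra_share`.
#' @export
community_flow_shares <- function(net, partition) {
  membership <- if (inherits(partition, "partition")) partition$membership
                else partition
  labs <- sort(unique(membership))
  k <- length(labs)
  fm <- matrix(0, k, k, dimnames = list(labs, labs))
  for (a in seq_len(k)) for (b in seq_len(k))
    fm[a, b] <- sum(net$q[membership == labs[a], membership == labs[b]])
  total <- sum(fm)
  list(flow_matrix = fm,
       intra_share = if (total > 0) sum(diag(fm)) / total else NA_real_)
}

# Riemann zeta truncated from below: sum_{k >= kmin} k^-s
zeta_from <- function(s, kmin) {
  z <- pracma::zeta(s)
  if (kmin > 1) z <- z - sum(seq_len(kmin - 1)^(-s))
  z
}

#' Discrete power-law fit to a degree sequence
#'
#' Maximum-likelihood exponent for p(k) proportional to k^-lambda on
#' k >= k_min (zeta-function normalization), by one-dimensional
#' likelihood maximization.
#'
#' @param degrees positive integer degrees (values below `k_min` are
#'   dropped from the fit).
#' @param k_min lower cut-off (default 1).
#' @return a `degree_fit`: exponent `lambda`, `k_min`, `n`,
#'   `log_likelihood`.
#' @export
powerlaw_degree_fit <- function(degrees, k_min = 1) {
  k <- degrees[degrees >= k_min]
  if (length(k) < 10) stop("need at least 10 degrees >= k_min")
  if (length(unique(k)) == 1)
    stop("degenerate degree sequence: all degrees equal; no power law to fit")
  slk <- sum(log(k))
  nll <- function(lambda) length(k) * log(zeta_from(lambda, k_min)) + lambda * slk
  opt <- stats::optimize(nll, interval = c(1.01, 20), tol = 1e-8)
  structure(list(lambda = opt$minimum, k_min = k_min, n = length(k),
                 log_likelihood = -opt$objective),
            class = "degree_fit")
}

#' @export
print.degree_fit <- function(x, ...) {
  cat(sprintf("<degree_fit> p(k) ~ k^-%.3f (k_min = %d, n = %d, logLik = %.2f)\n",
              x$lambda, x$k_min, x$n, x$log_likelihood))
  invisible(x)
}

#' Write a health network as GraphML and CSV edge list
#'
#' @param net a `health_network`.
#' @param graphml_path,csv_path output file paths (either may be NULL).
#' @return invisibly the edge list data frame.
#' @export
write_health_network <- function(net, graphml_path = NULL, csv_path = NULL) {
  idx <- which(net$q > 0, arr.ind = TRUE)
  edges <- data.frame(source = net$labels[idx[, 1]],
                      target = net$labels[idx[, 2]],
                      deaths = net$q[idx],
                      units = "deaths a-1",
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  if (!is.null(csv_path)) utils::write.csv(edges, csv_path, row.names = FALSE)
  if (!is.null(graphml_path)) {
    ig <- igraph::graph_from_data_frame(
      edges[, c("source", "target", "deaths")],
      directed = TRUE,
      vertices = data.frame(name = net$labels))
    igraph::write_graph(ig, graphml_path, format = "graphml")
  }
  invisible(edges)
}
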