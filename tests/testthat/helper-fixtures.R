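# Shared fixtures and independent oracles for the test suite.

small_config <- function(seed = 1, n_regions = 4, ...) {
  world_config(n_regions = n_regions, seed = seed, ...)
}

# hand-built MRIO table (bypasses the generator) from Z, destination-resolved
# final demand F (N x n) and the region/sector index
manual_mrio <- function(Z, F, index) {
  X <- rowSums(Z) + rowSums(F)
  labs <- paste(index$region, index$sector, sep = ":")
  dimnames(Z) <- list(labs, labs)
  rownames(F) <- labs
  names(X) <- labs
  structure(list(Z = Z, F = F, X = X, index = index,
                 regions = colnames(F)), class = "mrio_table")
}

manual_emissions <- function(index, X, emissions) {
  out <- data.frame(index, output = unname(X), emissions = emissions,
                    stringsAsFactors = FALSE)
  class(out) <- c("sector_emissions", "data.frame")
  out
}

# health network straight from a q matrix
net_from_q <- function(q, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("N%02d", seq_len(nrow(q)))
  dimnames(q) <- list(labels, labels)
  structure(list(q = q, labels = labels), class = "health_network")
}

# undirected unit-weight network from an edge list (each undirected edge
# becomes one directed flow i -> j so w = q + q' carries weight 1... or the
# given weight)
net_from_edges <- function(n, edges, weight = 1) {
  q <- matrix(0, n, n)
  w <- rep(weight, length.out = nrow(edges))
  for (e in seq_len(nrow(edges))) q[edges[e, 1], edges[e, 2]] <- w[e]
  net_from_q(q)
}

# --- independent oracles ----------------------------------------------------

# truncated Neumann series for the total-requirements matrix
neumann_inverse <- function(A, k_max = 60) {
  L <- diag(nrow(A))
  P <- diag(nrow(A))
  for (k in seq_len(k_max)) {
    P <- P %*% A
    L <- L + P
  }
  L
}

# brute-force betweenness by exhaustive simple-path enumeration (ordered
# pairs, endpoints excluded); lengths = matrix with Inf for non-edges
brute_betweenness <- function(lengths) {
  n <- nrow(lengths)
  paths_between <- function(i, j) {
    out <- list()
    grow <- function(path, len) {
      u <- path[length(path)]
      if (u == j) {
        out[[length(out) + 1]] <<- list(path = path, len = len)
        return()
      }
      for (v in which(is.finite(lengths[u, ]))) {
        if (v %in% path) next
        grow(c(path, v), len + lengths[u, v])
      }
    }
    grow(i, 0)
    out
  }
  b <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ps <- paths_between(i, j)
    if (length(ps) == 0) next
    lens <- vapply(ps, `[[`, 0, "len")
    short <- ps[abs(lens - min(lens)) < 1e-9]
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      through <- sum(vapply(short, function(p) k %in% p$path, TRUE))
      b[k] <- b[k] + through / length(short)
    }
  }
  b
}

# all set partitions of 1..n (Bell-number enumeration, fine for n <= 8)
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

partition_to_membership <- function(p, n) {
  m <- integer(n)
  for (b in seq_along(p)) m[p[[b]]] <- b
  m
}

# exhaustive modularity maximization
best_partition_exhaustive <- function(net) {
  n <- nrow(net$q)
  best <- list(q = -Inf, membership = NULL)
  for (p in all_partitions(n)) {
    m <- partition_to_membership(p, n)
    q <- modularity_q(net, m)
    if (q > best$q + 1e-12) best <- list(q = q, membership = m)
  }
  best
}

# vertex-enumeration LP oracle: max/min c'x s.t. A x (<=|>=|=) b, x >= 0
# by trying every square active set; exact for tiny problems
lp_enumerate <- function(c_obj, A, b, dir, maximize = TRUE) {
  n <- length(c_obj)
  Afull <- rbind(A, diag(n))         # x >= 0 as -x <= 0 handled via activity
  bfull <- c(b, rep(0, n))
  m <- nrow(Afull)
  best <- NULL
  for (active in utils::combn(m, n, simplify = FALSE)) {
    M <- Afull[active, , drop = FALSE]
    if (abs(det(M)) < 1e-12) next
    x <- tryCatch(solve(M, bfull[active]), error = function(e) NULL)
    if (is.null(x)) next
    if (any(x < -1e-9)) next
    lhs <- as.numeric(A %*% x)
    feas <- all(ifelse(dir == "<=", lhs <= b + 1e-9,
                       ifelse(dir == ">=", lhs >= b - 1e-9,
                              abs(lhs - b) <= 1e-9)))
    if (!feas) next
    val <- sum(c_obj * x)
    if (is.null(best) || (maximize && val > best$value + 1e-12) ||
        (!maximize && val < best$value - 1e-12))
      best <- list(value = val, x = x)
  }
  best
}

# draw n degrees from a discrete power law p(k) ~ k^-lambda (k >= 1)
rpowerlaw <- function(n, lambda, k_max = 1e5) {
  k <- seq_len(k_max)
  sample(k, n, replace = TRUE, prob = k^(-lambda))
}

# hand-built trade problem for the scenario LPs
manual_problem <- function(members, IM, EI, EX0, AC, I = NULL) {
  if (is.null(I)) I <- matrix(1, length(members), length(members))
  dimnames(IM) <- list(members, members)
  dimnames(I) <- list(members, members)
  structure(list(members = members, IM = IM,
                 EI = stats::setNames(EI, members),
                 EX0 = stats::setNames(EX0, members),
                 AC = stats::setNames(AC, members), I = I),
            class = "trade_problem")
}
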