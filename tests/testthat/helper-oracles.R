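# Independent brute-force oracles, deliberately naive: exhaustive path and
# triangle enumeration, Floyd-Warshall distances, power iteration. They
# share no code with the package implementations.

random_adjacency <- function(n, p) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) A[i, j] <- A[j, i] <- 1
    }
  }
  dimnames(A) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  A
}

graph_from_adjacency <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# All simple paths between s and t by depth-first enumeration.
all_simple_paths_bf <- function(A, s, t) {
  n <- nrow(A)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) { out[[length(out) + 1]] <<- path; return(invisible()) }
    for (w in seq_len(n)) {
      if (A[v, w] == 1 && !(w %in% path)) walk(c(path, w))
    }
  }
  walk(s)
  out
}

bf_betweenness <- function(A) {
  n <- nrow(A)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_simple_paths_bf(A, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
        bc[v] <- bc[v] + through / sigma
      }
    }
  }
  bc
}

bf_distances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A == 1, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

bf_closeness <- function(A) {
  D <- bf_distances(A)
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    comp <- which(is.finite(D[v, ]))
    if (length(comp) <= 1) return(0)
    (length(comp) - 1) / sum(D[v, comp])
  }, numeric(1))
}

bf_eigenvector <- function(A) {
  n <- nrow(A)
  D <- bf_distances(A)
  comp_id <- integer(n)
  cid <- 0
  for (v in seq_len(n)) {
    if (comp_id[v] == 0) {
      cid <- cid + 1
      comp_id[is.finite(D[v, ])] <- cid
    }
  }
  sizes <- tabulate(comp_id)
  largest <- which.max(sizes)
  members <- which(comp_id == largest)
  ec <- numeric(n)
  sub <- A[members, members, drop = FALSE]
  if (length(members) > 1 && sum(sub) > 0) {
    x <- rep(1 / sqrt(length(members)), length(members))
    M <- sub + diag(length(members))  # shift keeps iteration aperiodic
    for (it in 1:100000) {
      x_new <- as.numeric(M %*% x)
      x_new <- x_new / sqrt(sum(x_new^2))
      if (max(abs(x_new - x)) < 1e-14) { x <- x_new; break }
      x <- x_new
    }
    ec[members] <- abs(x)
  }
  ec
}

bf_lac <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1)
    if (length(nb) == 0) return(0)
    within_deg <- vapply(nb, function(w) sum(A[w, nb]), numeric(1))
    mean(within_deg)
  }, numeric(1))
}

bf_nc <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1)
    total <- 0
    for (w in nb) {
      tri <- 0
      for (u in seq_len(n)) if (A[v, u] == 1 && A[w, u] == 1) tri <- tri + 1
      denom <- min(deg[v] - 1, deg[w] - 1)
      if (denom > 0) total <- total + tri / denom
    }
    total
  }, numeric(1))
}

# Upper-tail hypergeometric by complete enumeration of all C(N, n) draws.
bf_hypergeom_upper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_term <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% in_term))
  mean(hits >= k)
}

# Median key-target rule, naive reimplementation.
bf_key_targets <- function(tbl) {
  med <- function(x) {
    s <- sort(x)
    m <- length(s)
    if (m %% 2 == 1) s[(m + 1) / 2] else (s[m / 2] + s[m / 2 + 1]) / 2
  }
  metrics <- c("bc", "cc", "dc", "ec", "lac", "nc")
  keep <- rep(TRUE, nrow(tbl))
  for (mname in metrics) keep <- keep & tbl[[mname]] >= med(tbl[[mname]])
  sort(tbl$node[keep])
}
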