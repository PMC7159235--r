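# Independent brute-force oracles. These deliberately avoid igraph and the
# package's own code paths: graphs are dense adjacency matrices built straight
# from edge tables, traversed with hand-written BFS / power iteration.

# adjacency matrix (directed) of a meganet-shaped edge set: regulation edges
# one-way, interactions both ways
bf_adjacency <- function(reg, interactions, nodes) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(reg))) A[reg$enhancer[i], reg$gene[i]] <- 1
  if (!is.null(interactions) && nrow(interactions) > 0) {
    for (i in seq_len(nrow(interactions))) {
      A[interactions$gene_a[i], interactions$gene_b[i]] <- 1
      A[interactions$gene_b[i], interactions$gene_a[i]] <- 1
    }
  }
  A
}

# single-source BFS distances over a directed adjacency matrix
bf_bfs <- function(A, from) {
  n <- nrow(A)
  dist <- rep(Inf, n)
  dist[from] <- 0
  frontier <- from
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !is.finite(dist))
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# reachability-scaled incoming closeness: (R/(n-1)) * (R/S) over distances
# from all other nodes into u
bf_closeness <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(u) {
    d <- bf_bfs(t(A), u)  # reversed edges: distance from v into u
    d <- d[is.finite(d) & d > 0]
    r <- length(d)
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(d))
  }, numeric(1))
}

bf_degree_frac <- function(A) {
  und <- (A + t(A)) > 0
  rowSums(und) / (nrow(A) - 1)
}

# power-iteration PageRank, dangling mass redistributed uniformly
bf_pagerank <- function(A, d = 0.85, tol = 1e-12) {
  n <- nrow(A)
  out <- rowSums(A)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) if (out[i] > 0) P[i, ] <- A[i, ] / out[i]
  x <- rep(1 / n, n)
  for (it in 1:50000) {
    dangling <- sum(x[out == 0])
    xn <- (1 - d) / n + d * (as.vector(t(P) %*% x) + dangling / n)
    if (max(abs(xn - x)) < tol) return(xn)
    x <- xn
  }
  xn
}

# shifted power iteration on the symmetrized adjacency, scaled to max 1
bf_eigenvector <- function(A, tol = 1e-13) {
  und <- ((A + t(A)) > 0) * 1
  x <- rep(1, nrow(und))
  M <- und + diag(nrow(und))
  for (it in 1:100000) {
    xn <- as.vector(M %*% x)
    xn <- xn / sqrt(sum(xn^2))
    if (max(abs(xn - x)) < tol) break
    x <- xn
  }
  xn / max(xn)
}

# random meganet edge tables whose undirected view is connected
random_meganet_tables <- function(n_enh = 5, n_gene = 6, p_reg = 0.4,
                                  p_int = 0.3) {
  repeat {
    enh <- sprintf("E%02d", seq_len(n_enh))
    gen <- sprintf("G%02d", seq_len(n_gene))
    reg <- expand.grid(enhancer = enh, gene = gen,
                       stringsAsFactors = FALSE)
    reg <- reg[stats::runif(nrow(reg)) < p_reg, , drop = FALSE]
    pairs <- t(utils::combn(gen, 2))
    keep <- stats::runif(nrow(pairs)) < p_int
    interactions <- tibble::tibble(gene_a = pairs[keep, 1],
                                   gene_b = pairs[keep, 2],
                                   type = "protein-protein")
    if (nrow(reg) == 0) next
    reg$tissues <- replicate(nrow(reg),
                             sample(c("t1", "t2", "t3"),
                                    sample(1:3, 1)), simplify = FALSE)
    reg <- tibble::as_tibble(reg)
    nodes <- c(sort(unique(reg$enhancer)),
               sort(unique(c(reg$gene, interactions$gene_a,
                             interactions$gene_b))))
    A <- bf_adjacency(reg, interactions, nodes)
    und <- (A + t(A)) > 0
    # connectivity check by BFS on the undirected view
    d <- bf_bfs(und * 1, 1)
    if (all(is.finite(d))) {
      return(list(reg = reg, interactions = interactions, nodes = nodes,
                  A = A))
    }
  }
}

# exact two-sided Fisher p by hypergeometric enumeration: sum of the
# probabilities of all tables (fixed margins) no more likely than observed
fisher_oracle_p <- function(a, b, c_, d) {
  m <- a + b          # row 1 total
  n <- c_ + d         # row 2 total
  k <- a + c_         # column 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# O(n^2) two-sample KS statistic: max ECDF gap over all pooled points
ks_oracle_D <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(p)
    abs(mean(x <= p) - mean(y <= p)), numeric(1)))
}

# exhaustive window scan for motif presence, written independently of the
# package scanner (per-window sapply over both strands)
motif_present_oracle <- function(seq, pwm, threshold_frac = 0.8,
                                 pseudocount = 0.5) {
  prob <- sweep(pwm + pseudocount, 2, colSums(pwm + pseudocount), "/")
  lo <- log2(prob / 0.25)
  w <- ncol(lo)
  thr <- threshold_frac * sum(apply(lo, 2, max))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  scan <- function(s) {
    ch <- strsplit(s, "")[[1]]
    if (length(ch) < w) return(FALSE)
    any(sapply(seq_len(length(ch) - w + 1), function(i) {
      win <- ch[i:(i + w - 1)]
      if (any(!win %in% c("A", "C", "G", "T"))) return(FALSE)
      sum(vapply(seq_len(w), function(k) lo[win[k], k], numeric(1))) >= thr
    }))
  }
  rc <- function(s) paste(rev(unname(comp[strsplit(s, "")[[1]]])),
                          collapse = "")
  s <- toupper(seq)
  scan(s) || scan(rc(s))
}
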