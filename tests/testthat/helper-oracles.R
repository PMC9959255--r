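# Independent oracles used across the suite.  Each reimplements a
# definition by brute force, never calling the code path it checks.

# exhaustive shortest-path betweenness on a small undirected graph
# (adjacency matrix); enumerates every shortest path per unordered pair
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  b <- numeric(n)
  if (n < 3) return(b)
  for (s in seq_len(n - 1)) {
    d <- rep(Inf, n); d[s] <- 0; q <- s
    while (length(q)) {
      u <- q[1]; q <- q[-1]
      for (v in which(adj[u, ] > 0)) {
        if (d[v] > d[u] + 1) { d[v] <- d[u] + 1; q <- c(q, v) }
      }
    }
    for (t in (s + 1):n) {
      if (!is.finite(d[t])) next
      paths <- list()
      rec <- function(path) {
        u <- path[length(path)]
        if (u == t) { paths[[length(paths) + 1L]] <<- path; return(invisible()) }
        for (v in which(adj[u, ] > 0)) {
          if (d[v] == d[u] + 1 && d[v] <= d[t]) rec(c(path, v))
        }
      }
      rec(s)
      cnt <- numeric(n)
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        cnt[interior] <- cnt[interior] + 1
      }
      b <- b + cnt / length(paths)
    }
  }
  b
}

# step-up BH straight from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- vapply(seq_len(m), function(i) min(1, min(m * sorted[i:m] / (i:m))),
                numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact hypergeometric upper tail by combinatorial summation
oracle_hyper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# connected components of mask (logical matrix), 4-connectivity;
# returns an integer label matrix (0 = background)
oracle_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (p in which(mask)) {
    if (lab[p] != 0L) next
    nxt <- nxt + 1L
    stack <- p
    lab[p] <- nxt
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (u - 1L) %% h + 1L; cc <- (u - 1L) %/% h + 1L
      for (v in c(if (r > 1) u - 1L, if (r < h) u + 1L,
                  if (cc > 1) u - h, if (cc < w) u + h)) {
        if (mask[v] && lab[v] == 0L) { lab[v] <- nxt; stack <- c(stack, v) }
      }
    }
  }
  lab
}

# brute-force MSER: thresholds at every integer level of the same 0..255
# quantization, stability (A(t-delta) - A(t+delta)) / A(t) along the branch
# identified by the component's brightest pixel, per-branch minimum,
# nested-duplicate collapse, intensity-weighted centroids
oracle_mser <- function(img, delta, min_area, max_area, max_stability) {
  q <- pmin(pmax(round(img / 257), 0), 255)
  h <- nrow(q); w <- ncol(q)
  qmax <- max(q); qmin <- min(q)
  labs <- lapply(qmin:qmax, function(t) oracle_label(q >= t))
  names(labs) <- as.character(qmin:qmax)
  area_of <- function(t, p) sum(labs[[as.character(t)]] == labs[[as.character(t)]][p])
  cands <- list()
  for (tc in qmin:qmax) {
    if (tc - delta < qmin || tc + delta > qmax) next
    lt <- labs[[as.character(tc)]]
    for (lb in setdiff(unique(as.vector(lt)), 0L)) {
      px <- which(lt == lb)
      A <- length(px)
      if (A < min_area || A > max_area) next
      seedq <- max(q[px])
      seed <- min(px[q[px] == seedq])
      if (seedq < tc + delta) next
      A_hi <- area_of(tc + delta, seed)
      A_lo <- area_of(tc - delta, seed)
      stab <- (A_lo - A_hi) / A
      if (stab <= max_stability) {
        cands[[length(cands) + 1L]] <- list(seed = seed, level = tc, area = A,
                                            stability = stab, px = px)
      }
    }
  }
  if (!length(cands)) {
    return(data.frame(x = numeric(0), y = numeric(0), area = integer(0),
                      stability = numeric(0), level = integer(0)))
  }
  # per-branch minimum
  df <- do.call(rbind, lapply(cands, function(cd)
    data.frame(seed = cd$seed, level = cd$level, area = cd$area,
               stability = cd$stability)))
  keep <- integer(0)
  for (s in unique(df$seed)) {
    i <- which(df$seed == s)
    i <- i[order(df$stability[i], -df$area[i], df$level[i])][1]
    keep <- c(keep, i)
  }
  df <- df[keep, , drop = FALSE]
  cands <- cands[keep]
  o <- order(df$stability, -df$area, df$level, df$seed)
  df <- df[o, , drop = FALSE]
  cands <- cands[o]
  accepted <- list()
  for (i in seq_len(nrow(df))) {
    nested <- any(vapply(accepted, function(a) df$seed[i] %in% a$px, logical(1)))
    if (!nested) accepted[[length(accepted) + 1L]] <- cands[[i]]
  }
  do.call(rbind, lapply(accepted, function(cd) {
    wgt <- img[cd$px]
    r <- (cd$px - 1L) %% h + 1L
    cc <- (cd$px - 1L) %/% h + 1L
    data.frame(x = sum(wgt * cc) / sum(wgt), y = sum(wgt * r) / sum(wgt),
               area = cd$area, stability = cd$stability, level = cd$level)
  }))
}

# random simple undirected graph as an edge data frame + adjacency matrix
random_graph <- function(n, p_edge, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  nodes <- sprintf("n%02d", seq_len(n))
  idx <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  edges <- data.frame(source = nodes[idx[, 1]], target = nodes[idx[, 2]],
                      stringsAsFactors = FALSE)
  list(adj = adj, edges = edges, nodes = nodes)
}

# small default scan used by several gridding tests
demo_scan <- function(noise_sd = 0, displacement = affine_params(), seed = 1,
                      rows = 4, cols = 4) {
  lay <- grid_layout(rows, cols)
  set.seed(seed)
  I <- matrix(stats::runif(rows * cols, 5000, 40000), rows, cols)
  sc <- simulate_array_scan(lay, I, displacement = displacement,
                            noise_sd = noise_sd, seed = seed)
  list(layout = lay, scan = sc, intensities = I)
}
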