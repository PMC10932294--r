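# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: path counting by exhaustive simple-path
# enumeration, PageRank by plain power iteration, BH by the literal step-up
# formula, hypergeometric tails by combinatorial summation.

# All five centralities by exhaustive shortest-path enumeration (n <= 8).
oracle_centralities <- function(g) {
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  comp <- igraph::components(g)$membership
  deg <- igraph::degree(g)
  dist <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(dist) <- 0
  sigma <- matrix(0, n, n)          # shortest-path counts s -> t
  through <- array(0, c(n, n, n))   # sigma_st(v)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t || comp[s] != comp[t]) next
      paths <- igraph::all_simple_paths(g, from = s, to = t)
      lens <- vapply(paths, length, integer(1)) - 1L
      d <- min(lens)
      dist[s, t] <- d
      shortest <- paths[lens == d]
      sigma[s, t] <- length(shortest)
      for (p in shortest) {
        inner <- setdiff(as.integer(p), c(s, t))
        for (v in inner) through[s, t, v] <- through[s, t, v] + 1
      }
    }
  }
  btw <- numeric(n); str <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in seq(s + 1, n)) {
        if (s == v || t == v || sigma[s, t] == 0) next
        btw[v] <- btw[v] + through[s, t, v] / sigma[s, t]
        str[v] <- str[v] + through[s, t, v]
      }
    }
  }
  tibble::tibble(
    node = nodes,
    degree = as.integer(deg),
    betweenness = vapply(seq_len(n), function(v) {
      nc <- sum(comp == comp[v])
      if (nc > 2) btw[v] / ((nc - 1) * (nc - 2) / 2) else 0
    }, numeric(1)),
    closeness = vapply(seq_len(n), function(v) {
      same <- which(comp == comp[v])
      if (length(same) < 2) return(NA_real_)
      (length(same) - 1) / sum(dist[v, same])
    }, numeric(1)),
    stress = as.integer(str),
    eccentricity = vapply(seq_len(n), function(v) {
      same <- which(comp == comp[v])
      max(dist[v, same])
    }, numeric(1))
  )
}

# Damped random-walk fixed point by power iteration on the degree-normalized
# adjacency operator (undirected, no dangling nodes assumed).
oracle_pagerank <- function(g, damping = 0.85, tol = 1e-13) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  deg <- rowSums(A)
  x <- rep(1 / n, n)
  repeat {
    x_new <- (1 - damping) / n + damping * as.numeric(t(A / deg) %*% x)
    if (max(abs(x_new - x)) < tol) break
    x <- x_new
  }
  stats::setNames(x_new, igraph::V(g)$name)
}

# Literal Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(n)
  for (i in seq_len(n)) {
    adj_sorted[i] <- min(1, min(p[ord][seq(i, n)] * n / seq(i, n)))
  }
  adj <- numeric(n)
  adj[ord] <- adj_sorted
  adj
}

# Upper-tail hypergeometric probability by direct combinatorial summation.
oracle_hyper_tail <- function(overlap, m, N, k) {
  j <- seq(overlap, min(m, k))
  sum(choose(m, j) * choose(N - m, k - j)) / choose(N, k)
}

# Minimal single-channel EDF writer (16-bit little-endian), independent of
# the package reader; used to fixture the EDF path at test time.
write_minimal_edf <- function(path, values, fs, record_duration = 1,
                              phys_min = -1000, phys_max = 1000,
                              label = "EEG ch1") {
  samples_per_record <- fs * record_duration
  n_records <- floor(length(values) / samples_per_record)
  values <- values[seq_len(n_records * samples_per_record)]
  dig_min <- -32768; dig_max <- 32767
  digital <- as.integer(round(
    (values - phys_min) / (phys_max - phys_min) * (dig_max - dig_min) + dig_min
  ))
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, n) {
    s <- sprintf("%-*s", n, as.character(x))
    writeChar(substr(s, 1, n), con, eos = NULL)
  }
  pad("0", 8); pad("test patient", 80); pad("test recording", 80)
  pad("01.01.24", 8); pad("00.00.00", 8)
  pad(256 + 256, 8)      # header bytes: fixed + one signal block
  pad("", 44); pad(n_records, 8); pad(record_duration, 8); pad(1, 4)
  pad(label, 16); pad("", 80); pad("uV", 8)
  pad(phys_min, 8); pad(phys_max, 8); pad(dig_min, 8); pad(dig_max, 8)
  pad("", 80); pad(samples_per_record, 8); pad("", 32)
  writeBin(digital, con, size = 2, endian = "little")
  invisible(path)
}

# Interval Jaccard index.
jaccard_interval <- function(a_start, a_end, b_start, b_end) {
  inter <- max(0, min(a_end, b_end) - max(a_start, b_start))
  union <- (a_end - a_start) + (b_end - b_start) - inter
  inter / union
}

random_test_graph <- function(seed, n_max = 8) {
  set.seed(seed)
  n <- sample(3:n_max, 1)
  g <- igraph::sample_gnp(n, p = runif(1, 0.3, 0.8))
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}
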