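# Independent oracles, deliberately coded apart from the package internals.

# Single-step Glicko update written directly from Glickman's published
# equations, scalar arithmetic only.
glicko_oracle_step <- function(r1, rd1, r2, rd2, s1) {
  q <- log(10) / 400
  g <- function(rd) 1 / sqrt(1 + 3 * (q^2) * (rd^2) / (pi^2))
  one <- function(r, rd, ro, rdo, s) {
    E <- 1 / (1 + 10^(-g(rdo) * (r - ro) / 400))
    d2 <- (q^2 * (g(rdo)^2) * E * (1 - E))^(-1)
    rp <- r + q / (1 / rd^2 + 1 / d2) * g(rdo) * (s - E)
    rdp <- sqrt((1 / rd^2 + 1 / d2)^(-1))
    c(rating = rp, rd = rdp)
  }
  list(p1 = one(r1, rd1, r2, rd2, s1), p2 = one(r2, rd2, r1, rd1, 1 - s1))
}

# All-pairs shortest paths on a binary directed adjacency by brute-force
# breadth over path lengths (Floyd-Warshall).
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Enumerate all simple paths s -> t; count shortest ones and those passing
# through each intermediate vertex (only feasible for tiny n).
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  all_paths <- function(s, t, visited) {
    if (s == t) return(list(s))
    out <- list()
    for (v in which(adj[s, ] > 0)) if (!(v %in% visited)) {
      for (p in all_paths(v, t, c(visited, v)))
        out[[length(out) + 1]] <- c(s, p)
    }
    out
  }
  for (s in seq_len(n)) for (t in seq_len(n)) if (s != t) {
    paths <- all_paths(s, t, s)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1))
    sp <- paths[lens == min(lens)]
    for (v in seq_len(n)) if (v != s && v != t) {
      thru <- sum(vapply(sp, function(p) v %in% p, logical(1)))
      btw[v] <- btw[v] + thru / length(sp)
    }
  }
  btw
}

oracle_closeness <- function(adj) {
  d <- oracle_distances(adj)
  vapply(seq_len(nrow(adj)), function(v) {
    dv <- d[v, -v]
    dv <- dv[is.finite(dv)]
    if (!length(dv)) NaN else 1 / sum(dv)
  }, numeric(1))
}

oracle_mean_path <- function(adj) {
  d <- oracle_distances(adj)
  off <- d[row(d) != col(d)]
  off <- off[is.finite(off) & off > 0]
  if (!length(off)) NA_real_ else mean(off)
}

# Offline least-squares single-break fit: best split of x into two
# constant segments.
oracle_single_break <- function(x) {
  n <- length(x)
  sse <- vapply(2:(n - 1), function(b) {
    sum((x[1:(b - 1)] - mean(x[1:(b - 1)]))^2) +
      sum((x[b:n] - mean(x[b:n]))^2)
  }, numeric(1))
  (2:(n - 1))[which.min(sse)]
}

# Small event-table fixture builder.
make_events <- function(actor, receiver, behavior, day = 1, phase = "dark",
                        time = seq_along(actor) * 10, group = "g1",
                        duration = 2, zone = 1) {
  validate_events(data.frame(group = group, day = day, phase = phase,
                             time = time, actor = actor, receiver = receiver,
                             behavior = behavior, duration = duration,
                             zone = zone))
}

# Tiny colony configuration for fast pipeline tests.
small_config <- function(seed = 1, ...) {
  sim_config(n_groups = c(wildtype = 1, knockout = 1), phase_seconds = 600,
             seed = seed, ...)
}

cognitive_vars <- c("AUC.DDT", "Flexibility", "RGT", "Latency.RGT")
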