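# Independent reference implementations used as oracles.  These deliberately
# share no code with the package internals: straightforward loops and
# exhaustive enumeration at tiny problem sizes.

# property distance by direct evaluation of the weighted-Euclidean formula
oracle_pd <- function(a, b, table = default_descriptors()) {
  lam <- attr(table, "lambda")
  s <- 0
  for (i in 1:5) s <- s + lam[[i]] * (table[a, i] - table[b, i])^2
  sqrt(s)
}

# all simple paths of length min_len..max_len in an adjacency list
oracle_all_simple_paths <- function(adj, min_len, max_len) {
  out <- list()
  grow <- function(path) {
    if (length(path) >= min_len) out[[length(out) + 1L]] <<- path
    if (length(path) == max_len) return()
    for (nb in adj[[path[length(path)]]])
      if (!nb %in% path) grow(c(path, nb))
  }
  for (v in names(adj)) grow(v)
  out
}

# seed enumeration: filter all simple paths by position-wise PD matching
# against every contiguous substring of the mimotope
oracle_seeds <- function(mimotope, adj, res_aa, cutoff, min_len,
                         table = default_descriptors()) {
  aas <- strsplit(mimotope, "")[[1]]
  L <- length(aas)
  paths <- oracle_all_simple_paths(adj, min_len, L)
  out <- list()
  for (p in paths) {
    k <- length(p)
    for (start in seq_len(L - k + 1)) {
      sub <- aas[start:(start + k - 1)]
      pd <- mapply(function(a, key) oracle_pd(a, res_aa[[key]], table),
                   sub, p)
      if (all(pd <= cutoff))
        out[[length(out) + 1L]] <- list(start = start,
                                        end = start + k - 1L,
                                        path = p, pd = unname(pd))
    }
  }
  out
}

seed_signature <- function(s)
  paste(s$start, s$end, paste(s$path, collapse = ">"), sep = "|")

# connection enumeration: every non-empty ordered subset of the seeds with
# strictly increasing spans, disjoint antigen residues, and the pairwise
# N-to-N gap test between consecutive members
oracle_connections <- function(seeds, nxyz, nn_step = 3.5) {
  n <- length(seeds)
  out <- list()
  idx_all <- seq_len(n)
  for (m in seq_len(n)) {
    combos <- utils::combn(idx_all, m, simplify = FALSE)
    for (cmb in combos) {
      mem <- seeds[cmb][order(vapply(seeds[cmb], `[[`, 1L, "start"))]
      okc <- TRUE
      resid <- unlist(lapply(mem, `[[`, "path"))
      if (anyDuplicated(resid)) next
      if (m > 1) {
        for (j in seq_len(m - 1)) {
          a <- mem[[j]]; b <- mem[[j + 1]]
          if (b$start <= a$end) { okc <- FALSE; break }
          gap <- b$start - a$end - 1L
          pa <- nxyz[a$path[length(a$path)], ]
          pb <- nxyz[b$path[1], ]
          if (anyNA(pa) || anyNA(pb)) { okc <- FALSE; break }
          dd <- sqrt(sum((pa - pb)^2))
          if (dd > (gap + 1) * nn_step) { okc <- FALSE; break }
        }
      }
      if (okc) out[[length(out) + 1L]] <- mem
    }
  }
  out
}

conn_signature <- function(seed_list)
  paste(vapply(seed_list, seed_signature, ""), collapse = "&")

# filter-then-union selection
oracle_select <- function(connections, avg_pd_max = 2) {
  if (!length(connections)) return(character(0))
  ml <- vapply(connections, function(cn) length(cn$pd), 0L)
  gmax <- max(ml)
  keep <- character(0)
  for (cn in connections) {
    avg <- mean(cn$pd)
    if (all(cn$pd == 0) ||
        (length(cn$pd) == gmax && avg > 0 && avg <= avg_pd_max))
      keep <- c(keep, cn$residues)
  }
  sort(unique(keep))
}

# random connected-ish labelled toy graph with 3D coordinates; returns the
# pieces needed both by find_seeds/connect_seeds and by the oracles
random_toy_graph <- function(n_nodes, seed) {
  set.seed(seed)
  keys <- paste0("A:", seq_len(n_nodes))
  aa <- sample(rownames(default_descriptors()), n_nodes, replace = TRUE)
  # random geometric adjacency keeps things sparse but connected enough
  xyz <- matrix(stats::runif(n_nodes * 3, 0, 2.1) * n_nodes^(1/3), ncol = 3)
  d <- as.matrix(stats::dist(xyz))
  cutoff <- stats::quantile(d[upper.tri(d)], 0.35)
  adj <- lapply(seq_len(n_nodes), function(i)
    keys[d[i, ] <= cutoff & seq_len(n_nodes) != i])
  names(adj) <- keys
  res_aa <- stats::setNames(as.list(aa), keys)
  residues <- data.frame(key = keys, chain = "A", resno = seq_len(n_nodes),
                         insert = "", resid = "UNK", aa1 = aa,
                         ca_x = xyz[, 1], ca_y = xyz[, 2], ca_z = xyz[, 3],
                         n_x = xyz[, 1], n_y = xyz[, 2], n_z = xyz[, 3],
                         sasa = NA_real_, max_sasa = NA_real_,
                         is_surface = TRUE, stringsAsFactors = FALSE)
  fake_antigen <- structure(list(atoms = NULL, residues = residues,
                                 source = "toy"), class = "antigen")
  smap <- structure(adj, class = "surface_map", cutoff = cutoff,
                    metric = "ca")
  list(keys = keys, aa = aa, adj = adj, res_aa = res_aa, xyz = xyz,
       antigen = fake_antigen, surface_map = smap)
}

# random synthetic seed set (not necessarily realisable on a graph) for
# exercising connect_seeds against the subset oracle
random_seed_set <- function(n_seeds, mimo_len, n_res, seed) {
  set.seed(seed)
  keys <- paste0("A:", seq_len(n_res))
  nxyz <- matrix(stats::runif(n_res * 3, 0, 12), ncol = 3,
                 dimnames = list(keys, c("n_x", "n_y", "n_z")))
  seeds <- lapply(seq_len(n_seeds), function(i) {
    len <- sample(2:3, 1)
    start <- sample.int(mimo_len - len + 1L, 1)
    path <- sample(keys, len)
    list(mimotope_id = "m1", start = start, end = start + len - 1L,
         path = path, pd = stats::runif(len, 0, 4))
  })
  residues <- data.frame(key = keys, chain = "A", resno = seq_len(n_res),
                         insert = "", resid = "UNK", aa1 = "A",
                         ca_x = nxyz[, 1], ca_y = nxyz[, 2],
                         ca_z = nxyz[, 3],
                         n_x = nxyz[, 1], n_y = nxyz[, 2], n_z = nxyz[, 3],
                         sasa = NA_real_, max_sasa = NA_real_,
                         is_surface = TRUE, stringsAsFactors = FALSE)
  fake_antigen <- structure(list(atoms = NULL, residues = residues,
                                 source = "toy"), class = "antigen")
  list(seeds = seeds, nxyz = nxyz, antigen = fake_antigen)
}

# random pool of synthetic connections for the selection oracle
random_connection_pool <- function(n_conn, seed) {
  set.seed(seed)
  lapply(seq_len(n_conn), function(i) {
    len <- sample(2:6, 1)
    pd <- if (stats::runif(1) < 0.3) rep(0, len) else
      stats::runif(len, 0, 3)
    list(mimotope_id = paste0("m", sample(3, 1)),
         residues = paste0("A:", sample(30, len)),
         pd = pd, matched_length = len, avg_pd = mean(pd))
  })
}

# hypergeometric upper tail by the explicit combinatorial sum
oracle_hyper_sum <- function(k, n, N, M) {
  xs <- k:min(n, M)
  sum(choose(M, xs) * choose(N - M, n - xs)) / choose(N, n)
}

# one-sided signed-rank p-value by full enumeration of sign assignments
oracle_signed_rank <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  mean(w_all >= w_obs - 1e-9)
}
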