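# Seed discovery, seed connection, selection and the full predictor

test_that("gap span limit follows the extended-chain rule", {
  expect_identical(gap_span_limit(2), 10.5)
  expect_identical(gap_span_limit(0), 3.5)
  for (step in c(3.4, 3.5, 3.6, 3.7, 3.8))
    expect_equal(gap_span_limit(5, step), 6 * step)
  expect_error(gap_span_limit(-1), "non-negative")
})

test_that("an exact mimotope is recovered as a full-length zero-PD seed", {
  fx <- make_toy_antigen(length = 12, geometry = "extended", seed = 21)
  ant <- compute_sasa(read_antigen(text = fx$pdb))
  surf <- select_surface_residues(ant)
  smap <- build_surface_map(ant, surf)
  mim <- substr(fx$sequence, 4, 9)
  seeds <- find_seeds(mim, smap, ant)
  full <- Filter(function(s) s$start == 1 && s$end == nchar(mim), seeds)
  expect_gte(length(full), 1L)
  hit <- Filter(function(s) all(s$pd == 0) &&
                  identical(s$path, fx$annotation$key[4:9]), full)
  expect_length(hit, 1L)
})

test_that("a mimotope matching nothing yields no seeds", {
  fx <- make_toy_antigen(length = 8, geometry = "extended",
                         sequence = "GGGGGGGG", seed = 1)
  ant <- compute_sasa(read_antigen(text = fx$pdb))
  smap <- build_surface_map(ant, select_surface_residues(ant))
  # I is far from G in property space; pick a tight cutoff
  expect_length(find_seeds("IIII", smap, ant, policy = match_policy(5)), 0L)
})

test_that("seed search equals brute-force path enumeration on random toy
           graphs", {
  for (s in 1:30) {
    g <- random_toy_graph(sample(6:12, 1), seed = 2000 + s)
    mim <- paste(sample(rownames(default_descriptors()), sample(3:5, 1),
                        replace = TRUE), collapse = "")
    cutoff <- sample(c(5, 8, 12), 1)
    seeds <- find_seeds(mim, g$surface_map, g$antigen,
                        policy = match_policy(cutoff))
    ref <- oracle_seeds(mim, g$adj, g$res_aa, cutoff, min_len = 2)
    expect_setequal(vapply(seeds, seed_signature, ""),
                    vapply(ref, seed_signature, ""))
    # per-position PDs agree with the direct formula
    if (length(seeds)) {
      s1 <- seeds[[1]]
      aas <- strsplit(mim, "")[[1]][s1$start:s1$end]
      expect_equal(s1$pd,
                   mapply(function(a, k) oracle_pd(a, g$res_aa[[k]]),
                          aas, s1$path),
                   ignore_attr = TRUE, tolerance = 1e-12)
    }
  }
})

test_that("raising the PD cutoff never removes a seed", {
  for (s in 1:5) {
    g <- random_toy_graph(10, seed = 3000 + s)
    mim <- paste(sample(rownames(default_descriptors()), 4), collapse = "")
    lo <- find_seeds(mim, g$surface_map, g$antigen, match_policy(6))
    hi <- find_seeds(mim, g$surface_map, g$antigen, match_policy(12))
    expect_true(all(vapply(lo, seed_signature, "") %in%
                      vapply(hi, seed_signature, "")))
  }
})

test_that("seed connection honours the inclusive N-to-N bound", {
  mk <- function(dist_nn) {
    # two 2-residue seeds separated by a 2-residue mimotope gap
    keys <- paste0("A:", 1:4)
    nx <- c(0, 1, 1 + dist_nn, 2 + dist_nn)
    residues <- data.frame(key = keys, chain = "A", resno = 1:4,
                           insert = "", resid = "UNK", aa1 = "A",
                           ca_x = nx, ca_y = 0, ca_z = 0,
                           n_x = nx, n_y = 0, n_z = 0,
                           sasa = NA_real_, max_sasa = NA_real_,
                           is_surface = TRUE)
    ant <- structure(list(atoms = NULL, residues = residues,
                          source = "toy"), class = "antigen")
    seeds <- list(
      list(mimotope_id = "m", start = 1L, end = 2L,
           path = c("A:1", "A:2"), pd = c(0, 0)),
      list(mimotope_id = "m", start = 5L, end = 6L,
           path = c("A:3", "A:4"), pd = c(0, 0)))
    connect_seeds(seeds, ant)
  }
  sizes <- function(cl) sort(vapply(cl, function(cn)
    length(cn$seeds), 0L))
  expect_equal(sizes(mk(10.4)), c(1L, 1L, 2L))   # bridged
  expect_equal(sizes(mk(10.5)), c(1L, 1L, 2L))   # inclusive at the bound
  expect_equal(sizes(mk(10.6)), c(1L, 1L))       # beyond the bound
})

test_that("connection enumeration equals the brute-force subset oracle", {
  for (s in 1:30) {
    rs <- random_seed_set(n_seeds = 4, mimo_len = 10,
                          n_res = 14, seed = 4000 + s)
    got <- connect_seeds(rs$seeds, rs$antigen)
    ref <- oracle_connections(rs$seeds, rs$nxyz)
    expect_setequal(vapply(got, function(cn) conn_signature(cn$seeds), ""),
                    vapply(ref, conn_signature, ""))
    # derived quantities are consistent
    for (cn in got) {
      expect_equal(cn$matched_length, length(cn$pd))
      expect_equal(cn$avg_pd, mean(cn$pd))
      expect_false(anyDuplicated(cn$residues) > 0)
    }
  }
})

test_that("a larger nn_step never shrinks the connection set", {
  for (s in 1:5) {
    rs <- random_seed_set(n_seeds = 4, mimo_len = 10, n_res = 14,
                          seed = 5000 + s)
    lo <- connect_seeds(rs$seeds, rs$antigen, nn_step = 3.4)
    hi <- connect_seeds(rs$seeds, rs$antigen, nn_step = 3.8)
    sig <- function(cl) vapply(cl, function(cn)
      conn_signature(cn$seeds), "")
    expect_true(all(sig(lo) %in% sig(hi)))
  }
})

test_that("a missing backbone N skips the candidate with a warning", {
  rs <- random_seed_set(n_seeds = 2, mimo_len = 10, n_res = 14, seed = 99)
  # force non-overlapping spans and a missing N on the second seed's head
  rs$seeds[[1]]$start <- 1L; rs$seeds[[1]]$end <- 2L
  rs$seeds[[2]]$start <- 5L; rs$seeds[[2]]$end <- 6L
  head2 <- rs$seeds[[2]]$path[1]
  rs$antigen$residues$n_x[rs$antigen$residues$key == head2] <- NA
  expect_warning(got <- connect_seeds(rs$seeds, rs$antigen),
                 "missing backbone N")
  expect_true(all(vapply(got, function(cn) length(cn$seeds), 0L) == 1L))
})

test_that("prediction selection applies the two clauses exactly", {
  # single perfect connection: its residues are the prediction
  one <- list(list(mimotope_id = "m1", residues = c("A:1", "A:2"),
                   pd = c(0, 0), matched_length = 2L, avg_pd = 0))
  expect_equal(select_prediction(one)$residues, c("A:1", "A:2"))
  # high-PD short connection contributes nothing
  pool <- c(one, list(list(mimotope_id = "m2", residues = c("A:7", "A:8"),
                           pd = c(2.5, 2.5), matched_length = 2L,
                           avg_pd = 2.5),
                      list(mimotope_id = "m3",
                           residues = c("A:3", "A:4", "A:5"),
                           pd = c(1, 1, 1), matched_length = 3L,
                           avg_pd = 1)))
  expect_equal(select_prediction(pool)$residues,
               c("A:1", "A:2", "A:3", "A:4", "A:5"))
  # empty pool is an empty prediction, not an error
  expect_equal(select_prediction(list())$residues, character(0))
})

test_that("selection equals the filter-then-union oracle on random pools", {
  for (s in 1:30) {
    pool <- random_connection_pool(n_conn = 6, seed = 6000 + s)
    expect_equal(select_prediction(pool)$residues, oracle_select(pool))
  }
})

test_that("inserting a bridgeable gap does not penalise the match", {
  fx <- make_toy_antigen(length = 14, geometry = "extended", seed = 31)
  ant <- compute_sasa(read_antigen(text = fx$pdb))
  smap <- build_surface_map(ant, select_surface_residues(ant))
  epi <- substr(fx$sequence, 3, 10)
  gapped <- paste0(substr(epi, 1, 4), "PP", substr(epi, 5, 8))
  conn_of <- function(mim) {
    seeds <- find_seeds(mim, smap, ant)
    connect_seeds(seeds, ant)
  }
  plain <- conn_of(epi)
  with_gap <- conn_of(gapped)
  best <- function(cl) cl[[which.max(vapply(cl, `[[`, 0L,
                                            "matched_length"))]]
  b1 <- best(plain); b2 <- best(with_gap)
  expect_equal(b2$matched_length, b1$matched_length)
  # matched positions carry the same (zero) penalty-free PDs
  expect_equal(mean(b2$pd), mean(b1$pd))
  expect_setequal(b2$residues, b1$residues)
})

test_that("the full run is deterministic and covers a planted epitope", {
  fx <- make_toy_antigen(length = 27, geometry = "lattice", epitope = 2:8,
                         seed = 41)
  mm <- make_mimotopes(fx$epitope_sequence, n = 4, substitution_rate = 0,
                       seed = 41)
  ant <- compute_sasa(read_antigen(text = fx$pdb))
  fit1 <- mimotree(ant, mm$sequence)
  fit2 <- mimotree(ant, mm$sequence)
  expect_identical(fit1$residues, fit2$residues)
  epi_keys <- fx$annotation$key[fx$annotation$is_epitope]
  expect_true(all(epi_keys %in% fit1$residues))
  # every predicted residue is a surface residue backed by a connection
  expect_true(all(fit1$residues %in% names(fit1$surface_map)))
  backed <- unique(unlist(lapply(fit1$connections, `[[`, "residues")))
  expect_setequal(fit1$residues, intersect(fit1$residues, backed))
})

test_that("an empty mimotope set is rejected and no-match sets give empty
           predictions", {
  fx <- make_toy_antigen(length = 10, geometry = "extended",
                         sequence = "GGGGGGGGGG", seed = 1)
  ant <- compute_sasa(read_antigen(text = fx$pdb))
  expect_error(mimotree(ant, character(0)), "no mimotope")
  fit <- mimotree(ant, "IIII", pd_cutoff = 5)
  expect_length(fit$residues, 0L)
  expect_equal(nrow(fit$prediction), 0L)
})

test_that("near-exact epitope input recovers sensitivity close to the
           fraction of the epitope supplied", {
  fx <- make_toy_antigen(length = 24, geometry = "helical", epitope = 5:16,
                         seed = 51)
  ant <- compute_sasa(read_antigen(text = fx$pdb))
  epi_keys <- fx$annotation$key[fx$annotation$is_epitope]
  # supply the antigen's own linear sequence over half of the epitope
  half <- substr(fx$epitope_sequence, 1, 6)
  fit <- mimotree(ant, half)
  ev <- evaluate_prediction(fit, epi_keys, universe = ant$residues$key)
  expect_gte(ev$sensitivity, 6 / 12)
  expect_lte(ev$sensitivity, 6 / 12 + 0.25)
  # the full epitope sequence reaches full coverage
  fit2 <- mimotree(ant, fx$epitope_sequence)
  ev2 <- evaluate_prediction(fit2, epi_keys, universe = ant$residues$key)
  expect_equal(ev2$sensitivity, 1)
})

test_that("the seed ceiling triggers a hard, advisory error", {
  # complete graph of identical residues: path count explodes
  n <- 9
  keys <- paste0("A:", 1:n)
  adj <- lapply(seq_len(n), function(i) keys[-i])
  names(adj) <- keys
  smap <- structure(adj, class = "surface_map", cutoff = 99, metric = "ca")
  residues <- data.frame(key = keys, chain = "A", resno = 1:n, insert = "",
                         resid = "ALA", aa1 = "A", ca_x = 0, ca_y = 0,
                         ca_z = 0, n_x = 0, n_y = 0, n_z = 0,
                         sasa = NA_real_, max_sasa = NA_real_,
                         is_surface = TRUE)
  ant <- structure(list(atoms = NULL, residues = residues, source = "toy"),
                   class = "antigen")
  expect_error(find_seeds("AAAAAAAA", smap, ant, max_seeds = 500),
               "pd_cutoff")
})
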