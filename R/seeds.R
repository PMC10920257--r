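## Seed discovery and seed connection.
##
## A seed is a contiguous stretch of a mimotope matched residue-by-residue
## (PD at or below the cutoff) onto a simple path of adjacent antigen surface
## residues.  Seeds are joined in mimotope sequence order into "seed
## connections" when each intervening mimotope gap, assumed fully extended at
## 3.5 Angstrom per residue (N-to-N), can physically span the 3D distance
## between the flanking matched residues.

#' Maximum surface span bridgeable by a mimotope gap
#'
#' Under the extended-linear model a gap of `gap_len` unmatched mimotope
#' residues can bridge at most `(gap_len + 1) * nn_step` Angstrom between the
#' backbone N atoms of the flanking matched residues. For the worked
#' seven-residue example with a two-residue gap this bound is
#' 3 * 3.5 = 10.5 Angstrom.
#'
#' @param gap_len Number of unmatched mimotope residues in the gap
#'   (non-negative integer; 0 means the seeds abut in the mimotope).
#' @param nn_step Extended-chain N-to-N distance per residue in Angstrom
#'   (default 3.5).
#' @return The maximum bridgeable N-to-N distance in Angstrom.
#' @export
#' @examples
#' gap_span_limit(2)      # 10.5
#' gap_span_limit(0)      # 3.5: abutting seeds must be within one step
gap_span_limit <- function(gap_len, nn_step = 3.5) {
  if (any(gap_len < 0)) stop("gap_len must be non-negative")
  stopifnot(nn_step > 0)
  (gap_len + 1) * nn_step
}

#' Find all mimotope seeds on the antigen surface
#'
#' Depth-first search from every mimotope position: every simple path on the
#' surface adjacency map whose residues match (PD <= cutoff) a contiguous
#' mimotope substring of length at least `min_seed_len` is reported as a
#' seed. Non-standard antigen residues never match. The search is exhaustive
#' and deterministic; a configurable ceiling guards against combinatorial
#' blow-up.
#'
#' @param mimotope One-letter amino-acid string (or a list with `id` and
#'   `sequence`).
#' @param surface_map A [build_surface_map()] result.
#' @param structure The `antigen` the map was built from.
#' @param policy A [match_policy()] or numeric PD cutoff (default 8).
#' @param min_seed_len Minimum matched length of a seed (default 2).
#' @param table Descriptor table ([default_descriptors()]).
#' @param max_seeds Ceiling on seeds discovered per mimotope start position;
#'   exceeding it is an error suggesting a lower PD cutoff.
#' @return List of seeds; each seed is a list with `mimotope_id`, `start`,
#'   `end` (1-based inclusive mimotope span), `path` (antigen residue keys)
#'   and `pd` (per-position property distances).
#' @export
find_seeds <- function(mimotope, surface_map, structure,
                       policy = match_policy(), min_seed_len = 2,
                       table = default_descriptors(), max_seeds = 1e5) {
  if (is.list(mimotope)) {
    mid <- mimotope$id
    seqc <- mimotope$sequence
  } else {
    mid <- mimotope
    seqc <- mimotope
  }
  if (is.numeric(policy)) policy <- match_policy(policy)
  stopifnot(is.character(seqc), length(seqc) == 1L, nchar(seqc) >= 2)
  aas <- strsplit(toupper(seqc), "")[[1]]
  .check_aa(aas, table)
  L <- length(aas)
  keys <- names(surface_map)
  res <- structure$residues
  surf_aa <- res$aa1[match(keys, res$key)]
  ok <- !is.na(surf_aa)
  if (!all(ok)) {
    warning("non-standard surface residue(s) never match: ",
            paste(keys[!ok], collapse = ", "))
    keys <- keys[ok]
    surf_aa <- surf_aa[ok]
  }
  if (!length(keys)) return(list())
  # PD of every mimotope position against every surface residue type
  pdm <- pd_matrix(table)
  pd_pos <- pdm[aas, , drop = FALSE]            # L x 20
  # allowed[[p]]: named pd vector over surface keys matching position p
  allowed <- lapply(seq_len(L), function(p) {
    v <- pd_pos[p, surf_aa]
    names(v) <- keys
    v[v <= policy$pd_cutoff]
  })
  seeds <- list()
  count <- 0L
  record <- function(start, path, pd) {
    count <<- count + 1L
    if (count > max_seeds)
      stop("seed ceiling (", max_seeds, ") exceeded for mimotope '", mid,
           "'; consider a lower pd_cutoff", call. = FALSE)
    seeds[[length(seeds) + 1L]] <<- list(
      mimotope_id = mid, start = start, end = start + length(path) - 1L,
      path = path, pd = pd)
  }
  dfs <- function(start, pos, path, pd) {
    if (length(path) >= min_seed_len) record(start, path, pd)
    if (pos > L) return()
    nxt <- allowed[[pos]]
    cand <- intersect(surface_map[[path[length(path)]]], names(nxt))
    cand <- setdiff(cand, path)
    for (k in cand)
      dfs(start, pos + 1L, c(path, k), c(pd, unname(nxt[k])))
  }
  for (start in seq_len(L)) {
    if (L - start + 1L < min_seed_len) break
    first <- allowed[[start]]
    count <- 0L
    for (k in names(first))
      dfs(start, start + 1L, k, unname(first[k]))
  }
  seeds
}

.seed_matched_len <- function(s) length(s$path)

#' Connect seeds of one mimotope into seed connections
#'
#' Depth-first enumeration of all ordered chains of one or more seeds with
#' strictly increasing, non-overlapping mimotope spans, pairwise-distinct
#' antigen residues, and, for every consecutive pair, a backbone N-to-N
#' distance between the last residue of the earlier seed and the first
#' residue of the later seed no greater than [gap_span_limit()] of the
#' mimotope gap between them (inclusive at the bound).
#'
#' @param seeds Seeds of a single mimotope, from [find_seeds()].
#' @param structure The `antigen` (supplies backbone N coordinates).
#' @param nn_step Extended-chain per-residue step in Angstrom (default 3.5).
#' @param max_connections Ceiling on enumerated connections (error beyond).
#' @return List of connections; each has `mimotope_id`, `seeds` (list of
#'   member seeds), `residues` (ordered antigen keys, gaps contribute none),
#'   `pd` (per matched position), `matched_length` and `avg_pd`. Candidate
#'   joins whose terminal residue lacks an N atom are skipped with a warning.
#' @export
connect_seeds <- function(seeds, structure, nn_step = 3.5,
                          max_connections = 2e5) {
  if (!length(seeds)) return(list())
  ids <- unique(vapply(seeds, `[[`, "", "mimotope_id"))
  if (length(ids) != 1L)
    stop("connect_seeds() expects seeds from a single mimotope")
  res <- structure$residues
  nxyz <- as.matrix(res[, c("n_x", "n_y", "n_z")])
  rownames(nxyz) <- res$key
  ord <- order(vapply(seeds, `[[`, 1L, "start"),
               vapply(seeds, `[[`, 1L, "end"))
  seeds <- seeds[ord]
  starts <- vapply(seeds, `[[`, 1L, "start")
  ends <- vapply(seeds, `[[`, 1L, "end")
  heads <- vapply(seeds, function(s) s$path[1L], "")
  tails <- vapply(seeds, function(s) s$path[length(s$path)], "")
  n <- length(seeds)
  missing_n <- character(0)
  nn_ok <- function(i, j) {
    # may seed j follow seed i?
    if (starts[j] <= ends[i]) return(FALSE)
    a <- nxyz[tails[i], ]
    b <- nxyz[heads[j], ]
    if (anyNA(a) || anyNA(b)) {
      missing_n <<- c(missing_n,
                      if (anyNA(a)) tails[i] else heads[j])
      return(NA)
    }
    gap <- starts[j] - ends[i] - 1L
    sqrt(sum((a - b)^2)) <= gap_span_limit(gap, nn_step)
  }
  out <- list()
  emit <- function(chain_idx) {
    if (length(out) >= max_connections)
      stop("connection ceiling (", max_connections, ") exceeded for ",
           "mimotope '", ids, "'; consider a lower pd_cutoff", call. = FALSE)
    mem <- seeds[chain_idx]
    pd <- unlist(lapply(mem, `[[`, "pd"), use.names = FALSE)
    out[[length(out) + 1L]] <<- list(
      mimotope_id = ids, seeds = mem,
      residues = unlist(lapply(mem, `[[`, "path"), use.names = FALSE),
      pd = pd, matched_length = length(pd), avg_pd = mean(pd))
  }
  extend <- function(chain_idx, used) {
    emit(chain_idx)
    last <- chain_idx[length(chain_idx)]
    for (j in seq_len(n)) {
      if (starts[j] <= ends[last]) next
      if (any(seeds[[j]]$path %in% used)) next
      okj <- nn_ok(last, j)
      if (is.na(okj) || !okj) next
      extend(c(chain_idx, j), c(used, seeds[[j]]$path))
    }
  }
  for (i in seq_len(n)) extend(i, seeds[[i]]$path)
  if (length(missing_n))
    warning("skipped connection candidate(s): missing backbone N atom on ",
            paste(unique(missing_n), collapse = ", "))
  out
}

#' Select the final prediction from the pool of seed connections
#'
#' The prediction is the union of matched antigen residues over (i) all seed
#' connections with average PD exactly 0 (perfect physicochemical matches,
#' every per-position PD zero) and (ii) seed connections whose matched
#' length equals the overall maximum across the whole mimotope set, with
#' average PD greater than 0 and at most `avg_pd_max` (default 2). Gap
#' positions contribute no residues.
#'
#' @param connections Seed connections pooled over all mimotopes.
#' @param avg_pd_max Upper bound on the average PD of clause-(ii)
#'   connections.
#' @return List with `residues` (sorted unique antigen keys), `selected`
#'   (the contributing connections) and `max_matched_length`.
#' @export
select_prediction <- function(connections, avg_pd_max = 2.0) {
  if (!length(connections))
    return(list(residues = character(0), selected = list(),
                max_matched_length = 0L))
  ml <- vapply(connections, `[[`, 1L, "matched_length")
  gmax <- max(ml)
  perfect <- vapply(connections, function(cn) all(cn$pd == 0), NA)
  near <- ml == gmax &
    vapply(connections, function(cn) {
      a <- cn$avg_pd; a > 0 && a <= avg_pd_max
    }, NA)
  sel <- connections[perfect | near]
  resid <- sort(unique(unlist(lapply(sel, `[[`, "residues"),
                              use.names = FALSE)))
  list(residues = resid, selected = sel, max_matched_length = gmax)
}
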