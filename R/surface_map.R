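## Surface adjacency map: each surface residue keyed to the list of surface
## residues adjacent to it in 3D.

#' Build the surface adjacency map
#'
#' Two surface residues are adjacent when the distance between their
#' reference atoms is at most `cutoff` (default 4 Angstrom, alpha-carbon to
#' alpha-carbon). With `metric = "any-atom"`, adjacency holds when any pair
#' of heavy atoms of the two residues lies within the cutoff.
#'
#' @param structure An `antigen` object.
#' @param surface_ids Character vector of surface residue keys, e.g. from
#'   [select_surface_residues()].
#' @param cutoff Adjacency distance cutoff in Angstrom (inclusive).
#' @param metric `"ca"` (alpha-carbon pairs, the default) or `"any-atom"`.
#' @return A named list of class `surface_map`: for each surface residue key,
#'   the character vector of adjacent surface residue keys. Symmetric and
#'   irreflexive. Residues lacking the reference atom are dropped with a
#'   warning.
#' @export
build_surface_map <- function(structure, surface_ids, cutoff = 4.0,
                              metric = c("ca", "any-atom")) {
  metric <- match.arg(metric)
  stopifnot(inherits(structure, "antigen"), cutoff > 0)
  res <- structure$residues
  # only standard, matchable residues participate in the map
  surface_ids <- surface_ids[surface_ids %in% res$key[!is.na(res$aa1)]]
  if (metric == "ca") {
    r <- res[match(surface_ids, res$key), , drop = FALSE]
    has <- !is.na(r$ca_x)
    if (any(!has))
      warning("dropping ", sum(!has),
              " surface residue(s) without an alpha-carbon")
    r <- r[has, , drop = FALSE]
    keys <- r$key
    if (length(keys) < 2L) {
      adj <- stats::setNames(replicate(length(keys), character(0),
                                       simplify = FALSE), keys)
    } else {
      d <- as.matrix(stats::dist(cbind(r$ca_x, r$ca_y, r$ca_z)))
      adj <- lapply(seq_along(keys), function(i)
        keys[d[i, ] <= cutoff & seq_along(keys) != i])
      names(adj) <- keys
    }
  } else {
    at <- structure$atoms[structure$atoms$key %in% surface_ids, , drop = FALSE]
    keys <- surface_ids[surface_ids %in% at$key]
    if (length(keys) < 2L) {
      adj <- stats::setNames(replicate(length(keys), character(0),
                                       simplify = FALSE), keys)
    } else {
      d <- as.matrix(stats::dist(cbind(at$x, at$y, at$z)))
      close <- d <= cutoff
      ridx <- match(at$key, keys)
      adj <- lapply(seq_along(keys), function(i) {
        ai <- which(ridx == i)
        hit <- unique(ridx[which(.col_any(close[ai, , drop = FALSE]))])
        keys[setdiff(hit, i)]
      })
      names(adj) <- keys
    }
  }
  structure(adj, class = "surface_map", cutoff = cutoff, metric = metric)
}

# column-wise any() without extra dependencies
.col_any <- function(m) {
  if (nrow(m) == 1L) m[1L, ] else colSums(m) > 0L
}

#' @export
print.surface_map <- function(x, ...) {
  deg <- lengths(x)
  cat("Surface map: ", length(x), " residues, ",
      sum(deg) / 2, " edges (", attr(x, "metric"), " <= ",
      attr(x, "cutoff"), " A)\n", sep = "")
  invisible(x)
}
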