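## The top-level predictor: surface map -> seeds -> connections -> selection.

#' Read a mimotope set
#'
#' Accepts plain text (one peptide per line, `#` comments allowed) or FASTA.
#' Sequences are upper-cased and validated against the 20-letter amino-acid
#' alphabet; peptides shorter than two residues or with non-standard letters
#' are rejected. Duplicate sequences are removed with a message (the
#' algorithm is frequency-blind).
#'
#' @param file Path to the mimotope file.
#' @param text Optional character vector of sequences given directly.
#' @return Data frame with columns `id` and `sequence`.
#' @export
read_mimotopes <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    lines <- readLines(file)
    if (any(grepl("^>", lines))) {
      fa <- bio3d::read.fasta(file)
      seqs <- toupper(apply(fa$ali, 1, function(r)
        paste(r[r != "-" & !is.na(r)], collapse = "")))
      ids <- rownames(fa$ali)
    } else {
      seqs <- toupper(trimws(lines))
      keep <- nzchar(seqs) & !grepl("^#", seqs)
      seqs <- seqs[keep]
      ids <- paste0("m", seq_along(seqs))
    }
  } else {
    seqs <- toupper(text)
    ids <- if (!is.null(names(text))) names(text) else
      paste0("m", seq_along(seqs))
  }
  if (!length(seqs)) stop("no mimotope sequences found")
  bad <- nchar(seqs) < 2 | grepl(paste0("[^", paste(.aa1, collapse = ""), "]"),
                                 seqs)
  if (any(bad))
    stop("invalid mimotope sequence(s): ",
         paste(seqs[bad], collapse = ", "),
         " (length >= 2, standard one-letter codes only)")
  dup <- duplicated(seqs)
  if (any(dup)) {
    message("removed ", sum(dup), " duplicate mimotope sequence(s)")
    seqs <- seqs[!dup]
    ids <- ids[!dup]
  }
  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

#' Predict an epitope from mimotopes and an antigen structure
#'
#' Runs the full mapping pipeline: per-residue SASA (Shrake-Rupley, probe
#' 1.4 Angstrom), surface-residue selection (SASA > 5% of the extended
#' Gly-X-Gly maximum), surface adjacency map (reference-atom distance <= 4
#' Angstrom), exhaustive depth-first seed search under the property-distance
#' cutoff, geometric seed connection (extended-chain gap bridging at 3.5
#' Angstrom per residue, N-to-N), and final selection (union of perfect-match
#' connections and longest near-match connections with average PD <= 2).
#' Fully deterministic.
#'
#' @param pdb Path to the antigen PDB file, or an `antigen` object from
#'   [read_antigen()].
#' @param mimotopes Character vector of peptide sequences, a path to a
#'   mimotope file, or a data frame from [read_mimotopes()].
#' @param chains Optional chain filter (when `pdb` is a path).
#' @param pd_cutoff Property-distance cutoff treating two amino acids as
#'   identical (default 8).
#' @param adjacency Surface-map adjacency cutoff in Angstrom (default 4).
#' @param adjacency_metric `"ca"` or `"any-atom"` (see
#'   [build_surface_map()]).
#' @param nn_step Extended-chain N-to-N step per gap residue in Angstrom
#'   (default 3.5).
#' @param avg_pd_max Average-PD bound for longest near-match connections
#'   (default 2).
#' @param surface_fraction Surface-exposure threshold (default 0.05).
#' @param min_seed_len Minimum seed length (default 2).
#' @param probe_radius SASA probe radius in Angstrom (default 1.4).
#' @param n_points SASA sphere points per atom (default 960).
#' @param descriptors Descriptor table ([default_descriptors()]).
#' @param max_seeds,max_connections Enumeration ceilings, see
#'   [find_seeds()] and [connect_seeds()].
#' @return An object of class `mimotree`: list with `prediction` (residue
#'   data frame: key, chain, seqnum, icode, name3, n_mimotopes, mimotopes),
#'   `residues` (predicted keys), `connections` (selected connections),
#'   `n_seeds` and `n_connections` per mimotope, `antigen` (with SASA and
#'   surface flags filled), `surface_map`, `params`.
#' @export
#' @examples
#' fx <- make_toy_antigen(length = 20, geometry = "extended",
#'                        epitope = 6:12, seed = 7)
#' mm <- make_mimotopes(fx$epitope_sequence, n = 3, substitution_rate = 0,
#'                      seed = 7)
#' fit <- mimotree(read_antigen(text = fx$pdb), mm$sequence)
#' fit
mimotree <- function(pdb, mimotopes, chains = NULL,
                     pd_cutoff = 8, adjacency = 4.0,
                     adjacency_metric = c("ca", "any-atom"),
                     nn_step = 3.5, avg_pd_max = 2.0,
                     surface_fraction = 0.05, min_seed_len = 2,
                     probe_radius = 1.4, n_points = 960,
                     descriptors = default_descriptors(),
                     max_seeds = 1e5, max_connections = 2e5) {
  adjacency_metric <- match.arg(adjacency_metric)
  params <- list(pd_cutoff = pd_cutoff, adjacency = adjacency,
                 adjacency_metric = adjacency_metric, nn_step = nn_step,
                 avg_pd_max = avg_pd_max, surface_fraction = surface_fraction,
                 min_seed_len = min_seed_len, probe_radius = probe_radius,
                 n_points = n_points)
  ant <- if (inherits(pdb, "antigen")) pdb else
    read_antigen(pdb, chains = chains)
  if (is.character(mimotopes) && length(mimotopes) == 1L &&
      file.exists(mimotopes)) {
    mims <- read_mimotopes(mimotopes)
  } else if (is.data.frame(mimotopes)) {
    mims <- read_mimotopes(text = stats::setNames(mimotopes$sequence,
                                                  mimotopes$id))
  } else {
    mims <- read_mimotopes(text = mimotopes)
  }
  if (all(is.na(ant$residues$sasa)))
    ant <- compute_sasa(ant, probe_radius = probe_radius,
                        n_points = n_points)
  surf <- select_surface_residues(ant, fraction = surface_fraction)
  ant$residues$is_surface <- ant$residues$key %in% surf
  smap <- build_surface_map(ant, surf, cutoff = adjacency,
                            metric = adjacency_metric)
  policy <- match_policy(pd_cutoff)
  all_conn <- list()
  n_seeds <- n_conn <- integer(nrow(mims))
  for (i in seq_len(nrow(mims))) {
    sds <- find_seeds(list(id = mims$id[i], sequence = mims$sequence[i]),
                      smap, ant, policy = policy,
                      min_seed_len = min_seed_len, table = descriptors,
                      max_seeds = max_seeds)
    cns <- connect_seeds(sds, ant, nn_step = nn_step,
                         max_connections = max_connections)
    n_seeds[i] <- length(sds)
    n_conn[i] <- length(cns)
    all_conn <- c(all_conn, cns)
  }
  sel <- select_prediction(all_conn, avg_pd_max = avg_pd_max)
  res <- ant$residues
  pred <- res[match(sel$residues, res$key),
              c("key", "chain", "resno", "insert", "resid")]
  names(pred) <- c("key", "chain", "seqnum", "icode", "name3")
  rownames(pred) <- NULL
  prov <- lapply(sel$residues, function(k) {
    unique(vapply(sel$selected[vapply(sel$selected,
                                      function(cn) k %in% cn$residues, NA)],
                  `[[`, "", "mimotope_id"))
  })
  pred$n_mimotopes <- lengths(prov)
  pred$mimotopes <- vapply(prov, paste, "", collapse = ",")
  structure(list(prediction = pred, residues = sel$residues,
                 connections = sel$selected,
                 max_matched_length = sel$max_matched_length,
                 n_seeds = stats::setNames(n_seeds, mims$id),
                 n_connections = stats::setNames(n_conn, mims$id),
                 mimotopes = mims, antigen = ant, surface_map = smap,
                 params = params),
            class = "mimotree")
}

#' @export
print.mimotree <- function(x, ...) {
  cat("MimoTree epitope prediction\n")
  cat("  mimotopes: ", nrow(x$mimotopes), "   surface residues: ",
      length(x$surface_map), " / ", nrow(x$antigen$residues), "\n", sep = "")
  cat("  seeds: ", sum(x$n_seeds), "   connections: ",
      sum(x$n_connections), " (longest matched length ",
      x$max_matched_length, ")\n", sep = "")
  cat("  predicted residues: ", length(x$residues), "\n", sep = "")
  if (length(x$residues))
    cat("  ", paste(utils::head(x$residues, 12), collapse = " "),
        if (length(x$residues) > 12) " ...", "\n", sep = "")
  invisible(x)
}

#' @export
summary.mimotree <- function(object, ...) {
  n_res <- nrow(object$antigen$residues)
  out <- list(
    n_mimotopes = nrow(object$mimotopes),
    n_surface = length(object$surface_map),
    n_residues = n_res,
    n_seeds = object$n_seeds,
    n_connections = object$n_connections,
    max_matched_length = object$max_matched_length,
    size = length(object$residues),
    density = length(object$residues) / n_res,
    params = object$params,
    prediction = object$prediction)
  class(out) <- "summary.mimotree"
  out
}

#' @export
print.summary.mimotree <- function(x, ...) {
  cat("MimoTree prediction summary\n")
  cat(sprintf("  antigen residues: %d (%d surface)\n",
              x$n_residues, x$n_surface))
  cat(sprintf("  mimotopes: %d, seeds: %d, connections: %d\n",
              x$n_mimotopes, sum(x$n_seeds), sum(x$n_connections)))
  cat(sprintf("  longest matched length: %d\n", x$max_matched_length))
  cat(sprintf("  prediction size: %d residues (density %.1f%%)\n",
              x$size, 100 * x$density))
  cat("  parameters: ",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      "\n", sep = "")
  if (x$size) {
    cat("\n")
    print(utils::head(x$prediction[, c("chain", "seqnum", "icode", "name3",
                                       "n_mimotopes")], 20))
    if (x$size > 20) cat("  ... ", x$size - 20, " more rows\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.mimotree <- function(x, ...) x$prediction

#' Plot a MimoTree prediction
#'
#' Per-residue relative solvent exposure (SASA / maximal SASA) along the
#' chain, with surface residues marked and predicted epitope residues
#' highlighted.
#'
#' @param x A `mimotree` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mimotree <- function(x, ...) {
  res <- x$antigen$residues
  rel <- res$sasa / res$max_sasa
  idx <- seq_len(nrow(res))
  pred <- res$key %in% x$residues
  graphics::plot(idx, rel, type = "h", col = "grey70",
                 xlab = "residue index (file order)",
                 ylab = "SASA / max SASA", ...)
  graphics::abline(h = x$params$surface_fraction, lty = 2, col = "grey40")
  graphics::points(idx[pred], rel[pred], pch = 19, col = "firebrick")
  graphics::legend("topright", bty = "n", pch = c(NA, 19),
                   lty = c(2, NA), col = c("grey40", "firebrick"),
                   legend = c("surface threshold", "predicted epitope"))
  invisible(x)
}

#' Write a prediction to the shared residue TSV dialect
#'
#' Columns: chain, seqnum, icode, name3 (tab-separated). The same dialect is
#' read back by [read_prediction_tsv()] and used for ensemble combination
#' and evaluation.
#'
#' @param x A `mimotree` fit, a prediction data frame, or a character vector
#'   of residue keys.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prediction_tsv <- function(x, path) {
  df <- if (inherits(x, "mimotree")) x$prediction
        else if (is.data.frame(x)) x
        else data.frame(key = x)
  if (!"chain" %in% names(df)) {
    parts <- .split_key(df$key)
    df <- data.frame(chain = parts$chain, seqnum = parts$seqnum,
                     icode = parts$icode, name3 = "UNK")
  }
  utils::write.table(df[, c("chain", "seqnum", "icode", "name3")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.split_key <- function(key) {
  chain <- sub(":.*$", "", key)
  rest <- sub("^[^:]*:", "", key)
  seqnum <- as.integer(sub("^(-?[0-9]+).*$", "\\1", rest))
  icode <- sub("^-?[0-9]+", "", rest)
  list(chain = chain, seqnum = seqnum, icode = icode)
}

#' Read a residue-level prediction TSV
#'
#' @param path TSV with columns chain, seqnum, icode (may be empty), name3.
#' @param method Optional method label attached to the result.
#' @return Data frame with the four columns plus `key`.
#' @export
read_prediction_tsv <- function(path, method = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(icode = "character"))
  need <- c("chain", "seqnum", "icode", "name3")
  if (!all(need %in% names(df)))
    stop("prediction TSV needs columns: ", paste(need, collapse = ", "))
  df$icode[is.na(df$icode)] <- ""
  df$key <- .residue_key(df$chain, df$seqnum,
                         ifelse(df$icode == "", NA, df$icode))
  attr(df, "method") <- method
  df
}
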