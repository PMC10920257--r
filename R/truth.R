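## True-epitope extraction from an antigen-antibody complex: an antigen
## residue belongs to the epitope when it loses more than 10 Angstrom^2 of
## solvent-accessible surface area upon antibody binding.  Both SASA passes
## use the complex coordinates (no relaxation); waters and non-polymer
## ligands are stripped at parse time.

#' Extract the true epitope from an antigen-antibody complex
#'
#' Per antigen residue, delta-SASA = SASA(antigen chains alone, complex
#' coordinates) - SASA(full complex); residues with delta-SASA strictly
#' greater than `threshold` (default 10 Angstrom^2) form the epitope.
#'
#' @param pdb Path to the complex PDB file (or an `antigen` object holding
#'   the full complex).
#' @param antigen_chains,antibody_chains Disjoint, non-empty chain ID sets.
#' @param threshold Burial threshold in Angstrom^2 (strict inequality).
#' @param probe_radius,n_points SASA parameters, see [compute_sasa()].
#' @param text Optional PDB text instead of a path.
#' @return Object of class `true_epitope`: data frame of epitope residues
#'   (key, chain, seqnum, icode, name3, delta_sasa) with attributes
#'   `universe` (all antigen-chain residue keys), `delta_sasa` (named,
#'   all antigen residues) and `threshold`.
#' @export
true_epitope <- function(pdb, antigen_chains, antibody_chains,
                         threshold = 10, probe_radius = 1.4, n_points = 960,
                         text = NULL) {
  if (!length(antigen_chains) || !length(antibody_chains))
    stop("antigen_chains and antibody_chains must both be non-empty")
  if (length(intersect(antigen_chains, antibody_chains)))
    stop("antigen and antibody chain sets overlap: ",
         paste(intersect(antigen_chains, antibody_chains), collapse = ", "))
  cx <- if (inherits(pdb, "antigen")) pdb else
    read_antigen(pdb, text = text)
  avail <- unique(cx$atoms$chain)
  miss <- setdiff(c(antigen_chains, antibody_chains), avail)
  if (length(miss))
    stop("chain(s) not found: ", paste(miss, collapse = ", "),
         " (available: ", paste(avail, collapse = ", "), ")")
  # antigen alone, complex coordinates
  ag <- cx
  ag$atoms <- cx$atoms[cx$atoms$chain %in% antigen_chains, , drop = FALSE]
  ag$residues <- cx$residues[cx$residues$chain %in% antigen_chains, ,
                             drop = FALSE]
  ag <- compute_sasa(ag, probe_radius = probe_radius, n_points = n_points)
  cxs <- compute_sasa(cx, probe_radius = probe_radius, n_points = n_points)
  free <- ag$residues$sasa
  names(free) <- ag$residues$key
  bound <- cxs$residues$sasa
  names(bound) <- cxs$residues$key
  delta <- free - bound[names(free)]
  epi <- names(delta)[delta > threshold]
  res <- ag$residues[match(epi, ag$residues$key),
                     c("key", "chain", "resno", "insert", "resid")]
  names(res) <- c("key", "chain", "seqnum", "icode", "name3")
  res$delta_sasa <- unname(delta[epi])
  rownames(res) <- NULL
  structure(res, class = c("true_epitope", "data.frame"),
            universe = ag$residues$key, delta_sasa = delta,
            threshold = threshold)
}

#' @export
print.true_epitope <- function(x, ...) {
  cat("True epitope (delta-SASA > ", attr(x, "threshold"), " A^2): ",
      nrow(x), " of ", length(attr(x, "universe")),
      " antigen residues\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a true epitope to TSV
#'
#' Same residue dialect as predictions, plus a `delta_sasa` column.
#'
#' @param x A [true_epitope()] result.
#' @param path Output path.
#' @export
write_epitope_tsv <- function(x, path) {
  out <- as.data.frame(x)[, c("chain", "seqnum", "icode", "name3",
                              "delta_sasa")]
  out$delta_sasa <- round(out$delta_sasa, 3)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
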