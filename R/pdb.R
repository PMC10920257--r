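## PDB ingestion (via bio3d) and the residue table the algorithm works on.
##
## Conventions: first model only; highest-occupancy altloc retained; waters
## and non-polymer HETATM ligands dropped; MSE treated as MET; other
## non-standard polymer residues kept as SASA obstacles but never matched;
## residue numbering preserved exactly as in the source file.

.water_names <- c("HOH", "WAT", "DOD", "H2O")

.residue_key <- function(chain, resno, insert) {
  ic <- ifelse(is.na(insert) | insert == " ", "", insert)
  ch <- ifelse(is.na(chain) | chain == " ", "_", chain)
  paste0(ch, ":", resno, ic)
}

.aa321 <- function(resid) {
  resid[resid == "MSE"] <- "MET"
  out <- vapply(resid, function(r) {
    a <- bio3d::aa321(r)
    if (is.na(a) || !a %in% .aa1) NA_character_ else a
  }, character(1))
  unname(out)
}

#' Read an antigen structure from a PDB file
#'
#' Parses ATOM records (plus selenomethionine HETATM records) of the first
#' model into an `antigen` object: an atom table used for SASA and a
#' per-residue table (one row per polymer residue, file order) used by the
#' mapping algorithm. Waters and non-polymer HETATM ligands are excluded.
#' When one atom carries alternate locations, the highest-occupancy altloc is
#' kept (ties resolved by file order). Hydrogens are dropped.
#'
#' @param file Path to a PDB file.
#' @param chains Optional character vector restricting to these chain
#'   identifiers; an error lists the available chains when one is missing.
#' @param text Optional PDB text given directly instead of `file`.
#' @return An object of class `antigen`: a list with `atoms` (data frame:
#'   key, chain, resno, insert, resid, elety, element, x, y, z, sasa),
#'   `residues` (data frame: key, chain, resno, insert, resid, aa1,
#'   ca_x/ca_y/ca_z, n_x/n_y/n_z, sasa, max_sasa, is_surface) and `source`.
#' @export
#' @examples
#' fx <- make_toy_antigen(length = 6, geometry = "extended", seed = 1)
#' ant <- read_antigen(text = fx$pdb)
#' ant
read_antigen <- function(file = NULL, chains = NULL, text = NULL) {
  if (is.null(file) && is.null(text))
    stop("supply either 'file' or 'text'")
  if (!is.null(text)) {
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file), add = TRUE)
    writeLines(text, file)
    src <- "<text>"
  } else {
    src <- file
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse PDB input: ", conditionMessage(e),
                             call. = FALSE))
  at <- pdb$atom
  # polymer atoms: ATOM records plus MSE; drop waters and other ligands
  keep <- (at$type == "ATOM" | at$resid == "MSE") & !at$resid %in% .water_names
  at <- at[keep, , drop = FALSE]
  # hydrogens out
  el <- .element_of(at$elety, at$elesy)
  at <- at[el != "H", , drop = FALSE]
  if (nrow(at) == 0L) stop("no polymer atoms found in PDB input")
  at$chain[is.na(at$chain)] <- "_"
  if (!is.null(chains)) {
    avail <- unique(at$chain)
    miss <- setdiff(chains, avail)
    if (length(miss))
      stop("chain(s) not found: ", paste(miss, collapse = ", "),
           " (available: ", paste(avail, collapse = ", "), ")",
           call. = FALSE)
    at <- at[at$chain %in% chains, , drop = FALSE]
  }
  # highest-occupancy altloc per (chain, resno, insert, elety)
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    grp <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
                 at$elety, sep = "\r")
    ord <- order(grp, -occ, seq_len(nrow(at)))
    at2 <- at[ord, , drop = FALSE]
    at <- at2[!duplicated(paste(at2$chain, at2$resno,
                                ifelse(is.na(at2$insert), "", at2$insert),
                                at2$elety, sep = "\r")), , drop = FALSE]
    at <- at[order(as.numeric(rownames(at))), , drop = FALSE]
  }
  key <- .residue_key(at$chain, at$resno, at$insert)
  atoms <- data.frame(
    key = key, chain = at$chain, resno = at$resno,
    insert = ifelse(is.na(at$insert) | at$insert == " ", "", at$insert),
    resid = at$resid, elety = at$elety,
    element = .element_of(at$elety, at$elesy),
    x = at$x, y = at$y, z = at$z, sasa = NA_real_,
    stringsAsFactors = FALSE)
  ridx <- !duplicated(atoms$key)
  res <- atoms[ridx, c("key", "chain", "resno", "insert", "resid")]
  rownames(res) <- NULL
  res$aa1 <- .aa321(res$resid)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  nn <- atoms[atoms$elety == "N", , drop = FALSE]
  mca <- match(res$key, ca$key)
  mn <- match(res$key, nn$key)
  res$ca_x <- ca$x[mca]; res$ca_y <- ca$y[mca]; res$ca_z <- ca$z[mca]
  res$n_x <- nn$x[mn];  res$n_y <- nn$y[mn];  res$n_z <- nn$z[mn]
  res$sasa <- NA_real_
  res$max_sasa <- unname(.max_sasa_gxg[res$resid])
  res$is_surface <- NA
  if (anyDuplicated(res$key))
    stop("duplicate residue identifiers (chain, seqnum, icode) in input")
  structure(list(atoms = atoms, residues = res, source = src),
            class = "antigen")
}

#' @export
print.antigen <- function(x, ...) {
  res <- x$residues
  cat("Antigen structure (", x$source, ")\n", sep = "")
  cat("  ", nrow(res), " residues in ", length(unique(res$chain)),
      " chain(s): ", paste(unique(res$chain), collapse = ", "), "\n", sep = "")
  cat("  ", nrow(x$atoms), " heavy atoms\n", sep = "")
  if (!all(is.na(res$sasa))) {
    ns <- sum(res$is_surface, na.rm = TRUE)
    cat("  SASA computed",
        if (!any(is.na(res$is_surface)))
          paste0("; ", ns, " surface residues"), "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.antigen <- function(x, ...) x$residues

#' Write the per-residue surface report
#'
#' TSV with columns chain, seqnum, icode, name3, sasa, max_sasa, is_surface.
#'
#' @param structure An `antigen` with SASA computed and surface flagged.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surface_tsv <- function(structure, path) {
  res <- structure$residues
  out <- data.frame(chain = res$chain, seqnum = res$resno,
                    icode = res$insert, name3 = res$resid,
                    sasa = round(res$sasa, 3), max_sasa = res$max_sasa,
                    is_surface = res$is_surface)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
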