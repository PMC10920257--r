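## Deterministic synthetic fixtures: toy antigen backbones with planted
## surface epitopes, and mimotope sets derived from the epitope sequence by
## PD-bounded substitutions and inserted gap stretches.  These emulate the
## "near exact mimotope" validation idea: peptides similar but not identical
## to the true epitope, with spacer residues that must be bridged on the
## antigen surface.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# backbone (N, CA, C, O) offsets relative to each CA position; chosen so
# atoms of one residue stay within ~1.6 A of the CA and chains built at
# ~3.8 A CA spacing have sensible N-to-N spacing
.bb_offsets <- matrix(c(
  -1.20,  0.80, 0.00,   # N
   0.00,  0.00, 0.00,   # CA
   1.10,  0.70, 0.00,   # C
   1.30,  1.90, 0.00),  # O
  ncol = 3, byrow = TRUE, dimnames = list(c("N", "CA", "C", "O"), NULL))

.ca_trace <- function(n, geometry, spacing = 3.8) {
  switch(geometry,
    extended = cbind(spacing * seq_len(n), 0, 0),
    helical = {
      # idealised alpha-helix: 1.5 A rise and 100 degrees per residue
      t <- (seq_len(n) - 1) * 100 * pi / 180
      cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * seq_len(n))
    },
    lattice = {
      # serpentine walk through a near-cubic grid; consecutive residues
      # stay one grid step apart so the chain is connected
      k <- ceiling(n^(1/3))
      pos <- matrix(0, n, 3)
      i <- 0L
      for (z in seq_len(k)) {
        ys <- if (z %% 2 == 1) seq_len(k) else rev(seq_len(k))
        for (y in ys) {
          xs <- if ((z + y) %% 2 == 0) seq_len(k) else rev(seq_len(k))
          for (x in xs) {
            i <- i + 1L
            if (i > n) return(pos * spacing)
            pos[i, ] <- c(x, y, z)
          }
        }
      }
      pos * spacing
    },
    stop("unknown geometry: ", geometry))
}

.lattice_interior <- function(n, spacing = 3.8) {
  xyz <- .ca_trace(n, "lattice", spacing) / spacing
  k <- ceiling(n^(1/3))
  present <- apply(xyz, 1, paste, collapse = ",")
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  vapply(seq_len(n), function(i) {
    all(vapply(seq_len(6), function(j)
      paste(xyz[i, ] + nb[j, ], collapse = ",") %in% present, NA))
  }, NA)
}

#' Generate a toy antigen structure with a planted epitope
#'
#' Builds a single-chain backbone (N, CA, C, O atoms) on one of three
#' geometries with ~3.8 Angstrom CA spacing and writes it as PDB text:
#' `"extended"` (a straight chain, every residue solvent-exposed),
#' `"helical"` (an idealised alpha-helix), or `"lattice"` (a serpentine fold
#' through a near-cubic grid, producing genuinely buried core residues).
#' The planted epitope is a set of sequence positions whose residues are
#' guaranteed surface-exposed (for the lattice geometry, requesting an
#' interior position is an error). Deterministic under `seed`: the same seed
#' yields byte-identical PDB text.
#'
#' @param length Chain length in residues (>= 4).
#' @param geometry `"extended"`, `"helical"` or `"lattice"`.
#' @param epitope Integer vector of planted epitope sequence positions
#'   (default: a central contiguous stretch of ~25% of the chain).
#' @param sequence Optional one-letter sequence (random under `seed`
#'   otherwise).
#' @param chain Chain identifier (default "A").
#' @param seed Random seed controlling the sequence draw.
#' @return List with `pdb` (character vector of PDB lines), `annotation`
#'   (data frame: position, key, aa, is_epitope, is_core), `sequence`,
#'   `epitope_sequence` (residues at the planted positions, in order) and
#'   `spec` (the generating parameters).
#' @export
#' @examples
#' fx <- make_toy_antigen(length = 27, geometry = "lattice", seed = 3)
#' sum(fx$annotation$is_core)
make_toy_antigen <- function(length, geometry = c("extended", "helical",
                                                  "lattice"),
                             epitope = NULL, sequence = NULL, chain = "A",
                             seed = 1) {
  geometry <- match.arg(geometry)
  if (length < 4) stop("chain length must be at least 4")
  n <- as.integer(length)
  if (is.null(epitope)) {
    w <- max(2L, round(n / 4))
    s <- max(1L, (n - w) %/% 2L)
    epitope <- seq(s, s + w - 1L)
  }
  epitope <- sort(unique(as.integer(epitope)))
  if (any(epitope < 1L | epitope > n))
    stop("planted epitope positions must lie within the chain")
  core <- if (geometry == "lattice") .lattice_interior(n) else rep(FALSE, n)
  if (any(core[epitope]))
    stop("impossible geometry request: planted epitope position(s) ",
         paste(epitope[core[epitope]], collapse = ", "),
         " are buried in the lattice core")
  if (is.null(sequence)) {
    sequence <- .with_seed(seed,
      paste(sample(.aa1, n, replace = TRUE), collapse = ""))
  }
  aas <- strsplit(toupper(sequence), "")[[1]]
  if (length(aas) != n) stop("sequence length must equal 'length'")
  .check_aa(aas, default_descriptors())
  ca <- .ca_trace(n, geometry)
  aa3 <- names(.max_sasa_gxg)[match(aas, .aa321(names(.max_sasa_gxg)))]
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n)) {
    for (a in rownames(.bb_offsets)) {
      serial <- serial + 1L
      xyz <- ca[i, ] + .bb_offsets[a, ]
      el <- substr(a, 1, 1)
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, paste0(" ", a), aa3[i], chain, i,
        xyz[1], xyz[2], xyz[3], 1.00, 0.00, el))
    }
  }
  lines <- c(lines, "END")
  ann <- data.frame(
    position = seq_len(n),
    key = .residue_key(rep(chain, n), seq_len(n), rep(NA, n)),
    aa = aas,
    is_epitope = seq_len(n) %in% epitope,
    is_core = core,
    stringsAsFactors = FALSE)
  list(pdb = lines, annotation = ann, sequence = paste(aas, collapse = ""),
       epitope_sequence = paste(aas[epitope], collapse = ""),
       spec = list(length = n, geometry = geometry, epitope = epitope,
                   chain = chain, seed = seed))
}

#' Derive a synthetic mimotope set from an epitope sequence
#'
#' Produces `n` peptides emulating phage-display hits against the planted
#' epitope: a window of the epitope sequence with (i) each position
#' substituted with probability `substitution_rate` by a different residue
#' whose property distance from the original is at most `pd_budget` (so the
#' substitution still matches under the default cutoff), and (ii)
#' `gap_spec$count` spacer stretches of `gap_spec$length` residues (drawn
#' from `gap_spec$alphabet`) inserted at random internal points. The
#' ground-truth alignment of each peptide is reported. Deterministic under
#' `seed`.
#'
#' @param epitope_sequence One-letter epitope sequence (non-empty).
#' @param n Number of peptides.
#' @param substitution_rate Per-position substitution probability in [0, 1].
#' @param pd_budget Maximum property distance of a substitute (default 8).
#' @param gap_spec List with `count`, `length` and `alphabet` for inserted
#'   spacers (default: none).
#' @param window Window length (default: the full epitope sequence).
#' @param seed Random seed.
#' @return Data frame: id, sequence, window_start, window_end, n_subs,
#'   sub_positions, gap_positions (positions in the final peptide).
#' @export
#' @examples
#' make_mimotopes("ACDEFGHIK", n = 3, substitution_rate = 0.2,
#'                gap_spec = list(count = 1, length = 2,
#'                                alphabet = c("G", "P")), seed = 42)
make_mimotopes <- function(epitope_sequence, n = 10, substitution_rate = 0.2,
                           pd_budget = 8,
                           gap_spec = list(count = 0, length = 2,
                                           alphabet = c("G", "P")),
                           window = NULL, seed = 1) {
  aas <- strsplit(toupper(epitope_sequence), "")[[1]]
  if (!length(aas)) stop("epitope_sequence must be non-empty")
  .check_aa(aas, default_descriptors())
  stopifnot(substitution_rate >= 0, substitution_rate <= 1, n >= 1)
  L <- length(aas)
  if (is.null(window)) window <- L
  if (window < 2 || window > L)
    stop("window must be between 2 and the epitope length")
  pdm <- pd_matrix()
  subs_for <- lapply(.aa1, function(a) {
    s <- names(which(pdm[a, ] <= pd_budget))
    setdiff(s, a)
  })
  names(subs_for) <- .aa1
  gcount <- gap_spec$count %||% 0
  glen <- gap_spec$length %||% 2
  galpha <- gap_spec$alphabet %||% c("G", "P")
  .with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      ws <- if (window == L) 1L else sample.int(L - window + 1L, 1L)
      we <- ws + window - 1L
      pep <- aas[ws:we]
      hit <- which(stats::runif(window) < substitution_rate)
      hit <- hit[lengths(subs_for[pep[hit]]) > 0]
      for (p in hit)
        pep[p] <- sample(subs_for[[pep[p]]], 1L)
      gpos <- integer(0)
      if (gcount > 0) {
        for (g in seq_len(gcount)) {
          # internal insertion point: after position 1..len-1
          at <- sample.int(length(pep) - 1L, 1L)
          spacer <- sample(galpha, glen, replace = TRUE)
          pep <- append(pep, spacer, after = at)
          gpos <- c(gpos, at + seq_len(glen))
        }
      }
      data.frame(id = sprintf("mimo%03d", i),
                 sequence = paste(pep, collapse = ""),
                 window_start = ws, window_end = we,
                 n_subs = length(hit),
                 sub_positions = paste(hit, collapse = ","),
                 gap_positions = paste(gpos, collapse = ","),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write fixture files to a directory
#'
#' Writes `antigen.pdb`, `mimotopes.txt` and `truth.tsv` for a generated
#' fixture.
#'
#' @param fixture A [make_toy_antigen()] result.
#' @param mimotopes A [make_mimotopes()] result (optional).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, mimotopes = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(fixture$pdb, file.path(dir, "antigen.pdb"))
  utils::write.table(fixture$annotation, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(mimotopes))
    writeLines(mimotopes$sequence, file.path(dir, "mimotopes.txt"))
  invisible(dir)
}
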