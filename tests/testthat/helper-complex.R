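# Two-chain synthetic complex: antigen chain A (extended) plus a chain B
# placed either in contact with the centre of A or far away.  Used by the
# truth-extraction and CLI tests.
two_chain_complex <- function(contact = TRUE, n_a = 10, n_b = 4,
                              seed = 1) {
  fa <- make_toy_antigen(length = n_a, geometry = "extended", seed = seed)
  fb <- make_toy_antigen(length = n_b, geometry = "extended", chain = "B",
                         seed = seed + 1)
  shift <- if (contact) c(3.8 * (n_a / 2 - n_b / 2), 4.5, 0) else
    c(0, 90, 0)
  blines <- fb$pdb[fb$pdb != "END"]
  moved <- vapply(blines, function(l) {
    x <- as.numeric(substr(l, 31, 38)) + shift[1]
    y <- as.numeric(substr(l, 39, 46)) + shift[2]
    z <- as.numeric(substr(l, 47, 54)) + shift[3]
    paste0(substr(l, 1, 30), sprintf("%8.3f%8.3f%8.3f", x, y, z),
           substr(l, 55, nchar(l)))
  }, "")
  c(fa$pdb[fa$pdb != "END"], unname(moved), "END")
}
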