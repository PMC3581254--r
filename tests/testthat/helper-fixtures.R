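# Fixtures are built in code: PDB/PSSM text written to tempfiles, plus naive
# double-loop oracles kept deliberately independent of the package internals.

pdb_atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                          occ = 1, b = 0, alt = " ", icode = " ",
                          record = "ATOM") {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, name, alt, resname, chain, resseq, icode,
          x, y, z, occ, b)
}

# 3-residue minimal chain: ALA/GLY/SER CA on the x axis, B = 10, 20, 30
minimal_pdb_lines <- function() {
  c(
    pdb_atom_line(1, "N", "ALA", "A", 1, -1.0, 0.5, 0.0, b = 9),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 0.0, 0.0, 0.0, b = 10),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 3.8, 0.0, 0.0, b = 20),
    pdb_atom_line(4, "CA", "SER", "A", 3, 7.6, 0.0, 0.0, b = 30),
    "END"
  )
}

write_pdb_fixture <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

# PSI-BLAST ASCII PSSM fixture: 2 header lines, rows with 20 scores +
# 20 frequencies + information-per-position + relative weight.
pssm_fixture_lines <- function(letters = c("A", "C", "D"),
                               info = c(0.52, 1.10, 0.00)) {
  header <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste(c("   ", rep(LETTERS[1:20], 2)), collapse = "  ")
  )
  rows <- vapply(seq_along(letters), function(i) {
    paste(c(sprintf("%5d %s", i, letters[i]),
            sprintf("%3d", rep(0L, 20)),
            sprintf("%4d", rep(5L, 20)),
            sprintf("%5.2f", info[i]), "0.30"),
          collapse = " ")
  }, character(1))
  c(header, rows, "")
}

# --- independent oracles -----------------------------------------------------

oracle_wcn <- function(coords) {
  n <- nrow(coords)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      s <- s + 1 / sum((coords[i, ] - coords[j, ])^2)
    }
    out[i] <- s
  }
  out
}

oracle_seq <- function(inv_wcn, n) {
  N <- length(inv_wcn)
  out <- numeric(N)
  for (i in seq_len(N)) {
    s <- 0; m <- 0
    for (x in (i - n):(i + n)) {
      if (x >= 1 && x <= N) { s <- s + inv_wcn[x]; m <- m + 1 }
    }
    out[i] <- s / m
  }
  out
}

oracle_str <- function(coords, inv_wcn, cutoff) {
  N <- nrow(coords)
  out <- numeric(N)
  for (i in seq_len(N)) {
    s <- 0; m <- 0
    for (x in seq_len(N)) {
      if (x == i || sqrt(sum((coords[i, ] - coords[x, ])^2)) < cutoff) {
        s <- s + inv_wcn[x]; m <- m + 1
      }
    }
    out[i] <- s / m
  }
  out
}

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# small labelled feature table built from synthetic chains
small_feature_table <- function(n_proteins = 6, n_residues = 60,
                                feature_set = "SEQ", seed = 11) {
  ds <- make_dataset(n_proteins, synthetic_spec(n_residues = n_residues,
                                                seed = seed), seed = seed)
  build_feature_table(profile_dataset(ds$chains), feature_set)
}

# shuffle labels within each protein, preserving per-protein counts
shuffle_labels_within_protein <- function(tab, seed) {
  prot <- paste(tab$groups$pdb_id, tab$groups$chain_id)
  y <- tab$y
  set.seed(seed)
  for (p in unique(prot)) {
    i <- which(prot == p)
    y[i] <- sample(y[i])
  }
  tab$y <- y
  tab
}

# coarse grids keep unit-test SVM runs fast; acceptance runs use the defaults
fast_config <- function(seed = 1) {
  svm_config(cost_grid = 2^c(-1, 3, 7), gamma_grid = 2^c(-7, -3, 1),
             seed = seed)
}
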