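# Shared fixture builders: random sequences and tiny hand-written
# PDB-format files, all generated in code at test time.

random_protein <- function(len) {
  paste(sample(rpiforest:::AA20, len, replace = TRUE), collapse = "")
}

random_rna <- function(len) {
  paste(sample(rpiforest:::RNA4, len, replace = TRUE), collapse = "")
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          alt = "", occ = 1, icode = "", element = "") {
  if (element == "") element <- substr(name, 1, 1)
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, icode, x, y, z, occ, 0, element)
}

# One protein chain (GLY x n_prot, one CA atom per residue) and one RNA
# chain (one P atom per residue).  The first protein atom sits at the
# origin and the first RNA atom at (d, 0, 0); all other atoms are far
# away, so the minimum protein-RNA atom distance is exactly `d`.
write_toy_complex <- function(path, d, n_prot = 30, n_rna = 12,
                              rna_bases = NULL, extra_lines = character()) {
  if (is.null(rna_bases)) rna_bases <- rep_len(c("A", "C", "G", "U"), n_rna)
  lines <- c("HEADER    TOY COMPLEX")
  serial <- 0
  for (i in seq_len(n_prot)) {
    serial <- serial + 1
    xyz <- if (i == 1) c(0, 0, 0) else c(i * 50, 500, 500)
    lines <- c(lines, pdb_atom_line(serial, "CA", "GLY", "A", i,
                                    xyz[1], xyz[2], xyz[3], element = "C"))
  }
  lines <- c(lines, "TER")
  for (i in seq_len(n_rna)) {
    serial <- serial + 1
    xyz <- if (i == 1) c(d, 0, 0) else c(i * 50, -500, -500)
    lines <- c(lines, pdb_atom_line(serial, "P", rna_bases[i], "B", i,
                                    xyz[1], xyz[2], xyz[3], element = "P"))
  }
  lines <- c(lines, extra_lines, "TER", "END")
  writeLines(lines, path)
  invisible(path)
}

# A random blob of protein + RNA atoms for brute-force distance checks.
write_random_complex <- function(path, n_prot_atoms = 60, n_rna_atoms = 40,
                                 spread = 15) {
  lines <- c("HEADER    RANDOM BLOB")
  serial <- 0
  # PDB fields carry 3 decimals; round so the returned coordinates are
  # exactly what the parser will see
  coords_p <- round(matrix(runif(3 * n_prot_atoms, 0, spread), ncol = 3), 3)
  for (i in seq_len(n_prot_atoms)) {
    serial <- serial + 1
    lines <- c(lines, pdb_atom_line(serial, "CA", "ALA", "A", i,
                                    coords_p[i, 1], coords_p[i, 2], coords_p[i, 3],
                                    element = "C"))
  }
  lines <- c(lines, "TER")
  coords_r <- round(matrix(runif(3 * n_rna_atoms, 0, spread), ncol = 3), 3)
  for (i in seq_len(n_rna_atoms)) {
    serial <- serial + 1
    lines <- c(lines, pdb_atom_line(serial, "P", "G", "B", i,
                                    coords_r[i, 1], coords_r[i, 2], coords_r[i, 3],
                                    element = "P"))
  }
  lines <- c(lines, "TER", "END")
  writeLines(lines, path)
  list(path = path, protein = coords_p, rna = coords_r)
}
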