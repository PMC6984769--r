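test_that("chain extraction recovers sequences, molecule types and atoms", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_complex(f, d = 3.0, n_prot = 3, n_rna = 4,
                    rna_bases = c("A", "C", "G", "U"))
  chains <- extract_chains(f)
  expect_length(chains, 2L)
  expect_identical(chains[[1]]$moltype, "protein")
  expect_identical(chains[[1]]$sequence, "GGG")
  expect_identical(chains[[2]]$moltype, "rna")
  expect_identical(chains[[2]]$sequence, "ACGU")
  expect_equal(nrow(chains[[1]]$atoms), 3L)

  # DNA chains are skipped with a warning
  dna <- c(pdb_atom_line(900, "P", "DA", "C", 1, 0, 50, 0, element = "P"),
           pdb_atom_line(901, "P", "DT", "C", 2, 5, 50, 0, element = "P"))
  write_toy_complex(f, d = 3.0, n_prot = 3, n_rna = 4, extra_lines = dna)
  expect_warning(chains <- extract_chains(f), "DNA")
  expect_length(chains, 2L)

  writeLines("HEADER    EMPTY", f)
  expect_error(suppressWarnings(extract_chains(f)))
})

test_that("alternate locations keep the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, alt = "A", occ = 0.3),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 9, 9, 9, alt = "B", occ = 0.7),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 1, 1, 1),
    "END")
  writeLines(lines, f)
  chains <- extract_chains(f)
  expect_equal(nrow(chains[[1]]$atoms), 2L)
  expect_equal(chains[[1]]$atoms$x[1], 9)  # the 0.7-occupancy conformer
})

test_that("the contact rule is strictly less-than the 3.4 angstrom cutoff", {
  for (case in list(list(d = 3.0, hit = TRUE),
                    list(d = 3.4, hit = FALSE),
                    list(d = 3.5, hit = FALSE))) {
    f <- withr::local_tempfile(fileext = ".pdb")
    write_toy_complex(f, d = case$d)
    pairs <- find_interacting_pairs(extract_chains(f))
    expect_equal(nrow(pairs), 1L)
    expect_equal(pairs$min_atom_distance, case$d)
    expect_identical(pairs$interacting, case$hit,
                     info = paste("d =", case$d))
  }
})

test_that("interacting sets are monotone in the cutoff and distances symmetric", {
  set.seed(51)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_random_complex(f)
  chains <- extract_chains(f)
  at30 <- find_interacting_pairs(chains, cutoff = 3.0)
  at34 <- find_interacting_pairs(chains, cutoff = 3.4)
  expect_true(all(!at30$interacting | at34$interacting))
  expect_equal(at30$min_atom_distance, at34$min_atom_distance)
  expect_gte(at34$n_contacts_under_cutoff, at30$n_contacts_under_cutoff)
})

test_that("minimum distances match the brute-force all-pairs oracle", {
  set.seed(52)
  for (i in 1:5) {
    f <- withr::local_tempfile(fileext = ".pdb")
    fx <- write_random_complex(f, n_prot_atoms = sample(20:120, 1),
                               n_rna_atoms = sample(20:80, 1))
    pairs <- find_interacting_pairs(extract_chains(f))
    brute <- Inf
    for (a in seq_len(nrow(fx$protein))) {
      for (b in seq_len(nrow(fx$rna))) {
        brute <- min(brute, sqrt(sum((fx$protein[a, ] - fx$rna[b, ])^2)))
      }
    }
    expect_equal(pairs$min_atom_distance, brute, tolerance = 1e-4)
  }
})

test_that("length-filter policies implement both readings", {
  pairs <- data.frame(protein_length = c(30, 20, 24, 30),
                      rna_length = c(12, 12, 9, 9))
  expect_identical(apply_length_filter(pairs, mode = "each"),
                   c(TRUE, FALSE, FALSE, FALSE))
  # literal reading: drop only when both chains are short simultaneously
  expect_identical(apply_length_filter(pairs, mode = "both-short"),
                   c(TRUE, TRUE, FALSE, TRUE))
})

test_that("build_dataset applies dates, filters, and dedup deterministically", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "cplx1.pdb")
  f2 <- file.path(d, "cplx2.pdb")
  write_toy_complex(f1, d = 3.0)                 # interacting, passes lengths
  write_toy_complex(f2, d = 3.0, n_prot = 20)    # protein too short
  meta <- data.frame(structure_id = c("cplx1", "cplx2"),
                     release_date = c("2015-06-01", "2015-06-01"))

  res <- build_dataset(c(f1, f2), metadata = meta,
                       date_from = "2014-01-01", date_to = "2016-12-31")
  expect_equal(nrow(res$pairs), 1L)
  expect_identical(res$pairs$protein_id, "cplx1_A")
  expect_identical(res$pairs$rna_id, "cplx1_B")
  expect_equal(nchar(res$proteins[["cplx1_A"]]), 30L)
  expect_identical(unname(res$rnas["cplx1_B"]),
                   paste(rep_len(c("A", "C", "G", "U"), 12), collapse = ""))

  # date window excludes everything
  none <- build_dataset(c(f1, f2), metadata = meta,
                        date_from = "2017-01-01", date_to = "2017-12-31")
  expect_equal(nrow(none$pairs), 0L)

  # the short-protein complex survives under the literal both-short policy
  lit <- build_dataset(c(f1, f2), filter_mode = "both-short")
  expect_equal(nrow(lit$pairs), 2L)

  # duplicated input structure collapses to one row per chain pair
  dup <- build_dataset(c(f1, f1))
  expect_equal(nrow(dup$pairs), 1L)

  # written outputs feed back into seqio
  out <- file.path(d, "built")
  build_dataset(f1, out_dir = out)
  expect_identical(read_pairs(file.path(out, "pairs.tsv"))$label, 1L)
  expect_length(read_fasta(file.path(out, "protein.fasta"), "protein"), 1L)
})
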