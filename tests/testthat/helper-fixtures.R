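# shared helpers: random clouds, tiny structure files, barcode comparison

random_distance_matrix <- function(n, seed, box = 2) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  as.matrix(stats::dist(matrix(stats::runif(3 * n, 0, box), ncol = 3)))
}

expect_same_bars <- function(a, b, tol = 1e-12) {
  expect_equal(nrow(a$bars), nrow(b$bars))
  if (nrow(a$bars) > 0) {
    expect_equal(a$bars$birth, b$bars$birth, tolerance = tol)
    expect_equal(a$bars$death, b$bars$death, tolerance = tol)
  }
}

pdb_atom_line <- function(serial, chain, resno, x, y, z, alt = " ",
                          resname = "ALA", occ = 1, elety = " CA ") {
  sprintf("ATOM  %5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, elety, alt, resname, chain, resno, x, y, z, occ, 0)
}

# two chains of n residues each on a line, with optional REMARK 350 assembly
write_test_pdb <- function(path, n = 3, remark350 = FALSE) {
  lines <- character()
  if (remark350) {
    lines <- c(lines,
      "REMARK 350 BIOMOLECULE: 1",
      "REMARK 350 APPLY THE FOLLOWING TO CHAINS: A, B",
      "REMARK 350   BIOMT1   1  1.000000  0.000000  0.000000        0.00000",
      "REMARK 350   BIOMT2   1  0.000000  1.000000  0.000000        0.00000",
      "REMARK 350   BIOMT3   1  0.000000  0.000000  1.000000        0.00000",
      "REMARK 350   BIOMT1   2  1.000000  0.000000  0.000000        0.00000",
      "REMARK 350   BIOMT2   2  0.000000  1.000000  0.000000        0.00000",
      "REMARK 350   BIOMT3   2  0.000000  0.000000  1.000000       10.00000")
  }
  serial <- 0
  for (ch in c("A", "B")) {
    for (r in seq_len(n)) {
      serial <- serial + 1
      lines <- c(lines, pdb_atom_line(serial, ch, r, r * 3.8,
                                      ifelse(ch == "A", 0, 5), 0))
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  path
}

make_fixture_trajectories <- function(n_frames = 12, class_effect = 0.4,
                                      noise_sd = 0.05, seed = 1) {
  sets <- list()
  for (t in 0:3) {
    pair <- make_labeled_frames(n_frames, class_effect, noise_sd,
                                seed = seed + t, trajectory_id = t)
    sets <- c(sets, unname(pair))
  }
  sets
}
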