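test_that("cloud construction validates, orders and counts records", {
  df <- data.frame(chain = c("B", "A", "A"), residue = c(5L, 2L, 1L),
                   x = 1:3, y = 0, z = 0)
  cloud <- alpha_carbon_cloud(df)
  expect_s3_class(cloud, "alpha_carbon_cloud")
  expect_equal(n_chains(cloud), 2L)
  # chain order = order of first appearance, residues ascending within chain
  expect_equal(cloud$chain, c("B", "A", "A"))
  expect_equal(cloud$residue, c(5L, 1L, 2L))

  expect_error(alpha_carbon_cloud(df[0, ]), "empty")
  expect_error(alpha_carbon_cloud(transform(df, x = c(1, NA, 3))), "finite")
  expect_error(alpha_carbon_cloud(transform(df, residue = c(5, 2, 2))),
               "duplicate")
  expect_error(alpha_carbon_cloud(transform(df, residue = c(-1, 2, 3))),
               "non-negative")
  expect_error(alpha_carbon_cloud(df, residue_range = c(1, 4)),
               "residue_range")
})

test_that("CSV table round-trips clouds and frame sets exactly", {
  cloud <- make_chain_loop(8, 2, gap = 2, noise_sd = 0.1, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cloud_table(cloud, path)
  back <- read_cloud_table(path)
  expect_equal(as.data.frame(back), as.data.frame(cloud))

  pair <- make_labeled_frames(3, 0.5, noise_sd = 0.05, seed = 2)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cloud_table(pair$glycosylated, path2)
  ts <- read_frames(path2, label = "glycosylated")
  expect_equal(length(ts$frames), 3L)
  expect_equal(ts$frame_indices, 0:2)
  expect_equal(as.data.frame(ts$frames[[2]]),
               as.data.frame(pair$glycosylated$frames[[2]]))
})

test_that("selection by residue range and chains is idempotent", {
  df <- data.frame(chain = rep(c("A", "B"), each = 300),
                   residue = rep(200:499, 2),
                   x = rnorm(600), y = rnorm(600), z = rnorm(600))
  cloud <- alpha_carbon_cloud(df)
  sel <- restrict_cloud(cloud, residue_range = c(241, 446))
  expect_equal(nrow(sel), 2 * 206)          # 206 residues per chain
  expect_equal(n_chains(sel), 2L)
  again <- restrict_cloud(sel, residue_range = c(241, 446))
  expect_equal(as.data.frame(again), as.data.frame(sel))
  expect_error(restrict_cloud(cloud, residue_range = c(1000, 1001)), "empty")
  only_a <- restrict_cloud(cloud, chain_ids = "A")
  expect_equal(unique(only_a$chain), "A")
})

test_that("PDB parsing keeps standard-residue alpha carbons in chain order", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(path, n = 4)
  cloud <- read_structure(path)
  expect_equal(nrow(cloud), 8L)
  expect_equal(n_chains(cloud), 2L)
  expect_equal(cloud$residue, rep(1:4, 2))
  sel <- read_structure(path, residue_range = c(2, 3), chain_ids = "A")
  expect_equal(nrow(sel), 2L)
  expect_error(read_structure(path, residue_range = c(90, 99)), "empty")
})

test_that("altloc duplicates are resolved deterministically", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "A", 1, 0, 0, 0, alt = "B", occ = 0.6),
    pdb_atom_line(2, "A", 1, 9, 9, 9, alt = "A", occ = 0.4),
    pdb_atom_line(3, "A", 2, 3.8, 0, 0),
    "END"), path)
  cloud <- read_structure(path)
  expect_equal(nrow(cloud), 2L)
  expect_equal(cloud$x[1], 9)               # altloc 'A' preferred over 'B'
})

test_that("biological assembly expansion applies BIOMT transforms", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(path, n = 3, remark350 = TRUE)
  cloud <- read_structure(path, assembly = 1)
  expect_equal(nrow(cloud), 12L)            # two copies of two 3-residue chains
  expect_equal(n_chains(cloud), 4L)
  copy <- cloud[cloud$chain == "A.2", ]
  orig <- cloud[cloud$chain == "A", ]
  expect_equal(copy$z, orig$z + 10)         # second operator translates +10 z
  expect_error(read_structure(path, assembly = 3), "not present")
})

test_that("mmCIF parsing produces the same cloud shape", {
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_test", "#", "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
             "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_model_num")),
    "ATOM 1 C CA . ALA A 1 1 ? 0.000 0.000 0.000 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 2 C CA . ALA A 1 2 ? 3.800 0.000 0.000 1.00 0.00 ? 2 ALA A CA 1",
    "ATOM 3 C CA . GLY B 1 1 ? 0.000 5.000 0.000 1.00 0.00 ? 1 GLY B CA 1",
    "#"), path)
  cloud <- read_structure(path)
  expect_equal(nrow(cloud), 3L)
  expect_equal(n_chains(cloud), 2L)
  expect_error(read_structure(path, assembly = 1), "PDB")
})

test_that("multi-model PDB files yield one frame per MODEL", {
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- character()
  for (m in 1:4) {
    lines <- c(lines, sprintf("MODEL     %4d", m),
               pdb_atom_line(1, "A", 1, m * 1.0, 0, 0),
               pdb_atom_line(2, "A", 2, m * 1.0 + 3.8, 0, 0),
               "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  ts <- read_frames(path, start_frame = 2)
  expect_equal(length(ts$frames), 2L)       # models 0..3, keep indices 2,3
  expect_equal(ts$frame_indices, 2:3)
  expect_equal(ts$frames[[1]]$x[1], 3)      # third model
  all_frames <- read_frames(path, start_frame = 0)
  expect_equal(length(all_frames$frames), 4L)
})

test_that("roster mismatches between frames are rejected with the frame", {
  tab <- data.frame(frame = rep(c(0, 7), c(3, 2)),
                    chain = "A", residue = c(1:3, 1:2),
                    x = rnorm(5), y = rnorm(5), z = rnorm(5))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  expect_error(read_frames(path), "frame 7")
})
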