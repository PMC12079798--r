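test_that("epsilon grid selection floors, ceils and buffers the sample", {
  # single-bar sample [5, 5*sqrt(2)): floor 5 -> 3, ceil 7.07 -> 8 -> 10
  sq <- make_chain_loop(4, 5 * sqrt(2) / 2)
  g <- select_epsilon_grid(list(sq), sigma_max = 0.5, spacing = 0.1)
  expect_equal(min(g), 3)
  expect_equal(max(g), 10)

  # sample with min birth 3.87 and max death 27.5 gives the 1-30 range
  hx <- make_chain_loop(6, 3.87)            # bar [3.87, 3.87*sqrt(3))
  bigsq <- make_chain_loop(4, 27.5 / 2)     # bar [27.5/sqrt(2), 27.5)
  g2 <- select_epsilon_grid(list(hx, bigsq), sigma_max = 0.5, spacing = 0.1)
  expect_equal(attr(g2, "min_birth"), 3.87, tolerance = 1e-12)
  expect_equal(attr(g2, "max_death"), 27.5, tolerance = 1e-12)
  expect_equal(min(g2), 1)
  expect_equal(max(g2), 30)

  # two far-apart points: no loops anywhere -> selection error
  lonely <- alpha_carbon_cloud(data.frame(chain = "A", residue = 1:2,
                                          x = c(0, 9), y = 0, z = 0))
  expect_error(select_epsilon_grid(list(lonely), 0.5), "empty")
  expect_error(select_epsilon_grid(list(), 0.5), "non-empty")
})

test_that("Gaussian CROCKER columns are the per-rho Gaussian Betti vectors", {
  cl <- make_chain_loop(10, 1.8, gap = 2, noise_sd = 0.1, seed = 21)
  grid <- epsilon_grid(0.2, 5, 0.1)
  sigma <- 0.25
  C <- gaussian_crocker(cl, grid, sigma)
  scheme <- attr(C, "scheme")
  cutoff <- attr(C, "cutoff")
  expect_equal(dim(C), c(length(grid), scheme$inter_chain_value))
  for (rho in c(1L, 3L, scheme$inter_chain_value)) {
    D <- build_dissimilarity(cl, rho, attr(C, "M"), scheme)
    bc <- rips_barcode(D, dims = 1, cutoff = cutoff)[["1"]]
    expect_equal(C[, rho],
                 as.numeric(gaussian_betti_vector(bc, grid, sigma)))
  }
  # column 1 is identically zero for dimension 1: paths carry no loops
  expect_equal(C[, 1], rep(0, length(grid)))
})

test_that("GCCD differencing telescopes back to the CROCKER matrix", {
  cl <- make_chain_loop(12, 1.5, gap = 4, noise_sd = 0.15, seed = 8)
  grid <- epsilon_grid(0.2, 5, 0.1)
  C <- gaussian_crocker(cl, grid, 0.25)
  G <- gccd_from_crocker(C)
  expect_equal(G[, 1], C[, 1])
  expect_equal(unclass(crocker_from_gccd(G)), unclass(C),
               tolerance = 1e-15, ignore_attr = TRUE)
  expect_lt(max(abs(unclass(crocker_from_gccd(G)) - unclass(C))),
            1.0001e-10)
  # summed GCCD columns equal the full-cloud Gaussian Betti vector
  de <- as.matrix(dist(cloud_xyz(cl)))
  bc <- rips_barcode(de, dims = 1, cutoff = attr(C, "cutoff"))[["1"]]
  expect_equal(rowSums(unclass(G)),
               as.numeric(gaussian_betti_vector(bc, grid, 0.25)),
               tolerance = 1e-12)
})

test_that("a constant-in-rho CROCKER matrix differences to a single column", {
  # single chain, consecutive numbering, rho >= 1 all give the same path
  # topology once every chord is admissible at once (2-point chain)
  C <- structure(matrix(rep(c(1, 2, 3), 4), nrow = 3),
                 grid = epsilon_grid(1, 3, 1), rhos = 1:4, sigma = 0.1,
                 dimension = 1L, cutoff = 3.001, M = 13,
                 scheme = residue_scheme(3), class = "gaussian_crocker")
  G <- gccd_from_crocker(C)
  expect_equal(unclass(G)[, 1], c(1, 2, 3))
  expect_equal(unclass(G)[, 2:4], matrix(0, 3, 3))
})

test_that("incremental and from-scratch column construction agree", {
  cl <- make_two_chain_ring(6, 1.5, noise_sd = 0.1, seed = 31)
  grid <- epsilon_grid(0.2, 4, 0.1)
  a <- gaussian_crocker(cl, grid, 0.25, column_mode = "independent")
  b <- gaussian_crocker(cl, grid, 0.25, column_mode = "incremental")
  expect_lt(max(abs(unclass(a) - unclass(b))), 1.0001e-10)
})

test_that("crocker matrices are invariant to record order within chains", {
  cl <- make_chain_loop(10, 1.5, gap = 2, noise_sd = 0.2, seed = 12)
  grid <- epsilon_grid(0.2, 4, 0.1)
  ref <- gaussian_crocker(cl, grid, 0.25)
  df <- as.data.frame(cl)
  perm <- alpha_carbon_cloud(df[sample(nrow(df)), ])  # constructor re-sorts
  expect_equal(unclass(gaussian_crocker(perm, grid, 0.25)), unclass(ref),
               ignore_attr = TRUE)
})

test_that("parameter validation rejects inconsistent cutoff and M", {
  cl <- make_chain_loop(6, 1)
  grid <- epsilon_grid(0.2, 4, 0.1)
  expect_error(gaussian_crocker(cl, grid, 0.25, cutoff = 2), "cutoff")
  expect_error(gaussian_crocker(cl, grid, 0.25, M = 3), "M must exceed")
})

test_that("matrix CSV round-trip preserves layout and ten-decimal values", {
  cl <- make_chain_loop(8, 1.5, gap = 2, noise_sd = 0.05, seed = 2)
  grid <- epsilon_grid(0.5, 3, 0.5)
  G <- gccd_matrix(cl, grid, 0.25)
  path <- withr::local_tempfile(fileext = ".csv")
  write_crocker_csv(G, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_equal(header[1], "epsilon")
  expect_equal(header[-1], paste0("rho_", attr(G, "rhos")))
  back <- read_crocker_csv(path)
  expect_equal(unclass(back), round(unclass(G), 10), ignore_attr = TRUE)
  expect_equal(as.numeric(attr(back, "grid")), as.numeric(grid))
})
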