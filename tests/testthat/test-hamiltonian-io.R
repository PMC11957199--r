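test_that("random Hamiltonians are reproducible and carry full eri symmetry", {
  H1 <- random_hamiltonian(4, 2, 2, seed = 7)
  H2 <- random_hamiltonian(4, 2, 2, seed = 7)
  expect_identical(H1, H2)
  expect_equal(H1$h, t(H1$h))
  for (perm in list(c(2, 1, 3, 4), c(1, 2, 4, 3), c(3, 4, 1, 2),
                    c(4, 3, 2, 1), c(2, 1, 4, 3)))
    expect_equal(H1$eri, aperm(H1$eri, perm))
  expect_error(random_hamiltonian(0, 0, 0, seed = 1),
               class = "sqdbinder_argument_error")
  expect_error(random_hamiltonian(2, 3, 1, seed = 1),
               class = "sqdbinder_argument_error")
})

test_that("a minimal FCIDUMP maps onto the expected fields", {
  path <- withr::local_tempfile(fileext = ".fcidump")
  writeLines(c("&FCI NORB=1,NELEC=2,MS2=0,", " ORBSYM=1,", " ISYM=1,", "&END",
               " 0.5  1 1 1 1", "-1.0  1 1 0 0", " 0.2  0 0 0 0"), path)
  H <- read_fcidump(path)
  expect_equal(H$M, 1L)
  expect_equal(H$n_alpha, 1L)
  expect_equal(H$n_beta, 1L)
  expect_equal(H$h, matrix(-1.0, 1, 1))
  expect_equal(H$eri[1, 1, 1, 1], 0.5)
  expect_equal(H$E0, 0.2)
})

test_that("FCIDUMP round trips preserve every field to 1e-12 for M = 1..6", {
  for (M in 1:6) {
    n <- max(1L, M %/% 2)
    H <- random_hamiltonian(M, n, n, seed = 100 + M)
    path <- withr::local_tempfile(fileext = ".fcidump")
    write_fcidump(H, path)
    H2 <- read_fcidump(path)
    expect_equal(H2$M, H$M)
    expect_equal(H2$n_alpha, H$n_alpha)
    expect_equal(H2$n_beta, H$n_beta)
    expect_equal(H2$E0, H$E0, tolerance = 1e-12)
    expect_lt(max(abs(H2$h - H$h)), 1e-12)
    expect_lt(max(abs(H2$eri - H$eri)), 1e-12)
  }
})

test_that("the written record count respects the symmetry-class bound", {
  M <- 4
  H <- random_hamiltonian(M, 2, 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".fcidump")
  write_fcidump(H, path)
  body <- readLines(path)
  body <- body[-(1:4)]
  # bound from exhaustive enumeration of the 8-fold symmetry orbits
  canon <- function(p, r, q, s) {
    reps <- list(c(p, r, q, s), c(r, p, q, s), c(p, r, s, q), c(r, p, s, q),
                 c(q, s, p, r), c(s, q, p, r), c(q, s, r, p), c(s, q, r, p))
    min(vapply(reps, function(t) sum((t - 1) * M^(3:0)), numeric(1)))
  }
  ids <- integer(0)
  for (p in 1:M) for (r in 1:M) for (q in 1:M) for (s in 1:M)
    ids <- c(ids, canon(p, r, q, s))
  n_classes <- length(unique(ids))
  expect_equal(n_classes, (M * (M + 1) / 2) * (M * (M + 1) / 2 + 1) / 2)
  bound <- n_classes + M * (M + 1) / 2 + 1
  expect_lte(length(body), bound)
  # energies are invariant under which symmetry representative was stored:
  # the round-tripped Hamiltonian gives the same ground energy
  e1 <- casci(H, compute_variance = FALSE)$energy
  e2 <- casci(read_fcidump(path), compute_variance = FALSE)$energy
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("malformed FCIDUMP input is rejected", {
  path <- withr::local_tempfile(fileext = ".fcidump")
  writeLines(c("no header here", "0.5 1 1 1 1"), path)
  expect_error(read_fcidump(path), class = "sqdbinder_format_error")
  writeLines(c("&FCI NORB=2,NELEC=2,MS2=0,", "&END", "0.5 3 1 1 1"), path)
  expect_error(read_fcidump(path), class = "sqdbinder_format_error")
  expect_error(read_fcidump(withr::local_tempfile()), class = "sqdbinder_io_error")
})

test_that("XYZ files round trip", {
  g <- geometry(c("O", "H", "H"), c(0, 0.96, -0.24), c(0, 0, 0.93),
                c(0, 0, 0), comment = "water monomer")
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(g, path)
  g2 <- read_xyz(path)
  expect_equal(g2$atoms$element, g$atoms$element)
  expect_equal(g2$atoms$x, g$atoms$x, tolerance = 1e-9)
  expect_equal(g2$comment, g$comment)
})

test_that("translate_monomer hits the target distance and keeps monomers rigid", {
  # synthetic water-dimer-like arrangement: atoms 1:3 monomer A, 4:6 B
  g <- geometry(c("O", "H", "H", "O", "H", "H"),
                x = c(0, 0.76, -0.76, 2.9, 3.66, 2.14),
                y = c(0, 0.59, 0.59, 0.1, 0.69, 0.69),
                z = c(0, 0, 0, 0.05, 0, 0))
  d0 <- atom_distance(g, 1, 4)

  same <- translate_monomer(g, 4:6, 1, 4, d0)
  expect_lt(max(abs(as.matrix(same$atoms[, 2:4]) - as.matrix(g$atoms[, 2:4]))),
            1e-12)

  far <- translate_monomer(g, 4:6, 1, 4, 48.0)
  expect_equal(atom_distance(far, 1, 4), 48.0, tolerance = 1e-10)

  # every intra-monomer distance preserved across a scan grid
  grid <- seq(1.4, 3.5, by = 0.3)
  scan <- pes_geometries(g, 4:6, 1, 4, grid)
  achieved <- vapply(scan, atom_distance, numeric(1), i = 1, j = 4)
  expect_equal(unname(achieved), grid, tolerance = 1e-10)
  expect_true(all(diff(achieved) > 0))
  for (gg in scan) {
    for (pair in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
      expect_equal(atom_distance(gg, pair[1], pair[2]),
                   atom_distance(g, pair[1], pair[2]), tolerance = 1e-10)
  }

  expect_error(translate_monomer(g, 4:6, 1, 2, 3.0),
               class = "sqdbinder_geometry_error")
  g_co <- g
  g_co$atoms[4, 2:4] <- g_co$atoms[1, 2:4]
  expect_error(translate_monomer(g_co, 4:6, 1, 4, 3.0),
               class = "sqdbinder_geometry_error")
})

test_that("active-space specs validate their electron/orbital counts", {
  sp <- active_space_spec(c("O 2s", "O 2p", "H 1s"), 16, 12)
  expect_s3_class(sp, "active_space_spec")
  expect_error(active_space_spec("O 2s", 6, 2),
               class = "sqdbinder_argument_error")
})

test_that("prepare_active_space fails cleanly without an engine and works through one", {
  g <- geometry(c("H", "H"), c(0, 0.74), c(0, 0), c(0, 0))
  sp <- active_space_spec("H 1s", 2, 2)
  withr::local_envvar(SQDBINDER_ENGINE = "")
  expect_error(prepare_active_space(g, sp, "sto-3g"),
               class = "sqdbinder_environment_error")

  # a stand-in engine script that writes a precomputed FCIDUMP exercises
  # the delegation contract end to end
  H_ref <- random_hamiltonian(2, 1, 1, seed = 42)
  dump <- withr::local_tempfile(fileext = ".fcidump")
  write_fcidump(H_ref, dump)
  eng <- withr::local_tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh",
               "while [ $# -gt 1 ]; do [ \"$1\" = \"--out\" ] && out=$2; shift; done",
               paste0("cp ", dump, " \"$out\"")), eng)
  Sys.chmod(eng, "0755")
  H <- prepare_active_space(g, sp, "sto-3g", engine = eng)
  expect_equal(casci(H, compute_variance = FALSE)$energy,
               casci(H_ref, compute_variance = FALSE)$energy, tolerance = 1e-10)
})
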