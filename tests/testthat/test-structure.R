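test_that("a minimal PDB round-trips through the parser", {
  txt <- c(pdb_line(1, "CA", "GLY", "A", 1, 1.0, 2.0, 3.0), "END")
  m <- read_structure(txt)
  expect_s3_class(m, "pdb_structure")
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$chain, "A")
  expect_equal(m$atoms$resno, 1L)
  expect_equal(unlist(m$atoms[, c("x", "y", "z")], use.names = FALSE),
               c(1, 2, 3))
})

test_that("only the first MODEL is retained and HETATM/waters are dropped", {
  txt <- c("MODEL        1",
           pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
           pdb_line(2, "O", "HOH", "A", 90, 9, 9, 9, record = "HETATM"),
           "ENDMDL",
           "MODEL        2",
           pdb_line(3, "CA", "GLY", "A", 2, 5, 5, 5),
           "ENDMDL", "END")
  m <- read_structure(txt)
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$resno, 1L)
})

test_that("alternate locations resolve to the highest occupancy", {
  txt <- c(pdb_line(1, "CA", "SER", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
           pdb_line(2, "CA", "SER", "A", 1, 9, 9, 9, occ = 0.6, alt = "B"),
           "END")
  m <- read_structure(txt)
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$x, 9)
})

test_that("malformed coordinates raise an error naming the line", {
  txt <- c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0), "END")
  substr(txt[1], 33, 36) <- "abcd"
  expect_error(read_structure(txt), "line 1")
  expect_error(read_structure("REMARK nothing here"), "no ATOM records")
})

test_that("charged residue sets depend on the pH mode", {
  atoms <- do.call(rbind, lapply(seq_along(c("HIS", "LYS", "ARG", "ASP")),
    function(i) single_atom_df(i, 0, 0, resno = i,
                               resname = c("HIS", "LYS", "ARG", "ASP")[i])))
  m <- toy_model(atoms)
  expect_setequal(charged_residue_set(m, "A", "acidic")$resname,
                  c("HIS", "LYS", "ARG"))
  expect_setequal(charged_residue_set(m, "A", "neutral")$resname,
                  c("LYS", "ARG"))
  gly <- toy_model(single_atom_df(0, 0, 0, resname = "GLY"))
  expect_equal(nrow(charged_residue_set(gly, "A", "acidic")), 0L)
  expect_error(charged_residue_set(m, "Z"), "chain 'Z'")
})

test_that("minimum residue distance is the exhaustive atom-pair minimum", {
  a <- single_atom_df(0, 0, 0)
  b <- single_atom_df(3, 4, 0)
  expect_equal(min_residue_distance(a, b), 5)           # 3-4-5 triangle
  expect_equal(min_residue_distance(a, a), 0)
  set.seed(42)
  r1 <- do.call(rbind, lapply(1:3, function(i)
    single_atom_df(rnorm(1), rnorm(1), rnorm(1), atom = paste0("C", i))))
  r2 <- do.call(rbind, lapply(1:2, function(i)
    single_atom_df(rnorm(1, 4), rnorm(1), rnorm(1), atom = paste0("C", i))))
  brute <- min(vapply(1:3, function(i) {
    min(vapply(1:2, function(j) {
      sqrt(sum((unlist(r1[i, c("x", "y", "z")]) -
                  unlist(r2[j, c("x", "y", "z")]))^2))
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(min_residue_distance(r1, r2), brute)
  expect_equal(min_residue_distance(r1, r2), min_residue_distance(r2, r1))
  expect_error(min_residue_distance(r1[0, ], r2), "no atoms")
})

test_that("distance profiles match the exhaustive double-loop oracle", {
  for (seed in 1:10) {
    m <- random_model(seed)
    charged <- charged_residue_set(m, "A", "acidic")
    if (nrow(charged) == 0) next
    dp <- distance_profile(m, "B", "A", "acidic")
    expect_equal(dp$min_distance, brute_force_profile(m, "B", "A", "acidic"),
                 tolerance = 1e-9)
  }
})

test_that("distances are translation invariant and shrink as charges are added", {
  m <- random_model(3)
  dp1 <- distance_profile(m, "B", "A", "neutral")
  dp2 <- distance_profile(m, "B", "A", "acidic")
  # acidic mode adds His to the charged set: minima can only decrease
  if (nrow(dp1) && nrow(dp2)) {
    expect_true(all(dp2$min_distance <= dp1$min_distance + 1e-12))
  }
  shifted <- m
  shifted$atoms$x <- shifted$atoms$x + 11.3
  shifted$atoms$y <- shifted$atoms$y - 2.7
  shifted$atoms$z <- shifted$atoms$z + 0.4
  dp3 <- distance_profile(shifted, "B", "A", "acidic")
  expect_equal(dp3$min_distance, dp2$min_distance, tolerance = 1e-9)
})

test_that("an empty charged set gives an advisory error", {
  m <- toy_model(rbind(single_atom_df(0, 0, 0, chain = "B"),
                       single_atom_df(5, 0, 0, chain = "A",
                                      resname = "GLY")))
  expect_error(distance_profile(m, "B", "A", "acidic"), "mode")
})
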