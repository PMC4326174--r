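test_that("PDB read-back reproduces hand-written coordinates", {
  f <- write_tmp_pdb(toy_pdb_lines())
  s <- readStructure(f)
  expect_equal(nAtoms(s), 3L)
  expect_equal(coords(s)[1, ], c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(coords(s)[2, ], c(4.5, -1.25, 0), ignore_attr = TRUE)
  a <- atomTable(s)
  expect_equal(a$name, c("CA", "CA", "CB"))
  expect_equal(a$resno, c(80L, 81L, 81L))
  expect_equal(a$chain, rep("A", 3))
})

test_that("multi-MODEL files read as first model only; trajectories keep all", {
  s1 <- toy_pdb_lines()[2:4]
  lines <- c("MODEL        1", s1, "ENDMDL",
             "MODEL        2", sub("   1\\.000", "   9.000", s1), "ENDMDL",
             "END")
  f <- write_tmp_pdb(lines)
  s <- readStructure(f)
  expect_equal(nAtoms(s), 3L)
  expect_equal(coords(s)[1, 1], 1)
  tr <- readTrajectory(f, s, timeStep = 0.5)
  expect_equal(nFrames(tr), 2L)
  expect_equal(coords(tr, 2)[1, 1], 9)
  expect_equal(frameTimes(tr), c(0, 0.5))
})

test_that("structure write/read round-trips to PDB precision", {
  toy <- buildToy(seed = 11)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(toy$structure, f)
  back <- readStructure(f)
  expect_equal(atomTable(back)[, c("name", "resname", "chain", "resno")],
               atomTable(toy$structure)[, c("name", "resname", "chain",
                                            "resno")])
  expect_lt(max(abs(coords(back) - coords(toy$structure))), 1e-3 + 1e-12)
  # second round trip is exact (coordinates already quantised)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(back, f2)
  expect_identical(coords(readStructure(f2)), coords(back))
})

test_that("trajectory round-trip matches generated coordinates to write precision", {
  toy <- buildToy(seed = 2)
  run <- generateEquilibration(toy, syntheticSpec("equilibration", seed = 2,
                                                  nFrames = 5, sigma = 0,
                                                  globalMotion = FALSE))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTrajectory(run$trajectory, f)
  back <- readTrajectory(f, toy$structure)
  expect_equal(nFrames(back), 5L)
  expect_lt(max(abs(back@coords - run$trajectory@coords)), 1e-3 + 1e-12)
})

test_that("reader errors name the offending MODEL or line", {
  s1 <- toy_pdb_lines()[2:4]
  lines <- c("MODEL        1", s1, "ENDMDL",
             "MODEL        2", s1, "ENDMDL",
             "MODEL        3", s1[1:2], "ENDMDL", "END")
  f <- write_tmp_pdb(lines)
  topo <- readStructure(f)
  expect_error(readTrajectory(f, topo), "MODEL 3")
  bad <- toy_pdb_lines()
  bad[3] <- sub("4\\.500", "4.5x0", bad[3])
  f2 <- write_tmp_pdb(bad)
  expect_error(readStructure(f2), "line 3")
  expect_error(readStructure(write_tmp_pdb(c("REMARK empty", "END"))),
               "no ATOM")
  expect_error(readStructure("/nonexistent/x.pdb"), "not found")
})

test_that("insertion codes are rejected; first altloc wins", {
  ins <- toy_pdb_lines()
  substr(ins[2], 27, 27) <- "A"
  expect_error(readStructure(write_tmp_pdb(ins)), "insertion code")
  alt <- c(
    "ATOM      1  CA AALA A  80       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA BALA A  80       9.000   9.000   9.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A  81       0.000   0.000   0.000  1.00  0.00           C",
    "END")
  s <- readStructure(write_tmp_pdb(alt))
  expect_equal(nAtoms(s), 2L)
  expect_equal(coords(s)[1, ], c(1, 2, 3), ignore_attr = TRUE)
})

test_that("selection grammar resolves documented expressions deterministically", {
  toy <- buildToy(seed = 1)
  s <- toy$structure
  expect_length(resolveSelection("resid 81-89 and name CA", s), 9L)
  expect_equal(resolveSelection("heavy", s), seq_len(nAtoms(s)))
  i1 <- resolveSelection("chain A and resid 122-141", s)
  expect_identical(i1, resolveSelection("chain A and resid 122-141", s))
  expect_equal(atomTable(s)$resno[i1], 122:141)
  # boolean structure and precedence
  expect_equal(resolveSelection("resid 81 or resid 82 and name CA", s),
               resolveSelection("resid 81 or (resid 82 and name CA)", s))
  expect_setequal(resolveSelection("not chain A", s),
                  which(atomTable(s)$chain != "A"))
  expect_length(resolveSelection("resname FUC", s), 1L)
  expect_error(resolveSelection("resid 9999", s), "matches no atoms")
  expect_error(resolveSelection("resid 81-", s), "parse error")
  expect_error(resolveSelection("chain", s), "parse error")
})

test_that("solvent predicate lets protein selections exclude water and ions", {
  a <- data.frame(serial = 1:4, name = c("CA", "O", "NA", "CA"),
                  resname = c("ALA", "HOH", "NA", "GLY"),
                  chain = "A", resno = 1:4,
                  x = as.numeric(1:4), y = 0, z = 0,
                  element = c("C", "O", "NA", "C"))
  s <- MolStructure(a)
  expect_equal(resolveSelection("not solvent", s), c(1L, 4L))
})

test_that("series writer round-trips numerics at 9 significant digits", {
  tab <- data.frame(time_ns = seq(0, 1, length.out = 11),
                    value = pi * 10^seq(-4, 6),
                    label = letters[1:11])
  f <- withr::local_tempfile(fileext = ".csv")
  writeSeries(tab, f, units = c(time_ns = "ns"))
  back <- readSeries(f)
  expect_equal(back$value / tab$value, rep(1, 11), tolerance = 1e-8)
  expect_identical(back$label, tab$label)
  expect_match(readLines(f)[1], "^# units: time_ns = ns")
  # empty table -> header only
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeSeries(tab[0, ], f2)
  expect_identical(readLines(f2), "time_ns,value,label")
  # larger series, exact numeric round trip at tolerance
  n <- 1e4
  big <- data.frame(a = stats::rnorm(n), b = stats::runif(n, -1e6, 1e6))
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeSeries(big, f3)
  b2 <- readSeries(f3)
  expect_equal(b2$a, big$a, tolerance = 1e-8)
  expect_equal(b2$b, big$b, tolerance = 1e-8)
})

test_that("nonbond parameter tables validate and cover structures", {
  toy <- buildToy(seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  writeNonbondParams(toy$params, f)
  p <- readNonbondParams(f)
  expect_equal(nrow(resolveParams(p, toy$structure)),
               nAtoms(toy$structure))
  bad <- toy$params
  bad$epsilon_kcal[1] <- -0.1
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, f2, row.names = FALSE)
  expect_error(readNonbondParams(f2), "epsilon")
  expect_error(resolveParams(toy$params[-1, ], toy$structure),
               "no nonbonded parameters")
})
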