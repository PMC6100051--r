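test_that("excitation tables round-trip losslessly", {
  x <- generateExcitations(
    data.frame(snapshot = 1:20, depth_nm = runif(20, 0.4, 1.2),
               tilt_deg = runif(20, 5, 170)),
    couplingParams(seed = 3L))
  path <- withr::local_tempfile(fileext = ".csv")
  writeExcitationTable(x, path)
  back <- readExcitationTable(path, kind = "emission")
  expect_equal(records(back), records(x), tolerance = 1e-12)
})

test_that("schema and validation errors carry useful locations", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("snapshot_id,state,energy_eV", path)  # missing column
  expect_error(readExcitationTable(path), "schema error")
  writeLines("snapshot_id,state,energy_eV,osc_strength", path)
  expect_error(readExcitationTable(path), "no data rows")
  writeLines(c("snapshot_id,state,energy_eV,osc_strength",
               "1,1,3.5,0.3",
               "2,1,3.4,-0.1"), path)
  expect_error(readExcitationTable(path), "line\\(s\\) 3")
})

test_that("the engine registry dispatches to a mock adapter", {
  fixture <- data.frame(state = 1:5,
                        energy_eV = c(3.64, 3.83, 3.95, 4.65, 5.13),
                        osc_strength = c(0.26, 0.000021, 0.062, 0.36,
                                         0.00014))
  registerEngine("mock", function(spec) {
    expect_equal(spec$functional, "PBE0")
    fixture
  })
  withr::defer(registerEngine("mock", NULL))
  expect_true("mock" %in% listEngines())
  out <- runEngine("mock", molecule = "fluorophore.xyz",
                   functional = "PBE0", basis = "cc-pVDZ")
  expect_equal(out$energy_eV, fixture$energy_eV)
  expect_equal(unique(out$functional), "PBE0")
  expect_equal(unique(out$environment), "gas")
  # point-charge runs are tagged with their environment label
  out2 <- runEngine("mock", molecule = "fluorophore.xyz",
                    pointCharges = "env.pc", environment = "membrane-charges")
  expect_equal(unique(out2$environment), "membrane-charges")
  expect_error(runEngine("absent", molecule = "x.xyz"),
               "no engine adapter registered")
})

test_that("a command-template adapter substitutes placeholders and parses CSV", {
  tmpl <- paste("printf 'state,energy_eV,osc_strength\\n1,{nstates}.5,0.3\\n'",
                "> {output}")
  registerEngine("cmd", commandEngine(tmpl))
  withr::defer(registerEngine("cmd", NULL))
  out <- runEngine("cmd", molecule = "m.xyz", nStates = 3)
  expect_equal(out$energy_eV, 3.5)
  registerEngine("bad", commandEngine("false"))
  withr::defer(registerEngine("bad", NULL))
  expect_error(runEngine("bad", molecule = "m.xyz"), "adapter error")
})

test_that("benchmark comparison flags failures and reports missing keys as untested", {
  ref <- referenceBenchmarks("gas")
  expect_true(all(c("functional", "basis", "state") %in% names(ref)))
  expect_equal(nrow(ref), 40L)
  # identical entries: everything passes
  rep1 <- compareToBenchmark(ref, ref)
  expect_true(all(rep1$status == "pass"))
  expect_equal(rep1$delta_energy_eV, rep(0, nrow(rep1)))
  # energy off by twice the tolerance fails only the perturbed key
  pert <- ref
  i <- which(pert$functional == "PBE0" & pert$basis == "cc-pVDZ" &
               pert$state == 1)
  pert$energy_eV[i] <- pert$energy_eV[i] + 0.04
  rep2 <- compareToBenchmark(pert, ref, tolEnergy = 0.02)
  expect_equal(sum(rep2$status == "fail"), 1L)
  # sign symmetry of reported deltas
  rep2b <- compareToBenchmark(ref, pert, tolEnergy = 0.02)
  expect_equal(rep2$delta_energy_eV[rep2$status == "fail"],
               -rep2b$delta_energy_eV[rep2b$status == "fail"])
  # missing states are untested, not failed
  partial <- ref[ref$state <= 3, ]
  rep3 <- compareToBenchmark(partial, ref)
  expect_true(all(rep3$status[rep3$state > 3] == "untested"))
  expect_false(any(rep3$status == "fail"))
  # disjoint keys: empty report with a warning
  other <- transform(ref, basis = "def2-TZVP")
  expect_warning(rep4 <- compareToBenchmark(other, ref), "in common")
  expect_equal(nrow(rep4), 0L)
})

test_that("energy-ordered pairing absorbs near-degenerate state swaps", {
  # the cyclohexane PBE0/cc-pVDZ S2/S3 pair lies 0.01 eV apart; an engine
  # reporting them in swapped index order must still match by energy rank
  ref <- referenceBenchmarks("cyclohexane-COSMO")
  sub <- ref[ref$functional == "PBE0" & ref$basis == "cc-pVDZ", ]
  swapped <- sub
  swapped$state[swapped$state == 2] <- 99L
  swapped$state[swapped$state == 3] <- 2L
  swapped$state[swapped$state == 99L] <- 3L
  byIndex <- compareToBenchmark(swapped, sub, stateMatching = "index")
  expect_true(any(byIndex$status == "fail"))
  byEnergy <- compareToBenchmark(swapped, sub, stateMatching = "energy")
  expect_true(all(byEnergy$status == "pass"))
  # idempotence: comparing twice gives the same report
  expect_identical(byEnergy, compareToBenchmark(swapped, sub,
                                                stateMatching = "energy"))
})
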