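toy <- buildToy(seed = 10)
sel <- toy$selections

test_that("force axis runs from the fixed end to the pulled atom, unit length", {
  a <- data.frame(serial = 1:3, name = c("CA", "CA", "CA"),
                  resname = "GLY", chain = c("A", "A", "B"),
                  resno = 1:3,
                  x = c(0, 1, 0), y = c(0, 1, 0), z = c(0, 2, 10),
                  element = "C")
  s <- MolStructure(a)
  tr <- as_traj(s)
  up <- PullingSetup("chain A and resid 1", "chain B", mode = "cf")
  expect_equal(forceAxis(up, tr), c(0, 0, 1))
  down <- PullingSetup("chain B", "chain A and resid 1", mode = "cf")
  expect_equal(forceAxis(down, tr), c(0, 0, -1))
  withr::with_seed(30, {
    a$x <- stats::rnorm(3); a$y <- stats::rnorm(3); a$z <- c(0, 1, 9)
    tr2 <- as_traj(MolStructure(a))
    expect_equal(sqrt(sum(forceAxis(up, tr2)^2)), 1, tolerance = 1e-12)
  })
  expect_error(forceAxis(PullingSetup("chain A", "chain A", mode = "cf"),
                         tr), "exactly one atom")
})

test_that("extension is the axis projection of the pulled-atom displacement", {
  setup <- PullingSetup(sel[["fixedEnd"]], sel[["pulled"]], mode = "cf")
  tr <- as_traj(toy$structure, nframes = 3)
  axis <- forceAxis(setup, tr)
  pulled <- resolveSelection(sel[["pulled"]], toy$structure)
  m <- tr@coords
  m[2, (3 * pulled - 2):(3 * pulled)] <-
    m[2, (3 * pulled - 2):(3 * pulled)] + 5 * axis
  # frame 3: displacement perpendicular to the axis projects to zero
  perp <- c(-axis[2], axis[1], 0); perp <- perp / sqrt(sum(perp^2))
  m[3, (3 * pulled - 2):(3 * pulled)] <-
    m[3, (3 * pulled - 2):(3 * pulled)] + 4 * perp
  tr@coords <- m
  ext <- extensionSeries(tr, setup)
  expect_equal(ext$extension_A, c(0, 5, 0), tolerance = 1e-9)
})

test_that("separation projects centre differences and ignores perpendicular shifts", {
  axis <- c(0, 0, 1)
  a <- data.frame(serial = 1:4, name = paste0("C", 1:4),
                  resname = c("AAA", "AAA", "BBB", "BBB"),
                  chain = c("A", "A", "B", "B"), resno = c(1, 1, 2, 2),
                  x = c(0, 2, 1, 1), y = c(0, 0, 3, -3),
                  z = c(0, 0, 30, 30), element = "C")
  s <- MolStructure(a)
  tr <- as_traj(s)
  expect_equal(separationSeries(tr, "chain A", "chain B",
                                axis)$separation_A, 30)
  # coincident centres
  a2 <- a; a2$z <- 0
  expect_equal(separationSeries(as_traj(MolStructure(a2)), "chain A",
                                "chain B", axis)$separation_A, 0)
  # translate both groups perpendicular to the axis: unchanged
  a3 <- a; a3$x <- a3$x + 17; a3$y <- a3$y - 4
  expect_equal(separationSeries(as_traj(MolStructure(a3)), "chain A",
                                "chain B", axis)$separation_A, 30)
})

test_that("marker distances are Euclidean and obey the triangle inequality", {
  a <- data.frame(serial = 1:3, name = c("C1", "CA", "N1"),
                  resname = c("FUC", "CAL", "XXX"),
                  chain = c("B", "C", "D"), resno = 1:3,
                  x = c(0, 3, 1), y = c(0, 4, -2), z = c(0, 0, 2),
                  element = c("C", "CA", "N"))
  tr <- as_traj(MolStructure(a))
  expect_equal(markerDistanceSeries(tr, "resname FUC",
                                    "resname CAL")$distance_A, 5)
  expect_equal(markerDistanceSeries(tr, "resname FUC",
                                    "resname FUC")$distance_A, 0)
  dAB <- markerDistanceSeries(tr, "resname FUC", "resname CAL")$distance_A
  dAC <- markerDistanceSeries(tr, "resname FUC", "resname XXX")$distance_A
  dCB <- markerDistanceSeries(tr, "resname XXX", "resname CAL")$distance_A
  expect_lte(dAB, dAC + dCB)
})

test_that("dissociation time finds the first persistent zero of the energy", {
  # constructed trace: zeros persist from the 4th frame on
  prof <- EnergyProfile(times = (0:4) * 0.1,
                        vdw = c(-50, -20, -5, 0, 0),
                        elec = rep(0, 5))
  ev <- dissociationTime(prof, zeroTol = 0.1, persistence = 2)
  expect_equal(ev$frame, 4L)
  expect_equal(ev$time_ns, 0.3)
  # never zero -> no event
  flat <- EnergyProfile((0:9) * 0.1, rep(-30, 10), rep(0, 10))
  expect_null(dissociationTime(flat))
  # a spike back out of tolerance restarts the persistence clock
  spiky <- EnergyProfile((0:9) * 0.1,
                         c(-40, -10, 0, 0, -2, 0, 0, 0, 0, 0),
                         rep(0, 10))
  ev2 <- dissociationTime(spiky, zeroTol = 0.5, persistence = 3)
  expect_equal(ev2$frame, 6L)
  # monotone in tolerance: larger zeroTol never gives a later event
  withr::with_seed(40, {
    for (k in 1:10) {
      e <- -stats::runif(30, 0, 5) * rev(seq(0, 1, length.out = 30))
      pr <- EnergyProfile((0:29) * 0.1, e, rep(0, 30))
      f1 <- dissociationTime(pr, zeroTol = 0.2, persistence = 3)
      f2 <- dissociationTime(pr, zeroTol = 1.0, persistence = 3)
      if (!is.null(f1)) {
        expect_false(is.null(f2))
        expect_lte(f2$frame, f1$frame)
      }
    }
  })
  expect_error(dissociationTime(EnergyProfile(numeric(0), numeric(0),
                                              numeric(0))), "empty")
})

test_that("force-profile features return the earliest global peak", {
  expect_equal(forceProfileFeatures(1:5, (1:5) * 2),
               c(peak_force_pN = 5, peak_extension_A = 10,
                 peak_frame = 5))
  f <- c(10, 50, 200, 60, 20)
  x <- c(0, 5, 11, 20, 30)
  expect_equal(forceProfileFeatures(f, x)[["peak_extension_A"]], 11)
  tie <- c(1, 7, 3, 7, 2)
  expect_equal(forceProfileFeatures(tie, 1:5)[["peak_frame"]], 2)
  expect_error(forceProfileFeatures(1:3, 1:4), "equal length")
})

test_that("replicate statistics use the sample SD and ignore order", {
  expect_equal(replicateStatistics(c(4, 4, 4))[c("mean", "sd")],
               c(mean = 4, sd = 0))
  st <- replicateStatistics(c(3, 5))
  expect_equal(st[["mean"]], 4)
  expect_equal(st[["sd"]], sqrt(2), tolerance = 1e-12)
  expect_equal(replicateStatistics(c(5, 3)), st)
  expect_true(is.na(replicateStatistics(7)[["sd"]]))
  expect_error(replicateStatistics(numeric(0)), "at least one")
})

test_that("unbinding summary reports the event with its extension and separation context", {
  spec <- syntheticSpec("cv", seed = 10)
  run <- generateDissociation(toy, spec)
  setup <- PullingSetup(sel[["fixedEnd"]], sel[["pulled"]], mode = "cv")
  ext <- extensionSeries(run$trajectory, setup)
  axis <- forceAxis(setup, run$trajectory)
  sep <- separationSeries(run$trajectory, sel[["lecDomain"]],
                          sel[["ligand"]], axis)
  prof <- groupEnergySeries(run$trajectory, sel[["receptor"]],
                            sel[["ligand"]], toy$params)
  ev <- unbindingSummary(prof, ext, sep)
  expect_equal(ev$frame, run$truth$event_frame)
  expect_equal(ev$time_ns, run$truth$event_time_ns)
  expect_equal(ev$extension_at_event_A,
               run$truth$extension_A[run$truth$event_frame],
               tolerance = 1e-9)
  # extension at the event exceeds the separation-onset extension
  expect_gte(ev$extension_at_event_A,
             run$truth$separation_onset_extension_A)
})
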