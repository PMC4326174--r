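scheme <- CutoffScheme(10, 12)

test_that("switching function hits its boundaries and the frozen midpoint value", {
  expect_identical(switchingFunction(10, scheme), 1)
  expect_identical(switchingFunction(12, scheme), 0)
  expect_identical(switchingFunction(13, scheme), 0)
  expect_identical(switchingFunction(0, scheme), 1)
  # r = 11: exact rational evaluation of the polynomial,
  # (144-121)^2 * (144 + 242 - 300) / (144-100)^3 = 529*86 / 44^3
  expect_equal(switchingFunction(11, scheme), 45494 / 85184,
               tolerance = 1e-14)
  s <- switchingFunction(seq(0, 13, by = 0.01), scheme)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("switching is C1-continuous at both cutoff boundaries", {
  h <- 1e-5
  for (r0 in c(scheme@rOn, scheme@rOff)) {
    left <- (switchingFunction(r0, scheme) -
             switchingFunction(r0 - h, scheme)) / h
    right <- (switchingFunction(r0 + h, scheme) -
              switchingFunction(r0, scheme)) / h
    expect_equal(left, right, tolerance = 1e-4)
    expect_equal(switchingFunction(r0 - 1e-9, scheme),
                 switchingFunction(r0 + 1e-9, scheme), tolerance = 1e-7)
  }
})

p_row <- function(q, eps, rmin2)
  data.frame(charge_e = q, epsilon_kcal = eps, rmin_half_A = rmin2)

test_that("pair energy reproduces the LJ minimum and Coulomb closed forms", {
  # uncharged pair at its Rmin (inside rOn): vdw = -eps exactly
  pa <- p_row(0, 0.2, 2.1); pb <- p_row(0, 0.05, 1.9)
  e <- pairEnergy(c(0, 0, 0), c(4.0, 0, 0), pa, pb, scheme)
  expect_equal(e[["vdw"]], -sqrt(0.2 * 0.05), tolerance = 1e-12)
  expect_identical(e[["elec"]], 0)
  # beyond cutoff: exactly zero
  expect_identical(pairEnergy(c(0, 0, 0), c(13, 0, 0), pa, pb, scheme),
                   c(vdw = 0, elec = 0))
  # unit charges, no LJ, 5 A: elec = 332.0636 / 5
  pc <- p_row(1, 0, 1); pd <- p_row(1, 0, 1)
  e2 <- pairEnergy(c(0, 0, 0), c(0, 0, 5), pc, pd, scheme)
  expect_equal(e2[["elec"]], 332.0636 / 5, tolerance = 1e-12)
  expect_identical(e2[["vdw"]], 0)
  expect_error(pairEnergy(c(0, 0, 0), c(0, 0, 1e-8), pa, pb, scheme),
               "coincident")
})

test_that("unswitched electrostatics remain available as an option", {
  pc <- p_row(1, 0, 1); pd <- p_row(-1, 0, 1)
  r <- 11
  sw <- pairEnergy(c(0, 0, 0), c(r, 0, 0), pc, pd, scheme)
  un <- pairEnergy(c(0, 0, 0), c(r, 0, 0), pc, pd, scheme,
                   switchElec = FALSE)
  expect_equal(un[["elec"]], -332.0636 / r, tolerance = 1e-12)
  expect_equal(sw[["elec"]], un[["elec"]] * switchingFunction(r, scheme),
               tolerance = 1e-12)
})

test_that("monotone decay: |elec| decreases with distance inside the cutoff", {
  pc <- p_row(1, 0, 1); pd <- p_row(-1, 0, 1)
  rs <- seq(0.5, 12, by = 0.25)
  es <- vapply(rs, function(r)
    pairEnergy(c(0, 0, 0), c(r, 0, 0), pc, pd, scheme)[["elec"]],
    numeric(1))
  expect_true(all(diff(abs(es)) < 0))
})

test_that("group energy matches the direct double-sum oracle, symmetry and additivity", {
  withr::with_seed(77, {
    for (rep in 1:3) {
      sys <- make_random_system(7, 5)
      st <- random_system_traj(sys)
      prof <- groupEnergySeries(st$traj, "chain A", "chain B", st$params,
                                scheme)
      orc <- oracle_group_energy(sys$xyzA, sys$xyzB, sys$pa, sys$pb,
                                 scheme)
      expect_equal(prof@vdw, orc[["vdw"]], tolerance = 1e-10)
      expect_equal(prof@elec, orc[["elec"]], tolerance = 1e-10)
      expect_equal(prof@total, prof@vdw + prof@elec)
      # symmetry E(A,B) = E(B,A)
      rev <- groupEnergySeries(st$traj, "chain B", "chain A", st$params,
                               scheme)
      expect_equal(rev@total, prof@total, tolerance = 1e-12)
      # additivity over a partition of A
      e1 <- groupEnergySeries(st$traj, "resid 1-3", "chain B",
                              st$params, scheme)
      e2 <- groupEnergySeries(st$traj, "resid 4-7", "chain B",
                              st$params, scheme)
      expect_equal(e1@total + e2@total, prof@total, tolerance = 1e-10)
    }
  })
})

test_that("group energy is zero beyond the cutoff, rigid-motion invariant, and guards overlap", {
  withr::with_seed(78, {
    sys <- make_random_system(6, 4)
    sys$xyzB <- sys$xyzB + 40                 # move B out of range
    st <- random_system_traj(sys)
    prof <- groupEnergySeries(st$traj, "chain A", "chain B", st$params,
                              scheme)
    expect_identical(prof@total, 0)
    # rigid-motion invariance
    sys2 <- make_random_system(6, 4)
    st2 <- random_system_traj(sys2)
    base <- groupEnergySeries(st2$traj, "chain A", "chain B", st2$params,
                              scheme)
    for (k in 1:5) {
      tr <- transform_traj(st2$traj, random_rotation(),
                           stats::runif(3, -50, 50))
      moved <- groupEnergySeries(tr, "chain A", "chain B", st2$params,
                                 scheme)
      expect_equal(moved@total, base@total, tolerance = 1e-9)
      expect_equal(moved@vdw, base@vdw, tolerance = 1e-9)
    }
    expect_error(groupEnergySeries(st2$traj, "chain A", "all",
                                   st2$params, scheme), "disjoint")
  })
})

test_that("single-atom groups reduce to the pair energy", {
  withr::with_seed(79, {
    sys <- make_random_system(1, 1)
    st <- random_system_traj(sys)
    prof <- groupEnergySeries(st$traj, "chain A", "chain B", st$params,
                              scheme)
    e <- pairEnergy(sys$xyzA[1, ], sys$xyzB[1, ], sys$pa, sys$pb, scheme)
    expect_equal(c(vdw = prof@vdw, elec = prof@elec), e,
                 tolerance = 1e-12)
  })
})

test_that("hinge energies average within trajectories first, then across them", {
  toy <- buildToy(seed = 6)
  doms <- c(lec = "chain A and resid 81-120",
            egf = "chain A and resid 121-158")
  # two constant 'trajectories' built by rigid displacement of the EGF
  tr1 <- as_traj(toy$structure, nframes = 3)
  a2 <- atomTable(toy$structure)
  idx <- resolveSelection("chain A and resid 121-158", toy$structure)
  a2$z[idx] <- a2$z[idx] + 1.0
  tr2 <- as_traj(MolStructure(a2), nframes = 2)
  one <- hingeEnergyTable(list(tr1), doms, toy$params)
  expect_equal(one$n_traj, 1L)
  expect_true(is.na(one$sd_kcal))
  m1 <- mean(groupEnergySeries(tr1, doms[["lec"]], doms[["egf"]],
                               toy$params)@total)
  m2 <- mean(groupEnergySeries(tr2, doms[["lec"]], doms[["egf"]],
                               toy$params)@total)
  both <- hingeEnergyTable(list(tr1, tr2), doms, toy$params)
  expect_equal(both$mean_kcal, (m1 + m2) / 2, tolerance = 1e-12)
  expect_equal(both$sd_kcal, abs(m1 - m2) / sqrt(2), tolerance = 1e-9)
  # permuting trajectory order leaves the result unchanged
  perm <- hingeEnergyTable(list(tr2, tr1), doms, toy$params)
  expect_equal(perm$mean_kcal, both$mean_kcal)
  expect_equal(perm$sd_kcal, both$sd_kcal)
  expect_error(hingeEnergyTable(list(tr1), doms[1], toy$params),
               "at least 2")
})
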