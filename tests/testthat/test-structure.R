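# Helix assignment, propensity/capping checks, disulfides, salt bridges.

test_that("an ideal helix yields one segment covering the core; strands none", {
  h <- assign_helices(fix_helix15())
  expect_equal(nrow(h), 1)
  expect_lte(h$start, 3)
  expect_gte(h$end, 13)
  s <- assign_helices(build_ideal_peptide(strrep("A", 15), "strand"))
  expect_equal(nrow(s), 0)
})

test_that("two helices separated by a loop give two segments", {
  nh <- 12
  phi <- c(rep(-57, nh), rep(-135, 6), rep(-57, nh))
  psi <- c(rep(-47, nh), rep(135, 6), rep(-47, nh))
  p <- build_ideal_peptide(strrep("A", 2 * nh + 6), "custom",
                           phi = phi, psi = psi)
  h <- assign_helices(p)
  expect_equal(nrow(h), 2)
  expect_lt(h$end[1], nh + 4)
  expect_gt(h$start[2], nh + 3)
})

test_that("helix assignment is deterministic", {
  p <- fix_helix15()
  expect_identical(assign_helices(p), assign_helices(p))
})

test_that("propensity delta applies only deep inside helices and antisymmetrizes", {
  h <- data.frame(chain = "A", start = 2L, end = 20L)
  expect_equal(propensity_delta("A:A11P", h), 13.22)
  expect_equal(propensity_delta("A:A11G", h), 4.18)
  expect_equal(propensity_delta("A:A4P", h), 0)    # < 5 from the N terminus
  expect_equal(propensity_delta("A:A18P", h), 0)   # < 5 from the C terminus
  expect_equal(propensity_delta("A:A25P", h), 0)   # outside the helix
  expect_equal(propensity_delta("A:G11A", h), -propensity_delta("A:A11G", h))
  expect_error(propensity_delta("A:A11Z", h), "cover")
})

test_that("capping disruption flags terminal motif losses only", {
  h <- data.frame(chain = "A", start = 10L, end = 30L)
  expect_true(capping_check("A:N9L", h))     # N-cap Asn lost
  expect_true(capping_check("A:G31A", h))    # C-cap Gly lost
  expect_false(capping_check("A:N9D", h))    # role preserved
  expect_false(capping_check("A:N20L", h))   # mid-helix
  expect_false(capping_check("A:L9F", h))    # wild type held no role
})

test_that("disulfides count from bond records or close SG pairs", {
  atoms <- data.frame(name = rep(c("CB", "SG"), 2), element = rep(c("C", "S"), 2),
                      resno = rep(c(1L, 5L), each = 2), resname = "CYS",
                      chain = "A")
  near <- rbind(c(0, 0, 0), c(1.8, 0, 0), c(5, 1.8, 0), c(3.85, 0, 0))
  bonds <- rbind(c(1L, 2L), c(3L, 4L), c(2L, 4L))
  with_bond <- structure_ensemble(atoms, bonds, list(near))
  expect_equal(disulfide_count(with_bond), 1)
  # no SG-SG bond record: fall back to the 2.3 A distance criterion
  no_rec <- structure_ensemble(atoms, rbind(c(1L, 2L), c(3L, 4L)), list(near))
  expect_equal(disulfide_count(no_rec), 1)
  far <- near; far[4, 1] <- 7
  apart <- structure_ensemble(atoms, rbind(c(1L, 2L), c(3L, 4L)), list(far))
  expect_equal(disulfide_count(apart), 0)
})

test_that("salt bridges use a strict 4 A residue-pair criterion, frame-averaged", {
  expect_equal(salt_bridge_count(build_salt_bridge_toy(3.5)), 1)
  expect_equal(salt_bridge_count(build_salt_bridge_toy(4.0)), 0)
  expect_equal(salt_bridge_count(build_salt_bridge_toy(3.9)), 1)
  expect_equal(salt_bridge_count(build_salt_bridge_toy(4.1)), 0)
  # present in half of the frames
  expect_equal(salt_bridge_count(build_salt_bridge_toy(3.5, 4, 2)), 0.5)
  # bidentate contacts still count once per residue pair
  toy <- build_salt_bridge_toy(3.0)
  toy$frames[[1]][3, ] <- toy$frames[[1]][5, ] + c(-3.0, 0.3, 0)  # OD2 close too
  expect_equal(salt_bridge_count(toy), 1)
})

test_that("salt-bridge counting is invariant to rigid-body motion", {
  toy <- build_salt_bridge_toy(3.7, 3)
  th <- 0.8
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  toy2 <- toy
  toy2$frames <- lapply(toy$frames, function(f) f %*% R + 5)
  expect_equal(salt_bridge_count(toy), salt_bridge_count(toy2))
})
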