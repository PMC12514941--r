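# Hydrogen-bond detection, ramp energetics, filtering/capping, water bridges
# and unsatisfied-partner counting.

test_that("ramp energy matches hand-evaluated values", {
  expect_equal(hbond_energy(2.0, 180, 120, FALSE), 25)
  expect_equal(hbond_energy(2.35, 132.5, 90, FALSE), 25 * 0.5^3)
  expect_equal(hbond_energy(2.6, 180, 120, FALSE), 0)
  # no acceptor neighbors -> unhindered
  expect_equal(hbond_energy(2.0, 180), 25)
  # hydrogen neighbors use the softer 75-85 ramp
  expect_equal(hbond_energy(2.0, 180, 80, TRUE), 25 * 0.5)
  expect_equal(hbond_energy(2.0, 180, 80, FALSE), 0)
  # several neighbors: the most hindering one wins
  expect_equal(hbond_energy(2.0, 180, c(120, 90), c(FALSE, FALSE)), 12.5)
})

test_that("energy is monotone in geometry and bounded", {
  set.seed(7)
  for (i in 1:200) {
    d <- runif(1, 1.6, 3.0); a <- runif(1, 100, 180); x <- runif(1, 70, 140)
    e <- hbond_energy(d, a, x, sample(c(TRUE, FALSE), 1))
    expect_gte(e, 0); expect_lte(e, 25)
    expect_lte(hbond_energy(d + 0.1, a, x, FALSE), hbond_energy(d, a, x, FALSE))
    expect_gte(hbond_energy(d, min(a + 5, 180), x, FALSE),
               hbond_energy(d, a, x, FALSE))
  }
})

test_that("detection applies the lenient distance and angle cutoffs", {
  pass <- build_hbond_toy(2.4, 120, 120, FALSE)   # D-A 3.4 A via construction?
  cand <- detect_candidate_hbonds(pass, 1)
  expect_equal(nrow(cand), 1)
  # angle below 100 rejected
  low <- build_hbond_toy(2.0, 99, 120, FALSE)
  expect_equal(nrow(detect_candidate_hbonds(low, 1)), 0)
  # D-A beyond 3.5 rejected (linear arrangement: D-A = 1.01 + dist_HA)
  far <- build_hbond_toy(2.6, 180, 120, FALSE)
  expect_equal(nrow(detect_candidate_hbonds(far, 1)), 0)
  near <- build_hbond_toy(2.4, 180, 120, FALSE)
  expect_equal(nrow(detect_candidate_hbonds(near, 1)), 1)
  # hydrogen-free topologies are rejected outright
  noh <- build_salt_bridge_toy(3.5)
  noh$atoms <- noh$atoms[noh$atoms$element != "H", ]
  noh$frames <- list(noh$frames[[1]][1:5, ])
  noh$bonds <- noh$bonds[noh$bonds[, 1] <= 5 & noh$bonds[, 2] <= 5, , drop = FALSE]
  expect_error(detect_candidate_hbonds(noh, 1), "no hydrogens")
})

test_that("filtering discards the 6.25 boundary and caps bifurcated bonds", {
  mk <- function(e) data.frame(donor = 1L, hydrogen = 2L, acceptor = 3L,
                               dist_HA = 2, dist_DA = 3, angle_DHA = 180,
                               water = FALSE, energy = e)
  expect_equal(nrow(filter_and_cap(mk(6.25))), 0)     # boundary not retained
  expect_equal(filter_and_cap(mk(7))$energy, 7)       # single bond untouched
  bi <- build_bifurcated_toy(2.0, 170)
  ret <- filter_and_cap(score_hbonds(bi, detect_candidate_hbonds(bi, 1), 1))
  expect_equal(sort(ret$energy), c(15, 25))
  # ties broken deterministically by atom-index order
  two <- rbind(mk(10), transform(mk(10), acceptor = 4L))
  capped <- filter_and_cap(two)
  expect_equal(capped$energy, c(10, 10))   # both under the cap: unchanged
})

test_that("retained bond sets match a brute-force triple enumeration", {
  # independent oracle: enumerate all (D,H,A) triples and re-derive the
  # ramps/cutoffs from scratch on small systems
  brute <- function(ens, frame) {
    a <- ens$atoms; xyz <- ens$frames[[frame]]
    b <- ens$bonds
    nb <- function(i) setdiff(as.vector(b[b[, 1] == i | b[, 2] == i, ]), i)
    polar <- which(a$element %in% c("N", "O", "S"))
    out <- character(0)
    for (d in polar) for (h in nb(d)) for (acc in polar) {
      if (a$element[h] != "H" || acc == d || acc %in% nb(d) || acc %in% nb(h))
        next
      if (sqrt(sum((xyz[d, ] - xyz[acc, ])^2)) > 3.5) next
      ang <- angle3(xyz[d, ], xyz[h, ], xyz[acc, ])
      if (ang < 100) next
      dha <- sqrt(sum((xyz[h, ] - xyz[acc, ])^2))
      sha <- min(1, max(0, (2.6 - max(dha, 2.1)) / 0.5))
      sdha <- min(1, max(0, (min(ang, 165) - 100) / 65))
      shax <- 1
      for (x in nb(acc)) {
        if (x == h) next
        hax <- angle3(xyz[h, ], xyz[acc, ], xyz[x, ])
        lo <- if (a$element[x] == "H") 75 else 85
        s <- min(1, max(0, (min(hax, lo + 10) - lo) / 10))
        shax <- min(shax, s)
      }
      if (25 * sha * sdha * shax > 6.25)
        out <- c(out, paste(d, h, acc))
    }
    sort(out)
  }
  toys <- list(build_hbond_toy(2.0, 180, 120, FALSE),
               build_hbond_toy(2.4, 140, 100, TRUE),
               build_bifurcated_toy(2.0, 170),
               build_water_bridge_toy(2.0, 2),
               build_hbond_toy(2.55, 160, 90, FALSE))
  for (toy in toys) {
    ret <- filter_and_cap(score_hbonds(toy, detect_candidate_hbonds(toy, 1), 1))
    got <- sort(paste(ret$donor, ret$hydrogen, ret$acceptor))
    expect_equal(got, brute(toy, 1), info = toy$variant_id)
  }
})

test_that("water bridges sum member energies minus the desolvation penalty", {
  wb <- build_water_bridge_toy(2.0, 2)
  ret <- filter_and_cap(score_hbonds(wb, detect_candidate_hbonds(wb, 1), 1))
  br <- find_water_bridges(wb, ret)
  expect_equal(nrow(br), 1)
  expect_equal(br$energy, 2 * 25 - 32.2)
  # negative bridge energies floor at zero (two ~7 kJ/mol members)
  weak <- build_water_bridge_toy(2.46, 2)
  retw <- filter_and_cap(score_hbonds(weak, detect_candidate_hbonds(weak, 1), 1))
  brw <- find_water_bridges(weak, retw)
  expect_equal(brw$energy, 0)
  # a water with a single protein bond is not a bridge
  one <- build_water_bridge_toy(2.0, 1)
  ret1 <- filter_and_cap(score_hbonds(one, detect_candidate_hbonds(one, 1), 1))
  expect_equal(nrow(find_water_bridges(one, ret1)), 0)
})

test_that("unsatisfied counting respects filtering and both partner definitions", {
  toy <- build_hbond_toy(2.0, 180, 120, FALSE)   # retained bond
  sel <- protein_atoms(toy)
  s <- frame_hbond_summary(toy, 1, sel)
  # engaged: donor N, its H, acceptor O; unsatisfied: none of those
  expect_equal(s$unsatisfied, 0)
  weak <- build_hbond_toy(2.5, 120, 120, FALSE)  # detected but filtered out
  sw <- frame_hbond_summary(weak, 1, protein_atoms(weak))
  # donor N + bound H + acceptor O all unsatisfied under the polar definition
  expect_equal(sw$unsatisfied, 3)
  # strict definition: only O and H-free N count as potential partners
  expect_equal(unsatisfied_count(weak, sw$retained, protein_atoms(weak),
                                 definition = "strict"), 1)
})

test_that("metric deltas are zero on self-comparison and frame-average bonds", {
  toy <- build_hbond_toy(2.0, 180, 120, FALSE)
  self <- hbond_metric_deltas(toy, toy, "A:N1A", "residue")
  expect_equal(unname(self), c(0, 0))
  # bond present in half the frames averages to half the ideal energy
  on <- toy
  off <- toy; off$frames[[1]][3:4, 1] <- off$frames[[1]][3:4, 1] + 20
  half <- toy; half$frames <- list(on$frames[[1]], off$frames[[1]])
  none <- toy; none$frames <- list(off$frames[[1]], off$frames[[1]])
  d <- hbond_metric_deltas(half, none, "A:N1A", "residue")
  expect_equal(unname(d["d_energy"]), 12.5)
})
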