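# Core ensemble container, PDB round trips, selections, frame averaging.

test_that("multi-model round trip preserves atoms, bonds, frames and replicates", {
  p <- fix_helix15()
  tr <- jitter_trajectory(p, 6, 0.05, seed = 3, n_replicates = 2)
  expect_equal(tr$replicate_ends, c(3L, 6L))
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(tr, tf)
  back <- load_ensemble(tf)
  expect_equal(n_frames(back), 6)
  expect_equal(back$replicate_ends, c(3L, 6L))
  expect_equal(back$atoms$name, tr$atoms$name)
  expect_equal(back$atoms$resno, tr$atoms$resno)
  key <- function(b) unique(paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2])))
  expect_setequal(key(back$bonds), key(tr$bonds))
  expect_lt(max(abs(back$frames[[4]] - tr$frames[[4]])), 1e-3)
})

test_that("trajectory files concatenate as replicates; model count = frame count", {
  p <- fix_helix15()
  t1 <- withr::local_tempfile(fileext = ".pdb")
  t2 <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(jitter_trajectory(p, 3, 0.02, seed = 1), t1)
  write_ensemble(jitter_trajectory(p, 2, 0.02, seed = 2), t2)
  ens <- load_ensemble(t1, t2)
  expect_equal(n_frames(ens), 5)
  expect_equal(ens$replicate_ends, c(3L, 5L))
})

test_that("atom-count mismatches and missing bonds are format errors", {
  t1 <- withr::local_tempfile(fileext = ".pdb")
  t2 <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(fix_helix15(), t1)
  write_ensemble(build_ideal_peptide("AAAA", "helix"), t2)
  expect_error(load_ensemble(t1, t2), "atoms")
  # strip the CONECT records
  t3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(grep("^CONECT", readLines(t1), value = TRUE, invert = TRUE), t3)
  expect_error(load_ensemble(t3), "bond")
})

test_that("frame validation rejects ragged coordinates", {
  p <- fix_helix15()
  bad <- p$frames[[1]][-1, ]
  expect_error(structure_ensemble(p$atoms, p$bonds, list(bad)),
               "coordinate triple per atom")
})

test_that("surrounding selection respects the radius and nests across levels", {
  # two short strands, second placed at a controlled distance from the first
  a <- build_ideal_peptide("AKA", "strand")
  width <- diff(range(a$frames[[1]][, 1]))
  shift <- function(ens, dx, dresno) {
    ens$frames[[1]][, 1] <- ens$frames[[1]][, 1] + dx
    ens$atoms$resno <- ens$atoms$resno + dresno
    ens
  }
  combine <- function(e1, e2) {
    structure_ensemble(rbind(e1$atoms, e2$atoms),
                       rbind(e1$bonds, e2$bonds + nrow(e1$atoms)),
                       list(rbind(e1$frames[[1]], e2$frames[[1]])))
  }
  site <- a$frames[[1]][a$atoms$resno == 2, , drop = FALSE]
  min_dist <- function(dx) {
    other <- a$frames[[1]]; other[, 1] <- other[, 1] + dx
    min(as.matrix(stats::dist(rbind(site, other)))[seq_len(nrow(site)),
                                                   -seq_len(nrow(site))])
  }
  gap_for <- function(d) {   # solve for the shift giving min distance d
    lo <- width; hi <- width + 2 * d
    for (i in 1:50) {
      mid <- (lo + hi) / 2
      if (min_dist(mid) < d) lo <- mid else hi <- mid
    }
    hi
  }
  for (case in list(list(d = 7.9, inside = TRUE), list(d = 8.1, inside = FALSE))) {
    dx <- gap_for(case$d) + if (case$inside) -0.02 else 0.02
    ens <- combine(a, shift(a, dx, 10L))
    sel <- select_atoms(ens, "A:K2A", "surrounding", radius = 8.0)
    far_res <- unique(ens$atoms$resno[sel][ens$atoms$resno[sel] > 10])
    if (case$inside) expect_true(11 %in% far_res) else
      expect_false(11 %in% far_res)
    res_sel <- select_atoms(ens, "A:K2A", "residue")
    whole <- select_atoms(ens, "A:K2A", "whole_protein")
    expect_true(all(res_sel %in% sel))
    expect_true(all(sel %in% whole))
    expect_length(whole, sum(!ens$atoms$is_water))
  }
})

test_that("unknown positions and malformed mutation specs error", {
  p <- fix_helix15()
  expect_error(select_atoms(p, "A:A99G", "residue"), "not found")
  expect_error(parse_mutation("A:A5"), "cannot parse")
  expect_error(parse_mutation("A:A5A"), "must differ")
  expect_error(select_atoms(p, "A:K5G", "residue"), "mutation says")
})

test_that("frame averaging is the plain mean over all replicate frames", {
  expect_equal(frame_average(c(2, 4)), 3)
  expect_equal(frame_average(rep(7.5, 9)), 7.5)
  set.seed(1)
  v <- rnorm(50)   # 5 replicates x 10 frames, concatenated
  expect_equal(frame_average(v), mean(v))
  expect_error(frame_average(numeric(0)), "at least one")
})
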