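# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

fix_curves <- function() memo("curves", {
  build_benchmark_curves(build_benchmark_samples(n = 30, seed = 42))
})

fix_helix15 <- function() memo("helix15", {
  build_ideal_peptide(strrep("A", 15), "helix")
})

fix_wt_traj <- function() memo("wt_traj", {
  jitter_trajectory(build_ideal_peptide("AAKAAAAEAAAA", "helix"),
                    n_frames = 3, amplitude = 0.05, seed = 11)
})

# an independent plain-R trapezoid AUC used as an oracle in several tests
oracle_auc_mw <- function(score, is_pos) {
  sp <- score[is_pos]; sn <- score[!is_pos]
  mean(outer(sp, sn, ">") + 0.5 * outer(sp, sn, "=="))
}
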