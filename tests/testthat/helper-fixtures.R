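# shared fixtures built in code

two_task_paradigm <- function(n_volumes = 360) {
  make_block_paradigm(c("A", "B"), task_s = 4, rest_s = 20, tr = 2,
                      n_volumes = n_volumes)
}

two_task_design <- function(n_volumes = 360) {
  build_design_matrix(two_task_paradigm(n_volumes), double_gamma_hrf(2))
}

# noiseless per-level generator for a halving profile
noiseless_subject <- function(profile, baseline = 100) {
  X <- build_design_matrix(halving_paradigm(), double_gamma_hrf(2))
  function(level) baseline + profile$amplitude_by_level[level] * X[, "task"]
}

# brute-force GLS via explicit V inversion (independent oracle)
gls_oracle <- function(X, y, V) {
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  list(beta = drop(b), rss = drop(t(r) %*% Vi %*% r))
}
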