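# shared fixtures, built in code at test time

# compact 3-shell scheme for fit tests (dense enough for stable powder means)
test_scheme <- function(n_per_shell = 40, n_b0 = 3) {
  default_scheme(n_per_shell = n_per_shell, n_b0 = n_b0)
}

# brute-force pair-counting prediction strength (independent oracle)
bf_pair_score <- function(test_clusters, train_assign) {
  scores <- numeric(0)
  for (j in unique(test_clusters)) {
    idx <- which(test_clusters == j)
    nj <- length(idx)
    if (nj < 2) { scores <- c(scores, 1); next }
    cnt <- 0
    for (a in idx) for (b in idx) {
      if (a != b && train_assign[a] == train_assign[b]) cnt <- cnt + 1
    }
    scores <- c(scores, cnt / (nj * (nj - 1)))
  }
  min(scores)
}

# numeric spherical quadrature of an axially symmetric per-direction signal:
# mean over the sphere of f((g.mu)^2) = integral_0^1 f(t^2) dt
sphere_quadrature <- function(f) {
  stats::integrate(function(t) f(t^2), 0, 1, rel.tol = 1e-12)$value
}

whole_brain_row <- function(metric) {
  mm <- default_lesion_moments()
  mm[mm$location == "whole_brain" & mm$metric == metric, ]
}
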