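# Shared oracles and fixture builders, independent of the package's
# internal code paths.

# Dense residual-projector oracle: (I - P P') x for a row vector x.
dense_residual <- function(P, x) {
  proj <- diag(nrow(P)) - P %*% t(P)
  x %*% proj
}

# Small random dataset with both classes, built directly from arrays.
random_dataset <- function(I = 6L, J = 4L, K = 2L, seed = 1L,
                           labels = NULL) {
  set.seed(seed)
  vals <- array(rnorm(I * J * K), c(I, J, K))
  if (is.null(labels))
    labels <- rep(c("fresh", "wi"), length.out = I)
  batch_dataset(vals, labels)
}

# Manual per-column scaling oracle on a batchwise-unfolded matrix.
scale_oracle <- function(M) {
  mu <- colMeans(M)
  s <- apply(M, 2L, sd)
  s[s == 0] <- 1
  sweep(sweep(M, 2L, mu), 2L, s, `/`)
}

# Default-generator study datasets reused across tests.
default_study <- function(seed = 1L, n_fresh = 10L, n_wi = 6L) {
  generate_study(generator_config(n_fresh = n_fresh, n_wi = n_wi,
                                  seed = seed))
}
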