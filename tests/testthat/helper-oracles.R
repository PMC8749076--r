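# Independent oracles used by the tests; deliberately separate from the
# package's implementation paths.

# Brute-force optimal-superposition RMSD by numerical optimization over a
# quaternion parameterization of rotations (mobile A onto fixed B).
quaternion_rmsd_oracle <- function(A, B, n_starts = 8, seed = 1) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  rot_of <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  fn <- function(q) {
    R <- rot_of(q)
    sqrt(mean(rowSums((A0 %*% t(R) - B0)^2)))
  }
  set.seed(seed)
  best <- Inf
  for (i in seq_len(n_starts)) {
    q0 <- rnorm(4)
    o <- optim(q0, fn, method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
    o <- optim(o$par, fn, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# Analytic accessible area of two intersecting spheres of equal radius R at
# center distance d (total over both spheres).
two_sphere_area_oracle <- function(R, d) {
  if (d >= 2 * R) return(2 * 4 * pi * R^2)
  h <- R - d / 2               # height of each buried cap
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

# Straight ideal alpha-helix chain spec (poly-Ala).
ideal_helix_spec <- function(n = 15, chain_id = "A", omega1 = 100, s = 0,
                             phi1 = 0) {
  chain_spec(chain_id, strrep("A", n), 1,
             crick_params(r1 = 0, r0 = 2.26, h = 1.51, omega1 = omega1,
                          phi1 = phi1, s = s))
}

# Exact binomial 95% CI for a count.
binom_ci <- function(x, n) {
  as.numeric(binom.test(x, n)$conf.int)
}

random_rigid_transform <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  list(R = R, t = rnorm(3, sd = 5))
}

apply_rigid <- function(xyz, tr) sweep(as.matrix(xyz) %*% t(tr$R), 2, tr$t, "+")

transform_model <- function(model, tr) {
  xyz <- apply_rigid(bundle_coords(model), tr)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}
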