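# Shared fixtures and independent oracles for the test suite.

# AEDANS-like bi-exponential donor used by the synthetic studies
# (intensity-weighted mean lifetime ~11.7 ns).
default_donor <- function() donor_model(c(0.6, 0.4), c(5, 15))

# Monte-Carlo oracle for the ensemble donor-acceptor decay: average the
# fixed-distance decay over Gaussian distance draws (truncated at r > 0).
# Returns the mean and its standard error per time point.
mc_ensemble_decay <- function(t, donor, R0, dist, n = 2e4, seed = 1) {
  set.seed(seed)
  r <- rnorm(n, dist$rbar, dist$sigma)
  r <- r[r > 0]
  boost <- 1 + (R0 / r)^6
  M <- matrix(0, length(r), length(t))
  for (i in seq_along(donor$amplitudes))
    M <- M + donor$amplitudes[i] *
      exp(-outer(boost, t / donor$lifetimes[i]))
  list(mean = colMeans(M), se = apply(M, 2, sd) / sqrt(length(r)))
}

# Kearsley quaternion least-squares superposition: an independent route
# to the optimal-superposition RMSD (no SVD/Kabsch step).
quat_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  d <- P - Q
  s <- P + Q
  K <- matrix(0, 4, 4)
  K[1, 1] <- sum(d^2)
  K[1, 2] <- K[2, 1] <- sum(s[, 2] * d[, 3] - d[, 2] * s[, 3])
  K[1, 3] <- K[3, 1] <- sum(d[, 1] * s[, 3] - s[, 1] * d[, 3])
  K[1, 4] <- K[4, 1] <- sum(s[, 1] * d[, 2] - d[, 1] * s[, 2])
  K[2, 2] <- sum(s[, 2]^2 + s[, 3]^2 + d[, 1]^2)
  K[2, 3] <- K[3, 2] <- sum(d[, 1] * d[, 2] - s[, 1] * s[, 2])
  K[2, 4] <- K[4, 2] <- sum(d[, 1] * d[, 3] - s[, 1] * s[, 3])
  K[3, 3] <- sum(s[, 1]^2 + s[, 3]^2 + d[, 2]^2)
  K[3, 4] <- K[4, 3] <- sum(d[, 2] * d[, 3] - s[, 2] * s[, 3])
  K[4, 4] <- sum(s[, 1]^2 + s[, 2]^2 + d[, 3]^2)
  sqrt(max(0, min(eigen(K, symmetric = TRUE)$values)) / nrow(P))
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# rigid motion applied to a structure_model (all frames)
transform_structure <- function(model, R = diag(3), shift = c(0, 0, 0)) {
  frames <- t(apply(model$frames, 1, function(v) {
    xyz <- matrix(v, ncol = 3, byrow = TRUE)
    as.numeric(t(sweep(xyz %*% t(R), 2, shift, `+`)))
  }))
  if (nrow(model$frames) == 1L) frames <- matrix(frames, nrow = 1L)
  atoms <- model$atoms
  xyz1 <- matrix(frames[1L, ], ncol = 3, byrow = TRUE)
  atoms$x <- xyz1[, 1]
  atoms$y <- xyz1[, 2]
  atoms$z <- xyz1[, 3]
  structure_model(atoms, frames)
}

# single-chain fixture carrying two rigid helical clusters whose anchor
# CA atoms (residues 13 and 51 of chain A) sit exactly 'd' apart
two_site_structure <- function(d) {
  db <- make_structure("two_domain_dumbbell", site_distances = d)
  atoms <- db$atoms
  atoms$resno <- ifelse(atoms$chain == "A", atoms$resno + 9L,
                        atoms$resno + 47L)   # anchors 4 -> 13 and 4 -> 51
  atoms$chain <- "A"
  structure_model(atoms)
}

tnc_map <- function() site_map(copies = list(c(cTnC = "A")))
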