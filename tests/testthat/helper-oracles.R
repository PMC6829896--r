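# Independent oracles and fixture builders used across tests.

# Cross-product/acos dihedral oracle (formulated differently from the
# package's projection/atan2 implementation): magnitude from the normal
# vectors, sign from the triple product with the central bond.
oracle_dihedral <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  mag <- acos(max(-1, min(1, cosang))) * 180 / pi
  s <- sign(sum(cr(n1, n2) * b2))
  if (s == 0) s <- 1
  s * mag
}

# Random rigid-body transform: rotation (QR-orthogonalised Gaussian with
# det +1) plus translation.
random_rigid_transform <- function() {
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  t <- rnorm(3, sd = 10)
  function(p) as.numeric(Q %*% p + t)
}

# Build a 4-atom chromophore fragment whose phi dihedral (CD-CG-CB-CA)
# equals phi_deg and tau dihedral (CG-CB-CA-N) equals tau_deg, by placing
# the outer atoms on cones about the shared backbone CG-CB-CA.
make_dihedral_frame <- function(phi_deg, tau_deg) {
  # backbone: CG at origin, CB along x, CA offset in xy-plane
  CG <- c(0, 0, 0); CB <- c(1.45, 0, 0); CA <- c(2.0, 1.3, 0)
  place <- function(a, b, c0, angle_deg, torsion_deg, bond = 1.4) {
    # position X so that angle(X-a-b) = angle_deg and torsion X-a-b-c0 = torsion_deg
    e1 <- (b - a) / sqrt(sum((b - a)^2))
    v <- c0 - b
    e2 <- v - sum(v * e1) * e1
    e2 <- e2 / sqrt(sum(e2^2))
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    th <- angle_deg * pi / 180; ph <- torsion_deg * pi / 180
    a + bond * (cos(th) * e1 + sin(th) * (cos(ph) * e2 - sin(ph) * e3))
  }
  # torsion X-CG-CB-CA: place X about the CG->CB axis
  CD <- place(CG, CB, CA, 120, phi_deg)
  # torsion N-CA-CB-CG: place N about the CA->CB axis
  N <- place(CA, CB, CG, 120, tau_deg)
  xyz <- array(NA_real_, c(1, 5, 3))
  xyz[1, 1, ] <- CD; xyz[1, 2, ] <- CG; xyz[1, 3, ] <- CB
  xyz[1, 4, ] <- CA; xyz[1, 5, ] <- N
  atoms <- data.frame(name = c("CD", "CG", "CB", "CA", "N"),
                      elem = c("C", "C", "C", "C", "N"),
                      resname = "CRO", stringsAsFactors = FALSE)
  fp_traj(atoms, xyz, time_ps = 0)
}
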