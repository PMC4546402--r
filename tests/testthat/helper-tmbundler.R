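# Shared fixtures, built in code.

# four long parallel helices on a 9 A square: a bundle on which every
# geometric penalty term vanishes (length 36 A > membrane 30 A, centred,
# untilted, no inter-helix CA pair below the clash distance)
perfect_specs <- function() {
  seqs <- strrep("L", 25)
  list(TM1 = helix_spec("TM1", seqs, 1, 25, "z", "extracellular"),
       TM2 = helix_spec("TM2", seqs, 101, 125, c("y", "z"), "cytoplasmic"),
       TM3 = helix_spec("TM3", seqs, 201, 225, c("x", "y", "z"),
                        "extracellular"),
       TM4 = helix_spec("TM4", seqs, 301, 325, c("x", "y", "z"),
                        "cytoplasmic"))
}

perfect_bundle <- function() build_bundle(perfect_specs(), side = 9)

# restraint set without residue-contact restraints (their satisfaction
# depends on axial phase, not on the bundle geometry under test)
geometric_restraints <- function(...) {
  restraint_set(contact_restraints = NULL, ...)
}

# independent, deliberately naive implementation of the 15N relaxation
# rates (scalar arithmetic, no shared code with the package internals)
oracle_rates <- function(S2, tau_e, tau_m, field = 18.8) {
  gH <- 2.6752218744e8; gN <- -2.7116e7
  hbar <- 1.054571817e-34; rNH <- 1.02e-10; csa <- -160e-6
  wH <- gH * field; wN <- abs(gN) * field
  d <- 1e-7 * hbar * gH * abs(gN) / rNH^3
  cc <- wN * csa / sqrt(3)
  J <- function(w) {
    tau <- if (tau_e > 0) tau_e * tau_m / (tau_e + tau_m) else 0
    term2 <- if (tau > 0) (1 - S2) * tau / (1 + (w * tau)^2) else 0
    2 / 5 * (S2 * tau_m / (1 + (w * tau_m)^2) + term2)
  }
  R1 <- d^2 / 4 * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) + cc^2 * J(wN)
  R2 <- d^2 / 8 * (4 * J(0) + J(wH - wN) + 3 * J(wN) + 6 * J(wH) +
                     6 * J(wH + wN)) + cc^2 / 6 * (4 * J(0) + 3 * J(wN))
  NOE <- 1 + (gH / gN) * (d^2 / 4) * (6 * J(wH + wN) - J(wH - wN)) / R1
  c(R1 = R1, R2 = R2, NOE = NOE)
}

# mean TM2-TM3 inter-axis (xy midpoint) distance over an ensemble
mean_axis_distance <- function(ens, h1 = "TM2", h2 = "TM3") {
  idx <- split(seq_len(nrow(ens$map)), ens$map$helix)
  mean(vapply(seq_len(nrow(ens$xyz)), function(i) {
    m <- matrix(ens$xyz[i, ], ncol = 3, byrow = TRUE)
    a <- colMeans(m[idx[[h1]], , drop = FALSE])
    b <- colMeans(m[idx[[h2]], , drop = FALSE])
    sqrt(sum((a[1:2] - b[1:2])^2))
  }, numeric(1)))
}
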