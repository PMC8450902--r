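# Independent oracles, coded separately from the package internals.

# Abeles transfer-matrix reflectivity (characteristic-matrix formulation),
# with Nevot-Croce roughness factors.  Complex arithmetic throughout; the
# package kernel instead uses the Parratt recursion with real/imaginary
# wave-vector special cases, so agreement is a genuine cross-check.
abeles_reflectivity <- function(stack, Q) {
  rho <- c(stack$fronting_sld, stack$sld, stack$backing_sld) * 1e-6
  d <- c(0, stack$thickness, 0)
  sig <- c(stack$fronting_roughness, stack$roughness)
  vapply(Q, function(q) {
    k <- sqrt(as.complex((q / 2)^2 - 4 * pi * (rho - rho[1])))
    n <- length(rho)
    M <- diag(2)
    for (i in 1:(n - 1)) {
      r <- (k[i] - k[i + 1]) / (k[i] + k[i + 1]) *
        exp(-2 * k[i] * k[i + 1] * sig[i]^2)
      beta <- if (i == 1) 0 + 0i else 1i * k[i] * d[i]
      Ci <- matrix(c(exp(beta), r * exp(beta),
                     r * exp(-beta), exp(-beta)), 2, 2, byrow = TRUE)
      M <- M %*% Ci
    }
    min(1, Mod(M[2, 1] / M[1, 1])^2)
  }, numeric(1))
}

# Kinematic (Born) reflectivity of a single rough interface:
# R = 16 pi^2 drho^2 / Q^4 * exp(-Q^2 sigma^2) = (Qc^4 / 16 Q^4) exp(...)
born_interface <- function(fronting_sld, backing_sld, sigma, Q) {
  drho <- (backing_sld - fronting_sld) * 1e-6
  16 * pi^2 * drho^2 / Q^4 * exp(-Q^2 * sigma^2)
}

# brute-force Gaussian smearing by fine Riemann sum (reference for the
# quadrature-based smearing)
smear_brute <- function(fn, Q, dq_over_q, span = 5, m = 801) {
  vapply(Q, function(q) {
    s <- dq_over_q * q
    x <- seq(-span * s, span * s, length.out = m)
    w <- exp(-x^2 / (2 * s^2))
    sum(w * fn(pmax(q + x, 1e-8))) / sum(w)
  }, numeric(1))
}

# random slab stack generator for property tests (physically plausible
# ranges; roughness kept below half the slab thickness)
random_stack <- function() {
  ns <- sample(1:6, 1)
  slab_stack(runif(1, -0.5, 4), runif(1, -0.56, 6.35),
             thickness = runif(ns, 5, 80),
             sld = runif(ns, -0.5, 6.3),
             roughness = runif(ns, 0, 4),
             fronting_roughness = runif(1, 0, 4))
}
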