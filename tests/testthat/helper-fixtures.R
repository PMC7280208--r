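# shared fixtures and independent oracles

# BSA-like component table: 94.1% monomer, 5.9% aggregates
bsa_fractions <- function() {
  component_table(1:4, c(0.941, 0.040, 0.013, 0.006))
}

default_q <- function(n = 150L, qmin = 0.010, qmax = 0.20) {
  exp(seq(log(qmin), log(qmax), length.out = n))
}

# analytic sphere per-mass profile, I(0) = I0, tiny relative sigma
sphere_profile <- function(Rg = 27.2, q = default_q(), I0 = 1,
                           rel = 1e-6, label = "sphere") {
  R <- Rg * sqrt(5 / 3)
  I <- I0 * sphere_intensity(q, R)
  scattering_profile(q, I, pmax(rel * I, 1e-15), label = label)
}

# independent Debye oracle: explicit monomer coordinates and full double sum
oracle_positions <- function(j, geometry, d) {
  if (geometry == "linear")
    return(cbind(0, 0, (seq_len(j) - 1) * d))
  switch(as.character(j),
         "1" = cbind(0, 0, 0),
         "2" = rbind(c(0, 0, 0), c(d, 0, 0)),
         "3" = rbind(c(0, 0, 0), c(d, 0, 0),
                     c(d / 2, d * sqrt(3) / 2, 0)),
         "4" = rbind(c(0, 0, 0), c(d, 0, 0),
                     c(d / 2, d * sqrt(3) / 2, 0),
                     c(d / 2, d * sqrt(3) / 6, d * sqrt(2 / 3))),
         stop("oracle: close-packed j > 4"))
}

oracle_structure_factor <- function(q, j, geometry, d) {
  xyz <- oracle_positions(j, geometry, d)
  S <- numeric(length(q))
  for (k in seq_len(j)) for (l in seq_len(j)) {
    r <- sqrt(sum((xyz[k, ] - xyz[l, ])^2))
    S <- S + if (r == 0) rep(1, length(q)) else {
      x <- q * r
      ifelse(x < 1e-8, 1, sin(x) / x)
    }
  }
  S
}

# hHR23b-UBL (9.5 kDa) / PNGase-PUB (12.5 kDa) style system
ubl_pub_system <- function(KD = 10) {
  equilibrium_system(species("A", 9500, 0.73, 0.012),
                     species("B", 12500, 0.73, 0.015),
                     KD = KD)
}
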