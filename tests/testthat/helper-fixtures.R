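# small structures used across tests

make_ion <- function(q = 1, radius = 0.2, group = "guest") {
  solute_structure(data.frame(
    name = "ION", element = "N", x = 0, y = 0, z = 0, charge = q,
    radius = radius, is_polar_hydrogen = FALSE, group = group,
    stringsAsFactors = FALSE), label = "ION")
}

make_pair <- function(qa = 1, qb = 1, d = 0.7, ra = 0, rb = 0,
                      groups = c("guest", "guest"), bond = FALSE) {
  s <- solute_structure(data.frame(
    name = c("A", "B"), element = "N",
    x = c(-d / 2, d / 2), y = 0, z = 0, charge = c(qa, qb),
    radius = c(ra, rb), is_polar_hydrogen = FALSE, group = groups,
    stringsAsFactors = FALSE),
    bonds = if (bond) rbind(c(1L, 2L)) else NULL, label = "PAIR")
  s
}

# independently coded naive Ewald sum for the periodic Coulomb Green's
# function: plain nested loops, different splitting parameter and larger
# cutoffs than the package implementation
naive_ewald <- function(rvec, L, alpha = 4.2 / L, nreal = 3, nrec = 10) {
  out <- -pi / (alpha^2 * L^3)
  for (nx in -nreal:nreal) for (ny in -nreal:nreal) for (nz in -nreal:nreal) {
    d <- rvec + L * c(nx, ny, nz)
    r <- sqrt(sum(d^2))
    out <- out + 2 * pnorm(-sqrt(2) * alpha * r) / r
  }
  for (nx in -nrec:nrec) for (ny in -nrec:nrec) for (nz in -nrec:nrec) {
    if (nx == 0 && ny == 0 && nz == 0) next
    k <- 2 * pi * c(nx, ny, nz) / L
    k2 <- sum(k^2)
    out <- out + (4 * pi / L^3) * exp(-k2 / (4 * alpha^2)) / k2 *
      cos(sum(k * rvec))
  }
  out
}
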