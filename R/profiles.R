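#' Solvent radial distribution around a centre
#'
#' Histogram of centre-to-water-oxygen distances normalized by shell
#' volume and bulk density rho = N_w / L^3.  Distances are counted over
#' all periodic images within sqrt(3) L / 2 (every image of a water
#' molecule whose distance falls inside the histogram range contributes),
#' so the profile remains meaningful beyond L/2.
#'
#' @param frames list of frames; each a list with \code{waters} (n x 3
#'   matrix of oxygen coordinates, nm) and optionally \code{solute}
#' @param center_rule "buckyball-COM" or "guest-charge-center"
#' @param bin_width histogram bin, nm (default 0.01)
#' @param L cubic box edge, nm
#' @param center optional explicit centre overriding the rule
#' @return object of class \code{polarization_profile} with fields
#'   \code{bin_edges}, \code{r} (bin mid-points), \code{g}
#' @export
radial_distribution <- function(frames, center_rule = c("buckyball-COM",
                                                        "guest-charge-center"),
                                bin_width = 0.01, L, center = NULL) {
  center_rule <- match.arg(center_rule)
  if (!length(frames)) stop("no frames supplied")
  rmax <- sqrt(3) * L / 2
  edges <- seq(0, rmax + bin_width, by = bin_width)
  counts <- numeric(length(edges) - 1)
  nw <- NULL
  for (fr in frames) {
    ctr <- if (is.null(center)) frame_center(fr$solute, center_rule) else center
    d <- all_image_distances(fr$waters, ctr, L, rmax)
    counts <- counts + graphics::hist(d, breaks = edges, plot = FALSE)$counts
    nw <- nw %||% nrow(fr$waters)
  }
  counts <- counts / length(frames)
  rho <- nw / L^3
  mids <- edges[-1] - bin_width / 2
  shell <- 4 * pi * mids^2 * bin_width
  structure(list(bin_edges = edges, r = mids, g = counts / (shell * rho),
                 counts = counts, rho = rho, L = L,
                 center_rule = center_rule),
            class = "polarization_profile")
}

# distances from ctr to every periodic image of each row of xyz within rmax
all_image_distances <- function(xyz, ctr, L, rmax) {
  sh <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1)) * L
  d0 <- sweep(xyz, 2, ctr, "-")
  d0 <- d0 - L * round(d0 / L)          # fold into central image first
  out <- lapply(seq_len(nrow(sh)), function(m) {
    d <- sweep(d0, 2, sh[m, ], "+")
    r <- sqrt(rowSums(d^2))
    r[r <= rmax]
  })
  unlist(out)
}

#' Solvent radial polarization around a centre
#'
#' Per-bin sum of the projections of water dipole moments on the outward
#' radial unit vector, normalized per shell area:
#' P(r) = mu * sum_j cos(theta_j) / (4 pi r^2 dr) per frame, in e/nm^2.
#' Positive values mean dipoles pointing outward (the expected sign around
#' a cation).
#'
#' @param frames list of frames; each a list with \code{waters} (oxygen
#'   coordinates) and \code{dipoles} (n x 3 matrix of unit vectors along
#'   each water dipole), optionally \code{solute}
#' @param center_rule "buckyball-COM" or "guest-charge-center"
#' @param bin_width bin width, nm
#' @param L box edge, nm
#' @param dipole molecular dipole moment magnitude, e nm (default SPC)
#' @param center optional explicit centre
#' @return \code{polarization_profile} with field \code{P}
#' @export
radial_polarization <- function(frames, center_rule = c("guest-charge-center",
                                                        "buckyball-COM"),
                                bin_width = 0.01, L,
                                dipole = phys_constants()$mu_spc,
                                center = NULL) {
  center_rule <- match.arg(center_rule)
  if (!length(frames)) stop("no frames supplied")
  rmax <- sqrt(3) * L / 2
  edges <- seq(0, rmax + bin_width, by = bin_width)
  proj_sum <- numeric(length(edges) - 1)
  for (fr in frames) {
    ctr <- if (is.null(center)) frame_center(fr$solute, center_rule) else center
    d0 <- sweep(fr$waters, 2, ctr, "-")
    d0 <- d0 - L * round(d0 / L)
    sh <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1)) * L
    for (m in seq_len(nrow(sh))) {
      d <- sweep(d0, 2, sh[m, ], "+")
      r <- sqrt(rowSums(d^2))
      keep <- r <= rmax & r > 0
      if (!any(keep)) next
      cosb <- rowSums(fr$dipoles[keep, , drop = FALSE] *
                        d[keep, , drop = FALSE] / r[keep])
      bins <- findInterval(r[keep], edges, rightmost.closed = TRUE)
      proj_sum <- proj_sum + vapply(seq_along(proj_sum), function(b)
        sum(cosb[bins == b]), numeric(1))
    }
  }
  proj_sum <- proj_sum / length(frames)
  mids <- edges[-1] - bin_width / 2
  structure(list(bin_edges = edges, r = mids,
                 P = dipole * proj_sum / (4 * pi * mids^2 * bin_width),
                 center_rule = center_rule, dipole_magnitude = dipole,
                 L = L),
            class = "polarization_profile")
}

#' Born continuum analog of the radial polarization
#'
#' Radial polarization of a homogeneous dielectric continuum of relative
#' permittivity \code{eps} around a centred net charge:
#' P_Born(r) = Q / (4 pi r^2) * (1 - 1/eps), in e/nm^2.
#'
#' @param r radial distance(s), nm (> 0)
#' @param Q_total net charge generating the field, e (summed over guest
#'   and host for the benchmark complexes)
#' @param eps relative permittivity (default SPC water, 66.6)
#' @return polarization value(s), e/nm^2
#' @export
#' @examples
#' born_polarization(1, 1)  # about 0.0784
born_polarization <- function(r, Q_total,
                              eps = phys_constants()$eps_spc) {
  stopifnot(all(r > 0), eps >= 1)
  Q_total / (4 * pi * r^2) * (1 - 1 / eps)
}

#' @export
print.polarization_profile <- function(x, ...) {
  cat(sprintf("<polarization_profile> %d bins up to %.3f nm (%s)%s\n",
              length(x$r), max(x$bin_edges), x$center_rule,
              if (!is.null(x$P)) ", with polarization" else ""))
  invisible(x)
}
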