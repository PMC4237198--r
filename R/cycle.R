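#' Correction ledger for one charging calculation
#'
#' Assembles a raw charging free energy and the four correction terms into
#' a methodology-independent corrected value.  For charging in pure water
#' (and for the uncharged CAPO host) the guest-host term must be zero.
#'
#' @param raw raw charging free energy from the simulation, kJ/mol
#' @param dG_pol polarization/permittivity correction, kJ/mol
#' @param dG_sum summation-scheme correction, kJ/mol
#' @param dG_hs guest-host direct-interaction correction, kJ/mol
#' @param dG_excl excluded-pair correction, kJ/mol
#' @param guest,environment,scheme metadata labels ("W" for water)
#' @return object of class \code{correction_ledger} with the exact sum in
#'   \code{corrected}
#' @export
#' @examples
#' assemble_corrected(-4.4, -71.2, -75.4, 0, -0.2,
#'                    guest = "MAM", environment = "CAPO",
#'                    scheme = "LS,ss")$corrected  # -151.2
assemble_corrected <- function(raw, dG_pol, dG_sum, dG_hs = 0, dG_excl = 0,
                               guest = "", environment = "W", scheme = "") {
  if (environment == "W" && dG_hs != 0)
    stop("charging in water has no guest-host correction (dG_hs must be 0)")
  structure(list(raw = raw, dG_pol = dG_pol, dG_sum = dG_sum,
                 dG_hs = dG_hs, dG_excl = dG_excl,
                 corrected = raw + dG_pol + dG_sum + dG_hs + dG_excl,
                 guest = guest, environment = environment, scheme = scheme),
            class = "correction_ledger")
}

#' @export
print.correction_ledger <- function(x, ...) {
  cat(sprintf("<correction_ledger> %s in %s (%s)\n", x$guest, x$environment,
              x$scheme))
  cat(sprintf("  raw %8.1f  pol %8.1f  sum %8.1f  hs %8.1f  excl %6.1f  ->  corrected %8.1f kJ/mol\n",
              x$raw, x$dG_pol, x$dG_sum, x$dG_hs, x$dG_excl, x$corrected))
  invisible(x)
}

#' Charging contribution to the binding free energy
#'
#' Difference of in-host and in-water charging free energies,
#' ddG = dG(H) - dG(W), for both the raw and corrected values.
#'
#' @param ledger_W ledger for charging the guest in water
#' @param ledger_H ledger for charging the guest in the host
#' @return object of class \code{binding_record} with \code{ddG_raw} and
#'   \code{ddG_cor}
#' @export
binding_contribution <- function(ledger_W, ledger_H) {
  if (nzchar(ledger_W$guest) && nzchar(ledger_H$guest) &&
      ledger_W$guest != ledger_H$guest)
    stop("ledgers refer to different guests")
  structure(list(guest = ledger_H$guest, host = ledger_H$environment,
                 water_scheme_tag = ledger_W$scheme,
                 host_scheme_tag = ledger_H$scheme,
                 ddG_raw = ledger_H$raw - ledger_W$raw,
                 ddG_cor = ledger_H$corrected - ledger_W$corrected),
            class = "binding_record")
}

#' @export
print.binding_record <- function(x, ...) {
  cat(sprintf("<binding_record> %s-%s (W: %s, H: %s): ddG_raw %.1f, ddG_cor %.1f kJ/mol\n",
              x$guest, x$host, x$water_scheme_tag, x$host_scheme_tag,
              x$ddG_raw, x$ddG_cor))
  invisible(x)
}

#' Root-mean-square deviation about the mean (divisor N)
#'
#' Consistency measure used for per-system spreads of charging free
#' energies over schemes and box sizes.
#'
#' @param values numeric vector (at least 2 values)
#' @return rmsd in the units of \code{values}
#' @export
consistency_rmsd <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  sqrt(mean((values - mean(values))^2))
}

#' Mean and rmsd of corrected binding contributions over box combinations
#'
#' Enumerates all (water-box, host-box) combinations within a scheme set
#' (all 16 LS combinations, all 4 BM combinations, or their 20-element
#' union) and returns the mean and rmsd (divisor N) of the corrected
#' charging contribution \code{ddG_cor} to the binding free energy.
#'
#' @param ledgers_W list of \code{correction_ledger}s for in-water charging
#'   (one per scheme/box)
#' @param ledgers_H list of \code{correction_ledger}s for in-host charging
#' @param scheme_set "LS", "BM" or "LS+BM"
#' @return list with \code{mean}, \code{rmsd}, \code{n}, and the vector of
#'   per-combination values
#' @export
combination_stats <- function(ledgers_W, ledgers_H,
                              scheme_set = c("LS", "BM", "LS+BM")) {
  scheme_set <- match.arg(scheme_set)
  pick <- function(ledgers, sch)
    Filter(function(l) startsWith(l$scheme, sch), ledgers)
  vals <- c()
  for (sch in strsplit(scheme_set, "+", fixed = TRUE)[[1]]) {
    w <- pick(ledgers_W, sch); h <- pick(ledgers_H, sch)
    for (lw in w) for (lh in h)
      vals <- c(vals, lh$corrected - lw$corrected)
  }
  if (!length(vals)) stop("no scheme/box combinations found")
  list(mean = mean(vals),
       rmsd = if (length(vals) > 1) consistency_rmsd(vals) else 0,
       n = length(vals), values = vals)
}

#' Solvent/host decomposition of a charging free energy
#'
#' Splits a raw in-host charging free energy into host and solvent
#' contributions from three charge-toggled re-evaluations of the sampled
#' energies (full guest and host charges; full guest, zeroed host; zeroed
#' guest, full host): the host part is the thermodynamic integral of the
#' cross term, the solvent part is the remainder.  Corrected variants add
#' \code{dG_hs} to the host part and \code{dG_pol + dG_sum + dG_excl} to
#' the solvent part.
#'
#' @param series_total \code{lambda_series} of dH/dlambda with full guest
#'   and host charges
#' @param series_guest_only same, with host charges zeroed
#' @param series_host_only same, with guest charges zeroed
#' @param dG_pol,dG_sum,dG_hs,dG_excl the correction terms, kJ/mol
#' @return object of class \code{decomposition_record} with fields
#'   \code{raw_solvent}, \code{raw_host}, \code{cor_solvent},
#'   \code{cor_host}
#' @export
decompose_charging <- function(series_total, series_guest_only, series_host_only,
                      dG_pol = 0, dG_sum = 0, dG_hs = 0, dG_excl = 0) {
  stopifnot(identical(series_total$lambdas, series_guest_only$lambdas),
            identical(series_total$lambdas, series_host_only$lambdas))
  cross <- lambda_series(series_total$lambdas,
                         series_total$values - series_guest_only$values -
                           series_host_only$values)
  raw_host <- trapezoid_ti(cross)$value
  raw_total <- trapezoid_ti(series_total)$value
  raw_solvent <- raw_total - raw_host
  structure(list(raw_solvent = raw_solvent, raw_host = raw_host,
                 cor_solvent = raw_solvent + dG_pol + dG_sum + dG_excl,
                 cor_host = raw_host + dG_hs),
            class = "decomposition_record")
}

#' @export
print.decomposition_record <- function(x, ...) {
  cat(sprintf("<decomposition_record> raw: solvent %.1f + host %.1f; corrected: solvent %.1f + host %.1f kJ/mol\n",
              x$raw_solvent, x$raw_host, x$cor_solvent, x$cor_host))
  invisible(x)
}
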