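#' Solute structure container
#'
#' Holds the atoms of a guest, a host, or a guest-host complex: names,
#' elements, Cartesian positions (nm), partial charges (e), continuum radii
#' (nm), polar-hydrogen flags and a guest/host group tag, together with the
#' covalent bond list and the electrostatic exclusion list (first and second
#' covalent neighbours).
#'
#' @param atoms data.frame with columns \code{name}, \code{element},
#'   \code{x}, \code{y}, \code{z}, \code{charge}, \code{radius},
#'   \code{is_polar_hydrogen}, \code{group} (values "guest" or "host")
#' @param bonds two-column integer matrix of 1-based atom indices
#' @param exclusions two-column integer matrix of unordered excluded pairs;
#'   if \code{NULL}, derived from \code{bonds} as all 1-2 and 1-3 pairs
#' @param label free-form system label, e.g. "MAM" or "complex:MAM-CNEG"
#' @return object of class \code{solute_structure}
#' @export
solute_structure <- function(atoms, bonds = NULL, exclusions = NULL,
                             label = "") {
  need <- c("name", "element", "x", "y", "z", "charge", "radius",
            "is_polar_hydrogen", "group")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  atoms <- atoms[, need]
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (is.null(exclusions)) exclusions <- exclusions_from_bonds(bonds, nrow(atoms))
  exclusions <- matrix(as.integer(exclusions), ncol = 2)
  structure(list(atoms = atoms, bonds = bonds, exclusions = exclusions,
                 label = label),
            class = "solute_structure")
}

#' @export
print.solute_structure <- function(x, ...) {
  cat(sprintf("<solute_structure> %s: %d atoms (%d guest, %d host), %d bonds, %d exclusions, net charge %+.3f e\n",
              x$label, nrow(x$atoms), sum(x$atoms$group == "guest"),
              sum(x$atoms$group == "host"), nrow(x$bonds),
              nrow(x$exclusions), net_charge(x)))
  invisible(x)
}

positions <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

#' Net charge of a structure or of one of its groups
#' @param s a \code{solute_structure}
#' @param group "all", "guest" or "host"
#' @return net charge in e
#' @export
net_charge <- function(s, group = "all") {
  a <- s$atoms
  if (group != "all") a <- a[a$group == group, ]
  sum(a$charge)
}

# All 1-2 and 1-3 neighbour pairs implied by a bond list.
exclusions_from_bonds <- function(bonds, n_atoms) {
  if (nrow(bonds) == 0) return(matrix(integer(0), 0, 2))
  adj <- vector("list", n_atoms)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  pairs <- list()
  for (i in seq_len(n_atoms)) {
    first <- adj[[i]]
    second <- setdiff(unique(unlist(adj[first])), c(i, first))
    for (j in c(first, second)) if (j > i) pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  if (!length(pairs)) return(matrix(integer(0), 0, 2))
  do.call(rbind, pairs)
}

#' Validate a solute structure
#'
#' Checks the container invariants: finite positions, nonnegative radii,
#' exclusion pairs referencing valid atoms without self-pairs, and for the
#' standard guest labels (MAM, ACE) the expected guest net charge (+1, -1).
#'
#' @param s a \code{solute_structure}
#' @return character vector of violation descriptions; empty if valid
#' @export
#' @examples
#' validate_structure(build_buckyball(fixture_recipe(host = "CAPO")))
validate_structure <- function(s) {
  v <- character(0)
  a <- s$atoms
  bad <- which(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))
  if (length(bad)) v <- c(v, paste0("non-finite position at atom(s) ",
                                    paste(bad, collapse = ",")))
  bad <- which(a$radius < 0)
  if (length(bad)) v <- c(v, paste0("negative radius at atom(s) ",
                                    paste(bad, collapse = ",")))
  ex <- s$exclusions
  if (nrow(ex)) {
    self <- which(ex[, 1] == ex[, 2])
    if (length(self))
      v <- c(v, paste0("self-pair exclusion (", ex[self[1], 1], ",",
                       ex[self[1], 2], ")"))
    oob <- which(ex < 1 | ex > nrow(a))
    if (length(oob)) v <- c(v, "exclusion pair references invalid atom index")
  }
  qg <- net_charge(s, "guest")
  expected <- c(MAM = 1, ACE = -1)
  gl <- guest_label(s)
  if (!is.na(gl) && gl %in% names(expected) &&
      abs(qg - expected[[gl]]) > 1e-10)
    v <- c(v, sprintf("guest net charge %.6f differs from %+d expected for %s",
                      qg, expected[[gl]], gl))
  v
}

guest_label <- function(s) {
  if (s$label %in% c("MAM", "ACE")) return(s$label)
  m <- regmatches(s$label, regexec("^complex:([A-Z]+)-", s$label))[[1]]
  if (length(m) == 2) m[2] else NA_character_
}

# minimum-image displacement(s) for a cubic box of edge L
min_image <- function(d, L) d - L * round(d / L)
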