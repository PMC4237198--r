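#' Write a structure to disk (coordinates + topology sidecar)
#'
#' Coordinates go to a GRO (nm) or PDB (Angstrom on disk, converted) file
#' chosen by extension; charges, radii, polar-hydrogen flags, group tags,
#' bonds and exclusions go to a plain-text \code{.chgtop} sidecar of the
#' package's own minimal format (the full force-field topology grammar is
#' out of scope).  Atom indices are 1-based in files.
#'
#' @param s a \code{solute_structure}
#' @param path coordinate file path (\code{.gro} or \code{.pdb})
#' @param topology_path sidecar path (default: \code{path} with extension
#'   \code{.chgtop})
#' @return invisibly, \code{path}
#' @export
write_structure <- function(s, path,
                            topology_path = sub("\\.[^.]+$", ".chgtop",
                                                path)) {
  ext <- tolower(tools::file_ext(path))
  pos <- positions(s)
  if (ext == "gro") {
    lines <- c(paste0("chargecorr structure ", s$label),
               sprintf("%5d", nrow(pos)),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       1L, "MOL", substr(s$atoms$name, 1, 5),
                       seq_len(nrow(pos)), pos[, 1], pos[, 2], pos[, 3]),
               sprintf("%10.5f%10.5f%10.5f", 0, 0, 0))
    writeLines(lines, path)
  } else if (ext == "pdb") {
    n <- nrow(pos)
    xyz <- as.vector(t(pos * 10))  # nm -> Angstrom
    bio3d::write.pdb(file = path, xyz = xyz, elety = s$atoms$name,
                     resid = rep("MOL", n), resno = rep(1L, n),
                     chain = rep("A", n), eleno = seq_len(n),
                     o = rep(1, n), b = rep(0, n))
  } else stop("unsupported coordinate format: .", ext)
  write_chgtop(s, topology_path)
  invisible(path)
}

write_chgtop <- function(s, path) {
  a <- s$atoms
  lines <- c("# chargecorr topology sidecar v1",
             paste("label", s$label),
             paste("atoms", nrow(a)),
             sprintf("%d %s %s %.10g %.10g %d %s", seq_len(nrow(a)),
                     a$name, a$element, a$charge,
                     ifelse(is.finite(a$radius), a$radius, -1),
                     as.integer(a$is_polar_hydrogen), a$group),
             paste("bonds", nrow(s$bonds)),
             if (nrow(s$bonds)) sprintf("%d %d", s$bonds[, 1], s$bonds[, 2]),
             paste("exclusions", nrow(s$exclusions)),
             if (nrow(s$exclusions)) sprintf("%d %d", s$exclusions[, 1],
                                             s$exclusions[, 2]))
  writeLines(lines, path)
  invisible(path)
}

read_chgtop <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  k <- 1
  expect <- function(key) {
    parts <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (parts[1] != key)
      stop("chgtop parse error at entry ", k, ": expected '", key, "'")
    k <<- k + 1
    parts[-1]
  }
  label <- paste(expect("label"), collapse = " ")
  n <- as.integer(expect("atoms"))
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- strsplit(trimws(lines[k]), "\\s+")[[1]]; k <<- k + 1
    if (length(p) != 7)
      stop("chgtop parse error: malformed atom record at entry ", k - 1)
    data.frame(name = p[2], element = p[3], x = NA_real_, y = NA_real_,
               z = NA_real_, charge = as.numeric(p[4]),
               radius = ifelse(as.numeric(p[5]) < 0, NA_real_,
                               as.numeric(p[5])),
               is_polar_hydrogen = as.integer(p[6]) == 1L, group = p[7],
               stringsAsFactors = FALSE)
  }))
  readpairs <- function(m) {
    if (m == 0) return(matrix(integer(0), 0, 2))
    out <- t(vapply(seq_len(m), function(i) {
      p <- as.integer(strsplit(trimws(lines[k]), "\\s+")[[1]]); k <<- k + 1
      p[1:2]
    }, integer(2)))
    out
  }
  nb <- as.integer(expect("bonds")); bonds <- readpairs(nb)
  ne <- as.integer(expect("exclusions")); excl <- readpairs(ne)
  list(label = label, atoms = atoms, bonds = bonds, exclusions = excl)
}

#' Read a structure from coordinates plus topology sidecar
#'
#' GRO coordinates are read as nm; PDB coordinates (read through bio3d
#' after a line-level validation pass) are converted from Angstrom to nm.
#' The sidecar supplies charges, radii, flags, group tags, bonds and
#' exclusions; an atom-count mismatch between the two files is an error.
#'
#' @param path coordinate file (\code{.gro} or \code{.pdb})
#' @param topology_path sidecar file
#' @return a \code{solute_structure}
#' @export
read_structure <- function(path,
                           topology_path = sub("\\.[^.]+$", ".chgtop",
                                               path)) {
  ext <- tolower(tools::file_ext(path))
  pos <- if (ext == "gro") read_gro_coords(path)
         else if (ext == "pdb") read_pdb_coords(path)
         else stop("unsupported coordinate format: .", ext)
  top <- read_chgtop(topology_path)
  if (nrow(pos) != nrow(top$atoms))
    stop("atom-count mismatch: ", nrow(pos), " coordinates vs ",
         nrow(top$atoms), " topology atoms")
  top$atoms[, c("x", "y", "z")] <- pos
  solute_structure(top$atoms, top$bonds, top$exclusions, top$label)
}

read_gro_coords <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("GRO file too short")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("GRO parse error at line 2: invalid atom count")
  if (length(lines) < 2 + n) stop("GRO file truncated: expected ", n,
                                  " atom lines")
  pos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- lines[2 + i]
    v <- suppressWarnings(as.numeric(c(substr(ln, 21, 28),
                                       substr(ln, 29, 36),
                                       substr(ln, 37, 44))))
    if (any(is.na(v)))
      stop("GRO parse error at line ", 2 + i, ": nonnumeric coordinate")
    pos[i, ] <- v
  }
  pos
}

read_pdb_coords <- function(path) {
  lines <- readLines(path)
  at <- grep("^(ATOM|HETATM)", lines)
  for (j in at) {
    v <- suppressWarnings(as.numeric(c(substr(lines[j], 31, 38),
                                       substr(lines[j], 39, 46),
                                       substr(lines[j], 47, 54))))
    if (any(is.na(v)))
      stop("PDB parse error at line ", j, ": nonnumeric coordinate")
  }
  pdb <- bio3d::read.pdb(path)
  matrix(pdb$xyz, ncol = 3, byrow = TRUE) / 10  # Angstrom -> nm
}

#' Read a per-lambda derivative series from CSV
#'
#' Expects columns \code{lambda}, \code{value} and optionally
#' \code{error}.
#'
#' @param path CSV file
#' @return a \code{lambda_series}
#' @export
read_lambda_series <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("lambda", "value") %in% names(df)))
    stop("lambda-series CSV needs columns 'lambda' and 'value'")
  lambda_series(df$lambda, df$value,
                errors = if ("error" %in% names(df)) df$error else NULL)
}
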