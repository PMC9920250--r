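# Atomic systems, element defaults, and XYZ file input/output.
# Coordinates are stored in Angstrom; the engine converts to Bohr
# internally.

# Valence-shell defaults per element: shells, reference occupations and
# masses.  X/Y/Z are the synthetic fixture elements of the packaged SK
# generator; the real-element rows serve the user-supplied-parameter
# pathway (s/p valence only).
element_defaults <- function() {
  read_tab <- function() {
    path <- system.file("extdata", "elements.tsv", package = "qmetad")
    if (path == "") path <- file.path("inst", "extdata", "elements.tsv")
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  }
  tab <- read_tab()
  rownames(tab) <- tab$symbol
  tab
}

#' Construct an atomic system
#'
#' @param symbols Character vector of element symbols.
#' @param coords Numeric n x 3 matrix of Cartesian positions in Angstrom.
#' @param net_charge Integer net charge in e (electron-count convention:
#'   total valence electrons = sum of reference occupations - net_charge).
#' @return An `atomic_system` object.
#' @export
atomic_system <- function(symbols, coords, net_charge = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3 || nrow(coords) != length(symbols))
    stop("atomic_system: coords must be length(symbols) x 3")
  eltab <- element_defaults()
  unknown <- setdiff(symbols, rownames(eltab))
  if (length(unknown))
    stop("atomic_system: unknown element(s): ", paste(unknown, collapse = ", "))
  if (nrow(coords) > 1) {
    dmin <- min(stats::dist(coords))
    if (dmin < 0.3)
      stop("atomic_system: atoms closer than 0.3 Angstrom (", signif(dmin, 3), ")")
  }
  info <- eltab[symbols, , drop = FALSE]
  shells <- lapply(seq_along(symbols), function(i)
    if (info$shells[i] == "sp") c("s", "p") else "s")
  electrons <- sum(info$occ_s + info$occ_p) - net_charge
  structure(list(symbols = as.character(symbols), coords = coords,
                 net_charge = as.integer(net_charge),
                 shells = shells,
                 ref_occ = info$occ_s + info$occ_p,
                 masses = info$mass,
                 electrons = electrons),
            class = "atomic_system")
}

#' @export
print.atomic_system <- function(x, ...) {
  cat(sprintf("atomic_system: %d atoms (%s), net charge %+d, %g valence electrons\n",
              length(x$symbols), paste(unique(x$symbols), collapse = ","),
              x$net_charge, x$electrons))
  invisible(x)
}

n_orbitals <- function(system) {
  vapply(system$shells, function(s) if ("p" %in% s) 4L else 1L, 1L)
}

#' Read an XYZ geometry file
#'
#' Standard XYZ: atom count line, comment line, then `symbol x y z` rows
#' in Angstrom.
#'
#' @param path File path.
#' @return List with `symbols`, `coords` (Angstrom), `comment`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("read_xyz: bad atom count on line 1")
  if (length(lines) < n + 2) stop("read_xyz: file shorter than atom count")
  rows <- strsplit(trimws(lines[3:(n + 2)]), "[ \t]+")
  symbols <- vapply(rows, `[`, "", 1)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  if (anyNA(coords)) stop("read_xyz: non-numeric coordinate")
  list(symbols = symbols, coords = coords, comment = lines[2])
}

#' Write an XYZ geometry file
#'
#' @param symbols Element symbols.
#' @param coords n x 3 coordinates in Angstrom.
#' @param path Output path.
#' @param comment Comment line.
#' @param append Append as an extra frame.
#' @export
write_xyz <- function(symbols, coords, path, comment = "", append = FALSE) {
  out <- c(as.character(length(symbols)), comment,
           sprintf("%-2s %16.10f %16.10f %16.10f",
                   symbols, coords[, 1], coords[, 2], coords[, 3]))
  if (append) cat(out, file = path, sep = "\n", append = TRUE)
  else writeLines(out, path)
  invisible(path)
}
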