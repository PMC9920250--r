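# Slater-Koster parameter tables: reading/writing the dftb.org-style text
# dialect (restricted to s/p shells), a synthetic-table generator so the
# quantum engine is testable without downloads, spline interpolation of the
# tabulated two-center integrals, and the repulsive pair potential.
#
# File dialect (whitespace separated):
#   line 1: gridDist nGridPoints
#   line 2 (homonuclear only): Ed Ep Es SPE Ud Up Us fd fp fs
#           Es/Ep are the free-atom on-site energies (Ha); Us/Up the
#           shell-resolved Hubbard parameters (Ha); fs/fp valence
#           occupations.  In this s/p-restricted dialect the Ud column
#           carries the third-order Hubbard derivative (Ha/e); Ed and fd
#           are present but ignored.
#   line 3: mass c2..c9 rcut d1..d10 (only mass is used)
#   nGridPoints rows of 20 columns: Hdd0 Hdd1 Hdd2 Hpd0 Hpd1 Hpp0 Hpp1
#           Hsd0 Hsp0 Hss0 then the same order for S (d columns read and
#           ignored; the distance of row k is k*gridDist Bohr)
#   "Spline" block: "nInt cutoff", one exponential head line "a1 a2 a3",
#           nInt-1 cubic rows "start end c0 c1 c2 c3", and a final 8-number
#           row "start end c0 c1 c2 c3 c4 c5".
# All distances in Bohr, energies in Hartree.

SK_CHANNELS <- c("ss_sigma", "sp_sigma", "pp_sigma", "pp_pi")

new_sk_table <- function(pair, grid_step, n_points, H, S, repulsive,
                         onsite = NULL, mass = 0) {
  tab <- structure(list(
    pair = as.character(pair),
    grid_start = grid_step,   # first tabulated distance = one grid step
    grid_step = grid_step,
    n_points = as.integer(n_points),
    H = H, S = S,
    onsite = onsite, mass = mass,
    repulsive = repulsive), class = "sk_table")
  validate_sk_table(tab)
  tab
}

validate_sk_table <- function(tab) {
  stopifnot(inherits(tab, "sk_table"))
  if (!(tab$grid_step > 0)) stop("sk_table: grid_step must be > 0")
  for (ch in SK_CHANNELS) {
    if (length(tab$H[[ch]]) != tab$n_points ||
        length(tab$S[[ch]]) != tab$n_points)
      stop("sk_table: channel ", ch, " length differs from n_points")
    if (abs(tab$H[[ch]][tab$n_points]) > 1e-6 ||
        abs(tab$S[[ch]][tab$n_points]) > 1e-6)
      stop("sk_table: channel ", ch, " does not decay below 1e-6 at grid end")
  }
  grid_end <- tab$grid_step * tab$n_points
  if (tab$repulsive$cutoff > grid_end + 1e-12)
    stop("sk_table: repulsive cutoff exceeds integral grid range")
  homo <- tab$pair[1] == tab$pair[2]
  if (homo && is.null(tab$onsite))
    stop("sk_table: homonuclear table must carry onsite data")
  if (!homo && !is.null(tab$onsite))
    stop("sk_table: heteronuclear table must not carry onsite data")
  invisible(tab)
}

#' @export
print.sk_table <- function(x, ...) {
  cat(sprintf("Slater-Koster table %s-%s: %d points, step %.4f Bohr, repulsive cutoff %.3f Bohr\n",
              x$pair[1], x$pair[2], x$n_points, x$grid_step, x$repulsive$cutoff))
  if (!is.null(x$onsite))
    cat(sprintf("  onsite: eps_s %.6f Ha, U_s %.4f Ha, Ud %.4f Ha/e\n",
                x$onsite$eps_s, x$onsite$U_s, x$onsite$Ud))
  invisible(x)
}

sk_grid_r <- function(tab) tab$grid_step * seq_len(tab$n_points)

#' Read one Slater-Koster parameter file
#'
#' Parses the simple (non-extended) dftb.org text dialect restricted to s/p
#' shells: the distance grid header, the homonuclear on-site line, the
#' two-center Hamiltonian/overlap integral table and the repulsive-spline
#' block.  d-shell columns are read and ignored.
#'
#' @param path Path to the `.skf` file.
#' @param pair Character vector of two element symbols, ordered
#'   (first index = element owning the row orbitals).
#' @return An `sk_table` object.
#' @export
read_sk_file <- function(path, pair) {
  if (!file.exists(path)) stop("SK file not found: ", path)
  lines <- readLines(path)
  pair <- as.character(pair)
  homo <- pair[1] == pair[2]
  nums <- function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[ \t,]+")[[1]]))
    if (anyNA(v)) stop("SK parse error at line ", i, ": non-numeric field")
    v
  }
  hdr <- nums(1)
  if (length(hdr) < 2) stop("SK parse error at line 1: need gridDist nGridPoints")
  grid_step <- hdr[1]; n_points <- as.integer(hdr[2])
  if (n_points <= 0) stop("SK parse error at line 1: nGridPoints must be positive")
  ln <- 2
  onsite <- NULL
  if (homo) {
    v <- nums(ln)
    if (length(v) < 10) stop("SK parse error at line ", ln, ": onsite line needs 10 fields")
    onsite <- list(eps_s = v[3], eps_p = v[2], spe = v[4],
                   Ud = v[5], U_p = v[6], U_s = v[7],
                   occ_s = v[10], occ_p = v[9])
    ln <- ln + 1
  }
  v <- nums(ln)
  mass <- v[1]
  ln <- ln + 1
  if (length(lines) < ln + n_points - 1)
    stop("SK parse error at line ", ln, ": integral table shorter than nGridPoints")
  tab_rows <- matrix(0, n_points, 20)
  for (k in seq_len(n_points)) {
    v <- nums(ln + k - 1)
    if (length(v) != 20)
      stop("SK parse error at line ", ln + k - 1, ": expected 20 columns, got ", length(v))
    tab_rows[k, ] <- v
  }
  ln <- ln + n_points
  # column order: Hdd0 Hdd1 Hdd2 Hpd0 Hpd1 Hpp0 Hpp1 Hsd0 Hsp0 Hss0, then S
  H <- list(ss_sigma = tab_rows[, 10], sp_sigma = tab_rows[, 9],
            pp_sigma = tab_rows[, 6], pp_pi = tab_rows[, 7])
  S <- list(ss_sigma = tab_rows[, 20], sp_sigma = tab_rows[, 19],
            pp_sigma = tab_rows[, 16], pp_pi = tab_rows[, 17])
  while (ln <= length(lines) && !grepl("^\\s*Spline\\s*$", lines[ln])) ln <- ln + 1
  if (ln > length(lines))
    stop("SK parse error: missing Spline block (expected after line ",
         ln - 1, ")")
  ln <- ln + 1
  v <- nums(ln); n_int <- as.integer(v[1]); cutoff <- v[2]; ln <- ln + 1
  if (n_int < 1) stop("SK parse error at line ", ln - 1, ": spline needs >= 1 interval")
  head_coef <- nums(ln); ln <- ln + 1
  if (length(head_coef) != 3)
    stop("SK parse error at line ", ln - 1, ": exponential head needs 3 numbers")
  knots <- vector("list", n_int)
  for (k in seq_len(n_int)) {
    v <- nums(ln)
    want <- if (k == n_int) 8L else 6L
    if (length(v) != want)
      stop("SK parse error at line ", ln, ": spline row needs ", want, " numbers")
    knots[[k]] <- c(v, rep(0, 8 - length(v)))
    ln <- ln + 1
  }
  km <- do.call(rbind, knots)
  repulsive <- list(head = head_coef, cutoff = cutoff,
                    start = km[, 1], end = km[, 2],
                    coef = km[, 3:8, drop = FALSE])
  new_sk_table(pair, grid_step, n_points, H, S, repulsive, onsite, mass)
}

#' Write one Slater-Koster parameter file
#'
#' Emits the dialect read by [read_sk_file()] with 15 significant digits so
#' that a read/write round trip is numerically exact.
#'
#' @param table An `sk_table`.
#' @param path Output file path.
#' @export
write_sk_file <- function(table, path) {
  validate_sk_table(table)
  fmt <- function(x) sprintf("%.15g", x)
  row <- function(...) paste(vapply(c(...), fmt, ""), collapse = " ")
  out <- character(0)
  out <- c(out, row(table$grid_step, table$n_points))
  if (!is.null(table$onsite)) {
    o <- table$onsite
    out <- c(out, row(0, o$eps_p, o$eps_s, o$spe, o$Ud, o$U_p, o$U_s,
                      0, o$occ_p, o$occ_s))
  }
  out <- c(out, row(table$mass, rep(0, 19)))
  for (k in seq_len(table$n_points)) {
    h <- c(0, 0, 0, 0, 0, table$H$pp_sigma[k], table$H$pp_pi[k], 0,
           table$H$sp_sigma[k], table$H$ss_sigma[k])
    s <- c(0, 0, 0, 0, 0, table$S$pp_sigma[k], table$S$pp_pi[k], 0,
           table$S$sp_sigma[k], table$S$ss_sigma[k])
    out <- c(out, row(h, s))
  }
  rep <- table$repulsive
  n_int <- length(rep$start)
  out <- c(out, "Spline", row(n_int, rep$cutoff), row(rep$head))
  for (k in seq_len(n_int)) {
    nc <- if (k == n_int) 6L else 4L
    out <- c(out, row(rep$start[k], rep$end[k], rep$coef[k, seq_len(nc)]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Interpolate a tabulated two-center integral channel
#'
#' Natural cubic-spline evaluation of one H or S channel on the table's
#' distance grid; exactly zero beyond the last grid point.
#'
#' @param table An `sk_table`.
#' @param r Distance(s) in Bohr, `r > 0`.
#' @param channel One of `"ss_sigma"`, `"sp_sigma"`, `"pp_sigma"`,
#'   `"pp_pi"`.
#' @param which `"H"` for Hamiltonian, `"S"` for overlap.
#' @return Interpolated value(s) in Hartree (H) or dimensionless (S).
#' @export
sk_interpolate <- function(table, r, channel, which = c("H", "S")) {
  which <- match.arg(which)
  if (!channel %in% SK_CHANNELS) stop("unknown SK channel: ", channel)
  if (any(r <= 0)) stop("sk_interpolate: r must be positive")
  y <- table[[which]][[channel]]
  x <- sk_grid_r(table)
  key <- paste0("spl_", which, "_", channel)
  f <- attr(table, key)
  if (is.null(f)) f <- stats::splinefun(x, y, method = "natural")
  out <- numeric(length(r))
  inside <- r <= x[length(x)]
  if (any(inside)) out[inside] <- f(r[inside])
  out
}

# memoize splinefuns on a table (returns table with cached attributes)
sk_cache_splines <- function(table) {
  x <- sk_grid_r(table)
  for (w in c("H", "S")) for (ch in SK_CHANNELS) {
    key <- paste0("spl_", w, "_", ch)
    if (is.null(attr(table, key)))
      attr(table, key) <- stats::splinefun(x, table[[w]][[ch]], method = "natural")
  }
  table
}

#' Repulsive pair energy from the SK spline block
#'
#' Evaluates the tabulated repulsive potential: exponential head below the
#' first knot, piecewise polynomial inside the knot range, exactly zero at
#' and beyond the cutoff.
#'
#' @param table An `sk_table`.
#' @param r Distance(s) in Bohr, `r > 0`.
#' @return Repulsive energy in Hartree.
#' @export
sk_repulsive_energy <- function(table, r) {
  if (any(r <= 0)) stop("sk_repulsive_energy: r must be positive")
  rep <- table$repulsive
  out <- numeric(length(r))
  for (i in seq_along(r)) {
    ri <- r[i]
    if (ri >= rep$cutoff) { out[i] <- 0; next }
    if (ri < rep$start[1]) {
      out[i] <- exp(-rep$head[1] * ri + rep$head[2]) + rep$head[3]
      next
    }
    k <- findInterval(ri, rep$start)
    d <- ri - rep$start[k]
    out[i] <- sum(rep$coef[k, ] * d^(0:5))
  }
  out
}

#' Default parameters of the synthetic Slater-Koster generator
#'
#' Per-element on-site data (energies, Hubbard U and derivative,
#' occupations) for the synthetic elements X (s shell), Y (s) and Z
#' (s,p), plus the per-channel amplitudes, decay length, repulsive
#' quadratic coefficient/cutoff and distance grid shared by all pairs.
#' Pass a modified copy to [make_synthetic_sk()] to change the fixture
#' chemistry.
#'
#' @return Parameter list (see [make_synthetic_sk()]).
#' @export
synthetic_sk_defaults <- function() {
  list(
    elements = list(
      X = list(shells = "s", eps_s = -0.5, eps_p = 0, U = 0.4, Ud = -0.1,
               occ_s = 1, occ_p = 0, mass = 2.0),
      Y = list(shells = "s", eps_s = -0.4, eps_p = 0, U = 0.3, Ud = -0.08,
               occ_s = 1, occ_p = 0, mass = 3.0),
      Z = list(shells = c("s", "p"), eps_s = -0.6, eps_p = -0.25,
               U = 0.35, Ud = -0.12, occ_s = 2, occ_p = 2, mass = 12.0)),
    # per-pair two-center channel shapes: value = amp * exp(-r / decay)
    amp_H = c(ss_sigma = -0.35, sp_sigma = 0.25, pp_sigma = 0.30,
              pp_pi = -0.15),
    amp_S = c(ss_sigma = 0.30, sp_sigma = -0.20, pp_sigma = -0.25,
              pp_pi = 0.12),
    decay = 0.8,           # Bohr
    rep_a = 0.08,          # Ha/Bohr^2, V_rep = a (r - rc)^2 inside cutoff
    rep_cutoff = 3.5,      # Bohr
    grid_step = 0.1,       # Bohr
    n_points = 140)
}

#' Generate a synthetic Slater-Koster table set
#'
#' Builds smooth, exponentially decaying H/S channels and a short-range
#' quadratic repulsive spline for every ordered element pair, deterministic
#' for a fixed seed.  The set replaces external parameter downloads in all
#' tests: overlap amplitudes are kept small enough that assembled overlap
#' matrices stay positive definite for the packaged fixture geometries, and
#' the repulsive potential is exactly `a (r - rc)^2` inside its cutoff.
#'
#' @param elements Character vector of element symbols (subset of the
#'   parameter list names).
#' @param params Parameter list as returned by `synthetic_sk_defaults()`;
#'   per-element on-site data plus per-channel amplitude and decay length.
#' @param seed Integer seed; amplitudes receive a small deterministic
#'   seed-dependent perturbation so different seeds give distinct sets.
#' @return Named list of `sk_table` objects, one per ordered pair
#'   (names like `"X-Y"`).
#' @export
make_synthetic_sk <- function(elements = c("X", "Y"),
                              params = synthetic_sk_defaults(),
                              seed = 1) {
  if (params$decay <= 0) stop("make_synthetic_sk: decay length must be positive")
  missing_el <- setdiff(elements, names(params$elements))
  if (length(missing_el))
    stop("make_synthetic_sk: no parameters for element(s) ",
         paste(missing_el, collapse = ", "))
  r <- params$grid_step * seq_len(params$n_points)
  jitter <- with_seed(seed, stats::runif(8, -0.05, 0.05))
  tables <- list()
  for (a in elements) for (b in elements) {
    ea <- params$elements[[a]]; eb <- params$elements[[b]]
    # pair scaling: ss/pp channels must be identical for tables A-B and
    # B-A (they tabulate the same physical integral), so their scale is
    # symmetric in the pair; only the sp channel is directional
    # (sp_sigma(A,B) tabulates <s_A|..|p_B>).
    sc_sym <- 1 + 0.1 * (ea$eps_s + eb$eps_s)
    sc_dir <- sc_sym * (1 + 0.1 * (ea$eps_s - eb$eps_s))
    mk <- function(amp, j, sc) (amp * (1 + j)) * sc * exp(-r / params$decay)
    H <- list(ss_sigma = mk(params$amp_H["ss_sigma"], jitter[1], sc_sym),
              sp_sigma = mk(params$amp_H["sp_sigma"], jitter[2], sc_dir),
              pp_sigma = mk(params$amp_H["pp_sigma"], jitter[3], sc_sym),
              pp_pi    = mk(params$amp_H["pp_pi"],    jitter[4], sc_sym))
    S <- list(ss_sigma = mk(params$amp_S["ss_sigma"], jitter[5], sc_sym),
              sp_sigma = mk(params$amp_S["sp_sigma"], jitter[6], sc_dir),
              pp_sigma = mk(params$amp_S["pp_sigma"], jitter[7], sc_sym),
              pp_pi    = mk(params$amp_S["pp_pi"],    jitter[8], sc_sym))
    # zero out channels not supported by the pair's shells
    if (!"p" %in% ea$shells && !"p" %in% eb$shells) {
      for (ch in c("sp_sigma", "pp_sigma", "pp_pi")) {
        H[[ch]] <- numeric(params$n_points); S[[ch]] <- numeric(params$n_points)
      }
    } else if (!("p" %in% ea$shells) || !("p" %in% eb$shells)) {
      H$pp_sigma <- H$pp_pi <- numeric(params$n_points)
      S$pp_sigma <- S$pp_pi <- numeric(params$n_points)
    }
    # force exact decay below threshold at grid end (smooth taper tail)
    grid_end <- r[length(r)]
    taper <- ifelse(r > grid_end - 2, (1 + cos(pi * pmin(1, (r - (grid_end - 2)) / 2))) / 2, 1)
    for (ch in SK_CHANNELS) { H[[ch]] <- H[[ch]] * taper; S[[ch]] <- S[[ch]] * taper }
    repulsive <- synthetic_repulsive(params$rep_a, params$rep_cutoff)
    onsite <- NULL
    if (a == b)
      onsite <- list(eps_s = ea$eps_s, eps_p = ea$eps_p, spe = 0,
                     Ud = ea$Ud, U_p = ea$U, U_s = ea$U,
                     occ_s = ea$occ_s, occ_p = ea$occ_p)
    tables[[paste(a, b, sep = "-")]] <-
      new_sk_table(c(a, b), params$grid_step, params$n_points, H, S,
                   repulsive, onsite, mass = ea$mass)
  }
  tables
}

# repulsive block encoding V(r) = a (r - rc)^2 for r in [r0, rc), with a
# C1-matched exponential head below r0
synthetic_repulsive <- function(a, rc, r0 = 0.4) {
  rm <- (r0 + rc) / 2
  poly_at <- function(start) c(a * (rc - start)^2, -2 * a * (rc - start), a, 0, 0, 0)
  V0 <- a * (r0 - rc)^2
  a1 <- 2 / (rc - r0)
  a2 <- log(V0) + a1 * r0
  list(head = c(a1, a2, 0), cutoff = rc,
       start = c(r0, rm), end = c(rm, rc),
       coef = rbind(poly_at(r0), poly_at(rm)))
}
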