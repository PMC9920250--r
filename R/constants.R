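# Physical constants and unit conversions. Single source of truth:
# everything else in the package converts through these names.
# Internal units of the quantum engine are Hartree / Bohr; the MD and
# metadynamics layers work in kJ/mol, Angstrom, fs, amu, Kelvin.

HARTREE_KJMOL <- 2625.499639          # 1 Ha in kJ/mol
BOHR_ANGSTROM <- 0.529177210903       # 1 Bohr in Angstrom
HARTREE_EV    <- 27.211386245988      # 1 Ha in eV
KB_KJMOL      <- 0.008314462618       # Boltzmann constant, kJ/(mol K)
# amu * (Angstrom/fs)^2 expressed in kJ/mol (1 amu = 1 g/mol)
AMU_A2_FS2_KJMOL <- 1e4

#' Physical constants used by the package
#'
#' Returns the conversion factors the engine, dynamics and analysis layers
#' share: Hartree to kJ/mol, Bohr to Angstrom, Hartree to eV, the Boltzmann
#' constant in kJ/(mol K) and the kinetic-energy conversion for amu,
#' Angstrom and fs units.
#'
#' @return Named list of conversion factors.
#' @export
qm_constants <- function() {
  list(hartree_kjmol = HARTREE_KJMOL,
       bohr_angstrom = BOHR_ANGSTROM,
       hartree_ev = HARTREE_EV,
       kb_kjmol = KB_KJMOL,
       amu_a2_fs2_kjmol = AMU_A2_FS2_KJMOL)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

# wrap angles into (-pi, pi]
wrap_angle <- function(x) {
  y <- x - 2 * pi * floor((x + pi) / (2 * pi))
  y[y <= -pi] <- y[y <= -pi] + 2 * pi
  y
}
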