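#' Physical constants used throughout the package
#'
#' CODATA-2018 values, SI units. All internal computation is done in SI;
#' file formats use the chemistry-friendly units documented in
#' [read_cluster_set()].
#'
#' | symbol  | quantity                    | value                     | unit        |
#' |---------|-----------------------------|---------------------------|-------------|
#' | `h`     | Planck constant             | 6.62607015e-34            | J s         |
#' | `hbar`  | reduced Planck constant     | h / (2*pi)                | J s         |
#' | `kB`    | Boltzmann constant          | 1.380649e-23              | J / K       |
#' | `NA`    | Avogadro constant           | 6.02214076e23             | 1 / mol     |
#' | `R`     | molar gas constant          | kB * NA                   | J / (mol K) |
#' | `c`     | speed of light              | 2.99792458e8              | m / s       |
#' | `amu`   | atomic mass unit            | 1.66053906660e-27         | kg          |
#'
#' @format A named list of numeric scalars.
#' @export
qce_constants <- local({
  h  <- 6.62607015e-34
  kB <- 1.380649e-23
  Na <- 6.02214076e23
  list(
    h    = h,
    hbar = h / (2 * pi),
    kB   = kB,
    N_A  = Na,
    R    = kB * Na,
    c    = 2.99792458e8,
    amu  = 1.66053906660e-27
  )
})

# unit conversion factors (file units -> SI)
.u_kJmol   <- 1e3                 # kJ/mol -> J/mol
.u_amuA2   <- qce_constants$amu * 1e-20   # amu Angstrom^2 -> kg m^2
.u_A3      <- 1e-30               # Angstrom^3 -> m^3
.u_bar     <- 1e5                 # bar -> Pa
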