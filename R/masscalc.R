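# Peptide monoisotopic mass and m/z arithmetic for the ComX decapeptide
# (backbone ADPITRQWGD; active form carries a farnesyl group on the
# tryptophan, a net +C15H24).

# standard monoisotopic residue masses (Da), 5-decimal convention
.residue_masses <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
.water_mono <- 18.010565
.proton_mass <- 1.007276

# built-in modification deltas (Da)
.known_mods <- c(farnesyl = 204.18780)

#' Peptide specification for mass arithmetic
#'
#' @param sequence One-letter amino-acid string over the 20 standard
#'   residues (case-insensitive).
#' @param modifications Either names of built-in modifications (currently
#'   `"farnesyl"`, +204.18780 Da, the C15H24 prenyl group on the ComX
#'   tryptophan) or a named numeric vector of mass deltas in Da.
#' @param charge Positive integer charge state (default 1).
#' @return An object of class `peptide_spec`.
#' @export
#' @examples
#' peptide_spec("ADPITRQWGD", "farnesyl", charge = 2)
peptide_spec <- function(sequence, modifications = NULL, charge = 1L) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("`sequence` must be non-empty", call. = FALSE)
  letters_ <- strsplit(sequence, "")[[1L]]
  unknown <- setdiff(letters_, names(.residue_masses))
  if (length(unknown)) {
    stop("unknown residue(s): ", paste(unique(unknown), collapse = ", "),
         call. = FALSE)
  }
  if (is.character(modifications)) {
    miss <- setdiff(modifications, names(.known_mods))
    if (length(miss)) {
      stop("unknown modification(s): ", paste(miss, collapse = ", "),
           "; pass a named numeric vector of Da deltas instead",
           call. = FALSE)
    }
    modifications <- .known_mods[modifications]
  }
  if (!is.null(modifications) && !is.numeric(modifications)) {
    stop("`modifications` must be mod names or a numeric vector", call. = FALSE)
  }
  if (charge < 1) stop("`charge` must be >= 1", call. = FALSE)
  structure(list(sequence = sequence, modifications = modifications,
                 charge = as.integer(charge)),
            class = "peptide_spec")
}

#' Monoisotopic mass of a peptide
#'
#' Sum of standard monoisotopic residue masses plus one water
#' (18.010565 Da) plus any modification deltas.
#'
#' @param spec A [peptide_spec()] or a plain sequence string.
#' @param modifications As in [peptide_spec()] (ignored when `spec` is a
#'   `peptide_spec`).
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("ADPITRQWGD")               # 1157.5465
#' monoisotopic_mass("ADPITRQWGD", "farnesyl")   # 1361.7343
monoisotopic_mass <- function(spec, modifications = NULL) {
  if (!inherits(spec, "peptide_spec")) {
    spec <- peptide_spec(spec, modifications)
  }
  letters_ <- strsplit(spec$sequence, "")[[1L]]
  sum(.residue_masses[letters_]) + .water_mono + sum(spec$modifications %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mass-to-charge ratio of a protonated ion
#'
#' `m/z = (M + z * 1.007276) / z` for the `[M + zH]^z+` ion.
#'
#' @param mass Neutral monoisotopic mass (Da), or a [peptide_spec()] (its
#'   charge is then used unless `charge` is given).
#' @param charge Positive integer charge state.
#' @return m/z value.
#' @export
#' @examples
#' mz(monoisotopic_mass("ADPITRQWGD"), 2)  # 579.7805
mz <- function(mass, charge = NULL) {
  if (inherits(mass, "peptide_spec")) {
    charge <- charge %||% mass$charge
    mass <- monoisotopic_mass(mass)
  }
  if (is.null(charge) || any(charge < 1)) {
    stop("`charge` must be >= 1", call. = FALSE)
  }
  (mass + charge * .proton_mass) / charge
}

#' Convert a mass concentration to molar concentration
#'
#' @param conc Concentration in ug/L.
#' @param molar_mass Molar mass in g/mol (> 0).
#' @return Concentration in nmol/L.
#' @export
#' @examples
#' mass_conc_to_molar(4.5, monoisotopic_mass("ADPITRQWGD", "farnesyl")) # 3.3 nM
mass_conc_to_molar <- function(conc, molar_mass) {
  if (any(molar_mass <= 0)) stop("`molar_mass` must be > 0", call. = FALSE)
  conc / molar_mass * 1000
}
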