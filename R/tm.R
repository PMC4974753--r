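# Unified nearest-neighbor duplex parameters (SantaLucia 1998):
# dH in kcal/mol, dS in cal/(mol K), indexed by the top-strand dinucleotide
# step. Initiation terms depend on the terminal base pair (G.C vs A.T).
nn_params <- local({
  dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
          CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
          CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
          CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
          CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
          CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
          CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
  list(dH = dH, dS = dS,
       init_dH = c(GC = 0.1, AT = 2.3), init_dS = c(GC = -2.8, AT = 4.1))
})

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature of a primer against its perfect complement,
#' computed with the unified nearest-neighbor thermodynamic table
#' (SantaLucia 1998) at fixed default conditions: 50 mM monovalent cation
#' and 50 nM annealing oligo. The salt correction is applied to the entropy
#' (`dS + 0.368 * (n-1) * ln[Na+]`). Deterministic; a primer and its reverse
#' complement have equal Tm.
#'
#' @param primer character vector of unambiguous DNA strings, 10--40 nt.
#' @param Na monovalent cation concentration, mol/L.
#' @param conc oligo concentration, mol/L.
#' @return numeric vector of melting temperatures in degrees Celsius.
#' @examples
#' melting_temperature("ACGTACGTACGTACGTACGT")
#' @export
melting_temperature <- function(primer, Na = 0.05, conc = 50e-9) {
  primer <- toupper(primer)
  vapply(primer, function(p) {
    n <- nchar(p)
    if (n < 10L || n > 40L) stop("primer must be 10-40 nt: ", p)
    if (grepl("[^ACGT]", p)) stop("ambiguous base in primer: ", p)
    steps <- substring(p, 1:(n - 1L), 2:n)
    dH <- sum(nn_params$dH[steps])
    dS <- sum(nn_params$dS[steps])
    for (term in c(substr(p, 1L, 1L), substr(p, n, n))) {
      cl <- if (term %in% c("G", "C")) "GC" else "AT"
      dH <- dH + nn_params$init_dH[[cl]]
      dS <- dS + nn_params$init_dS[[cl]]
    }
    dS <- dS + 0.368 * (n - 1L) * log(Na)
    dH * 1000 / (dS + 1.987 * log(conc / 4)) - 273.15
  }, 0, USE.NAMES = FALSE)
}
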