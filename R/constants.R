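#' The RD1 endotoxin aptamer construct
#'
#' 66-nt ssDNA used as the tether: a 36-nt endotoxin-binding core flanked by
#' two 15-nt non-complementary extension arms. The 5' end carries an amino
#' modification (film coupling via EDC/NHS), the 3' end a thiol (AuNP
#' coupling).
#'
#' @return A single character string (5' to 3').
#' @export
#' @examples
#' nchar(rd1_sequence())
rd1_sequence <- function() {
  paste0(
    "AAGAAACAGTGAGGA",
    "GTCGAATGCTCTGCCTGGAAGAGTTGTTAGCAGGGA",
    "ACAGGAAAGAGTGGT"
  )
}

#' @rdname rd1_sequence
#' @export
rd1_binding_region <- function() "GTCGAATGCTCTGCCTGGAAGAGTTGTTAGCAGGGA"

# Boltzmann constant, J/K
.kB <- 1.380649e-23
# Avogadro constant, 1/mol
.NA_const <- 6.02214076e23
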