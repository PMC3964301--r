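## Packaged per-residue tables: average residue masses (Da, i.e. the amino
## acid minus water, as summed in a peptide chain) and Kyte-Doolittle
## hydropathy values used by the "statistical" contact-energy scheme.

#' Average amino-acid residue masses
#'
#' Average (isotope-abundance weighted) residue masses in Da for the twenty
#' standard amino acids, i.e. the mass contributed by each residue inside a
#' peptide chain (free amino acid minus one water). Each coarse-grained bead
#' carries the mass of its residue type.
#'
#' @format Named numeric vector, three-letter residue codes in upper case.
#' @export
residue_masses <- c(
  GLY =  57.052, ALA =  71.079, SER =  87.078, PRO =  97.117,
  VAL =  99.133, THR = 101.105, CYS = 103.144, LEU = 113.160,
  ILE = 113.160, ASN = 114.104, ASP = 115.089, GLN = 128.131,
  LYS = 128.174, GLU = 129.116, MET = 131.198, HIS = 137.141,
  PHE = 147.177, ARG = 156.188, TYR = 163.176, TRP = 186.213
)

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values used to derive pairwise weights for the
#' optional "statistical" contact-energy scheme (more hydrophobic pairs get
#' deeper wells, renormalized to a configured mean depth).
#'
#' @format Named numeric vector, three-letter residue codes in upper case.
#' @export
kyte_doolittle <- c(
  ILE =  4.5, VAL =  4.2, LEU =  3.8, PHE =  2.8, CYS =  2.5,
  MET =  1.9, ALA =  1.8, GLY = -0.4, THR = -0.7, SER = -0.8,
  TRP = -0.9, TYR = -1.3, PRO = -1.6, HIS = -3.2, GLU = -3.5,
  GLN = -3.5, ASP = -3.5, ASN = -3.5, LYS = -3.9, ARG = -4.5
)

#' Look up residue masses, failing loudly on unknown residue names
#' @noRd
lookup_residue_mass <- function(res_names) {
  res_names <- toupper(res_names)
  unknown <- setdiff(unique(res_names), names(residue_masses))
  if (length(unknown) > 0L) {
    stop("unknown residue name(s), no mass assigned: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unname(residue_masses[res_names])
}
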