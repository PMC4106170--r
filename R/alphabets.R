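#' @keywords internal
"_PACKAGE"

#' Backbone atom kinds, standard residues and secondary-structure states
#'
#' The four protein backbone nuclei tracked by the package, in the fixed
#' block order used throughout (\code{N15}, \code{C13A}, \code{H1A},
#' \code{H1N}); the 20 standard one-letter amino-acid codes in alphabetical
#' order; and the three-state secondary-structure alphabet
#' (H = helix, E = strand, C = coil/other).
#'
#' @name alphabets
#' @aliases acs_atoms acs_residues acs_ss_states
NULL

#' @rdname alphabets
#' @export
acs_atoms <- function() c("N15", "C13A", "H1A", "H1N")

#' @rdname alphabets
#' @export
acs_residues <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname alphabets
#' @export
acs_ss_states <- function() c("H", "E", "C")

# 3-letter -> 1-letter residue code map (upper case keys)
.aa3to1 <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y"
)

.aa1to3 <- structure(names(.aa3to1), names = unname(.aa3to1))

# normalize a residue name (1- or 3-letter) to the one-letter code,
# NA if unknown
.normalize_residue <- function(x) {
  x <- toupper(x)
  out <- ifelse(nchar(x) == 3L, unname(.aa3to1[x]),
                ifelse(x %in% unname(.aa3to1), x, NA_character_))
  out
}

.check_atom <- function(atom) {
  if (!all(atom %in% acs_atoms())) {
    stop("unknown atom kind(s): ",
         paste(setdiff(atom, acs_atoms()), collapse = ", "),
         "; must be one of ", paste(acs_atoms(), collapse = ", "),
         call. = FALSE)
  }
  invisible(atom)
}
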