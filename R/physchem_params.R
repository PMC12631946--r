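# Element parameters and the bundled coarse charge template.

# Coulomb constant in kcal*Angstrom/(mol*e^2)
COULOMB_K <- 332.0637

# Bondi van der Waals radii (Angstrom)
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
               F = 1.47, Cl = 1.75, Br = 1.85, Se = 1.90)

# Lennard-Jones well depths (kcal/mol) and zero-crossing distances sigma
# (Angstrom) per element, Amber-like magnitudes; combined with
# Lorentz-Berthelot mixing
LJ_EPSILON <- c(C = 0.086, N = 0.170, O = 0.210, S = 0.250, H = 0.0157,
                P = 0.200)
LJ_SIGMA   <- c(C = 3.40, N = 3.25, O = 2.96, S = 3.56, H = 2.47, P = 3.74)

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
names(AA1) <- AA3

# hydrophobic side chains (Kyte-Doolittle positive)
HYDROPHOBIC_AA <- c("ALA", "VAL", "LEU", "ILE", "PHE", "MET", "CYS")

#' Coarse per-atom charge template
#'
#' Assigns partial charges (elementary charge units) to heavy atoms from a
#' residue-level template: charged side-chain groups carry their formal
#' charge split over the equivalent atoms (carboxylate oxygens -0.5 each,
#' lysine NZ +1, arginine NH1/NH2 +0.5 each), and the backbone carries a
#' neutral dipole pattern (C +0.45 / O -0.45, N -0.35 / CA +0.35). All other
#' atoms are 0. This is a deliberately simple stand-in for a full
#' force-field assignment; per-atom charges from a PQR file (e.g. PDB2PQR
#' output) can be supplied wherever charges are accepted.
#'
#' @param atoms atom table from [parse_structure()].
#' @return Numeric vector of charges, one per atom row.
#' @export
assign_default_charges <- function(atoms) {
  q <- numeric(nrow(atoms))
  nm <- atoms$name; rn <- atoms$resname
  q[nm == "C"] <- 0.45
  q[nm == "O" | nm == "OXT"] <- -0.45
  q[nm == "N"] <- -0.35
  q[nm == "CA" & atoms$element == "C"] <- 0.35
  q[rn == "ASP" & nm %in% c("OD1", "OD2")] <- -0.5
  q[rn == "GLU" & nm %in% c("OE1", "OE2")] <- -0.5
  q[rn == "LYS" & nm == "NZ"] <- 1.0
  q[rn == "ARG" & nm %in% c("NH1", "NH2")] <- 0.5
  q
}

#' Read charges and radii from a PQR file
#'
#' PQR is the PDB2PQR output format: ATOM records whose last two whitespace
#' separated fields are the partial charge and radius.
#'
#' @param pqr_text character scalar or vector of lines.
#' @return data.frame with `name`, `resname`, `chain`, `resno`, `charge`,
#'   `radius`.
#' @export
read_pqr <- function(pqr_text) {
  lines <- if (length(pqr_text) == 1L && grepl("\n", pqr_text, fixed = TRUE))
    strsplit(pqr_text, "\n", fixed = TRUE)[[1L]] else pqr_text
  lines <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (length(lines) == 0L) stop("no ATOM records in PQR input")
  parts <- strsplit(trimws(lines), "\\s+")
  do.call(rbind, lapply(parts, function(p) {
    k <- length(p)
    data.frame(name = p[3L], resname = p[4L], chain = p[5L],
               resno = as.integer(p[6L]),
               charge = as.numeric(p[k - 1L]), radius = as.numeric(p[k]),
               stringsAsFactors = FALSE)
  }))
}
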