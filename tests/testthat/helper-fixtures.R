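# shared fixtures built in code

# minimal empty bonded tables
emptyBonded <- function() list(
  bonds = data.frame(i = integer(0), j = integer(0), kb = numeric(0),
                     r0 = numeric(0)),
  angles = data.frame(i = integer(0), j = integer(0), k = integer(0),
                      ka = numeric(0), theta0 = numeric(0)),
  dihedrals = data.frame(i = integer(0), j = integer(0), k = integer(0),
                         l = integer(0), barrier = numeric(0),
                         periodicity = integer(0), phase = numeric(0)))

# a bare ForceFieldTable from per-atom parameter vectors
makeFF <- function(charge, lj_sigma = 3.0, lj_epsilon = 0.1,
                   gb_radius = 1.7, gb_scale = 0.8,
                   bonds = NULL, angles = NULL, dihedrals = NULL) {
  n <- length(charge)
  eb <- emptyBonded()
  new("ForceFieldTable",
      atoms = data.frame(charge = charge,
                         lj_sigma = rep_len(lj_sigma, n),
                         lj_epsilon = rep_len(lj_epsilon, n),
                         gb_radius = rep_len(gb_radius, n),
                         gb_scale = rep_len(gb_scale, n)),
      bonds = if (is.null(bonds)) eb$bonds else bonds,
      angles = if (is.null(angles)) eb$angles else angles,
      dihedrals = if (is.null(dihedrals)) eb$dihedrals else dihedrals)
}

# simple n-atom structure on given coordinates (single ALA-like chain,
# one residue per atom so any subset is a valid model)
makeModel <- function(xyz, element = "C", chain = "A") {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  structureModel(data.frame(
    serial = seq_len(n), name = paste0("C", seq_len(n)),
    element = rep_len(element, n), resname = "ALA",
    chain = rep_len(chain, n), resseq = seq_len(n), icode = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE))
}

# deterministic random rotation matrix from a seed
randomRotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# one-line PDB records for parser tests
pdbLine <- function(serial = 1, name = "CA", resname = "ALA",
                    chain = "A", resseq = 1, x = 0, y = 0, z = 0,
                    element = "C", icode = " ", altloc = " ") {
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, altloc, resname, chain, resseq, icode,
          x, y, z, 1, 0, element)
}
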