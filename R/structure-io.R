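#' @include AllClasses.R AllGenerics.R
NULL

.AMINO_RESNAMES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                     "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                     "PRO", "SER", "THR", "TRP", "TYR", "VAL")

.BACKBONE_NAMES <- c("N", "CA", "C", "O")

.substr_trim <- function(line, a, b) trimws(substring(line, a, b))

.num_field <- function(line, a, b, lineno, what) {
  s <- .substr_trim(line, a, b)
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v))
    stop(sprintf("line %d: malformed %s field '%s'", lineno, what, s),
         call. = FALSE)
  v
}

.parse_atom_line <- function(line, lineno) {
  name <- .substr_trim(line, 13, 16)
  element <- .substr_trim(line, 77, 78)
  if (!nzchar(element)) {
    # fall back to the first alphabetic character of the atom name
    element <- regmatches(name, regexpr("[A-Za-z]", name))
    if (!length(element))
      stop(sprintf("line %d: cannot determine element for atom '%s'",
                   lineno, name), call. = FALSE)
  }
  list(
    serial  = as.integer(.num_field(line, 7, 11, lineno, "serial")),
    name    = name,
    altloc  = substring(line, 17, 17),
    resname = .substr_trim(line, 18, 20),
    chain   = substring(line, 22, 22),
    resseq  = as.integer(.num_field(line, 23, 26, lineno, "residue number")),
    icode   = trimws(substring(line, 27, 27)),
    x = .num_field(line, 31, 38, lineno, "x coordinate"),
    y = .num_field(line, 39, 46, lineno, "y coordinate"),
    z = .num_field(line, 47, 54, lineno, "z coordinate"),
    element = element)
}

.parse_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substring(lines, 1, 6)
  is_atom <- grepl("^(ATOM|HETATM)", rec)
  model_id <- integer(length(lines))
  cur <- 1L
  seen_model <- FALSE
  for (i in seq_along(lines)) {
    r <- trimws(rec[i])
    if (r == "MODEL") {
      if (seen_model) cur <- cur + 1L
      seen_model <- TRUE
    } else if (r == "ENDMDL") {
      # next MODEL record advances; tolerate ENDMDL without MODEL
    }
    model_id[i] <- cur
  }
  idx <- which(is_atom)
  if (!length(idx)) stop("empty structure: no ATOM/HETATM records in ",
                         path, call. = FALSE)
  parsed <- lapply(idx, function(i) .parse_atom_line(lines[i], i))
  keep <- vapply(parsed, function(p) p$altloc %in% c(" ", "", "A"),
                 logical(1))
  parsed <- parsed[keep]
  mid <- model_id[idx][keep]
  atoms <- data.frame(
    serial  = vapply(parsed, `[[`, integer(1), "serial"),
    name    = vapply(parsed, `[[`, character(1), "name"),
    element = vapply(parsed, `[[`, character(1), "element"),
    resname = vapply(parsed, `[[`, character(1), "resname"),
    chain   = vapply(parsed, `[[`, character(1), "chain"),
    resseq  = vapply(parsed, `[[`, integer(1), "resseq"),
    icode   = vapply(parsed, `[[`, character(1), "icode"),
    x = vapply(parsed, `[[`, numeric(1), "x"),
    y = vapply(parsed, `[[`, numeric(1), "y"),
    z = vapply(parsed, `[[`, numeric(1), "z"),
    stringsAsFactors = FALSE)
  split(atoms, mid)
}

#' Read a protein structure from a PDB file
#'
#' Parses `ATOM`/`HETATM` records in file order. Only alternate location
#' `'A'` or blank is kept (occupancies are ignored), giving a
#' deterministic single-conformer model. Residue identity is the triple
#' (chain, residue number, insertion code), taken verbatim from the
#' file. If the file holds several `MODEL` blocks the first model is
#' returned and the model count reported via a message.
#'
#' @param path Path to a PDB file.
#' @param chainRoles Optional named character vector assigning roles
#'   (`ligand_alpha`, `ligand_beta`, `receptor`, `other`) to chain ids;
#'   unassigned chains default to `"other"`.
#' @return A [StructureModel-class].
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(paste0(
#'   "ATOM      1  CA  ALA A   1       0.000   0.000   0.000",
#'   "  1.00  0.00           C"), pdb)
#' m <- readPDB(pdb)
#' nAtoms(m)
#' @export
readPDB <- function(path, chainRoles = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  models <- .parse_pdb_models(path)
  if (length(models) > 1L)
    message(length(models), " models in ", basename(path),
            "; returning the first")
  atoms <- models[[1L]]
  if (!nrow(atoms)) stop("empty structure: no atoms in first model",
                         call. = FALSE)
  rownames(atoms) <- NULL
  chains <- unique(atoms$chain)
  roles <- stats::setNames(rep("other", length(chains)), chains)
  if (!is.null(chainRoles)) roles[names(chainRoles)] <- chainRoles
  new("StructureModel", atoms = atoms, chainRoles = roles)
}

#' Construct a StructureModel from an atom table
#'
#' @param atoms `data.frame` with the columns listed in
#'   [StructureModel-class].
#' @param chainRoles Optional named role vector; defaults to `"other"`.
#' @return A [StructureModel-class].
#' @export
structureModel <- function(atoms, chainRoles = NULL) {
  chains <- unique(atoms$chain)
  roles <- stats::setNames(rep("other", length(chains)), chains)
  if (!is.null(chainRoles)) roles[names(chainRoles)] <- chainRoles
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms, chainRoles = roles)
}

.format_atom_line <- function(a) {
  name <- a$name
  # PDB convention: names of < 4 characters start in column 14
  name <- if (nchar(name) < 4L) paste0(" ", name) else name
  sprintf("ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$serial, name, a$resname, a$chain, a$resseq,
          ifelse(nzchar(a$icode), a$icode, " "),
          a$x, a$y, a$z, 1, 0, a$element)
}

#' Write a structure (or trajectory) as PDB
#'
#' Coordinates are written at the PDB precision of 3 decimals; a
#' read/write/read round trip preserves atom order and coordinates to
#' that precision.
#'
#' @param x A [StructureModel-class] or [Trajectory-class]. A trajectory
#'   is written as a multi-model PDB (`MODEL`/`ENDMDL` per frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(x, path) {
  if (is(x, "Trajectory")) {
    topo <- x@topology
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_len(nFrames(x))) {
      m <- topo
      coords(m) <- frameCoords(x, f)
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(vapply(seq_len(nAtoms(m)), function(i)
        .format_atom_line(m@atoms[i, ]), character(1)), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    return(invisible(path))
  }
  lines <- vapply(seq_len(nAtoms(x)), function(i)
    .format_atom_line(x@atoms[i, ]), character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a trajectory against a known topology
#'
#' Two interchange dialects are supported and auto-detected:
#' a multi-model PDB (canonical), or a compact whitespace-separated
#' frame format whose first line is the atom count, second line a free
#' comment, followed by `n_atoms` lines of `x y z` per frame (see the
#' package README for the grammar). Every frame must match the topology
#' atom count.
#'
#' @param path Path to the trajectory file.
#' @param topology The shared [StructureModel-class].
#' @param spacingPs Time per frame, ps.
#' @return A [Trajectory-class].
#' @export
readTrajectory <- function(path, topology, spacingPs) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  nat <- nAtoms(topology)
  if (grepl("^(MODEL|ATOM|HETATM|REMARK|HEADER|TITLE|CRYST)", first)) {
    models <- .parse_pdb_models(path)
    frames <- lapply(models, function(m) unname(as.matrix(
      m[, c("x", "y", "z")])))
  } else {
    lines <- readLines(path, warn = FALSE)
    n_declared <- suppressWarnings(as.integer(trimws(lines[1L])))
    if (is.na(n_declared))
      stop("frame file header must begin with the atom count",
           call. = FALSE)
    body <- lines[-(1:2)]
    body <- body[nzchar(trimws(body))]
    if (length(body) %% n_declared != 0L)
      stop(sprintf(
        "frame file holds %d coordinate lines, not a multiple of %d atoms",
        length(body), n_declared), call. = FALSE)
    vals <- matrix(scan(text = body, quiet = TRUE), ncol = 3L,
                   byrow = TRUE)
    frames <- lapply(seq_len(nrow(vals) / n_declared), function(f)
      vals[((f - 1L) * n_declared + 1L):(f * n_declared), , drop = FALSE])
  }
  for (f in seq_along(frames))
    if (nrow(frames[[f]]) != nat)
      stop(sprintf("frame %d: expected %d atoms, got %d",
                   f, nat, nrow(frames[[f]])), call. = FALSE)
  arr <- array(0, dim = c(length(frames), nat, 3L))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  new("Trajectory", topology = topology, coords = arr,
      frameSpacing = spacingPs)
}

#' Build a Trajectory from in-memory frames
#'
#' @param topology A [StructureModel-class].
#' @param frames List of `n x 3` coordinate matrices, or an
#'   `nFrames x nAtoms x 3` array.
#' @param spacingPs Time per frame, ps.
#' @return A [Trajectory-class].
#' @export
trajectory <- function(topology, frames, spacingPs) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    arr <- frames
  } else {
    nat <- nAtoms(topology)
    arr <- array(0, dim = c(length(frames), nat, 3L))
    for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  }
  new("Trajectory", topology = topology, coords = arr,
      frameSpacing = spacingPs)
}

#' Write a trajectory in the compact frame dialect
#'
#' @param traj A [Trajectory-class].
#' @param path Output path.
#' @param comment Free-text comment for the header line.
#' @return `path`, invisibly.
#' @export
writeFrames <- function(traj, path, comment = "gfdyn frames") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nAtoms(traj)), comment), con)
  for (f in seq_len(nFrames(traj))) {
    xyz <- frameCoords(traj, f)
    writeLines(sprintf("%.6f %.6f %.6f", xyz[, 1], xyz[, 2], xyz[, 3]),
               con)
  }
  invisible(path)
}

.residue_key <- function(atoms) paste(atoms$chain, atoms$resseq,
                                      atoms$icode, sep = "|")

.residue_table <- function(model, indices = NULL) {
  a <- model@atoms
  if (!is.null(indices)) a <- a[indices, , drop = FALSE]
  key <- .residue_key(a)
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resseq = a$resseq[first],
             icode = a$icode[first], stringsAsFactors = FALSE)
}

.parse_int_set <- function(s) {
  out <- integer(0)
  for (part in strsplit(s, ",", fixed = TRUE)[[1L]]) {
    part <- trimws(part)
    if (grepl("-", part, fixed = TRUE)) {
      ab <- as.integer(strsplit(part, "-", fixed = TRUE)[[1L]])
      out <- c(out, seq(ab[1L], ab[2L]))
    } else out <- c(out, as.integer(part))
  }
  out
}

#' Create a named atom selection
#'
#' The selection expression is a conjunction of clauses separated by
#' `and` (or `&`):
#' \describe{
#'   \item{`all`}{every atom}
#'   \item{`protein`}{atoms in standard amino-acid residues}
#'   \item{`calpha`}{C-alpha atoms of protein residues}
#'   \item{`backbone`}{heavy backbone atoms `N, CA, C, O` of protein
#'     residues}
#'   \item{`heavy`}{non-hydrogen atoms}
#'   \item{`chain A,B`}{atoms of the listed chains}
#'   \item{`resseq 10-20,25`}{atoms of the listed residue numbers}
#'   \item{`name CA,NZ`}{atoms by atom name}
#'   \item{`element N,O`}{atoms by element}
#' }
#' Selections preserve atom (file) order; an empty result is an error
#' because every downstream stage requires at least one atom.
#'
#' @param model A [StructureModel-class].
#' @param spec Selection expression string.
#' @return A [Selection-class].
#' @examples
#' \dontrun{
#' makeSelection(model, "backbone and chain A")
#' }
#' @export
makeSelection <- function(model, spec) {
  a <- model@atoms
  keep <- rep(TRUE, nrow(a))
  for (clause in trimws(strsplit(spec, "\\band\\b|&")[[1L]])) {
    if (!nzchar(clause)) next
    low <- tolower(clause)
    if (low == "all") {
    } else if (low == "protein") {
      keep <- keep & a$resname %in% .AMINO_RESNAMES
    } else if (low == "calpha") {
      keep <- keep & a$resname %in% .AMINO_RESNAMES & a$name == "CA"
    } else if (low == "backbone") {
      keep <- keep & a$resname %in% .AMINO_RESNAMES &
        a$name %in% .BACKBONE_NAMES
    } else if (low == "heavy") {
      keep <- keep & toupper(a$element) != "H"
    } else if (grepl("^chain\\s+", low)) {
      ids <- trimws(strsplit(sub("^chain\\s+", "", clause), ",")[[1L]])
      keep <- keep & a$chain %in% ids
    } else if (grepl("^(resseq|resid)\\s+", low)) {
      nums <- .parse_int_set(sub("^(resseq|resid)\\s+", "", low))
      keep <- keep & a$resseq %in% nums
    } else if (grepl("^name\\s+", low)) {
      nms <- toupper(trimws(strsplit(sub("^name\\s+", "", clause),
                                     ",")[[1L]]))
      keep <- keep & toupper(a$name) %in% nms
    } else if (grepl("^element\\s+", low)) {
      els <- toupper(trimws(strsplit(sub("^element\\s+", "", clause),
                                     ",")[[1L]]))
      keep <- keep & toupper(a$element) %in% els
    } else {
      stop("unknown selection clause: '", clause, "'", call. = FALSE)
    }
  }
  idx <- which(keep)
  if (!length(idx))
    stop("empty selection for '", spec,
         "': downstream stages require at least one atom", call. = FALSE)
  new("Selection", name = spec, indices = as.integer(idx))
}

#' Read a force-field parameter file
#'
#' The parameter file is a plain-text dialect defined by this package
#' (see the README for the grammar): an `[atoms]` section keyed by
#' chain / residue number / atom name carrying charge, LJ sigma/epsilon,
#' GB radius and GB scale, followed by `[bonds]`, `[angles]` and
#' `[dihedrals]` sections whose indices are 1-based atom positions in
#' the model's file order. Every model atom must be covered.
#'
#' @param path Path to the parameter file.
#' @param model The [StructureModel-class] the parameters describe.
#' @return A [ForceFieldTable-class] with rows aligned to the model's
#'   atoms.
#' @export
readForceField <- function(path, model) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- ""
  rows <- list(atoms = list(), bonds = list(), angles = list(),
               dihedrals = list())
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      if (!section %in% names(rows))
        stop("unknown parameter section: [", section, "]", call. = FALSE)
      next
    }
    if (!nzchar(section)) stop("parameter data before any section header",
                               call. = FALSE)
    rows[[section]][[length(rows[[section]]) + 1L]] <-
      strsplit(ln, "\\s+")[[1L]]
  }
  at <- rows$atoms
  if (!length(at)) stop("parameter file has no [atoms] entries",
                        call. = FALSE)
  keys <- vapply(at, function(f) paste(f[1L], f[2L], f[3L], sep = "|"),
                 character(1))
  vals <- t(vapply(at, function(f) as.numeric(f[4:8]), numeric(5)))
  a <- model@atoms
  model_keys <- paste(a$chain, a$resseq, a$name, sep = "|")
  pos <- match(model_keys, keys)
  if (anyNA(pos)) {
    missing <- unique(model_keys[is.na(pos)])
    stop("parameter coverage error; no entry for atom(s): ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) " ..." else "", call. = FALSE)
  }
  atoms <- data.frame(charge = vals[pos, 1L], lj_sigma = vals[pos, 2L],
                      lj_epsilon = vals[pos, 3L],
                      gb_radius = vals[pos, 4L], gb_scale = vals[pos, 5L])
  parse_num_rows <- function(lst, ncol, what) {
    if (!length(lst))
      return(matrix(numeric(0), ncol = ncol))
    bad <- which(vapply(lst, length, integer(1)) != ncol)
    if (length(bad))
      stop(sprintf("malformed [%s] entry (expected %d fields): '%s'",
                   what, ncol, paste(lst[[bad[1L]]], collapse = " ")),
           call. = FALSE)
    t(vapply(lst, as.numeric, numeric(ncol)))
  }
  b <- parse_num_rows(rows$bonds, 4L, "bonds")
  g <- parse_num_rows(rows$angles, 5L, "angles")
  d <- parse_num_rows(rows$dihedrals, 7L, "dihedrals")
  bonds <- data.frame(i = as.integer(b[, 1L]), j = as.integer(b[, 2L]),
                      kb = b[, 3L], r0 = b[, 4L])
  angles <- data.frame(i = as.integer(g[, 1L]), j = as.integer(g[, 2L]),
                       k = as.integer(g[, 3L]), ka = g[, 4L],
                       theta0 = g[, 5L])
  dihedrals <- data.frame(i = as.integer(d[, 1L]), j = as.integer(d[, 2L]),
                          k = as.integer(d[, 3L]), l = as.integer(d[, 4L]),
                          barrier = d[, 5L],
                          periodicity = as.integer(d[, 6L]),
                          phase = d[, 7L])
  idx <- c(bonds$i, bonds$j, angles$i, angles$j, angles$k,
           dihedrals$i, dihedrals$j, dihedrals$k, dihedrals$l)
  if (length(idx) && (any(idx < 1L) || any(idx > nrow(a))))
    stop("bonded term references atom index outside the ",
         nrow(a), "-atom model: ",
         paste(unique(idx[idx < 1L | idx > nrow(a)]), collapse = ", "),
         call. = FALSE)
  new("ForceFieldTable", atoms = atoms, bonds = bonds, angles = angles,
      dihedrals = dihedrals)
}

#' Write a force-field parameter file
#'
#' @param ff A [ForceFieldTable-class].
#' @param model The matching [StructureModel-class] (supplies the
#'   chain/residue/name keys).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeForceField <- function(ff, model, path) {
  a <- model@atoms
  p <- ff@atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# force-field parameters (gfdyn dialect)", con)
  writeLines("[atoms]", con)
  writeLines("# chain resseq name charge lj_sigma lj_epsilon gb_radius gb_scale",
             con)
  writeLines(sprintf("%s %d %s %.6f %.6f %.6f %.6f %.6f",
                     a$chain, a$resseq, a$name, p$charge, p$lj_sigma,
                     p$lj_epsilon, p$gb_radius, p$gb_scale), con)
  writeLines("[bonds]", con)
  if (nrow(ff@bonds))
    writeLines(sprintf("%d %d %.6f %.6f", ff@bonds$i, ff@bonds$j,
                       ff@bonds$kb, ff@bonds$r0), con)
  writeLines("[angles]", con)
  if (nrow(ff@angles))
    writeLines(sprintf("%d %d %d %.6f %.6f", ff@angles$i, ff@angles$j,
                       ff@angles$k, ff@angles$ka, ff@angles$theta0), con)
  writeLines("[dihedrals]", con)
  if (nrow(ff@dihedrals))
    writeLines(sprintf("%d %d %d %d %.6f %d %.6f",
                       ff@dihedrals$i, ff@dihedrals$j, ff@dihedrals$k,
                       ff@dihedrals$l, ff@dihedrals$barrier,
                       ff@dihedrals$periodicity, ff@dihedrals$phase), con)
  invisible(path)
}
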