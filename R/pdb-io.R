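# PDB input/output for blocked polyalanine conformations. Writing emits
# fixed-width ATOM records with MODEL/ENDMDL framing for trajectories;
# reading of multi-model files is delegated to bio3d.

# map internal role/residue labels to PDB atom and residue names
pdb_names <- function(conf) {
  n <- conf$spec$n_residues
  resname <- ifelse(conf$resno == 0L, "ACE",
                    ifelse(conf$resno == n + 1L, "NH2", "ALA"))
  name <- conf$atom
  name[name == "CH3"] <- "CH3"
  name[name == "H1"] <- "HT1"
  name[name == "H2"] <- "HT2"
  list(name = name, resname = resname)
}

#' Write conformations to a (multi-model) PDB file
#'
#' Writes a single conformation as one MODEL, or every frame of a
#' trajectory as consecutive MODEL records.
#'
#' @param x a `"conformation"` or `"trajectory"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  frames <- if (inherits(x, "trajectory")) x$frames else list(x)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1L
  for (m in seq_along(frames)) {
    conf <- frames[[m]]
    nm <- pdb_names(conf)
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    elem <- substr(sub("^([A-Za-z]).*", "\\1", conf$atom), 1L, 1L)
    lines <- sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(conf$xyz)),
      ifelse(nchar(nm$name) < 4L, paste0(" ", nm$name), nm$name),
      nm$resname, conf$resno + 1L,
      conf$xyz[, 1L], conf$xyz[, 2L], conf$xyz[, 3L], elem)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a (multi-model) PDB file as a trajectory
#'
#' Parses the file with [bio3d::read.pdb()] (`multi = TRUE`) and maps
#' the atoms back onto the blocked-polyalanine role labels.
#'
#' @param path PDB file path.
#' @param dt sampling interval in ns assigned to the frames.
#' @param label optional trajectory label.
#' @return a [trajectory()] (a single-model file gives one frame).
#' @export
read_pdb_trajectory <- function(path, dt = 1, label = "") {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  resno <- at$resno - 1L
  n <- max(resno) - 1L
  spec <- peptide_spec(n)
  role <- at$elety
  role[role == "HT1"] <- "H1"
  role[role == "HT2"] <- "H2"
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  frames <- lapply(seq_len(nrow(xyz)), function(m) {
    new_conformation(matrix(xyz[m, ], ncol = 3L, byrow = TRUE),
                     role, resno, spec)
  })
  trajectory(frames, dt = dt, label = label)
}
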