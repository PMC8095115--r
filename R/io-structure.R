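# Pre-scan a PDB file's MODEL blocks: returns integer vector of ATOM/HETATM
# counts per model (length 1 for single-model files without MODEL records).
scan_pdb_models <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(substr(rec, 1, 5) == "MODEL")
  if (length(model_starts) == 0) return(sum(is_atom))
  model_ends <- which(rec == "ENDMDL")
  if (length(model_ends) < length(model_starts)) model_ends <- c(model_ends, length(lines))
  vapply(seq_along(model_starts), function(m) {
    sum(is_atom[model_starts[m]:model_ends[m]])
  }, integer(1))
}

#' Read a structural ensemble
#'
#' Reads a multi-frame ensemble from either a multi-model PDB file
#' (`MODEL`/`ENDMDL` blocks; parsing delegated to \pkg{bio3d}) or a plain
#' whitespace-separated frame table (`frame atom_id x y z`) with a sidecar
#' topology file. All models must have identical atom counts and order.
#'
#' @param path input file.
#' @param dialect `"pdb_multimodel"` or `"frame_table"`.
#' @param rules a [classify_rules()] object for category assignment.
#' @param topology_path for the frame-table dialect: path to the sidecar
#'   topology TSV (columns `atom_id`, `atom_name`, `element`, `residue_seq`,
#'   `residue_name`, `subunit_id`); defaults to `<path>.top.tsv`.
#' @return an [ensemble()].
#' @export
read_structure_ensemble <- function(path,
                                    dialect = c("pdb_multimodel", "frame_table"),
                                    rules = classify_rules(),
                                    topology_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "pdb_multimodel") {
    lines <- readLines(path, warn = FALSE)
    counts <- scan_pdb_models(lines)
    if (length(counts) == 0 || counts[1] == 0) stop("no ATOM/HETATM records in ", path)
    bad <- which(counts != counts[1])
    if (length(bad) > 0)
      stop(sprintf("model %d: %d atoms, expected %d", bad[1], counts[bad[1]], counts[1]))
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
    at <- pdb$atom
    el <- trimws(as.character(at$elesy))
    el[is.na(el) | el == ""] <- guess_element(at$elety[is.na(el) | el == ""])
    top <- topology(data.frame(
      atom_id = as.integer(at$eleno),
      atom_name = trimws(at$elety),
      element = el,
      residue_seq = as.integer(at$resno),
      residue_name = trimws(at$resid),
      subunit_id = ifelse(is.na(at$chain) | at$chain == "", "A", as.character(at$chain)),
      stringsAsFactors = FALSE), rules = rules)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    nT <- nrow(xyz)
    coords <- array(NA_real_, c(nrow(top), 3, nT))
    for (f in seq_len(nT)) coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    ensemble(top, coords)
  } else {
    if (is.null(topology_path)) topology_path <- paste0(path, ".top.tsv")
    if (!file.exists(topology_path)) stop("sidecar topology file not found: ", topology_path)
    tt <- read.table(topology_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    top <- topology(tt, rules = rules)
    ft <- read.table(path, header = FALSE,
                     col.names = c("frame", "atom_id", "x", "y", "z"))
    frames <- sort(unique(ft$frame))
    n <- nrow(top)
    ord <- match(ft$atom_id, top$atom_id)
    if (anyNA(ord)) stop("frame table refers to atom_id values absent from the topology")
    coords <- array(NA_real_, c(n, 3, length(frames)))
    for (fi in seq_along(frames)) {
      rows <- ft[ft$frame == frames[fi], , drop = FALSE]
      if (nrow(rows) != n)
        stop(sprintf("model %d: %d atoms, expected %d", fi, nrow(rows), n))
      coords[match(rows$atom_id, top$atom_id), , fi] <- as.matrix(rows[, c("x", "y", "z")])
    }
    if (!all(is.finite(coords))) stop("frame table: missing coordinates for some atoms")
    ensemble(top, coords)
  }
}

#' Write an ensemble as a multi-model PDB file
#'
#' Fixed-width PDB `ATOM` records (coordinates at 0.001 Angstrom precision),
#' one `MODEL`/`ENDMDL` block per frame. The element symbol is written in
#' columns 77-78 so topologies round-trip.
#'
#' @param ens an `ensemble`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_ensemble_pdb <- function(ens, path) {
  top <- ens$topology
  nm <- top$atom_name
  # standard PDB name justification: 1-3 character names start in column 14
  nm4 <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
  pre <- sprintf("ATOM  %5d %s%1s%-4s%1s%4d%1s   ",
                 top$atom_id %% 100000L, nm4, "",
                 substr(top$residue_name, 1, 4), substr(top$subunit_id, 1, 1),
                 top$residue_seq %% 10000L, "")
  post <- sprintf("%6.2f%6.2f          %2s", 1, 0, toupper(substr(top$element, 1, 2)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(n_frames(ens))) {
    x <- frame_coords(ens, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(paste0(pre, sprintf("%8.3f%8.3f%8.3f", x[, 1], x[, 2], x[, 3]), post), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write an ensemble in the frame-table dialect
#'
#' Writes a whitespace-separated coordinate table (`frame atom_id x y z`,
#' frames 1-based) and a sidecar topology TSV at `<path>.top.tsv`.
#'
#' @param ens an `ensemble`.
#' @param path output coordinate-table path.
#' @return invisibly, `path`.
#' @export
write_frame_table <- function(ens, path) {
  top <- ens$topology
  write.table(data.frame(atom_id = top$atom_id, atom_name = top$atom_name,
                         element = top$element, residue_seq = top$residue_seq,
                         residue_name = top$residue_name,
                         subunit_id = top$subunit_id),
              paste0(path, ".top.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(n_frames(ens))) {
    x <- frame_coords(ens, f)
    writeLines(sprintf("%d %d %.6f %.6f %.6f", f, top$atom_id,
                       x[, 1], x[, 2], x[, 3]), con)
  }
  invisible(path)
}
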