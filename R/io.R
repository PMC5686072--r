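# Readers and writers for the pipeline's exchange formats: SDF V2000
# conformer libraries (plain or gzipped), multi-model PDB ensembles, FASTA
# sequences, and the documented CSV schemas for chemical-shift tables and
# score matrices. Readers validate and reject malformed records rather
# than coercing them.

#' Read an SDF V2000 file into a molecule list
#'
#' @importClassesFrom ChemmineR SDF SDFset
#' @param path Path to an SDF file (plain or gzip).
#' @return List of molecules; each a list with `id`, `atoms` (data frame
#'   `elem`, `x`, `y`, `z`), `bonds` (data frame `a1`, `a2`, `order`) and
#'   `data` (named character vector of the data block).
#' @export
read_sdf <- function(path) {
  if (!file.exists(path))
    stop_dynappi(sprintf("SDF file not found: %s", path), "dynappi_io_error")
  sdfset <- tryCatch(ChemmineR::read.SDFset(path),
                     error = function(e)
                       stop_dynappi(sprintf("%s: SDF parse failure: %s",
                                            path, conditionMessage(e)),
                                    "dynappi_io_error"))
  lapply(seq_along(sdfset@SDF), function(i) {
    sdf <- sdfset@SDF[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elem <- sub("_.*$", "", rownames(ab))
    atoms <- data.frame(elem = elem, x = ab[, 1], y = ab[, 2], z = ab[, 3],
                        stringsAsFactors = FALSE, row.names = NULL)
    bonds <- if (is.null(dim(bb)) || NROW(bb) == 0L || NCOL(bb) < 3L) {
      data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
    } else {
      data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]), row.names = NULL)
    }
    dat <- ChemmineR::datablock(sdf)
    hdr <- ChemmineR::header(sdf)
    id <- if (!is.null(dat) && "molecule_id" %in% names(dat))
      unname(dat[["molecule_id"]]) else unname(hdr[["Molecule_Name"]])
    list(id = id, atoms = atoms, bonds = bonds, data = dat)
  })
}

# internal: one conformer_features -> ChemmineR SDF with pseudo-atoms.
# Feature kinds are carried both as pseudo-elements (acceptor -> O,
# donor -> N, hydrophobic -> C) and verbatim in the data block.
KIND_TO_ELEM <- c(acceptor = "O", donor = "N", hydrophobic = "C")

conformer_to_sdf <- function(conf) {
  pts <- conf$points
  nat <- nrow(pts)
  ab <- cbind(as.matrix(pts[, c("x", "y", "z")]), matrix(0, nat, 13))
  colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:17))
  rownames(ab) <- paste0(KIND_TO_ELEM[pts$kind], "_", seq_len(nat))
  # chain of formal single bonds between consecutive pseudo-atoms: feature
  # points are not chemically bonded, but a bond-less molfile is rejected
  # by strict V2000 readers
  nb <- max(nat - 1L, 0L)
  bb <- cbind(seq_len(nb), seq_len(nb) + 1L, rep(1L, nb), rep(0L, nb))
  colnames(bb) <- paste0("C", 1:4)
  hdr <- c(Molecule_Name = conf$molecule_id, Source = "dynappi",
           Comment = "synthetic feature-point conformer",
           Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                 nat, nb))
  methods::new("SDF", header = hdr, atomblock = ab, bondblock = bb,
               datablock = c(molecule_id = conf$molecule_id,
                             conformer_id = conf$conformer_id,
                             feature_kinds = paste(pts$kind, collapse = ","),
                             feature_labels = paste(pts$label, collapse = ",")))
}

#' Write a conformer-features library to SDF
#'
#' Feature points are stored as pseudo-atoms (acceptor as O, donor as N,
#' hydrophobic as C) with the feature kinds and labels repeated verbatim in
#' the SDF data block, so the round trip is lossless.
#'
#' @param library List of [conformer_features()].
#' @param path Output SDF path.
#' @return `path`, invisibly.
#' @export
write_library_sdf <- function(library, path) {
  sdfs <- lapply(library, conformer_to_sdf)
  sdfset <- methods::new("SDFset", SDF = sdfs,
                         ID = vapply(library, function(x) x$molecule_id, ""))
  ChemmineR::write.SDF(sdfset, path)
  invisible(path)
}

#' Read a conformer-features library back from SDF
#'
#' @param path SDF path written by [write_library_sdf()].
#' @return List of [conformer_features()].
#' @export
read_library_sdf <- function(path) {
  mols <- read_sdf(path)
  lapply(mols, function(m) {
    kinds <- strsplit(m$data[["feature_kinds"]], ",")[[1]]
    labels <- strsplit(m$data[["feature_labels"]], ",")[[1]]
    if (length(kinds) != nrow(m$atoms))
      stop_dynappi(sprintf("%s: feature_kinds does not match atom count", path),
                   "dynappi_io_error")
    conformer_features(
      m$data[["molecule_id"]], m$data[["conformer_id"]],
      pharm_features(kinds, as.matrix(m$atoms[, c("x", "y", "z")]),
                     radius = 1, label = labels))
  })
}

#' Read a multi-model PDB file into a coordinate ensemble
#'
#' @param path PDB path (MODEL/ENDMDL records for ensembles; a single-model
#'   file yields a one-model ensemble).
#' @return A [coord_ensemble()].
#' @export
read_pdb_ensemble <- function(path) {
  if (!file.exists(path))
    stop_dynappi(sprintf("PDB file not found: %s", path), "dynappi_io_error")
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop_dynappi(sprintf("%s: PDB parse failure: %s",
                                         path, conditionMessage(e)),
                                 "dynappi_io_error"))
  atoms <- pdb$atom[, c("elety", "resno", "resid", "chain")]
  rownames(atoms) <- NULL
  coord_ensemble(atoms, unclass(pdb$xyz))
}

#' Write a coordinate ensemble as a multi-model PDB file
#'
#' @param ens A [coord_ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ens, path) {
  at <- ens$atoms
  pdb <- list(atom = data.frame(
    type = "ATOM", eleno = seq_len(nrow(at)), elety = at$elety, alt = NA,
    resid = at$resid, chain = at$chain, resno = at$resno, insert = NA,
    x = 0, y = 0, z = 0, o = 1, b = 0, segid = NA,
    elesy = substr(at$elety, 1, 1), charge = NA,
    stringsAsFactors = FALSE))
  class(pdb) <- c("pdb", "sse")
  bio3d::write.pdb(pdb, file = path, xyz = ens$xyz)
  invisible(path)
}

#' Read a chemical-shift table CSV
#'
#' Schema (exact column names, units in the suffixes):
#' `residue_number`, `residue_type`, `atom` (H or N), `titration_point`
#' (0 = free protein), `shift_ppm`, `ligand_total_mM`, `protein_total_mM`.
#'
#' @param path CSV path.
#' @return Validated data frame of shift records.
#' @export
read_shift_table <- function(path) {
  if (!file.exists(path))
    stop_dynappi(sprintf("shift table not found: %s", path), "dynappi_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("residue_number", "residue_type", "atom", "titration_point",
              "shift_ppm", "ligand_total_mM", "protein_total_mM")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L)
    stop_dynappi(sprintf("%s: shift table missing column(s): %s",
                         path, paste(missing, collapse = ", ")),
                 "dynappi_schema_error")
  if (!all(df$atom %in% c("H", "N")))
    stop_dynappi(sprintf("%s: column 'atom' must be H or N", path),
                 "dynappi_schema_error")
  if (any(!is.finite(df$shift_ppm)))
    stop_dynappi(sprintf("%s: non-finite values in shift_ppm", path),
                 "dynappi_schema_error")
  df
}

#' Build a titration series from shift records
#'
#' Per-residue H and N shift changes relative to titration point 0 are
#' combined with [combined_csp()].
#'
#' @param records Data frame from [read_shift_table()].
#' @param alpha Nitrogen weighting for [combined_csp()].
#' @return A [titration_series()].
#' @export
shifts_to_series <- function(records, alpha = 0.14) {
  pts <- sort(unique(records$titration_point))
  residues <- sort(unique(records$residue_number))
  lt <- vapply(pts, function(p)
    unique(records$ligand_total_mM[records$titration_point == p])[1], numeric(1))
  pt_conc <- unique(records$protein_total_mM)[1]
  grab <- function(res, p, at) {
    v <- records$shift_ppm[records$residue_number == res &
                           records$titration_point == p & records$atom == at]
    if (length(v) != 1L)
      stop_dynappi(sprintf("residue %d point %d atom %s: expected 1 record, got %d",
                           res, p, at, length(v)),
                   "dynappi_schema_error")
    v
  }
  csp <- t(vapply(residues, function(res) {
    h0 <- grab(res, pts[1], "H"); n0 <- grab(res, pts[1], "N")
    vapply(pts, function(p)
      combined_csp(grab(res, p, "H") - h0, grab(res, p, "N") - n0, alpha),
      numeric(1))
  }, numeric(length(pts))))
  rownames(csp) <- paste0("res", residues)
  titration_series(pt_conc, lt, csp)
}

#' Read a protein sequence from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of one-letter sequences.
#' @export
read_fasta_sequence <- function(path) {
  if (!file.exists(path))
    stop_dynappi(sprintf("FASTA file not found: %s", path), "dynappi_io_error")
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  vapply(seqs, function(s) toupper(as.character(s)[1]), character(1))
}

#' Write a binding fit as JSON
#'
#' @param fit A `binding_fit` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(kd_mM = fit$kd, se_kd_mM = fit$se_kd,
         dmax_ppm = as.list(fit$dmax), se_dmax_ppm = as.list(fit$se_dmax),
         rss = fit$rss, converged = fit$converged,
         identifiable = fit$identifiable),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
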