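# Three-letter codes of the 20 standard amino acids; anything else is
# excluded from traces unless explicitly allowlisted.
.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

# PDB one-character chain identifier alphabet (62 ids).
.chain_alphabet <- c(LETTERS, letters, as.character(0:9))

#' Read a structure file into the C-alpha data model
#'
#' Parses a PDB or mmCIF file (via bio3d) and reduces it to one
#' [chain_trace()] per protein chain:
#' * only the FIRST model of multi-model (NMR) files is used;
#' * only `ATOM` records with atom name `CA` of standard amino acids are
#'   kept (extend via `extra_residues` for modified residues);
#' * for alternate locations, the conformer with the highest occupancy
#'   wins (ties broken by file order);
#' * chains left with zero C-alpha atoms are dropped.
#'
#' Deposited beta-strand annotation (`SHEET` records or
#' `_struct_sheet_range`) is attached as `sheet_annotation` when present.
#'
#' @param path Path to a structure file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (detect from the file
#'   extension, falling back to content sniffing).
#' @param extra_residues Character vector of additional residue names to
#'   accept (e.g. `"MSE"`).
#' @return A [structure_record()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           extra_residues = character()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .detect_format(path)
  parsed <- tryCatch(
    suppressWarnings(switch(format,
      pdb   = bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
      mmcif = bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))),
    error = function(e)
      stop("failed to parse ", path, " as ", format, ": ",
           conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  keep <- at$type == "ATOM" & at$elety == "CA" &
    at$resid %in% c(.standard_aa, extra_residues) & !is.na(at$chain)
  at <- at[keep, , drop = FALSE]
  if (nrow(at) > 0L) at <- .resolve_altloc(at)
  if (nrow(at) == 0L)
    stop("no protein chains with C-alpha atoms in ", path, call. = FALSE)

  chains <- lapply(split(seq_len(nrow(at)), factor(at$chain,
                                                  levels = unique(at$chain))),
                   function(idx) {
    rows <- at[idx, , drop = FALSE]
    ins <- ifelse(is.na(rows$insert), "", rows$insert)
    chain_trace(rows$chain[1L],
                cbind(rows$x, rows$y, rows$z),
                auth_seq_id = paste0(rows$resno, ins),
                auth_seq_num = rows$resno,
                source_model = 1L)
  })
  sheet <- switch(format,
                  pdb = .sheet_from_bio3d(parsed),
                  mmcif = .read_cif_sheet_ranges(path))
  structure_record(tools::file_path_sans_ext(basename(path)),
                   unname(chains), sheet_annotation = sheet)
}

.detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  headlines <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^data_|^_atom_site\\.", headlines))) "mmcif" else "pdb"
}

# Highest-occupancy altloc per (chain, resno, insert); ties and missing
# occupancies resolve to the first conformer in file order.
.resolve_altloc <- function(at) {
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               sep = "\r")
  pick <- vapply(split(seq_len(nrow(at)), factor(key, levels = unique(key))),
                 function(idx) idx[which.max(occ[idx])], 1L)
  at[sort(pick), , drop = FALSE]
}

.sheet_from_bio3d <- function(parsed) {
  sh <- parsed$sheet
  if (is.null(sh) || length(sh$start) == 0L) return(NULL)
  out <- data.frame(chain_id = as.character(sh$chain),
                    beg = as.integer(sh$start), end = as.integer(sh$end),
                    stringsAsFactors = FALSE)
  out <- out[stats::complete.cases(out), , drop = FALSE]
  if (nrow(out) == 0L) NULL else out
}

# Minimal reader for the _struct_sheet_range loop of an mmCIF file
# (bio3d's cif reader does not expose this category).  Prefers author
# numbering, falls back to label numbering.
.read_cif_sheet_ranges <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  for (ls in loop_starts) {
    i <- ls + 1L
    tags <- character()
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, sub("^\\s*(\\S+).*$", "\\1", lines[i]))
      i <- i + 1L
    }
    if (!any(grepl("^_struct_sheet_range\\.", tags))) next
    rows <- character()
    while (i <= length(lines) &&
           !grepl("^\\s*(#|loop_|_|data_)", lines[i])) {
      if (nzchar(trimws(lines[i]))) rows <- c(rows, lines[i])
      i <- i + 1L
    }
    if (length(rows) == 0L) return(NULL)
    vals <- lapply(rows, function(r)
      scan(text = r, what = "character", quiet = TRUE))
    if (!all(lengths(vals) == length(tags))) return(NULL)
    tab <- as.data.frame(do.call(rbind, vals), stringsAsFactors = FALSE)
    names(tab) <- sub("^_struct_sheet_range\\.", "", tags)
    pick <- function(auth, label) {
      if (auth %in% names(tab)) tab[[auth]]
      else if (label %in% names(tab)) tab[[label]]
      else rep(NA_character_, nrow(tab))
    }
    out <- data.frame(
      chain_id = pick("beg_auth_asym_id", "beg_label_asym_id"),
      beg = suppressWarnings(as.integer(pick("beg_auth_seq_id",
                                             "beg_label_seq_id"))),
      end = suppressWarnings(as.integer(pick("end_auth_seq_id",
                                             "end_label_seq_id"))),
      stringsAsFactors = FALSE)
    out <- out[stats::complete.cases(out), , drop = FALSE]
    return(if (nrow(out) == 0L) NULL else out)
  }
  NULL
}

#' Write a structure record as a C-alpha-only PDB file
#'
#' Emits standard fixed-width `ATOM` records (atom name `CA`, residue type
#' `ALA`), one `TER` per chain.  Coordinates are written to three decimals,
#' the PDB convention, so a [read_structure()] round trip reproduces the
#' record to 1e-3 Angstrom.  Chain ids that are not single characters are
#' remapped to the 62-letter PDB chain alphabet.
#'
#' @param record A [structure_record()] with at least one non-empty chain.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(record, path) {
  stopifnot(inherits(record, "StructureRecord"))
  if (length(record$chains) == 0L)
    stop("cannot write a StructureRecord with no chains")
  if (length(record$chains) > length(.chain_alphabet))
    stop("more than ", length(.chain_alphabet),
         " chains: PDB chain-id alphabet exhausted")
  ids <- vapply(record$chains, `[[`, "", "chain_id")
  if (!all(nchar(ids) == 1L)) ids <- .chain_alphabet[seq_along(ids)]
  lines <- character()
  serial <- 0L
  for (k in seq_along(record$chains)) {
    ch <- record$chains[[k]]
    resno <- ch$auth_seq_num
    if (any(!is.finite(resno) | resno < -999L | resno > 9999L))
      resno <- seq_len(length(ch))
    for (i in seq_len(length(ch))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial %% 100000L, ids[k], resno[i],
        ch$xyz[i, 1L], ch$xyz[i, 2L], ch$xyz[i, 3L], 1, 0))
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      ALA %1s%4d",
                              serial %% 100000L, ids[k],
                              resno[length(ch)]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
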