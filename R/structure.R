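#' C-alpha trace of a single polypeptide chain
#'
#' A `ChainTrace` is the minimal per-chain data model used throughout the
#' package: one C-alpha coordinate per resolved residue, in deposition
#' order.  Residues are addressed by a 0-based, contiguous `seq_index`
#' (position along the trace); the author residue numbering from the file
#' is carried alongside for reporting and for matching sheet annotations.
#'
#' @param chain_id Chain identifier (character scalar).
#' @param xyz Numeric matrix with one row per residue and 3 columns
#'   (Cartesian coordinates, Angstrom).
#' @param auth_seq_id Character vector of author residue numbers with
#'   insertion codes, one per residue.  Defaults to `"1"..."n"`.
#' @param auth_seq_num Integer vector of author residue numbers without
#'   insertion codes (used for annotation interval matching).
#' @param source_model Model number the coordinates came from (always the
#'   first model of multi-model files).
#' @param offset 0-based seq_index of this trace's first residue within
#'   its parent chain; non-zero only for break segments produced by
#'   [split_on_breaks()].
#' @return An object of class `ChainTrace`.
#' @seealso [residue_points()], [split_on_breaks()]
#' @export
chain_trace <- function(chain_id, xyz, auth_seq_id = NULL,
                        auth_seq_num = NULL, source_model = 1L,
                        offset = 0L) {
  if (!is.character(chain_id) || length(chain_id) != 1L || is.na(chain_id))
    stop("chain_id must be a single character string")
  xyz <- as.matrix(xyz)
  if (is.null(dim(xyz)) || ncol(xyz) != 3L)
    stop("xyz must be an n x 3 matrix")
  storage.mode(xyz) <- "double"
  if (nrow(xyz) < 1L)
    stop("a ChainTrace needs at least one residue")
  if (!all(is.finite(xyz)))
    stop("xyz contains non-finite coordinates")
  n <- nrow(xyz)
  if (is.null(auth_seq_num)) auth_seq_num <- seq_len(n)
  auth_seq_num <- as.integer(auth_seq_num)
  if (is.null(auth_seq_id)) auth_seq_id <- as.character(auth_seq_num)
  auth_seq_id <- as.character(auth_seq_id)
  if (length(auth_seq_id) != n || length(auth_seq_num) != n)
    stop("auth_seq_id/auth_seq_num must have one entry per residue")
  dimnames(xyz) <- NULL
  structure(
    list(chain_id = chain_id, xyz = xyz,
         auth_seq_id = auth_seq_id, auth_seq_num = auth_seq_num,
         source_model = as.integer(source_model),
         offset = as.integer(offset)),
    class = "ChainTrace")
}

#' Number of residues in a chain trace
#' @param x A `ChainTrace`.
#' @param ... Ignored.
#' @export
length.ChainTrace <- function(x) nrow(x$xyz)

#' @export
print.ChainTrace <- function(x, ...) {
  cat(sprintf("<ChainTrace %s: %d residues, model %d%s>\n",
              x$chain_id, length(x), x$source_model,
              if (x$offset > 0L) sprintf(", offset %d", x$offset) else ""))
  invisible(x)
}

#' Per-residue view of a chain trace
#'
#' Expands a [chain_trace()] into one row per residue: chain id, 0-based
#' `seq_index`, author residue id and coordinates.
#'
#' @param chain A `ChainTrace`.
#' @return A data.frame with columns `chain_id`, `seq_index`,
#'   `auth_seq_id`, `x`, `y`, `z`.
#' @export
residue_points <- function(chain) {
  stopifnot(inherits(chain, "ChainTrace"))
  data.frame(chain_id = chain$chain_id,
             seq_index = seq_len(length(chain)) - 1L + chain$offset,
             auth_seq_id = chain$auth_seq_id,
             x = chain$xyz[, 1L], y = chain$xyz[, 2L], z = chain$xyz[, 3L],
             stringsAsFactors = FALSE)
}

#' A structure reduced to its C-alpha chain traces
#'
#' @param entry_id Entry identifier (PDB accession or file stem).
#' @param chains List of [chain_trace()] objects with unique chain ids.
#' @param sheet_annotation Optional data.frame of deposited beta-strand
#'   ranges (`SHEET` / `_struct_sheet_range`) with columns `chain_id`,
#'   `beg`, `end` (author residue numbers, inclusive); `NULL` when the
#'   file carries no annotation.
#' @return An object of class `StructureRecord`.
#' @export
structure_record <- function(entry_id, chains, sheet_annotation = NULL) {
  if (!is.character(entry_id) || length(entry_id) != 1L)
    stop("entry_id must be a single character string")
  if (!is.list(chains) || !all(vapply(chains, inherits, TRUE, "ChainTrace")))
    stop("chains must be a list of ChainTrace objects")
  ids <- vapply(chains, `[[`, "", "chain_id")
  if (anyDuplicated(ids))
    stop("duplicate chain_id in StructureRecord: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(chains) <- ids
  if (!is.null(sheet_annotation)) {
    stopifnot(is.data.frame(sheet_annotation),
              all(c("chain_id", "beg", "end") %in% names(sheet_annotation)))
  }
  structure(list(entry_id = entry_id, chains = chains,
                 sheet_annotation = sheet_annotation),
            class = "StructureRecord")
}

#' @export
print.StructureRecord <- function(x, ...) {
  cat(sprintf("<StructureRecord %s: %d chain(s)%s>\n", x$entry_id,
              length(x$chains),
              if (is.null(x$sheet_annotation)) ""
              else sprintf(", %d sheet range(s)", nrow(x$sheet_annotation))))
  for (ch in x$chains)
    cat(sprintf("  %s: %d residues\n", ch$chain_id, length(ch)))
  invisible(x)
}

#' Split a chain trace at physical chain breaks
#'
#' Consecutive residues whose C-alpha to C-alpha distance exceeds
#' `max_gap` are placed in separate traces.  The default of 4.5 Angstrom
#' sits above the trans C-alpha step (about 3.8 Angstrom), so only real
#' gaps in the resolved density split a chain.  Fragment search is run per
#' segment so that no window ever averages geometry across a break.
#'
#' @param chain A `ChainTrace`.
#' @param max_gap Maximum allowed consecutive C-alpha distance (Angstrom).
#' @return List of `ChainTrace` segments whose concatenation equals the
#'   input; each carries its 0-based `offset` into the parent chain.
#' @export
split_on_breaks <- function(chain, max_gap = 4.5) {
  stopifnot(inherits(chain, "ChainTrace"), max_gap > 0)
  n <- length(chain)
  if (n == 1L) return(list(chain))
  d <- sqrt(rowSums((chain$xyz[-1L, , drop = FALSE] -
                     chain$xyz[-n, , drop = FALSE])^2))
  seg <- cumsum(c(0L, as.integer(d > max_gap)))
  lapply(split(seq_len(n), seg), function(idx) {
    chain_trace(chain$chain_id, chain$xyz[idx, , drop = FALSE],
                auth_seq_id = chain$auth_seq_id[idx],
                auth_seq_num = chain$auth_seq_num[idx],
                source_model = chain$source_model,
                offset = chain$offset + idx[1L] - 1L)
  })
}
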