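#' Configuration of the beta-sheet chain call
#'
#' Screening only considers chain pairs in which both chains look like
#' beta-sheets.  Deposited annotation is authoritative when present, but
#' many solid-state NMR amyloid depositions carry no `SHEET` records, so a
#' C-alpha-only geometric fallback (in the spirit of P-SEA) is provided:
#' a residue is called extended when its pseudo-bond angle lies in
#' `theta_range` and its pseudo-dihedral is outside the helical band
#' (`|dihedral| >= dihedral_min_abs`).
#'
#' Modes:
#' * `"annotation"` — use deposited strand ranges only; error (class
#'   `amyloidscreen_no_annotation`) when the record has none;
#' * `"geometric"` — use the C-alpha geometric call only;
#' * `"annotation_then_geometric"` (default) — annotation when present,
#'   else geometric;
#' * `"none"` — accept every chain; rules (a)-(c) carry the full burden.
#'
#' @param mode See description.
#' @param min_extended_fraction Minimum fraction of extended residues for
#'   a chain to qualify (default 0.25, deliberately permissive: rule (c)
#'   already demands a long parallel fragment).
#' @param theta_range Closed pseudo-bond-angle interval for an extended
#'   residue, degrees (default `c(100, 155)`).
#' @param dihedral_min_abs Minimum `|pseudo-dihedral|` in degrees
#'   (default 90; alpha-helices sit near +50).
#' @return An object of class `SheetCallConfig`.
#' @export
sheet_call_config <- function(mode = c("annotation_then_geometric",
                                       "annotation", "geometric", "none"),
                              min_extended_fraction = 0.25,
                              theta_range = c(100, 155),
                              dihedral_min_abs = 90) {
  mode <- match.arg(mode)
  stopifnot(min_extended_fraction >= 0, min_extended_fraction <= 1,
            length(theta_range) == 2L, theta_range[1L] <= theta_range[2L],
            theta_range[1L] >= 0, theta_range[2L] <= 180,
            dihedral_min_abs >= 0, dihedral_min_abs <= 180)
  structure(list(mode = mode,
                 min_extended_fraction = min_extended_fraction,
                 theta_range = as.numeric(theta_range),
                 dihedral_min_abs = dihedral_min_abs),
            class = "SheetCallConfig")
}

#' Per-residue extended (beta) flags for one chain
#'
#' @param chain A `ChainTrace`.
#' @param config A [sheet_call_config()]; modes `"annotation"` and
#'   `"geometric"` are honoured here, `"annotation_then_geometric"` and
#'   `"none"` are resolved by [is_sheet_chain()].
#' @param annotation Optional strand-range data.frame (columns `chain_id`,
#'   `beg`, `end`), normally `record$sheet_annotation`.  Required for
#'   annotation mode.
#' @return Logical vector, one flag per residue.  In geometric mode an
#'   interior residue is flagged when its pseudo-bond angle lies in
#'   `theta_range` and its pseudo-dihedral has absolute value at least
#'   `dihedral_min_abs` (where no four-residue dihedral exists the angle
#'   criterion alone decides); terminal residues inherit the nearest
#'   interior flag; chains shorter than 3 residues get all-`FALSE`.
#' @export
residue_extended_flags <- function(chain, config = sheet_call_config(),
                                   annotation = NULL) {
  stopifnot(inherits(chain, "ChainTrace"), inherits(config, "SheetCallConfig"))
  n <- length(chain)
  mode <- config$mode
  if (mode == "none") return(rep(TRUE, n))
  if (mode %in% c("annotation", "annotation_then_geometric")) {
    has_ann <- !is.null(annotation) && nrow(annotation) > 0L
    if (!has_ann && mode == "annotation")
      stop(structure(class = c("amyloidscreen_no_annotation",
                               "error", "condition"),
                     list(message = paste0("no sheet annotation for chain ",
                                           chain$chain_id),
                          call = NULL)))
    if (has_ann) {
      ann <- annotation[annotation$chain_id == chain$chain_id, , drop = FALSE]
      flags <- rep(FALSE, n)
      for (j in seq_len(nrow(ann)))
        flags <- flags | (chain$auth_seq_num >= ann$beg[j] &
                          chain$auth_seq_num <= ann$end[j])
      return(flags)
    }
    # annotation_then_geometric without annotation: fall through.
  }
  if (n < 3L) return(rep(FALSE, n))
  ang <- .chain_angles(chain$xyz)
  dih <- .chain_dihedrals(chain$xyz)
  interior <- 2:(n - 1L)
  flags <- rep(FALSE, n)
  flags[interior] <- !is.na(ang[interior]) &
    ang[interior] >= config$theta_range[1L] &
    ang[interior] <= config$theta_range[2L] &
    (is.na(dih[interior]) | abs(dih[interior]) >= config$dihedral_min_abs)
  flags[1L] <- flags[2L]
  flags[n] <- flags[n - 1L]
  flags
}

#' Does a chain qualify as a beta-sheet chain?
#'
#' True when the fraction of extended residues reaches
#' `min_extended_fraction`; mode `"none"` accepts every chain.  In the
#' default `"annotation_then_geometric"` mode, deposited strand ranges are
#' used when the record carries any and the geometric call otherwise.
#'
#' @param chain A `ChainTrace`.
#' @param config A [sheet_call_config()].
#' @param record Optional parent [structure_record()] supplying the
#'   sheet annotation.
#' @return Logical scalar.
#' @export
is_sheet_chain <- function(chain, config = sheet_call_config(),
                           record = NULL) {
  stopifnot(inherits(config, "SheetCallConfig"))
  if (config$mode == "none") return(TRUE)
  annotation <- if (!is.null(record)) record$sheet_annotation else NULL
  flags <- residue_extended_flags(chain, config, annotation = annotation)
  mean(flags) >= config$min_extended_fraction
}
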