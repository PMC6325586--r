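#' Batch-screen structure files and write the amyloid list 
#'
#' (Named `scan_structures` rather than `scan` to avoid masking base R.)
#'
#' Screens every input file with [screen_structure()] and writes three
#' artifacts into `out_dir`:
#' * `amyloid_list.txt` — one entry id per line for every positive
#'   verdict, sorted;
#' * `fragments.tsv` — one row per passing fragment across all entries;
#' * `manifest.json` — run parameters, per-entry outcomes and tool
#'   version.
#'
#' A file that fails to parse is recorded as `parse_error` and never
#' aborts the batch.  One structured log line per entry goes to stderr;
#' stdout stays clean.
#'
#' @param inputs Character vector of structure file paths (non-empty).
#' @param out_dir Output directory (created if needed).
#' @param params A [rule_params()].
#' @param sheet_config A [sheet_call_config()].
#' @param max_gap Chain-break threshold, Angstrom.
#' @param quiet Suppress per-entry log lines.
#' @return The run manifest (list), invisibly.  `entries` holds one row
#'   per input with outcome `positive`, `negative` or `parse_error`.
#' @export
scan_structures <- function(inputs, out_dir, params = rule_params(),
                 sheet_config = sheet_call_config(), max_gap = 4.5,
                 quiet = FALSE) {
  if (length(inputs) == 0L) stop("scan_structures: empty input set")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("scan_structures: cannot create output directory ", out_dir)
  entries <- data.frame(entry_id = character(), path = character(),
                        outcome = character(), n_fragments = integer(),
                        stringsAsFactors = FALSE)
  frag_tabs <- list()
  for (p in inputs) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      rec <- read_structure(p)
      screen_structure(rec, params, sheet_config, max_gap = max_gap)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      entry_id <- tools::file_path_sans_ext(basename(p))
      outcome <- "parse_error"
      nfr <- 0L
      if (!quiet)
        message(sprintf("%s\tparse_error\t%s", entry_id,
                        conditionMessage(res)))
    } else {
      entry_id <- res$entry_id
      outcome <- if (res$verdict) "positive" else "negative"
      nfr <- nrow(res$fragments)
      if (nfr > 0L) frag_tabs[[length(frag_tabs) + 1L]] <-
        fragments_table(res)
      if (!quiet)
        message(sprintf("%s\t%s\t%d fragment(s)\t%.2fs", entry_id, outcome,
                        nfr, proc.time()[["elapsed"]] - t0))
    }
    entries <- rbind(entries, data.frame(entry_id = entry_id, path = p,
                                         outcome = outcome,
                                         n_fragments = nfr,
                                         stringsAsFactors = FALSE))
  }
  positives <- sort(entries$entry_id[entries$outcome == "positive"])
  writeLines(positives, file.path(out_dir, "amyloid_list.txt"))
  frag_all <- if (length(frag_tabs)) do.call(rbind, frag_tabs)
    else data.frame(entry_id = character(), source_chain = character(),
                    target_chain = character(), start_auth = character(),
                    end_auth = character(), length = integer(),
                    sigma = numeric(), d_lo = numeric(), d_hi = numeric(),
                    mean_theta = numeric(), stringsAsFactors = FALSE)
  utils::write.table(frag_all, file.path(out_dir, "fragments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    tool = "amyloidscreen",
    tool_version = as.character(utils::packageVersion("amyloidscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = unclass(params),
    sheet_config = unclass(sheet_config),
    max_gap = max_gap,
    inputs = as.character(inputs),
    entries = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Fetch structure files from the RCSB PDB by accession
#'
#' Downloads mmCIF files into a local cache; idempotent, a cached file is
#' never re-downloaded.  Accessions must match the 4-character PDB
#' pattern (digit followed by three alphanumerics) and are validated
#' before any network access.  Per-accession download failures are
#' recorded and do not abort the batch.  Requires network access.
#'
#' @param accessions Character vector of PDB ids.
#' @param cache_dir Cache directory (created if needed).
#' @param base_url Download URL prefix.
#' @param quiet Suppress download progress.
#' @return Named character vector of file paths, `NA` for accessions that
#'   failed to download (with a warning naming them).
#' @export
fetch <- function(accessions, cache_dir,
                  base_url = "https://files.rcsb.org/download/",
                  quiet = TRUE) {
  accessions <- toupper(as.character(accessions))
  bad <- accessions[!grepl("^[0-9][A-Z0-9]{3}$", accessions)]
  if (length(bad))
    stop("invalid PDB accession(s): ", paste(bad, collapse = ", "))
  if (!dir.exists(cache_dir) &&
      !dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create cache directory ", cache_dir)
  out <- setNames(rep(NA_character_, length(accessions)), accessions)
  for (id in accessions) {
    dest <- file.path(cache_dir, paste0(id, ".cif"))
    if (file.exists(dest)) { out[id] <- dest; next }
    ok <- tryCatch({
      utils::download.file(paste0(base_url, id, ".cif"), dest,
                           quiet = quiet, mode = "wb")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (ok && file.exists(dest) && file.size(dest) > 0) {
      out[id] <- dest
    } else {
      unlink(dest)
      warning("failed to fetch ", id, call. = FALSE)
    }
  }
  out
}
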