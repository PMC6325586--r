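.empty_fragments <- function() {
  data.frame(source_chain_id = character(), target_chain_id = character(),
             start = integer(), end = integer(), length = integer(),
             start_auth = character(), end_auth = character(),
             sigma = numeric(), d_lo = numeric(), d_hi = numeric(),
             mean_theta = numeric(), stringsAsFactors = FALSE)
}

#' Screen one ordered chain pair for parallel fragments
#'
#' Computes the minimum-distance profile of `source` against `target`,
#' finds the maximal rule-(a) windows within each break segment of the
#' source chain, then keeps a window iff its mean pseudo-bond angle lies
#' in `[theta_min, theta_max]` (rule b) and its length is at least
#' `len(source) / length_ratio_divisor` (rule c; `len` counts the
#' residues of the full deposited chain with a C-alpha, not the break
#' segment).
#'
#' @param source,target `ChainTrace` objects with different chain ids.
#' @param params A [rule_params()].
#' @param max_gap Chain-break threshold passed to [split_on_breaks()].
#' @return A fragment data.frame (possibly 0-row) with 0-based inclusive
#'   `start`/`end` on the source chain, author residue bounds, `sigma`,
#'   distance bounds and `mean_theta`.  The attribute `"rejects"` tallies
#'   `failed_a` (1 when no window passed rule a at all), `failed_b` and
#'   `failed_c` (windows lost to rules b and c).
#' @export
screen_pair <- function(source, target, params = rule_params(),
                        max_gap = 4.5) {
  stopifnot(inherits(source, "ChainTrace"), inherits(target, "ChainTrace"))
  full_len <- length(source)
  min_len_c <- full_len / params$length_ratio_divisor
  prof <- distance_profile(source, target)
  frags <- .empty_fragments()
  failed_b <- 0L; failed_c <- 0L; n_windows <- 0L
  for (seg in split_on_breaks(source, max_gap = max_gap)) {
    if (length(seg) < params$min_fragment_residues) next
    idx <- seg$offset + seq_len(length(seg))  # 1-based into profile
    wins <- maximal_windows(prof$dmin[idx], params)
    if (nrow(wins) == 0L) next
    n_windows <- n_windows + nrow(wins)
    for (w in seq_len(nrow(wins))) {
      s <- wins$start[w] + seg$offset       # 0-based on full chain
      e <- wins$end[w] + seg$offset
      theta <- mean_fragment_angle(source, s, e)
      if (theta < params$theta_min || theta > params$theta_max) {
        failed_b <- failed_b + 1L
        next
      }
      if (e - s + 1L < min_len_c) {
        failed_c <- failed_c + 1L
        next
      }
      frags <- rbind(frags, data.frame(
        source_chain_id = source$chain_id,
        target_chain_id = target$chain_id,
        start = s, end = e, length = e - s + 1L,
        start_auth = source$auth_seq_id[s + 1L],
        end_auth = source$auth_seq_id[e + 1L],
        sigma = wins$sigma[w], d_lo = wins$d_lo[w], d_hi = wins$d_hi[w],
        mean_theta = theta, stringsAsFactors = FALSE))
    }
  }
  rownames(frags) <- NULL
  attr(frags, "rejects") <- list(failed_a = as.integer(n_windows == 0L),
                                 failed_b = failed_b, failed_c = failed_c)
  frags
}

#' Screen a whole structure for amyloid-like architecture
#'
#' Evaluates [screen_pair()] over every ordered pair (A, B), A != B, of
#' sheet-qualifying chains.  The verdict is positive iff any pair yields
#' at least one fragment passing all three rules.  Structures with fewer
#' than two chains are negative by construction: amyloid aggregates
#' consist of many distinct, approximately parallel chains, so isolated
#' hairpins and single-chain beta-barrels (self-parallel geometry within
#' one chain) are excluded regardless of their geometry.
#'
#' @param record A [structure_record()].
#' @param params A [rule_params()].
#' @param sheet_config A [sheet_call_config()].
#' @param max_gap Chain-break threshold (Angstrom).
#' @return An object of class `ScreenResult`: `entry_id`, logical
#'   `verdict`, `fragments` (all passing fragments), `n_chains`,
#'   `n_sheet_chains`, `n_pairs` and the per-rule reject tallies.
#' @export
screen_structure <- function(record, params = rule_params(),
                             sheet_config = sheet_call_config(),
                             max_gap = 4.5) {
  stopifnot(inherits(record, "StructureRecord"),
            inherits(params, "RuleParams"))
  rejects <- list(failed_a = 0L, failed_b = 0L, failed_c = 0L)
  frags <- .empty_fragments()
  n_chains <- length(record$chains)
  n_sheet <- 0L
  n_pairs <- 0L
  if (n_chains >= 2L) {
    sheet_ok <- vapply(record$chains, is_sheet_chain, TRUE,
                       config = sheet_config, record = record)
    n_sheet <- sum(sheet_ok)
    qual <- record$chains[sheet_ok]
    if (length(qual) >= 2L) {
      for (i in seq_along(qual)) for (j in seq_along(qual)) {
        if (i == j) next
        n_pairs <- n_pairs + 1L
        pf <- screen_pair(qual[[i]], qual[[j]], params, max_gap = max_gap)
        rj <- attr(pf, "rejects")
        rejects$failed_a <- rejects$failed_a + rj$failed_a
        rejects$failed_b <- rejects$failed_b + rj$failed_b
        rejects$failed_c <- rejects$failed_c + rj$failed_c
        if (nrow(pf) > 0L) frags <- rbind(frags, pf)
      }
    }
  }
  rownames(frags) <- NULL
  attr(frags, "rejects") <- NULL
  structure(list(entry_id = record$entry_id,
                 verdict = nrow(frags) > 0L,
                 fragments = frags,
                 n_chains = n_chains,
                 n_sheet_chains = n_sheet,
                 n_pairs = n_pairs,
                 rejects = rejects),
            class = "ScreenResult")
}

#' @export
print.ScreenResult <- function(x, ...) {
  cat(sprintf("<ScreenResult %s: %s>\n", x$entry_id,
              if (x$verdict) "AMYLOID-LIKE" else "negative"))
  cat(sprintf("  chains: %d (%d sheet-qualifying), ordered pairs: %d\n",
              x$n_chains, x$n_sheet_chains, x$n_pairs))
  cat(sprintf("  fragments passing all rules: %d\n", nrow(x$fragments)))
  cat(sprintf("  windows rejected: rule-a-empty pairs %d, rule b %d, rule c %d\n",
              x$rejects$failed_a, x$rejects$failed_b, x$rejects$failed_c))
  if (nrow(x$fragments) > 0L)
    print(utils::head(x$fragments, 10L))
  invisible(x)
}

#' Fragment table of a screening result
#'
#' One row per passing fragment in the TSV report layout.
#'
#' @param result A `ScreenResult`.
#' @return data.frame with columns `entry_id`, `source_chain`,
#'   `target_chain`, `start_auth`, `end_auth`, `length`, `sigma`, `d_lo`,
#'   `d_hi`, `mean_theta`.
#' @export
fragments_table <- function(result) {
  stopifnot(inherits(result, "ScreenResult"))
  fr <- result$fragments
  data.frame(entry_id = rep(result$entry_id, nrow(fr)),
             source_chain = fr$source_chain_id,
             target_chain = fr$target_chain_id,
             start_auth = fr$start_auth, end_auth = fr$end_auth,
             length = fr$length, sigma = fr$sigma,
             d_lo = fr$d_lo, d_hi = fr$d_hi, mean_theta = fr$mean_theta,
             stringsAsFactors = FALSE)
}

#' JSON document for a screening result
#'
#' @param result A `ScreenResult`.
#' @param pretty Pretty-print the JSON.
#' @return A JSON string (class `json`).
#' @export
screen_result_json <- function(result, pretty = TRUE) {
  stopifnot(inherits(result, "ScreenResult"))
  jsonlite::toJSON(unclass(result), dataframe = "rows", auto_unbox = TRUE,
                   pretty = pretty, digits = NA)
}
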