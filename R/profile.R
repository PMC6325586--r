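#' Screening rule parameters
#'
#' All numeric thresholds of the three geometric rules in one validated
#' object:
#' * rule (a): `sigma_max` — maximum standard deviation of the fragment's
#'   minimum-distance profile (default 1.5 Angstrom); `d_min`/`d_max` —
#'   closed bounds on every profile value (defaults 2 and 15 Angstrom);
#' * rule (b): `theta_min`/`theta_max` — closed bounds on the fragment's
#'   mean pseudo-bond angle (defaults 110 and 180 degrees);
#' * rule (c): `length_ratio_divisor` — the fragment must span at least
#'   `len(chain) / length_ratio_divisor` residues (default 7).
#'
#' `min_fragment_residues` (default 3) is the absolute floor below which a
#' window has no interior vertex and rule (b)'s mean angle is undefined.
#' `sd_type` selects the population (divide by n, the default) or sample
#' (divide by n-1) form of the standard deviation; the population form is
#' the plain reading of sigma and is stable for length-3 windows.
#'
#' @param sigma_max,d_min,d_max,theta_min,theta_max,length_ratio_divisor,min_fragment_residues
#'   See description.
#' @param sd_type `"population"` or `"sample"`.
#' @return An object of class `RuleParams`.
#' @export
rule_params <- function(sigma_max = 1.5, d_min = 2, d_max = 15,
                        theta_min = 110, theta_max = 180,
                        length_ratio_divisor = 7,
                        min_fragment_residues = 3L,
                        sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(sigma_max > 0, d_min > 0, d_min < d_max,
            theta_min >= 0, theta_min <= theta_max, theta_max <= 180,
            length_ratio_divisor >= 1, min_fragment_residues >= 3L)
  structure(list(sigma_max = sigma_max, d_min = d_min, d_max = d_max,
                 theta_min = theta_min, theta_max = theta_max,
                 length_ratio_divisor = length_ratio_divisor,
                 min_fragment_residues = as.integer(min_fragment_residues),
                 sd_type = sd_type),
            class = "RuleParams")
}

#' Minimum cross-chain C-alpha distance profile
#'
#' For every C-alpha of the source chain, the distance to the closest
#' C-alpha of the target chain.  A fragment of the source chain running
#' parallel to the target at constant spacing shows up as a near-constant
#' stretch of this profile.
#'
#' @param source,target `ChainTrace` objects with different chain ids.
#' @return An object of class `DistanceProfile`: list with
#'   `source_chain_id`, `target_chain_id` and `dmin` (numeric vector,
#'   Angstrom, one value per source residue).
#' @export
distance_profile <- function(source, target) {
  stopifnot(inherits(source, "ChainTrace"), inherits(target, "ChainTrace"))
  if (source$chain_id == target$chain_id)
    stop("distance_profile requires two distinct chains")
  if (length(target) == 0L) stop("empty target chain")
  sx <- source$xyz; tx <- target$xyz
  d2 <- outer(rowSums(sx^2), rowSums(tx^2), "+") - 2 * tcrossprod(sx, tx)
  dmin <- sqrt(pmax(apply(d2, 1L, min), 0))
  structure(list(source_chain_id = source$chain_id,
                 target_chain_id = target$chain_id,
                 dmin = as.numeric(dmin)),
            class = "DistanceProfile")
}

#' @export
print.DistanceProfile <- function(x, ...) {
  cat(sprintf("<DistanceProfile %s -> %s: n = %d, range %.2f-%.2f A>\n",
              x$source_chain_id, x$target_chain_id, length(x$dmin),
              min(x$dmin), max(x$dmin)))
  invisible(x)
}

#' Mean pseudo-bond angle over a fragment
#'
#' Arithmetic mean of the pseudo-bond angle at every interior vertex of
#' the fragment `[start, end]` (0-based seq_index, inclusive), i.e. at
#' vertices `start+1 .. end-1` with both neighbours inside the fragment.
#' This is the curvature statistic of rule (b).
#'
#' @param chain A `ChainTrace`.
#' @param start,end 0-based seq_index bounds, inclusive;
#'   `end - start + 1 >= 3`.
#' @return Mean angle in degrees.
#' @export
mean_fragment_angle <- function(chain, start, end) {
  stopifnot(inherits(chain, "ChainTrace"))
  start <- as.integer(start); end <- as.integer(end)
  if (end - start + 1L < 3L)
    stop("fragment must span at least 3 residues for a mean angle")
  if (start < 0L || end > length(chain) - 1L)
    stop("fragment bounds outside chain")
  xyz <- chain$xyz
  verts <- (start + 1L):(end - 1L)
  mean(vapply(verts, function(i) {
    pseudo_bond_angle(xyz[i, ], xyz[i + 1L, ], xyz[i + 2L, ])
  }, numeric(1L)))
}

#' Maximal low-variance windows of a distance profile (rule a)
#'
#' Finds every inclusion-maximal window `[start, end]` of the profile such
#' that (i) every value lies in the closed interval `[d_min, d_max]`,
#' (ii) the standard deviation of the window's values is at most
#' `sigma_max`, and (iii) the window spans at least
#' `min_fragment_residues`.  Maximal means no strict superwindow also
#' satisfies (i) and (ii); because the standard deviation is not monotone
#' under extension, maximal windows may overlap and all are returned.
#'
#' @param profile A [distance_profile()] or bare numeric vector of
#'   distances (Angstrom).
#' @param params A [rule_params()].
#' @return data.frame with 0-based inclusive `start`, `end` plus the
#'   window's `sigma`, `d_lo`, `d_hi`; zero rows when nothing qualifies.
#'   Sorted by `start`.
#' @export
maximal_windows <- function(profile, params = rule_params()) {
  stopifnot(inherits(params, "RuleParams"))
  dmin <- if (inherits(profile, "DistanceProfile")) profile$dmin
          else as.numeric(profile)
  if (length(dmin) == 0L) stop("empty profile")
  minlen <- params$min_fragment_residues
  empty <- data.frame(start = integer(), end = integer(),
                      sigma = numeric(), d_lo = numeric(), d_hi = numeric())
  inb <- dmin >= params$d_min & dmin <= params$d_max
  if (!any(inb)) return(empty)
  runs <- rle(inb)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  out <- empty
  for (r in which(runs$values & runs$lengths >= minlen)) {
    a <- run_start[r]; b <- run_end[r]
    best_prev <- -1L
    for (s in a:(b - minlen + 1L)) {
      # Welford scan from s: longest qualifying end for this start.
      m <- 0; M2 <- 0; k <- 0L
      maxe <- -1L
      sig_at <- dlo_at <- dhi_at <- NA_real_
      lo <- Inf; hi <- -Inf
      for (e in s:b) {
        k <- k + 1L
        x <- dmin[e]
        delta <- x - m
        m <- m + delta / k
        M2 <- M2 + delta * (x - m)
        lo <- min(lo, x); hi <- max(hi, x)
        if (k >= minlen) {
          sig <- sqrt(M2 / if (params$sd_type == "population") k else k - 1L)
          if (sig <= params$sigma_max) {
            maxe <- e
            sig_at <- sig; dlo_at <- lo; dhi_at <- hi
          }
        }
      }
      if (maxe > best_prev) {
        out <- rbind(out, data.frame(start = s - 1L, end = maxe - 1L,
                                     sigma = sig_at, d_lo = dlo_at,
                                     d_hi = dhi_at))
        best_prev <- maxe
      }
    }
  }
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}
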