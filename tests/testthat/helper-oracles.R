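# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: plain enumeration and textbook formulas only.

# Brute-force maximal-window oracle: enumerate every window, test the
# bounds and standard-deviation predicate directly, then discard windows
# strictly contained in another qualifying window.  0-based output.
oracle_windows <- function(dmin, params) {
  n <- length(dmin)
  minlen <- params$min_fragment_residues
  qual <- list()
  for (s in seq_len(n)) for (e in s:n) {
    if (e - s + 1L < minlen) next
    w <- dmin[s:e]
    if (any(w < params$d_min | w > params$d_max)) next
    k <- length(w)
    sig <- if (params$sd_type == "population")
      sqrt(sum((w - mean(w))^2) / k) else stats::sd(w)
    if (sig <= params$sigma_max) qual[[length(qual) + 1L]] <- c(s, e)
  }
  if (length(qual) == 0L)
    return(data.frame(start = integer(), end = integer()))
  keep <- vapply(seq_along(qual), function(i) {
    wi <- qual[[i]]
    !any(vapply(seq_along(qual), function(j) {
      if (i == j) return(FALSE)
      wj <- qual[[j]]
      wj[1L] <= wi[1L] && wj[2L] >= wi[2L]
    }, TRUE))
  }, TRUE)
  m <- do.call(rbind, qual[keep])
  out <- data.frame(start = m[, 1L] - 1L, end = m[, 2L] - 1L)
  out[order(out$start), , drop = FALSE]
}

# Angle at vertex q via the law of cosines on the three side lengths —
# a different formulation than the implementation's dot product.
oracle_angle <- function(p, q, r) {
  a <- sqrt(sum((p - q)^2)); b <- sqrt(sum((r - q)^2))
  cc <- sqrt(sum((p - r)^2))
  acos(max(-1, min(1, (a^2 + b^2 - cc^2) / (2 * a * b)))) * 180 / pi
}

# A uniformly random rotation matrix (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Write PDB-format lines to a temp file and return its path.
tmp_pdb <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

# Fixed-width PDB ATOM line for a single CA.
ca_line <- function(serial, resid, chain, resno, x, y, z,
                    occ = 1, alt = " ", type = "ATOM  ") {
  sprintf("%s%5d  CA %s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          type, serial, alt, resid, chain, resno, x, y, z, occ, 0)
}

default_params <- function(...) rule_params(...)
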