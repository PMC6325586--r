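# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Parameters of a synthetic cross-beta fibril
#'
#' Describes an idealized stack of planar zig-zag beta-strands.  The
#' defaults are textbook cross-beta values: a 3.8 Angstrom C-alpha step
#' along the strand with a 3.4 Angstrom axial advance per residue
#' (giving the characteristic extended-strand vertex angle of about
#' 127 degrees) and 4.8 Angstrom spacing between stacked chains — the
#' inter-strand hydrogen-bonding distance of amyloid fibrils.
#'
#' @param n_chains Number of stacked chains (>= 1).
#' @param n_residues Residues per chain (>= 3).
#' @param rise Axial advance per residue along the strand axis, Angstrom.
#' @param strand_step C-alpha to C-alpha distance along the strand,
#'   Angstrom; must exceed `rise`.
#' @param stack_spacing Distance between adjacent stacked chains,
#'   Angstrom.
#' @param twist_deg Rotation about the stacking axis per stacking step,
#'   degrees (0 = untwisted).
#' @param noise_sd Isotropic Gaussian coordinate noise, Angstrom.
#' @param seed RNG seed for the noise (ignored when `noise_sd = 0`).
#' @return An object of class `FibrilSpec`.
#' @export
fibril_spec <- function(n_chains, n_residues, rise = 3.4, strand_step = 3.8,
                        stack_spacing = 4.8, twist_deg = 0, noise_sd = 0,
                        seed = 1L) {
  stopifnot(n_chains >= 1L, n_residues >= 3L, rise > 0, strand_step > 0,
            strand_step > rise, stack_spacing > 0, noise_sd >= 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_residues = as.integer(n_residues),
                 rise = rise, strand_step = strand_step,
                 stack_spacing = stack_spacing, twist_deg = twist_deg,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "FibrilSpec")
}

#' Synthetic cross-beta stack (ground-truth positive)
#'
#' Builds `n_chains` identical planar zig-zag strands stacked
#' `stack_spacing` apart along z.  With zero noise and zero twist the
#' minimum-distance profile between adjacent chains is exactly constant,
#' so the structure is a clean positive for the screening rules whenever
#' it has at least two chains.
#'
#' @param spec A [fibril_spec()].
#' @return A [structure_record()] with entry id `"crossbeta"`.
#' @export
make_cross_beta <- function(spec) {
  stopifnot(inherits(spec, "FibrilSpec"))
  i <- seq_len(spec$n_residues) - 1L
  h <- sqrt(spec$strand_step^2 - spec$rise^2)
  strand <- cbind(i * spec$rise, (i %% 2L) * h, 0)
  chains <- vector("list", spec$n_chains)
  for (k in seq_len(spec$n_chains)) {
    xyz <- strand
    if (spec$twist_deg != 0) {
      # twist accumulates about the stacking (z) axis
      a <- (k - 1L) * spec$twist_deg * pi / 180
      Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                   3L, 3L, byrow = TRUE)
      xyz <- xyz %*% t(Rz)
    }
    xyz[, 3L] <- xyz[, 3L] + (k - 1L) * spec$stack_spacing
    chains[[k]] <- xyz
  }
  if (spec$noise_sd > 0) {
    chains <- .with_seed(spec$seed, lapply(chains, function(xyz)
      xyz + matrix(rnorm(length(xyz), sd = spec$noise_sd),
                   nrow(xyz), 3L)))
  }
  structure_record("crossbeta", lapply(seq_along(chains), function(k)
    chain_trace(.chain_alphabet[k], chains[[k]])))
}

#' Synthetic bundle of parallel alpha-helices (ground-truth negative)
#'
#' Ideal alpha-helical C-alpha traces (default 2.3 Angstrom radius,
#' 1.5 Angstrom rise and 100 degrees rotation per residue) laid out in a
#' row at `spacing` Angstrom.  Adjacent helices run parallel at
#' near-constant separation — many windows satisfy rule (a) — but every
#' interior pseudo-bond angle is near 90 degrees, so rule (b) rejects all
#' of them: this fixture isolates the curvature rule.
#'
#' @param n_chains Number of helices (>= 1).
#' @param n_residues Residues per helix (>= 4).
#' @param radius Helix radius, Angstrom.
#' @param rise_per_res Rise per residue, Angstrom.
#' @param turn_deg Rotation per residue, degrees.
#' @param spacing Distance between adjacent helix axes, Angstrom.
#' @param noise_sd Isotropic Gaussian noise, Angstrom.
#' @param seed RNG seed for the noise.
#' @return A [structure_record()] with entry id `"helixbundle"`.
#' @export
make_helix_bundle <- function(n_chains = 2L, n_residues = 20L, radius = 2.3,
                              rise_per_res = 1.5, turn_deg = 100,
                              spacing = 10, noise_sd = 0, seed = 1L) {
  stopifnot(n_chains >= 1L, n_residues >= 4L, radius > 0, rise_per_res > 0,
            spacing > 0, noise_sd >= 0)
  i <- seq_len(n_residues) - 1L
  t <- turn_deg * pi / 180 * i
  helix <- cbind(radius * cos(t), radius * sin(t), rise_per_res * i)
  chains <- lapply(seq_len(n_chains), function(k)
    sweep(helix, 2L, c((k - 1L) * spacing, 0, 0), "+"))
  if (noise_sd > 0) {
    chains <- .with_seed(seed, lapply(chains, function(xyz)
      xyz + matrix(rnorm(length(xyz), sd = noise_sd), nrow(xyz), 3L)))
  }
  structure_record("helixbundle", lapply(seq_along(chains), function(k)
    chain_trace(.chain_alphabet[k], chains[[k]])))
}

#' Synthetic single-chain beta-barrel (ground-truth negative)
#'
#' One polypeptide chain threading `n_strands` straight strands arranged
#' on a cylinder, connected by short turns, strands alternating up/down.
#' The geometry is self-parallel — adjacent strands sit at near-constant
#' separation — but it is all one chain, so the distinct-chain
#' requirement alone makes the verdict negative.  With
#' `split_chains = TRUE` the turns are dropped and each strand becomes
#' its own chain, demonstrating that the exclusion is the chain rule,
#' not the geometry.
#'
#' @param n_strands Number of strands (>= 4).
#' @param n_res_per_strand Residues per strand (>= 3).
#' @param radius Barrel radius, Angstrom; the default spaces adjacent
#'   strands 4.8 Angstrom apart.
#' @param step C-alpha step along a strand, Angstrom.
#' @param split_chains Emit each strand as a separate chain (turns
#'   removed) instead of one threaded chain.
#' @return A [structure_record()] with entry id `"barrel"` (or
#'   `"barrel_split"`).
#' @export
make_barrel <- function(n_strands = 8L, n_res_per_strand = 10L,
                        radius = NULL, step = 3.8, split_chains = FALSE) {
  stopifnot(n_strands >= 4L, n_res_per_strand >= 3L, step > 0)
  if (is.null(radius)) radius <- 4.8 / (2 * sin(pi / n_strands))
  stopifnot(radius > 0)
  phi <- 2 * pi * (seq_len(n_strands) - 1L) / n_strands
  zs <- (seq_len(n_res_per_strand) - 1L) * step
  strands <- lapply(seq_len(n_strands), function(k) {
    z <- if (k %% 2L == 1L) zs else rev(zs)   # alternate up/down
    cbind(radius * cos(phi[k]), radius * sin(phi[k]), z)
  })
  if (split_chains) {
    return(structure_record("barrel_split",
      lapply(seq_len(n_strands), function(k)
        chain_trace(.chain_alphabet[k], strands[[k]]))))
  }
  # thread strands into one chain with 2-residue connecting turns
  xyz <- strands[[1L]]
  for (k in seq_len(n_strands)[-1L]) {
    a <- xyz[nrow(xyz), ]
    b <- strands[[k]][1L, ]
    turn <- rbind(a + (b - a) / 3 + c(0, 0, step),
                  a + 2 * (b - a) / 3 + c(0, 0, step))
    xyz <- rbind(xyz, turn, strands[[k]])
  }
  structure_record("barrel", list(chain_trace("A", xyz)))
}
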