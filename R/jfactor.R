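# Jacobson-Stockmayer J-factor estimation: chains are generated from the
# step model, closure observables (r, cos gamma, cos phi) are gated by nested
# thresholds, and the three pass fractions are converted into the densities
# of the ring-closure factorization
#   J = (4 pi / N_A) W(r ~ 0) Gamma_r(cos gamma ~ 1) Phi_{r,cos gamma}(phi ~ 0).

#' Closure thresholds
#'
#' Defaults: end-to-end distance below 30 Angstrom, normal alignment
#' `cos gamma > 0.86`, torsional register `cos phi > 0.86`.
#'
#' @param r_c End-to-end capture radius in Angstrom.
#' @param c_gamma Threshold on `cos gamma` (in (0, 1)).
#' @param c_phi Threshold on `cos phi` (in (0, 1)).
#' @return An object of class `closure_thresholds`.
#' @export
closure_thresholds <- function(r_c = 30, c_gamma = 0.86, c_phi = 0.86) {
  stopifnot(r_c > 0, c_gamma > 0, c_gamma < 1, c_phi > 0, c_phi < 1)
  structure(list(r_c = r_c, c_gamma = c_gamma, c_phi = c_phi),
            class = "closure_thresholds")
}

#' Nested cyclization counts
#'
#' @param n_total Chains generated.
#' @param n_r Chains with `r < r_c`.
#' @param n_gamma Of those, chains with `cos gamma > c_gamma`.
#' @param n_phi Of those, chains with `cos phi > c_phi`.
#' @return An object of class `cyclization_counts`.
#' @export
cyclization_counts <- function(n_total, n_r, n_gamma, n_phi) {
  v <- c(n_total = as.numeric(n_total), n_r = as.numeric(n_r),
         n_gamma = as.numeric(n_gamma), n_phi = as.numeric(n_phi))
  if (any(v < 0) || any(diff(v) > 0)) {
    stop("counts must satisfy n_total >= n_r >= n_gamma >= n_phi >= 0")
  }
  structure(as.list(v), class = "cyclization_counts")
}

#' Accumulate nested closure counts from an observable stream
#'
#' @param obs Data frame or matrix with columns `r`, `cos_gamma`, `cos_phi`.
#' @param thresholds A [closure_thresholds()].
#' @return A [cyclization_counts()]. Order-independent.
#' @export
accumulate_counts <- function(obs, thresholds = closure_thresholds()) {
  obs <- as.data.frame(obs)
  if (is.null(obs$r)) names(obs)[1:3] <- c("r", "cos_gamma", "cos_phi")
  stopifnot(all(is.finite(obs$r)), all(is.finite(obs$cos_gamma)),
            all(is.finite(obs$cos_phi)))
  in_r <- obs$r < thresholds$r_c
  in_g <- in_r & obs$cos_gamma > thresholds$c_gamma
  in_p <- in_g & obs$cos_phi > thresholds$c_phi
  cyclization_counts(nrow(obs), sum(in_r), sum(in_g), sum(in_p))
}

#' Combine cyclization counts from independent runs
#'
#' Counts are additive, so an estimate may be split across runs with
#' partitioned seeds and merged; the resulting J equals the one computed from
#' the pooled observable stream.
#'
#' @param ... `cyclization_counts` objects.
#' @return A `cyclization_counts`.
#' @export
combine_counts <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) > 0,
            all(vapply(xs, inherits, TRUE, "cyclization_counts")))
  tot <- Reduce(function(a, b) Map(`+`, a, b), lapply(xs, unclass))
  cyclization_counts(tot$n_total, tot$n_r, tot$n_gamma, tot$n_phi)
}

#' J-factor from nested counts
#'
#' The three factors are estimated as densities at their target values:
#' `W = (n_r / n_total) / V_c` with `V_c = (4/3) pi r_c^3` converted to
#' liters (probability density per liter of the ends coinciding),
#' `Gamma = (n_gamma / n_r) / (1 - c_gamma)` (density per unit cos gamma at
#' alignment), and `Phi = (n_phi / n_gamma) / (2 arccos(c_phi))` (density per
#' radian of torsional register at zero). Then
#' `J = (4 pi / N_A) W Gamma Phi` in mol/L. With no chain passing all gates,
#' `J = 0` is returned with an `insufficient_sampling` flag. The standard
#' error combines the binomial errors of the three ratios in quadrature on
#' log J.
#'
#' @param counts A [cyclization_counts()].
#' @param thresholds The [closure_thresholds()] used for the counts.
#' @param mode `"cso"` or `"cso_epbd"` (annotation only).
#' @param settings Optional list snapshot (seed, n_chains, ...) stored on the
#'   estimate.
#' @return An object of class `jfactor_estimate` with fields `J` (mol/L),
#'   `stderr`, `counts`, `mode`, `thresholds`, `settings`, `flags`.
#' @export
jfactor_from_counts <- function(counts, thresholds = closure_thresholds(),
                                mode = "cso", settings = list()) {
  stopifnot(inherits(counts, "cyclization_counts"))
  if (counts$n_total <= 0) stop("n_total must be positive")
  const <- physical_constants()
  flags <- character()
  V_c <- (4 / 3) * pi * thresholds$r_c^3 / const$angstrom3_per_liter  # liters
  if (counts$n_phi == 0) {
    J <- 0
    stderr <- NA_real_
    flags <- c(flags, "insufficient_sampling")
  } else {
    p_r <- counts$n_r / counts$n_total
    p_g <- counts$n_gamma / counts$n_r
    p_p <- counts$n_phi / counts$n_gamma
    W <- p_r / V_c
    Gam <- p_g / (1 - thresholds$c_gamma)
    Phi <- p_p / (2 * acos(thresholds$c_phi))
    J <- (4 * pi / const$avogadro) * W * Gam * Phi
    rel2 <- (1 - p_r) / (counts$n_total * p_r) +
      (1 - p_g) / (counts$n_r * p_g) +
      (1 - p_p) / (counts$n_gamma * p_p)
    stderr <- J * sqrt(rel2)
    if (counts$n_phi < 10) flags <- c(flags, "low_counts")
  }
  structure(list(J = J, stderr = stderr, counts = counts, mode = mode,
                 thresholds = thresholds, settings = settings, flags = flags),
            class = "jfactor_estimate")
}

#' @export
print.jfactor_estimate <- function(x, ...) {
  cat(sprintf("<jfactor_estimate> J = %.3E mol/L (mode %s)\n", x$J, x$mode))
  cat(sprintf("  counts: total %g | r %g | gamma %g | phi %g\n",
              x$counts$n_total, x$counts$n_r, x$counts$n_gamma,
              x$counts$n_phi))
  if (!is.na(x$stderr)) cat(sprintf("  stderr = %.2E mol/L\n", x$stderr))
  if (length(x$flags) > 0) cat("  flags:", paste(x$flags, collapse = ", "),
                               "\n")
  invisible(x)
}

#' Estimate the J-factor of a sequence by chain Monte Carlo
#'
#' Applies the periodic two-base-pair extension, then generates `n_chains`
#' chains: for each chain a hinge mask is drawn from the opening profile (if
#' one is given), step angles are sampled with duplex or single-strand RMS
#' widths per step, the chain of frames is composed, and the closure
#' observables are gated by the thresholds. With `profile = NULL` (or an
#' all-zero profile) this reproduces the original, hinge-free chain model
#' exactly. The hinge state applies to the step entering an open base pair.
#'
#' Randomness is consumed in a fixed documented order (per chain: one uniform
#' per step for the hinge mask — only when the profile has a positive entry —
#' then tilt, roll, twist normals per step), so results are reproducible with
#' `seed` and mergeable across runs via [combine_counts()].
#'
#' @param seq A [dna_seq()].
#' @param table A `step_table`.
#' @param flex A [flexibility_model()].
#' @param thresholds A [closure_thresholds()].
#' @param profile Optional [opening_profile()] of the same (unextended)
#'   length; mismatch positions on `seq` are forced to probability one.
#' @param n_chains Number of chains.
#' @param seed Optional RNG seed.
#' @param store_max Keep the observables of the first `store_max` chains
#'   (attribute `observables`); 0 (default) stores none and memory stays O(1)
#'   in `n_chains`.
#' @return A `jfactor_estimate` (see [jfactor_from_counts()]) with mode
#'   `"cso"` or `"cso_epbd"`.
#' @export
estimate_jfactor <- function(seq, table, flex = flexibility_model(),
                             thresholds = closure_thresholds(),
                             profile = NULL, n_chains = 1e5, seed = NULL,
                             store_max = 0) {
  stopifnot(inherits(seq, "dna_seq"), inherits(table, "step_table"))
  n <- length(seq$bases)
  if (!is.null(profile)) {
    stopifnot(inherits(profile, "opening_profile"))
    if (length(profile$p) != n) {
      stop("profile length (", length(profile$p),
           ") does not match sequence length (", n, ")")
    }
    profile <- set_mismatch(profile, seq$mismatch)
  }
  ext <- extend_periodic(seq, profile)
  theta0 <- seq_steps(ext$sequence, table)
  theta0[, 1:3] <- theta0[, 1:3] * pi / 180
  # step s (s = 1..N) enters base pair s+1 of the extended sequence
  p_open <- if (is.null(profile)) rep(0, n) else ext$profile$p[2:(n + 1)]
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_closure_counts(theta0, flex$duplex * pi / 180,
                            flex$single_strand * pi / 180, p_open,
                            as.numeric(n_chains), thresholds$r_c,
                            thresholds$c_gamma, thresholds$c_phi,
                            as.integer(store_max))
  counts <- cyclization_counts(res$n_total, res$n_r, res$n_gamma, res$n_phi)
  est <- jfactor_from_counts(
    counts, thresholds,
    mode = if (is.null(profile)) "cso" else "cso_epbd",
    settings = list(seed = seed, n_chains = n_chains, sequence = seq$id,
                    length_bp = n))
  if (store_max > 0) {
    obs <- res$observables
    colnames(obs) <- c("r", "cos_gamma", "cos_phi")
    attr(est, "observables") <- obs
  }
  est
}

#' Shimada-Yamakawa ring-closure density of a torsion-free wormlike chain
#'
#' Closed-form reference for the closure density of an intrinsically straight
#' wormlike chain with the end normals aligned but no torsional constraint.
#' The Shimada-Yamakawa-type interpolation
#' `G(t) = 112.04 t^{-2} exp(0.246 t - 14.055 / t)` with `t = L / (2 l_p)`
#' (contour length in Kuhn lengths) gives the joint density of end-to-end
#' closure and normal alignment, per Kuhn volume and per unit cosine of the
#' end-normal angle; multiplying by `4 pi / N_A` expresses it in the same
#' normalization as the `(4 pi / N_A) * W * Gamma` factor pair of
#' [jfactor_from_counts()], in mol/L. The interpolation is a
#' sub-persistence-to-few-persistence-length form; it is used here around the
#' cyclization optimum (`t` of order 1-3) and degrades for `t` well above
#' that range.
#'
#' @param n_bp Chain length in base pairs.
#' @param lp_bp Persistence length in base pairs.
#' @param rise Rise per base pair in Angstrom.
#' @return Closure density in mol/L (comparable to
#'   `(4 pi / N_A) * W * Gamma`).
#' @export
sy_closure_density <- function(n_bp, lp_bp, rise = 3.4) {
  stopifnot(n_bp > 0, lp_bp > 0, rise > 0)
  const <- physical_constants()
  kuhn <- 2 * lp_bp * rise                 # Angstrom
  t <- n_bp * rise / kuhn                  # contour length in Kuhn lengths
  g <- 112.04 * t^-2 * exp(0.246 * t - 14.055 / t)  # per Kuhn vol, per cos
  4 * pi * g / kuhn^3 * const$angstrom3_per_liter / const$avogadro
}
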