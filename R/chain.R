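# Rigid base-pair chain model: base-pair frames related by tilt/roll/twist
# rotations and shift/slide/rise translations in the symmetric mid-step
# convention. Angular fluctuations are Gaussian around the trinucleotide
# equilibrium values, with separate RMS widths for duplex and single-stranded
# (hinge) steps; shift/slide/rise are held at their equilibrium values.

#' Angular flexibility model (duplex and single-strand RMS widths)
#'
#' Defaults follow the standard parameterization: isotropic bending with an
#' RMS fluctuation of 4.84 degrees for tilt and roll and 4.09 degrees for
#' twist of duplex DNA (corresponding to a persistence length of ~147 bp),
#' and ~30.08 / ~27.96 degrees for single-stranded (open) base pairs, whose
#' persistence length is only a few bp.
#'
#' @param duplex Length-3 numeric, RMS in degrees for (tilt, roll, twist) of
#'   double-stranded steps.
#' @param single_strand Length-3 numeric, RMS for single-stranded steps.
#' @return An object of class `flex_model`.
#' @export
flexibility_model <- function(duplex = c(tilt = 4.84, roll = 4.84,
                                         twist = 4.09),
                              single_strand = c(tilt = 30.08, roll = 30.08,
                                                twist = 27.96)) {
  duplex <- unname(as.numeric(duplex))
  single_strand <- unname(as.numeric(single_strand))
  stopifnot(length(duplex) == 3, length(single_strand) == 3,
            all(duplex > 0), all(single_strand > 0))
  structure(list(duplex = duplex, single_strand = single_strand),
            class = "flex_model")
}

#' Draw a hinge mask from an opening profile
#'
#' For each base pair, a uniform random number on (0, 1) is compared with the
#' opening probability; the base pair is in the single-stranded state when
#' the number is less than or equal to the probability. Redrawn independently
#' per generated chain.
#'
#' @param profile An [opening_profile()].
#' @return A logical vector (`TRUE` = open / single-stranded).
#' @export
draw_hinge_mask <- function(profile) {
  stopifnot(inherits(profile, "opening_profile"))
  runif(length(profile$p)) <= profile$p
}

#' Sample one base-pair step
#'
#' Tilt, roll and twist are drawn from independent normal distributions
#' centred at the equilibrium values with the state-appropriate RMS widths;
#' shift, slide and rise are returned at their equilibrium values.
#'
#' @param theta0 Named numeric of length 6 (tilt, roll, twist, shift, slide,
#'   rise; degrees and Angstrom).
#' @param flex A [flexibility_model()].
#' @param is_ss Logical; single-stranded (hinge) state for this step.
#' @return Named numeric of length 6.
#' @export
sample_step <- function(theta0, flex = flexibility_model(), is_ss = FALSE) {
  sdv <- if (isTRUE(is_ss)) flex$single_strand else flex$duplex
  out <- as.numeric(theta0[.STEP_COLS])
  out[1:3] <- rnorm(3, mean = out[1:3], sd = sdv)
  names(out) <- .STEP_COLS
  out
}

.rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}
.rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

#' Rigid transform of a base-pair step (mid-step convention)
#'
#' The net bend `Gamma = sqrt(tilt^2 + roll^2)` is applied about an axis in
#' the base-pair plane at angle `phi = atan2(tilt, roll)` from the roll axis,
#' split symmetrically around the half-twist; the translation (shift, slide,
#' rise) is expressed in the mid-step frame. Pure-twist steps rotate about
#' the base-pair normal only, and the construction is invariant under strand
#' relabelling.
#'
#' @param step Named numeric of length 6 (degrees / Angstrom).
#' @return A list with `rotation` (3x3 proper rotation, parent-frame
#'   coordinates) and `translation` (length-3, parent-frame coordinates).
#' @export
step_transform <- function(step) {
  tilt <- step[["tilt"]] * pi / 180
  roll <- step[["roll"]] * pi / 180
  twist <- step[["twist"]] * pi / 180
  gam <- sqrt(tilt^2 + roll^2)
  phi <- if (gam > 0) atan2(tilt, roll) else 0
  R <- .rot_z(twist / 2 - phi) %*% .rot_y(gam) %*% .rot_z(twist / 2 + phi)
  M <- .rot_z(twist / 2 - phi) %*% .rot_y(gam / 2) %*% .rot_z(phi)
  list(rotation = R,
       translation = as.numeric(M %*% c(step[["shift"]], step[["slide"]],
                                        step[["rise"]])))
}

#' Default (world) base-pair frame
#' @return A list with `origin` (0,0,0) and identity `triad` (columns are the
#'   frame axes; the third column is the base-pair normal).
#' @export
default_frame <- function() list(origin = c(0, 0, 0), triad = diag(3))

#' Build a chain of base-pair frames from a step list
#'
#' Frames are composed as `triad_n = triad_{n-1} %*% R(step_n)` with origins
#' advanced by the mid-step translation; the running triad is
#' re-orthogonalized every 64 compositions (nearest-orthogonal projection).
#'
#' @param steps Matrix or data frame with columns tilt, roll, twist, shift,
#'   slide, rise (degrees / Angstrom), one row per step.
#' @param start Optional starting frame as from [default_frame()].
#' @return An object of class `chain_conformation`: list with `origins`
#'   (`(n+1) x 3`) and `triads` (`3 x 3 x (n+1)`).
#' @export
build_chain <- function(steps, start = NULL) {
  steps <- as.matrix(as.data.frame(steps)[, .STEP_COLS])
  n <- nrow(steps)
  if (n < 1) stop("empty step list")
  if (is.null(start)) start <- default_frame()
  origins <- matrix(0, n + 1, 3)
  triads <- array(0, c(3, 3, n + 1))
  o <- start$origin
  Tr <- start$triad
  origins[1, ] <- o
  triads[, , 1] <- Tr
  for (s in seq_len(n)) {
    tf <- step_transform(steps[s, ])
    o <- o + as.numeric(Tr %*% tf$translation)
    Tr <- Tr %*% tf$rotation
    if (s %% 64 == 0) {
      # one Newton step toward the nearest orthogonal matrix
      Tr <- Tr %*% (1.5 * diag(3) - 0.5 * crossprod(Tr))
    }
    origins[s + 1, ] <- o
    triads[, , s + 1] <- Tr
  }
  structure(list(origins = origins, triads = triads),
            class = "chain_conformation")
}

#' Closure observables of a chain
#'
#' Returns the end-to-end distance `r = |o_last - o_first|`, the alignment of
#' the first and last base-pair normals `cos_gamma`, and the torsional
#' register `cos_phi`: the cosine of the angle between the first frame's
#' in-plane long axis and the last frame's long axis projected onto the first
#' base-pair plane.
#'
#' @param chain A `chain_conformation` from [build_chain()].
#' @return Named numeric `(r, cos_gamma, cos_phi)`.
#' @export
closure_observables <- function(chain) {
  stopifnot(inherits(chain, "chain_conformation"))
  n <- nrow(chain$origins)
  if (n < 2) stop("chain must have at least 2 frames")
  o1 <- chain$origins[1, ]; on <- chain$origins[n, ]
  T1 <- chain$triads[, , 1]; Tn <- chain$triads[, , n]
  r <- sqrt(sum((on - o1)^2))
  z1 <- T1[, 3]; zn <- Tn[, 3]
  cg <- sum(z1 * zn)
  x1 <- T1[, 1]; xn <- Tn[, 1]
  proj <- xn - sum(xn * z1) * z1
  nrm <- sqrt(sum(proj^2))
  cp <- if (nrm > 1e-12) sum(x1 * proj) / nrm else 0
  c(r = r, cos_gamma = max(-1, min(1, cg)), cos_phi = max(-1, min(1, cp)))
}

#' Estimate the persistence length from normal-vector correlations
#'
#' Generates chains from an intrinsically straight equilibrium geometry (or a
#' supplied step matrix), computes the mean autocorrelation of the base-pair
#' normal `<n(0) . n(s)>`, and fits `exp(-s / L_p)` over the initial decay.
#' The block-resampled standard error and a small-angle closed form
#' `2 / (sd_tilt^2 + sd_roll^2)` (radians) are attached for reference.
#'
#' @param flex A [flexibility_model()].
#' @param state `"duplex"` or `"single_strand"`: which RMS set to use.
#' @param n_chains Number of chains.
#' @param chain_length Steps per chain.
#' @param seed Optional RNG seed.
#' @param steps Optional `chain_length x 6` equilibrium step matrix; by
#'   default a straight fixture with 34.3 degree twist and 3.4 A rise.
#' @param corr_min Correlations below this value are excluded from the fit.
#' @param n_blocks Chain blocks for the standard error.
#' @return A list of class `persistence_fit` with `lp_bp`, `se_bp`,
#'   `lp_small_angle`, `rigid` flag and the correlation curve.
#' @export
estimate_persistence_length <- function(flex = flexibility_model(),
                                        state = c("duplex", "single_strand"),
                                        n_chains = 2000, chain_length = 600,
                                        seed = NULL, steps = NULL,
                                        corr_min = 0.2, n_blocks = 20) {
  state <- match.arg(state)
  if (!is.null(seed)) set.seed(seed)
  sdv <- if (state == "duplex") flex$duplex else flex$single_strand
  if (is.null(steps)) {
    steps <- matrix(0, chain_length, 6,
                    dimnames = list(NULL, .STEP_COLS))
    steps[, "twist"] <- 34.3
    steps[, "rise"] <- 3.4
  }
  theta0 <- as.matrix(steps)
  theta0[, 1:3] <- theta0[, 1:3] * pi / 180
  blocks <- cpp_normal_corr(theta0, sdv * pi / 180,
                            as.integer(n_chains), as.integer(n_blocks))
  corr <- rowMeans(blocks)
  sa <- 2 / sum((sdv[1:2] * pi / 180)^2)
  if (all(corr > 0.999)) {
    return(structure(list(lp_bp = Inf, se_bp = NA_real_,
                          lp_small_angle = sa, rigid = TRUE, corr = corr),
                     class = "persistence_fit"))
  }
  if (corr[1] <= 0) {
    stop("non-positive normal correlation at lag 1; cannot fit a decay length")
  }
  usable <- which(corr > corr_min)
  sel <- seq_len(if (length(usable) > 0) max(1L, max(usable)) else 1L)
  sel <- sel[corr[sel] > 0]
  if (length(sel) < 3) stop("too few usable lags for the persistence fit")
  fit_lp <- function(cv) {
    s <- sel
    -1 / coef(lm(log(cv[s]) ~ 0 + s))[[1]]
  }
  lp <- fit_lp(corr)
  lp_b <- apply(blocks, 2, function(cv) {
    if (any(cv[sel] <= 0)) NA_real_ else fit_lp(cv)
  })
  se <- stats::sd(lp_b, na.rm = TRUE) / sqrt(sum(!is.na(lp_b)))
  structure(list(lp_bp = lp, se_bp = se, lp_small_angle = sa, rigid = FALSE,
                 corr = corr, n_chains = n_chains,
                 chain_length = chain_length),
            class = "persistence_fit")
}

#' @export
print.persistence_fit <- function(x, ...) {
  if (x$rigid) {
    cat("<persistence_fit> rigid limit: correlation ~ 1, L_p -> Inf\n")
  } else {
    cat(sprintf(
      "<persistence_fit> L_p = %.1f bp (SE %.2f); small-angle form %.1f bp\n",
      x$lp_bp, x$se_bp, x$lp_small_angle))
  }
  invisible(x)
}
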