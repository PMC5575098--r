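# Per-base-pair opening probability profiles: the probability that each base
# pair is in a single-stranded (open) state, as produced by the EPBD sampler,
# read from file, or generated synthetically.

#' Construct an opening profile
#'
#' @param p Numeric vector of per-base-pair opening probabilities in `[0, 1]`.
#' @param source Provenance tag: `"epbd_mcmc"`, `"file"` or `"synthetic"`.
#' @return An object of class `opening_profile` with fields `p` and `source`.
#' @export
opening_profile <- function(p, source = c("synthetic", "file", "epbd_mcmc")) {
  source <- match.arg(source)
  p <- as.numeric(p)
  if (length(p) == 0L) stop("empty opening profile")
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("opening probabilities must lie in [0, 1]")
  }
  structure(list(p = p, source = source), class = "opening_profile")
}

#' @export
length.opening_profile <- function(x) length(x$p)

#' @export
print.opening_profile <- function(x, ...) {
  cat("<opening_profile> ", length(x$p), " bp, source = ", x$source,
      ", mean p = ", signif(mean(x$p), 3),
      ", max p = ", signif(max(x$p), 3), "\n", sep = "")
  invisible(x)
}

#' Force a base pair to be permanently open
#'
#' Sets the opening probability at `position` to exactly 1, the convention for
#' a mismatched (non-complementary) base pair, which is always in the
#' single-stranded state. Idempotent; all other entries are unchanged.
#'
#' @param profile An [opening_profile()].
#' @param position 1-based position(s) within the profile.
#' @return The modified profile.
#' @export
set_mismatch <- function(profile, position) {
  stopifnot(inherits(profile, "opening_profile"))
  position <- as.integer(position)
  if (length(position) == 0L) return(profile)
  if (min(position) < 1L || max(position) > length(profile$p)) {
    stop("mismatch position outside [1, ", length(profile$p), "]")
  }
  profile$p[position] <- 1.0
  profile
}

#' Write an opening profile to TSV
#'
#' Columns: `position` (1-based), `base`, `probability`. Probabilities are
#' written with full precision so that a write/read cycle is bit-exact.
#'
#' @param profile An [opening_profile()].
#' @param seq The matching [dna_seq()] (same length).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, seq, path) {
  stopifnot(inherits(profile, "opening_profile"), inherits(seq, "dna_seq"))
  n <- length(profile$p)
  if (n != length(seq$bases)) {
    stop("profile length (", n, ") does not match sequence length (",
         length(seq$bases), ")")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# opening profile for ", seq$id,
                      " (source: ", profile$source, ")"),
               "# position is 1-based"), con)
  df <- data.frame(position = seq_len(n), base = seq$bases,
                   probability = sprintf("%.17g", profile$p))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an opening profile from TSV
#'
#' @param path Path to a TSV written by [write_profile()] (columns `position`,
#'   `base`, `probability`; `#` comments allowed).
#' @return An [opening_profile()] with source `"file"`.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("position", "probability") %in% names(df))) {
    stop("profile file must have columns 'position' and 'probability'")
  }
  df <- df[order(df$position), ]
  if (!identical(as.integer(df$position), seq_len(nrow(df)))) {
    stop("profile positions must be contiguous starting at 1")
  }
  opening_profile(df$probability, source = "file")
}

#' Synthetic opening profile with AT-tract hotspots
#'
#' Emulates the qualitative shape of breathing profiles of double-stranded
#' DNA at biological temperature: a low log-uniform baseline everywhere
#' (default 1e-5 to 1e-3) with elevated opening probability (up to `hotspot_p`)
#' inside AT-rich tracts, where the weaker two-hydrogen-bond pairing makes
#' transient bubbles most likely.
#'
#' @param seq A [dna_seq()].
#' @param baseline Length-2 numeric range of the baseline probability.
#' @param hotspot_p Upper opening probability inside AT tracts.
#' @param min_run Minimum run length of consecutive A/T bases that counts as a
#'   hotspot tract.
#' @return An [opening_profile()] with source `"synthetic"`. Mismatch
#'   positions recorded on `seq` are set to probability one.
#' @export
synthetic_profile <- function(seq, baseline = c(1e-5, 1e-3),
                              hotspot_p = 1e-2, min_run = 4) {
  stopifnot(inherits(seq, "dna_seq"))
  n <- length(seq$bases)
  p <- exp(runif(n, log(baseline[1]), log(baseline[2])))
  is_at <- seq$bases %in% c("A", "T")
  r <- rle(is_at)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values & r$lengths >= min_run)) {
    idx <- starts[k]:ends[k]
    lo <- max(baseline[2], hotspot_p / 10)
    p[idx] <- pmax(p[idx], exp(runif(length(idx), log(lo), log(hotspot_p))))
  }
  prof <- opening_profile(pmin(p, 1), source = "synthetic")
  set_mismatch(prof, seq$mismatch)
}

#' Free-energy equivalent of an opening profile
#'
#' A descriptive, non-normative diagnostic: reports `-log(p)` per base pair in
#' units of kT (the apparent free-energy cost of observing each base pair
#' open) and the mean over base pairs with finite values. Sites with `p = 0`
#' are reported as `Inf` and excluded from the mean.
#'
#' @param profile An [opening_profile()].
#' @return A list with `per_site` (kT units), `mean` (over finite entries) and
#'   `n_infinite`.
#' @export
#' @examples
#' free_energy_equivalent(opening_profile(c(1, exp(-10))))
free_energy_equivalent <- function(profile) {
  stopifnot(inherits(profile, "opening_profile"))
  g <- -log(profile$p)
  finite <- is.finite(g)
  list(per_site = g,
       mean = if (any(finite)) mean(g[finite]) else NA_real_,
       n_infinite = sum(!finite))
}
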