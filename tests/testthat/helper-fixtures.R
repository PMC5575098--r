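# Shared fixtures: tiny sequences, tables and fast sampler settings.

STEP_COLS <- c("tilt", "roll", "twist", "shift", "slide", "rise")

poly_seq <- function(base, n, id = paste0("poly", base)) {
  dna_seq(rep(base, n), id = id)
}

# deterministic 50-bp sequence for parser tests
fifty_bp <- paste(rep("ACGTTGCAAC", 5), collapse = "")

write_tmp_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  lines <- unlist(lapply(seqs, function(s) c(paste0(">", s$id),
                                             as.character(s))))
  writeLines(lines, path)
  path
}

# step matrix with constant values (degrees / Angstrom)
const_steps <- function(n, tilt = 0, roll = 0, twist = 34.3, shift = 0,
                        slide = 0, rise = 3.4) {
  m <- matrix(rep(c(tilt, roll, twist, shift, slide, rise), each = n), n, 6)
  colnames(m) <- STEP_COLS
  m
}

# fast EPBD settings for tests: small cap keeps the dissociated plateau
# narrow so the opening fraction equilibrates within a few thousand sweeps
fast_epbd_settings <- function(...) {
  args <- list(n_equil = 1000, n_sweeps = 8000, thin = 4, y_max = 5)
  over <- list(...)
  args[names(over)] <- over
  do.call(mcmc_settings, args)
}

random_steps <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- cbind(tilt = rnorm(n, 0, 6), roll = rnorm(n, 0, 6),
             twist = rnorm(n, 34, 5), shift = rnorm(n, 0, 0.3),
             slide = rnorm(n, 0, 0.3), rise = rnorm(n, 3.4, 0.2))
  m
}
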