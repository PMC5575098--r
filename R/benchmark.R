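# Benchmark harness: order-of-magnitude agreement statistics between
# computed and experimental J-factors, with length strata (< 100 bp vs
# >= 100 bp), and a synthetic panel generator for end-to-end testing.

#' Fraction of sequences within k orders of magnitude
#'
#' @param J_calc,J_exp Positive numeric vectors of equal length (mol/L).
#' @param k Orders-of-magnitude bound.
#' @return Fraction of pairs with `|log10(J_calc / J_exp)| <= k`.
#' @export
#' @examples
#' within_order_fraction(c(1e-9, 1e-9), c(1e-9, 1e-12), k = 1)  # 0.5
within_order_fraction <- function(J_calc, J_exp, k) {
  stopifnot(length(J_calc) == length(J_exp), k >= 0)
  bad <- which(!is.finite(J_calc) | !is.finite(J_exp) | J_calc <= 0 |
                 J_exp <= 0)
  if (length(bad) > 0) {
    stop("non-positive or non-finite J at record(s): ",
         paste(bad, collapse = ", "))
  }
  mean(abs(log10(J_calc / J_exp)) <= k)
}

# Zero/NA-tolerant version used inside the benchmark curves: a record whose
# model estimate is zero or missing is certainly not within k orders, so it
# counts as a failure rather than an error.
.fraction_within <- function(J_calc, J_exp, k) {
  ok <- is.finite(J_calc) & is.finite(J_exp) & J_calc > 0 & J_exp > 0
  sum(ok & abs(log10(J_calc / J_exp)) <= k) / length(J_exp)
}

#' Agreement curve over a grid of order-of-magnitude bounds
#'
#' @param J_calc,J_exp Positive numeric vectors (mol/L).
#' @param k_grid Numeric grid of bounds.
#' @return Data frame with columns `k` and `fraction` (nondecreasing in `k`).
#' @export
comparison_curve <- function(J_calc, J_exp, k_grid = seq(0, 6, by = 0.5)) {
  data.frame(k = k_grid,
             fraction = vapply(k_grid, function(k)
               .fraction_within(J_calc, J_exp, k), numeric(1)))
}

#' Run the benchmark comparison
#'
#' Two input forms are accepted. (1) A data frame of precomputed records with
#' columns `id`, `length`, `J_exp` and one or both of `J_cso`, `J_cso_epbd`:
#' only the summary statistics are computed. (2) A synthetic panel from
#' [make_synthetic_panel()] (or any list with `sequences`, `profiles`,
#' `records`): J-factors are recomputed for both models by chain Monte Carlo
#' before summarizing.
#'
#' Records with a missing experimental J are skipped with a warning. Model
#' estimates of zero (insufficient sampling) count as disagreement at every
#' `k`. Sequences are stratified at 100 bp: `short` is < 100 bp, `long` is
#' >= 100 bp.
#'
#' @param panel Precomputed record data frame, or a synthetic panel list.
#' @param table,flex,thresholds Model settings for recomputation.
#' @param n_chains Chains per sequence and model when recomputing.
#' @param seed RNG seed for recomputation.
#' @param k_grid Orders-of-magnitude grid for the curves.
#' @return A list of class `benchmark_summary` with `records` (per-sequence
#'   table) and `curves` (columns `model`, `stratum`, `k`, `fraction`, `n`).
#' @export
run_benchmark <- function(panel, table = NULL, flex = flexibility_model(),
                          thresholds = closure_thresholds(), n_chains = 1e5,
                          seed = 1, k_grid = seq(0, 6, by = 0.5)) {
  if (is.data.frame(panel)) {
    records <- panel
  } else {
    stopifnot(is.list(panel), !is.null(panel$sequences),
              !is.null(panel$records))
    if (is.null(table)) table <- synthetic_step_table()
    records <- panel$records
    records$J_cso <- NA_real_
    records$J_cso_epbd <- NA_real_
    for (i in seq_along(panel$sequences)) {
      s <- panel$sequences[[i]]
      records$J_cso[i] <- estimate_jfactor(
        s, table, flex, thresholds, profile = NULL, n_chains = n_chains,
        seed = seed + 2L * i)$J
      records$J_cso_epbd[i] <- estimate_jfactor(
        s, table, flex, thresholds, profile = panel$profiles[[i]],
        n_chains = n_chains, seed = seed + 2L * i + 1L)$J
    }
  }
  if (!all(c("J_exp", "length") %in% names(records))) {
    stop("records must carry columns 'J_exp' and 'length'")
  }
  drop <- !is.finite(records$J_exp) | records$J_exp <= 0
  if (any(drop)) {
    warning(sum(drop), " record(s) without experimental J skipped")
    records <- records[!drop, , drop = FALSE]
  }
  strata <- list(all = rep(TRUE, nrow(records)),
                 short = records$length < 100,
                 long = records$length >= 100)
  models <- intersect(c("J_cso", "J_cso_epbd"), names(records))
  curves <- do.call(rbind, lapply(models, function(m) {
    do.call(rbind, lapply(names(strata), function(st) {
      idx <- strata[[st]]
      if (!any(idx)) return(NULL)
      cv <- comparison_curve(records[[m]][idx], records$J_exp[idx], k_grid)
      data.frame(model = sub("^J_", "", m), stratum = st, k = cv$k,
                 fraction = cv$fraction, n = sum(idx))
    }))
  }))
  rownames(curves) <- NULL
  structure(list(records = records, curves = curves),
            class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat("<benchmark_summary>", nrow(x$records), "records\n")
  at1 <- x$curves[x$curves$k == 1, ]
  for (i in seq_len(nrow(at1))) {
    cat(sprintf("  %-10s %-6s within 1 order: %5.1f%%  (n = %d)\n",
                at1$model[i], at1$stratum[i], 100 * at1$fraction[i], at1$n[i]))
  }
  invisible(x)
}

#' Write a benchmark summary to TSV (+ JSON)
#'
#' @param summary A `benchmark_summary`.
#' @param path Output TSV path for the curves; a matching `.json` with both
#'   records and curves is written alongside.
#' @return Invisibly, `path`.
#' @export
write_benchmark_summary <- function(summary, path) {
  stopifnot(inherits(summary, "benchmark_summary"))
  write.table(summary$curves, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(records = summary$records,
                            curves = summary$curves),
                       sub("\\.tsv$", ".json", path), digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read / write a benchmark panel TSV
#'
#' Columns: `id`, `sequence`, `J_exp`, optionally `J_cso`, `J_cso_epbd`.
#' @param path File path.
#' @return For the reader, a data frame with an added `length` column.
#' @export
read_benchmark_table <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("id", "sequence", "J_exp") %in% names(df))) {
    stop("benchmark table needs columns id, sequence, J_exp")
  }
  df$length <- nchar(df$sequence)
  df
}

#' Synthetic benchmark panel
#'
#' Generates a reproducible stand-in for an experimental cyclization panel:
#' random sequences in the given length and GC ranges, synthetic opening
#' profiles with AT-tract hotspots (see [synthetic_profile()]), and toy
#' "experimental" J-factors obtained by running the breathing-coupled
#' pipeline itself at `n_chains_truth` chains and perturbing the result by
#' lognormal noise of `noise_sd_log10` decades. Defaults emulate the
#' published study panel: 86 sequences, lengths 50-325 bp. Sequences whose
#' truth run yields no closures get `J_exp = NA` (skipped by the benchmark
#' with a warning).
#'
#' @param n_seqs Number of sequences.
#' @param length_range Length-2 integer range of sequence lengths (bp).
#' @param gc_range Length-2 numeric range of GC content.
#' @param profile_model List with `baseline` (length-2 probability range) and
#'   `hotspot` (upper AT-tract probability).
#' @param table Step table (default [synthetic_step_table()]).
#' @param flex,thresholds Model settings.
#' @param n_chains_truth Chains for the truth run per sequence.
#' @param noise_sd_log10 SD of the lognormal perturbation, in decades.
#' @param seed RNG seed; a fixed seed gives a bit-identical panel.
#' @return A list of class `synthetic_panel` with `sequences`, `profiles`,
#'   `records` (`id`, `length`, `J_true`, `J_exp`).
#' @export
make_synthetic_panel <- function(n_seqs = 86, length_range = c(50, 325),
                                 gc_range = c(0.3, 0.7),
                                 profile_model = list(baseline = c(1e-5, 1e-3),
                                                      hotspot = 1e-2),
                                 table = synthetic_step_table(),
                                 flex = flexibility_model(),
                                 thresholds = closure_thresholds(),
                                 n_chains_truth = 1e5, noise_sd_log10 = 0.3,
                                 seed = 1) {
  set.seed(seed)
  lens <- sample(seq(length_range[1], length_range[2]), n_seqs,
                 replace = TRUE)
  gcs <- runif(n_seqs, gc_range[1], gc_range[2])
  sequences <- lapply(seq_len(n_seqs), function(i)
    random_dna(lens[i], gcs[i], id = sprintf("syn%03d", i)))
  profiles <- lapply(sequences, function(s)
    synthetic_profile(s, baseline = profile_model$baseline,
                      hotspot_p = profile_model$hotspot))
  J_true <- numeric(n_seqs)
  for (i in seq_len(n_seqs)) {
    J_true[i] <- estimate_jfactor(sequences[[i]], table, flex, thresholds,
                                  profile = profiles[[i]],
                                  n_chains = n_chains_truth,
                                  seed = seed + 1000L + i)$J
  }
  noise <- rnorm(n_seqs, 0, noise_sd_log10)
  J_exp <- ifelse(J_true > 0, J_true * 10^noise, NA_real_)
  records <- data.frame(id = vapply(sequences, function(s) s$id,
                                    character(1)),
                        length = lens, J_true = J_true, J_exp = J_exp,
                        stringsAsFactors = FALSE)
  structure(list(sequences = sequences, profiles = profiles,
                 records = records, seed = seed),
            class = "synthetic_panel")
}
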