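# Trinucleotide step-parameter tables: equilibrium tilt/roll/twist (degrees)
# and shift/slide/rise (Angstrom) for every XYZ trinucleotide. The step
# entering base pair n takes its equilibrium geometry from the trinucleotide
# (base[n-1], base[n], base[n+1]); the periodic extension guarantees a defined
# context for the terminal steps.

.STEP_COLS <- c("tilt", "roll", "twist", "shift", "slide", "rise")

#' All 64 trinucleotides in lexicographic order
#' @return Character vector of length 64.
#' @export
all_trinucleotides <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(z = b, y = b, x = b, stringsAsFactors = FALSE)
  sort(paste0(g$x, g$y, g$z))
}

.validate_step_table <- function(df) {
  need <- c("trinuc", .STEP_COLS)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("step table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$trinuc <- toupper(df$trinuc)
  dup <- df$trinuc[duplicated(df$trinuc)]
  if (length(dup) > 0L) {
    stop("duplicate trinucleotide(s) in step table: ",
         paste(unique(dup), collapse = ", "))
  }
  absent <- setdiff(all_trinucleotides(), df$trinuc)
  if (length(absent) > 0L) {
    stop("step table is incomplete; missing trinucleotide(s): ",
         paste(absent, collapse = ", "))
  }
  vals <- as.matrix(df[, .STEP_COLS])
  if (!all(is.finite(vals))) stop("step table contains non-finite values")
  if (any(df$rise <= 0)) stop("step table has non-positive rise entries")
  df <- df[order(df$trinuc), need]
  rownames(df) <- df$trinuc
  class(df) <- c("step_table", "data.frame")
  df
}

#' Load a trinucleotide step-parameter table from TSV
#'
#' The file must be tab-delimited with a header, `#` comment lines allowed,
#' and contain one row per trinucleotide with columns `trinuc`, `tilt`,
#' `roll`, `twist` (degrees) and `shift`, `slide`, `rise` (Angstrom).
#' A `col_map` (named character vector, new = old) can adapt other layouts.
#'
#' @param path Path to the TSV file.
#' @param col_map Optional named character vector mapping the required column
#'   names to the names used in the file, e.g. `c(trinuc = "XYZ")`.
#' @return A `step_table` (data frame with 64 rows keyed by trinucleotide).
#' @export
load_step_table <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("step table file not found: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (new in names(col_map)) {
      old <- col_map[[new]]
      if (!old %in% names(df)) stop("col_map refers to absent column: ", old)
      names(df)[names(df) == old] <- new
    }
  }
  .validate_step_table(df)
}

#' Write a step table to TSV
#' @param table A `step_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_step_table <- function(table, path) {
  stopifnot(inherits(table, "step_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# trinucleotide step-parameter table",
               "# angles in degrees, displacements in Angstrom",
               "# coordinates 1-based; step n context = bases (n-1, n, n+1)"),
             con)
  df <- as.data.frame(table)
  for (cc in .STEP_COLS) df[[cc]] <- sprintf("%.17g", df[[cc]])
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Intrinsically straight step table (fixture)
#'
#' Every trinucleotide gets zero tilt/roll/shift/slide, a fixed twist, and a
#' fixed rise: a straight, uniformly twisted B-DNA-like reference used for
#' persistence-length calibration and tests.
#'
#' @param twist Twist angle in degrees (default 34.3).
#' @param rise Rise in Angstrom (default 3.4).
#' @return A `step_table`.
#' @export
straight_step_table <- function(twist = 34.3, rise = 3.4) {
  df <- data.frame(trinuc = all_trinucleotides(), tilt = 0, roll = 0,
                   twist = twist, shift = 0, slide = 0, rise = rise,
                   stringsAsFactors = FALSE)
  .validate_step_table(df)
}

# Representative B-DNA dinucleotide step means used to assemble the synthetic
# trinucleotide table (twist, roll, tilt in degrees; shift, slide, rise in A).
.DINUC_MEANS <- local({
  m <- rbind(
    AA = c(35.6,  0.5, -1.0,  0.0, -0.2, 3.32),
    AC = c(34.4,  0.7, -0.5,  0.1, -0.6, 3.36),
    AG = c(27.7,  4.5, -0.6,  0.1, -0.3, 3.34),
    AT = c(31.5, -1.0,  0.0,  0.0, -0.7, 3.31),
    CA = c(34.5,  4.7,  0.5, -0.1,  0.4, 3.37),
    CC = c(33.7,  3.6, -0.1,  0.0, -0.1, 3.40),
    CG = c(29.8,  5.4,  0.0,  0.0,  0.6, 3.41),
    CT = c(27.7,  4.5,  0.6, -0.1, -0.3, 3.34),
    GA = c(36.9,  1.9, -0.6,  0.0, -0.1, 3.37),
    GC = c(40.0,  0.3,  0.0,  0.0, -0.1, 3.38),
    GG = c(33.7,  3.6,  0.1,  0.0, -0.1, 3.40),
    GT = c(34.4,  0.7,  0.5, -0.1, -0.6, 3.36),
    TA = c(36.0,  3.3,  0.0,  0.0,  0.1, 3.42),
    TC = c(36.9,  1.9,  0.6,  0.0, -0.1, 3.37),
    TG = c(34.5,  4.7, -0.5,  0.1,  0.4, 3.37),
    TT = c(35.6,  0.5,  1.0,  0.0, -0.2, 3.32))
  colnames(m) <- c("twist", "roll", "tilt", "shift", "slide", "rise")
  m
})

#' Synthetic trinucleotide step table
#'
#' A stand-in for an experimentally derived trinucleotide table, assembled
#' from representative B-DNA dinucleotide step means: the entry for XYZ is the
#' average of the XY and YZ dinucleotide values. It carries realistic
#' sequence-dependent intrinsic curvature (e.g. roll at pyrimidine-purine
#' steps) but is synthetic and is labelled as such; supply a measured table
#' via [load_step_table()] for production work.
#'
#' @return A `step_table`.
#' @export
synthetic_step_table <- function() {
  tri <- all_trinucleotides()
  first <- substr(tri, 1, 2)
  second <- substr(tri, 2, 3)
  vals <- (.DINUC_MEANS[first, ] + .DINUC_MEANS[second, ]) / 2
  df <- data.frame(trinuc = tri,
                   tilt = vals[, "tilt"], roll = vals[, "roll"],
                   twist = vals[, "twist"], shift = vals[, "shift"],
                   slide = vals[, "slide"], rise = vals[, "rise"],
                   stringsAsFactors = FALSE)
  .validate_step_table(df)
}

#' Planar-circle step set (fixture)
#'
#' A matrix of `n` identical steps with constant roll `360/n` degrees and zero
#' tilt/twist/shift/slide: composing all `n` steps traces a closed regular
#' polygon in a plane.
#'
#' @param n Number of steps.
#' @param rise Rise in Angstrom.
#' @return An `n x 6` matrix with columns tilt, roll, twist, shift, slide,
#'   rise (degrees / Angstrom).
#' @export
circle_steps <- function(n, rise = 3.4) {
  stopifnot(n >= 3)
  m <- matrix(0, n, 6, dimnames = list(NULL, .STEP_COLS))
  m[, "roll"] <- 360 / n
  m[, "rise"] <- rise
  m
}

#' Equilibrium step parameters of a sequence
#'
#' Maps an extended sequence (length N+2, see [extend_periodic()]) to the
#' equilibrium step parameters of the N steps entering base pairs
#' `2 .. N+1`, using the trinucleotide context `(n-1, n, n+1)` for step `n`.
#'
#' @param seq_ext A periodically extended [dna_seq()].
#' @param table A `step_table`.
#' @return An `N x 6` numeric matrix (columns tilt, roll, twist, shift, slide,
#'   rise; degrees and Angstrom).
#' @export
seq_steps <- function(seq_ext, table) {
  stopifnot(inherits(seq_ext, "dna_seq"), inherits(table, "step_table"))
  b <- seq_ext$bases
  n_ext <- length(b)
  idx <- 2:(n_ext - 1)
  tri <- paste0(b[idx - 1], b[idx], b[idx + 1])
  j <- match(tri, table$trinuc)
  if (anyNA(j)) stop("trinucleotide lookup failed for: ",
                     paste(unique(tri[is.na(j)]), collapse = ", "))
  m <- as.matrix(as.data.frame(table)[j, .STEP_COLS])
  rownames(m) <- NULL
  m
}
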