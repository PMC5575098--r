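# Sequence containers and readers. Coordinates are 1-based and inclusive
# throughout the package, matching the usual base-pair indexing.

.DNA_ALPHABET <- c("A", "C", "G", "T")

#' Construct a DNA sequence object
#'
#' A light container for a single DNA sequence: an id, the bases as an
#' uppercase character vector over \{A, C, G, T\}, and an optional set of
#' 1-based mismatch positions (base pairs that are permanently open, e.g. a
#' C:C mismatch).
#'
#' @param bases A single string or a character vector of bases.
#' @param id Text label.
#' @param mismatch Integer vector of 1-based mismatch positions (may be empty).
#' @return An object of class `dna_seq` with fields `id`, `bases`, `mismatch`.
#' @export
#' @examples
#' s <- dna_seq("ACGTACGT", id = "demo")
#' length(s)
dna_seq <- function(bases, id = "seq", mismatch = integer()) {
  if (length(bases) == 1L && nchar(bases[1]) > 1L) {
    bases <- strsplit(bases, "", fixed = TRUE)[[1]]
  }
  bases <- toupper(as.character(bases))
  n <- length(bases)
  if (n < 3L) stop("sequence '", id, "' is shorter than 3 bp")
  bad <- which(!(bases %in% .DNA_ALPHABET))
  if (length(bad) > 0L) {
    stop("sequence '", id, "': non-ACGT symbol '", bases[bad[1]],
         "' at position ", bad[1])
  }
  mismatch <- sort(unique(as.integer(mismatch)))
  if (length(mismatch) > 0L && (min(mismatch) < 1L || max(mismatch) > n)) {
    stop("sequence '", id, "': mismatch position outside [1, ", n, "]")
  }
  structure(list(id = id, bases = bases, mismatch = mismatch),
            class = "dna_seq")
}

#' @export
length.dna_seq <- function(x) length(x$bases)

#' @export
print.dna_seq <- function(x, ...) {
  n <- length(x$bases)
  cat("<dna_seq> ", x$id, ": ", n, " bp", sep = "")
  if (length(x$mismatch) > 0L) {
    cat("  [mismatch at ", paste(x$mismatch, collapse = ", "), "]", sep = "")
  }
  cat("\n  ", paste(head(x$bases, 60), collapse = ""),
      if (n > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.character.dna_seq <- function(x, ...) paste(x$bases, collapse = "")

#' Read DNA sequences from FASTA or plain text
#'
#' Plain format is one sequence per line, optionally preceded by an id and a
#' tab; lines starting with `#` and blank lines are ignored. Mismatch
#' annotations can be supplied in a sidecar TSV with columns
#' `id`, `position` (1-based) and `type`.
#'
#' @param path Path to the sequence file.
#' @param format `"auto"` (default, decided by first non-blank character and
#'   extension), `"fasta"` or `"plain"`.
#' @param mismatch_path Optional path to a mismatch sidecar TSV.
#' @return A list of [dna_seq()] objects.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "plain"),
                           mismatch_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("sequence file not found: ", path)
  if (format == "auto") {
    lines <- readLines(path, warn = FALSE)
    first <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")][1]
    format <- if (!is.na(first) && startsWith(trimws(first), ">")) "fasta"
              else "plain"
  }
  seqs <- if (format == "fasta") {
    set <- tryCatch(Biostrings::readDNAStringSet(path),
                    error = function(e) stop("malformed FASTA in ", path,
                                             ": ", conditionMessage(e)))
    lapply(seq_along(set), function(i) {
      dna_seq(as.character(set[[i]]), id = names(set)[i])
    })
  } else {
    lines <- readLines(path, warn = FALSE)
    keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
    out <- vector("list", length(keep))
    for (k in seq_along(keep)) {
      ln <- trimws(lines[keep[k]])
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      out[[k]] <- tryCatch({
        if (length(parts) >= 2L) dna_seq(parts[2], id = parts[1])
        else dna_seq(parts[1], id = paste0("seq", k))
      }, error = function(e) {
        stop("parse error at line ", keep[k], " of ", path, ": ",
             conditionMessage(e))
      })
    }
    out
  }
  if (!is.null(mismatch_path)) {
    mm <- read.delim(mismatch_path, comment.char = "#",
                     stringsAsFactors = FALSE)
    if (!all(c("id", "position") %in% names(mm))) {
      stop("mismatch sidecar must have columns 'id' and 'position'")
    }
    ids <- vapply(seqs, function(s) s$id, character(1))
    for (i in seq_len(nrow(mm))) {
      j <- match(mm$id[i], ids)
      if (is.na(j)) {
        warning("mismatch annotation for unknown sequence id '", mm$id[i], "'")
        next
      }
      seqs[[j]] <- dna_seq(seqs[[j]]$bases, id = seqs[[j]]$id,
                           mismatch = c(seqs[[j]]$mismatch,
                                        as.integer(mm$position[i])))
    }
  }
  seqs
}

#' Generate a random DNA sequence
#'
#' @param n Length in base pairs.
#' @param gc GC content in `[0, 1]`.
#' @param id Sequence label.
#' @return A [dna_seq()] object.
#' @export
random_dna <- function(n, gc = 0.5, id = "random") {
  stopifnot(n >= 3, gc >= 0, gc <= 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  dna_seq(sample(names(p), n, replace = TRUE, prob = p), id = id)
}

#' Periodically extend a sequence (and optionally its opening profile)
#'
#' Appends copies of the first two base pairs to the end of the sequence so
#' that every interior base-pair step has a full trinucleotide context and the
#' chain can be closed head-to-tail. An opening profile, when supplied, is
#' extended in the same way (its first two entries are appended).
#'
#' @param seq A [dna_seq()].
#' @param profile Optional [opening_profile()] of the same length.
#' @return A list with elements `sequence` (length N+2) and `profile`
#'   (length N+2, or `NULL`).
#' @export
#' @examples
#' e <- extend_periodic(dna_seq("ACGT"))
#' as.character(e$sequence)  # "ACGTAC"
extend_periodic <- function(seq, profile = NULL) {
  stopifnot(inherits(seq, "dna_seq"))
  n <- length(seq$bases)
  ext <- dna_seq(c(seq$bases, seq$bases[1:2]), id = seq$id,
                 mismatch = seq$mismatch)
  prof_ext <- NULL
  if (!is.null(profile)) {
    stopifnot(inherits(profile, "opening_profile"))
    if (length(profile$p) != n) {
      stop("profile length (", length(profile$p),
           ") does not match sequence length (", n, ")")
    }
    prof_ext <- opening_profile(c(profile$p, profile$p[1:2]),
                                source = profile$source)
  }
  list(sequence = ext, profile = prof_ext)
}
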