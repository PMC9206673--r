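## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over plain character strings.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Run code with a temporarily-seeded RNG, restoring global state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

## Scoring matrix for +match / -mismatch nucleotide alignment; N never matches.
nuc_matrix <- function(match = 1, mismatch = -2) {
  m <- matrix(mismatch, 5, 5,
              dimnames = list(c(DNA_BASES, "N"), c(DNA_BASES, "N")))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

## Validate a DNA alphabet after normalisation; stops with a labelled error.
check_alphabet <- function(seqs, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- which(!grepl(pat, seqs))
  if (length(bad) > 0) {
    stop(sprintf("%s %d contains characters outside the %s alphabet",
                 what, bad[1], if (allow_n) "A/C/G/T/N" else "A/C/G/T"))
  }
  invisible(TRUE)
}

## Uppercase and convert RNA 'U' to 'T'.
normalize_seq <- function(seqs) {
  chartr("u", "T", chartr("U", "T", toupper(seqs)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Modal value of an integer vector; ties broken toward the smaller value.
modal_value <- function(x) {
  tab <- table(x)
  vals <- as.integer(names(tab))
  vals[order(-as.integer(tab), vals)][1]
}
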