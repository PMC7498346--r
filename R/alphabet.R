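# Sequence alphabet helpers. Sequences are plain character scalars; RNA is
# accepted on input where documented and mapped to DNA (U -> A pairing).

.ALPHABETS <- list(
  DNA  = c("A", "C", "G", "T"),
  RNA  = c("A", "C", "G", "U"),
  auto = c("A", "C", "G", "T", "U")
)

# error on the first character outside the alphabet, naming its position
.check_alphabet <- function(seq, alphabet = "auto") {
  allowed <- .ALPHABETS[[alphabet]]
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% allowed))
  if (length(bad)) {
    stop(sprintf("invalid %s character '%s' at position %d",
                 if (alphabet == "auto") "nucleotide" else alphabet,
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}

# internal uppercase-DNA reverse complement (no validation)
.revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGTU", "TGCAA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Reverse complement
#'
#' Returns the reverse complement of a nucleotide sequence in the DNA
#' alphabet: `U` is complemented to `A` exactly as `T` is, so an RNA target
#' maps directly to the DNA sequence of its hybridization probe. Case is
#' preserved position-by-position (after reversal).
#'
#' @param seq Single nucleotide string (upper or lower case).
#' @param alphabet `"auto"` (default, accepts both `T` and `U`), `"DNA"`, or
#'   `"RNA"`; used for validation only, the output is always DNA.
#' @return The reverse-complemented DNA string, same length as `seq`.
#' @examples
#' reverse_complement("ACGU")  # "ACGT"
#' @export
reverse_complement <- function(seq, alphabet = c("auto", "DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop("seq must be a single non-empty nucleotide string", call. = FALSE)
  }
  .check_alphabet(seq, alphabet)
  comp <- chartr("ACGTUacgtu", "TGCAAtgcaa", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# split an uppercase DNA string into a character vector of bases
.bases <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# complement base vector (uppercase DNA)
.comp_bases <- function(b) chartr("ACGT", "TGCA", b)
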