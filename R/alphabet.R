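# Alphabet: $ < % < A < C < G < T, integer codes 0..5.
# '$' is the sentinel (appended once, lexicographically smallest), '%'
# separates consecutive sequences.  Codes are the working representation;
# strings are only materialised at the API boundary.

ALPHABET <- c("$", "%", "A", "C", "G", "T")
SEP_CODES <- 0:1
DNA_CODES <- 2:5

.code_lut <- local({
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("$")] <- 0L
  lut[utf8ToInt("%")] <- 1L
  lut[utf8ToInt("A")] <- 2L
  lut[utf8ToInt("C")] <- 3L
  lut[utf8ToInt("G")] <- 4L
  lut[utf8ToInt("T")] <- 5L
  lut
})

chars_to_codes <- function(x, what = "text") {
  ints <- utf8ToInt(x)
  bad <- ints > 127L
  codes <- rep(NA_integer_, length(ints))
  codes[!bad] <- .code_lut[ints[!bad]]
  if (anyNA(codes)) {
    pos <- which(is.na(codes))[1L]
    stop(sprintf("invalid character '%s' in %s at position %d (0-based)",
                 substr(x, pos, pos), what, pos - 1L), call. = FALSE)
  }
  codes
}

codes_to_chars <- function(codes) {
  paste(ALPHABET[codes + 1L], collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
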