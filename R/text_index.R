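# Pan-genome text container and the bidirectional FM-index over it.

#' Pan-genome text
#'
#' Concatenates a set of DNA sequences (one per strain/genome) into the
#' search text `T`: sequences are joined by `'%'` separators and a single
#' sentinel `'$'` is appended, so that `T` contains exactly `S - 1`
#' separators and ends in the sentinel.  The alphabet is ordered
#' `$ < % < A < C < G < T` and all coordinates are 0-based, half-open.
#'
#' @param seqs Character vector of sequences over A/C/G/T (one per genome).
#' @param names Optional sequence identifiers; defaults to `seq_0`, `seq_1`, ...
#' @return An object of class `pan_genome_text` with fields `T` (the
#'   concatenated text), `n` (its length), `S` (number of sequences),
#'   `seq_names`, and `seq_starts` (0-based start of each sequence in `T`).
#' @examples
#' txt <- pan_genome_text(c("CTATGTC", "ATATGTTGGTC"))
#' txt$T  # "CTATGTC%ATATGTTGGTC$"
#' @export
pan_genome_text <- function(seqs, names = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names)) names <- paste0("seq_", seq_along(seqs) - 1L)
  stopifnot(length(names) == length(seqs))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L)
      stop("sequence ", i - 1L, " is empty")
    if (grepl("[^ACGT]", seqs[i]))
      stop("sequence ", i - 1L, " contains characters outside A/C/G/T")
  }
  T <- paste0(paste(seqs, collapse = "%"), "$")
  lens <- nchar(seqs)
  starts <- c(0L, cumsum(lens[-length(lens)] + 1L))
  structure(
    list(T = T, n = nchar(T), S = length(seqs),
         seq_names = as.character(names), seq_starts = as.integer(starts),
         seq_lens = as.integer(lens)),
    class = "pan_genome_text")
}

#' Parse an already concatenated pan-genome text
#'
#' Accepts a string of the form `"SEQ1%SEQ2%...%SEQS$"` and recovers the
#' per-sequence structure.
#'
#' @param T Concatenated text ending in `'$'` with `'%'` separators.
#' @param names Optional sequence identifiers.
#' @return A `pan_genome_text` object.
#' @export
as_pan_genome_text <- function(T, names = NULL) {
  if (substr(T, nchar(T), nchar(T)) != "$")
    stop("text must end with the sentinel '$'")
  body <- substr(T, 1L, nchar(T) - 1L)
  if (grepl("\\$", body)) stop("'$' may only appear as the final sentinel")
  seqs <- strsplit(body, "%", fixed = TRUE)[[1L]]
  pan_genome_text(seqs, names)
}

#' @export
print.pan_genome_text <- function(x, ...) {
  cat(sprintf("pan_genome_text: %d sequence(s), n = %d\n", x$S, x$n))
  invisible(x)
}

seq_index_of <- function(text, global_pos) {
  findInterval(global_pos, text$seq_starts) - 1L
}

# ---------------------------------------------------------------------------

#' Build the bidirectional FM-index of a pan-genome text
#'
#' Indexes both `T` and its full reversal `T^r` (sentinel included), storing
#' for each the Burrows-Wheeler transform with full cumulative
#' character-count (rank) tables and a sparse suffix array sampled at text
#' positions that are multiples of `s_SA`.  Backward and forward extension of
#' a bidirectional range are O(1); recovering a suffix-array value takes at
#' most `s_SA - 1` LF steps.
#'
#' @param text A [pan_genome_text] object.
#' @param s_SA Suffix-array sparseness factor (default 16, `1` stores all
#'   entries).  One factor is used for both the forward and reverse side.
#' @return An object of class `bd_fm_index`.
#' @examples
#' idx <- build_index(pan_genome_text(c("CTATGTC", "ATATGTTGGTC")), s_SA = 1)
#' match_exact(idx, "ATG")  # SA[3,5[, SA^r[9,11[
#' @export
build_index <- function(text, s_SA = 16L) {
  stopifnot(inherits(text, "pan_genome_text"))
  s_SA <- as.integer(s_SA)
  stopifnot(length(s_SA) == 1L, s_SA >= 1L)
  codes <- chars_to_codes(text$T)
  n <- length(codes)

  side <- function(cd) {
    sa <- sa_build_cpp(cd)
    bwt <- cd[((sa - 1L) %% n) + 1L]
    occ <- matrix(0L, nrow = n + 1L, ncol = 6L)
    for (c in 0:5) occ[, c + 1L] <- c(0L, cumsum(bwt == c))
    mark <- (sa %% s_SA) == 0L
    list(bwt = bwt, occ = occ, sa_mark = mark,
         sa_samp = sa[mark], mark_rank = cumsum(mark))
  }
  fwd <- side(codes)
  rev_ <- side(rev(codes))

  tab <- tabulate(codes + 1L, nbins = 6L)
  C <- c(0L, cumsum(tab))  # length 7; C[c+1] = # chars with code < c

  # per-character row lists over the forward BWT (psi support)
  pos_list <- lapply(0:5, function(c) which(fwd$bwt == c) - 1L)

  structure(
    list(text = text, n = n, s_SA = s_SA, C = C,
         bwt = fwd$bwt, occ = fwd$occ,
         sa_mark = fwd$sa_mark, sa_samp = fwd$sa_samp,
         sa_mark_rank = fwd$mark_rank,
         bwt_r = rev_$bwt, occ_r = rev_$occ,
         sa_r_mark = rev_$sa_mark, sa_r_samp = rev_$sa_samp,
         sa_r_mark_rank = rev_$mark_rank,
         pos_list = pos_list),
    class = "bd_fm_index")
}

#' @export
print.bd_fm_index <- function(x, ...) {
  cat(sprintf("bd_fm_index: n = %d, S = %d, s_SA = %d\n",
              x$n, x$text$S, x$s_SA))
  invisible(x)
}

#' LF mapping
#'
#' Maps suffix-array row `i` to the row `j` with `SA[j] = SA[i] - 1 (mod n)`,
#' i.e. one text position to the left (cyclically through the sentinel).
#'
#' @param index A [build_index] result.
#' @param i 0-based SA row (vectorised).
#' @param reverse Operate on the reverse side (`SA^r`/`BWT^r`).
#' @return 0-based SA row(s).
#' @export
lf <- function(index, i, reverse = FALSE) {
  if (any(i < 0L | i >= index$n)) stop("SA row out of [0, n[")
  bwt <- if (reverse) index$bwt_r else index$bwt
  occ <- if (reverse) index$occ_r else index$occ
  c <- bwt[i + 1L]
  index$C[c + 1L] + occ[cbind(i + 1L, c + 1L)]
}

# inverse of LF on the forward side: row of SA[i] + 1
psi_step <- function(index, i) {
  c <- findInterval(i, index$C[2:7])  # code with C[c] <= i < C[c+1]
  index$pos_list[[c + 1L]][i - index$C[c + 1L] + 1L]
}

# Recover SA[i] through the sparse sample (<= s_SA - 1 LF steps).
sa_value <- function(index, i, reverse = FALSE) {
  mark <- if (reverse) index$sa_r_mark else index$sa_mark
  samp <- if (reverse) index$sa_r_samp else index$sa_samp
  mrank <- if (reverse) index$sa_r_mark_rank else index$sa_mark_rank
  vapply(i, function(row) {
    steps <- 0L
    while (!mark[row + 1L]) {
      row <- lf(index, row, reverse = reverse)
      steps <- steps + 1L
    }
    (samp[mrank[row + 1L]] + steps) %% index$n
  }, integer(1))
}

# ---------------------------------------------------------------------------

#' Bidirectional range
#'
#' A synchronized pair of half-open intervals: `[b, e[` over the suffix array
#' of `T` (suffixes prefixed by the current pattern `P`) and `[b_r, e_r[`
#' over the suffix array of `T^r` (suffixes prefixed by `P` reversed).  The
#' two intervals always have equal width.
#'
#' @param b,e,b_r,e_r 0-based interval bounds.
#' @return An object of class `bd_range`.
#' @export
bd_range <- function(b, e, b_r, e_r) {
  stopifnot(e - b == e_r - b_r)
  structure(list(b = as.integer(b), e = as.integer(e),
                 b_r = as.integer(b_r), e_r = as.integer(e_r)),
            class = "bd_range")
}

#' @export
print.bd_range <- function(x, ...) {
  cat(sprintf("bd_range: SA[%d,%d[  SA^r[%d,%d[  (width %d)\n",
              x$b, x$e, x$b_r, x$e_r, x$e - x$b))
  invisible(x)
}

#' Width of a bidirectional range
#' @param r A [bd_range].
#' @return Number of occurrences represented.
#' @export
range_width <- function(r) r$e - r$b

full_range <- function(index) bd_range(0L, index$n, 0L, index$n)

#' Extend a partial match to the left (pattern `cP`)
#'
#' @param index A [build_index] result.
#' @param r Current [bd_range] for pattern `P`.
#' @param c Single character in the alphabet.
#' @return The [bd_range] of `cP` (possibly empty).
#' @export
extend_backward <- function(index, r, c) {
  code <- chars_to_codes(c, "extension character")
  stopifnot(length(code) == 1L)
  occ <- index$occ
  b2 <- index$C[code + 1L] + occ[r$b + 1L, code + 1L]
  e2 <- index$C[code + 1L] + occ[r$e + 1L, code + 1L]
  smaller <- if (code > 0L)
    sum(occ[r$e + 1L, seq_len(code)] - occ[r$b + 1L, seq_len(code)])
  else 0L
  b_r2 <- r$b_r + smaller
  bd_range(b2, e2, b_r2, b_r2 + (e2 - b2))
}

#' Extend a partial match to the right (pattern `Pc`)
#'
#' @inheritParams extend_backward
#' @return The [bd_range] of `Pc` (possibly empty).
#' @export
extend_forward <- function(index, r, c) {
  code <- chars_to_codes(c, "extension character")
  stopifnot(length(code) == 1L)
  occ_r <- index$occ_r
  b_r2 <- index$C[code + 1L] + occ_r[r$b_r + 1L, code + 1L]
  e_r2 <- index$C[code + 1L] + occ_r[r$e_r + 1L, code + 1L]
  smaller <- if (code > 0L)
    sum(occ_r[r$e_r + 1L, seq_len(code)] - occ_r[r$b_r + 1L, seq_len(code)])
  else 0L
  b2 <- r$b + smaller
  bd_range(b2, b2 + (e_r2 - b_r2), b_r2, e_r2)
}

#' Exact pattern matching
#'
#' Matches `P` character by character (backward search with synchronized
#' reverse bounds) and returns the bidirectional range of all its exact
#' occurrences in `T`.  The empty pattern yields the full range.
#'
#' @param index A [build_index] result.
#' @param P Pattern over the alphabet.
#' @return A [bd_range]; empty (`b == e`) iff `P` does not occur.
#' @export
match_exact <- function(index, P) {
  r <- full_range(index)
  if (nchar(P) == 0L) return(r)
  codes <- chars_to_codes(P, "pattern")
  for (pos in rev(seq_along(codes))) {
    r <- extend_backward(index, r, ALPHABET[codes[pos] + 1L])
    if (r$e <= r$b) return(r)
  }
  r
}

#' Locate a range in the underlying sequences
#'
#' Resolves every suffix-array row of a range to a text position via the
#' sparse suffix array and attributes it to its pan-genome sequence.
#'
#' @param index A [build_index] result.
#' @param r A [bd_range].
#' @param length Length of the located occurrence (carried through).
#' @return A data.frame with one row per SA row in `[b, e[`: `seq_index`
#'   (0-based sequence number), `local_pos` (0-based position within that
#'   sequence), `global_pos` (position in `T`), and `length`.
#' @export
locate <- function(index, r, length = NA_integer_) {
  if (r$e <= r$b) {
    return(data.frame(seq_index = integer(0), local_pos = integer(0),
                      global_pos = integer(0), length = integer(0)))
  }
  rows <- seq.int(r$b, r$e - 1L)
  g <- sa_value(index, rows)
  s <- seq_index_of(index$text, g)
  data.frame(seq_index = s,
             local_pos = g - index$text$seq_starts[s + 1L],
             global_pos = g,
             length = rep(as.integer(length), length(g)))
}
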