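# Search schemes for lossless approximate pattern matching under edit
# distance.  A search (pi, L, U) processes the p parts of the pattern in pi
# order (pi must extend the processed span contiguously); L and U bound the
# cumulative number of errors after each processed part.  A scheme is a set
# of searches that together cover every distribution of at most K errors
# over the parts.

new_search <- function(pi, L, U) {
  pi <- as.integer(pi); L <- as.integer(L); U <- as.integer(U)
  p <- length(pi)
  stopifnot(length(L) == p, length(U) == p)
  if (!setequal(pi, seq_len(p) - 1L))
    stop("pi must be a permutation of 0..p-1")
  lo <- hi <- pi[1L]
  for (i in seq_len(p)[-1L]) {
    if (pi[i] == hi + 1L) hi <- pi[i]
    else if (pi[i] == lo - 1L) lo <- pi[i]
    else stop("pi violates the connectivity property: ",
              paste(pi, collapse = ""))
  }
  if (any(diff(L) < 0L) || any(diff(U) < 0L))
    stop("L and U must be non-decreasing")
  if (any(L > U)) stop("L must not exceed U")
  list(pi = pi, L = L, U = U)
}

new_scheme <- function(searches, K) {
  p <- length(searches[[1L]]$pi)
  for (s in searches) stopifnot(length(s$pi) == p)
  structure(list(K = as.integer(K), p = p, searches = searches),
            class = "search_scheme")
}

#' @export
print.search_scheme <- function(x, ...) {
  cat(sprintf("search_scheme: K = %d, p = %d, %d search(es)\n",
              x$K, x$p, length(x$searches)))
  for (s in x$searches)
    cat(sprintf("  (%s, %s, %s)\n", paste(s$pi, collapse = ""),
                paste(s$L, collapse = ""), paste(s$U, collapse = "")))
  invisible(x)
}

#' Pigeonhole search scheme
#'
#' Partitions the pattern into `K + 1` parts; if at most `K` errors occur,
#' at least one part matches exactly.  Search `i` matches part `i` first
#' (error-free), then extends over the remaining parts — leftward ones
#' first, then rightward — allowing up to `K` errors.
#'
#' @param K Maximum edit distance, 0..4.
#' @return A `search_scheme` object with `K + 1` searches.
#' @examples
#' pigeonhole_scheme(2)  # (012,000,022), (102,000,022), (210,000,022)
#' @export
pigeonhole_scheme <- function(K) {
  K <- as.integer(K)
  if (K < 0L || K > 4L) stop("K must be between 0 and 4")
  p <- K + 1L
  searches <- lapply(seq_len(p) - 1L, function(i) {
    pi <- c(i, rev(seq_len(i) - 1L), if (i < p - 1L) (i + 1L):(p - 1L))
    U <- c(0L, rep(K, p - 1L))
    new_search(pi, rep(0L, p), U)
  })
  new_scheme(searches, K)
}

#' Kucherov two-error search scheme
#'
#' The three-search scheme for `K = 2` with tighter cumulative bounds than
#' the pigeonhole construction: `S0 = (012, 012, 022)`,
#' `S1 = (210, 000, 012)`, `S2 = (102, 001, 012)`.
#'
#' @return A `search_scheme` object.
#' @export
kucherov_k2_scheme <- function() {
  new_scheme(list(
    new_search(c(0L, 1L, 2L), c(0L, 1L, 2L), c(0L, 2L, 2L)),
    new_search(c(2L, 1L, 0L), c(0L, 0L, 0L), c(0L, 1L, 2L)),
    new_search(c(1L, 0L, 2L), c(0L, 0L, 1L), c(0L, 1L, 2L))),
    K = 2L)
}

#' Load a search scheme from a file
#'
#' Plain-text format: a header line `p K`, then one search per line as three
#' whitespace-separated digit strings `pi L U` (e.g. `012 000 022`).  The
#' scheme is validated structurally (connectivity, monotone bounds) and for
#' coverage of every error distribution.
#'
#' @param path File path.
#' @return A validated `search_scheme` object.
#' @export
load_scheme <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) stop("scheme file needs a header and >= 1 search")
  hd <- as.integer(strsplit(lines[1L], "\\s+")[[1L]])
  if (length(hd) != 2L || anyNA(hd)) stop("malformed header line (want 'p K')")
  p <- hd[1L]; K <- hd[2L]
  digits <- function(x) as.integer(strsplit(x, "")[[1L]])
  searches <- lapply(lines[-1L], function(ln) {
    f <- strsplit(ln, "\\s+")[[1L]]
    if (length(f) != 3L || any(nchar(f) != p))
      stop("malformed search line: ", ln)
    new_search(digits(f[1L]), digits(f[2L]), digits(f[3L]))
  })
  sch <- new_scheme(searches, K)
  v <- validate_scheme(sch, K)
  if (!v$valid)
    stop("scheme does not cover all error distributions; first uncovered: [",
         paste(v$uncovered[1L, ], collapse = ","), "]")
  sch
}

# all vectors of p non-negative integers with sum <= K
error_distributions <- function(p, K) {
  grid <- as.matrix(expand.grid(rep(list(0:K), p)))
  grid <- grid[rowSums(grid) <= K, , drop = FALSE]
  dimnames(grid) <- NULL
  grid[order(rowSums(grid), apply(grid, 1, paste, collapse = "")), ,
       drop = FALSE]
}

search_covers <- function(search, dist) {
  cum <- cumsum(dist[search$pi + 1L])
  all(cum >= search$L & cum <= search$U)
}

#' Validate the coverage of a search scheme
#'
#' Enumerates every distribution of at most `K` errors over the `p` parts
#' and checks that each is covered by at least one search (its cumulative
#' sums in `pi` order lie within `[L, U]` after every part).
#'
#' @param scheme A `search_scheme`.
#' @param K Maximum number of errors to cover (default `scheme$K`).
#' @return List with `valid` (logical) and `uncovered` (matrix of uncovered
#'   distributions, zero rows when valid).
#' @export
validate_scheme <- function(scheme, K = scheme$K) {
  dists <- error_distributions(scheme$p, K)
  cov <- apply(dists, 1L, function(d)
    any(vapply(scheme$searches, search_covers, logical(1), dist = d)))
  list(valid = all(cov), uncovered = dists[!cov, , drop = FALSE])
}

#' Error distributions covered by one search
#'
#' @param search One element of `scheme$searches`.
#' @param p Number of parts.
#' @param K Maximum number of errors.
#' @param exact_sum Only distributions with exactly `K` errors.
#' @return Matrix of covered distributions (one per row).
#' @export
covered_distributions <- function(search, p, K, exact_sum = TRUE) {
  dists <- error_distributions(p, K)
  if (exact_sum) dists <- dists[rowSums(dists) == K, , drop = FALSE]
  keep <- apply(dists, 1L, search_covers, search = search)
  dists[keep, , drop = FALSE]
}

#' Partition a pattern into contiguous parts
#'
#' Uniform lengths; when `|P|` is not divisible by `p` the remainder is
#' given to the leftmost parts.
#'
#' @param P Pattern string.
#' @param p Number of parts (`|P| >= p`).
#' @return Character vector of `p` parts whose concatenation is `P`.
#' @export
partition_pattern <- function(P, p) {
  m <- nchar(P)
  if (m < p) stop("pattern of length ", m, " cannot be cut into ", p, " parts")
  lens <- rep(m %/% p, p) + (seq_len(p) <= m %% p)
  ends <- cumsum(lens)
  substring(P, c(1L, ends[-p] + 1L), ends)
}

part_boundaries <- function(m, p) {
  lens <- rep(m %/% p, p) + (seq_len(p) <= m %% p)
  c(0L, cumsum(lens))
}

#' Lossless approximate pattern matching
#'
#' Finds every occurrence `O` of pattern `P` in the text with edit distance
#' `ED(O, P) <= K` (substitutions and indels), by executing a search scheme
#' over the bidirectional FM-index.  Occurrences are exact substrings of the
#' text over A/C/G/T; each is reported once with its minimal edit distance,
#' as a bidirectional range plus length.
#'
#' @param index A [build_index] result.
#' @param P Pattern over A/C/G/T.
#' @param K Maximum edit distance, 0..4.
#' @param scheme A `search_scheme` valid for `K` (default: pigeonhole).
#' @return A data.frame of class `fm_occurrences` with 0-based columns `b`,
#'   `e`, `b_r`, `e_r` (the bidirectional range), `length` and `ed`, sorted
#'   by `(b, length)`.
#' @examples
#' # approximate_match(idx, "ATGTC", K = 1) finds the exact hit at global
#' # position 2 and the 1-error hit at position 10 of the worked example.
#' @export
approximate_match <- function(index, P, K, scheme = NULL) {
  K <- as.integer(K)
  if (K < 0L || K > 4L)
    stop("unsupported edit distance: K must be between 0 and 4")
  if (grepl("[^ACGT]", P)) stop("pattern must be over A/C/G/T")
  if (is.null(scheme)) scheme <- pigeonhole_scheme(K)
  stopifnot(inherits(scheme, "search_scheme"))
  if (max(vapply(scheme$searches, function(s) max(s$U), integer(1))) > K ||
      scheme$K != K)
    stop("scheme is not valid for K = ", K)
  m <- nchar(P)
  if (m < scheme$p)
    stop("pattern shorter than the number of parts (", scheme$p, ")")
  bounds <- part_boundaries(m, scheme$p)
  res <- scheme_match_cpp(index$C, index$occ, index$occ_r,
                          chars_to_codes(P, "pattern"), K,
                          lapply(scheme$searches, function(s)
                            list(pi = s$pi, L = s$L, U = s$U)),
                          bounds)
  out <- data.frame(b = res[, "b"], e = res[, "e"],
                    b_r = res[, "br"], e_r = res[, "er"],
                    length = res[, "len"], ed = res[, "ed"])
  out <- out[order(out$b, out$length), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fm_occurrences", "data.frame")
  out
}

#' Brute-force reference scan for approximate occurrences
#'
#' Independent banded dynamic-programming scan that enumerates every
#' substring `T[s, s+len[` over A/C/G/T with `ED <= K` to the pattern,
#' without using the FM-index.  Used as the reference in the package's
#' validation suite; exported because it is also a convenient ground truth
#' for small inputs.
#'
#' @param text A [pan_genome_text] object.
#' @param P Pattern over A/C/G/T.
#' @param K Maximum edit distance.
#' @return data.frame with 0-based columns `start` (global), `length`, `ed`.
#' @export
brute_force_occurrences <- function(text, P, K) {
  res <- brute_occurrences_cpp(chars_to_codes(text$T),
                               chars_to_codes(P, "pattern"), as.integer(K))
  out <- data.frame(start = res[, "start"], length = res[, "len"],
                    ed = res[, "ed"])
  out[order(out$start, out$length), , drop = FALSE]
}
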