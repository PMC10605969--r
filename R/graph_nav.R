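# Elementary graph operations: node identification from extreme or arbitrary
# k-mers, neighbor jumps by character, predecessor jumps through a specific
# edge.  All O(1) (find_id: O(s_cp)) given constant-time rank on B / B_r.

rank_B <- function(graph, i) graph$B_rank0[i + 1L]       # ones before row i
rank_B_r <- function(graph, i) graph$B_r_rank0[i + 1L]

#' Node identifier from a rightmost k-mer interval
#'
#' Given any SA row whose suffix is prefixed by the *rightmost* k-mer of a
#' node, returns that node's identifier via a rank on bit vector `B` and a
#' lookup in `IDmap`.
#'
#' @param graph A [build_graph] result.
#' @param b 0-based SA row (any row of the k-mer's interval).
#' @return 0-based node identifier.
#' @examples
#' # k-mer "GTC" of the worked example has SA interval [9,11[:
#' # find_id_right(g, 9) == 0
#' @export
find_id_right <- function(graph, b) {
  if (b < 0L || b >= graph$n) stop("SA row out of [0, n[")
  graph$idmap$id[rank_B(graph, b) + 1L]
}

#' Node identifier from a reversed leftmost k-mer interval
#'
#' Mirror of [find_id_right] on the reverse side: any reverse-SA row whose
#' suffix (of `T^r`) is prefixed by the reverse of a node's *leftmost* k-mer
#' resolves through `B_r` and `IDmap_r`.
#'
#' @param graph A [build_graph] result.
#' @param b_r 0-based reverse-SA row.
#' @return 0-based node identifier.
#' @export
find_id_left <- function(graph, b_r) {
  if (b_r < 0L || b_r >= graph$n) stop("reverse SA row out of [0, n[")
  graph$idmap_r[rank_B_r(graph, b_r) + 1L]
}

#' Node position of an arbitrary k-mer
#'
#' Resolves any k-mer of the text to its unique `(node id, offset)` position.
#' For finite `s_cp` the k-length window is walked leftward by LF steps from
#' the lexicographically largest suffix of the k-mer's interval until a
#' marked row is met (at most `s_cp - 1` steps; checkpoint k-mers guarantee
#' termination inside the node).  Without checkpoints (`s_cp = Inf`) the
#' window is walked rightward (inverse LF) toward the node's rightmost
#' k-mer, which is always marked.  A k-mer ending in a separation character
#' is the offset-0 k-mer of an end node and is resolved directly; a k-mer
#' with an interior separator has no graph position and raises an error.
#'
#' @param graph A [build_graph] result.
#' @param index The underlying [build_index] result.
#' @param b Either a 0-based SA row of the k-mer's interval or a [bd_range].
#' @return List with `id` (0-based node identifier) and `offset` (0-based
#'   offset of the k-mer within the node's substring).
#' @export
find_id <- function(graph, index, b) {
  k <- graph$k
  n <- graph$n
  if (inherits(b, "bd_range")) {
    if (b$e <= b$b) stop("empty range has no graph position")
    row <- b$b
    i <- b$e - 1L
  } else {
    row <- as.integer(b)
    i <- NA_integer_
  }
  pos <- sa_value(index, row)
  if (pos + k > n) stop("suffix at row ", row, " is shorter than k")
  wcodes <- chars_to_codes(substr(index$text$T, pos + 1L, pos + k))
  if (any(wcodes[seq_len(k - 1L)] <= 1L))
    stop("k-mer has an interior separation character: no graph position")
  if (wcodes[k] <= 1L) {
    # separator at last position: offset-0 k-mer of an end node
    return(list(id = end_node_of_sep(graph, pos + k - 1L), offset = 0L))
  }
  if (is.na(i)) {
    r <- match_exact(index, codes_to_chars(wcodes))
    i <- r$e - 1L
  }
  steps <- 0L
  if (is.finite(graph$s_cp)) {
    while (graph$B[i + 1L] == 0L) {
      i <- lf(index, i)
      steps <- steps + 1L
      if (steps > graph$s_cp) stop("checkpoint walk failed to terminate")
    }
    entry <- rank_B(graph, i) + 1L
    list(id = graph$idmap$id[entry],
         offset = graph$idmap$offset[entry] + steps)
  } else {
    while (graph$B[i + 1L] == 0L) {
      i <- psi_step(index, i)
      steps <- steps + 1L
      if (steps > n) stop("rightmost-k-mer walk failed to terminate")
    }
    entry <- rank_B(graph, i) + 1L
    list(id = graph$idmap$id[entry],
         offset = graph$idmap$offset[entry] - steps)
  }
}

node_kmer_range <- function(graph, id) {
  nd <- graph$nodes[id + 1L, ]
  list(b = nd$left_kmer, e = nd$left_kmer + nd$mult)
}

#' Predecessor node reached by prepending a character
#'
#' Computes the identifier of the predecessor encountered by prepending `c`
#' to the node's substring, i.e. following the `(k+1)`-mer
#' `c + leftmost-k-mer` if it occurs in the text.  Separation characters are
#' allowed, which makes the cyclic edges of end nodes discoverable.
#'
#' @param graph A [build_graph] result.
#' @param index The underlying [build_index] result.
#' @param id 0-based node identifier.
#' @param c Single character of the alphabet.
#' @return 0-based predecessor identifier, or `NA` if no such edge exists.
#' @export
get_pred_id_with_char <- function(graph, index, id, c) {
  stopifnot(id >= 0L, id < graph$n_nodes)
  code <- chars_to_codes(c, "character")
  kr <- node_kmer_range(graph, id)
  b2 <- index$C[code + 1L] + index$occ[kr$b + 1L, code + 1L]
  e2 <- index$C[code + 1L] + index$occ[kr$e + 1L, code + 1L]
  if (e2 <= b2) return(NA_integer_)
  find_id_right(graph, b2)
}

#' Successor node reached by appending a character
#'
#' Mirror of [get_pred_id_with_char] during forward matching: appends `c` to
#' the node's rightmost k-mer on the reverse side and resolves the new node
#' through [find_id_left].
#'
#' @inheritParams get_pred_id_with_char
#' @return 0-based successor identifier, or `NA` if no such edge exists.
#' @export
get_succ_id_with_char <- function(graph, index, id, c) {
  stopifnot(id >= 0L, id < graph$n_nodes)
  code <- chars_to_codes(c, "character")
  nd <- graph$nodes[id + 1L, ]
  br <- nd$right_kmer_r
  er <- br + nd$mult
  b2 <- index$C[code + 1L] + index$occ_r[br + 1L, code + 1L]
  e2 <- index$C[code + 1L] + index$occ_r[er + 1L, code + 1L]
  if (e2 <= b2) return(NA_integer_)
  find_id_left(graph, b2)
}

#' Jump to a predecessor through a specific edge
#'
#' A node with multiplicity `mult` has `mult` incoming edges, one per
#' occurrence of its substring; `edge_offset` selects the occurrence
#' (relative row in `SA[left_kmer, left_kmer + mult[`).  One LF step moves
#' to the suffix prefixed by the predecessor's rightmost k-mer, whose
#' identifier follows from [find_id_right].  The returned `edge_offset` is
#' the relative row within the predecessor's rightmost-k-mer interval, which
#' identifies the incoming edge of the predecessor that was traversed.
#'
#' @param graph A [build_graph] result.
#' @param index The underlying [build_index] result.
#' @param id 0-based node identifier.
#' @param edge_offset Occurrence selector in `[0, mult[`.
#' @return List with `id` (predecessor identifier) and `edge_offset`
#'   (relative row in the predecessor's rightmost-k-mer interval).
#' @export
jump_pred_via_edge <- function(graph, index, id, edge_offset) {
  stopifnot(id >= 0L, id < graph$n_nodes)
  nd <- graph$nodes[id + 1L, ]
  if (edge_offset < 0L || edge_offset >= nd$mult)
    stop("edge_offset out of [0, mult[")
  i <- nd$left_kmer + as.integer(edge_offset)
  j <- lf(index, i)
  pid <- find_id_right(graph, j)
  # left bound of the predecessor's rightmost-k-mer interval: its marked row
  # is the interval's last row (no other marked row can sit inside it)
  bitrow <- graph$B_sel[rank_B(graph, j) + 1L]
  pmult <- graph$nodes$mult[pid + 1L]
  lb <- bitrow + 1L - pmult
  list(id = pid, edge_offset = j - lb)
}

#' All predecessor / successor identifiers of a node
#'
#' Convenience wrapper looping [get_pred_id_with_char] /
#' [get_succ_id_with_char] over the alphabet.
#'
#' @param graph A [build_graph] result.
#' @param index The underlying [build_index] result.
#' @param id 0-based node identifier.
#' @param dna_only Restrict the alphabet loop to A/C/G/T, hiding the cyclic
#'   edges through separation characters (default `FALSE`).
#' @return List with integer vectors `pred` and `succ` (deduplicated,
#'   ascending).
#' @export
node_neighbors <- function(graph, index, id, dna_only = FALSE) {
  chars <- if (dna_only) ALPHABET[3:6] else ALPHABET
  pr <- su <- integer(0)
  for (ch in chars) {
    p <- get_pred_id_with_char(graph, index, id, ch)
    if (!is.na(p)) pr <- c(pr, p)
    s <- get_succ_id_with_char(graph, index, id, ch)
    if (!is.na(s)) su <- c(su, s)
  }
  list(pred = sort(unique(pr)), succ = sort(unique(su)))
}
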