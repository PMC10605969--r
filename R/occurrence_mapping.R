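# Mapping FM occurrences to graph node paths (including the short-occurrence
# case) and to per-sequence text coordinates, plus redundancy filtering.

fm_occ <- function(b, e, b_r, e_r, length, ed = 0L) {
  list(b = as.integer(b), e = as.integer(e), b_r = as.integer(b_r),
       e_r = as.integer(e_r), length = as.integer(length),
       ed = as.integer(ed))
}

as_fm_occ <- function(occ) {
  if (inherits(occ, "bd_range"))
    stop("pass an occurrence (range plus length), not a bare range")
  if (is.data.frame(occ)) {
    stopifnot(nrow(occ) == 1L)
    occ <- as.list(occ)
  }
  if (is.null(occ$ed)) occ$ed <- 0L
  if (is.null(occ$b_r)) occ$b_r <- 0L
  if (is.null(occ$e_r)) occ$e_r <- occ$b_r + (occ$e - occ$b)
  fm_occ(occ$b, occ$e, occ$b_r, occ$e_r, occ$length, occ$ed)
}

occ_string <- function(index, occ) {
  start <- sa_value(index, occ$b)
  substr(index$text$T, start + 1L, start + occ$length)
}

#' Graph node path of an occurrence
#'
#' An occurrence `O` with `|O| >= k` aligns with a unique walk in the graph.
#' The first node is identified from a single k-mer of `O` ([find_id]); by
#' default the leftmost one, but any internal k-mer may seed the walk
#' (`seed_offset`), in which case the walk is first extended leftward
#' through character jumps.  Subsequent nodes are found by jumping directly
#' to each node's end and following one successor jump per boundary
#' character; `O` is never re-matched character by character.
#'
#' @param graph A [build_graph] result.
#' @param index The underlying [build_index] result.
#' @param occ An FM occurrence: one row of an [approximate_match] result (or
#'   a list with `b`, `e`, `length`, optionally `ed`).
#' @param seed_offset 0-based offset within `O` of the k-mer that seeds the
#'   walk (default 0, the leftmost k-mer).
#' @return An object of class `graph_occurrence`: `node_path` (integer
#'   vector of 0-based ids), `start_offset` (offset of `O`'s first character
#'   in the first node), `length`, `edit_distance`.
#' @export
find_node_path <- function(graph, index, occ, seed_offset = 0L) {
  occ <- as_fm_occ(occ)
  k <- graph$k
  if (occ$length < k)
    stop("occurrence shorter than k: use resolve_short_occurrence()")
  O <- occ_string(index, occ)
  stopifnot(seed_offset >= 0L, seed_offset <= occ$length - k)
  seed <- substr(O, seed_offset + 1L, seed_offset + k)
  hit <- find_id(graph, index, match_exact(index, seed))
  cur <- hit$id
  off <- hit$offset
  # walk leftward to the node holding O's first character
  rem <- seed_offset
  while (rem > 0L) {
    if (off > 0L) {
      off <- off - 1L
      rem <- rem - 1L
    } else {
      c <- substr(O, rem, rem)
      cur <- get_pred_id_with_char(graph, index, cur, c)
      if (is.na(cur)) stop("internal: leftward walk left the text")
      off <- graph$nodes$len[cur + 1L] - k
      rem <- rem - 1L
    }
  }
  start_offset <- off
  # forward walk: skip to each node end, one successor jump per boundary
  path <- cur
  consumed <- k                  # characters of O covered so far
  covered <- off + k             # prefix of current node aligned with O
  while (consumed < occ$length) {
    nlen <- graph$nodes$len[cur + 1L]
    skip <- min(nlen - covered, occ$length - consumed)
    consumed <- consumed + skip
    covered <- covered + skip
    if (consumed == occ$length) break
    c <- substr(O, consumed + 1L, consumed + 1L)
    cur <- get_succ_id_with_char(graph, index, cur, c)
    if (is.na(cur)) stop("internal: forward walk left the text")
    path <- c(path, cur)
    consumed <- consumed + 1L
    covered <- k                 # new node: first k chars are aligned
  }
  structure(list(node_path = path, start_offset = start_offset,
                 length = occ$length, edit_distance = occ$ed),
            class = "graph_occurrence")
}

#' @export
print.graph_occurrence <- function(x, ...) {
  cat(sprintf("graph_occurrence: path [%s], start_offset %d, len %d, ED %d\n",
              paste(x$node_path, collapse = ","), x$start_offset, x$length,
              x$edit_distance))
  invisible(x)
}

#' Graph positions of a short occurrence
#'
#' An occurrence with `|O| < k` can sit at several places in the graph.  All
#' k-length extensions of `O` that exist in the text are enumerated through
#' the bidirectional index; each extension window resolves to a node
#' position, and the implied start positions of `O` itself are deduplicated.
#'
#' @param graph A [build_graph] result.
#' @param index The underlying [build_index] result.
#' @param occ An FM occurrence with `length < k` (list or one-row
#'   data.frame with `b`, `e`, `b_r`, `e_r`, `length`).
#' @return data.frame with 0-based columns `id` (node) and `offset` (start
#'   of `O` within the node), sorted, deduplicated.
#' @export
resolve_short_occurrence <- function(graph, index, occ) {
  occ <- as_fm_occ(occ)
  k <- graph$k
  l <- occ$length
  if (l >= k) stop("occurrence of length >= k: use find_node_path()")
  if (k - l > 12L) stop("extension enumeration too large (k - |O| > 12)")
  r0 <- bd_range(occ$b, occ$e, occ$b_r, occ$e_r)
  ids <- offs <- integer(0)
  # extend left by a characters, then right by k - l - a, over the full
  # alphabet (separators may legally occupy the window's last position)
  grow_right <- function(r, need, a) {
    if (need == 0L) {
      last <- sa_value(index, r$b) + k - 1L
      if (chars_to_codes(substr(index$text$T, last + 1L, last + 1L)) <= 1L) {
        # window ends in a separator: one end node per occurrence (several
        # sequences may share the same tail)
        for (row in seq.int(r$b, r$e - 1L)) {
          sep <- sa_value(index, row) + k - 1L
          ids <<- c(ids, end_node_of_sep(graph, sep))
          offs <<- c(offs, a)
        }
      } else {
        hit <- find_id(graph, index, r)
        ids <<- c(ids, hit$id)
        offs <<- c(offs, hit$offset + a)
      }
      return(invisible())
    }
    for (ch in ALPHABET) {
      r2 <- extend_forward(index, r, ch)
      if (r2$e > r2$b) {
        # interior separators make the window invalid
        if (chars_to_codes(ch) <= 1L && need > 1L) next
        grow_right(r2, need - 1L, a)
      }
    }
  }
  grow_left <- function(r, a_left, a_done) {
    if (a_left == 0L) {
      grow_right(r, k - l - a_done, a_done)
      return(invisible())
    }
    for (ch in ALPHABET[3:6]) {       # O's window cannot start left of a sep
      r2 <- extend_backward(index, r, ch)
      if (r2$e > r2$b) grow_left(r2, a_left - 1L, a_done + 1L)
    }
  }
  for (a in 0:(k - l)) grow_left(r0, a, 0L)
  out <- unique(data.frame(id = ids, offset = offs))
  out <- out[order(out$id, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Text occurrences of an FM occurrence
#'
#' One text occurrence per suffix-array row of the range: the occurrence is
#' located through the sparse suffix array and attributed to its pan-genome
#' sequence.
#'
#' @param index A [build_index] result.
#' @param text The [pan_genome_text] (for sequence names).
#' @param occ An FM occurrence (list or one-row data.frame).
#' @param query_id Optional query identifier carried into the result.
#' @param strand `"+"` or `"-"` (carried through; the caller matches the
#'   reverse complement separately).
#' @return data.frame of class `text_occurrences`: `query_id`, `strand`,
#'   `seq_index`, `seq_name`, `start` (0-based, within the sequence),
#'   `length`, `ed`.
#' @export
to_text_occurrences <- function(index, text, occ, query_id = NA_character_,
                                strand = "+") {
  occ <- as_fm_occ(occ)
  loc <- locate(index, bd_range(occ$b, occ$e, occ$b_r, occ$e_r),
                length = occ$length)
  out <- data.frame(query_id = rep(query_id, nrow(loc)),
                    strand = rep(strand, nrow(loc)),
                    seq_index = loc$seq_index,
                    seq_name = text$seq_names[loc$seq_index + 1L],
                    start = loc$local_pos,
                    length = loc$length,
                    ed = rep(occ$ed, nrow(loc)))
  class(out) <- c("text_occurrences", "data.frame")
  out
}

#' Filter redundant occurrences
#'
#' Occurrences sharing a locus keep only their best representative.  Two
#' text occurrences belong to the same locus when they stem from the same
#' query and strand, lie on the same sequence and their intervals overlap
#' (transitively).  Within a locus the minimal edit distance wins; ties go
#' to the longer occurrence, then to the smaller start.  The operation is
#' idempotent.  FM occurrences (columns `b`, `length`, `ed`) are instead
#' deduplicated per distinct substring, keeping the minimal edit distance.
#'
#' @param occurrences data.frame: either text occurrences (`seq_index`,
#'   `start`, `length`, `ed`, optionally `query_id`, `strand`) or FM
#'   occurrences (`b`, `length`, `ed`).
#' @return The filtered data.frame, same columns, sorted.
#' @export
filter_redundant <- function(occurrences) {
  occ <- occurrences
  if (nrow(occ) == 0L) return(occ)
  if ("b" %in% names(occ) && !("start" %in% names(occ))) {
    occ <- occ[order(occ$b, occ$length, occ$ed), , drop = FALSE]
    occ <- occ[!duplicated(occ[c("b", "length")]), , drop = FALSE]
    rownames(occ) <- NULL
    return(occ)
  }
  if (!("query_id" %in% names(occ))) occ$query_id <- NA_character_
  if (!("strand" %in% names(occ))) occ$strand <- "+"
  grp <- interaction(occ$query_id, occ$strand, occ$seq_index, drop = TRUE)
  keep <- lapply(split(seq_len(nrow(occ)), grp), function(ix) {
    sub <- occ[ix, , drop = FALSE]
    o <- order(sub$start, sub$start + sub$length)
    sub <- sub[o, , drop = FALSE]; ix <- ix[o]
    cl <- integer(nrow(sub))
    cur <- 1L; cl[1L] <- 1L; maxend <- sub$start[1L] + sub$length[1L]
    for (i in seq_len(nrow(sub))[-1L]) {
      if (sub$start[i] < maxend) {
        cl[i] <- cur
        maxend <- max(maxend, sub$start[i] + sub$length[i])
      } else {
        cur <- cur + 1L
        cl[i] <- cur
        maxend <- sub$start[i] + sub$length[i]
      }
    }
    vapply(split(seq_len(nrow(sub)), cl), function(jx) {
      s <- sub[jx, , drop = FALSE]
      best <- order(s$ed, -s$length, s$start)[1L]
      ix[jx[best]]
    }, integer(1))
  })
  out <- occ[sort(unlist(keep, use.names = FALSE)), , drop = FALSE]
  out <- out[order(out$query_id, out$strand, out$seq_index, out$start,
                   out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}
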