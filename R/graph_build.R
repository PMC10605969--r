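# Construction of the implicit colored compacted de Bruijn graph (ccdBG).
#
# Strategy: enumerate all valid k-mers of T directly, compact maximal
# non-branching chains into unitigs, then derive the implicit components
# (node vector G, marker bit vectors B / B^r, IDmap / IDmap^r) from suffix
# array lookups of each node's extreme and checkpoint k-mers.  This explicit
# build is O(n k) and produces the same data structure a streaming,
# LCP-based construction would.

# valid k-mer windows: separation characters allowed only at the last position
valid_windows <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(logical(0))
  valid <- rep(TRUE, n - k + 1L)
  seps <- which(codes <= 1L) - 1L            # 0-based separator positions
  for (s in seps) {
    lo <- max(0L, s - k + 2L)
    hi <- min(s, n - k)
    if (lo <= hi) valid[(lo:hi) + 1L] <- FALSE
    if (s - k + 1L >= 0L && s - k + 1L <= n - k)
      valid[s - k + 2L] <- TRUE              # separator at last position
  }
  valid
}

#' Build the implicit ccdBG over a bidirectional FM-index
#'
#' Nodes are the unitigs of the de Bruijn graph of order `k` over the
#' pan-genome text (k-mers containing a separation character anywhere but
#' their last position are excluded).  Each of the `S` sequences contributes
#' a distinct end node: the k-mer whose last character is its separator;
#' end nodes are never merged into chains and sit in the last `S` slots of
#' the node vector.  Stored per node: `len`, `mult`, `left_kmer` (left bound
#' of the SA interval of the leftmost k-mer) and `right_kmer_r` (left bound
#' of the reverse-SA interval of the reversed rightmost k-mer; for end nodes
#' the rightmost k-mer is the cyclic extension starting at the separator).
#'
#' Bit vector `B` marks, at the lexicographically largest suffix of the
#' corresponding k-mer, every node's rightmost k-mer plus — for finite
#' `s_cp` — every checkpoint k-mer (separator-free k-mers at node offsets
#' `j * s_cp`); `B_r` marks reversed leftmost k-mers on the reverse side.
#' `IDmap` translates ranks in `B` to `(node id, offset)` pairs, `IDmap_r`
#' ranks in `B_r` to node ids.
#'
#' Node identifiers are canonical: non-end nodes ordered by decreasing
#' multiplicity, ties by increasing `left_kmer`; end nodes last, in the
#' order of their separator suffix rows.
#'
#' @param index A [build_index] result.
#' @param text The [pan_genome_text] the index was built from.
#' @param k k-mer size (>= 2); every sequence must be at least `k` long.
#' @param s_cp Checkpoint sparseness factor; `Inf` disables checkpoint
#'   k-mers (default 128).
#' @return An object of class `ccdbg`.
#' @examples
#' txt <- pan_genome_text(c("CTATGTC", "ATATGTTGGTC"))
#' idx <- build_index(txt, s_SA = 1)
#' g <- build_graph(idx, txt, k = 3, s_cp = 2)
#' node_substring(g, idx, 4)  # "GTTGGT"
#' @export
build_graph <- function(index, text, k, s_cp = 128) {
  stopifnot(inherits(index, "bd_fm_index"), inherits(text, "pan_genome_text"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (any(text$seq_lens < k))
    stop("every sequence must have length >= k (shortest: ",
         min(text$seq_lens), ", k = ", k, ")")
  if (!identical(is.infinite(s_cp), TRUE)) {
    s_cp <- as.integer(s_cp)
    stopifnot(s_cp >= 1L)
  }

  codes <- chars_to_codes(text$T)
  n <- length(codes)
  sa <- sa_build_cpp(codes)
  sa_r <- sa_build_cpp(rev(codes))
  isa <- integer(n); isa[sa + 1L] <- seq_len(n) - 1L
  isa_r <- integer(n); isa_r[sa_r + 1L] <- seq_len(n) - 1L

  valid <- valid_windows(codes, k)
  starts0 <- which(valid) - 1L               # 0-based window starts
  win <- substring(text$T, starts0 + 1L, starts0 + k)
  uk <- unique(win)
  kid <- match(win, uk)                      # per valid window, kmer id
  nk <- length(uk)
  is_barrier <- substr(uk, k, k) %in% c("$", "%")

  # occurrence positions per kmer
  occ_pos <- split(starts0, kid)

  # adjacency between consecutive valid windows, with edge counts.  Two
  # k-mers u -> v merge only when every occurrence of u is followed by v and
  # every occurrence of v is preceded by u (edge count equals both
  # occurrence counts); this keeps every occurrence of every constituent
  # k-mer an occurrence of its unitig, also at sequence starts.
  pv <- logical(n); pv[starts0 + 1L] <- TRUE
  from_ok <- starts0[starts0 + 1L <= n - k & pv[starts0 + 2L]]
  widx <- integer(n); widx[starts0 + 1L] <- seq_along(starts0)
  efrom <- kid[widx[from_ok + 1L]]
  eto   <- kid[widx[from_ok + 2L]]
  kcount <- lengths(occ_pos)
  pairkey <- efrom * (nk + 1) + eto
  paircnt <- table(pairkey)
  upair <- as.numeric(names(paircnt))
  upair_from <- as.integer(upair %/% (nk + 1))
  upair_to <- as.integer(upair %% (nk + 1))
  upair_n <- as.integer(paircnt)
  full_edge <- upair_n == kcount[upair_from] & upair_n == kcount[upair_to] &
    !is_barrier[upair_from] & !is_barrier[upair_to]
  succ1 <- rep(NA_integer_, nk)              # mergeable unique successor
  succ1[upair_from[full_edge]] <- upair_to[full_edge]
  pred1 <- rep(NA_integer_, nk)
  pred1[upair_to[full_edge]] <- upair_from[full_edge]

  mergeable_into_pred <- function(x) !is_barrier[x] && !is.na(pred1[x])

  # chain heads, then follow unique successors; buf avoids quadratic append
  assigned <- logical(nk)
  chains <- vector("list", nk)
  nchain <- 0L
  buf <- integer(nk)
  follow <- function(x) {
    cnt <- 1L
    buf[1L] <<- x
    assigned[x] <<- TRUE
    cur <- x
    repeat {
      nx <- succ1[cur]
      if (is.na(nx) || assigned[nx]) break
      cnt <- cnt + 1L
      buf[cnt] <<- nx
      assigned[nx] <<- TRUE
      cur <- nx
    }
    buf[seq_len(cnt)]
  }
  for (x in seq_len(nk)) {
    if (is_barrier[x] || assigned[x] || mergeable_into_pred(x)) next
    nchain <- nchain + 1L
    chains[[nchain]] <- follow(x)
  }
  # unbranching cycles (possible only in degenerate texts): break arbitrarily
  for (x in seq_len(nk)) {
    if (assigned[x] || is_barrier[x]) next
    nchain <- nchain + 1L
    chains[[nchain]] <- follow(x)
  }
  chains <- chains[seq_len(nchain)]

  # --- non-end nodes ------------------------------------------------------
  ne_len <- ne_mult <- ne_left <- ne_rkr <- integer(nchain)
  ne_pos <- vector("list", nchain)           # occurrence start positions
  for (i in seq_len(nchain)) {
    ch <- chains[[i]]
    len <- k + length(ch) - 1L
    pos <- occ_pos[[as.character(ch[1L])]]
    if (is.null(pos)) pos <- occ_pos[[ch[1L]]]
    ne_len[i] <- len
    ne_mult[i] <- length(pos)
    ne_left[i] <- min(isa[pos + 1L])
    rstart <- n - pos - len                  # reversed rightmost k-mer start
    ne_rkr[i] <- min(isa_r[rstart + 1L])
    ne_pos[[i]] <- sort(pos)
  }

  # --- end nodes (one per sequence; the separator k-mer, len = k) ---------
  seps <- which(codes <= 1L) - 1L            # S separator positions, 0-based
  S <- text$S
  stopifnot(length(seps) == S)
  en_start <- seps - k + 1L
  en_row <- isa[seps + 1L]                   # suffix row at the separator
  ord_en <- order(en_row)                    # = rows 0..S-1 of B
  en_start <- en_start[ord_en]
  en_sep <- seps[ord_en]
  en_left <- isa[en_start + 1L]
  # reversed cyclic rightmost k-mer: starts in T^r at n-1-((sep+k-1) mod n)
  en_rkr <- isa_r[(n - 1L - ((en_sep + k - 1L) %% n)) + 1L]

  # --- canonical ordering -------------------------------------------------
  ord_ne <- order(-ne_mult, ne_left)
  nV <- nchain + S
  len_v <- c(ne_len[ord_ne], rep(k, S))
  mult_v <- c(ne_mult[ord_ne], rep(1L, S))
  left_v <- c(ne_left[ord_ne], en_left)
  rkr_v <- c(ne_rkr[ord_ne], en_rkr)
  is_end <- c(rep(FALSE, nchain), rep(TRUE, S))
  pos_l <- c(ne_pos[ord_ne], as.list(en_start))

  # --- bit vector B, IDmap ------------------------------------------------
  acc_row <- vector("list", nV)
  acc_off <- vector("list", nV)
  for (id0 in seq_len(nV)) {
    pos <- pos_l[[id0]]
    len <- len_v[id0]
    if (is_end[id0]) {
      acc_row[[id0]] <- isa[((pos + len - 1L) %% n) + 1L]  # separator suffix
      acc_off[[id0]] <- len - 1L             # cyclic rightmost offset
    } else {
      offs <- len - k                        # rightmost k-mer
      if (is.finite(s_cp) && len - k >= 1L)
        offs <- c(seq.int(0L, len - k - 1L, by = s_cp), offs)
      acc_row[[id0]] <- vapply(offs, function(off) max(isa[pos + off + 1L]),
                               integer(1))
      acc_off[[id0]] <- as.integer(offs)
    }
  }
  brow <- unlist(acc_row, use.names = FALSE)
  boff <- unlist(acc_off, use.names = FALSE)
  bid <- rep.int(seq_len(nV) - 1L, lengths(acc_row))
  o <- order(brow)
  brow <- brow[o]; bid <- bid[o]; boff <- boff[o]
  stopifnot(!anyDuplicated(brow))
  B <- integer(n); B[brow + 1L] <- 1L

  # --- bit vector B_r, IDmap_r -------------------------------------------
  rrow <- integer(nV); rid <- seq_len(nV) - 1L
  for (id0 in seq_len(nV)) {
    pos <- pos_l[[id0]]
    rrow[id0] <- max(isa_r[(n - pos - k) + 1L])  # reversed leftmost k-mer
  }
  o <- order(rrow)
  rrow <- rrow[o]; rid <- rid[o]
  stopifnot(!anyDuplicated(rrow))
  B_r <- integer(n); B_r[rrow + 1L] <- 1L

  structure(
    list(nodes = data.frame(len = len_v, mult = mult_v, left_kmer = left_v,
                            right_kmer_r = rkr_v, is_end = is_end),
         n_nodes = nV, k = k, s_cp = s_cp, S = S, n = n,
         B = B, B_rank0 = c(0L, cumsum(B)),    # ones strictly before row i
         B_sel = brow,
         idmap = data.frame(id = bid, offset = boff),
         B_r = B_r, B_r_rank0 = c(0L, cumsum(B_r)),
         idmap_r = rid,
         end_sep = en_sep,                     # separator position per end node
         end_start = en_start),               # 0-based start per end node
    class = "ccdbg")
}

#' @export
print.ccdbg <- function(x, ...) {
  cat(sprintf(
    "ccdbg: k = %d, |V| = %d (%d end nodes), %d checkpoint k-mers, s_cp = %s\n",
    x$k, x$n_nodes, x$S, length(x$B_sel) - x$n_nodes,
    if (is.finite(x$s_cp)) x$s_cp else "Inf"))
  invisible(x)
}

#' Substring represented by a graph node
#'
#' Recovers the unitig `omega` of a node as
#' `T[SA[left_kmer], SA[left_kmer] + len[` through the (sparse) suffix array;
#' the substring itself is never stored.
#'
#' @param graph A [build_graph] result.
#' @param index The underlying [build_index] result.
#' @param id 0-based node identifier.
#' @return Character string of length `len`.
#' @export
node_substring <- function(graph, index, id) {
  stopifnot(id >= 0L, id < graph$n_nodes)
  nd <- graph$nodes[id + 1L, ]
  start <- sa_value(index, nd$left_kmer)
  substr(index$text$T, start + 1L, start + nd$len)
}

end_node_of_sep <- function(graph, sep_pos) {
  id0 <- match(sep_pos, graph$end_sep)
  if (is.na(id0)) stop("no end node at separator position ", sep_pos)
  graph$n_nodes - graph$S + id0 - 1L
}
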