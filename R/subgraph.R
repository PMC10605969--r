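# Symmetric subgraph extraction (undirected BFS ball around seed nodes),
# edge listing through specific-edge predecessor jumps, exports, implicit
# node colors, and the neighbor-variant scan.

#' Extract the symmetric neighborhood of seed nodes
#'
#' Breadth-first search over undirected distance (edge orientation is
#' ignored) from a set of seed nodes, up to `max_depth`.  Neighbors are
#' discovered with the character-jump operations; edges of the induced
#' subgraph are recovered by enumerating every node's incoming edges through
#' [jump_pred_via_edge] and collapsing parallel edges into a multiplicity
#' count.  Nodes found at equal depth are processed in ascending identifier
#' order, so the result is deterministic.
#'
#' @param graph A [build_graph] result.
#' @param index The underlying [build_index] result.
#' @param seed_ids Integer vector of 0-based node identifiers.
#' @param max_depth Maximum undirected distance from any seed (>= 0).
#' @param dna_only Restrict neighbor discovery to A/C/G/T jumps, making the
#'   cyclic edges through separation characters invisible to the traversal
#'   (default `FALSE`).
#' @return An object of class `ccdbg_subgraph`: `node_ids` (ascending),
#'   `edges` (data.frame `from`, `to`, `mult`), `seed_ids`, `max_depth`,
#'   `depth` (named by node id).
#' @export
extract_subgraph <- function(graph, index, seed_ids, max_depth,
                             dna_only = FALSE) {
  seed_ids <- sort(unique(as.integer(seed_ids)))
  if (any(seed_ids < 0L | seed_ids >= graph$n_nodes))
    stop("unknown seed id")
  stopifnot(max_depth >= 0L)
  depth <- integer(0)
  frontier <- seed_ids
  depth[as.character(seed_ids)] <- 0L
  d <- 0L
  while (d < max_depth && length(frontier) > 0L) {
    nxt <- integer(0)
    for (id in frontier) {
      nb <- node_neighbors(graph, index, id, dna_only = dna_only)
      nxt <- c(nxt, nb$pred, nb$succ)
    }
    nxt <- sort(unique(nxt))
    nxt <- nxt[!(as.character(nxt) %in% names(depth))]
    d <- d + 1L
    depth[as.character(nxt)] <- d
    frontier <- nxt
  }
  ids <- sort(as.integer(names(depth)))
  # edge listing: incoming edges of every member node
  ef <- et <- integer(0)
  for (v in ids) {
    mult <- graph$nodes$mult[v + 1L]
    for (eo in seq_len(mult) - 1L) {
      u <- jump_pred_via_edge(graph, index, v, eo)$id
      if (u %in% ids) { ef <- c(ef, u); et <- c(et, v) }
    }
  }
  edges <- if (length(ef)) {
    agg <- stats::aggregate(list(mult = rep(1L, length(ef))),
                            by = list(from = ef, to = et), FUN = sum)
    agg[order(agg$from, agg$to), , drop = FALSE]
  } else {
    data.frame(from = integer(0), to = integer(0), mult = integer(0))
  }
  rownames(edges) <- NULL
  structure(list(node_ids = ids, edges = edges, seed_ids = seed_ids,
                 max_depth = as.integer(max_depth), depth = depth),
            class = "ccdbg_subgraph")
}

#' @export
print.ccdbg_subgraph <- function(x, ...) {
  cat(sprintf("ccdbg_subgraph: %d node(s), %d collapsed edge(s), depth <= %d\n",
              length(x$node_ids), nrow(x$edges), x$max_depth))
  invisible(x)
}

#' Export a subgraph as DOT, GFA 1.0 or a TSV edge list
#'
#' Writers are deterministic (ascending identifiers) so identical subgraphs
#' export byte-for-byte identically.  Cyclic edges (those leaving an end
#' node through its separator) are excluded by default.
#'
#' @param sub An [extract_subgraph] result.
#' @param graph A [build_graph] result.
#' @param index The underlying [build_index] result.
#' @param format One of `"dot"`, `"gfa1"`, `"tsv"`.
#' @param trim_overlap In DOT labels, drop the first `k - 1` characters of
#'   every node substring (the overlap shared with its predecessors);
#'   default `FALSE`.
#' @param include_cyclic Keep edges leaving end nodes (default `FALSE`).
#' @return A single character scalar holding the document.
#' @export
export_subgraph <- function(sub, graph, index,
                            format = c("dot", "gfa1", "tsv"),
                            trim_overlap = FALSE, include_cyclic = FALSE) {
  format <- match.arg(format)
  ids <- sub$node_ids
  edges <- sub$edges
  if (!include_cyclic && nrow(edges) > 0L) {
    from_end <- graph$nodes$is_end[edges$from + 1L]
    edges <- edges[!from_end, , drop = FALSE]
  }
  omega <- vapply(ids, function(id) node_substring(graph, index, id),
                  character(1))
  k <- graph$k
  if (format == "dot") {
    lab <- if (trim_overlap) substring(omega, k) else omega
    lab[nchar(lab) == 0L] <- "-"
    lines <- c("digraph ccdbg {",
               sprintf("  n%d [label=\"%d: %s\"];", ids, ids, lab),
               if (nrow(edges) > 0L)
                 sprintf("  n%d -> n%d [label=\"%d\"];",
                         edges$from, edges$to, edges$mult),
               "}")
  } else if (format == "gfa1") {
    lines <- c("H\tVN:Z:1.0",
               sprintf("S\t%d\t%s", ids, omega),
               if (nrow(edges) > 0L)
                 sprintf("L\t%d\t+\t%d\t+\t%dM\tRC:i:%d",
                         edges$from, edges$to, k - 1L, edges$mult))
  } else {
    lines <- c("from_id\tto_id\tmultiplicity",
               if (nrow(edges) > 0L)
                 sprintf("%d\t%d\t%d", edges$from, edges$to, edges$mult))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Colors (sequence indices) of a node
#'
#' Colors are not stored: the node's occurrences are located through the
#' suffix array and attributed to their sequences on demand.
#'
#' @param graph A [build_graph] result.
#' @param index The underlying [build_index] result.
#' @param id 0-based node identifier.
#' @return Ascending integer vector of 0-based sequence indices in which the
#'   node's substring occurs.
#' @export
node_colors <- function(graph, index, id) {
  stopifnot(id >= 0L, id < graph$n_nodes)
  nd <- graph$nodes[id + 1L, ]
  loc <- locate(index, bd_range(nd$left_kmer, nd$left_kmer + nd$mult, 0L,
                                nd$mult),
                length = nd$len)
  sort(unique(loc$seq_index))
}

# positions (0-based, local) of a node's substring inside one sequence
node_positions_in_seq <- function(graph, index, id, seq_index) {
  nd <- graph$nodes[id + 1L, ]
  loc <- locate(index, bd_range(nd$left_kmer, nd$left_kmer + nd$mult, 0L,
                                nd$mult),
                length = nd$len)
  sort(loc$local_pos[loc$seq_index == seq_index])
}

#' Scan the neighborhood of a reference walk for co-segregating variants
#'
#' Given a walk of node identifiers following a reference sequence through
#' the graph, examines every depth-1 off-walk neighbor as a candidate
#' variant node.  A candidate is reported when (i) a coordinate can be
#' assigned by jumping back through predecessor edges for at most
#' `max_back_steps` until a node is met whose substring occurs exactly once
#' in the reference sequence (the coordinate is that occurrence's position
#' plus the walked distance), (ii) the candidate's colors are a subset of
#' one single marker-carrier set, and (iii) its multiplicity is at least
#' `min_mult`.
#'
#' @param graph A [build_graph] result.
#' @param index The underlying [build_index] result.
#' @param reference_path Integer vector of 0-based node ids forming a
#'   connected walk (consecutive nodes must be linked by an edge).
#' @param marker_carriers A set of 0-based sequence indices, or a list of
#'   such sets (one per marker mutation); condition (ii) requires the
#'   candidate's colors to fall entirely within a *single* set.
#' @param max_back_steps Maximum predecessor jumps for coordinate assignment.
#' @param min_mult Minimum candidate multiplicity (default 2).
#' @param ref_seq 0-based index of the reference sequence (default 0).
#' @return data.frame with columns `node_id` and `coord` (0-based position
#'   in the reference sequence), one row per accepted candidate.
#' @export
neighbor_variant_scan <- function(graph, index, reference_path,
                                  marker_carriers, max_back_steps = 10L,
                                  min_mult = 2L, ref_seq = 0L) {
  reference_path <- as.integer(reference_path)
  if (!is.list(marker_carriers)) marker_carriers <- list(marker_carriers)
  stopifnot(min_mult >= 1L, length(reference_path) >= 1L)
  # connectivity of the walk
  if (length(reference_path) > 1L) {
    for (i in seq_len(length(reference_path) - 1L)) {
      succs <- node_neighbors(graph, index, reference_path[i])$succ
      if (!(reference_path[i + 1L] %in% succs))
        stop("reference_path is not a connected walk (between positions ",
             i - 1L, " and ", i, ")")
    }
  }
  # depth-1 off-path neighbors
  cand <- integer(0)
  for (id in reference_path) {
    nb <- node_neighbors(graph, index, id)
    cand <- c(cand, nb$pred, nb$succ)
  }
  cand <- sort(unique(cand))
  cand <- cand[!(cand %in% reference_path)]

  assign_coord <- function(id) {
    # BFS back through predecessor edges until an unambiguous node
    seen <- as.character(id)
    frontier <- id
    for (d in seq_len(max_back_steps)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (eo in seq_len(graph$nodes$mult[v + 1L]) - 1L) {
          nxt <- c(nxt, jump_pred_via_edge(graph, index, v, eo)$id)
        }
      }
      nxt <- sort(unique(nxt))
      nxt <- nxt[!(as.character(nxt) %in% seen)]
      for (u in nxt) {
        p <- node_positions_in_seq(graph, index, u, ref_seq)
        if (length(p) == 1L) return(p + d)
      }
      seen <- c(seen, as.character(nxt))
      frontier <- nxt
      if (length(frontier) == 0L) break
    }
    NA_integer_
  }

  keep_id <- keep_coord <- integer(0)
  for (id in cand) {
    if (graph$nodes$mult[id + 1L] < min_mult) next
    cols <- node_colors(graph, index, id)
    ok <- any(vapply(marker_carriers,
                     function(s) length(cols) > 0L && all(cols %in% s),
                     logical(1)))
    if (!ok) next
    co <- assign_coord(id)
    if (is.na(co)) next
    keep_id <- c(keep_id, id)
    keep_coord <- c(keep_coord, co)
  }
  data.frame(node_id = keep_id, coord = keep_coord)
}
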