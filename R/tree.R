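#' Resolve a haplotype network into a most-parsimonious mutation tree
#'
#' Chooses one spanning resolution of every reticulation in the network and
#' returns a rooted mutation tree. The objective is lexicographic: first
#' minimise the total number of mutations (parsimony length), then the
#' rate-weighted cost of the postulated events, so that among equally
#' parsimonious resolutions recurrent mutations are assigned to the
#' positions with the highest relative rate; remaining ties are broken
#' deterministically by node state order. For small instances the optimum
#' over all Steiner-node subsets is found exactly; large instances use a
#' minimum spanning tree over the network followed by pruning.
#'
#' @param network A `haplo_network` from [build_rm_network()].
#' @param rates A [rate_table()]; defaults to the one used to build the
#'   network.
#' @param root Root node: a node id (`"H1"`, ...), a sample id, or
#'   `"reference"` for the reference (outgroup) node when the network was
#'   built with `add_reference = TRUE`.
#' @param exact_terminal_cap,exact_node_cap Exact minimum Steiner trees
#'   (Dreyfus-Wagner dynamic programme) are computed when the network has
#'   at most this many terminal haplotypes and nodes; larger instances use
#'   the spanning-tree heuristic.
#' @return An object of class `mutation_tree`.
#' @export
resolve_to_tree <- function(network, rates = network$rates, root = NULL,
                            exact_terminal_cap = 10L,
                            exact_node_cap = 250L) {
  stopifnot(inherits(network, "haplo_network"))
  n <- nrow(network$nodes)
  root_idx <- .resolve_root(network, root)
  costs <- .site_costs(network$sites, rates)
  e <- network$edges
  ecost <- vapply(e$sites, function(s)
    sum(costs[match(s, network$sites$label)]), numeric(1))
  big <- sum(ecost) + 1
  ew <- e$nmut * big + ecost
  keys <- .state_key(network$states)
  eord <- order(ew, keys[e$from], keys[e$to])

  terminals <- which(network$nodes$multiplicity > 0L)
  terminals <- sort(unique(c(terminals, root_idx)))

  pick <- if (n <= 1L) {
    integer(0)
  } else if (length(terminals) <= exact_terminal_cap &&
             n <= exact_node_cap) {
    .steiner_dw(n, e, ew, eord, terminals)
  } else if (n <= 900L) {
    .steiner_kmb(n, e, ew, eord, terminals)
  } else {
    .mst_prune(n, e, ew, eord, terminals)
  }

  .build_mutation_tree(network, pick, root_idx)
}

.resolve_root <- function(network, root) {
  if (is.null(root)) {
    if (!is.na(network$reference_node)) {
      root <- network$reference_node
    } else {
      stop("no root given and the network has no reference node; pass ",
           "`root = <node or sample id>`", call. = FALSE)
    }
  }
  if (identical(root, "reference")) {
    if (is.na(network$reference_node)) {
      stop("network was built without `add_reference = TRUE`", call. = FALSE)
    }
    root <- network$reference_node
  }
  idx <- match(root, network$nodes$id)
  if (is.na(idx)) {
    s <- match(root, network$samples$sample_id)
    if (!is.na(s)) idx <- match(network$samples$node[s], network$nodes$id)
  }
  if (is.na(idx)) stop("root '", root, "' is not a node or sample id",
                       call. = FALSE)
  idx
}

# Kruskal over an edge subset; returns edge indices or NULL if disconnected
.kruskal <- function(nodes_in, e, eord) {
  idx <- setNames(seq_along(nodes_in), nodes_in)
  parent <- seq_along(nodes_in)
  find <- function(x) {
    while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }
    x
  }
  chosen <- integer(0)
  for (k in eord) {
    a <- idx[as.character(e$from[k])]
    b <- idx[as.character(e$to[k])]
    if (is.na(a) || is.na(b)) next
    ra <- find(a); rb <- find(b)
    if (ra != rb) { parent[ra] <- rb; chosen <- c(chosen, k) }
  }
  if (length(chosen) != length(nodes_in) - 1L) return(NULL)
  chosen
}

# all-pairs shortest paths over the network graph with next-hop tracking
.apsp <- function(n, e, ew) {
  D <- matrix(Inf, n, n); diag(D) <- 0
  nxt <- matrix(0L, n, n)
  for (k in seq_len(nrow(e))) {
    a <- e$from[k]; b <- e$to[k]
    if (ew[k] < D[a, b]) {
      D[a, b] <- D[b, a] <- ew[k]
      nxt[a, b] <- b; nxt[b, a] <- a
    }
  }
  for (k in seq_len(n)) {
    cand <- outer(D[, k], D[k, ], "+")
    upd <- cand < D
    if (any(upd)) {
      D[upd] <- cand[upd]
      idx <- which(upd, arr.ind = TRUE)
      nxt[upd] <- nxt[cbind(idx[, 1], k)]
    }
  }
  list(D = D, nxt = nxt)
}

# walk the next-hop matrix collecting the node pairs of a shortest path
.walk_pairs <- function(nxt, a, b) {
  pairs <- NULL
  while (a != b) {
    s <- nxt[a, b]
    pairs <- rbind(pairs, sort(c(a, s)))
    a <- s
  }
  pairs
}

# Shortest-path heuristic Steiner tree (terminal metric closure): MST over
# the terminals under graph distance, expanded into the underlying paths.
.steiner_kmb <- function(n, e, ew, eord, terminals) {
  ap <- .apsp(n, e, ew)
  t <- length(terminals)
  intree <- c(TRUE, rep(FALSE, t - 1L))
  pairs <- NULL
  for (step in seq_len(t - 1L)) {
    best <- NULL; bw <- Inf
    for (a in which(intree)) {
      for (b in which(!intree)) {
        w <- ap$D[terminals[a], terminals[b]]
        if (w < bw) { bw <- w; best <- c(a, b) }
      }
    }
    if (!is.finite(bw)) stop("network is not connected", call. = FALSE)
    pairs <- rbind(pairs, .walk_pairs(ap$nxt, terminals[best[1]],
                                      terminals[best[2]]))
    intree[best[2]] <- TRUE
  }
  nodes_in <- sort(unique(c(terminals, as.vector(pairs))))
  edge_key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  picked <- unique(paste(pairs[, 1], pairs[, 2]))
  sub <- which(edge_key %in% picked)
  ch <- .kruskal(nodes_in, e[sub, , drop = FALSE], order(ew[sub], sub))
  if (is.null(ch)) stop("internal error: path expansion disconnected",
                        call. = FALSE)
  sub[ch]
}

# Exact minimum Steiner tree (Dreyfus-Wagner) over the network graph with
# scalar weights `ew`; returns indices of the chosen network edges.
.steiner_dw <- function(n, e, ew, eord, terminals) {
  INF <- Inf
  ap <- .apsp(n, e, ew)
  D <- ap$D; nxt <- ap$nxt
  tN <- length(terminals)
  if (tN == 1L) return(integer(0))
  full <- bitwShiftL(1L, tN) - 1L
  dp <- matrix(INF, full, n)
  ch_split <- matrix(0L, full, n)     # subset S1 of a split, 0 = none
  ch_anchor <- matrix(0L, full, n)    # node u reached by a path, 0 = none
  for (i in seq_len(tN)) {
    S <- bitwShiftL(1L, i - 1L)
    dp[S, ] <- D[terminals[i], ]
    ch_anchor[S, ] <- terminals[i]
  }
  pop <- vapply(seq_len(full), function(S) sum(
    bitwAnd(bitwShiftR(S, 0:(tN - 1L)), 1L)), numeric(1))
  for (S in seq_len(full)[order(pop)]) {
    if (pop[S] < 2L) next
    # proper splits: S1 strictly between 0 and S, take S1 < S2 once
    S1 <- bitwAnd(S - 1L, S)
    while (S1 > 0L) {
      S2 <- S - S1
      if (S1 < S2) {
        cand <- dp[S1, ] + dp[S2, ]
        upd <- cand < dp[S, ]
        if (any(upd)) {
          dp[S, upd] <- cand[upd]
          ch_split[S, upd] <- S1
          ch_anchor[S, upd] <- 0L
        }
      }
      S1 <- bitwAnd(S1 - 1L, S)
    }
    # extend by shortest paths
    M <- dp[S, ] + D                  # M[u, v] = dp[S, u] + d(u, v)
    best_u <- apply(M, 2, which.min)
    best_w <- M[cbind(best_u, seq_len(n))]
    upd <- best_w < dp[S, ] & best_u != seq_len(n)
    if (any(upd)) {
      dp[S, upd] <- best_w[upd]
      ch_anchor[S, upd] <- best_u[upd]
      ch_split[S, upd] <- 0L
    }
  }
  v_star <- which.min(dp[full, ])
  if (!is.finite(dp[full, v_star])) stop("network is not connected",
                                         call. = FALSE)
  # traceback, collecting node pairs along shortest paths
  pairs <- NULL
  walk_path <- function(a, b) {
    while (a != b) {
      s <- nxt[a, b]
      pairs <<- rbind(pairs, sort(c(a, s)))
      a <- s
    }
  }
  stack <- list(c(full, v_star))
  while (length(stack)) {
    st <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    S <- st[1]; v <- st[2]
    if (ch_anchor[S, v] > 0L && pop[S] == 1L) {
      walk_path(ch_anchor[S, v], v)
    } else if (ch_anchor[S, v] > 0L) {
      u <- ch_anchor[S, v]
      walk_path(u, v)
      stack[[length(stack) + 1L]] <- c(S, u)
    } else if (ch_split[S, v] > 0L) {
      stack[[length(stack) + 1L]] <- c(ch_split[S, v], v)
      stack[[length(stack) + 1L]] <- c(S - ch_split[S, v], v)
    }
  }
  nodes_in <- sort(unique(c(terminals, if (!is.null(pairs)) as.vector(pairs))))
  # minimal spanning structure over the traced edges (dedups overlaps)
  edge_key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  picked_keys <- unique(paste(pairs[, 1], pairs[, 2]))
  sub <- which(edge_key %in% picked_keys)
  ch <- .kruskal(nodes_in, e[sub, , drop = FALSE],
                 order(ew[sub], sub))
  if (is.null(ch)) stop("internal error: Steiner traceback disconnected",
                        call. = FALSE)
  sub[ch]
}

.mst_prune <- function(n, e, ew, eord, terminals) {
  ch <- .kruskal(seq_len(n), e, eord)
  if (is.null(ch)) stop("network is not connected", call. = FALSE)
  repeat {
    deg <- tabulate(c(e$from[ch], e$to[ch]), nbins = n)
    leaf <- which(deg == 1L & !(seq_len(n) %in% terminals))
    if (!length(leaf)) break
    drop <- ch[e$from[ch] %in% leaf | e$to[ch] %in% leaf]
    ch <- setdiff(ch, drop)
  }
  ch
}

# orient chosen edges from the root, prune and contract unsampled
# pass-through nodes, and assemble the mutation_tree object
.build_mutation_tree <- function(network, pick, root_idx) {
  n <- nrow(network$nodes)
  adj <- vector("list", n)
  for (k in pick) {
    a <- network$edges$from[k]; b <- network$edges$to[k]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  parent <- rep(NA_integer_, n)
  intree <- rep(FALSE, n)
  queue <- root_idx; intree[root_idx] <- TRUE
  order_visit <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order_visit <- c(order_visit, v)
    for (w in adj[[v]]) {
      if (!intree[w]) { intree[w] <- TRUE; parent[w] <- v; queue <- c(queue, w) }
    }
  }
  keep <- which(intree)
  mult <- network$nodes$multiplicity
  # prune unsampled leaves, then splice unsampled degree-2 nodes
  repeat {
    kids <- table(factor(parent[keep], levels = keep))
    leaf <- keep[kids == 0L & mult[keep] == 0L & keep != root_idx]
    if (!length(leaf)) break
    keep <- setdiff(keep, leaf)
  }
  repeat {
    kids <- lapply(setNames(keep, keep), function(v)
      keep[!is.na(parent[keep]) & parent[keep] == v])
    splice <- keep[vapply(as.character(keep), function(v)
      length(kids[[v]]), integer(1)) == 1L &
        mult[keep] == 0L & keep != root_idx]
    if (!length(splice)) break
    v <- splice[1]
    child <- kids[[as.character(v)]]
    parent[child] <- parent[v]
    keep <- setdiff(keep, v)
  }

  states <- network$states[keep, , drop = FALSE]
  ids <- network$nodes$id[keep]
  par_id <- network$nodes$id[parent[keep]]
  par_id[keep == root_idx] <- NA_character_
  edges <- data.frame(parent = par_id[!is.na(par_id)],
                      child = ids[!is.na(par_id)],
                      stringsAsFactors = FALSE)
  esites <- lapply(seq_len(nrow(edges)), function(k) {
    a <- match(edges$parent[k], ids); b <- match(edges$child[k], ids)
    diff <- which(states[a, ] != states[b, ])
    network$sites$label[diff]
  })
  edges$nmut <- vapply(esites, length, integer(1))
  edges$sites <- I(esites)

  samples <- network$samples[network$samples$node %in% ids, , drop = FALSE]
  rownames(samples) <- NULL
  structure(
    list(nodes = data.frame(id = ids, multiplicity = mult[keep],
                            clade = NA_character_, stringsAsFactors = FALSE),
         states = states, sites = network$sites, edges = edges,
         root = network$nodes$id[root_idx], samples = samples,
         length = sum(edges$nmut)),
    class = "mutation_tree")
}

#' @export
print.mutation_tree <- function(x, ...) {
  cat(sprintf(
    "<mutation_tree> %d nodes, %d samples, parsimony length %d, root %s\n",
    nrow(x$nodes), nrow(x$samples), x$length, x$root))
  invisible(x)
}

# children list keyed by node id
.children <- function(tree) {
  split(tree$edges$child, factor(tree$edges$parent, levels = tree$nodes$id))
}

# node ids of the subtree rooted at `node` (inclusive), preorder
.subtree_ids <- function(tree, node) {
  ch <- .children(tree)
  out <- character(0)
  stack <- node
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    out <- c(out, v)
    stack <- c(ch[[v]], stack)
  }
  out
}

#' Label clades with haplogroup motifs
#'
#' Labels every tree node whose derived-variant set (relative to the
#' reference) contains a haplogroup-defining motif, using the most derived
#' (largest) matching motif, PhyloTree-style.
#'
#' @param tree A `mutation_tree`.
#' @param motifs Data frame with columns `haplogroup` and `motif`, the motif
#'   being a comma- or space-separated list of variant labels
#'   (e.g. `"T16217C, A16247G"`).
#' @return The tree with its `nodes$clade` column filled.
#' @export
annotate_clades <- function(tree, motifs) {
  stopifnot(inherits(tree, "mutation_tree"))
  if (!nrow(motifs)) return(tree)
  stopifnot(all(c("haplogroup", "motif") %in% names(motifs)))
  parsed <- lapply(strsplit(motifs$motif, "[,[:space:]]+"),
                   function(x) x[nzchar(x)])
  sizes <- lengths(parsed)
  ord <- order(sizes, motifs$haplogroup)   # later = more derived wins
  derived <- lapply(seq_len(nrow(tree$nodes)), function(i)
    tree$sites$label[tree$states[i, ] == 1L])
  for (k in ord) {
    hit <- vapply(derived, function(d) all(parsed[[k]] %in% d), logical(1))
    if (!any(hit)) {
      warning("motif for haplogroup '", motifs$haplogroup[k],
              "' matches no node", call. = FALSE)
      next
    }
    tree$nodes$clade[hit] <- motifs$haplogroup[k]
  }
  tree
}

#' Find the root node of a labeled clade
#'
#' @param tree A `mutation_tree` labeled by [annotate_clades()].
#' @param clade Haplogroup label.
#' @return The node id of the shallowest node carrying the label.
#' @export
clade_node <- function(tree, clade) {
  hit <- tree$nodes$id[!is.na(tree$nodes$clade) & tree$nodes$clade == clade]
  if (!length(hit)) stop("no node labeled '", clade, "'", call. = FALSE)
  # shallowest = fewest derived variants
  depth <- rowSums(tree$states)[match(hit, tree$nodes$id)]
  hit[which.min(depth)]
}

#' Write a mutation tree in Newick format
#'
#' Samples are written as pendant tips of length 0 at their haplotype node;
#' branch lengths are mutation counts and each branch carries its variant
#' list as a bracketed comment.
#'
#' @param tree A `mutation_tree`.
#' @param path Optional output file.
#' @return The Newick string, invisibly if `path` is given.
#' @export
write_tree_newick <- function(tree, path = NULL) {
  ch <- .children(tree)
  smp <- split(tree$samples$sample_id, tree$samples$node)
  rec <- function(id, sites) {
    parts <- character(0)
    for (k in ch[[id]]) {
      i <- which(tree$edges$child == k)
      parts <- c(parts, rec(k, tree$edges$sites[[i]]))
    }
    for (s in smp[[id]]) parts <- c(parts, paste0(s, ":0"))
    body <- if (length(parts)) paste0("(", paste(parts, collapse = ","), ")")
    else ""
    com <- if (length(sites)) paste0("[&mut=", paste(sites, collapse = "|"),
                                     "]") else ""
    paste0(body, id, ":", length(sites), com)
  }
  nwk <- paste0(rec(tree$root, character(0)), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
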