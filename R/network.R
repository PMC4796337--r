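.state_key <- function(states) {
  apply(states, 1L, paste, collapse = "")
}

# site table + samples-by-sites binary matrix from a list of profiles
.profiles_to_matrix <- function(profiles) {
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicated sample ids", call. = FALSE)
  tabs <- lapply(profiles, function(p) p$variants)
  all_vars <- do.call(rbind, tabs)
  if (is.null(all_vars) || !nrow(all_vars)) {
    sites <- .empty_variants()
    mat <- matrix(0L, nrow = length(ids), ncol = 0L,
                  dimnames = list(ids, NULL))
    return(list(sites = sites, matrix = mat))
  }
  sites <- all_vars[!duplicated(all_vars$label), , drop = FALSE]
  sites <- sites[order(sites$position, sites$ins_index, sites$alt), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  subs <- sites[sites$kind %in% c("transition", "transversion"), ]
  multi <- unique(subs$position[duplicated(subs$position)])
  if (length(multi)) {
    warning("multi-allelic position(s) split into binary characters: ",
            paste(sort(multi), collapse = ", "), call. = FALSE)
  }
  mat <- matrix(0L, nrow = length(ids), ncol = nrow(sites),
                dimnames = list(ids, sites$label))
  for (k in seq_along(profiles)) {
    mat[k, match(tabs[[k]]$label, sites$label)] <- 1L
  }
  list(sites = sites, matrix = mat)
}

#' Build a reduced-median haplotype network
#'
#' Constructs the median network of the observed haplotypes (binary
#' characters: presence/absence of each derived variant relative to the
#' reference), by closing the set of haplotype state vectors under
#' coordinatewise majority of triples, then linking every pair of states
#' with no third state geodesically between them. A reduction step then
#' simplifies reticulations caused by incompatible character pairs: when the
#' rate-weighted cost of postulating recurrent mutation at one character
#' exceeds `reduction_threshold` times the cost at the other, the resolution
#' requiring recurrence at the expensive character is removed from the
#' network (the cheap character becomes the recurrent one). With uniform
#' rates nothing is removed and the network embeds every most-parsimonious
#' tree.
#'
#' @param profiles List of [haplotype_profile()] objects (typically
#'   filtered).
#' @param rates A [rate_table()].
#' @param reduction_threshold Positive real; conventional default 2.
#' @param add_reference Add the reference state (no derived variants) as an
#'   outgroup node, usable later as the root.
#' @param max_nodes Safety cap on the median closure size.
#' @return An object of class `haplo_network` with elements `nodes` (data
#'   frame: `id`, `multiplicity`, `median`), `states` (0/1 matrix),
#'   `sites` (character table), `edges` (data frame with `from`, `to`,
#'   `nmut` and a list column `sites`), `samples`, and metadata.
#' @export
build_rm_network <- function(profiles, rates = rate_table(),
                             reduction_threshold = 2, add_reference = FALSE,
                             max_nodes = 20000L) {
  stopifnot(length(profiles) >= 1L, reduction_threshold > 0)
  pm <- .profiles_to_matrix(profiles)
  sites <- pm$sites
  smat <- pm$matrix
  obs <- unique(smat)
  if (add_reference && (nrow(sites) == 0L || !any(rowSums(obs) == 0))) {
    obs <- rbind(obs, matrix(0L, 1L, ncol(obs)))
  }
  # canonical node order: lexicographic state strings, observed first
  cl <- buneman_graph_cpp(obs, max_nodes = max_nodes)
  nodes_states <- cl$nodes
  keys <- .state_key(nodes_states)
  obs_flag <- seq_len(nrow(nodes_states)) %in% cl$input_index
  ord <- order(!obs_flag, keys)
  nodes_states <- nodes_states[ord, , drop = FALSE]
  keys <- keys[ord]
  obs_flag <- obs_flag[ord]
  colnames(nodes_states) <- sites$label
  reindex <- match(seq_len(nrow(nodes_states)), ord)

  sample_keys <- .state_key(smat)
  node_of_sample <- match(sample_keys, keys)
  multiplicity <- tabulate(node_of_sample, nbins = nrow(nodes_states))
  ids <- character(nrow(nodes_states))
  ids[obs_flag] <- paste0("H", seq_len(sum(obs_flag)))
  ids[!obs_flag] <- paste0("M", seq_len(sum(!obs_flag)))

  D <- hamming_cpp(nodes_states)
  E <- .network_edges(nodes_states, D, cl$flip_edges, reindex)
  costs <- .site_costs(sites, rates)
  edge_sites <- lapply(seq_len(nrow(E)), function(k) {
    which(nodes_states[E[k, 1], ] != nodes_states[E[k, 2], ])
  })
  edges <- data.frame(from = E[, 1], to = E[, 2],
                      nmut = vapply(edge_sites, length, integer(1)))
  edges$cost <- vapply(edge_sites, function(s) sum(costs[s]), numeric(1))
  edges$sites <- I(lapply(edge_sites, function(s) sites$label[s]))

  net <- structure(
    list(nodes = data.frame(id = ids, multiplicity = multiplicity,
                            median = !obs_flag, stringsAsFactors = FALSE),
         states = nodes_states, sites = sites, edges = edges,
         samples = data.frame(sample_id = rownames(smat),
                              node = ids[node_of_sample],
                              stringsAsFactors = FALSE),
         rates = rates, reduction_threshold = reduction_threshold,
         reference_node = if (add_reference) ids[match(
           paste(rep("0", ncol(nodes_states)), collapse = ""), keys)]
         else NA_character_),
    class = "haplo_network")
  .reduce_network(net, smat, n_zero_rows = as.integer(add_reference))
}

# Link structure of the network. Small node sets get the exact geodesic
# rule (a link wherever no third state lies strictly between). At scale,
# links are the single-character flips plus minimal multi-mutation bridges
# between flip-components (parallel minimal bridges are all kept, so
# reticulations survive).
.network_edges <- function(states, D, flip_edges, reindex,
                           geodesic_cap = 1200L) {
  n <- nrow(states)
  if (n <= 1L) return(matrix(integer(), 0L, 2L))
  if (n <= geodesic_cap) return(geodesic_edges_cpp(D))
  fe <- cbind(reindex[flip_edges[, 1]], reindex[flip_edges[, 2]])
  # flip-graph components
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_len(nrow(fe))) {
    a <- find(fe[k, 1]); b <- find(fe[k, 2])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), comp)
  if (length(comps) > 1L) {
    cidx <- seq_along(comps)
    cd <- matrix(Inf, length(comps), length(comps))
    for (a in cidx) {
      for (b in cidx) {
        if (a < b) cd[a, b] <- cd[b, a] <-
            min(D[comps[[a]], comps[[b]], drop = FALSE])
      }
    }
    # component MST (Prim, deterministic)
    intree <- c(TRUE, rep(FALSE, length(comps) - 1L))
    bridges <- NULL
    for (step in seq_len(length(comps) - 1L)) {
      best <- NULL; bw <- Inf
      for (a in cidx[intree]) {
        for (b in cidx[!intree]) {
          if (cd[a, b] < bw) { bw <- cd[a, b]; best <- c(a, b) }
        }
      }
      a <- best[1]; b <- best[2]
      blk <- D[comps[[a]], comps[[b]], drop = FALSE]
      hit <- which(blk == bw, arr.ind = TRUE)
      cand <- cbind(comps[[a]][hit[, 1]], comps[[b]][hit[, 2]])
      # prefer bridges with no state strictly between; never drop them all
      ok <- vapply(seq_len(nrow(cand)), function(k) {
        u <- cand[k, 1]; v <- cand[k, 2]
        !any(D[u, ] > 0L & D[, v] > 0L & D[u, ] + D[, v] == D[u, v])
      }, logical(1))
      if (!any(ok)) ok[] <- TRUE
      bridges <- rbind(bridges, cand[ok, , drop = FALSE])
      intree[b] <- TRUE
      # merge b into a: distances and membership
      cd[, a] <- cd[a, ] <- pmin(cd[a, ], cd[b, ])
      cd[, b] <- cd[b, ] <- Inf
      comps[[a]] <- c(comps[[a]], comps[[b]])
    }
    fe <- rbind(fe, bridges)
  }
  fe <- t(apply(fe, 1L, sort))
  fe[!duplicated(fe), , drop = FALSE]
}

# remove disfavoured resolutions of incompatible character pairs
.reduce_network <- function(net, smat, n_zero_rows = 0L) {
  sites <- net$sites
  if (nrow(sites) < 2L || !nrow(net$edges)) return(net)
  costs <- .site_costs(sites, net$rates)
  thr <- net$reduction_threshold
  keep <- rep(TRUE, nrow(net$edges))
  single <- which(net$edges$nmut == 1L)
  esite <- rep(NA_integer_, nrow(net$edges))
  esite[single] <- vapply(single, function(k)
    match(net$edges$sites[[k]][1], sites$label), integer(1))
  # candidate pairs: rate-weighted cost ratio at or above the threshold
  ratio_mat <- outer(costs, costs, function(a, b) pmax(a, b) / pmin(a, b))
  cand_pairs <- which(upper.tri(ratio_mat) & ratio_mat >= thr, arr.ind = TRUE)
  if (!nrow(cand_pairs)) return(net)
  # four-gamete test from co-occurrence counts
  cooc <- crossprod(smat)
  ntot <- nrow(smat) + n_zero_rows
  for (pk in seq_len(nrow(cand_pairs))) {
    i <- cand_pairs[pk, 1]; j <- cand_pairs[pk, 2]
    n11 <- cooc[i, j]
    n10 <- cooc[i, i] - n11
    n01 <- cooc[j, j] - n11
    n00 <- ntot - n11 - n10 - n01
    if (!(n11 > 0 && n10 > 0 && n01 > 0 && n00 > 0)) next  # compatible
    {
      expensive <- if (costs[i] >= costs[j]) i else j
      cheap <- if (expensive == i) j else i
      # parallel edges flipping the expensive character across a square in
      # the cheap character: drop the weaker-supported one
      cand <- which(keep & !is.na(esite) & esite == expensive)
      if (length(cand) < 2L) next
      for (a in seq_along(cand)) {
        for (b in seq_along(cand)) {
          if (a >= b) next
          e1 <- cand[a]; e2 <- cand[b]
          if (!keep[e1] || !keep[e2]) next
          u1 <- net$edges$from[e1]; v1 <- net$edges$to[e1]
          u2 <- net$edges$from[e2]; v2 <- net$edges$to[e2]
          sq <- function(x, y) {
            d <- which(net$states[x, ] != net$states[y, ])
            length(d) == 1L && d == cheap
          }
          is_square <- (sq(u1, u2) && sq(v1, v2)) ||
            (sq(u1, v2) && sq(v1, u2))
          if (!is_square) next
          m1 <- sum(net$nodes$multiplicity[c(u1, v1)])
          m2 <- sum(net$nodes$multiplicity[c(u2, v2)])
          drop_e <- if (m1 < m2) e1 else if (m2 < m1) e2 else
            c(e1, e2)[which.max(c(.state_key(net$states[u1, , drop = FALSE]),
                                  .state_key(net$states[u2, , drop = FALSE])))]
          keep[drop_e] <- FALSE
          if (!.edges_connected(nrow(net$states),
                                net$edges[keep, c("from", "to")])) {
            keep[drop_e] <- TRUE                    # never disconnect
          }
        }
      }
    }
  }
  net$edges <- net$edges[keep, , drop = FALSE]
  rownames(net$edges) <- NULL
  net
}

.edges_connected <- function(n, ft) {
  if (n <= 1L) return(TRUE)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_len(nrow(ft))) {
    a <- find(ft$from[k]); b <- find(ft$to[k])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1L
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf(
    "<haplo_network> %d nodes (%d observed, %d median), %d links, %d characters\n",
    nrow(x$nodes), sum(!x$nodes$median), sum(x$nodes$median),
    nrow(x$edges), nrow(x$sites)))
  invisible(x)
}

#' Export a haplotype network as a TSV edge list
#'
#' @param network A `haplo_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  e <- network$edges
  df <- data.frame(from = network$nodes$id[e$from],
                   to = network$nodes$id[e$to], nmut = e$nmut,
                   sites = vapply(e$sites, paste, character(1),
                                  collapse = ","))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a haplotype network in GML format
#'
#' @param network A `haplo_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_gml <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("graph [", con)
  writeLines("  directed 0", con)
  for (i in seq_len(nrow(network$nodes))) {
    writeLines(sprintf(
      '  node [ id %d label "%s" multiplicity %d median %d ]',
      i, network$nodes$id[i], network$nodes$multiplicity[i],
      as.integer(network$nodes$median[i])), con)
  }
  for (k in seq_len(nrow(network$edges))) {
    writeLines(sprintf(
      '  edge [ source %d target %d label "%s" ]',
      network$edges$from[k], network$edges$to[k],
      paste(network$edges$sites[[k]], collapse = ",")), con)
  }
  writeLines("]", con)
  invisible(path)
}
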