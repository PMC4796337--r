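# Shared builders and independent oracles used across the test files.

# transition partner of a base
.ts <- c(A = "G", G = "A", C = "T", T = "C")

# profile carrying transitions at the given rCRS positions
transition_profile <- function(id, positions, reference = mito_reference()) {
  if (!length(positions)) return(haplotype_profile(id))
  rf <- substring(reference, positions, positions)
  haplotype_profile(id, data.frame(
    position = as.integer(positions), ins_index = 0L, ref = rf,
    alt = unname(.ts[rf]), kind = "transition", stringsAsFactors = FALSE))
}

# profiles from a binary haplotype-by-site matrix; sites become transitions
# at distinct positions 101, 102, ...
profiles_from_matrix <- function(mat, reference = mito_reference()) {
  pos <- 100L + seq_len(ncol(mat))
  lapply(seq_len(nrow(mat)), function(i) {
    transition_profile(paste0("s", i), pos[mat[i, ] == 1L], reference)
  })
}

# random rooted mutation tree built directly (bypassing the network code):
# random topology by sequential attachment, random multiplicities, and
# edge mutations drawn from a pool of sites with mixed kinds/classes
random_mutation_tree <- function(n_tips, n_mut, seed) {
  set.seed(seed)
  n_sites <- max(n_mut, 2L)
  kinds <- sample(c("transition", "transversion"), n_sites, replace = TRUE,
                  prob = c(0.8, 0.2))
  fclass <- sample(c("synonymous", "nonsynonymous", "control_region"),
                   n_sites, replace = TRUE)
  sites <- data.frame(position = 200L + seq_len(n_sites), ins_index = 0L,
                      ref = "A",
                      alt = ifelse(kinds == "transition", "G", "C"),
                      kind = kinds, functional_class = fclass,
                      stringsAsFactors = FALSE)
  sites$label <- paste0(sites$ref, sites$position, sites$alt)

  ids <- paste0("N", seq_len(2L * n_tips - 1L))
  parent <- rep(NA_character_, length(ids))
  # sequential random attachment below the root
  for (k in 2:length(ids)) parent[k] <- ids[sample(k - 1L, 1L)]
  mult <- integer(length(ids))
  leaf <- !(ids %in% parent)
  mult[leaf] <- 1L
  extra <- sample(length(ids), min(n_tips, length(ids)), replace = TRUE)
  for (e in extra) mult[e] <- mult[e] + sample(0:1, 1L)
  edge_nodes <- ids[-1]
  alloc <- sample(length(edge_nodes), n_mut, replace = TRUE)
  esites <- lapply(seq_along(edge_nodes), function(k)
    sites$label[which(alloc == k)])
  edges <- data.frame(parent = parent[-1], child = edge_nodes,
                      stringsAsFactors = FALSE)
  edges$nmut <- lengths(esites)
  edges$sites <- I(esites)

  samples <- data.frame(
    sample_id = unlist(lapply(seq_along(ids), function(i)
      if (mult[i] > 0) paste0(ids[i], "_t", seq_len(mult[i])) else
        character(0))),
    stringsAsFactors = FALSE)
  samples$node <- sub("_t[0-9]+$", "", samples$sample_id)

  structure(
    list(nodes = data.frame(id = ids, multiplicity = mult,
                            clade = NA_character_, stringsAsFactors = FALSE),
         states = matrix(0L, length(ids), n_sites,
                         dimnames = list(NULL, sites$label)),
         sites = sites, edges = edges, root = ids[1], samples = samples,
         length = sum(edges$nmut)),
    class = "mutation_tree")
}

# --- independent rho/sigma oracle: per-sample path walking ----------------

oracle_eligible <- function(sites, scope) {
  switch(scope,
    all = sites$label[sites$kind %in% c("transition", "transversion")],
    transitions = sites$label[sites$kind == "transition"],
    synonymous = sites$label[sites$kind %in% c("transition", "transversion") &
                               sites$functional_class == "synonymous"])
}

# exact rho as (numerator, denominator) by brute-force path enumeration
oracle_rho <- function(tree, node, scope = "all") {
  elig <- oracle_eligible(tree$sites, scope)
  par <- setNames(rep(NA_character_, nrow(tree$nodes)), tree$nodes$id)
  par[tree$edges$child] <- tree$edges$parent
  edge_m <- setNames(vapply(seq_len(nrow(tree$edges)), function(k)
    sum(tree$edges$sites[[k]] %in% elig), integer(1)), tree$edges$child)
  below <- function(v) {           # is `node` an ancestor of v (inclusive)?
    while (!is.na(v)) { if (v == node) return(TRUE); v <- par[[v]] }
    FALSE
  }
  keep <- vapply(tree$samples$node, below, logical(1))
  num <- 0L
  for (v in tree$samples$node[keep]) {
    while (v != node) { num <- num + edge_m[[v]]; v <- par[[v]] }
  }
  c(num = num, den = sum(keep))
}

# exact sigma^2 numerator (sum m_e n_e^2) and n by edge enumeration
oracle_sigma2 <- function(tree, node, scope = "all") {
  elig <- oracle_eligible(tree$sites, scope)
  par <- setNames(rep(NA_character_, nrow(tree$nodes)), tree$nodes$id)
  par[tree$edges$child] <- tree$edges$parent
  anc_of <- function(a, v) {       # is a an ancestor of v (inclusive)?
    while (!is.na(v)) { if (v == a) return(TRUE); v <- par[[v]] }
    FALSE
  }
  samples_below <- tree$samples$node[vapply(tree$samples$node,
                                            function(v) anc_of(node, v),
                                            logical(1))]
  n <- length(samples_below)
  num2 <- 0
  for (k in seq_len(nrow(tree$edges))) {
    child <- tree$edges$child[k]
    if (!anc_of(node, child) || child == node) next
    m_e <- sum(tree$edges$sites[[k]] %in% elig)
    if (!m_e) next
    n_e <- sum(vapply(samples_below, function(v) anc_of(child, v),
                      logical(1)))
    num2 <- num2 + m_e * n_e^2
  }
  c(num2 = num2, den = n)
}

# --- exhaustive parsimony oracle (small instances) ------------------------

# per-site Sankoff over a rooted binary-character topology; returns the
# minimum mutation count and, per node, the set of states taken in at
# least one minimum-length reconstruction
sankoff_site <- function(phy, tip_states) {
  nt <- length(phy$tip.label)
  nn <- nt + phy$Nnode
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  root <- nt + 1L
  # up[v, s]: minimum mutations within the subtree of v given state s at v;
  # for internal nodes accumulated child by child in postorder
  up <- matrix(0, nn, 2)
  up[seq_len(nt), ] <- Inf
  for (i in seq_len(nt)) up[i, tip_states[i] + 1L] <- 0
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; v <- edge[k, 2]
    for (s in 1:2) {
      up[p, s] <- up[p, s] + min(up[v, s], up[v, 3 - s] + 1)
    }
  }
  total <- min(up[root, ])
  # down[v, s]: minimum mutations outside the subtree of v given state s
  down <- matrix(Inf, nn, 2)
  down[root, ] <- 0
  for (k in rev(seq_len(nrow(edge)))) {
    p <- edge[k, 1]; v <- edge[k, 2]
    for (s in 1:2) {
      for (t in 1:2) {
        rest <- up[p, t] - min(up[v, t], up[v, 3 - t] + 1)
        down[v, s] <- min(down[v, s],
                          down[p, t] + rest + as.numeric(s != t))
      }
    }
  }
  opt <- matrix(FALSE, nn, 2)
  for (v in seq_len(nn)) {
    for (s in 1:2) {
      opt[v, s] <- is.finite(up[v, s]) && is.finite(down[v, s]) &&
        up[v, s] + down[v, s] == total
    }
  }
  list(total = total, opt = opt)
}

# all states (0/1 vectors over sites) that internal nodes can take across
# minimum reconstructions of one topology
mp_node_state_sets <- function(phy, mat) {
  nt <- length(phy$tip.label)
  res <- lapply(seq_len(ncol(mat)), function(j)
    sankoff_site(phy, mat[phy$tip.label, j]))
  total <- sum(vapply(res, `[[`, numeric(1), "total"))
  sets <- lapply((nt + 1L):(nt + phy$Nnode), function(v) {
    lapply(res, function(r) which(r$opt[v, ]) - 1L)
  })
  list(total = total, sets = sets)
}

# does the network contain a node for every vector in the product set?
network_has_states <- function(net, site_labels, state_sets) {
  keys <- apply(net$states[, site_labels, drop = FALSE], 1, paste,
                collapse = "")
  for (set in state_sets) {
    if (any(lengths(set) == 0)) return(FALSE)
    grid <- expand.grid(set, KEEP.OUT.ATTRS = FALSE)
    if (nrow(grid) > 4096) stop("state product set too large for the check")
    for (r in seq_len(nrow(grid))) {
      key <- paste(unlist(grid[r, ]), collapse = "")
      if (!key %in% keys) return(FALSE)
    }
  }
  TRUE
}

# weighted graph distance (mutation count) between two network nodes
network_distance <- function(net, from, to) {
  n <- nrow(net$nodes)
  dist <- rep(Inf, n)
  dist[from] <- 0
  active <- TRUE
  while (active) {
    active <- FALSE
    for (k in seq_len(nrow(net$edges))) {
      a <- net$edges$from[k]; b <- net$edges$to[k]; w <- net$edges$nmut[k]
      if (dist[a] + w < dist[b]) { dist[b] <- dist[a] + w; active <- TRUE }
      if (dist[b] + w < dist[a]) { dist[a] <- dist[b] + w; active <- TRUE }
    }
  }
  dist[to]
}
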