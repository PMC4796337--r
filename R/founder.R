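#' Founder-selection criterion
#'
#' The f-criteria grade candidate founder types by their diversity in the
#' source population: `f0` accepts any haplotype attested in the source,
#' `f1` requires at least one derived branch in the source below the
#' founder node (guarding against back-migration and recurrent mutation),
#' `f2` requires two.
#'
#' @param name `"f0"`, `"f1"` or `"f2"`.
#' @return An object of class `founder_criterion` with the implied
#'   `min_source_derived_branches`.
#' @export
founder_criterion <- function(name = c("f1", "f0", "f2")) {
  name <- match.arg(name)
  structure(list(name = name,
                 min_source_derived_branches =
                   c(f0 = 0L, f1 = 1L, f2 = 2L)[[name]]),
            class = "founder_criterion")
}

# population label per sample, validated against the tree
.sample_populations <- function(tree, populations) {
  if (is.data.frame(populations)) {
    populations <- setNames(populations$population, populations$sample_id)
  }
  lab <- populations[tree$samples$sample_id]
  missing <- tree$samples$sample_id[is.na(lab)]
  if (length(missing)) {
    stop("unlabeled sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  setNames(as.character(lab), tree$samples$sample_id)
}

# rho/sigma/m over a subset of samples below a node
.rho_sigma_subset <- function(tree, node, scope, sample_ids) {
  ids <- .subtree_ids(tree, node)
  elig <- .eligible_sites(tree$sites, scope)
  ch <- .children(tree)
  at_node <- table(factor(
    tree$samples$node[tree$samples$sample_id %in% sample_ids], levels = ids))
  n_below <- setNames(integer(length(ids)), ids)
  for (v in rev(ids)) n_below[v] <- at_node[[v]] + sum(n_below[ch[[v]]])
  m_edge <- setNames(integer(length(ids)), ids)
  for (v in setdiff(ids, node)) {
    k <- which(tree$edges$child == v)
    m_edge[v] <- sum(tree$edges$sites[[k]] %in% elig)
  }
  n <- n_below[[node]]
  m_total <- sum(m_edge[ids] * n_below[ids])
  sigma2num <- sum(m_edge[ids] * as.numeric(n_below[ids])^2)
  list(n = n, m = m_total, rho = m_total / n,
       sigma = sqrt(sigma2num) / n)
}

#' Identify founder clusters from a source into a sink population
#'
#' Walks every sink sample up the rooted mutation tree to the most recent
#' ancestor that is attested in the source population (samples of the
#' founder haplotype itself, or source-bearing descendant branches) and that
#' satisfies the f-criterion; that ancestor is the founder node and stem
#' mutations below it count toward the cluster's sink diversity. Clusters
#' partition the sink samples. Clusters whose source evidence is entangled
#' with sink lineages (no source samples of the founder haplotype and every
#' source-bearing branch also carrying sink samples) are flagged as possible
#' back-migration.
#'
#' @param tree A rooted `mutation_tree`.
#' @param populations Named vector (`sample_id -> population`) or a sample
#'   sheet data frame.
#' @param source,sink Population labels.
#' @param criterion A [founder_criterion()] or its name.
#' @param scope Mutation-class filter used for the cluster's mutation
#'   counts (match it to the clock used for dating).
#' @return An object of class `founder_clusters`: a list of clusters, each
#'   with `founder_id`, `founder_node`, `source_derived_branches`,
#'   `sink_ids`, `n` (sink tips), `m` (scope-eligible sink mutation total),
#'   `rho`, `sigma`, `criterion_met`, `back_migration`.
#' @export
identify_founders <- function(tree, populations, source, sink,
                              criterion = founder_criterion("f1"),
                              scope = "all") {
  stopifnot(inherits(tree, "mutation_tree"))
  if (is.character(criterion)) criterion <- founder_criterion(criterion)
  lab <- .sample_populations(tree, populations)
  if (!any(lab == sink)) {
    return(structure(list(), class = "founder_clusters",
                     criterion = criterion$name, source = source,
                     sink = sink, scope = scope))
  }
  ids <- tree$nodes$id
  ch <- .children(tree)
  src_at <- snk_at <- setNames(integer(length(ids)), ids)
  t1 <- table(factor(tree$samples$node[lab[tree$samples$sample_id] == source],
                     levels = ids))
  t2 <- table(factor(tree$samples$node[lab[tree$samples$sample_id] == sink],
                     levels = ids))
  src_at[] <- as.integer(t1); snk_at[] <- as.integer(t2)
  src_below <- snk_below <- setNames(integer(length(ids)), ids)
  for (v in rev(.subtree_ids(tree, tree$root))) {
    src_below[v] <- src_at[v] + sum(src_below[ch[[v]]])
    snk_below[v] <- snk_at[v] + sum(snk_below[ch[[v]]])
  }
  n_src_branch <- vapply(ids, function(v)
    sum(src_below[ch[[v]]] > 0L), integer(1))
  qualifies <- (src_at > 0L | n_src_branch > 0L) &
    n_src_branch >= criterion$min_source_derived_branches

  parent <- setNames(rep(NA_character_, length(ids)), ids)
  parent[tree$edges$child] <- tree$edges$parent

  sink_samples <- tree$samples[lab[tree$samples$sample_id] == sink, ]
  founder_of <- character(nrow(sink_samples))
  met <- logical(nrow(sink_samples))
  for (i in seq_len(nrow(sink_samples))) {
    v <- sink_samples$node[i]
    while (!is.na(v) && !qualifies[[v]]) v <- parent[[v]]
    if (is.na(v)) { founder_of[i] <- tree$root; met[i] <- FALSE }
    else { founder_of[i] <- v; met[i] <- TRUE }
  }

  fnodes <- unique(founder_of)
  # stable order: by node depth (derived variant count), then id
  depth <- rowSums(tree$states)[match(fnodes, ids)]
  fnodes <- fnodes[order(depth, fnodes)]
  clusters <- vector("list", length(fnodes))
  for (k in seq_along(fnodes)) {
    f <- fnodes[k]
    members <- sink_samples$sample_id[founder_of == f]
    rs <- .rho_sigma_subset(tree, f, scope, members)
    src_children <- ch[[f]][src_below[ch[[f]]] > 0L]
    back <- src_at[[f]] == 0L && length(src_children) > 0L &&
      all(snk_below[src_children] > 0L)
    clusters[[k]] <- structure(
      list(founder_id = paste0("F", k), founder_node = f,
           source_derived_branches = n_src_branch[[f]],
           sink_ids = members, n = unname(rs$n), m = unname(rs$m),
           rho = rs$rho, sigma = rs$sigma,
           criterion_met = all(met[founder_of == f]),
           back_migration = back),
      class = "founder_cluster")
  }
  structure(clusters, class = "founder_clusters",
            criterion = criterion$name, source = source, sink = sink,
            scope = scope)
}

#' @export
print.founder_clusters <- function(x, ...) {
  cat(sprintf("<founder_clusters> %d cluster(s), criterion %s (%s -> %s)\n",
              length(x), attr(x, "criterion"), attr(x, "source"),
              attr(x, "sink")))
  if (length(x)) print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @method as.data.frame founder_clusters
#' @export
as.data.frame.founder_clusters <- function(x, ...) {
  data.frame(
    founder_id = vapply(x, `[[`, character(1), "founder_id"),
    founder_node = vapply(x, `[[`, character(1), "founder_node"),
    source_derived_branches = vapply(x, `[[`, integer(1),
                                     "source_derived_branches"),
    n = vapply(x, `[[`, integer(1), "n"),
    m = vapply(x, `[[`, numeric(1), "m"),
    rho = vapply(x, `[[`, numeric(1), "rho"),
    sigma = vapply(x, `[[`, numeric(1), "sigma"),
    criterion_met = vapply(x, `[[`, logical(1), "criterion_met"),
    back_migration = vapply(x, `[[`, logical(1), "back_migration"),
    stringsAsFactors = FALSE)
}

#' Date a founder cluster
#'
#' Converts a cluster's sink-side rho and Saillard sigma to years under a
#' clock (default: the founder-scan clock, one mutation per 2,639 years).
#'
#' @param cluster A `founder_cluster` from [identify_founders()].
#' @param clock A [clock_model()].
#' @return A `clade_age`.
#' @export
founder_age <- function(cluster, clock = clock_model("founder")) {
  stopifnot(inherits(cluster, "founder_cluster"))
  convert_to_age(cluster$rho, cluster$sigma, clock, n_tips = cluster$n)
}

#' Migration-time scan
#'
#' Accumulates each founder cluster's age estimate on a fixed time grid
#' (200-year cells by default): every cluster contributes a normal kernel
#' centred at its founder age with standard deviation equal to its Saillard
#' error in years, weighted by its sink sample count (or equally); cell
#' mass is the kernel integral over the cell and the scan is normalised to
#' total mass 1.
#'
#' @param clusters A `founder_clusters` object (or list of clusters).
#' @param clock A [clock_model()].
#' @param grid_step Cell width in years (200 by default).
#' @param grid_start,grid_end Grid limits in years; `grid_end` defaults to
#'   covering the largest age + 3 standard deviations (if given below that,
#'   mass is truncated with a warning and renormalised).
#' @param weight `"frequency"` (sink sample count) or `"equal"`.
#' @return An object of class `migration_scan` with a data frame `grid`
#'   (`grid_time` = cell start, `mid`, `mass`).
#' @export
migration_scan <- function(clusters, clock = clock_model("founder"),
                           grid_step = 200, grid_start = 0,
                           grid_end = NULL, weight = c("frequency", "equal")) {
  weight <- match.arg(weight)
  stopifnot(length(clusters) >= 1L)
  ypm <- clock$years_per_mutation
  ages <- vapply(clusters, function(cl)
    .apply_correction(clock$correction, cl$rho * ypm), numeric(1))
  sds <- vapply(clusters, function(cl) cl$sigma * ypm, numeric(1))
  w <- if (weight == "frequency")
    vapply(clusters, `[[`, integer(1), "n") else rep(1, length(clusters))
  need_end <- max(ages + 3 * sds)
  if (is.null(grid_end)) {
    grid_end <- grid_start + grid_step * ceiling((need_end - grid_start) /
                                                   grid_step)
  } else if (grid_end < need_end) {
    warning(sprintf(
      "grid_end (%g) below largest founder age + 3 SD (%g): mass truncated and renormalised",
      grid_end, need_end), call. = FALSE)
  }
  lo <- seq(grid_start, grid_end - grid_step, by = grid_step)
  hi <- lo + grid_step
  mass <- numeric(length(lo))
  for (i in seq_along(clusters)) {
    m <- if (sds[i] > 0) {
      pnorm(hi, ages[i], sds[i]) - pnorm(lo, ages[i], sds[i])
    } else {
      as.numeric(ages[i] >= lo & ages[i] < hi)
    }
    mass <- mass + w[i] * m
  }
  mass <- mass / sum(mass)
  structure(list(grid = data.frame(grid_time = lo, mid = lo + grid_step / 2,
                                   mass = mass),
                 grid_start = grid_start, grid_step = grid_step,
                 grid_end = grid_end, weight = weight, clock = clock$name,
                 ages = ages, sds = sds),
            class = "migration_scan")
}

#' Scan peaks
#'
#' Local maxima of a migration scan, ordered by mass.
#'
#' @param scan A `migration_scan`.
#' @param k Number of peaks to return.
#' @return Numeric vector of cell midpoints (years) of the top `k` local
#'   maxima.
#' @export
scan_peaks <- function(scan, k = 2L) {
  m <- scan$grid$mass
  n <- length(m)
  left <- c(-Inf, m[-n]); right <- c(m[-1], -Inf)
  is_peak <- m > left & m >= right & m > 0
  peaks <- which(is_peak)
  peaks <- peaks[order(-m[peaks], scan$grid$mid[peaks])]
  scan$grid$mid[head(peaks, k)]
}

#' @export
print.migration_scan <- function(x, ...) {
  pk <- scan_peaks(x, 2L)
  cat(sprintf(
    "<migration_scan> %g-year cells over [%g, %g], %s-weighted; top peaks at %s ka\n",
    x$grid_step, x$grid_start, x$grid_end, x$weight,
    paste(sprintf("%.1f", pk / 1000), collapse = " and ")))
  invisible(x)
}

#' Allocate founder clusters to stipulated migration events
#'
#' For each cluster the probability of arrival with migration event j is
#' proportional to `prior_j * Poisson(m; n * T_j / years_per_mutation)`:
#' the likelihood of the cluster's total sink mutation count `m` over `n`
#' sampled lineages had the founder arrived at time `T_j`. Computed in log
#' space and normalised per cluster.
#'
#' @param clusters A `founder_clusters` object (or list of clusters).
#' @param migration_times Numeric vector of event times in years (e.g.
#'   `c(6500, 11000)`).
#' @param clock A [clock_model()].
#' @param prior Per-event prior weights (default uniform); any constant
#'   rescaling leaves the result unchanged.
#' @return An object of class `allocation_result`: a matrix of
#'   probabilities (clusters x events) with attributes.
#' @export
allocate_to_migrations <- function(clusters, migration_times,
                                   clock = clock_model("founder"),
                                   prior = NULL) {
  stopifnot(length(migration_times) >= 1L, length(clusters) >= 1L)
  if (is.null(prior)) prior <- rep(1, length(migration_times))
  stopifnot(length(prior) == length(migration_times), all(prior > 0))
  ypm <- clock$years_per_mutation
  P <- matrix(NA_real_, length(clusters), length(migration_times),
              dimnames = list(vapply(clusters, `[[`, character(1),
                                     "founder_id"),
                              paste0("T", migration_times)))
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    ll <- dpois(cl$m, cl$n * migration_times / ypm, log = TRUE) + log(prior)
    if (all(!is.finite(ll))) ll[] <- 0        # degenerate: uniform
    ll <- ll - max(ll[is.finite(ll)])
    p <- exp(ll)
    P[i, ] <- p / sum(p)
  }
  structure(P, class = c("allocation_result", "matrix"),
            migration_times = migration_times, clock = clock$name)
}

#' @export
print.allocation_result <- function(x, ...) {
  cat(sprintf("<allocation_result> %d cluster(s) x %d event(s) (years: %s)\n",
              nrow(x), ncol(x),
              paste(attr(x, "migration_times"), collapse = ", ")))
  print(round(unclass(x), 3))
  invisible(x)
}
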