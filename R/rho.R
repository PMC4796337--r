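.SCOPES <- c("all", "transitions", "synonymous")

# eligible site labels under a mutation-class scope
.eligible_sites <- function(sites, scope) {
  scope <- match.arg(scope, .SCOPES)
  switch(scope,
    all = sites$label[sites$kind %in% c("transition", "transversion")],
    transitions = sites$label[sites$kind == "transition"],
    synonymous = sites$label[sites$kind %in% c("transition", "transversion") &
                               !is.na(sites$functional_class) &
                               sites$functional_class == "synonymous"])
}

# per-subtree bookkeeping: for each node below `node` (inclusive), the number
# of samples at/below it and the eligible mutation count on its stem edge
.subtree_counts <- function(tree, node, scope) {
  ids <- .subtree_ids(tree, node)
  elig <- .eligible_sites(tree$sites, scope)
  mult <- setNames(tree$nodes$multiplicity, tree$nodes$id)
  ch <- .children(tree)
  n_below <- setNames(integer(length(ids)), ids)
  for (v in rev(ids)) {   # preorder reversed = children before parents
    n_below[v] <- mult[v] + sum(n_below[ch[[v]]])
  }
  m_edge <- setNames(integer(length(ids)), ids)
  for (v in setdiff(ids, node)) {
    k <- which(tree$edges$child == v)
    m_edge[v] <- sum(tree$edges$sites[[k]] %in% elig)
  }
  list(ids = ids, n_below = n_below, m_edge = m_edge)
}

#' The rho statistic
#'
#' Mean number of scope-eligible mutations separating a clade's root node
#' from each of its sampled descendants (samples sitting at internal
#' haplotype nodes count, with their path length). Computed in exact integer
#' arithmetic; the numerator and denominator are attached as attributes
#' `num` and `den`.
#'
#' @param tree A `mutation_tree`.
#' @param node Node id of the clade root.
#' @param scope Mutation-class filter: `"all"` (all substitutions),
#'   `"transitions"` or `"synonymous"`.
#' @return rho as a numeric scalar, with exact `num`/`den` attributes.
#' @export
rho_statistic <- function(tree, node = tree$root, scope = "all") {
  stopifnot(inherits(tree, "mutation_tree"))
  if (!node %in% tree$nodes$id) stop("node '", node, "' not in tree",
                                     call. = FALSE)
  sc <- .subtree_counts(tree, node, scope)
  n <- sc$n_below[node]
  if (n == 0L) stop("node '", node, "' has no sampled descendants",
                    call. = FALSE)
  # sum over samples of path length = sum over edges of m_e * n_e
  num <- sum(sc$m_edge[sc$ids] * sc$n_below[sc$ids])
  structure(num / n, num = unname(num), den = unname(n))
}

#' Saillard standard error of rho
#'
#' The standard error of the rho statistic from the tree's edge structure:
#' sigma^2 = sum over edges e below the node of m_e (n_e / n)^2, with m_e
#' the scope-eligible mutations on e, n_e the samples below e and n the
#' samples below the node. The exact integer numerator of sigma^2 (sum of
#' m_e n_e^2) and the denominator n are attached as attributes `num2` and
#' `den`.
#'
#' @inheritParams rho_statistic
#' @return sigma as a numeric scalar.
#' @export
saillard_sigma <- function(tree, node = tree$root, scope = "all") {
  stopifnot(inherits(tree, "mutation_tree"))
  if (!node %in% tree$nodes$id) stop("node '", node, "' not in tree",
                                     call. = FALSE)
  sc <- .subtree_counts(tree, node, scope)
  n <- sc$n_below[node]
  if (n == 0L) stop("node '", node, "' has no sampled descendants",
                    call. = FALSE)
  num2 <- sum(sc$m_edge[sc$ids] * as.numeric(sc$n_below[sc$ids])^2)
  structure(sqrt(num2) / n, num2 = unname(num2), den = unname(n))
}

#' Molecular clock models
#'
#' A clock converts rho (mutations) to calendar years. Three calibrated
#' constants are built in: the whole-mtDNA transition clock (one transition
#' per 3,624 years, selection-corrected), the synonymous clock (one
#' substitution per 7,884 years) and the founder-scan clock (one
#' substitution per 2,639 years, the average point-estimate rate over the
#' founder time depth). A purifying-selection correction can be supplied as
#' a monotone piecewise-linear table mapping uncorrected to corrected ages.
#'
#' @param name `"transition"`, `"synonymous"`, `"founder"`, or any label for
#'   a custom clock.
#' @param years_per_mutation Years per scope-eligible mutation; required for
#'   custom clocks.
#' @param scope Mutation-class filter the clock counts (see
#'   [rho_statistic()]).
#' @param correction Optional data frame with columns `uncorrected` and
#'   `corrected` (years): non-decreasing and fixing 0; applied by linear
#'   interpolation (linear extrapolation beyond the last row).
#' @return An object of class `clock_model`.
#' @examples
#' clock_model("transition")
#' clock_model("fast", years_per_mutation = 1000, scope = "all")
#' @export
clock_model <- function(name, years_per_mutation = NULL, scope = NULL,
                        correction = NULL) {
  builtin <- list(
    transition = list(ypm = 3624, scope = "transitions"),
    synonymous = list(ypm = 7884, scope = "synonymous"),
    founder    = list(ypm = 2639, scope = "all"))
  if (name %in% names(builtin)) {
    if (is.null(years_per_mutation)) years_per_mutation <- builtin[[name]]$ypm
    if (is.null(scope)) scope <- builtin[[name]]$scope
  }
  if (is.null(years_per_mutation) || years_per_mutation <= 0) {
    stop("years_per_mutation must be a positive number", call. = FALSE)
  }
  scope <- match.arg(scope, .SCOPES)
  if (!is.null(correction)) {
    stopifnot(all(c("uncorrected", "corrected") %in% names(correction)))
    correction <- correction[order(correction$uncorrected), ]
    if (any(diff(correction$corrected) < 0) ||
        any(correction$uncorrected < 0) ||
        .apply_correction(correction, 0) != 0) {
      stop("correction must be non-decreasing over non-negative ages and ",
           "fix 0", call. = FALSE)
    }
  }
  structure(list(name = name, years_per_mutation = years_per_mutation,
                 scope = scope, correction = correction),
            class = "clock_model")
}

.apply_correction <- function(correction, years) {
  if (is.null(correction)) return(years)
  x <- c(0, correction$uncorrected)
  y <- c(0, correction$corrected)
  kp <- !duplicated(x)
  x <- x[kp]; y <- y[kp]
  out <- approx(x, y, xout = pmin(years, max(x)), rule = 2)$y
  over <- years > max(x)
  if (any(over)) {
    # linear extrapolation with the last segment's slope
    k <- length(x)
    slope <- if (k >= 2 && x[k] > x[k - 1]) (y[k] - y[k - 1]) / (x[k] - x[k - 1]) else 1
    out[over] <- y[k] + slope * (years[over] - x[k])
  }
  out
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> %s: 1 mutation / %g years (scope: %s)%s\n",
              x$name, x$years_per_mutation, x$scope,
              if (is.null(x$correction)) "" else ", with correction table"))
  invisible(x)
}

#' Convert rho and sigma to a calendar age
#'
#' age = correction(rho x years_per_mutation); the 95% confidence interval
#' is correction((rho +/- 1.96 sigma) x years_per_mutation), truncated at 0.
#'
#' @param rho,sigma Non-negative reals (mutation units).
#' @param clock A [clock_model()].
#' @param n_tips Optional sample count, carried into the result.
#' @return An object of class `clade_age` with fields `rho`, `sigma`, `age`,
#'   `ci_low`, `ci_high` (years), `clock`, `n_tips`.
#' @export
convert_to_age <- function(rho, sigma = 0, clock, n_tips = NA_integer_) {
  stopifnot(inherits(clock, "clock_model"), rho >= 0, sigma >= 0)
  ypm <- clock$years_per_mutation
  raw <- pmax(0, c(rho, rho - 1.96 * sigma, rho + 1.96 * sigma) * ypm)
  cor <- .apply_correction(clock$correction, raw)
  structure(list(rho = as.numeric(rho), sigma = as.numeric(sigma),
                 age = cor[1], ci_low = cor[2], ci_high = cor[3],
                 clock = clock$name, n_tips = n_tips),
            class = "clade_age")
}

#' Date a clade of a mutation tree
#'
#' Computes rho and its Saillard standard error below a node and converts
#' them to years under a clock.
#'
#' @param tree A `mutation_tree`.
#' @param node Node id (default: the root).
#' @param clock A [clock_model()] (default: the transition clock).
#' @return A `clade_age`.
#' @export
date_clade <- function(tree, node = tree$root, clock = clock_model("transition")) {
  rho <- rho_statistic(tree, node, scope = clock$scope)
  sigma <- saillard_sigma(tree, node, scope = clock$scope)
  sc <- .subtree_counts(tree, node, clock$scope)
  convert_to_age(as.numeric(rho), as.numeric(sigma), clock,
                 n_tips = unname(sc$n_below[node]))
}

#' @export
print.clade_age <- function(x, ...) {
  cat(sprintf(
    "<clade_age> %.1f ka [%.1f-%.1f]  (rho=%.3f, sigma=%.3f, clock=%s%s)\n",
    x$age / 1000, x$ci_low / 1000, x$ci_high / 1000, x$rho, x$sigma,
    x$clock, if (is.na(x$n_tips)) "" else sprintf(", n=%d", x$n_tips)))
  invisible(x)
}
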