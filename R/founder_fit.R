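#' Founder analysis of a sink population
#'
#' The package's central estimator: given a rooted mutation tree whose
#' samples are labeled as source or sink, it identifies founder clusters
#' under an f-criterion, dates each cluster with the rho statistic under a
#' calibrated clock, accumulates the migration-time scan on a 200-year grid,
#' and (optionally) allocates each cluster probabilistically to stipulated
#' migration events.
#'
#' @param tree A rooted `mutation_tree` (see [resolve_to_tree()]).
#' @param populations Named vector or sample sheet mapping sample ids to
#'   population labels.
#' @param source,sink Population labels for the source and sink.
#' @param criterion Founder criterion (`"f0"`, `"f1"`, `"f2"`); default f1.
#' @param clock A [clock_model()]; default the founder-scan clock
#'   (1 mutation / 2,639 years).
#' @param grid_step Scan cell width in years.
#' @param events Optional stipulated migration times in years (e.g.
#'   `c(6500, 11000)`) for probabilistic allocation.
#' @param prior Optional per-event prior weights.
#' @param weight Scan weighting, `"frequency"` or `"equal"`.
#' @return An object of class `founder_analysis` with components
#'   `clusters`, `ages` (list of `clade_age`), `scan`, `allocation` (or
#'   `NULL`), and the settings used.
#' @seealso [identify_founders()], [migration_scan()],
#'   [allocate_to_migrations()]
#' @export
founder_analysis <- function(tree, populations, source, sink,
                             criterion = "f1",
                             clock = clock_model("founder"),
                             grid_step = 200, events = NULL, prior = NULL,
                             weight = c("frequency", "equal")) {
  weight <- match.arg(weight)
  clusters <- identify_founders(tree, populations, source, sink,
                                criterion = criterion, scope = clock$scope)
  if (!length(clusters)) {
    return(structure(list(clusters = clusters, ages = list(), scan = NULL,
                          allocation = NULL, clock = clock,
                          criterion = criterion, events = events,
                          source = source, sink = sink),
                     class = "founder_analysis"))
  }
  ages <- lapply(clusters, founder_age, clock = clock)
  names(ages) <- vapply(clusters, `[[`, character(1), "founder_id")
  scan <- migration_scan(clusters, clock = clock, grid_step = grid_step,
                         weight = weight)
  allocation <- if (!is.null(events)) {
    allocate_to_migrations(clusters, events, clock = clock, prior = prior)
  }
  structure(list(clusters = clusters, ages = ages, scan = scan,
                 allocation = allocation, clock = clock,
                 criterion = criterion, events = events, source = source,
                 sink = sink),
            class = "founder_analysis")
}

#' @export
print.founder_analysis <- function(x, ...) {
  cat(sprintf("Founder analysis: %s -> %s, criterion %s, clock %s\n",
              x$source, x$sink, x$criterion, x$clock$name))
  cat(sprintf("  %d founder cluster(s), %d sink sample(s)\n",
              length(x$clusters),
              sum(vapply(x$clusters, `[[`, integer(1), "n"))))
  if (!is.null(x$scan)) {
    pk <- scan_peaks(x$scan, 2L)
    cat(sprintf("  scan peaks: %s ka\n",
                paste(sprintf("%.1f", pk / 1000), collapse = ", ")))
  }
  if (!is.null(x$allocation)) {
    cat(sprintf("  allocation events (years): %s\n",
                paste(attr(x$allocation, "migration_times"),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @method summary founder_analysis
#' @export
summary.founder_analysis <- function(object, ...) {
  df <- as.data.frame(object$clusters)
  if (nrow(df)) {
    df$age <- vapply(object$ages, `[[`, numeric(1), "age")
    df$ci_low <- vapply(object$ages, `[[`, numeric(1), "ci_low")
    df$ci_high <- vapply(object$ages, `[[`, numeric(1), "ci_high")
    if (!is.null(object$allocation)) {
      df <- cbind(df, round(unclass(object$allocation), 3))
    }
  }
  structure(list(table = df, analysis = object),
            class = "summary.founder_analysis")
}

#' @export
print.summary.founder_analysis <- function(x, ...) {
  print(x$analysis)
  if (nrow(x$table)) {
    cat("\n")
    print(x$table, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @method coef founder_analysis
#' @export
coef.founder_analysis <- function(object, ...) {
  vapply(object$ages, `[[`, numeric(1), "age")
}

#' Plot a founder analysis
#'
#' Draws the migration-time scan (mass per 200-year cell against time in
#' ka) and, when events were stipulated, the per-cluster allocation
#' probabilities.
#'
#' @param x A `founder_analysis`.
#' @param which `"scan"`, `"allocation"`, or both.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @method plot founder_analysis
#' @export
plot.founder_analysis <- function(x, which = c("scan", "allocation"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if (is.null(x$scan)) {
    warning("nothing to plot: no founder clusters", call. = FALSE)
    return(invisible(x))
  }
  both <- length(which) == 2L && !is.null(x$allocation)
  if (both) {
    old <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(par(old))
  }
  if ("scan" %in% which) {
    g <- x$scan$grid
    plot(g$mid / 1000, g$mass, type = "l", xlab = "time (ka)",
         ylab = "probability mass",
         main = sprintf("Migration-time scan (%s -> %s)", x$source, x$sink),
         ...)
    if (!is.null(x$events)) {
      segments(x$events / 1000, 0, x$events / 1000, max(g$mass),
               lty = 2, col = "grey50")
    }
  }
  if ("allocation" %in% which && !is.null(x$allocation)) {
    barplot(t(unclass(x$allocation)), beside = FALSE,
            names.arg = rownames(x$allocation), las = 2,
            legend.text = colnames(x$allocation),
            ylab = "allocation probability",
            main = "Allocation to migration events")
  }
  invisible(x)
}
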