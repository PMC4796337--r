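#' Relative mutation-rate table
#'
#' Holds per-position relative mutation rates and per-class parsimony
#' weights used when building and resolving haplotype networks. The cost of
#' a mutation event at a character equals `class_weight / position_rate`, so
#' fast positions and transitions are the cheapest places to postulate
#' recurrent mutation. Defaults: uniform position rates, transversions
#' weighted 3x transitions and indels 5x.
#'
#' @param position_rates Named numeric vector of relative rates keyed by
#'   rCRS position (positions absent default to 1).
#' @param class_weights Named numeric vector with entries `transition`,
#'   `transversion`, `indel`; all strictly positive.
#' @return An object of class `rate_table`.
#' @examples
#' rate_table(c("16189" = 8, "152" = 5))
#' @export
rate_table <- function(position_rates = numeric(0),
                       class_weights = c(transition = 1, transversion = 3,
                                         indel = 5)) {
  if (length(position_rates)) {
    if (is.null(names(position_rates)) || any(position_rates <= 0)) {
      stop("position_rates must be a named vector of strictly positive rates",
           call. = FALSE)
    }
  }
  need <- c("transition", "transversion", "indel")
  if (!all(need %in% names(class_weights)) || any(class_weights <= 0)) {
    stop("class_weights must contain strictly positive 'transition', ",
         "'transversion' and 'indel' entries", call. = FALSE)
  }
  structure(list(position_rates = position_rates,
                 class_weights = class_weights[need]),
            class = "rate_table")
}

#' Read a rate table from TSV
#'
#' @param path TSV file with columns `position` and `rate`.
#' @param class_weights Passed to [rate_table()].
#' @return A [rate_table()].
#' @export
read_rate_table <- function(path, class_weights = c(transition = 1,
                                                    transversion = 3,
                                                    indel = 5)) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("position", "rate") %in% names(df))) {
    stop("rate table TSV needs columns 'position' and 'rate'", call. = FALSE)
  }
  rate_table(setNames(df$rate, df$position), class_weights)
}

# per-character event cost = class_weight / position_rate
.site_costs <- function(sites, rates) {
  stopifnot(inherits(rates, "rate_table"))
  pr <- rates$position_rates[as.character(sites$position)]
  pr[is.na(pr)] <- 1
  cw <- ifelse(sites$kind %in% c("insertion", "deletion"),
               rates$class_weights[["indel"]],
               ifelse(sites$kind == "transversion",
                      rates$class_weights[["transversion"]],
                      rates$class_weights[["transition"]]))
  unname(cw / pr)
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf(
    "<rate_table> %d position-specific rates; class weights ts=%g tv=%g indel=%g\n",
    length(x$position_rates), x$class_weights[["transition"]],
    x$class_weights[["transversion"]], x$class_weights[["indel"]]))
  invisible(x)
}
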