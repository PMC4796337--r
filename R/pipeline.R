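#' Run the whole founder pipeline from files
#'
#' Convenience wrapper chaining the stages: read sequences, score and
#' filter variants against the reference, build the reduced-median network
#' with the reference as outgroup, resolve it to a rooted mutation tree,
#' and run the founder analysis from source to sink.
#'
#' @param fasta FASTA of sequences in rCRS coordinates.
#' @param sample_sheet Sample sheet TSV (or data frame) with `sample_id`
#'   and `population`.
#' @param source,sink Population labels.
#' @param region rCRS interval the sequences cover.
#' @param reference Reference genome string.
#' @param rates A [rate_table()].
#' @param filter Apply the exclusion filters (default `TRUE`).
#' @param ... Passed to [founder_analysis()] (criterion, clock, events,
#'   grid_step, ...).
#' @return A list with `profiles`, `network`, `tree` and `fit` (the
#'   [founder_analysis()] object).
#' @export
founder_pipeline <- function(fasta, sample_sheet, source, sink,
                             region = c(1L, 16569L),
                             reference = mito_reference(),
                             rates = rate_table(), filter = TRUE, ...) {
  seqs <- read_sequences(fasta, sample_sheet, region = region)
  profiles <- lapply(seqs, call_variants, reference = reference)
  if (filter) profiles <- lapply(profiles, apply_exclusion_filters)
  network <- build_rm_network(profiles, rates = rates, add_reference = TRUE)
  tree <- resolve_to_tree(network, root = "reference")
  sheet <- read_sample_sheet(sample_sheet)
  fit <- founder_analysis(tree, sheet, source = source, sink = sink, ...)
  list(profiles = profiles, network = network, tree = tree, fit = fit)
}
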