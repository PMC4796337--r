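#' Construct a mitochondrial sequence record
#'
#' @param sample_id Sample identifier.
#' @param sequence Nucleotide sequence (IUPAC codes; `-` gaps allowed).
#'   Converted to upper case.
#' @param region Integer vector `c(start, end)`, 1-based closed interval in
#'   rCRS coordinates. Whole genome is `c(1, 16569)` (default).
#' @param population Population label (e.g. `"taiwan"`, `"mainland"`).
#' @param haplogroup Optional haplogroup label.
#' @return An object of class `mito_sequence`.
#' @export
mito_sequence <- function(sample_id, sequence, region = c(1L, 16569L),
                          population = NA_character_,
                          haplogroup = NA_character_) {
  stopifnot(length(sample_id) == 1L, length(sequence) == 1L)
  region <- as.integer(region)
  if (length(region) != 2L || anyNA(region) ||
      region[1] < 1L || region[2] > 16569L || region[1] > region[2]) {
    stop("region must be within [1, 16569] with start <= end", call. = FALSE)
  }
  sequence <- toupper(sequence)
  bad <- .non_iupac_chars(sequence)
  if (length(bad)) {
    stop(sprintf("sequence for sample '%s' contains non-IUPAC characters: %s",
                 sample_id, paste(unique(bad), collapse = " ")), call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id), sequence = sequence,
         region = region, population = as.character(population),
         haplogroup = as.character(haplogroup)),
    class = "mito_sequence")
}

.IUPAC <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N", "-", ".")

.non_iupac_chars <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  ch[!(ch %in% .IUPAC)]
}

#' @export
print.mito_sequence <- function(x, ...) {
  cat(sprintf("<mito_sequence> %s  [%d-%d]  %d bp  population=%s\n",
              x$sample_id, x$region[1], x$region[2], nchar(x$sequence),
              x$population))
  invisible(x)
}

#' Read aligned mitochondrial sequences with a sample sheet
#'
#' Reads a FASTA file of sequences in rCRS coordinates together with a
#' tab-separated sample sheet carrying population labels. Every FASTA record
#' must have a sample-sheet row; input order is preserved.
#'
#' @param fasta Path to a FASTA file.
#' @param sample_sheet Path to a TSV with columns `sample_id`, `population`
#'   and optionally `haplogroup`, or a data frame with those columns.
#' @param region Interval `c(start, end)` on the rCRS the sequences cover.
#' @return A list of [mito_sequence()] objects (empty, with a warning, for an
#'   empty FASTA).
#' @export
read_sequences <- function(fasta, sample_sheet, region = c(1L, 16569L)) {
  seqs <- Biostrings::readBStringSet(fasta)
  sheet <- read_sample_sheet(sample_sheet)
  if (length(seqs) == 0L) {
    warning("FASTA file '", fasta, "' contains no records", call. = FALSE)
    return(list())
  }
  ids <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(ids, sheet$sample_id)
  if (length(missing)) {
    stop("FASTA records missing from the sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    row <- sheet[match(ids[i], sheet$sample_id), ]
    hg <- if ("haplogroup" %in% names(sheet)) row$haplogroup else NA_character_
    out[[i]] <- mito_sequence(ids[i], as.character(seqs[[i]]), region = region,
                              population = row$population, haplogroup = hg)
  }
  names(out) <- ids
  out
}

#' Read a sample sheet
#'
#' @param x Path to a TSV file with columns `sample_id` and `population`
#'   (optionally `haplogroup`), or a data frame already holding them.
#' @return A data frame.
#' @export
read_sample_sheet <- function(x) {
  sheet <- if (is.data.frame(x)) x else
    read.delim(x, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "population")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sheet$sample_id <- as.character(sheet$sample_id)
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicated sample_id in sample sheet", call. = FALSE)
  }
  sheet
}

# write named character vector of sequences as FASTA
.write_fasta <- function(sequences, path, width = 70L) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}
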