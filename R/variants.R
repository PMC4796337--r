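.PURINES <- c("A", "G")
.PYRIMIDINES <- c("C", "T")

.sub_kind <- function(ref, alt) {
  ifelse((ref %in% .PURINES & alt %in% .PURINES) |
           (ref %in% .PYRIMIDINES & alt %in% .PYRIMIDINES),
         "transition", "transversion")
}

.variant_label <- function(position, ins_index, ref, alt, kind) {
  out <- character(length(position))
  sub <- kind %in% c("transition", "transversion")
  out[sub] <- paste0(ref[sub], position[sub], alt[sub])
  ins <- kind == "insertion"
  out[ins] <- paste0(position[ins], ".", ins_index[ins], alt[ins])
  del <- kind == "deletion"
  out[del] <- paste0(position[del], "d")
  out
}

# canonical empty variant table
.empty_variants <- function() {
  data.frame(position = integer(), ins_index = integer(),
             ref = character(), alt = character(), kind = character(),
             label = character(), functional_class = character(),
             stringsAsFactors = FALSE)
}

.make_variants <- function(position, ins_index, ref, alt, kind,
                           functional_class = NA_character_) {
  df <- data.frame(position = as.integer(position),
                   ins_index = as.integer(ins_index),
                   ref = ref, alt = alt, kind = kind,
                   functional_class = rep_len(functional_class,
                                              length(position)),
                   stringsAsFactors = FALSE)
  df$label <- .variant_label(df$position, df$ins_index, df$ref, df$alt, df$kind)
  o <- order(df$position, df$ins_index, df$alt)
  df <- df[o, c("position", "ins_index", "ref", "alt", "kind", "label",
                "functional_class")]
  rownames(df) <- NULL
  df
}

#' Construct a haplotype profile
#'
#' A haplotype profile is a sample's set of scored variants relative to the
#' reference, ordered by position, with a flag recording whether the
#' community exclusion filters have been applied.
#'
#' @param sample_id Sample identifier.
#' @param variants Data frame with columns `position`, `ins_index`, `ref`,
#'   `alt`, `kind` (and optionally `functional_class`); see
#'   [call_variants()].
#' @param filtered Logical; `TRUE` once [apply_exclusion_filters()] has run.
#' @param missing Integer count of positions masked by ambiguity codes.
#' @return An object of class `haplotype_profile`.
#' @export
haplotype_profile <- function(sample_id, variants = .empty_variants(),
                              filtered = FALSE, missing = 0L) {
  if (!nrow(variants)) variants <- .empty_variants()
  if (is.null(variants$functional_class)) {
    variants$functional_class <- NA_character_
  }
  if (is.null(variants$ins_index)) variants$ins_index <- 0L
  variants <- .make_variants(variants$position, variants$ins_index,
                             variants$ref, variants$alt, variants$kind,
                             variants$functional_class)
  stopifnot(all(variants$kind %in%
                  c("transition", "transversion", "insertion", "deletion")))
  if (anyDuplicated(variants$label)) {
    stop("duplicate variants in profile for sample '", sample_id, "'",
         call. = FALSE)
  }
  tr <- variants$kind %in% c("transition", "transversion")
  if (any(tr)) {
    chk <- .sub_kind(variants$ref[tr], variants$alt[tr])
    if (!all(chk == variants$kind[tr])) {
      stop("transition/transversion labels inconsistent with ref/alt",
           call. = FALSE)
    }
  }
  if (any(variants$position < 1L | variants$position > 16569L)) {
    stop("variant positions must lie in [1, 16569]", call. = FALSE)
  }
  structure(list(sample_id = as.character(sample_id), variants = variants,
                 filtered = isTRUE(filtered), missing = as.integer(missing)),
            class = "haplotype_profile")
}

#' @export
print.haplotype_profile <- function(x, ...) {
  cat(sprintf("<haplotype_profile> %s: %d variants%s%s\n", x$sample_id,
              nrow(x$variants), if (x$filtered) " (filtered)" else "",
              if (x$missing > 0) sprintf(", %d sites missing", x$missing)
              else ""))
  if (nrow(x$variants)) {
    cat(" ", paste(x$variants$label, collapse = " "), "\n")
  }
  invisible(x)
}

#' Score variants relative to the reference
#'
#' Compares a sequence with the reference over its declared region and
#' returns every difference as a variant in rCRS coordinates. Equal-length
#' input (gaps allowed) is compared column by column; shorter or longer
#' input is first aligned to the reference with a global pairwise alignment.
#' Ambiguity codes (N, R, Y, ...) never yield variants and are counted as
#' missing data. Indels are placed at their 3'-most equivalent position,
#' following mtDNA nomenclature (insertions `309.1C`, deletions `16166d`).
#'
#' @param seq A [mito_sequence()] object (or a plain character string, in
#'   which case `region` applies).
#' @param reference Reference genome string; defaults to the bundled
#'   synthetic reference ([mito_reference()]).
#' @param region Region used when `seq` is a bare string.
#' @param min_coverage Minimum fraction of the region that must be covered
#'   by unambiguous, aligned bases; below it an error is raised.
#' @param classify If `TRUE`, fill `functional_class` via
#'   [classify_functional()].
#' @param annotation Gene map used for classification.
#' @return An unfiltered [haplotype_profile()].
#' @export
call_variants <- function(seq, reference = mito_reference(),
                          region = c(1L, 16569L), min_coverage = 0.5,
                          classify = TRUE, annotation = mito_gene_map()) {
  if (is.character(seq)) seq <- mito_sequence("sample", seq, region = region)
  stopifnot(inherits(seq, "mito_sequence"))
  region <- seq$region
  ref_region <- substr(reference, region[1], region[2])
  width <- region[2] - region[1] + 1L
  s <- seq$sequence
  if (nchar(s) == width) {
    aln_ref <- ref_region
    aln_smp <- s
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::BString(gsub("[-.]", "", s)),
      Biostrings::BString(ref_region),
      type = "global", gapOpening = 10, gapExtension = 0.5)
    aln_smp <- as.character(Biostrings::alignedPattern(pa))
    aln_ref <- as.character(Biostrings::alignedSubject(pa))
  }
  .diff_aligned(seq$sample_id, aln_ref, aln_smp, offset = region[1] - 1L,
                width = width, min_coverage = min_coverage,
                classify = classify, annotation = annotation,
                reference = reference)
}

# walk two aligned strings (ref may contain '-' = insertion in sample;
# sample '-' or '.' = deletion); emit variants with 3'-normalised indels
.diff_aligned <- function(sample_id, aln_ref, aln_smp, offset, width,
                          min_coverage, classify, annotation, reference) {
  r <- strsplit(aln_ref, "", fixed = TRUE)[[1]]
  s <- strsplit(aln_smp, "", fixed = TRUE)[[1]]
  if (length(r) != length(s)) stop("alignment strings differ in length")
  s[s == "."] <- "-"
  s[s == "U"] <- "T"
  n <- length(r)
  # rCRS position of each alignment column (ref gaps carry previous position)
  pos <- offset + cumsum(r != "-")
  is_base <- s %in% c("A", "C", "G", "T")
  ambiguous <- !is_base & s != "-"
  covered <- sum(is_base & r != "-")
  if (covered / width < min_coverage) {
    stop(sprintf(
      "sample '%s': only %.1f%% of the region covered by unambiguous bases (minimum %.1f%%)",
      sample_id, 100 * covered / width, 100 * min_coverage), call. = FALSE)
  }

  positions <- integer(); ins_index <- integer()
  refs <- character(); alts <- character(); kinds <- character()

  # substitutions
  mm <- which(r != "-" & is_base & s != r)
  if (length(mm)) {
    positions <- c(positions, pos[mm])
    ins_index <- c(ins_index, rep(0L, length(mm)))
    refs <- c(refs, r[mm]); alts <- c(alts, s[mm])
    kinds <- c(kinds, .sub_kind(r[mm], s[mm]))
  }

  # deletions: runs of '-' in sample over ref bases, shifted 3'
  del_cols <- which(s == "-" & r != "-")
  if (length(del_cols)) {
    runs <- split(del_cols, cumsum(c(1L, diff(del_cols) != 1L)))
    for (run in runs) {
      i <- run[1]; j <- run[length(run)]
      # slide right while the next ref base repeats the first deleted base
      # and the sample carries it unchanged
      while (j + 1L <= n && r[j + 1L] != "-" && r[i] != "-" &&
             r[j + 1L] == r[i] && s[j + 1L] == r[j + 1L]) {
        i <- i + 1L; j <- j + 1L
      }
      cols <- seq(i, j)
      cols <- cols[r[cols] != "-"]
      positions <- c(positions, pos[cols])
      ins_index <- c(ins_index, rep(0L, length(cols)))
      refs <- c(refs, r[cols]); alts <- c(alts, rep("-", length(cols)))
      kinds <- c(kinds, rep("deletion", length(cols)))
    }
  }

  # insertions: runs of '-' in ref, shifted 3'
  ins_cols <- which(r == "-")
  if (length(ins_cols)) {
    runs <- split(ins_cols, cumsum(c(1L, diff(ins_cols) != 1L)))
    for (run in runs) {
      bases <- s[run]
      bases <- bases[bases != "-"]
      if (!length(bases)) next
      anchor <- pos[run[1]]  # inserted after this rCRS position
      j <- run[length(run)]
      # rotate rightwards through identical following bases
      while (j + 1L <= n && r[j + 1L] != "-" && s[j + 1L] == r[j + 1L] &&
             bases[1] == r[j + 1L]) {
        bases <- c(bases[-1], bases[1])
        anchor <- anchor + 1L
        j <- j + 1L
      }
      positions <- c(positions, rep(anchor, length(bases)))
      ins_index <- c(ins_index, seq_along(bases))
      refs <- c(refs, rep("-", length(bases)))
      alts <- c(alts, bases)
      kinds <- c(kinds, rep("insertion", length(bases)))
    }
  }

  vars <- .make_variants(positions, ins_index, refs, alts, kinds)
  if (classify && nrow(vars)) {
    vars$functional_class <- classify_functional(
      vars$position, vars$alt, ref = vars$ref, kind = vars$kind,
      annotation = annotation, reference = reference)
  }
  haplotype_profile(sample_id, vars, filtered = FALSE,
                    missing = sum(ambiguous))
}

#' Apply the community exclusion filters
#'
#' Removes the transition at position 16,519 and all length variants
#' (insertions and deletions) in the hypermutable C-stretches 16,180--16,193
#' and 309--315 from a haplotype profile, leaving every other variant
#' untouched. Idempotent.
#'
#' @param profile A [haplotype_profile()].
#' @return The filtered profile (`filtered` flag set).
#' @export
apply_exclusion_filters <- function(profile) {
  stopifnot(inherits(profile, "haplotype_profile"))
  v <- profile$variants
  drop <- (v$kind == "transition" & v$position == 16519L) |
    (v$kind %in% c("insertion", "deletion") &
       ((v$position >= 16180L & v$position <= 16193L) |
          (v$position >= 309L & v$position <= 315L)))
  profile$variants <- v[!drop, , drop = FALSE]
  rownames(profile$variants) <- NULL
  profile$filtered <- TRUE
  profile
}

#' Classify variants by functional class
#'
#' Assigns each variant to one of `synonymous`, `nonsynonymous`, `rRNA`,
#' `tRNA`, `control_region` or `intergenic` using the embedded gene map.
#' Substitutions in protein-coding genes are classified by translating the
#' affected codon before and after the change under the vertebrate
#' mitochondrial genetic code (light-strand genes are handled on the
#' complementary strand); indels in coding genes are reported as
#' `nonsynonymous` (frameshift-equivalent). Positions covered by two genes
#' take the first matching row of the annotation.
#'
#' @param position Integer vector of rCRS positions.
#' @param alt Alternate allele (base, or `-` for deletions).
#' @param ref Reference allele (unused for classification but accepted for a
#'   uniform interface).
#' @param kind Variant kind (`transition`, `transversion`, `insertion`,
#'   `deletion`); recycled.
#' @param annotation Gene map data frame, see [mito_gene_map()].
#' @param reference Reference genome string.
#' @return Character vector of functional classes.
#' @export
classify_functional <- function(position, alt, ref = NULL,
                                kind = "transition",
                                annotation = mito_gene_map(),
                                reference = mito_reference()) {
  position <- as.integer(position)
  if (any(position < 1L | position > 16569L)) {
    stop("positions must lie in [1, 16569]", call. = FALSE)
  }
  n <- length(position)
  alt <- rep_len(alt, n)
  kind <- rep_len(kind, n)
  code <- .mito_code()
  out <- character(n)
  for (i in seq_len(n)) {
    row <- annotation[annotation$start <= position[i] &
                        annotation$end >= position[i], , drop = FALSE]
    if (!nrow(row)) { out[i] <- "intergenic"; next }
    row <- row[1, ]
    out[i] <- switch(row$type,
      control = "control_region",
      rRNA = "rRNA",
      tRNA = "tRNA",
      protein = {
        if (kind[i] %in% c("insertion", "deletion")) {
          "nonsynonymous"
        } else {
          .codon_class(position[i], alt[i], row, reference, code)
        }
      })
  }
  out
}

.codon_class <- function(pos, alt, gene, reference, code) {
  if (gene$strand == "+") {
    off <- pos - gene$start
    cstart <- gene$start + 3L * (off %/% 3L)
    if (cstart + 2L > gene$end) return("nonsynonymous")  # incomplete codon
    codon <- substr(reference, cstart, cstart + 2L)
    idx <- off %% 3L + 1L
    mut <- codon
    substr(mut, idx, idx) <- alt
  } else {
    off <- gene$end - pos
    ci <- off %/% 3L
    gpos <- gene$end - 3L * ci - (0:2)     # genomic positions, 5'->3' on (-)
    if (min(gpos) < gene$start) return("nonsynonymous")
    codon <- .complement(paste(substring(reference, gpos, gpos), collapse = ""))
    idx <- off %% 3L + 1L
    mut <- codon
    substr(mut, idx, idx) <- .complement(alt)
  }
  aa0 <- unname(code[codon])
  aa1 <- unname(code[mut])
  if (is.na(aa0) || is.na(aa1)) return("nonsynonymous")
  if (identical(aa0, aa1)) "synonymous" else "nonsynonymous"
}

#' Combine haplotype profiles into a variant table
#'
#' @param profiles List of [haplotype_profile()] objects.
#' @return Data frame with one row per sample/variant (columns `sample_id`,
#'   `position`, `ref`, `alt`, `kind`, `label`, `functional_class`).
#' @export
variant_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    if (!nrow(p$variants)) return(NULL)
    cbind(sample_id = p$sample_id, p$variants)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- cbind(sample_id = character(), .empty_variants())
  }
  rownames(out) <- NULL
  out
}
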