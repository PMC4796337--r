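ref <- mito_reference()

test_that("read_sequences preserves records and enforces the sample sheet", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "x.fasta")
  writeLines(c(">a", substr(ref, 1, 60), ">b", substr(ref, 1, 60),
               ">c", substr(ref, 1, 60)), fa)
  sheet <- data.frame(sample_id = c("a", "b", "c"),
                      population = "pop1")
  seqs <- read_sequences(fa, sheet, region = c(1, 60))
  expect_length(seqs, 3L)
  expect_equal(names(seqs), c("a", "b", "c"))
  expect_s3_class(seqs[[1]], "mito_sequence")

  expect_error(read_sequences(fa, sheet[1:2, ], region = c(1, 60)), "c")

  empty <- file.path(dir, "empty.fasta")
  writeLines(character(0), empty)
  expect_warning(out <- read_sequences(empty, sheet), "no records")
  expect_length(out, 0L)
})

test_that("non-IUPAC characters are rejected with the record named", {
  expect_error(mito_sequence("bad1", "ACG?T"), "bad1")
  expect_error(mito_sequence("bad1", "ACG?T"), "\\?")
  expect_silent(mito_sequence("ok", "ACGTNRYWSKM-"))
})

test_that("a sequence identical to the reference yields no variants", {
  p <- call_variants(ref)
  expect_s3_class(p, "haplotype_profile")
  expect_identical(nrow(p$variants), 0L)
  expect_false(p$filtered)
})

test_that("single mismatches are scored with the right kind and label", {
  b <- substr(ref, 16223, 16223)
  ts <- c(A = "G", G = "A", C = "T", T = "C")[[b]]
  s <- ref; substr(s, 16223, 16223) <- ts
  p <- call_variants(s)
  expect_identical(p$variants$position, 16223L)
  expect_identical(p$variants$kind, "transition")
  expect_identical(p$variants$label, paste0(b, 16223, ts))
  expect_identical(p$variants$functional_class, "control_region")

  tv <- setdiff(c("A", "C", "G", "T"), c(b, ts))[1]
  s2 <- ref; substr(s2, 16223, 16223) <- tv
  expect_identical(call_variants(s2)$variants$kind, "transversion")
})

test_that("variant sets equal a brute-force columnwise diff on random mutants", {
  set.seed(42)
  for (rep in 1:15) {
    s <- ref
    pos <- sample(16569, sample(1:20, 1))
    for (p0 in pos) {
      b <- substr(s, p0, p0)
      substr(s, p0, p0) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }
    prof <- call_variants(s, classify = FALSE)
    rs <- strsplit(ref, "")[[1]]
    ss <- strsplit(s, "")[[1]]
    d <- which(rs != ss)
    expect_identical(prof$variants$position, as.integer(d))
    expect_identical(prof$variants$ref, rs[d])
    expect_identical(prof$variants$alt, ss[d])
  }
})

test_that("applying the called variants to the reference reconstructs the input", {
  set.seed(7)
  s <- ref
  pos <- sample(16569, 12)
  for (p0 in pos) {
    b <- substr(s, p0, p0)
    substr(s, p0, p0) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }
  prof <- call_variants(s, classify = FALSE)
  rebuilt <- ref
  for (k in seq_len(nrow(prof$variants))) {
    v <- prof$variants[k, ]
    substr(rebuilt, v$position, v$position) <- v$alt
  }
  expect_identical(rebuilt, s)
})

test_that("ambiguity codes yield no variants and are counted as missing", {
  s <- ref
  substr(s, 5000, 5000) <- "N"
  substr(s, 6000, 6000) <- "R"
  p <- call_variants(s)
  expect_identical(nrow(p$variants), 0L)
  expect_identical(p$missing, 2L)
  expect_error(call_variants(paste(rep("N", 16569), collapse = "")),
               "covered")
})

test_that("indels are placed at their 3'-most position", {
  run <- gregexpr("CCCC+", ref)[[1]]
  st <- run[1]
  en <- st + attr(run, "match.length")[1] - 1L
  # deletion of the first C in the run is reported at the run's 3' end
  s <- ref; substr(s, st, st) <- "-"
  p <- call_variants(s, classify = FALSE)
  expect_identical(p$variants$kind, "deletion")
  expect_identical(p$variants$position, as.integer(en))
  expect_identical(p$variants$label, paste0(en, "d"))
  # insertion of a C before the run is reported after the run's 3' end
  s2 <- paste0(substr(ref, 1, st - 1), "C", substr(ref, st, 16569))
  p2 <- call_variants(s2, classify = FALSE)
  expect_identical(p2$variants$kind, "insertion")
  expect_identical(p2$variants$label, paste0(en, ".1C"))
})

test_that("exclusion filters remove exactly the prescribed variants", {
  b16519 <- substr(ref, 16519, 16519)
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  prof <- haplotype_profile("x", data.frame(
    position = c(16519L, 310L, 16223L, 16185L),
    ins_index = c(0L, 1L, 0L, 0L),
    ref = c(b16519, "-", substr(ref, 16223, 16223), substr(ref, 16185, 16185)),
    alt = c(ts[[b16519]], "C", ts[[substr(ref, 16223, 16223)]], "-"),
    kind = c("transition", "insertion", "transition", "deletion")))
  out <- apply_exclusion_filters(prof)
  expect_true(out$filtered)
  expect_identical(out$variants$position, 16223L)
  # idempotent
  expect_identical(apply_exclusion_filters(out)$variants, out$variants)
  # empty profile stays empty
  expect_identical(nrow(apply_exclusion_filters(
    haplotype_profile("e"))$variants), 0L)
})

test_that("a transversion at 16519 and substitutions in the C-stretches survive", {
  b <- substr(ref, 16519, 16519)
  tv <- setdiff(c("A", "C", "G", "T"),
                c(b, c(A = "G", G = "A", C = "T", T = "C")[[b]]))[1]
  b2 <- substr(ref, 311, 311)
  prof <- haplotype_profile("x", data.frame(
    position = c(16519L, 311L), ins_index = 0L,
    ref = c(b, b2),
    alt = c(tv, c(A = "G", G = "A", C = "T", T = "C")[[b2]]),
    kind = c("transversion", "transition")))
  out <- apply_exclusion_filters(prof)
  expect_identical(out$variants$position, c(311L, 16519L))
})

test_that("functional classification matches a translate-and-compare oracle", {
  ann <- mito_gene_map()
  genes <- ann[ann$type == "protein", ]
  code <- Biostrings::getGeneticCode("2")
  set.seed(11)
  tested <- 0L
  for (rep in 1:1000) {
    g <- genes[sample(nrow(genes), 1), ]
    ncod <- (g$end - g$start + 1) %/% 3
    pos <- sample(g$start:(g$start + ncod * 3 - 1), 1)
    first <- ann[ann$start <= pos & ann$end >= pos, ][1, ]
    if (first$gene != g$gene) next       # overlapped by an earlier gene
    b <- substr(ref, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    got <- classify_functional(pos, alt)
    gseq <- substr(ref, g$start, g$start + ncod * 3 - 1)
    mut <- gseq
    substr(mut, pos - g$start + 1, pos - g$start + 1) <- alt
    tr <- function(x) {
      d <- Biostrings::DNAString(x)
      if (g$strand == "-") d <- Biostrings::reverseComplement(d)
      as.character(Biostrings::translate(d, genetic.code = code,
                                         no.init.codon = TRUE))
    }
    expected <- if (tr(gseq) == tr(mut)) "synonymous" else "nonsynonymous"
    expect_identical(got, expected,
                     info = sprintf("%s %d %s>%s", g$gene, pos, b, alt))
    tested <- tested + 1L
  }
  expect_gt(tested, 900L)
})

test_that("non-coding classes come from coordinate ranges", {
  expect_identical(classify_functional(16223, "C"), "control_region")
  expect_identical(classify_functional(300, "G"), "control_region")
  expect_identical(classify_functional(1000, "G"), "rRNA")
  expect_identical(classify_functional(600, "G"), "tRNA")
  expect_identical(classify_functional(5850, "G"), "tRNA")  # light strand
  # indel inside a protein gene is nonsynonymous-equivalent
  expect_identical(classify_functional(4000, "-", kind = "deletion"),
                   "nonsynonymous")
  expect_error(classify_functional(0, "A"), "16,569|16569")
})

test_that("variant_table combines profiles", {
  p1 <- call_variants(ref)
  b <- substr(ref, 100, 100)
  s <- ref
  substr(s, 100, 100) <- c(A = "G", G = "A", C = "T", T = "C")[[b]]
  p2 <- call_variants(mito_sequence("z", s))
  tab <- variant_table(list(p1, p2))
  expect_identical(tab$sample_id, "z")
  expect_identical(tab$position, 100L)
})
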