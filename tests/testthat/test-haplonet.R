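test_that("identical profiles collapse to a single node with no links", {
  profs <- list(transition_profile("a", c(150, 250)),
                transition_profile("b", c(150, 250)),
                transition_profile("c", c(150, 250)))
  net <- build_rm_network(profs)
  expect_identical(nrow(net$nodes), 1L)
  expect_identical(nrow(net$edges), 0L)
  expect_identical(net$nodes$multiplicity, 3L)
})

test_that("three haplotypes one step from a shared type form a star", {
  profs <- list(transition_profile("a", 101), transition_profile("b", 102),
                transition_profile("c", 103), transition_profile("d", integer(0)))
  net <- build_rm_network(profs)
  expect_identical(nrow(net$nodes), 4L)
  expect_identical(nrow(net$edges), 3L)
  center <- net$samples$node[net$samples$sample_id == "d"]
  deg <- table(c(net$nodes$id[net$edges$from], net$nodes$id[net$edges$to]))
  expect_identical(unname(deg[[center]]), 3L)
})

test_that("two incompatible characters give a reticulation with both resolutions", {
  mat <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  net <- build_rm_network(profiles_from_matrix(mat))
  expect_identical(nrow(net$nodes), 4L)
  expect_identical(nrow(net$edges), 4L)        # a 4-cycle
  expect_equal(as.integer(sort(table(unlist(net$edges$sites)))), c(2L, 2L))
  # both single-recurrence resolutions are spanning trees of the square
  tr <- resolve_to_tree(net, root = net$samples$node[1])
  expect_identical(tr$length, 3L)
})

test_that("multi-allelic positions are split into binary characters", {
  ref <- mito_reference()
  b <- substr(ref, 400, 400)
  alts <- setdiff(c("A", "C", "G", "T"), b)
  mk <- function(id, alt) {
    haplotype_profile(id, data.frame(position = 400L, ins_index = 0L,
                                     ref = b, alt = alt,
                                     kind = mitofounder:::.sub_kind(b, alt)))
  }
  expect_warning(net <- build_rm_network(list(mk("a", alts[1]),
                                              mk("b", alts[2]),
                                              haplotype_profile("c"))),
                 "400")
  expect_identical(nrow(net$sites), 2L)
})

test_that("the network is invariant under permutation of input profiles", {
  set.seed(31)
  mat <- matrix(rbinom(6 * 7, 1, 0.4), 6, 7)
  mat <- unique(rbind(mat, 0))
  profs <- profiles_from_matrix(mat)
  net1 <- build_rm_network(profs)
  net2 <- build_rm_network(rev(profs))
  expect_identical(nrow(net1$nodes), nrow(net2$nodes))
  lab1 <- sort(vapply(net1$edges$sites, paste, character(1), collapse = "+"))
  lab2 <- sort(vapply(net2$edges$sites, paste, character(1), collapse = "+"))
  expect_identical(lab1, lab2)
})

test_that("a network that is already a tree resolves to itself", {
  # caterpillar: a -101- b -102- c -103- d
  profs <- list(transition_profile("a", integer(0)),
                transition_profile("b", 101),
                transition_profile("c", c(101, 102)),
                transition_profile("d", c(101, 102, 103)))
  net <- build_rm_network(profs)
  expect_identical(nrow(net$edges), 3L)
  tr <- resolve_to_tree(net, root = "a")
  expect_identical(tr$length, 3L)
  expect_identical(nrow(tr$edges), 3L)
  expect_identical(tr$root, net$samples$node[net$samples$sample_id == "a"])
})

test_that("equally parsimonious resolutions recur at the fastest position", {
  mat <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  profs <- profiles_from_matrix(mat)     # sites at positions 101 and 102
  net <- build_rm_network(profs)         # uniform rates: reticulation kept
  rts <- rate_table(position_rates = c("101" = 5, "102" = 1))
  tr <- resolve_to_tree(net, rates = rts, root = net$samples$node[1])
  tally <- table(unlist(tr$edges$sites))
  lab101 <- net$sites$label[net$sites$position == 101]
  lab102 <- net$sites$label[net$sites$position == 102]
  expect_identical(unname(tally[[lab101]]), 2L)
  expect_identical(unname(tally[[lab102]]), 1L)
})

test_that("reduction removes the disfavoured resolution at the threshold", {
  mat <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  profs <- profiles_from_matrix(mat)
  rts <- rate_table(position_rates = c("101" = 5, "102" = 1))
  net <- build_rm_network(profs, rates = rts, reduction_threshold = 2)
  expect_identical(nrow(net$edges), 3L)  # square opened
  # the surviving resolution makes the fast site recurrent
  tally <- table(unlist(net$edges$sites))
  lab101 <- net$sites$label[net$sites$position == 101]
  expect_identical(unname(tally[[lab101]]), 2L)
  # below the threshold the reticulation is kept
  net2 <- build_rm_network(profs, rates = rts, reduction_threshold = 10)
  expect_identical(nrow(net2$edges), 4L)
})

test_that("parsimony length is bounded below by the number of characters", {
  set.seed(77)
  for (rep in 1:5) {
    mat <- unique(rbind(matrix(rbinom(5 * 6, 1, 0.4), 5, 6), 0))
    mat <- mat[, colSums(mat) > 0, drop = FALSE]
    if (ncol(mat) < 2) next
    profs <- profiles_from_matrix(mat)
    net <- build_rm_network(profs)
    tr <- resolve_to_tree(net, root = net$samples$node[nrow(mat)])
    expect_gte(tr$length, ncol(mat))
  }
})

test_that("clade annotation labels the most derived matching haplogroup", {
  profs <- list(transition_profile("a", integer(0)),
                transition_profile("b", 101),
                transition_profile("c", c(101, 102)),
                transition_profile("d", c(101, 102, 103)))
  net <- build_rm_network(profs)
  tr <- resolve_to_tree(net, root = net$samples$node[1])
  labs <- net$sites$label
  motifs <- data.frame(
    haplogroup = c("B4", "B4b1"),
    motif = c(labs[1], paste(labs[1], labs[2], sep = ", ")))
  tr2 <- annotate_clades(tr, motifs)
  node_b <- tr2$samples$node[tr2$samples$sample_id == "b"]
  node_c <- tr2$samples$node[tr2$samples$sample_id == "c"]
  node_d <- tr2$samples$node[tr2$samples$sample_id == "d"]
  expect_identical(tr2$nodes$clade[tr2$nodes$id == node_b], "B4")
  expect_identical(tr2$nodes$clade[tr2$nodes$id == node_c], "B4b1")
  expect_identical(tr2$nodes$clade[tr2$nodes$id == node_d], "B4b1")
  expect_identical(clade_node(tr2, "B4"), node_b)
  # empty motif table leaves the tree unchanged
  expect_identical(annotate_clades(tr, motifs[0, ])$nodes$clade,
                   tr$nodes$clade)
  # unmatched motif warns with the haplogroup name
  expect_warning(annotate_clades(tr, data.frame(haplogroup = "Z9",
                                                motif = "A9999G")), "Z9")
})

test_that("network and tree exports are well formed", {
  profs <- list(transition_profile("a", 101), transition_profile("b", 102),
                transition_profile("r", integer(0)))
  net <- build_rm_network(profs)
  dir <- withr::local_tempdir()
  tsv <- write_network_tsv(net, file.path(dir, "net.tsv"))
  tab <- read.delim(tsv)
  expect_identical(nrow(tab), nrow(net$edges))
  gml <- write_network_gml(net, file.path(dir, "net.gml"))
  expect_true(any(grepl("^graph", readLines(gml))))

  tr <- resolve_to_tree(net, root = "r")
  nwk <- write_tree_newick(tr)
  expect_match(nwk, "^\\(.*\\).*;$")
  expect_match(nwk, "a:0")
  expect_match(nwk, "&mut=")
  path <- file.path(dir, "tree.nwk")
  write_tree_newick(tr, path)
  expect_identical(readLines(path), nwk)
})
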