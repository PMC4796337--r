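# Build a rooted tree from transition profiles with the reference outgroup,
# returning the tree plus a population lookup.
build_labeled_tree <- function(spec) {
  # spec: data.frame(sample_id, population, positions (list))
  profs <- lapply(seq_len(nrow(spec)), function(i)
    transition_profile(spec$sample_id[i], spec$positions[[i]]))
  net <- build_rm_network(profs, add_reference = TRUE)
  tree <- resolve_to_tree(net, root = "reference")
  list(tree = tree, pops = setNames(spec$population, spec$sample_id))
}

two_intro_spec <- function() {
  # source backbone: 101; introduction A at {101,102} with sink diversity
  # 104/105; introduction B at {103} with sink diversity 106/107;
  # each founder haplotype has a derived source branch (f1 satisfied)
  data.frame(
    sample_id = c("src1", "src2", "src3", "src4", "src5",
                  "snkA1", "snkA2", "snkB1", "snkB2"),
    population = c(rep("china", 5), rep("taiwan", 4)),
    positions = I(list(
      c(101),                 # src1
      c(101, 102),            # src2: founder A haplotype in source
      c(101, 102, 110),       # src3: derived source branch under A
      c(103),                 # src4: founder B haplotype in source
      c(103, 111),            # src5: derived source branch under B
      c(101, 102, 104),       # snkA1
      c(101, 102, 105),       # snkA2
      c(103, 106),            # snkB1
      c(103, 106, 107))))     # snkB2
}

test_that("a hand-built tree with two introductions yields two clusters", {
  bl <- build_labeled_tree(two_intro_spec())
  cl <- identify_founders(bl$tree, bl$pops, source = "china",
                          sink = "taiwan", criterion = "f1")
  expect_length(cl, 2L)
  df <- as.data.frame(cl)
  df <- df[order(df$n, df$m), ]
  # cluster A: two sink tips, one private mutation each (104, 105)
  expect_identical(df$n, c(2L, 2L))
  expect_identical(sort(df$m), c(2, 3))
  # cluster B: tips at {106} and {106,107}: path counts 1 and 2
  expect_identical(sort(df$rho), c(1, 1.5))
  expect_true(all(df$source_derived_branches >= 1L))
  expect_true(all(df$criterion_met))
})

test_that("f0 accepts a founder attested only by identical source samples", {
  # founder haplotype {101} sampled in source but with no derived source
  # branch; one sink tip below it
  spec <- data.frame(
    sample_id = c("src1", "src2", "snk1"),
    population = c("china", "china", "taiwan"),
    positions = I(list(c(101), c(102), c(101, 104))))
  bl <- build_labeled_tree(spec)
  cl0 <- identify_founders(bl$tree, bl$pops, "china", "taiwan",
                           criterion = "f0")
  cl1 <- identify_founders(bl$tree, bl$pops, "china", "taiwan",
                           criterion = "f1")
  f0 <- as.data.frame(cl0)
  f1 <- as.data.frame(cl1)
  # under f0 the founder sits at {101} (m = 1); under f1 it is pushed to a
  # deeper ancestor with a derived source branch, absorbing more mutations
  expect_identical(f0$m, 1)
  expect_gt(f1$m, f0$m)
  expect_identical(f0$source_derived_branches, 0L)
})

test_that("no sink samples gives an empty result", {
  spec <- data.frame(sample_id = c("a", "b"),
                     population = c("china", "china"),
                     positions = I(list(c(101), c(102))))
  bl <- build_labeled_tree(spec)
  cl <- identify_founders(bl$tree, bl$pops, "china", "taiwan")
  expect_length(cl, 0L)
  expect_s3_class(cl, "founder_clusters")
})

test_that("an unlabeled sample is reported by name", {
  bl <- build_labeled_tree(two_intro_spec())
  pops <- bl$pops[-3]
  expect_error(identify_founders(bl$tree, pops, "china", "taiwan"), "src3")
})

test_that("clusters partition the sink samples for every criterion", {
  fx <- make_fixture("two-pulse-taiwan", dir = withr::local_tempdir())
  res <- suppressWarnings(founder_pipeline(
    fx$paths$fasta, fx$paths$samples, source = "mainland", sink = "taiwan"))
  sheet <- read.delim(fx$paths$samples)
  sink_ids <- sheet$sample_id[sheet$population == "taiwan"]
  counts <- integer(0)
  for (crit in c("f0", "f1", "f2")) {
    cl <- identify_founders(res$tree, sheet, "mainland", "taiwan",
                            criterion = crit)
    got <- sort(unlist(lapply(cl, `[[`, "sink_ids")))
    expect_identical(got, sort(sink_ids))          # disjoint and covering
    counts <- c(counts, length(cl))
  }
  # tightening the criterion never increases the number of founders
  expect_true(all(diff(counts) <= 0))
})

test_that("founder ages use the founder-scan clock", {
  cl <- structure(list(founder_id = "F1", founder_node = "X",
                       source_derived_branches = 1L, sink_ids = "t",
                       n = 1L, m = 1, rho = 1, sigma = 1,
                       criterion_met = TRUE, back_migration = FALSE),
                  class = "founder_cluster")
  expect_equal(founder_age(cl)$age, 2639)
  cl$rho <- 0; cl$sigma <- 0
  expect_equal(founder_age(cl)$age, 0)
  cl$rho <- 2.5
  expect_equal(founder_age(cl)$age, 6597.5)
})

mk_cluster <- function(id, n, m) {
  structure(list(founder_id = id, founder_node = id,
                 source_derived_branches = 1L,
                 sink_ids = paste0(id, seq_len(n)), n = as.integer(n),
                 m = m, rho = m / n, sigma = sqrt(m) / n,
                 criterion_met = TRUE, back_migration = FALSE),
            class = "founder_cluster")
}

test_that("the migration scan integrates normal kernels per 200-year cell", {
  ck <- clock_model("unit", years_per_mutation = 1000, scope = "all")
  # sigma -> 0: all mass lands in the cell containing the age
  cl <- mk_cluster("F1", 4, 24)          # age 6000, sigma 1.22
  cl$sigma <- 0
  sc <- migration_scan(list(cl), ck, grid_end = 10000)
  expect_equal(sum(sc$grid$mass), 1, tolerance = 1e-12)
  expect_equal(sc$grid$mass[sc$grid$grid_time == 6000], 1)
  # two equal clusters at 4,000 and 10,000: half the mass on each side
  c1 <- mk_cluster("F1", 4, 16); c1$sigma <- 0.2   # age 4000, sd 200
  c2 <- mk_cluster("F2", 4, 40); c2$sigma <- 0.2   # age 10000, sd 200
  sc2 <- migration_scan(list(c1, c2), ck, grid_end = 16000)
  expect_equal(sum(sc2$grid$mass), 1, tolerance = 1e-9)
  left <- sum(sc2$grid$mass[sc2$grid$mid < 7000])
  expect_equal(left, 0.5, tolerance = 1e-9)
  expect_equal(sort(scan_peaks(sc2, 2)), c(3900, 9900), tolerance = 200)
  # truncation warns and renormalises
  expect_warning(sc3 <- migration_scan(list(c2), ck, grid_end = 10000),
                 "truncated")
  expect_equal(sum(sc3$grid$mass), 1, tolerance = 1e-12)
})

test_that("equal weighting is available as an alternative", {
  ck <- clock_model("unit", years_per_mutation = 1000, scope = "all")
  c1 <- mk_cluster("F1", 9, 18); c1$sigma <- 0.1   # age 2000, big cluster
  c2 <- mk_cluster("F2", 1, 8);  c2$sigma <- 0.1   # age 8000, singleton
  fr <- migration_scan(list(c1, c2), ck, grid_end = 12000)
  eq <- migration_scan(list(c1, c2), ck, grid_end = 12000, weight = "equal")
  m_fr <- sum(fr$grid$mass[fr$grid$mid < 5000])
  m_eq <- sum(eq$grid$mass[eq$grid$mid < 5000])
  expect_equal(m_fr, 0.9, tolerance = 1e-6)
  expect_equal(m_eq, 0.5, tolerance = 1e-6)
})

test_that("allocation follows the Poisson likelihood of sink mutation counts", {
  ck <- clock_model("founder")
  cl <- mk_cluster("F1", 1, 2)
  al <- allocate_to_migrations(list(cl), c(6500, 11000), ck)
  lam <- c(6500, 11000) / 2639
  manual <- exp(-lam) * lam^2 / 2
  expect_equal(as.vector(al), manual / sum(manual), tolerance = 1e-12)
  # single event: probability 1 regardless of the data
  expect_equal(as.vector(allocate_to_migrations(list(cl), 6500, ck)), 1)
  # identical stipulated times: symmetric split
  expect_equal(as.vector(allocate_to_migrations(list(cl), c(7000, 7000), ck)),
               c(0.5, 0.5))
  # rescaling the prior changes nothing
  a1 <- allocate_to_migrations(list(cl), c(6500, 11000), ck,
                               prior = c(1, 2))
  a2 <- allocate_to_migrations(list(cl), c(6500, 11000), ck,
                               prior = c(10, 20))
  expect_equal(as.vector(a1), as.vector(a2), tolerance = 1e-12)
  # rows are normalised
  expect_equal(rowSums(al), 1, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("founder_analysis bundles clusters, ages, scan and allocation", {
  bl <- build_labeled_tree(two_intro_spec())
  fit <- founder_analysis(bl$tree, bl$pops, source = "china",
                          sink = "taiwan", events = c(6500, 11000))
  expect_s3_class(fit, "founder_analysis")
  expect_length(fit$clusters, 2L)
  expect_identical(names(coef(fit)), c("F1", "F2"))
  expect_equal(unname(coef(fit)),
               vapply(fit$ages, `[[`, numeric(1), "age"),
               ignore_attr = TRUE)
  s <- summary(fit)
  expect_identical(nrow(s$table), 2L)
  expect_true(all(c("T6500", "T11000") %in% colnames(s$table)))
  expect_output(print(fit), "2 founder cluster")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
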