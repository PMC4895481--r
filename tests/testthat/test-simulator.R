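zero_rates <- c(inversion = 0, translocation = 0, fusion = 0, fission = 0,
                deletion = 0, insertion = 0, duplication = 0)

test_that("with all event rates zero every leaf equals the root genome", {
  p <- sim_params(rates = zero_rates, n_families = 60L, n_chrom = 3L,
                  seed = 5L)
  sim <- simulate_genomes(p)
  expect_equal(nrow(sim$log), 0L)
  sigs <- lapply(sim$genomes, function(g) {
    lapply(g$orders, function(o) paste(o$sign, o$family))
  })
  for (g in sigs[-1]) expect_equal(g, sigs[[1]])
  expect_equal(sum(vapply(sim$genomes[[1]]$orders, nrow, 0L)), 60L)
  expect_length(sim$genomes[[1]]$orders, 3L)
})

test_that("simulation is reproducible under a fixed seed", {
  p <- sim_params(n_families = 80L, n_chrom = 4L, seed = 17L)
  s1 <- simulate_genomes(p)
  s2 <- simulate_genomes(p)
  expect_identical(s1, s2)
  f1 <- fragment_target(s1$genomes$Target, p)
  f2 <- fragment_target(s2$genomes$Target, p)
  expect_identical(f1, f2)
  m1 <- simulate_maps(f1$truth, p)
  m2 <- simulate_maps(f2$truth, p)
  expect_identical(m1, m2)
})

test_that("a single inversion changes the breakpoint count as expected", {
  root <- list(chr01 = data.frame(family = sprintf("f%02d", 1:10),
                                  sign = 1L, stringsAsFactors = FALSE))
  adj_of <- function(g) {
    o <- g$chr01
    reference_adjacencies(make_order("G", c1 = ord_df(o$family, o$sign)))
  }
  env <- new.env(); env$ins <- 0L; env$fis <- 0L
  for (s in 1:20) {
    set.seed(s)
    res <- scaflink:::apply_event(root, "inversion", 5L, env)
    breaks <- length(setdiff(adj_of(root), adj_of(res$genome)))
    at_start <- res$pos == 1L
    at_end <- res$pos + res$span - 1L == 10L
    expect_equal(breaks, 2L - at_start - at_end, info = paste("seed", s))
  }
})

test_that("gene occurrences are conserved according to the event log", {
  p <- sim_params(rates = c(inversion = 3, translocation = 1, fusion = 0,
                            fission = 0, deletion = 2, insertion = 2,
                            duplication = 1),
                  n_families = 150L, n_chrom = 4L, seed = 23L)
  sim <- simulate_genomes(p)
  tree <- p$tree
  nt <- length(tree$tip.label)
  root_count <- 150L
  for (tip_i in seq_len(nt)) {
    tip <- tree$tip.label[tip_i]
    path <- ape::nodepath(tree, from = nt + 1L, to = tip_i)[-1L]
    labels <- ifelse(path <= nt, tree$tip.label[pmin(path, nt)],
                     paste0("node", path))
    lg <- sim$log[sim$log$branch %in% labels &
                    sim$log$status == "applied", , drop = FALSE]
    expected <- root_count +
      sum(lg$span[lg$type == "insertion"]) +
      sum(lg$span[lg$type == "duplication"]) -
      sum(lg$span[lg$type == "deletion"])
    got <- sum(vapply(sim$genomes[[tip]]$orders, nrow, 0L))
    expect_equal(got, expected, info = tip)
  }
})

test_that("fragment_target splits at the stated breaks with true adjacencies", {
  p <- sim_params(n_families = 10L, n_chrom = 1L, seed = 3L)
  target <- make_order("Target", chr01 = ord_df(sprintf("f%02d", 1:10),
                                                rep(1, 10)))
  frag <- fragment_target(target, p, breaks = list(chr01 = c(4L, 7L)))
  sizes <- vapply(frag$order$orders, nrow, 0L)
  expect_equal(unname(sizes), c(4L, 3L, 3L))
  expect_equal(nrow(frag$truth$adjacencies), 2L)
  expect_equal(frag$truth$adjacencies$key,
               c("chr01_s01:3p--chr01_s02:5p", "chr01_s02:3p--chr01_s03:5p"))

  # zero breaks: one scaffold per chromosome, empty truth set
  p0 <- sim_params(n_families = 10L, n_chrom = 1L, breaks_per_chrom = 0,
                   seed = 3L)
  frag0 <- fragment_target(target, p0)
  expect_length(frag0$order$orders, 1L)
  expect_equal(nrow(frag0$truth$adjacencies), 0L)

  # saturation: every inter-gene position broken
  fragS <- fragment_target(target, p, breaks = list(chr01 = 1:9))
  expect_true(all(vapply(fragS$order$orders, nrow, 0L) == 1L))
})

test_that("re-joining truth adjacencies reconstructs the unfragmented order", {
  p <- sim_params(n_families = 120L, n_chrom = 3L, breaks_per_chrom = 6,
                  seed = 29L)
  sim <- simulate_genomes(p)
  target <- sim$genomes$Target
  frag <- fragment_target(target, p)
  rejoined <- lapply(split(frag$truth$membership,
                           frag$truth$membership$chrom), function(mem) {
    mem <- mem[order(mem$ordinal), ]
    do.call(rbind, lapply(mem$scaffold_id,
                          function(s) frag$order$orders[[s]]))
  })
  for (ch in names(target$orders)) {
    expect_equal(rejoined[[ch]]$family, target$orders[[ch]]$family)
    expect_equal(rejoined[[ch]]$sign, target$orders[[ch]]$sign)
  }
})

test_that("noise-free maps are identical across sexes and increasing in true order", {
  p <- sim_params(n_families = 100L, n_chrom = 4L, breaks_per_chrom = 4,
                  dropout = 0, noise_sd = 0, swap_prob = 0, seed = 37L)
  sim <- simulate_genomes(p)
  frag <- fragment_target(sim$genomes$Target, p)
  maps <- simulate_maps(frag$truth, p)
  male <- as.data.frame(maps$male)[, -1]
  female <- as.data.frame(maps$female)[, -1]
  male$marker_id <- sub("^male_", "", male$marker_id)
  female$marker_id <- sub("^female_", "", female$marker_id)
  expect_equal(male, female)
  for (lg in unique(maps$male$lg_id)) {
    m <- maps$male[maps$male$lg_id == lg, ]
    pos <- tapply(m$position_cM, m$scaffold_id, unique)
    mem <- frag$truth$membership[frag$truth$membership$chrom == lg, ]
    ordinals <- mem$ordinal[match(names(pos), mem$scaffold_id)]
    expect_false(is.unsorted(as.numeric(pos)[order(ordinals)],
                             strictly = TRUE))
  }
})

test_that("full dropout yields empty maps", {
  p <- sim_params(n_families = 40L, n_chrom = 2L, dropout = 1, seed = 41L)
  sim <- simulate_genomes(p)
  frag <- fragment_target(sim$genomes$Target, p)
  maps <- simulate_maps(frag$truth, p)
  expect_equal(nrow(maps$male), 0L)
  expect_equal(nrow(maps$female), 0L)
})

test_that("evaluate_links counts orientation-aware true positives", {
  truth <- structure(list(adjacencies = data.frame(
    ext_a = c("A:3p", "B:3p", "C:3p"),
    ext_b = c("B:5p", "C:5p", "D:5p"),
    key = c("A:3p--B:5p", "B:3p--C:5p", "C:3p--D:5p"),
    stringsAsFactors = FALSE)), class = "sim_truth")

  exact <- make_candidates(c("A:3p", "B:3p", "C:3p"),
                           c("B:5p", "C:5p", "D:5p"), c(1, 1, 1))
  ev <- evaluate_links(exact, truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)

  none <- make_candidates(character(), character(), numeric())
  ev0 <- evaluate_links(none, truth)
  expect_true(is.na(ev0$precision))
  expect_equal(ev0$recall, 0)

  # wrong side is not a true positive
  mixed <- make_candidates(c("A:3p", "B:3p", "A:5p", "D:3p"),
                           c("B:5p", "C:5p", "C:5p", "E:5p"),
                           c(1, 1, 1, 1))
  ev2 <- evaluate_links(mixed, truth)
  expect_equal(ev2$precision, 0.5)
  expect_equal(ev2$recall, 2 / 3)
})
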