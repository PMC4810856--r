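test_that("newick round-trips preserve topology and polytomies are visible", {
  p1 <- tempfile(fileext = ".nwk")
  writeLines("((A,B),C);", p1)
  tr <- read_newick(p1)
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tr$Nnode, 2L)

  p2 <- tempfile(fileext = ".nwk")
  writeLines("((A,B,C),D);", p2)
  tr2 <- read_newick(p2)
  tab <- tabulate(tr2$edge[, 1])
  expect_equal(max(tab), 3L) # a degree-3 polytomy is preserved

  set.seed(8)
  big <- ape::rtree(50, br = NULL)
  p3 <- tempfile(fileext = ".nwk")
  write_newick(big, p3)
  back <- read_newick(p3)
  expect_true(ape::all.equal.phylo(big, back, use.edge.length = FALSE))

  p4 <- tempfile(fileext = ".nwk")
  writeLines("((A,B,C);", p4)
  expect_error(read_newick(p4), "parse")
  expect_error(read_newick(tempfile()), "not found")
})

test_that("ordered resolution nests lineages by first appearance", {
  tr <- ape::read.tree(text = "(A,B,C);")
  fads <- c(A = 150, B = 140, C = 130)
  out <- resolve_polytomies(tr, "ordered", fads = fads, seed = 1)
  expect_true(ape::all.equal.phylo(out, ape::read.tree(text = "(A,(B,C));"),
                                   use.edge.length = FALSE))
  # four-way polytomy: full caterpillar by decreasing FAD
  tr4 <- ape::read.tree(text = "(D,B,A,C);")
  f4 <- c(A = 160, B = 150, C = 140, D = 130)
  out4 <- resolve_polytomies(tr4, "ordered", fads = f4, seed = 1)
  expect_true(ape::all.equal.phylo(out4, ape::read.tree(text = "(A,(B,(C,D)));"),
                                   use.edge.length = FALSE))
  expect_error(resolve_polytomies(tr, "ordered", fads = fads[-1]), "A")
})

test_that("already-binary trees pass through every resolution method unchanged", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  fads <- c(A = 150, B = 140, C = 130, D = 120)
  for (m in c("equal", "random", "ordered")) {
    out <- resolve_polytomies(tr, m, fads = fads, seed = 3)
    expect_true(ape::all.equal.phylo(out, tr, use.edge.length = FALSE))
  }
})

test_that("equal first appearances are tie-broken randomly, covering both orders", {
  tr <- ape::read.tree(text = "((A,B),C);")
  tr_poly <- ape::read.tree(text = "(A,B,C);")
  fads <- c(A = 150, B = 150, C = 130)
  first <- vapply(1:20, function(s) {
    out <- resolve_polytomies(tr_poly, "ordered", fads = fads, seed = s)
    # basal lineage of the caterpillar
    root <- ape::Ntip(out) + 1L
    kids <- out$edge[out$edge[, 1] == root, 2]
    out$tip.label[kids[kids <= 3L][1L]]
  }, character(1L))
  expect_setequal(unique(first), c("A", "B"))
})

test_that("ordered resolutions never place a later taxon basal to an earlier one", {
  for (s in 1:50) {
    set.seed(s)
    n <- 5L
    fads <- stats::setNames(sort(stats::runif(n, 100, 200), decreasing = TRUE),
                            paste0("t", seq_len(n)))
    tr <- ape::read.tree(text = paste0("(", paste(sample(names(fads)),
                                                  collapse = ","), ");"))
    out <- resolve_polytomies(tr, "ordered", fads = fads, seed = s)
    # walk the caterpillar spine: pendant FADs must be non-increasing
    idx <- ape::Ntip(out) + 1L
    pend <- character(0)
    repeat {
      kids <- out$edge[out$edge[, 1] == idx, 2]
      tipkids <- kids[kids <= ape::Ntip(out)]
      intkids <- kids[kids > ape::Ntip(out)]
      if (length(intkids) == 0L) { pend <- c(pend, out$tip.label[tipkids]); break }
      pend <- c(pend, out$tip.label[tipkids])
      idx <- intkids[1L]
    }
    expect_true(all(diff(fads[pend]) <= 1e-9))
  }
})

test_that("equal-method dating reproduces the hand-worked cherry", {
  tr <- ape::read.tree(text = "(A,B);")
  dt <- time_scale(tr, fads = c(A = 150, B = 140), method = "equal",
                   root_extension = 10)
  root <- 3L
  expect_equal(dt$ages[root], 155)
  expect_equal(dt$stem_top, 160)
  expect_equal(dt$tree$root.edge, 5)
  la <- dt$tree$edge.length[dt$tree$edge[, 2] == which(dt$tree$tip.label == "A")]
  lb <- dt$tree$edge.length[dt$tree$edge[, 2] == which(dt$tree$tip.label == "B")]
  expect_equal(la, 5)
  expect_equal(lb, 15)
})

test_that("time-scaled trees are internally consistent across methods and seeds", {
  sc <- tenmyr_bins()
  for (s in 1:30) {
    tr <- simulate_ranges(6, sc, 0.3, 0.3, seed = s)
    if (nrow(tr$taxa) < 3) next
    st <- simulate_tree(tr, polytomy_fraction = 0.4, seed = s)
    for (m in c("equal", "random", "ordered")) {
      dt <- time_scale(st$tree, st$fads, st$lads, method = m, seed = s)
      expect_true(all(dt$tree$edge.length >= -1e-9))
      # child never older than parent
      expect_true(all(dt$ages[dt$tree$edge[, 1]] - dt$ages[dt$tree$edge[, 2]] >= -1e-9))
      # tip ages equal first appearances
      expect_equal(unname(dt$ages[seq_len(ape::Ntip(dt$tree))]),
                   unname(st$fads[dt$tree$tip.label]))
    }
    # equal method leaves no zero-length branch when stem slack exists
    dt_eq <- time_scale(st$tree, st$fads, st$lads, method = "equal",
                        root_extension = 5)
    if (dt_eq$n_zero_flagged == 0) expect_gt(min(dt_eq$tree$edge.length), 0)
  }
})

test_that("dating is invariant to tip input order", {
  fads <- c(A = 150, B = 140, C = 135, D = 120)
  t1 <- time_scale(ape::read.tree(text = "((A,B),(C,D));"), fads, method = "equal")
  t2 <- time_scale(ape::read.tree(text = "((D,C),(B,A));"), fads, method = "equal")
  a1 <- stats::setNames(t1$ages[1:4], t1$tree$tip.label)
  a2 <- stats::setNames(t2$ages[1:4], t2$tree$tip.label)
  expect_equal(a1[sort(names(a1))], a2[sort(names(a2))])
  expect_equal(t1$ages[5], t2$ages[5]) # root age
  expect_equal(sort(t1$tree$edge.length), sort(t2$tree$edge.length))
})

test_that("dropping tips preserves the ages of retained nodes", {
  fads <- c(A = 150, B = 140, C = 130)
  dt <- time_scale(ape::read.tree(text = "((A,B),C);"), fads, method = "equal",
                   root_extension = 6)
  sub <- drop_tips(dt, c("A", "B"))
  expect_equal(ape::Ntip(sub$tree), 2L)
  # the (A,B) node keeps the age it had in the full tree
  ab_old <- dt$ages[ape::getMRCA(dt$tree, c("A", "B"))]
  expect_equal(sub$ages[3L], ab_old)
  expect_equal(sub$stem_top, dt$stem_top)
  expect_error(drop_tips(dt, character(0)), "at least 2")
})

test_that("pde counts ghost lineages the way the worked example demands", {
  # cherry with root at 150; A ranges 150-145, B 140-130 (ghost 150->140)
  tr <- ape::read.tree(text = "(A,B);")
  dt <- structure(list(
    tree = local({
      t <- tr
      t$edge.length <- c(0, 10)
      t$root.edge <- 5
      t
    }),
    ages = c(150, 140, 150), fad = c(A = 150, B = 140),
    lad = c(A = 145, B = 130), stem_top = 155, method = "manual",
    root_extension = 5, n_zero_flagged = 0L
  ), class = "dated_tree")
  sch <- bin_scheme(c("q1", "q2", "q3"), older = c(158, 148, 143),
                    younger = c(148, 143, 120))
  p <- pde(dt, sch)
  # bin (143,148]: A's lineage (150->145) and B's ghost+range (150->130)
  expect_equal(p$value[2], 2)
  # only one taxon is actually sampled in that window
  expect_lt(1, p$value[2])
  # a bin younger than every last appearance holds no lineage
  sch2 <- bin_scheme("late", older = 125, younger = 110)
  expect_equal(pde(dt, sch2)$value, 0)
})

test_that("pde never falls below the in-bin sampled taxon count", {
  sc <- tenmyr_bins()
  for (s in 1:25) {
    tr <- simulate_ranges(8, sc, 0.25, 0.25, seed = s)
    if (nrow(tr$taxa) < 3) next
    st <- simulate_tree(tr, seed = s)
    dt <- time_scale(st$tree, st$fads, st$lads, method = "equal")
    p <- pde(dt, sc)
    # taxa whose true range intersects each bin
    present <- vapply(seq_len(nrow(sc)), function(b) {
      sum(st$fads > sc$younger[b] & st$lads <= sc$older[b])
    }, numeric(1L))
    expect_true(all(p$value >= present - 1e-9))
  }
})

test_that("pde is monotone under subtree extraction", {
  sc <- tenmyr_bins()
  tr <- simulate_ranges(12, sc, 0.2, 0.2, seed = 14)
  st <- simulate_tree(tr, seed = 14)
  dt <- time_scale(st$tree, st$fads, st$lads, method = "equal")
  full <- pde(dt, sc)$value
  keep <- sample(st$tree$tip.label, max(2, ape::Ntip(st$tree) - 4))
  sub <- pde(drop_tips(dt, keep), sc)$value
  expect_true(all(sub <= full + 1e-9))
})

test_that("the reported pde lies within the envelope of its three methods", {
  sc <- tenmyr_bins()
  tr <- simulate_ranges(10, sc, 0.25, 0.25, seed = 17)
  st <- simulate_tree(tr, polytomy_fraction = 0.3, seed = 17)
  est <- pde_estimate(st$tree, st$fads, st$lads, sc, n_resolutions = 5, seed = 17)
  m <- vapply(est$methods, function(x) x$value, numeric(nrow(sc)))
  expect_true(all(est$mean$value >= apply(m, 1, min) - 1e-9))
  expect_true(all(est$mean$value <= apply(m, 1, max) + 1e-9))
})

test_that("genus collapse pools species ranges onto one lineage per genus", {
  tr <- ape::read.tree(text = "((Ga_x,Ga_y),Gb_z);")
  fads <- c(Ga_x = 150, Ga_y = 145, Gb_z = 140)
  lads <- c(Ga_x = 148, Ga_y = 130, Gb_z = 120)
  out <- collapse_to_genus(tr, fads, lads)
  expect_setequal(out$tree$tip.label, c("Ga", "Gb"))
  expect_equal(unname(out$fads["Ga"]), 150)
  expect_equal(unname(out$lads["Ga"]), 130)
  out2 <- collapse_to_genus(tr, fads, lads, earliest_species_only = TRUE)
  expect_equal(unname(out2$lads["Ga"]), 148)
})
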