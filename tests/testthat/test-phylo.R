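test_that("Newick ingestion yields rooted trees and round-trips topology", {
  tr <- read_tree("((A,B),C);")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_true(ape::is.rooted(tr))
  tr2 <- read_tree("(A,B);")
  expect_equal(length(tr2$tip.label), 2)
  # round-trip preserves topology
  big <- simulate_tree(25, seed = 4)
  txt <- ape::write.tree(big)
  again <- read_tree(txt)
  expect_true(ape::all.equal.phylo(big, again, use.edge.length = FALSE))
  expect_error(read_tree("((A,B),A);"), "duplicate")
})

test_that("Grafen heights match the descendant-tip formula by hand", {
  # 2-tip cherry: both pendant branches have length 1
  ch <- grafen_lengths(read_tree("(A,B);"))
  expect_equal(unname(ch$edge.length), c(1, 1))

  # ((A,B),C): internal node height (2-1)/(3-1) = 0.5
  tr <- grafen_lengths(read_tree("((A,B),C);"))
  d <- ape::dist.nodes(tr)
  root <- length(tr$tip.label) + 1
  tipd <- d[root, seq_along(tr$tip.label)]
  expect_equal(unname(tipd), rep(1, 3))            # root-to-tip = 1
  # branch lengths: pendant A,B = 0.5, internal = 0.5, pendant C = 1
  expect_equal(sort(unname(tr$edge.length)), c(0.5, 0.5, 0.5, 1.0))

  # balanced 4-tip tree: internal heights (2-1)/(4-1) = 1/3
  tb <- grafen_lengths(read_tree("((A,B),(C,D));"))
  expect_equal(sort(unique(round(tb$edge.length, 12))),
               round(c(1 / 3, 2 / 3), 12))

  expect_error(grafen_lengths(read_tree("(A,B);") |>
                                ape::keep.tip("A")), "2 tips")
})

test_that("VCV entries are shared root-to-tip path lengths", {
  tr <- grafen_lengths(read_tree("((A,B),C);"))
  V <- phylo_vcv(tr)
  expect_equal(unname(diag(V)), rep(1, 3))
  expect_equal(V["A", "B"], 0.5)
  expect_equal(V["A", "C"], 0)
  expect_true(isSymmetric(V))

  # star tree: identity
  star <- read_tree("(A,B,C,D);")
  star$edge.length <- rep(1, 4)
  expect_equal(unname(phylo_vcv(star)), diag(4))

  # any random tree: PSD
  rt <- grafen_lengths(simulate_tree(40, seed = 9))
  ev <- eigen(phylo_vcv(rt), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)

  # root-to-tip sums are 1 on every path (Grafen scaling)
  d <- ape::dist.nodes(rt)[41, 1:40]
  expect_equal(unname(d), rep(1, 40), tolerance = 1e-12)
})

test_that("lambda transform scales off-diagonals only and stays PSD", {
  V <- phylo_vcv(grafen_lengths(read_tree("((A,B),C);")))
  expect_equal(lambda_transform(V, 0), diag(3),
               ignore_attr = TRUE)
  expect_equal(lambda_transform(V, 1), V)
  expect_equal(lambda_transform(V, 0.5)["A", "B"], 0.25)
  # diagonal preserved, PSD across a lambda grid
  Vr <- phylo_vcv(grafen_lengths(simulate_tree(30, seed = 2)))
  for (la in c(0, 0.25, 0.5, 0.75, 1)) {
    W <- lambda_transform(Vr, la)
    expect_equal(diag(W), diag(Vr))
    expect_gt(min(eigen(W, only.values = TRUE)$values), -1e-10)
  }
  expect_error(lambda_transform(V, 1.2), "\\[0, 1\\]")
})

test_that("tree-table intersection prunes both sides consistently", {
  tr <- simulate_tree(10, seed = 1)
  gt <- data.frame(genus = c(tr$tip.label[1:6], "missing_genus"),
                   log_rate_corrected = rnorm(7), log_mass = rnorm(7))
  mt <- suppressMessages(match_tree_table(gt, tr))
  expect_equal(sort(mt$tree$tip.label), sort(gt$genus[1:6]))
  expect_equal(mt$genus_table$genus, mt$tree$tip.label)
})
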