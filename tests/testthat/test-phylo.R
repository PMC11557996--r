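test_that("parse_newick preserves tips, labels and patristic distances", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  d <- ape::cophenetic.phylo(tr)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)

  tr2 <- parse_newick("(A:1,B:1);")
  expect_equal(length(tr2$tip.label), 2L)
  expect_equal(unname(ape::node.depth.edgelength(tr2)[1:2]), c(1, 1))
})

test_that("parse_newick rejects malformed input and flags zero branches", {
  expect_error(parse_newick("(A:1,B);"), "missing branch lengths")
  expect_error(parse_newick("(A:1,A:1);"), "duplicated tip labels")
  expect_error(suppressWarnings(parse_newick("((A:1,B:1")), "malformed")
  expect_warning(parse_newick("(A:0,B:1);"), "zero-length terminal")
})

test_that("pruning preserves patristic distances and handles edge cases", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  pr <- prune_to_taxa(tr, c("A", "C"))
  expect_setequal(pr$tip.label, c("A", "C"))
  expect_equal(ape::cophenetic.phylo(pr)["A", "C"], 4)

  expect_identical(prune_to_taxa(tr, c("A", "B", "C")), tr)
  expect_error(prune_to_taxa(tr, "A"), "at least 2")
  expect_error(prune_to_taxa(tr, c("A", "Z")), "unknown tip")
})

test_that("pruning then vcv equals row/column subsetting of the full vcv", {
  set.seed(7)
  for (rep in 1:5) {
    tr <- ape::rtree(12)
    keep <- sample(tr$tip.label, 6)
    sub <- vcv_matrix(prune_to_taxa(tr, keep), order = sort(keep))
    full <- vcv_matrix(tr)[sort(keep), sort(keep)]
    expect_equal(unclass(sub), full, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("graft_tip adds a tip without disturbing existing distances", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  g <- graft_tip(tr, "X", "A", attach_age = 0.5, tip_age = 0)
  expect_equal(length(g$tip.label), 4L)
  d <- ape::cophenetic.phylo(g)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["A", "X"], 1)  # 0.5 up, 0.5 down

  gf <- graft_tip(tr, "X", "A", attach_age = 0.5, tip_age = 0.3)
  xlen <- gf$edge.length[gf$edge[, 2] == which(gf$tip.label == "X")]
  expect_equal(xlen, 0.2)

  expect_error(graft_tip(tr, "X", "A", attach_age = 0.5, tip_age = 0.8),
               "negative branch")
  expect_error(graft_tip(tr, "X", "A", attach_age = 1.7, tip_age = 0),
               "outside the edge age span")
  expect_error(graft_tip(tr, "A", "B", attach_age = 0.5), "already present")
})

test_that("grafting never changes the vcv among pre-existing tips", {
  set.seed(11)
  for (rep in 1:5) {
    tr <- ape::rtree(8)
    C0 <- vcv_matrix(tr, order = sort(tr$tip.label))
    ages <- tip_ages(tr)
    tip <- sample(tr$tip.label, 1)
    row <- which(tr$edge[, 2] == match(tip, tr$tip.label))
    span <- tr$edge.length[row]
    at <- ages[[tip]] + runif(1, 0.2, 0.8) * span
    g <- suppressWarnings(graft_tip(tr, "new", tip, attach_age = at,
                                    tip_age = runif(1, 0, at)))
    C1 <- vcv_matrix(g, order = sort(tr$tip.label))
    expect_equal(unclass(C1), unclass(C0), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("vcv matches hand computation and the brute-force path oracle", {
  C <- vcv_matrix(parse_newick("((A:1,B:1):1,C:2);"),
                  order = c("A", "B", "C"))
  expect_equal(unclass(C), matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3,
                                  dimnames = list(c("A", "B", "C"),
                                                  c("A", "B", "C"))),
               ignore_attr = TRUE)

  Cs <- vcv_matrix(parse_newick("(A:1,B:1,C:1);"))
  expect_equal(unclass(Cs), diag(3), ignore_attr = TRUE)

  set.seed(3)
  for (rep in 1:3) {
    tr <- ape::rtree(10)
    expect_equal(unclass(vcv_matrix(tr, order = tr$tip.label)),
                 brute_vcv(tr)[tr$tip.label, tr$tip.label],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("vcv is symmetric positive semi-definite on simulated trees", {
  set.seed(5)
  for (rep in 1:5) {
    tr <- ape::rtree(15)
    C <- unclass(vcv_matrix(tr))
    expect_equal(C, t(C))
    expect_true(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
                >= -1e-10)
  }
})

test_that("lambda transform scales off-diagonals only and is monotone", {
  C <- vcv_matrix(parse_newick("(A:2,(B:1,C:1):1);"), order = c("B", "C", "A"))
  expect_equal(unclass(lambda_transform(C, 0))[1, 2], 0)
  expect_equal(diag(lambda_transform(C, 0)), diag(unclass(C)))
  expect_equal(unclass(lambda_transform(C, 1)), unclass(C), ignore_attr = TRUE)
  expect_equal(unclass(lambda_transform(C, 0.5))[1, 2], 0.5)
  expect_error(lambda_transform(C, 1.2), "\\[0, 1\\]")
  expect_error(lambda_transform(C, -0.1), "\\[0, 1\\]")

  lams <- seq(0, 1, 0.25)
  offs <- vapply(lams, function(l) lambda_transform(C, l)[1, 2], numeric(1))
  expect_true(all(diff(offs) > 0))
})

test_that("tip ages are zero for extant tips and positive for fossils", {
  tr <- parse_newick("((A:1,B:0.6):1,C:2);")
  a <- tip_ages(tr)
  expect_equal(a[["A"]], 0)
  expect_equal(a[["C"]], 0)
  expect_equal(a[["B"]], 0.4)
})
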