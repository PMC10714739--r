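test_that("complexity reproduces LD and C from S and L", {
  cx <- complexity(S = 69, L = 780)
  expect_equal(round(cx$LD, 2), 11.30)
  expect_equal(round(cx$C, 2), 0.16)
  cx2 <- complexity(S = 61, L = 462)
  expect_equal(round(cx2$LD, 2), 7.57)
  expect_equal(round(cx2$C, 2), 0.12)

  edgeless <- makeWeb(nodes = paste0("n", 1:5))
  cx3 <- complexity(edgeless)
  expect_identical(unlist(cx3[c("S", "L")]), c(S = 5L, L = 0L))
  expect_identical(cx3$LD, 0)
  expect_identical(cx3$C, 0)
})

undirected <- function(pairs, n) {
  ids <- letters[seq_len(n)]
  a <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (e in pairs) a[e[1], e[2]] <- 1L
  a
}

test_that("clustering coefficient averages local values, degree<2 as zero", {
  tri <- undirected(list(c("a", "b"), c("b", "c"), c("a", "c")), 3)
  expect_equal(clusteringCoefficient(tri), 1)

  star <- undirected(list(c("a", "b"), c("a", "c"), c("a", "d")), 4)
  expect_equal(clusteringCoefficient(star), 0)

  ## per-node values: a = 1, b = 1, c = 1/3, d = 0, e = 0
  g5 <- undirected(list(c("a", "b"), c("a", "c"), c("b", "c"),
                        c("c", "d"), c("d", "e")), 5)
  expect_equal(clusteringCoefficient(g5), (1 + 1 + 1 / 3 + 0 + 0) / 5)
})

test_that("characteristic path length averages reachable pairs only", {
  path3 <- undirected(list(c("a", "b"), c("b", "c")), 3)
  expect_equal(characteristicPathLength(path3)$CPL, 4 / 3)

  k4 <- undirected(utils::combn(letters[1:4], 2, simplify = FALSE), 4)
  expect_equal(characteristicPathLength(k4)$CPL, 1)

  two <- undirected(list(c("a", "b"), c("c", "d")), 4)
  r <- characteristicPathLength(two)
  expect_equal(r$CPL, 1)
  expect_identical(r$excluded_pairs, 4L)

  none <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(characteristicPathLength(none), "no reachable")
})

test_that("trophic levels solve the prey-averaged linear system", {
  expect_equal(unname(trophicLevels(chainWeb(3))$TL), c(1, 2, 3))
  expect_equal(trophicLevels(chainWeb(3))$meanTL, 2)

  expect_equal(unname(trophicLevels(igpWeb())$TL), c(1, 2, 2.5))

  ## loop: a basal; b eats {a, c}; c eats b. Solving
  ## TL_b = 1 + (1 + TL_c)/2 and TL_c = 1 + TL_b gives (4, 5); an
  ## independent damped fixed-point iteration agrees.
  loop <- matrix(0L, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  loop["a", "b"] <- 1L; loop["c", "b"] <- 1L; loop["b", "c"] <- 1L
  tl <- trophicLevels(loop)$TL
  expect_equal(unname(tl), c(1, 4, 5))
  it <- c(1, 1, 1)
  for (k in 1:200) it <- c(1, 1 + (it[1] + it[3]) / 2, 1 + it[2])
  expect_equal(unname(tl), it, tolerance = 1e-8)

  ## consumer cycle with no basal input is singular; error names the cycle
  cyc <- matrix(0L, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  cyc["b", "c"] <- 1L; cyc["c", "b"] <- 1L
  expect_error(trophicLevels(cyc), "no basal input.*b.*c")
})

test_that("omnivory counts consumers feeding at distinct trophic levels", {
  expect_equal(omnivory(chainWeb(3)), 0)
  expect_equal(omnivory(igpWeb()), 1 / 3)
  expect_equal(omnivory(igpWeb(), consumersOnly = TRUE), 1 / 2)

  ## brute-force per-node check on generated niche-style webs
  for (seed in 1:5) {
    a <- randomDag(20, 0.25, seed = seed)
    if (sum(a) == 0) next
    TL <- trophicLevels(a)$TL
    brute <- 0
    for (j in seq_len(ncol(a))) {
      prey <- which(a[, j] == 1L)
      if (length(prey) >= 2 && diff(range(TL[prey])) > 1e-9)
        brute <- brute + 1
    }
    expect_equal(omnivory(a), brute / nrow(a))
  }
})

test_that("greedy modularity is deterministic with known small answers", {
  two <- undirected(list(c("a", "b"), c("b", "c"), c("a", "c"),
                         c("d", "e"), c("e", "f"), c("d", "f")), 6)
  r <- modularityQ(two)
  expect_equal(r$Q, 0.5)
  expect_identical(r$membership[["a"]], r$membership[["b"]])
  expect_false(r$membership[["a"]] == r$membership[["d"]])

  k4 <- undirected(utils::combn(letters[1:4], 2, simplify = FALSE), 4)
  expect_equal(modularityQ(k4)$Q, 0)

  d <- sharedDataset()
  w <- buildWeb(detectedTaxa(d$protist, "winter"), d$annotation, d$catalog)
  r1 <- modularityQ(w)
  r2 <- modularityQ(w)
  expect_identical(r1, r2)
})

test_that("degree stats satisfy AD = 2L/S", {
  w <- makeWeb(list(c("a", "b")))
  expect_equal(degreeStats(w)$AD, 1)
  expect_equal(degreeStats(makeWeb(nodes = c("a", "b")))$AD, 0)
  for (seed in 1:5) {
    w <- randomWeb(seed = seed)
    expect_equal(degreeStats(w)$AD, 2 * nLinks(w) / nNodes(w))
  }
})

test_that("metrics are invariant to node permutation", {
  a <- randomDag(12, 0.3, seed = 3)
  perm <- sample(12)
  b <- a[perm, perm]
  expect_equal(sort(unname(trophicLevels(a)$TL)),
               sort(unname(trophicLevels(b)$TL)))
  expect_equal(omnivory(a), omnivory(b))
  expect_equal(clusteringCoefficient(a), clusteringCoefficient(b))
  expect_equal(characteristicPathLength(a)$CPL,
               characteristicPathLength(b)$CPL)
})

test_that("removing an edge never increases L, LD or C", {
  a <- randomDag(10, 0.4, seed = 9)
  cx <- complexity(a)
  idx <- which(a == 1L, arr.ind = TRUE)
  for (k in seq_len(min(5, nrow(idx)))) {
    b <- a
    b[idx[k, 1], idx[k, 2]] <- 0L
    cx2 <- complexity(b)
    expect_lte(cx2$L, cx$L)
    expect_lte(cx2$LD, cx$LD)
    expect_lte(cx2$C, cx$C)
  }
})

test_that("webs whose consumers eat only basal prey have meanTL <= 2", {
  for (seed in 1:5) {
    basal <- paste0("b", 1:4)
    cons <- paste0("c", 1:4)
    set.seed(seed)
    edges <- list()
    for (cn in cons)
      for (pr in basal[runif(4) < 0.6])
        edges[[length(edges) + 1]] <- c(pr, cn)
    if (!length(edges)) next
    w <- makeWeb(edges, nodes = c(basal, cons))
    expect_lte(trophicLevels(w)$meanTL, 2)
  }
})
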