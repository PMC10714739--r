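test_that("Shannon H matches closed forms and errors on empty input", {
  expect_equal(shannonIndex(c(1, 1, 1, 1)), log(4))
  expect_equal(shannonIndex(c(5, 0, 0)), 0)
  expect_equal(shannonIndex(c(2, 1, 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_error(shannonIndex(c(0, 0)), "all-zero")
})

test_that("Shannon H is maximal at the uniform distribution", {
  for (n in 2:6) {
    hUnif <- shannonIndex(rep(1, n))
    set.seed(n)
    for (k in 1:50) {
      v <- rmultinom(1, 60, prob = runif(n))[, 1]
      if (sum(v > 0) == 0) next
      expect_lte(shannonIndex(v), hUnif + 1e-12)
    }
  }
})

test_that("sample subwebs are induced subgraphs plus standing aggregates", {
  d <- sharedDataset()
  w <- buildWeb(detectedTaxa(d$protist, "spring"), d$annotation, d$catalog,
                label = "spring")
  all <- sampleSubweb(w, nodeInfo(w)$node_id)
  expect_identical(adjacencyMatrix(all), adjacencyMatrix(w))

  small <- makeWeb(list(c("bacteria", "p")),
                   guilds = list(p = "B"),
                   compartments = c(bacteria = "bacteria"))
  sub <- sampleSubweb(small, "p")
  expect_identical(nLinks(sub), 1L)   # aggregate stays, edge kept

  genus <- nodeInfo(w)$node_id[nodeInfo(w)$kind == "genus"]
  a <- adjacencyMatrix(w)
  set.seed(1)
  for (k in 1:100) {
    taxa <- sample(genus, length(genus) %/% 2)
    sb <- sampleSubweb(w, taxa)
    bs <- adjacencyMatrix(sb)
    idx <- which(bs == 1L, arr.ind = TRUE)
    if (!nrow(idx)) next
    expect_true(all(a[cbind(rownames(bs)[idx[, 1]],
                            colnames(bs)[idx[, 2]])] == 1L))
    expect_true(all(rownames(bs) %in%
                    c(taxa, aggregateCompartments())))
  }
})

test_that("interaction proportion counts bacterivore-to-bacteria links", {
  w <- makeWeb(list(c("bacteria", "p")), guilds = list(p = "B"),
               compartments = c(bacteria = "bacteria"))
  expect_equal(interactionProportion(w), 1)

  w2 <- makeWeb(list(c("x", "r")), guilds = list(r = "R", x = "P"))
  expect_equal(interactionProportion(w2), 0)

  ## 4 links, one qualifying
  w3 <- makeWeb(list(c("bacteria", "p"), c("x", "r"), c("y", "r"),
                     c("x", "q")),
                guilds = list(p = "B", r = "R", q = "N", x = "P", y = "P"),
                compartments = c(bacteria = "bacteria"))
  expect_equal(interactionProportion(w3), 0.25)
  expect_equal(interactionProportion(w3, denominator = "bacterivore"), 1)

  expect_error(interactionProportion(makeWeb(nodes = "a")), "no links")

  ## invariant to adding an isolated non-bacterial, non-bacterivore node
  w4 <- makeWeb(list(c("bacteria", "p"), c("x", "r"), c("y", "r"),
                     c("x", "q")), nodes = "iso",
                guilds = list(p = "B", r = "R", q = "N", x = "P", y = "P"),
                compartments = c(bacteria = "bacteria"))
  expect_equal(interactionProportion(w4), interactionProportion(w3))
})

test_that("OLS regression returns closed-form slope, R2 and p", {
  x <- 1:10
  r <- regressFeature(x, 2 * x + 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r.squared, 1)
  expect_lt(r$p, 1e-10)

  r2 <- regressFeature(x, rep(3, 10))
  expect_equal(r2$slope, 0)
  expect_equal(r2$r.squared, 0)

  r3 <- regressFeature(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r3$slope, 0.6)
  expect_equal(r3$r.squared, 0.36)

  expect_error(regressFeature(rep(1, 5), 1:5), "zero variance")
})

test_that("Spearman correlation matrix handles ties and constants", {
  df <- data.frame(sub_L = 1:5, sub_LD = c(1, 3, 2, 5, 4),
                   sub_C = 5:1, sub_meanTL = 1:5, sub_O = rep(2, 5),
                   sub_Mod = c(2, 4, 6, 8, 10))
  r <- metricCorrelations(df)
  expect_equal(r$rho["sub_L", "sub_meanTL"], 1)
  expect_equal(r$rho["sub_C", "sub_meanTL"], -1)
  expect_equal(r$rho["sub_LD", "sub_meanTL"], 0.8)
  expect_true(is.na(r$rho["sub_L", "sub_O"]))
})

test_that("per-sample features line up with their sub-networks", {
  d <- sharedDataset()
  s <- "winter"
  genera <- detectedTaxa(d$protist, s)
  w <- buildWeb(genera, d$annotation, d$catalog, label = s)
  iw <- buildWeb(c(genera, detectedTaxa(d$bacteria, s)), d$annotation,
                 d$catalog, label = s)
  f <- sampleFeatures(d$protist, w, bacteria = d$bacteria, intWeb = iw,
                      metrics = TRUE, qssDraws = 0)
  expect_identical(nrow(f), 9L)
  expect_true(all(f$season == s))
  expect_true(all(f$Int >= 0 & f$Int <= 1))
  expect_equal(f$AD, 2 * f$sub_L / f$sub_S)
  expect_equal(f$sub_C, f$sub_L / f$sub_S^2)

  ## spot-check one sample against a manual sub-network
  sm <- f$sample_id[1]
  sub <- sampleSubweb(w, sampleTaxa(d$protist, sm))
  expect_identical(f$sub_S[1], nNodes(sub))
  expect_identical(f$sub_L[1], nLinks(sub))
  expect_equal(f$sub_Mod[1], modularityQ(sub)$Q)
  expect_equal(f$shannon_H[1], shannonIndex(countsMatrix(d$protist)[sm, ]))
})
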