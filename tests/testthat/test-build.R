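test_that("detectedTaxa applies the summed-count threshold per season", {
  m <- matrix(c(5, 0, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("g1", "g2")))
  ct <- communityTable(m, season = c("spring", "spring"))
  expect_identical(detectedTaxa(ct, "spring"), "g1")
  expect_length(detectedTaxa(ct, "spring", minCount = 6), 0)
  expect_error(detectedTaxa(ct, "summer"), "unknown season")
})

test_that("generated seasonal data hit the configured richness exactly", {
  d <- sharedDataset()
  cfg <- d$manifest$config
  for (s in cfg$seasons)
    expect_length(detectedTaxa(d$protist, s), cfg$richness[[s]])
})

simpleAnnotation <- function(ids, guilds) {
  ann <- data.frame(taxon_id = ids, compartment = "protist", phylum = "",
                    stringsAsFactors = FALSE)
  ann$guilds <- guilds
  ann
}

test_that("buildWeb keeps catalog edges with present endpoints only", {
  ann <- simpleAnnotation(c("p", "q"), list("B", "R"))
  cat1 <- interactionCatalog("p", "bacteria")
  w <- buildWeb("p", ann, cat1, aggregates = "bacteria")
  expect_identical(nNodes(w), 2L)
  expect_identical(nLinks(w), 1L)

  cat2 <- interactionCatalog(c("q", "r"), c("p", "q"))
  ## r undetected, no aggregates requested: its edge is excluded and counted
  w2 <- buildWeb(c("p", "q"), ann, cat2, aggregates = "detritus")
  expect_identical(buildReport(w2)$n_excluded_edges, 1L)
  expect_identical(buildReport(w2)$n_genus_nodes, 2L)
  expect_error(buildWeb(character(), ann, cat2, aggregates = character(0)))
})

test_that("aggregates are retained when isolated, isolated genera dropped", {
  ann <- simpleAnnotation(c("p", "q", "z"), list("B", "P", "P"))
  cat1 <- interactionCatalog("p", "q")
  w <- buildWeb(c("p", "q", "z"), ann, cat1)
  nd <- nodeInfo(w)
  expect_true(all(aggregateCompartments() %in% nd$node_id))
  expect_false("z" %in% nd$node_id)          # isolated genus dropped
  expect_identical(buildReport(w)$n_dropped_isolated, 1L)
  expect_identical(buildReport(w)$n_aggregate_nodes, 5L)
})

test_that("web construction is deterministic and monotone in the catalog", {
  d <- sharedDataset()
  taxa <- detectedTaxa(d$protist, "spring")
  w1 <- buildWeb(taxa, d$annotation, d$catalog, label = "spring")
  w2 <- buildWeb(taxa, d$annotation, d$catalog, label = "spring")
  expect_identical(adjacencyMatrix(w1), adjacencyMatrix(w2))

  ## every web edge exists in the catalog; L bounded by catalog size
  a <- adjacencyMatrix(w1)
  idx <- which(a == 1L, arr.ind = TRUE)
  edges <- paste(colnames(a)[idx[, 2]], rownames(a)[idx[, 1]])
  expect_true(all(edges %in% paste(d$catalog$predator_id,
                                   d$catalog$prey_id)))
  expect_lte(nLinks(w1), nrow(d$catalog))

  ## an edge to an undetected taxon never changes the built web
  cat2 <- rbind(d$catalog,
                data.frame(predator_id = "ghost", prey_id = taxa[1],
                           provenance = "", stringsAsFactors = FALSE))
  w3 <- buildWeb(taxa, d$annotation, cat2, label = "spring")
  expect_identical(adjacencyMatrix(w3), adjacencyMatrix(w1))
})

test_that("guild partition computes predator shares on distinct predators", {
  w <- makeWeb(list(c("x", "p")), guilds = list(p = "B", x = "P"))
  gp <- guildPartition(w)
  expect_identical(gp$predators, "p")
  expect_identical(gp$predatorShare[["B"]], 1)

  w2 <- makeWeb(list(c("x", "p"), c("x", "q")),
                guilds = list(p = "B", q = "R", x = "P"))
  gp2 <- guildPartition(w2)
  expect_identical(gp2$predatorShare[["B"]], 0.5)
  expect_identical(gp2$predatorShare[["R"]], 0.5)

  ## multi-guild nodes appear in each of their guilds
  w3 <- makeWeb(list(c("x", "p")), guilds = list(p = c("B", "R"), x = "P"))
  gp3 <- guildPartition(w3)
  expect_identical(gp3$guilds$B, "p")
  expect_identical(gp3$guilds$R, "p")
})

test_that("seasonal webs keep the bacterivore predator share in band", {
  for (seed in c(7, 19, 101)) {
    d <- generateSeasonalDataset(seed)
    for (s in d$manifest$config$seasons) {
      w <- buildWeb(detectedTaxa(d$protist, s), d$annotation, d$catalog,
                    label = s)
      share <- guildPartition(w)$predatorShare[["B"]]
      expect_gte(share, 0.45)
      expect_lte(share, 0.78)
    }
  }
})
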