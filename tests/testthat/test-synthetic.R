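test_that("the generator is deterministic given the seed", {
  d1 <- generateSeasonalDataset(7)
  d2 <- generateSeasonalDataset(7)
  expect_identical(countsMatrix(d1$protist), countsMatrix(d2$protist))
  expect_identical(countsMatrix(d1$bacteria), countsMatrix(d2$bacteria))
  expect_identical(d1$catalog, d2$catalog)
  expect_identical(d1$annotation$guilds, d2$annotation$guilds)
  expect_identical(d1$env, d2$env)
})

test_that("built webs hit the published-scale node counts exactly", {
  d <- sharedDataset()
  cfg <- d$manifest$config
  want <- c(spring = 69L, summer = 70L, autumn = 61L, winter = 59L)
  for (s in cfg$seasons) {
    w <- buildWeb(detectedTaxa(d$protist, s), d$annotation, d$catalog,
                  label = s)
    rep <- buildReport(w)
    expect_identical(rep$n_genus_nodes, as.integer(cfg$richness[[s]]))
    expect_identical(rep$n_nodes, want[[s]])
  }
})

test_that("catalog edges obey the guild-to-prey-class rules", {
  d <- sharedDataset()
  ann <- d$annotation
  guilds <- setNames(ann$guilds, ann$taxon_id)
  comp <- setNames(ann$compartment, ann$taxon_id)
  phyla <- ann$taxon_id[ann$compartment == "bacteria" &
                        ann$taxon_id != "bacteria"]
  isPhoto <- setNames(vapply(ann$guilds, function(g) "P" %in% g,
                             logical(1)), ann$taxon_id)
  cat <- d$catalog[d$catalog$provenance != "patch", ]
  for (k in seq_len(nrow(cat))) {
    pd <- cat$predator_id[k]
    py <- cat$prey_id[k]
    if (pd == "bacteria") {
      expect_identical(py, "DOC")
      next
    }
    g <- guilds[[pd]]
    allowed <-
      ("B" %in% g && (py %in% phyla || py == "bacteria")) ||
      ("A" %in% g && (py == "algae" || isTRUE(isPhoto[py]))) ||
      ("M" %in% g && py == "fungi") ||
      ("R" %in% g && isTRUE(comp[py] == "protist")) ||
      ("S" %in% g && py == "detritus") ||
      ("H-P" %in% g && isTRUE(comp[py] == "protist")) ||
      ("N" %in% g)
    expect_true(allowed, label = paste("edge", pd, "->", py))
  }
  ## phototroph-only genera never appear as predators
  photoOnly <- ann$taxon_id[vapply(ann$guilds, function(g)
    length(g) > 0 && all(g == "P"), logical(1))]
  expect_false(any(d$catalog$predator_id %in% photoOnly))
})

test_that("a forced single-phylum bacterivore diet yields exactly 2 edges", {
  ann <- data.frame(taxon_id = c("b1", "ph1", "ph2"),
                    compartment = c("protist", "bacteria", "bacteria"),
                    phylum = c("Ciliophora", "ph1", "ph2"),
                    stringsAsFactors = FALSE)
  ann$guilds <- list("B", character(), character())
  cfg <- syntheticConfig(preyMeans = c(B = 2, A = 12, R = 75, N = 80,
                                       M = 1, S = 1, `H-P` = 2),
                         preyMins = c(B = 2, A = 1, R = 45, N = 45,
                                      M = 1, S = 1, `H-P` = 1))
  set.seed(1)
  cat <- generateCatalog(ann, cfg)
  bEdges <- cat[cat$predator_id == "b1", ]
  expect_identical(nrow(bEdges), 2L)   # forced bacteria aggregate + 1 phylum
  expect_true("bacteria" %in% bEdges$prey_id)
})

test_that("a guildless raptor pool errors and no raptors means no raptor edges", {
  lone <- data.frame(taxon_id = "r1", compartment = "protist", phylum = "",
                     stringsAsFactors = FALSE)
  lone$guilds <- list("R")
  expect_error(generateCatalog(lone, syntheticConfig()),
               "no available prey class for guild R")

  noR <- syntheticConfig(guildCounts = c(P = 40L, B = 40L, A = 6L, N = 0L,
                                         R = 0L, `H-P` = 0L, M = 2L,
                                         S = 1L, U = 1L))
  set.seed(3)
  ann <- generateAnnotation(noR)
  cat <- generateCatalog(ann, noR)
  comp <- setNames(ann$compartment, ann$taxon_id)
  protProt <- comp[cat$predator_id] == "protist" &
              comp[cat$prey_id] == "protist"
  guilds <- setNames(ann$guilds, ann$taxon_id)
  raptorEdges <- protProt &
    vapply(cat$predator_id, function(p) "R" %in% guilds[[p]], logical(1))
  expect_false(any(raptorEdges))
})

test_that("generated artifacts pass every parser warning-free", {
  d <- sharedDataset()
  dir <- withr::local_tempdir()
  expect_no_warning(writeDataset(d, dir))
  expect_no_warning({
    p <- readCommunityTable(file.path(dir, "protist_counts.tsv"))
    b <- readCommunityTable(file.path(dir, "bacteria_counts.tsv"))
    a <- readAnnotation(file.path(dir, "annotation.tsv"))
    cat <- readInteractionCatalog(file.path(dir, "catalog.tsv"))
  })
  expect_identical(countsMatrix(p), countsMatrix(d$protist))
  expect_identical(nrow(cat), nrow(d$catalog))
  expect_identical(nrow(validateInputs(list(protist = p, bacteria = b,
                                            annotation = a, catalog = cat))),
                   0L)
})

test_that("generator summaries stay inside the documented bands", {
  for (seed in c(3, 13, 23, 33, 43)) {
    d <- generateSeasonalDataset(seed)
    for (s in d$manifest$config$seasons) {
      w <- buildWeb(detectedTaxa(d$protist, s), d$annotation, d$catalog,
                    label = s)
      C <- nLinks(w) / nNodes(w)^2
      expect_gte(C, 0.09)
      expect_lte(C, 0.22)
      expect_gte(length(basalNodes(w)), 1)
      expect_true(all(diag(adjacencyMatrix(w)) == 0L))
    }
  }
})

test_that("plantAssociation at strength zero is the identity", {
  d <- sharedDataset()
  d2 <- plantAssociation(d, "Int", "Mod", "+", strength = 0)
  expect_identical(countsMatrix(d2$protist), countsMatrix(d$protist))
  expect_identical(countsMatrix(d2$bacteria), countsMatrix(d$bacteria))
})

test_that("plantAssociation preserves season-level phylum detection", {
  d <- sharedDataset()
  set.seed(99)
  d2 <- plantAssociation(d, "Int", "Mod", "-", strength = 1)
  for (s in d$manifest$config$seasons)
    expect_setequal(detectedTaxa(d2$bacteria, s),
                    detectedTaxa(d$bacteria, s))
  expect_error(plantAssociation(d, "AD", "Mod", "+"), "unknown feature")
})
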