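## Seeded synthetic-data generator emulating the processed level of a
## seasonal subalpine-lake survey: four seasons x 9 samples, genus-level
## protist tables, phylum-level bacterial tables, a guild annotation and a
## guild-driven predator-prey catalog yielding webs of 59-70 nodes with
## connectance around 0.12-0.19 and a bacterivore predator share inside
## 0.45-0.78.

#' Default configuration of the synthetic-data generator
#'
#' The defaults define the emulated study conditions: per-season detected
#' genus richness 64/65/56/54 (so built webs, with the five aggregate
#' compartments, have 69/70/61/59 nodes), a 90-genus pool whose guild
#' composition keeps bacterivores at roughly half of all predators,
#' truncated-geometric diet sizes dense enough for connectance near 0.15,
#' log-normal abundances and Bernoulli per-sample occupancy.
#'
#' @param ... Named overrides of any default.
#' @return Named list of generator parameters.
#' @export
syntheticConfig <- function(...) {
  cfg <- list(
    seasons = c("spring", "summer", "autumn", "winter"),
    samplesPerSeason = 9L,
    genusPool = 90L,
    ## genus counts per primary guild (sums to genusPool)
    guildCounts = c(P = 12L, B = 46L, A = 6L, N = 5L, R = 15L, `H-P` = 3L,
                    M = 1L, S = 1L, U = 1L),
    ## detected genus richness per season (webs add 5 aggregate nodes)
    richness = c(spring = 64L, summer = 65L, autumn = 56L, winter = 54L),
    nBacterialPhyla = 17L,
    ## secondary guild memberships (multi-guild genera)
    detritivoreProb = 0.50,  # bacterivore that also ingests detritus (S)
    mixotrophProb = 0.10,    # phototroph that also grazes bacteria (B)
    ## diet sizes per guild: truncated geometric, lower-truncated at
    ## preyMins (generalists never have degenerate diets) and capped at the
    ## prey pool
    preyMeans = c(B = 14, A = 12, R = 75, N = 80, M = 1, S = 1, `H-P` = 2),
    preyMins = c(B = 8, A = 1, R = 45, N = 45, M = 1, S = 1, `H-P` = 1),
    occupancy = 0.8,
    ## per-sample bacterial phylum counts vary widely (uniform draw), so the
    ## bacterivore-bacteria interaction proportion has strong idiosyncratic
    ## per-sample variation independent of the protist backbone
    phylaPerSample = c(1L, 17L),
    abundanceMeanlog = 3,
    abundanceSdlog = 1.2,
    bacterivoreShareBand = c(0.45, 0.78),
    plantStrength = 1)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

truncGeom <- function(n, mean, max, min = 1) {
  if (max < 1) stop("empty prey pool", call. = FALSE)
  min <- base::min(min, max)
  p <- base::min(1, 1 / base::max(1, mean - min + 1))
  pmin(as.integer(min) + stats::rgeom(n, p), as.integer(max))
}

syntheticPhyla <- function(n)
  sprintf("bacphy%02d", seq_len(n))

#' Generate a guild annotation for a synthetic community
#'
#' Assigns each genus a primary guild according to the configured guild
#' composition, adds secondary guilds (detritivorous bacterivores that also
#' carry the saprotroph guild, mixotrophic phototrophs that also graze
#' bacteria) with the configured probabilities, and appends annotation rows
#' for the bacterial phylum nodes and the five aggregate compartments. Uses
#' the ambient RNG stream.
#'
#' @param config See \code{\link{syntheticConfig}}.
#' @return Annotation data.frame (see \code{\link{readAnnotation}}).
#' @export
generateAnnotation <- function(config = syntheticConfig()) {
  gc <- config$guildCounts
  stopifnot(sum(gc) == config$genusPool)
  ids <- sprintf("g%03d", seq_len(config$genusPool))
  primary <- sample(rep(names(gc), gc))
  guilds <- as.list(primary)
  for (i in seq_along(ids)) {
    g <- primary[i]
    if (g == "B" && stats::runif(1) < config$detritivoreProb)
      guilds[[i]] <- c(guilds[[i]], "S")
    else if (g == "P" && stats::runif(1) < config$mixotrophProb)
      guilds[[i]] <- c(guilds[[i]], "B")
  }
  phylumPool <- c("Ciliophora", "Cercozoa", "Chlorophyta", "Ochrophyta",
                  "Dinoflagellata", "Chrysophyceae", "Apicomplexa")
  ann <- data.frame(taxon_id = ids, compartment = "protist",
                    phylum = sample(phylumPool, length(ids), replace = TRUE),
                    stringsAsFactors = FALSE)
  ann$guilds <- guilds
  phyla <- syntheticPhyla(config$nBacterialPhyla)
  bac <- data.frame(taxon_id = phyla, compartment = "bacteria",
                    phylum = phyla, stringsAsFactors = FALSE)
  bac$guilds <- rep(list(character()), nrow(bac))
  agg <- data.frame(taxon_id = AGGREGATE_COMPARTMENTS,
                    compartment = AGGREGATE_COMPARTMENTS, phylum = "",
                    stringsAsFactors = FALSE)
  agg$guilds <- rep(list(character()), nrow(agg))
  rbind(ann, bac, agg)
}

hasGuild <- function(annotation, code)
  vapply(annotation$guilds, function(g) code %in% g, logical(1))

#' Generate a predator-prey interaction catalog by guild rules
#'
#' Diets follow the guild semantics: bacterivores (B) take bacterial phyla
#' and the bacteria aggregate (the aggregate is always in a bacterivore's
#' diet); algivores (A) take phototroph genera and the algae aggregate;
#' mycophagous genera (M) take fungi; raptors (R) take other protist
#' genera; nonselective omnivores (N) take any node class; saprotrophs (S)
#' take detritus; heterotrophic parasites (H-P) attach to one or two host
#' genera as predator; phototrophs (P) consume nothing; the bacteria
#' aggregate consumes DOC. Diet sizes are truncated-geometric with the
#' configured means. If both directions of a pair arise (a 2-cycle), the
#' second is dropped so sign pairs stay classic predator-prey. Uses the
#' ambient RNG stream.
#'
#' @param annotation Annotation as from \code{\link{generateAnnotation}}
#'   (must contain at least one genus per consumer guild it names).
#' @param config See \code{\link{syntheticConfig}}.
#' @return Interaction catalog data.frame.
#' @export
generateCatalog <- function(annotation, config = syntheticConfig()) {
  genera <- annotation$taxon_id[annotation$compartment == "protist"]
  phyla <- annotation$taxon_id[annotation$compartment == "bacteria" &
                               annotation$taxon_id != "bacteria"]
  photoGenera <- annotation$taxon_id[annotation$compartment == "protist" &
                                     hasGuild(annotation, "P")]
  pm <- config$preyMeans
  pmin0 <- config$preyMins
  pred <- character()
  prey <- character()
  addEdges <- function(p, q) {
    pred <<- c(pred, rep(p, length(q)))
    prey <<- c(prey, q)
  }
  pickDiet <- function(pool, mean, guild, forced = character()) {
    pool <- setdiff(pool, forced)
    k <- truncGeom(1, mean, max(1, length(pool) + length(forced)),
                   min = pmin0[[guild]])
    k <- max(0, k - length(forced))
    if (length(pool) == 0 && length(forced) == 0)
      stop("no available prey class for guild ", guild, call. = FALSE)
    c(forced, if (k > 0) sample(pool, min(k, length(pool))))
  }
  for (i in which(annotation$compartment == "protist")) {
    g <- annotation$taxon_id[i]
    for (guild in annotation$guilds[[i]]) {
      diet <- switch(guild,
        B = pickDiet(phyla, pm[["B"]], "B", forced = "bacteria"),
        A = pickDiet(setdiff(photoGenera, g), pm[["A"]], "A",
                     forced = "algae"),
        M = "fungi",
        R = {
          pool <- setdiff(genera, g)
          if (!length(pool))
            stop("no available prey class for guild R", call. = FALSE)
          sample(pool, min(truncGeom(1, pm[["R"]], length(pool),
                                     min = pmin0[["R"]]), length(pool)))
        },
        N = {
          pool <- c(setdiff(genera, g), "algae", "bacteria", "fungi",
                    "detritus")
          sample(pool, min(truncGeom(1, pm[["N"]], length(pool),
                                     min = pmin0[["N"]]), length(pool)))
        },
        S = "detritus",
        `H-P` = {
          pool <- setdiff(genera, g)
          if (!length(pool))
            stop("no available prey class for guild H-P", call. = FALSE)
          sample(pool, min(truncGeom(1, pm[["H-P"]], length(pool),
                                     min = pmin0[["H-P"]]), length(pool)))
        },
        character())
      if (length(diet)) addEdges(g, diet)
    }
  }
  addEdges("bacteria", "DOC")
  cat <- interactionCatalog(pred, prey, provenance = "synthetic")
  ## drop the reverse direction of mutual pairs (keep first occurrence)
  key <- paste(cat$predator_id, cat$prey_id)
  revKey <- paste(cat$prey_id, cat$predator_id)
  mutualLater <- revKey %in% key & duplicated(pmin(key, revKey))
  cat <- cat[!mutualLater, , drop = FALSE]
  rownames(cat) <- NULL
  cat
}

## every detected genus must interact within its season; returns the catalog
## with the minimal deterministic patch edges added
patchSeasonConnectivity <- function(catalog, annotation, detected, phyla) {
  for (season in names(detected)) {
    D <- detected[[season]]
    present <- c(D, phyla, AGGREGATE_COMPARTMENTS)
    sub <- catalog[catalog$predator_id %in% present &
                   catalog$prey_id %in% present, , drop = FALSE]
    connected <- union(sub$predator_id, sub$prey_id)
    orphans <- setdiff(D, connected)
    if (!length(orphans)) next
    idx <- match(orphans, annotation$taxon_id)
    nGenera <- sort(intersect(
      D, annotation$taxon_id[hasGuild(annotation, "N")]))
    newPred <- character()
    newPrey <- character()
    for (k in seq_along(orphans)) {
      g <- orphans[k]
      gl <- annotation$guilds[[idx[k]]]
      if (any(c("R", "H-P") %in% gl)) {
        host <- sort(setdiff(D, g))[1]
        newPred <- c(newPred, g); newPrey <- c(newPrey, host)
      } else {
        ## phototroph or unknown: make it prey of a detected nonselective
        ## omnivore (guaranteed by the generator), else of a detected raptor
        eater <- if (length(nGenera)) setdiff(nGenera, g)[1] else
          sort(setdiff(D, g))[1]
        newPred <- c(newPred, eater); newPrey <- c(newPrey, g)
      }
    }
    add <- interactionCatalog(newPred, newPrey, provenance = "patch")
    catalog <- rbind(catalog, add)
    catalog <- catalog[!duplicated(catalog[, c("predator_id", "prey_id")]), ,
                       drop = FALSE]
  }
  rownames(catalog) <- NULL
  catalog
}

## fixed-size occupancy: every sample holds the same number of taxa,
## round(occupancy * n), drawn without replacement, so per-sample richness
## carries no shared variance; each detected taxon is forced into at least
## one sample
occupancyCounts <- function(detected, allTaxa, samples, occupancy,
                            meanlog, sdlog) {
  m <- matrix(0, length(samples), length(allTaxa),
              dimnames = list(samples, allTaxa))
  k <- max(1, round(occupancy * length(detected)))
  for (sm in samples) {
    present <- sample(detected, k)
    m[sm, present] <- pmax(1, round(stats::rlnorm(k, meanlog, sdlog)))
  }
  missing <- detected[colSums(m[, detected, drop = FALSE] > 0) == 0]
  for (g in missing)
    m[sample(samples, 1), g] <- pmax(1, round(stats::rlnorm(1, meanlog,
                                                            sdlog)))
  m
}

## bacterial phylum occupancy: the number of phyla per sample is drawn
## uniformly from the configured range
phylumCounts <- function(phyla, samples, sizeRange, meanlog, sdlog) {
  m <- matrix(0, length(samples), length(phyla),
              dimnames = list(samples, phyla))
  sizes <- sample(seq(sizeRange[1], sizeRange[2]), length(samples),
                  replace = TRUE)
  for (i in seq_along(samples)) {
    present <- sample(phyla, min(sizes[i], length(phyla)))
    m[samples[i], present] <- pmax(1, round(stats::rlnorm(length(present),
                                                          meanlog, sdlog)))
  }
  missing <- phyla[colSums(m > 0) == 0]
  for (g in missing)
    m[sample(samples, 1), g] <- pmax(1, round(stats::rlnorm(1, meanlog,
                                                            sdlog)))
  m
}

#' Generate a full seasonal dataset
#'
#' Produces everything the pipeline consumes: a 36-sample protist genus
#' table and bacterial phylum table (both with per-sample season labels), a
#' guild annotation, a guild-rule interaction catalog (patched so that every
#' detected genus interacts within its season, making per-season built-web
#' genus counts hit the richness targets exactly) and a simple
#' environmental table. Deterministic given the seed.
#'
#' @param seed Integer seed.
#' @param config See \code{\link{syntheticConfig}}.
#' @return List with elements \code{protist} and \code{bacteria}
#'   (\linkS4class{CommunityTable}), \code{annotation}, \code{catalog},
#'   \code{env} (data.frame) and \code{manifest} (seed and config).
#' @export
generateSeasonalDataset <- function(seed, config = syntheticConfig()) {
  set.seed(seed)
  stopifnot(setequal(names(config$richness), config$seasons))
  if (any(config$richness > config$genusPool))
    stop("infeasible richness target: more genera requested than the pool",
         call. = FALSE)
  annotation <- generateAnnotation(config)
  catalog <- generateCatalog(annotation, config)
  genera <- annotation$taxon_id[annotation$compartment == "protist"]
  phyla <- annotation$taxon_id[annotation$compartment == "bacteria" &
                               annotation$taxon_id != "bacteria"]
  nGenera <- annotation$taxon_id[annotation$compartment == "protist" &
                                 hasGuild(annotation, "N")]

  detected <- lapply(config$seasons, function(s) {
    D <- sample(genera, config$richness[[s]])
    if (!any(D %in% nGenera)) {
      ## guarantee a nonselective omnivore so connectivity can be patched
      swapOut <- sample(setdiff(D, nGenera), 1)
      D <- c(setdiff(D, swapOut), sample(nGenera, 1))
    }
    sort(D)
  })
  names(detected) <- config$seasons
  catalog <- patchSeasonConnectivity(catalog, annotation, detected, phyla)

  sampleIds <- unlist(lapply(config$seasons, function(s)
    sprintf("%s_%02d", s, seq_len(config$samplesPerSeason))))
  seasonVec <- rep(config$seasons, each = config$samplesPerSeason)

  protCounts <- matrix(0, length(sampleIds), length(genera),
                       dimnames = list(sampleIds, genera))
  bacCounts <- matrix(0, length(sampleIds), length(phyla),
                      dimnames = list(sampleIds, phyla))
  for (s in config$seasons) {
    rows <- seasonVec == s
    protCounts[rows, ] <- occupancyCounts(
      detected[[s]], genera, sampleIds[rows], config$occupancy,
      config$abundanceMeanlog, config$abundanceSdlog)
    bacCounts[rows, ] <- phylumCounts(
      phyla, sampleIds[rows], config$phylaPerSample,
      config$abundanceMeanlog, config$abundanceSdlog)
  }

  seasonTemp <- c(spring = 10, summer = 18, autumn = 9, winter = 3)
  env <- data.frame(
    sample_id = sampleIds, season = seasonVec,
    temperature = seasonTemp[seasonVec] + stats::rnorm(length(sampleIds), 0, 1),
    pH = 8 + stats::rnorm(length(sampleIds), 0, 0.2),
    DO = 9 + stats::rnorm(length(sampleIds), 0, 0.8),
    stringsAsFactors = FALSE)
  rownames(env) <- NULL

  list(protist = communityTable(protCounts, seasonVec),
       bacteria = communityTable(bacCounts, seasonVec),
       annotation = annotation, catalog = catalog, env = env,
       manifest = list(seed = seed, config = config))
}

## per-sample value of a buildable metric on the topology sub-network
## (bacteria as one aggregate node, matching the analysis convention)
perSampleMetric <- function(dataset, metric) {
  vals <- numeric()
  ids <- character()
  for (s in unique(seasonOf(dataset$protist))) {
    genera <- detectedTaxa(dataset$protist, s)
    web <- buildWeb(genera, dataset$annotation, dataset$catalog, label = s)
    samples <- sampleIDs(dataset$protist)[seasonOf(dataset$protist) == s]
    for (sm in samples) {
      taxa <- sampleTaxa(dataset$protist, sm)
      sub <- sampleSubweb(web, taxa, label = sm)
      cx <- complexity(sub)
      vals <- c(vals, switch(metric, Mod = modularityQ(sub)$Q, L = cx$L,
                             LD = cx$LD, C = cx$C,
                             stop("unknown metric: ", metric,
                                  call. = FALSE)))
      ids <- c(ids, sm)
    }
  }
  names(vals) <- ids
  vals
}

#' Plant a feature-metric association into a dataset
#'
#' Perturbs per-sample bacterial phylum incidence so that the association
#' between the bacterivore-bacteria interaction proportion (Int) and a web
#' metric has the requested sign: samples ranked high (for
#' \code{sign = "+"}) or low (for \code{sign = "-"}) on the baseline metric
#' keep or gain detected phyla, the opposite tail loses them. Phylum
#' incidence moves Int almost linearly (every present phylum feeds most
#' bacterivores) while leaving the protist backbone untouched, so the
#' feedback of the perturbation on the target metric stays small relative to
#' its baseline spread. Association strength is monotone in
#' \code{strength}; \code{strength = 0} returns the dataset unchanged. A
#' phylum is never removed from its last sample in a season, so
#' season-level detection is preserved. Uses the ambient RNG stream.
#'
#' @param dataset As returned by \code{\link{generateSeasonalDataset}}.
#' @param feature Currently only \code{"Int"}.
#' @param metric One of \code{"Mod"}, \code{"L"}, \code{"LD"}, \code{"C"}.
#' @param sign \code{"+"} or \code{"-"}.
#' @param strength Nonnegative effect strength (default: the configured
#'   \code{plantStrength}).
#' @return The perturbed dataset; \code{manifest$planted} records the
#'   effect.
#' @export
plantAssociation <- function(dataset, feature = "Int",
                             metric = c("Mod", "L", "LD", "C"),
                             sign = c("+", "-"), strength = NULL) {
  if (!identical(feature, "Int"))
    stop("unknown feature: ", feature, call. = FALSE)
  metric <- match.arg(metric)
  sign <- match.arg(sign)
  if (is.null(strength)) strength <- dataset$manifest$config$plantStrength
  stopifnot(strength >= 0)
  if (strength == 0) return(dataset)

  m <- perSampleMetric(dataset, metric)
  n <- length(m)
  r <- (rank(m, ties.method = "average") - (n + 1) / 2) / ((n - 1) / 2)
  delta <- pmax(-1, pmin(1, (if (sign == "+") 1 else -1) * strength * r))
  names(delta) <- names(m)

  counts <- countsMatrix(dataset$bacteria)
  seas <- seasonOf(dataset$bacteria)
  cfg <- dataset$manifest$config
  for (sm in names(m)) {
    rowsSeason <- names(seas)[seas == seas[[sm]]]
    detected <- colnames(counts)[colSums(
      counts[rowsSeason, , drop = FALSE]) > 0]
    present <- detected[counts[sm, detected] > 0]
    d <- delta[[sm]]
    if (d > 0) {
      absent <- setdiff(detected, present)
      add <- absent[stats::runif(length(absent)) < d]
      if (length(add))
        counts[sm, add] <- pmax(1, round(stats::rlnorm(
          length(add), cfg$abundanceMeanlog, cfg$abundanceSdlog)))
    } else if (d < 0) {
      drop <- present[stats::runif(length(present)) < -d]
      for (g in drop)
        if (sum(counts[setdiff(rowsSeason, sm), g] > 0) > 0)
          counts[sm, g] <- 0
    }
  }
  dataset$bacteria <- communityTable(counts, unname(seas))
  dataset$manifest$planted <- list(feature = feature, metric = metric,
                                   sign = sign, strength = strength)
  dataset
}

#' Write a synthetic dataset to a directory
#'
#' Writes the protist and bacterial tables, annotation, catalog and
#' environment table in the package's TSV dialects, plus a
#' \code{manifest.json} recording the seed and configuration.
#'
#' @param dataset As returned by \code{\link{generateSeasonalDataset}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCommunityTable(dataset$protist, file.path(dir, "protist_counts.tsv"))
  writeCommunityTable(dataset$bacteria, file.path(dir, "bacteria_counts.tsv"))
  writeAnnotation(dataset$annotation, file.path(dir, "annotation.tsv"))
  writeInteractionCatalog(dataset$catalog, file.path(dir, "catalog.tsv"))
  writeTsv(dataset$env, file.path(dir, "environment.tsv"))
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
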