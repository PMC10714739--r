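#' Taxa detected in a season
#'
#' A taxon is detected in a season when its counts summed over that season's
#' samples reach \code{minCount}. The default \code{minCount = 1} treats any
#' presence as detection; no abundance threshold is applied beyond that.
#'
#' @param table A \linkS4class{CommunityTable}.
#' @param season Season label present in the table's metadata.
#' @param minCount Minimum summed count (>= 1).
#' @return Character vector of detected taxon ids.
#' @export
detectedTaxa <- function(table, season, minCount = 1) {
  stopifnot(minCount >= 1)
  seas <- seasonOf(table)
  if (!season %in% seas)
    stop("unknown season: ", season, call. = FALSE)
  cts <- SummarizedExperiment::assay(table, "counts")
  tot <- rowSums(cts[, seas == season, drop = FALSE])
  names(tot)[tot >= minCount]
}

#' Taxa detected in a single sample
#'
#' @param table A \linkS4class{CommunityTable}.
#' @param sampleId Sample identifier.
#' @param minCount Minimum count (>= 1).
#' @return Character vector of taxon ids present in the sample.
#' @export
sampleTaxa <- function(table, sampleId, minCount = 1) {
  stopifnot(minCount >= 1)
  if (!sampleId %in% sampleIDs(table))
    stop("unknown sample: ", sampleId, call. = FALSE)
  cts <- SummarizedExperiment::assay(table, "counts")
  v <- cts[, sampleId]
  rownames(cts)[v >= minCount]
}

#' Build a food web from detected taxa, annotation and catalog
#'
#' Nodes are the detected taxa plus the requested aggregate compartments
#' (algae, bacteria, fungi, detritus, DOC); edges are the catalog edges whose
#' endpoints are both present. Catalog edges with an absent endpoint are
#' silently excluded but counted in the build report (literature catalogs
#' routinely reference taxa absent from a given season). Aggregate
#' compartments are retained even when isolated, because the webs treat them
#' as standing compartments; detected taxa that end up with no links are
#' dropped so that S counts interacting trophic species.
#'
#' @param taxa Character vector of detected taxon ids (each must be
#'   annotated).
#' @param annotation Annotation data.frame (see \code{\link{readAnnotation}}).
#' @param catalog Interaction catalog data.frame.
#' @param aggregates Aggregate compartments to include (default all five).
#' @param label Web label, e.g. the season.
#' @return A \linkS4class{FoodWeb} whose \code{\link{buildReport}} lists
#'   \code{n_nodes}, \code{n_genus_nodes}, \code{n_aggregate_nodes},
#'   \code{n_links}, \code{n_excluded_edges}, \code{n_dropped_isolated} and
#'   \code{guild_counts}.
#' @export
buildWeb <- function(taxa, annotation, catalog,
                     aggregates = aggregateCompartments(), label = "") {
  taxa <- unique(as.character(taxa))
  aggregates <- match.arg(aggregates, AGGREGATE_COMPARTMENTS,
                          several.ok = TRUE)
  missing <- setdiff(taxa, annotation$taxon_id)
  if (length(missing))
    stop("unannotated taxa: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ann <- annotation[match(taxa, annotation$taxon_id), , drop = FALSE]

  ## canonical aggregate nodes, created whether or not annotated
  aggNodes <- data.frame(taxon_id = aggregates, compartment = aggregates,
                         phylum = "", stringsAsFactors = FALSE)
  aggNodes$guilds <- rep(list(character()), nrow(aggNodes))
  ann <- ann[!ann$taxon_id %in% aggregates, , drop = FALSE]
  ann <- ann[order(ann$taxon_id), , drop = FALSE]
  all <- rbind(ann[, c("taxon_id", "compartment", "phylum", "guilds")],
               aggNodes)

  ids <- all$taxon_id
  keep <- catalog$predator_id %in% ids & catalog$prey_id %in% ids
  edges <- catalog[keep, , drop = FALSE]
  nExcluded <- sum(!keep)

  a <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(edges))
    a[cbind(edges$prey_id, edges$predator_id)] <- 1L

  ## drop isolated non-aggregate nodes; requested aggregates always stay
  isolated <- rowSums(a) == 0 & colSums(a) == 0
  drop <- isolated & !(ids %in% aggregates)
  nDropped <- sum(drop)
  if (sum(!drop) == 0)
    stop("web construction produced zero nodes", call. = FALSE)
  all <- all[!drop, , drop = FALSE]
  a <- a[!drop, !drop, drop = FALSE]

  nodes <- data.frame(node_id = all$taxon_id, name = all$taxon_id,
                      stringsAsFactors = FALSE)
  nodes$kind <- ifelse(all$compartment %in% AGGREGATE_COMPARTMENTS,
                       "aggregate", "genus")
  nodes$compartment <- all$compartment
  nodes$phylum <- all$phylum
  nodes$guilds <- all$guilds

  guildCounts <- vapply(GUILD_CODES, function(g)
    sum(vapply(nodes$guilds, function(x) g %in% x, logical(1))), integer(1))
  report <- list(n_nodes = nrow(nodes),
                 n_genus_nodes = sum(nodes$kind == "genus"),
                 n_aggregate_nodes = sum(nodes$kind == "aggregate"),
                 n_links = as.integer(sum(a)),
                 n_excluded_edges = as.integer(nExcluded),
                 n_dropped_isolated = as.integer(nDropped),
                 guild_counts = as.list(guildCounts))
  foodWeb(nodes, a, label = label, report = report)
}

#' Write a build report as JSON
#'
#' @param web A \linkS4class{FoodWeb} built by \code{\link{buildWeb}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeBuildReport <- function(web, path) {
  jsonlite::write_json(buildReport(web), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Partition web nodes by trophic guild
#'
#' A node belongs to every guild in its guild set (multi-guild membership is
#' allowed). Predators are the nodes with at least one prey; per-guild
#' predator shares use the number of distinct predators as denominator, so a
#' multi-guild predator contributes to several shares and the shares need
#' not sum to one.
#'
#' @param web A \linkS4class{FoodWeb}.
#' @return List with \code{guilds} (named list of node-id vectors),
#'   \code{predators} (ids of nodes with >= 1 prey) and
#'   \code{predatorShare} (named numeric; NA when there are no predators).
#' @export
guildPartition <- function(web) {
  nd <- nodeInfo(web)
  a <- adjacencyMatrix(web)
  guilds <- lapply(GUILD_CODES, function(g)
    nd$node_id[vapply(nd$guilds, function(x) g %in% x, logical(1))])
  names(guilds) <- GUILD_CODES
  predators <- nd$node_id[colSums(a) > 0]
  share <- vapply(guilds, function(ids) {
    if (!length(predators)) return(NA_real_)
    length(intersect(ids, predators)) / length(predators)
  }, numeric(1))
  list(guilds = guilds, predators = predators, predatorShare = share)
}
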