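#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
NULL

## Controlled vocabularies used across the package.
GUILD_CODES <- c("A", "B", "M", "N", "H-P", "P", "R", "S", "U")
AGGREGATE_COMPARTMENTS <- c("bacteria", "algae", "fungi", "detritus", "DOC")
COMPARTMENTS <- c("protist", AGGREGATE_COMPARTMENTS)

#' Trophic guild codes
#'
#' The protist trophic functional groups recognised by the package, coded as
#' in the Protist Interaction Database style: algivore (A), bacterivore (B),
#' mycophagous (M), nonselective omnivore (N), heterotrophic parasite (H-P),
#' phototroph (P), raptor (R), saprotroph (S) and unknown (U).
#'
#' @return Character vector of the nine guild codes.
#' @examples
#' guildCodes()
#' @export
guildCodes <- function() GUILD_CODES

#' Aggregate compartment names
#'
#' Non-genus web compartments treated as single trophic species: bacteria,
#' algae, fungi, detritus and dissolved organic carbon (DOC).
#'
#' @return Character vector of the five aggregate compartment names.
#' @examples
#' aggregateCompartments()
#' @export
aggregateCompartments <- function() AGGREGATE_COMPARTMENTS

## ---------------------------------------------------------------------------
## CommunityTable
## ---------------------------------------------------------------------------

#' CommunityTable: taxon abundance table with season metadata
#'
#' A thin wrapper around \linkS4class{SummarizedExperiment} holding a
#' nonnegative \code{counts} assay (taxa in rows, samples in columns) and a
#' per-sample \code{season} label in \code{colData}. On disk the table is a
#' TSV with samples as rows (see \code{\link{readCommunityTable}}); the
#' constructor transposes into the assay orientation.
#'
#' @seealso \code{\link{communityTable}}, \code{\link{readCommunityTable}}
#' @export
setClass("CommunityTable", contains = "SummarizedExperiment")

setValidity("CommunityTable", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(cts)) msg <- c(msg, "counts contain missing values")
    else if (any(cts < 0)) msg <- c(msg, "counts must be nonnegative")
    if (is.null(rownames(cts)) || anyDuplicated(rownames(cts)))
      msg <- c(msg, "taxon ids must be unique and non-empty")
    if (is.null(colnames(cts)) || anyDuplicated(colnames(cts)))
      msg <- c(msg, "sample ids must be unique and non-empty")
  }
  if (!"season" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'season' column")
  if (length(msg)) msg else TRUE
})

#' Construct a CommunityTable
#'
#' @param counts Nonnegative numeric matrix, samples in rows and taxa in
#'   columns (the file orientation); row and column names are required and
#'   must be unique.
#' @param season Character vector of per-sample season labels, one per row of
#'   \code{counts}.
#' @return A \linkS4class{CommunityTable}.
#' @examples
#' m <- matrix(c(1, 2, 3, 0, 0, 4), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
#' communityTable(m, season = c("spring", "spring"))
#' @export
communityTable <- function(counts, season) {
  counts <- as.matrix(counts)
  stopifnot(length(season) == nrow(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = t(counts)),
    colData = S4Vectors::DataFrame(season = as.character(season),
                                   row.names = rownames(counts)))
  new("CommunityTable", se)
}

#' @describeIn communityTable Sample identifiers (column names of the assay).
#' @param x A \code{CommunityTable}.
#' @export
sampleIDs <- function(x) colnames(SummarizedExperiment::assay(x, "counts"))

#' @describeIn communityTable Taxon identifiers (row names of the assay).
#' @export
taxonIDs <- function(x) rownames(SummarizedExperiment::assay(x, "counts"))

#' @describeIn communityTable Per-sample season labels, named by sample.
#' @export
seasonOf <- function(x) {
  s <- as.character(SummarizedExperiment::colData(x)$season)
  names(s) <- sampleIDs(x)
  s
}

#' @describeIn communityTable Counts in file orientation (samples x taxa).
#' @export
countsMatrix <- function(x) t(SummarizedExperiment::assay(x, "counts"))

## ---------------------------------------------------------------------------
## FoodWeb
## ---------------------------------------------------------------------------

#' FoodWeb: a binary directed trophic network
#'
#' Nodes are genus-level taxa or aggregate compartments; the adjacency matrix
#' follows the convention \eqn{a_{ij} = 1} when node \eqn{j} preys on node
#' \eqn{i} (prey in rows, predators in columns). The diagonal is zero
#' (cannibalism is not represented) and, whenever the web has links, at least
#' one basal node (a node that is eaten but eats nothing) must exist.
#'
#' @slot nodes data.frame with columns \code{node_id}, \code{name},
#'   \code{kind} ("genus" or "aggregate"), \code{compartment}, \code{phylum}
#'   and a list-column \code{guilds} of guild-code character vectors.
#' @slot adjacency binary integer matrix, dimnames equal to \code{node_id} in
#'   registry order.
#' @slot label free-text label, e.g. the season.
#' @slot report list; the build report when the web came from
#'   \code{\link{buildWeb}}.
#' @seealso \code{\link{foodWeb}}, \code{\link{buildWeb}}
#' @export
setClass("FoodWeb",
         representation(nodes = "data.frame", adjacency = "matrix",
                        label = "character", report = "list"))

setValidity("FoodWeb", function(object) {
  nd <- object@nodes
  a <- object@adjacency
  msg <- character()
  need <- c("node_id", "name", "kind", "compartment", "phylum", "guilds")
  if (!all(need %in% colnames(nd)))
    return(paste("nodes must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(nd$node_id)) msg <- c(msg, "node_id values must be unique")
  if (!all(nd$kind %in% c("genus", "aggregate")))
    msg <- c(msg, "kind must be 'genus' or 'aggregate'")
  if (!all(nd$compartment %in% COMPARTMENTS))
    msg <- c(msg, paste("compartment must be one of:",
                        paste(COMPARTMENTS, collapse = ", ")))
  agg <- nd$kind == "aggregate"
  if (!all(agg == (nd$compartment %in% AGGREGATE_COMPARTMENTS)))
    msg <- c(msg, "kind is 'aggregate' iff compartment is an aggregate class")
  if (!is.list(nd$guilds))
    msg <- c(msg, "guilds must be a list-column")
  else {
    codes <- unlist(nd$guilds, use.names = FALSE)
    if (length(codes) && !all(codes %in% GUILD_CODES))
      msg <- c(msg, paste("unknown guild code(s):",
                          paste(setdiff(codes, GUILD_CODES), collapse = ", ")))
    nonliving <- nd$compartment %in% c("detritus", "DOC")
    if (any(lengths(nd$guilds[nonliving]) > 0))
      msg <- c(msg, "detritus and DOC nodes must have an empty guild set")
  }
  S <- nrow(nd)
  if (!is.matrix(a) || nrow(a) != S || ncol(a) != S)
    msg <- c(msg, "adjacency must be a square matrix matching the registry")
  else {
    if (!all(a %in% c(0L, 1L))) msg <- c(msg, "adjacency entries must be 0/1")
    if (S > 0 && any(diag(a) != 0)) msg <- c(msg, "diagonal must be zero")
    if (S > 0 && (!identical(rownames(a), nd$node_id) ||
                  !identical(colnames(a), nd$node_id)))
      msg <- c(msg, "adjacency dimnames must equal node_id in order")
    if (S > 0 && sum(a) > 0) {
      basal <- colSums(a) == 0 & rowSums(a) > 0
      if (!any(basal))
        msg <- c(msg, "a web with links needs at least one basal node")
    }
  }
  if (length(object@label) != 1) msg <- c(msg, "label must be length one")
  if (length(msg)) msg else TRUE
})

#' Construct a FoodWeb
#'
#' @param nodes data.frame of node attributes (see \linkS4class{FoodWeb});
#'   missing optional columns (\code{name}, \code{phylum}) are filled, and
#'   \code{kind} is derived from \code{compartment} when absent.
#' @param adjacency Binary matrix, prey in rows and predators in columns,
#'   dimnames matching \code{nodes$node_id}. Defaults to the empty web.
#' @param label Free-text label, e.g. a season name.
#' @param report Optional build report list.
#' @return A validated \linkS4class{FoodWeb}.
#' @examples
#' nd <- data.frame(node_id = c("g1", "bacteria"), stringsAsFactors = FALSE)
#' nd$compartment <- c("protist", "bacteria")
#' nd$guilds <- list("B", character())
#' a <- matrix(0L, 2, 2, dimnames = list(nd$node_id, nd$node_id))
#' a["bacteria", "g1"] <- 1L   # g1 preys on bacteria
#' foodWeb(nd, a, label = "demo")
#' @export
foodWeb <- function(nodes, adjacency = NULL, label = "", report = list()) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  nodes$node_id <- as.character(nodes$node_id)
  if (is.null(nodes$compartment))
    nodes$compartment <- rep("protist", nrow(nodes))
  if (is.null(nodes$kind))
    nodes$kind <- ifelse(nodes$compartment %in% AGGREGATE_COMPARTMENTS,
                         "aggregate", "genus")
  if (is.null(nodes$name)) nodes$name <- nodes$node_id
  if (is.null(nodes$phylum)) nodes$phylum <- rep("", nrow(nodes))
  if (is.null(nodes$guilds)) nodes$guilds <- rep(list(character()), nrow(nodes))
  nodes <- nodes[, c("node_id", "name", "kind", "compartment", "phylum",
                     "guilds")]
  rownames(nodes) <- NULL
  if (is.null(adjacency))
    adjacency <- matrix(0L, nrow(nodes), nrow(nodes),
                        dimnames = list(nodes$node_id, nodes$node_id))
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "integer"
  new("FoodWeb", nodes = nodes, adjacency = adjacency,
      label = as.character(label), report = as.list(report))
}

#' @describeIn foodWeb Node registry data.frame.
#' @param web A \code{FoodWeb}.
#' @export
nodeInfo <- function(web) web@nodes

#' @describeIn foodWeb Binary adjacency matrix (prey rows, predator columns).
#' @export
adjacencyMatrix <- function(web) web@adjacency

#' @describeIn foodWeb Web label.
#' @export
webLabel <- function(web) web@label

#' @describeIn foodWeb Number of nodes S.
#' @export
nNodes <- function(web) nrow(web@nodes)

#' @describeIn foodWeb Number of trophic links L.
#' @export
nLinks <- function(web) as.integer(sum(web@adjacency))

#' @describeIn foodWeb Build report recorded by \code{\link{buildWeb}}.
#' @export
buildReport <- function(web) web@report

#' @describeIn foodWeb ids of basal nodes (nodes with no prey).
#' @export
basalNodes <- function(web) {
  if (nNodes(web) == 0) return(character())
  web@nodes$node_id[colSums(web@adjacency) == 0]
}

setMethod("show", "FoodWeb", function(object) {
  S <- nNodes(object)
  L <- nLinks(object)
  cat("FoodWeb", if (nzchar(object@label)) sQuote(object@label) else "",
      sprintf("with %d nodes and %d links\n", S, L))
  if (S > 0) {
    cat("  compartments:",
        paste(sprintf("%s (%d)", names(table(object@nodes$compartment)),
                      table(object@nodes$compartment)), collapse = ", "), "\n")
    cat(sprintf("  connectance C = %.4g\n", L / S^2))
  }
})

## ---------------------------------------------------------------------------
## QSSResult
## ---------------------------------------------------------------------------

#' QSSResult: quasi sign-stability Monte Carlo summary
#'
#' @slot nDraws number of sampled community matrices.
#' @slot propStable fraction of draws whose eigenvalues all have negative
#'   real part (locally stable draws).
#' @slot meanMaxEig mean over draws of the largest eigenvalue real part;
#'   lower values indicate faster return to equilibrium.
#' @slot maxEigDraws per-draw largest real parts, length \code{nDraws}.
#' @slot seed RNG seed used (NA when drawn from the ambient stream).
#' @slot label web label carried through from the input.
#' @seealso \code{\link{qss}}
#' @export
setClass("QSSResult",
         representation(nDraws = "integer", propStable = "numeric",
                        meanMaxEig = "numeric", maxEigDraws = "numeric",
                        seed = "integer", label = "character"))

setValidity("QSSResult", function(object) {
  msg <- character()
  if (object@propStable < 0 || object@propStable > 1)
    msg <- c(msg, "propStable must lie in [0, 1]")
  if (length(object@maxEigDraws) != object@nDraws)
    msg <- c(msg, "maxEigDraws must have length nDraws")
  if (length(msg)) msg else TRUE
})

#' @describeIn qss Proportion of stable draws.
#' @param x A \code{QSSResult}.
#' @export
propStable <- function(x) x@propStable

#' @describeIn qss Mean largest eigenvalue real part over draws.
#' @export
meanMaxEig <- function(x) x@meanMaxEig

#' @describeIn qss Per-draw largest eigenvalue real parts.
#' @export
maxEigDraws <- function(x) x@maxEigDraws

setMethod("show", "QSSResult", function(object) {
  cat(sprintf("QSSResult%s: %d draws, prop. stable = %.4g, mean max Re(eig) = %.4g\n",
              if (nzchar(object@label)) paste0(" [", object@label, "]") else "",
              object@nDraws, object@propStable, object@meanMaxEig))
})

## ---------------------------------------------------------------------------
## NullEnsemble
## ---------------------------------------------------------------------------

#' NullEnsemble: a metric's distribution over curveball-randomized webs
#'
#' @slot metricName name of the metric.
#' @slot nRandom number of randomized replicates requested.
#' @slot values metric values on the replicates (NA where the metric was
#'   undefined on a replicate, e.g. an ungrounded trophic cycle).
#' @slot empirical the observed web's value.
#' @slot ci95 2.5/97.5 empirical percentile bounds of \code{values}.
#' @slot within TRUE when the empirical value lies inside the simulated
#'   range [min, max].
#' @slot seed RNG seed (NA when drawn from the ambient stream).
#' @slot nFailed number of replicates on which the metric was undefined.
#' @seealso \code{\link{nullDistribution}}
#' @export
setClass("NullEnsemble",
         representation(metricName = "character", nRandom = "integer",
                        values = "numeric", empirical = "numeric",
                        ci95 = "numeric", within = "logical",
                        seed = "integer", nFailed = "integer"))

setValidity("NullEnsemble", function(object) {
  msg <- character()
  if (length(object@values) != object@nRandom)
    msg <- c(msg, "values must have length nRandom")
  if (length(object@ci95) != 2 ||
      (!anyNA(object@ci95) && object@ci95[1] > object@ci95[2]))
    msg <- c(msg, "ci95 must be (low, high) with low <= high")
  if (length(msg)) msg else TRUE
})

#' @describeIn nullDistribution Replicate metric values.
#' @param x A \code{NullEnsemble}.
#' @export
nullValues <- function(x) x@values

#' @describeIn nullDistribution Observed web's metric value.
#' @export
empiricalValue <- function(x) x@empirical

#' @describeIn nullDistribution 95 percent percentile interval of the null.
#' @export
ci95 <- function(x) x@ci95

#' @describeIn nullDistribution Is the empirical value inside the simulated
#'   range?
#' @export
isWithinNull <- function(x) x@within

setMethod("show", "NullEnsemble", function(object) {
  cat(sprintf("NullEnsemble '%s': %d replicates (%d failed)\n",
              object@metricName, object@nRandom, object@nFailed))
  cat(sprintf("  empirical = %.4g, null 95%% CI = [%.4g, %.4g], within range: %s\n",
              object@empirical, object@ci95[1], object@ci95[2],
              object@within))
})
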