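## Complexity, topology and trophic-structure metrics.
##
## Adjacency convention everywhere: a[i, j] = 1 means node j preys on node i,
## so column j lists predator j's prey and row i lists prey i's predators.
## CC, CPL and modularity are computed on the symmetrized (undirected) graph;
## trophic direction carries no information for neighborhood structure.

asAdjacency <- function(web) {
  if (is(web, "FoodWeb")) adjacencyMatrix(web) else {
    a <- as.matrix(web)
    if (is.null(rownames(a)))
      dimnames(a) <- list(as.character(seq_len(nrow(a))),
                          as.character(seq_len(nrow(a))))
    storage.mode(a) <- "integer"
    a
  }
}

symGraph <- function(a) {
  s <- (a + t(a)) > 0
  igraph::graph_from_adjacency_matrix(s * 1, mode = "undirected")
}

#' Food-web complexity: S, L, LD, C
#'
#' Species count S, link count L, linkage density LD = L/S and directed
#' connectance C = L/S^2.
#'
#' @param web A \linkS4class{FoodWeb}, or a pair can be supplied directly via
#'   \code{S} and \code{L} (e.g. published values) with \code{web = NULL}.
#' @param S,L Optional species and link counts overriding \code{web}.
#' @return Named list with \code{S}, \code{L}, \code{LD}, \code{C}.
#' @examples
#' complexity(S = 69, L = 780)  # LD = 11.30, C = 0.16 at 2 dp
#' @export
complexity <- function(web = NULL, S = NULL, L = NULL) {
  if (is.null(S) || is.null(L)) {
    stopifnot(!is.null(web))
    a <- asAdjacency(web)
    S <- nrow(a)
    L <- sum(a)
  }
  stopifnot(S > 0)
  list(S = as.integer(S), L = as.integer(L), LD = L / S, C = L / S^2)
}

#' Mean clustering coefficient
#'
#' Mean over all nodes of the local clustering coefficient on the symmetrized
#' graph; nodes of degree < 2 contribute 0.
#'
#' @param web A \linkS4class{FoodWeb} or adjacency matrix.
#' @return Mean clustering coefficient in [0, 1].
#' @export
clusteringCoefficient <- function(web) {
  a <- asAdjacency(web)
  stopifnot(nrow(a) >= 1)
  g <- symGraph(a)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  mean(cc)
}

#' Characteristic path length
#'
#' Mean shortest-path length over all unordered reachable node pairs of the
#' symmetrized graph. Unreachable pairs are excluded from the mean and
#' counted in the returned report.
#'
#' @param web A \linkS4class{FoodWeb} or adjacency matrix (S >= 2).
#' @return List with \code{CPL} and \code{excluded_pairs}.
#' @export
characteristicPathLength <- function(web) {
  a <- asAdjacency(web)
  stopifnot(nrow(a) >= 2)
  d <- igraph::distances(symGraph(a))
  up <- d[upper.tri(d)]
  reach <- is.finite(up)
  if (!any(reach)) stop("no reachable node pair", call. = FALSE)
  list(CPL = mean(up[reach]), excluded_pairs = sum(!reach))
}

## Grounded nodes: basal nodes, plus consumers that can reach a basal node by
## following prey links. The prey-averaged linear system is nonsingular
## exactly when every node is grounded.
groundedNodes <- function(a) {
  S <- nrow(a)
  basal <- colSums(a) == 0
  grounded <- basal
  repeat {
    ## consumer j becomes grounded when any of its prey is grounded
    newG <- grounded | (colSums(a * grounded) > 0)
    if (all(newG == grounded)) break
    grounded <- newG
  }
  grounded
}

#' Prey-averaged trophic levels
#'
#' Basal nodes (no prey) have trophic level exactly 1; every consumer's level
#' is 1 plus the arithmetic mean of its prey's levels. The definition is
#' solved as a linear system, so loops (e.g. intraguild predation cycles)
#' are handled, provided every node draws, directly or indirectly, on a
#' basal resource. A consumer cycle with no basal input makes the system
#' singular; the error names the offending nodes.
#'
#' @param web A \linkS4class{FoodWeb} or adjacency matrix (prey rows,
#'   predator columns).
#' @return List with \code{TL} (named numeric vector) and \code{meanTL}.
#' @examples
#' a <- matrix(0L, 3, 3, dimnames = rep(list(c("r", "h", "c")), 2))
#' a["r", "h"] <- 1L; a["h", "c"] <- 1L
#' trophicLevels(a)$TL  # 1, 2, 3
#' @export
trophicLevels <- function(web) {
  a <- asAdjacency(web)
  S <- nrow(a)
  if (S == 0) stop("empty web", call. = FALSE)
  grounded <- groundedNodes(a)
  if (!all(grounded))
    stop("trophic levels undefined: consumer cycle with no basal input: ",
         paste(rownames(a)[!grounded], collapse = ", "), call. = FALSE)
  nPrey <- colSums(a)
  ## (I - W) TL = 1 with W[j, i] = 1/nPrey_j for i in prey(j)
  W <- t(a)
  cons <- nPrey > 0
  W[cons, ] <- W[cons, , drop = FALSE] / nPrey[cons]
  W[!cons, ] <- 0
  TL <- as.numeric(solve(diag(S) - W, rep(1, S)))
  names(TL) <- rownames(a)
  list(TL = TL, meanTL = mean(TL))
}

#' Omnivory fraction
#'
#' The fraction of species that feed at more than one trophic level: a node
#' is an omnivore when it has at least two prey whose trophic levels differ
#' by more than \code{tol}. The default denominator is all S nodes (the
#' "percentage of omnivory" convention); set \code{consumersOnly = TRUE} to
#' divide by the number of consumers instead.
#'
#' @param web A \linkS4class{FoodWeb} or adjacency matrix.
#' @param consumersOnly Use consumers as the denominator.
#' @param tol Numeric tolerance for distinct prey levels.
#' @return Omnivory fraction in [0, 1].
#' @export
omnivory <- function(web, consumersOnly = FALSE, tol = 1e-9) {
  a <- asAdjacency(web)
  TL <- trophicLevels(a)$TL
  isOmni <- vapply(seq_len(ncol(a)), function(j) {
    prey <- which(a[, j] == 1L)
    length(prey) >= 2 && (max(TL[prey]) - min(TL[prey])) > tol
  }, logical(1))
  denom <- if (consumersOnly) sum(colSums(a) > 0) else nrow(a)
  if (denom == 0) return(0)
  sum(isOmni) / denom
}

#' Modularity of a greedy agglomerative partition
#'
#' Newman modularity Q of the partition found by greedy agglomerative
#' optimization (Clauset-Newman-Moore, via igraph) on the symmetrized,
#' simplified graph. The algorithm is deterministic, so repeated runs on the
#' same web give identical Q and membership. A web without links returns
#' Q = 0 with every node in its own community.
#'
#' @param web A \linkS4class{FoodWeb} or adjacency matrix (S >= 2).
#' @return List with \code{Q} and named integer \code{membership}.
#' @export
modularityQ <- function(web) {
  a <- asAdjacency(web)
  stopifnot(nrow(a) >= 2)
  g <- igraph::simplify(symGraph(a))
  if (igraph::ecount(g) == 0) {
    memb <- seq_len(nrow(a))
    names(memb) <- rownames(a)
    return(list(Q = 0, membership = memb))
  }
  comm <- igraph::cluster_fast_greedy(g)
  memb <- as.integer(igraph::membership(comm))
  q <- igraph::modularity(g, memb)
  ## the agglomeration ends at the all-in-one partition, whose Q is exactly
  ## 0; never return a worse cut than that
  if (q < 0) {
    memb <- rep(1L, nrow(a))
    q <- 0
  }
  names(memb) <- rownames(a)
  list(Q = q, membership = memb)
}

#' Per-node degrees and average degree
#'
#' In energy-flow terms a node's prey count is its number of incoming
#' resources (column sum) and its predator count the number of consumers it
#' feeds (row sum). AD, the average total degree, equals 2L/S.
#'
#' @param web A \linkS4class{FoodWeb} or adjacency matrix.
#' @return List with \code{perNode} (data.frame node_id, nPrey, nPredators,
#'   total) and \code{AD}.
#' @export
degreeStats <- function(web) {
  a <- asAdjacency(web)
  stopifnot(nrow(a) >= 1)
  df <- data.frame(node_id = rownames(a), nPrey = unname(colSums(a)),
                   nPredators = unname(rowSums(a)),
                   stringsAsFactors = FALSE)
  df$total <- df$nPrey + df$nPredators
  list(perNode = df, AD = mean(df$total))
}

#' All web metrics in one row
#'
#' Computes S, L, LD, C, CC, CPL, Mod, mean trophic level and omnivory for a
#' web; optionally quasi sign-stability summaries when \code{qssDraws > 0}.
#'
#' @param web A \linkS4class{FoodWeb}.
#' @param qssDraws Number of QSS Monte Carlo draws (0 skips QSS).
#' @param seed Optional seed for the QSS stage.
#' @return One-row data.frame with columns \code{label, S, L, LD, C, CC,
#'   CPL, Mod, meanTL, O} and, when requested, \code{qssPropStable},
#'   \code{qssMeanMaxEig}.
#' @export
webMetrics <- function(web, qssDraws = 0, seed = NULL) {
  cx <- complexity(web)
  tl <- trophicLevels(web)
  out <- data.frame(label = webLabel(web), S = cx$S, L = cx$L, LD = cx$LD,
                    C = cx$C, CC = clusteringCoefficient(web),
                    CPL = characteristicPathLength(web)$CPL,
                    Mod = modularityQ(web)$Q, meanTL = tl$meanTL,
                    O = omnivory(web), stringsAsFactors = FALSE)
  if (qssDraws > 0) {
    q <- qss(web, nDraws = qssDraws, seed = seed)
    out$qssPropStable <- propStable(q)
    out$qssMeanMaxEig <- meanMaxEig(q)
  }
  out
}

#' Write a metrics table
#'
#' One row per web, tab-separated, numbers at 6 significant digits.
#'
#' @param metrics data.frame as returned by \code{\link{webMetrics}} (rows
#'   may be concatenated with \code{rbind}).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeMetricsTable <- function(metrics, path) {
  writeTsv(metrics, path)
  invisible(path)
}
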