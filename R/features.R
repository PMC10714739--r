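## Per-sample diversity and sub-network features (AD, Int) and their
## relationships with web metrics.

#' Shannon diversity (natural log)
#'
#' \eqn{H = -\sum p_i \ln p_i} over the nonzero proportions of a count
#' vector, in nats (computed via vegan).
#'
#' @param counts Nonnegative numeric vector with a positive sum.
#' @return Shannon H in nats.
#' @examples
#' shannonIndex(c(1, 1, 1, 1))  # log(4)
#' @export
shannonIndex <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (sum(counts) <= 0) stop("all-zero count vector", call. = FALSE)
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Induced per-sample sub-network
#'
#' The subgraph of a web induced by the taxa present in one sample, plus the
#' canonical aggregate compartments, which are standing nodes of every
#' sub-network. Taxa absent from the web are ignored (their ids are recorded
#' in the returned web's report).
#'
#' @param web A \linkS4class{FoodWeb}.
#' @param taxa Character vector of taxon ids present in the sample.
#' @param label Label for the sub-network (e.g. the sample id).
#' @return A \linkS4class{FoodWeb}.
#' @export
sampleSubweb <- function(web, taxa, label = "") {
  nd <- nodeInfo(web)
  canonical <- nd$node_id[nd$node_id %in% AGGREGATE_COMPARTMENTS]
  present <- intersect(taxa, nd$node_id)
  absent <- setdiff(taxa, nd$node_id)
  keep <- nd$node_id %in% union(present, canonical)
  if (!any(keep)) stop("empty induced node set", call. = FALSE)
  a <- adjacencyMatrix(web)[keep, keep, drop = FALSE]
  foodWeb(nd[keep, , drop = FALSE], a, label = label,
          report = list(n_absent_taxa = length(absent),
                        absent_taxa = absent))
}

#' Bacterivore-bacteria interaction proportion (Int)
#'
#' The proportion of a sub-network's trophic links that run from a
#' bacterivorous (guild B) predator to a bacterial prey node. The
#' denominator is all links of the sub-network; set
#' \code{denominator = "bacterivore"} to divide by the bacterivores'
#' outgoing links only.
#'
#' @param subweb A \linkS4class{FoodWeb} with L >= 1.
#' @param bacterialNodes ids counted as bacterial prey; defaults to every
#'   node in the bacteria compartment (the aggregate and any phylum-level
#'   nodes).
#' @param denominator \code{"all"} (default) or \code{"bacterivore"}.
#' @return Int in [0, 1].
#' @export
interactionProportion <- function(subweb, bacterialNodes = NULL,
                                  denominator = c("all", "bacterivore")) {
  denominator <- match.arg(denominator)
  a <- adjacencyMatrix(subweb)
  if (sum(a) == 0) stop("sub-network has no links", call. = FALSE)
  nd <- nodeInfo(subweb)
  if (is.null(bacterialNodes))
    bacterialNodes <- nd$node_id[nd$compartment == "bacteria"]
  isB <- vapply(nd$guilds, function(g) "B" %in% g, logical(1))
  idx <- which(a == 1L, arr.ind = TRUE)
  preyId <- nd$node_id[idx[, 1]]
  predIsB <- isB[idx[, 2]]
  qual <- predIsB & preyId %in% bacterialNodes
  den <- if (denominator == "all") nrow(idx) else sum(predIsB)
  if (den == 0) return(0)
  sum(qual) / den
}

#' Simple linear regression of a feature pair
#'
#' Ordinary least squares of y on x with the two-sided t test on the slope.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with \code{slope}, \code{intercept}, \code{r.squared},
#'   \code{p}.
#' @export
regressFeature <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0) stop("x has zero variance", call. = FALSE)
  if (stats::var(y) == 0)
    return(list(slope = 0, intercept = y[1], r.squared = 0, p = 1))
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(sm)
  list(slope = unname(co["x", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r.squared = sm$r.squared,
       p = if (sm$sigma == 0) 0 else unname(co["x", "Pr(>|t|)"]))
}

#' Spearman correlations between complexity and stability metrics
#'
#' Tie-corrected rank correlations with two-sided asymptotic p values for
#' every (complexity, stability) column pair of a per-sample metrics table.
#' Pairs involving a constant column are reported as NA.
#'
#' @param metrics data.frame of per-sample metric columns.
#' @param complexityCols,stabilityCols Column names to correlate.
#' @return List of matrices \code{rho} and \code{p} (complexity rows,
#'   stability columns).
#' @export
metricCorrelations <- function(metrics,
                               complexityCols = c("sub_L", "sub_LD", "sub_C"),
                               stabilityCols = c("sub_meanTL", "sub_O",
                                                 "sub_Mod")) {
  stopifnot(nrow(metrics) >= 4,
            all(c(complexityCols, stabilityCols) %in% colnames(metrics)))
  rho <- p <- matrix(NA_real_, length(complexityCols), length(stabilityCols),
                     dimnames = list(complexityCols, stabilityCols))
  for (i in complexityCols) for (j in stabilityCols) {
    x <- metrics[[i]]
    y <- metrics[[j]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 4 || stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) next
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                           exact = FALSE))
    rho[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(rho = rho, p = p)
}

#' Per-sample sub-network features
#'
#' For each sample: Shannon H of the protist counts, the induced
#' sub-network's S and L, average degree AD = 2L/S, the
#' bacterivore-bacteria interaction proportion Int and, when
#' \code{metrics = TRUE}, the sub-network's LD, C, modularity, mean trophic
#' level and omnivory (and QSS when \code{qssDraws > 0}). The sample's taxon
#' set is its detected protist genera plus, when a bacterial table is
#' supplied, its detected bacterial phyla.
#'
#' @param protist \linkS4class{CommunityTable} of protist genus counts.
#' @param web A \linkS4class{FoodWeb}: the seasonal topology web (bacteria
#'   as one aggregate compartment). Structural metrics are computed on its
#'   induced sub-networks.
#' @param bacteria Optional \linkS4class{CommunityTable} of bacterial phylum
#'   counts for the same samples; used with \code{intWeb} for Int.
#' @param intWeb Optional phylum-expanded seasonal web on which Int is
#'   evaluated (bacterial phyla enter the analysis only through Int); when
#'   NULL, Int is computed on the topology sub-network's aggregate bacteria
#'   node.
#' @param samples Sample ids to process (default: all samples of
#'   \code{protist} whose season matches \code{webLabel(web)}, or all
#'   samples when the label is empty).
#' @param intDenominator Denominator convention for Int (see
#'   \code{\link{interactionProportion}}). The per-sample analysis defaults
#'   to \code{"bacterivore"} (share of bacterivore diet links that point at
#'   bacteria): unlike the all-links denominator, it is invariant to the
#'   size of the protist backbone, so Int is not mechanically confounded
#'   with sub-network size.
#' @param metrics Also compute sub-network structure/stability metrics.
#' @param qssDraws QSS draws per sample (0 skips QSS; sub-network QSS is
#'   Monte Carlo, so a few hundred draws suffice).
#' @param minCount Presence threshold.
#' @return data.frame with one row per sample.
#' @export
sampleFeatures <- function(protist, web, bacteria = NULL, intWeb = NULL,
                           samples = NULL,
                           intDenominator = c("bacterivore", "all"),
                           metrics = TRUE, qssDraws = 0, minCount = 1) {
  intDenominator <- match.arg(intDenominator)
  if (is.null(samples)) {
    seas <- seasonOf(protist)
    samples <- if (nzchar(webLabel(web)) && webLabel(web) %in% seas)
      sampleIDs(protist)[seas == webLabel(web)] else sampleIDs(protist)
  }
  seas <- seasonOf(protist)
  rows <- lapply(samples, function(s) {
    taxa <- sampleTaxa(protist, s, minCount)
    sub <- sampleSubweb(web, taxa, label = s)
    intTaxa <- taxa
    if (!is.null(bacteria) && s %in% sampleIDs(bacteria))
      intTaxa <- union(intTaxa, sampleTaxa(bacteria, s, minCount))
    intSub <- if (is.null(intWeb)) sub
              else sampleSubweb(intWeb, intTaxa, label = s)
    cts <- countsMatrix(protist)[s, ]
    out <- data.frame(sample_id = s, season = unname(seas[s]),
                      shannon_H = shannonIndex(cts),
                      sub_S = nNodes(sub), sub_L = nLinks(sub),
                      AD = degreeStats(sub)$AD,
                      Int = if (nLinks(intSub) >= 1)
                        interactionProportion(
                          intSub, denominator = intDenominator)
                      else NA_real_,
                      stringsAsFactors = FALSE)
    if (metrics) {
      out$sub_LD <- out$sub_L / out$sub_S
      out$sub_C <- out$sub_L / out$sub_S^2
      out$sub_Mod <- modularityQ(sub)$Q
      tl <- tryCatch(trophicLevels(sub), error = function(e) NULL)
      out$sub_meanTL <- if (is.null(tl)) NA_real_ else tl$meanTL
      out$sub_O <- if (is.null(tl)) NA_real_ else omnivory(sub)
      if (qssDraws > 0) {
        q <- qss(sub, nDraws = qssDraws)
        out$sub_qssPropStable <- propStable(q)
        out$sub_qssMeanMaxEig <- meanMaxEig(q)
      }
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
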