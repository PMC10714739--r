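## Curveball degree-preserving randomization and null-model machinery.

#' Curveball randomization of a food web
#'
#' Repeatedly picks two predators at random and trades a random subset of
#' the prey found in one diet but not the other, preserving every species'
#' number of prey (column sums) and of predators (row sums) exactly. The two
#' trading predators' own ids are withheld from the tradable pool so the
#' zero diagonal (no cannibalism) is preserved; a trade between predators
#' with identical diets is a no-op but still counts towards
#' \code{nTrades}, so runtime is bounded.
#'
#' With \code{withinKind = TRUE} (the default) prey are traded only against
#' prey of the same node kind: genus-level prey against genus-level prey,
#' aggregate-compartment prey against aggregate-compartment prey. This
#' additionally preserves each consumer's number of links to standing
#' compartments (bacteria, algae, fungi, detritus, DOC), so the null keeps
#' every consumer's basal anchoring and randomizes the genus-level
#' interaction structure — compartment attachments are construction
#' conventions, not literature-sampled interactions to resample.
#' \code{withinKind = FALSE} gives the unconstrained classic trade.
#'
#' @param web A \linkS4class{FoodWeb} with L >= 2.
#' @param nTrades Number of trades (default 5 * S, a burn-in long enough to
#'   decorrelate successive snapshots on webs of this size).
#' @param withinKind Restrict trades to prey of the same node kind.
#' @return A randomized \linkS4class{FoodWeb} with the same node registry
#'   and label.
#' @export
curveball <- function(web, nTrades = 5 * nNodes(web), withinKind = TRUE) {
  if (nTrades < 1) stop("nTrades must be >= 1", call. = FALSE)
  a <- adjacencyMatrix(web)
  S <- nrow(a)
  if (sum(a) < 2) stop("curveball needs at least 2 links", call. = FALSE)
  kinds <- if (withinKind) nodeInfo(web)$kind else rep("all", S)
  prey <- lapply(seq_len(S), function(j) which(a[, j] == 1L))
  for (t in seq_len(nTrades)) {
    jj <- sample.int(S, 2)
    p1 <- prey[[jj[1]]]
    p2 <- prey[[jj[2]]]
    a1 <- setdiff(setdiff(p1, p2), jj)
    a2 <- setdiff(setdiff(p2, p1), jj)
    for (k in unique(kinds[c(a1, a2)])) {
      a1k <- a1[kinds[a1] == k]
      a2k <- a2[kinds[a2] == k]
      if (length(a1k) == 0 || length(a2k) == 0) next
      pool <- sample(c(a1k, a2k))
      p1 <- c(setdiff(p1, a1k), pool[seq_along(a1k)])
      p2 <- c(setdiff(p2, a2k), pool[-seq_along(a1k)])
    }
    prey[[jj[1]]] <- p1
    prey[[jj[2]]] <- p2
  }
  b <- matrix(0L, S, S, dimnames = dimnames(a))
  for (j in seq_len(S)) b[prey[[j]], j] <- 1L
  foodWeb(nodeInfo(web), b, label = webLabel(web))
}

nullMetricFun <- function(metric, qssDraws) {
  switch(metric,
         meanTL = function(w) trophicLevels(w)$meanTL,
         omnivory = function(w) omnivory(w),
         modularity = function(w) modularityQ(w)$Q,
         L = function(w) as.numeric(nLinks(w)),
         qssPropStable = function(w) propStable(qss(w, nDraws = qssDraws)),
         qssMeanMaxEig = function(w) meanMaxEig(qss(w, nDraws = qssDraws)),
         stop("unknown metric: ", metric, call. = FALSE))
}

#' Null distribution of a web metric under curveball randomization
#'
#' Runs a curveball chain from the empirical web, taking one snapshot every
#' \code{nTrades} trades, and evaluates the metric on each snapshot. The 95
#' percent interval is the empirical 2.5/97.5 percentile band and
#' \code{within} records whether the empirical value falls inside the
#' simulated [min, max] range (the range-based reading of "within the
#' distribution"); both are reported. Snapshots on which the metric is
#' undefined (e.g. a randomized web whose trophic levels are ungrounded)
#' yield NA and are counted in \code{nFailed}.
#'
#' @param web A \linkS4class{FoodWeb}.
#' @param metric One of \code{"meanTL"}, \code{"omnivory"},
#'   \code{"modularity"}, \code{"L"}, \code{"qssPropStable"},
#'   \code{"qssMeanMaxEig"}.
#' @param nRandom Number of randomized replicates (default 1000).
#' @param seed Optional integer seed; the full ensemble is reproducible
#'   given the seed.
#' @param nTrades Trades between snapshots (default 5 * S).
#' @param qssDraws Monte Carlo draws per snapshot for the QSS metrics
#'   (default 100).
#' @return A \linkS4class{NullEnsemble}.
#' @export
nullDistribution <- function(web, metric, nRandom = 1000, seed = NULL,
                             nTrades = 5 * nNodes(web), qssDraws = 100) {
  stopifnot(nRandom >= 1)
  f <- nullMetricFun(metric, qssDraws)
  if (!is.null(seed)) set.seed(seed)
  empirical <- f(web)
  values <- numeric(nRandom)
  cur <- web
  for (k in seq_len(nRandom)) {
    cur <- curveball(cur, nTrades = nTrades)
    values[k] <- tryCatch(f(cur), error = function(e) NA_real_)
  }
  ok <- values[!is.na(values)]
  ci <- if (length(ok)) unname(stats::quantile(ok, c(0.025, 0.975)))
        else c(NA_real_, NA_real_)
  within <- length(ok) > 0 && empirical >= min(ok) && empirical <= max(ok)
  new("NullEnsemble", metricName = metric, nRandom = as.integer(nRandom),
      values = values, empirical = empirical, ci95 = ci, within = within,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      nFailed = as.integer(sum(is.na(values))))
}

#' Write a null ensemble to disk
#'
#' Writes \code{<prefix>_values.tsv} (one replicate value per row) and
#' \code{<prefix>_summary.json} with the metric name, replicate count,
#' empirical value, percentile interval, within flag and seed.
#'
#' @param ensemble A \linkS4class{NullEnsemble}.
#' @param prefix Output path prefix.
#' @return Invisibly, \code{prefix}.
#' @export
writeNullEnsemble <- function(ensemble, prefix) {
  writeTsv(data.frame(value = ensemble@values), paste0(prefix, "_values.tsv"))
  jsonlite::write_json(
    list(metric = ensemble@metricName, n_random = ensemble@nRandom,
         empirical = ensemble@empirical,
         ci95 = as.numeric(ensemble@ci95), within = ensemble@within,
         n_failed = ensemble@nFailed, seed = ensemble@seed),
    paste0(prefix, "_summary.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(prefix)
}

#' Two-sample two-sided Kolmogorov-Smirnov comparison
#'
#' D is the supremum distance between the two empirical CDFs; the p value is
#' the asymptotic two-sided one. Ties are tolerated (the exact p value is
#' never requested).
#'
#' @param a,b Numeric vectors, each of length >= 1.
#' @return List with \code{D} and \code{p}.
#' @export
ksCompare <- function(a, b) {
  if (!length(a) || !length(b))
    stop("both samples must be non-empty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided",
                                        exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}
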