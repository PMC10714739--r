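## Orchestration: simulate/read -> validate -> build -> metrics -> null
## models -> QSS -> per-sample features -> associations, with one global
## seed fanned out to per-stage child seeds via a counter so any stage can
## be re-run in isolation reproducibly.

REPORT_SCHEMA_VERSION <- "1.0"

childSeed <- function(seed, counter) as.integer(seed) + 1000L * counter

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form \code{key = value}; \code{#} comments and blank lines
#' are ignored; values that parse as numbers become numeric.
#'
#' @param path Path to the configuration file.
#' @return Named list.
#' @export
readPipelineConfig <- function(path) {
  lines <- readTsvLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad))
    stop("malformed config line: ", lines[bad][1], call. = FALSE)
  vals <- lapply(kv, function(x) {
    v <- trimws(x[2])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- trimws(vapply(kv, `[`, "", 1))
  vals
}

#' Validate cross-file referential integrity of a dataset
#'
#' Checks, before any computation, that every catalog endpoint is annotated
#' (or an aggregate compartment), that every community-table taxon is
#' annotated, and that guild sets are non-degenerate. Returns a problem
#' table rather than failing, so callers can decide on severity.
#'
#' @param dataset List with \code{protist}, \code{bacteria} (optional),
#'   \code{annotation}, \code{catalog} as produced by
#'   \code{\link{generateSeasonalDataset}} or assembled from the readers.
#' @return data.frame with columns \code{component}, \code{id},
#'   \code{problem}; zero rows when the bundle is consistent.
#' @export
validateInputs <- function(dataset) {
  problems <- list()
  note <- function(component, id, problem)
    problems[[length(problems) + 1]] <<- data.frame(
      component = component, id = id, problem = problem,
      stringsAsFactors = FALSE)
  known <- union(dataset$annotation$taxon_id, AGGREGATE_COMPARTMENTS)
  for (col in c("predator_id", "prey_id")) {
    bad <- setdiff(dataset$catalog[[col]], known)
    for (id in bad) note("catalog", id, paste("unannotated", col))
  }
  loops <- dataset$catalog$predator_id == dataset$catalog$prey_id
  for (id in unique(dataset$catalog$predator_id[loops]))
    note("catalog", id, "self-loop")
  for (tab in c("protist", "bacteria")) {
    if (is.null(dataset[[tab]])) next
    bad <- setdiff(taxonIDs(dataset[[tab]]), known)
    for (id in bad) note("community", id, paste("unannotated taxon in", tab))
  }
  badG <- !vapply(dataset$annotation$guilds,
                  function(g) all(g %in% GUILD_CODES), logical(1))
  for (id in dataset$annotation$taxon_id[badG])
    note("annotation", id, "unknown guild code")
  if (length(problems)) do.call(rbind, problems)
  else data.frame(component = character(), id = character(),
                  problem = character(), stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages: \code{simulate} (or load the configured input files),
#' \code{validate}, \code{build} (one topology web per season, plus a
#' phylum-expanded web for per-sample features), \code{metrics},
#' \code{null} (curveball ensembles for mean trophic level, omnivory and
#' modularity per season, with pairwise season Kolmogorov-Smirnov tests and
#' Benjamini-Hochberg adjustment within the family), \code{qss},
#' \code{features} (per-sample sub-network features) and
#' \code{associations} (Int-versus-metric regressions and the
#' complexity-stability Spearman matrix, each family BH-adjusted). The
#' report is a pure function of (inputs, config, seed).
#'
#' @param config Named list (or path to a key=value file). Recognised keys:
#'   \code{seed} (default 1), \code{nRandom} (null replicates, default
#'   1000), \code{nDraws} (QSS draws per web, default 1000),
#'   \code{qssDrawsSample} (QSS draws per sample sub-network, default 200),
#'   \code{stages} (character vector; default all), \code{dataset} (an
#'   in-memory dataset, else one is simulated from \code{seed}), and file
#'   paths \code{protist}, \code{bacteria}, \code{annotation},
#'   \code{catalog} to load instead of simulating.
#' @param out Optional directory; when given, tables and JSON summaries are
#'   written there.
#' @return Report list with \code{schema_version}, \code{seed},
#'   \code{webs}, \code{metrics}, \code{null}, \code{ks}, \code{qss},
#'   \code{features}, \code{associations}, \code{validation}.
#' @export
runPipeline <- function(config = list(), out = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  seed <- as.integer(config$seed %||% 1L)
  nRandom <- as.integer(config$nRandom %||% 1000L)
  nDraws <- as.integer(config$nDraws %||% 1000L)
  qssDrawsSample <- as.integer(config$qssDrawsSample %||% 200L)
  allStages <- c("simulate", "validate", "build", "metrics", "null", "qss",
                 "features", "associations")
  stages <- config$stages %||% allStages
  report <- list(schema_version = REPORT_SCHEMA_VERSION, seed = seed)

  withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  dataset <- config$dataset
  if (is.null(dataset)) {
    if (!is.null(config$protist)) {
      dataset <- withStage("load", list(
        protist = readCommunityTable(config$protist),
        bacteria = if (!is.null(config$bacteria))
          readCommunityTable(config$bacteria),
        annotation = readAnnotation(config$annotation),
        catalog = readInteractionCatalog(config$catalog)))
    } else {
      dataset <- withStage("simulate",
        generateSeasonalDataset(childSeed(seed, 1L),
                                config$synthConfig %||% syntheticConfig()))
    }
  }

  if ("validate" %in% stages) {
    report$validation <- withStage("validate", validateInputs(dataset))
    if (nrow(report$validation))
      warning("input validation found ", nrow(report$validation),
              " problem(s)", call. = FALSE)
  }

  seasons <- unique(seasonOf(dataset$protist))
  webs <- featWebs <- list()
  if ("build" %in% stages) {
    for (s in seasons) {
      genera <- withStage("build", detectedTaxa(dataset$protist, s))
      webs[[s]] <- withStage("build",
        buildWeb(genera, dataset$annotation, dataset$catalog, label = s))
      if (!is.null(dataset$bacteria)) {
        bp <- detectedTaxa(dataset$bacteria, s)
        featWebs[[s]] <- withStage("build",
          buildWeb(c(genera, bp), dataset$annotation, dataset$catalog,
                   label = s))
      } else featWebs[[s]] <- webs[[s]]
    }
    report$webs <- lapply(webs, buildReport)
  }

  if ("metrics" %in% stages && length(webs)) {
    rows <- lapply(seq_along(seasons), function(i)
      withStage("metrics", webMetrics(webs[[seasons[i]]],
                                      qssDraws = if ("qss" %in% stages)
                                        nDraws else 0,
                                      seed = childSeed(seed, 10L + i))))
    report$metrics <- do.call(rbind, rows)
  }

  if ("qss" %in% stages && length(webs)) {
    report$qss <- lapply(seq_along(seasons), function(i)
      withStage("qss", qss(webs[[seasons[i]]], nDraws = nDraws,
                           seed = childSeed(seed, 20L + i))))
    names(report$qss) <- seasons
  }

  if ("null" %in% stages && length(webs)) {
    nullMetrics <- c("meanTL", "omnivory", "modularity")
    report$null <- list()
    ens <- list()
    for (mi in seq_along(nullMetrics)) {
      m <- nullMetrics[mi]
      ens[[m]] <- lapply(seq_along(seasons), function(i)
        withStage("null", nullDistribution(
          webs[[seasons[i]]], m, nRandom = nRandom,
          seed = childSeed(seed, 100L + 10L * mi + i))))
      names(ens[[m]]) <- seasons
      report$null[[m]] <- lapply(ens[[m]], function(e)
        list(empirical = empiricalValue(e), ci95 = as.numeric(ci95(e)),
             within = isWithinNull(e), n_failed = e@nFailed))
    }
    ## pairwise KS between the seasons' null ensembles, per metric
    ksRows <- list()
    for (m in names(ens)) {
      prs <- utils::combn(seasons, 2)
      for (k in seq_len(ncol(prs))) {
        a <- nullValues(ens[[m]][[prs[1, k]]])
        b <- nullValues(ens[[m]][[prs[2, k]]])
        kt <- withStage("null", ksCompare(a[!is.na(a)], b[!is.na(b)]))
        ksRows[[length(ksRows) + 1]] <- data.frame(
          metric = m, season_a = prs[1, k], season_b = prs[2, k],
          D = kt$D, p = kt$p, stringsAsFactors = FALSE)
      }
    }
    report$ks <- do.call(rbind, ksRows)
    report$ks$p_adj <- stats::p.adjust(report$ks$p, method = "BH")
  }

  if ("features" %in% stages && length(featWebs)) {
    set.seed(childSeed(seed, 200L))
    feats <- lapply(seasons, function(s)
      withStage("features", sampleFeatures(
        dataset$protist, webs[[s]], bacteria = dataset$bacteria,
        intWeb = featWebs[[s]], metrics = TRUE,
        qssDraws = qssDrawsSample)))
    report$features <- do.call(rbind, feats)
  }

  if ("associations" %in% stages && !is.null(report$features)) {
    f <- report$features
    targets <- intersect(c("sub_Mod", "sub_L", "sub_LD", "sub_C",
                           "sub_meanTL"), colnames(f))
    regRows <- lapply(targets, function(m) {
      r <- withStage("associations", regressFeature(f$Int, f[[m]]))
      data.frame(feature = "Int", metric = m, slope = r$slope,
                 intercept = r$intercept, r.squared = r$r.squared, p = r$p,
                 stringsAsFactors = FALSE)
    })
    reg <- do.call(rbind, regRows)
    reg$p_adj <- stats::p.adjust(reg$p, method = "BH")
    stab <- intersect(c("sub_meanTL", "sub_O", "sub_Mod",
                        "sub_qssPropStable"), colnames(f))
    report$associations <- list(
      regressions = reg,
      correlations = withStage("associations", metricCorrelations(
        f, stabilityCols = stab)))
  }

  if (!is.null(out)) writePipelineReport(report, out)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the machine-readable pipeline report
#'
#' Writes \code{report.json} (schema-versioned) plus TSVs for the metrics,
#' features and KS tables under \code{dir}.
#'
#' @param report As returned by \code{\link{runPipeline}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
writePipelineReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$metrics))
    writeMetricsTable(report$metrics, file.path(dir, "web_metrics.tsv"))
  if (!is.null(report$features))
    writeTsv(report$features, file.path(dir, "sample_features.tsv"))
  if (!is.null(report$ks))
    writeTsv(report$ks, file.path(dir, "ks_tests.tsv"))
  if (!is.null(report$qss))
    writeQssReport(report$qss, file.path(dir, "qss.tsv"))
  json <- report
  json$qss <- lapply(report$qss, function(q)
    list(n_draws = q@nDraws, prop_stable = q@propStable,
         mean_max_eig = q@meanMaxEig, seed = q@seed))
  if (!is.null(json$associations))
    json$associations$correlations <- lapply(
      json$associations$correlations, function(m)
        as.data.frame(as.table(m), stringsAsFactors = FALSE))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(dir)
}
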