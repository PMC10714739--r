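## TSV dialect: UTF-8, tab-separated, '#'-prefixed comment lines ignored.
## All numeric output is written with 6 significant digits.

readTsvLines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
}

parseTsv <- function(lines, path) {
  if (!length(lines)) stop("empty table in ", path, call. = FALSE)
  utils::read.delim(text = lines, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", quote = "")
}

fmtNum <- function(x) {
  # 6 significant digits, no scientific notation surprises for counts
  ifelse(is.na(x), "NA",
         format(signif(x, 6), trim = TRUE, scientific = FALSE))
}

writeTsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmtNum)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
}

#' Read a community table
#'
#' Reads a samples-by-taxa abundance TSV: header row of taxon ids, first
#' column \code{sample_id}, optional second column \code{season}; remaining
#' cells are nonnegative numbers. Lines starting with \code{#} are ignored.
#' Missing or negative cells, and duplicate sample or taxon ids, are rejected
#' with an error naming the offending row/column.
#'
#' @param path Path to a TSV file.
#' @param season Optional character vector of per-sample seasons, used when
#'   the file has no \code{season} column (default: "unknown").
#' @return A \linkS4class{CommunityTable}.
#' @seealso \code{\link{writeCommunityTable}}
#' @export
readCommunityTable <- function(path, season = NULL) {
  df <- parseTsv(readTsvLines(path), path)
  if (ncol(df) < 2) stop("malformed header in ", path, call. = FALSE)
  taxHdr <- colnames(df)[-1]
  taxHdr <- taxHdr[taxHdr != "season"]
  if (anyDuplicated(taxHdr))
    stop("duplicate taxon id(s): ",
         paste(unique(taxHdr[duplicated(taxHdr)]), collapse = ", "),
         call. = FALSE)
  sampleIds <- df[[1]]
  df <- df[, -1, drop = FALSE]
  fileSeason <- NULL
  if ("season" %in% colnames(df)) {
    fileSeason <- df[["season"]]
    df <- df[, colnames(df) != "season", drop = FALSE]
  }
  if (anyDuplicated(sampleIds))
    stop("duplicate sample id(s): ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "),
         call. = FALSE)
  m <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(sampleIds, colnames(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) | !nzchar(trimws(df[[j]])))
    if (length(bad))
      stop("empty or non-numeric cell at sample '", sampleIds[bad[1]],
           "', taxon '", colnames(df)[j], "'", call. = FALSE)
    neg <- which(v < 0)
    if (length(neg))
      stop("negative count at sample '", sampleIds[neg[1]], "', taxon '",
           colnames(df)[j], "'", call. = FALSE)
    m[, j] <- v
  }
  if (is.null(season)) season <- if (is.null(fileSeason))
    rep("unknown", nrow(m)) else fileSeason
  communityTable(m, season = season)
}

#' Write a community table
#'
#' Writes the samples-by-taxa TSV read back by
#' \code{\link{readCommunityTable}}, including the \code{season} column.
#'
#' @param table A \linkS4class{CommunityTable}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeCommunityTable <- function(table, path) {
  m <- countsMatrix(table)
  df <- data.frame(sample_id = rownames(m), season = unname(seasonOf(table)),
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  writeTsv(df, path)
  invisible(path)
}

parseGuilds <- function(s) {
  out <- lapply(strsplit(as.character(s), ";", fixed = TRUE), function(g) {
    g <- trimws(g)
    g[nzchar(g)]
  })
  codes <- unlist(out, use.names = FALSE)
  bad <- setdiff(codes, GUILD_CODES)
  if (length(bad))
    stop("unknown guild code(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  out
}

#' Read a functional-group annotation table
#'
#' TSV columns \code{taxon_id}, \code{compartment}, \code{phylum},
#' \code{guilds} (semicolon-joined guild codes; may be empty). Guild codes
#' are validated against \code{\link{guildCodes}}.
#'
#' @param path Path to a TSV file.
#' @return data.frame with columns \code{taxon_id}, \code{compartment},
#'   \code{phylum} and list-column \code{guilds}.
#' @export
readAnnotation <- function(path) {
  df <- parseTsv(readTsvLines(path), path)
  need <- c("taxon_id", "compartment", "phylum", "guilds")
  if (!all(need %in% colnames(df)))
    stop("annotation must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$taxon_id))
    stop("duplicate taxon_id(s): ",
         paste(unique(df$taxon_id[duplicated(df$taxon_id)]), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(df$compartment, COMPARTMENTS)
  if (length(bad))
    stop("unknown compartment(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- data.frame(taxon_id = df$taxon_id, compartment = df$compartment,
                    phylum = df$phylum, stringsAsFactors = FALSE)
  out$guilds <- parseGuilds(df$guilds)
  out
}

#' Write a functional-group annotation table
#'
#' @param annotation data.frame as returned by \code{\link{readAnnotation}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeAnnotation <- function(annotation, path) {
  df <- data.frame(taxon_id = annotation$taxon_id,
                   compartment = annotation$compartment,
                   phylum = annotation$phylum,
                   guilds = vapply(annotation$guilds, paste, "",
                                   collapse = ";"),
                   stringsAsFactors = FALSE)
  writeTsv(df, path)
  invisible(path)
}

#' Read a predator-prey interaction catalog
#'
#' TSV columns \code{predator_id}, \code{prey_id} and optional
#' \code{provenance}. Duplicate (predator, prey) pairs are collapsed to one
#' edge; self-loops (cannibalism) are rejected because the adjacency
#' convention used throughout forces a zero diagonal.
#'
#' @param path Path to a TSV file.
#' @return data.frame with columns \code{predator_id}, \code{prey_id},
#'   \code{provenance}.
#' @export
readInteractionCatalog <- function(path) {
  df <- parseTsv(readTsvLines(path), path)
  if (!all(c("predator_id", "prey_id") %in% colnames(df)))
    stop("catalog must have columns predator_id and prey_id", call. = FALSE)
  if (!"provenance" %in% colnames(df)) df$provenance <- ""
  interactionCatalog(df$predator_id, df$prey_id, df$provenance)
}

#' Construct an interaction catalog
#'
#' @param predator_id,prey_id Character vectors of equal length.
#' @param provenance Optional character vector (recycled).
#' @return Deduplicated catalog data.frame; errors on self-loops.
#' @export
interactionCatalog <- function(predator_id, prey_id, provenance = "") {
  df <- data.frame(predator_id = as.character(predator_id),
                   prey_id = as.character(prey_id),
                   provenance = as.character(provenance),
                   stringsAsFactors = FALSE)
  loops <- df$predator_id == df$prey_id
  if (any(loops))
    stop("self-loop (cannibalism) not allowed: ",
         paste(unique(df$predator_id[loops]), collapse = ", "),
         call. = FALSE)
  df <- df[!duplicated(df[, c("predator_id", "prey_id")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write an interaction catalog
#'
#' @param catalog Catalog data.frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeInteractionCatalog <- function(catalog, path) {
  writeTsv(catalog[, c("predator_id", "prey_id", "provenance")], path)
  invisible(path)
}

#' Serialize / deserialize a food web
#'
#' A web is stored as a pair of TSVs sharing a path prefix:
#' \code{<prefix>_nodes.tsv} (node registry, with the web label on a comment
#' line) and \code{<prefix>_edges.tsv} (columns \code{prey_id},
#' \code{predator_id}). \code{readWeb(writeWeb(w))} reproduces the web
#' exactly, including node order and label.
#'
#' @param web A \linkS4class{FoodWeb}.
#' @param prefix Path prefix for the two files.
#' @return \code{writeWeb}: invisibly, the prefix. \code{readWeb}: the
#'   \linkS4class{FoodWeb}.
#' @export
writeWeb <- function(web, prefix) {
  nd <- nodeInfo(web)
  nodes <- data.frame(node_id = nd$node_id, name = nd$name, kind = nd$kind,
                      compartment = nd$compartment, phylum = nd$phylum,
                      guilds = vapply(nd$guilds, paste, "", collapse = ";"),
                      stringsAsFactors = FALSE)
  writeTsv(nodes, paste0(prefix, "_nodes.tsv"),
           comment = paste0("label: ", webLabel(web)))
  a <- adjacencyMatrix(web)
  idx <- which(a == 1L, arr.ind = TRUE)
  edges <- data.frame(prey_id = as.character(rownames(a)[idx[, 1]]),
                      predator_id = as.character(colnames(a)[idx[, 2]]),
                      stringsAsFactors = FALSE)
  if (nrow(edges))
    edges <- edges[order(edges$prey_id, edges$predator_id), , drop = FALSE]
  writeTsv(edges, paste0(prefix, "_edges.tsv"))
  invisible(prefix)
}

#' @rdname writeWeb
#' @export
readWeb <- function(prefix) {
  nodePath <- paste0(prefix, "_nodes.tsv")
  edgePath <- paste0(prefix, "_edges.tsv")
  if (!file.exists(nodePath)) stop("file not found: ", nodePath, call. = FALSE)
  raw <- readLines(nodePath, encoding = "UTF-8", warn = FALSE)
  labelLine <- grep("^#\\s*label:", raw, value = TRUE)
  label <- if (length(labelLine))
    sub("^#\\s*label:\\s*", "", labelLine[1]) else ""
  body <- raw[!grepl("^\\s*#", raw) & nzchar(trimws(raw))]
  nodes <- parseTsv(body, nodePath)
  nodes$guilds <- parseGuilds(nodes$guilds)
  edgeLines <- readTsvLines(edgePath)
  a <- matrix(0L, nrow(nodes), nrow(nodes),
              dimnames = list(nodes$node_id, nodes$node_id))
  if (length(edgeLines) > 1) {
    edges <- parseTsv(edgeLines, edgePath)
    unknown <- setdiff(c(edges$prey_id, edges$predator_id), nodes$node_id)
    if (length(unknown))
      stop("edge endpoint(s) missing from node table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    a[cbind(edges$prey_id, edges$predator_id)] <- 1L
  }
  foodWeb(nodes, a, label = label)
}
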