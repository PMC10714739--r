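# Fixture builders used across the suite. All webs are constructed in code.

# FoodWeb from an edge list of c(prey, predator) pairs.
# guilds: named list node_id -> character vector of guild codes
# compartments: named character node_id -> compartment (default protist)
makeWeb <- function(edges = list(), nodes = NULL, guilds = list(),
                    compartments = character(), label = "") {
  ids <- unique(c(nodes, unlist(edges)))
  comp <- setNames(rep("protist", length(ids)), ids)
  comp[names(compartments)] <- compartments
  nd <- data.frame(node_id = ids, compartment = unname(comp[ids]),
                   stringsAsFactors = FALSE)
  nd$guilds <- lapply(ids, function(i)
    if (i %in% names(guilds)) guilds[[i]] else character())
  a <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (e in edges) a[e[1], e[2]] <- 1L
  foodWeb(nd, a, label = label)
}

# linear chain: n1 eaten by n2 eaten by n3 ...
chainWeb <- function(n) {
  ids <- paste0("n", seq_len(n))
  makeWeb(lapply(seq_len(n - 1), function(i) c(ids[i], ids[i + 1])))
}

# intraguild predation motif: a basal; b eats a; c eats both a and b
igpWeb <- function()
  makeWeb(list(c("a", "b"), c("a", "c"), c("b", "c")))

# random adjacency matrix guaranteed acyclic (upper triangular under a
# permutation), returned as plain matrix
randomDag <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- rbinom(sum(upper.tri(a)), 1, p)
  perm <- sample(n)
  a <- a[perm, perm]
  dimnames(a) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  a
}

# a small valid FoodWeb drawn at random: bipartite basal/consumer structure
# plus optional extra consumer-consumer links
randomWeb <- function(nBasal = 4, nCons = 6, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  basal <- paste0("b", seq_len(nBasal))
  cons <- paste0("c", seq_len(nCons))
  edges <- list()
  for (cn in cons) {
    prey <- basal[runif(nBasal) < p]
    if (!length(prey)) prey <- sample(basal, 1)
    for (pr in prey) edges[[length(edges) + 1]] <- c(pr, cn)
  }
  for (i in seq_len(nCons - 1))
    if (runif(1) < p / 2)
      edges[[length(edges) + 1]] <- c(cons[i], cons[i + 1])
  makeWeb(edges, nodes = c(basal, cons))
}

# shared small synthetic dataset (computed once per test run)
sharedDataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateSeasonalDataset(42)
    cache
  }
})
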