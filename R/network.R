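#' @importFrom igraph graph_from_data_frame is_connected mst girth degree
NULL

.REF_STATE <- "."

# build the (site x haplotype) state matrix from a HaplotypeSet.
# Site labels are "position" or "position+index" for insertions; states are
# the derived allele string, or "." for the reference state. Variants with
# an odd back-mutation count sit in the reference state; heteroplasmic
# calls are excluded from scoring.
.stateMatrix <- function(hs, ref = NULL) {
  ids <- sampleIds(hs)
  vlist <- lapply(ids, function(id) {
    v <- variantsOf(hs, id)
    v[is.na(v$het) & v$back %% 2L == 0L, , drop = FALSE]
  })
  siteOf <- function(v) ifelse(is.na(v$ins_index), as.character(v$position),
    paste0(v$position, "+", v$ins_index))
  sites <- unique(unlist(lapply(vlist, siteOf)))
  sites <- sites[order(as.numeric(sub("\\+.*", "", sites)))]
  m <- matrix(.REF_STATE, nrow = length(ids), ncol = length(sites),
    dimnames = list(ids, sites))
  for (k in seq_along(ids)) {
    v <- vlist[[k]]
    if (!nrow(v)) next
    st <- v$derived
    if (!is.null(ref)) {
      miss <- is.na(st)
      if (any(miss))
        st[miss] <- chartr("ACGT", "GTAC", referenceBase(ref, v$position[miss]))
    }
    st[is.na(st)] <- "1"  # unresolved derived state: presence marker
    m[k, siteOf(v)] <- st
  }
  m
}

.weightedDist <- function(states, w) {
  n <- nrow(states)
  d <- matrix(0, n, n, dimnames = list(rownames(states), rownames(states)))
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(w[states[i, ] != states[j, ]])
    }
  }
  d
}

# epsilon-relaxed minimum spanning network: pair (u,v) is linked iff
# d(u,v) <= c(u,v) + epsilon, where c(u,v) is the minimax path distance
# (largest edge on the MST path between u and v). epsilon = 0 gives the
# union of all minimum spanning trees.
.msnEdges <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n < 2L) return(cbind(from = integer(0), to = integer(0)))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected", weighted = TRUE)
  tr <- igraph::mst(g, weights = igraph::E(g)$weight)
  # minimax distances over the MST by per-root traversal
  adj <- lapply(seq_len(n), function(i) integer(0))
  wadj <- lapply(seq_len(n), function(i) numeric(0))
  el <- igraph::as_edgelist(tr, names = FALSE)
  ew <- igraph::E(tr)$weight
  for (k in seq_len(nrow(el))) {
    a <- el[k, 1L]; b <- el[k, 2L]
    adj[[a]] <- c(adj[[a]], b); wadj[[a]] <- c(wadj[[a]], ew[k])
    adj[[b]] <- c(adj[[b]], a); wadj[[b]] <- c(wadj[[b]], ew[k])
  }
  cc <- matrix(0, n, n)
  for (r in seq_len(n)) {
    seen <- rep(FALSE, n); seen[r] <- TRUE
    stack <- r
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (k in seq_along(adj[[u]])) {
        v <- adj[[u]][k]
        if (!seen[v]) {
          seen[v] <- TRUE
          cc[r, v] <- max(cc[r, u], wadj[[u]][k])
          stack <- c(stack, v)
        }
      }
    }
  }
  keep <- which(upper.tri(d) & d <= cc + epsilon + 1e-9, arr.ind = TRUE)
  cbind(from = keep[, 1L], to = keep[, 2L])
}

# quasi-medians of a state-vector triplet: per-site majority; sites where
# all three states differ expand combinatorially (capped at 27 = 3 sites)
.quasiMedians <- function(u, v, w, cap = 27L) {
  maj <- ifelse(u == v | u == w, u, ifelse(v == w, v, NA))
  tied <- which(is.na(maj))
  if (!length(tied)) return(list(unname(maj)))
  # bound the expansion: fully tied sites beyond the first three keep u's state
  if (length(tied) > 3L) {
    maj[tied[-(1:3)]] <- u[tied[-(1:3)]]
    tied <- tied[1:3]
  }
  opts <- lapply(tied, function(s) unique(c(u[s], v[s], w[s])))
  grid <- expand.grid(opts, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    m <- maj
    m[tied] <- unlist(grid[i, ], use.names = FALSE)
    unname(m)
  })
}

#' Build a median-joining haplotype network
#'
#' Implements the median-joining algorithm: starting from the
#' epsilon-relaxed minimum spanning network of the observed haplotypes,
#' quasi-median vectors of linked triplets are added iteratively when their
#' connection cost is within `epsilon` of the minimum, and superfluous
#' median vectors are pruned at the end. With `epsilon = 0` on tree-like
#' (compatible-site) data the result is the perfect phylogeny.
#'
#' Highly recurrent positions can be down-weighted so that reticulations
#' prefer to form (and later be resolved) at them; the default gives weight
#' 0.5 to a small set of well-known hypermutable sites.
#'
#' @param hs a [HaplotypeSet].
#' @param epsilon nonnegative relaxation of the minimum-spanning-network
#'   cost bound.
#' @param weights named numeric vector of per-position weights overriding
#'   the defaults.
#' @param hypermutable positions given weight `hyperWeight` when `weights`
#'   does not name them.
#' @param hyperWeight weight applied to `hypermutable` positions.
#' @param ref optional [MtReference] used to resolve the derived base of
#'   bare transition tokens.
#' @return A [HaploNetwork].
#' @export
buildMJNetwork <- function(hs, epsilon = 0, weights = NULL,
                           hypermutable = c(150L, 152L, 195L, 16189L),
                           hyperWeight = 0.5, ref = NULL) {
  if (length(hs) == 0L) stop("at least one haplotype is required")
  states0 <- .stateMatrix(hs, ref = ref)
  sites <- colnames(states0)
  pos <- as.integer(sub("\\+.*", "", sites))
  w <- rep(1, length(sites))
  names(w) <- sites
  w[pos %in% hypermutable] <- hyperWeight
  if (!is.null(weights)) {
    hitPos <- match(as.character(pos), names(weights))
    w[!is.na(hitPos)] <- weights[hitPos[!is.na(hitPos)]]
    hitSite <- match(sites, names(weights))
    w[!is.na(hitSite)] <- weights[hitSite[!is.na(hitSite)]]
  }

  # condense identical haplotypes
  key <- apply(states0, 1L, paste, collapse = "\r")
  uniq <- !duplicated(key)
  states <- states0[uniq, , drop = FALSE]
  carried <- split(rownames(states0), factor(key, levels = key[uniq]))
  nodeSamples <- vapply(carried, paste, collapse = ",", FUN.VALUE = "")
  nObs <- nrow(states)
  nodeType <- rep("observed", nObs)
  rownames(states) <- paste0("H", seq_len(nObs))
  names(nodeSamples) <- rownames(states)

  mvCounter <- 0L
  for (iter in seq_len(50L)) {
    d <- .weightedDist(states, w)
    edges <- .msnEdges(d, epsilon)
    if (nrow(edges) == 0L) break
    adj <- lapply(seq_len(nrow(states)), function(i)
      c(edges[edges[, 1L] == i, 2L], edges[edges[, 2L] == i, 1L]))
    haveKeys <- apply(states, 1L, paste, collapse = "\r")
    cand <- list(); candCost <- numeric(0); candKeys <- character(0)
    for (k in seq_len(nrow(edges))) {
      uI <- edges[k, 1L]; vI <- edges[k, 2L]
      for (wI in setdiff(union(adj[[uI]], adj[[vI]]), c(uI, vI))) {
        for (m in .quasiMedians(states[uI, ], states[vI, ], states[wI, ])) {
          mk <- paste(m, collapse = "\r")
          if (mk %in% haveKeys || mk %in% candKeys) next
          cost <- sum(w[m != states[uI, ]]) + sum(w[m != states[vI, ]]) + sum(w[m != states[wI, ]])
          cand[[length(cand) + 1L]] <- m
          candCost <- c(candCost, cost)
          candKeys <- c(candKeys, mk)
        }
      }
    }
    if (!length(cand)) break
    pick <- which(candCost <= min(candCost) + epsilon + 1e-9)
    for (p in pick) {
      mvCounter <- mvCounter + 1L
      states <- rbind(states, cand[[p]])
      rownames(states)[nrow(states)] <- paste0("mv", mvCounter)
      nodeType <- c(nodeType, "median")
    }
  }

  # prune superfluous median vectors: latent nodes of degree <= 2 in the
  # recomputed network lie on a geodesic and are not branch points
  repeat {
    d <- .weightedDist(states, w)
    edges <- .msnEdges(d, epsilon)
    deg <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = nrow(states))
    drop <- which(nodeType == "median" & deg <= 2L)
    if (!length(drop)) break
    states <- states[-drop, , drop = FALSE]
    nodeType <- nodeType[-drop]
  }

  d <- .weightedDist(states, w)
  edges <- .msnEdges(d, epsilon)
  ids <- rownames(states)
  edgeDf <- data.frame(
    from = ids[edges[, 1L]], to = ids[edges[, 2L]],
    weight = d[edges], stringsAsFactors = FALSE)
  edgeDf$sites <- vapply(seq_len(nrow(edgeDf)), function(k) {
    diffs <- sites[states[edges[k, 1L], ] != states[edges[k, 2L], ]]
    paste(diffs, collapse = ",")
  }, character(1))
  nodeDf <- data.frame(id = ids, type = nodeType,
    samples = ifelse(ids %in% names(nodeSamples), nodeSamples[ids], ""),
    stringsAsFactors = FALSE)
  methods::new("HaploNetwork", states = states, nodes = nodeDf,
    edges = edgeDf, siteWeights = w)
}

setMethod("show", "HaploNetwork", function(object) {
  cat("HaploNetwork:", sum(object@nodes$type == "observed"), "observed +",
    sum(object@nodes$type == "median"), "median nodes,",
    nrow(object@edges), "edges,", ncol(object@states), "sites\n")
})

#' Total weighted length of a network
#' @param net a [HaploNetwork].
#' @export
networkLength <- function(net) sum(net@edges$weight)

#' Export a network as an edge-list TSV
#' @param net a [HaploNetwork].
#' @param path file path.
#' @export
exportEdgeList <- function(net, path) {
  utils::write.table(net@edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.networkGraph <- function(net) {
  igraph::graph_from_data_frame(net@edges[, c("from", "to")],
    directed = FALSE, vertices = net@nodes$id)
}

#' Break reticulations by recurrent-mutation preference
#'
#' Cycles in a haplotype network represent homoplasy. Each cycle is broken
#' at the position with the highest background recurrence count (the number
#' of independent occurrences of that mutation across haplogroup
#' backgrounds): that mutation is deemed recurrent and one of its parallel
#' edges is removed, duplicating the change in the resulting tree. Ties are
#' broken deterministically towards the lower position number with a
#' warning.
#'
#' @param net a [HaploNetwork].
#' @param recurrence named numeric vector: position -> background
#'   recurrence count.
#' @return An acyclic [HaploNetwork].
#' @export
resolveReticulation <- function(net, recurrence = numeric(0)) {
  edges <- net@edges
  repeat {
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
      directed = FALSE, vertices = net@nodes$id)
    gr <- igraph::girth(g)
    if (!is.finite(gr$girth) || gr$girth == 0) break
    cyc <- as.character(names(gr$circle))
    if (!length(cyc)) cyc <- as.character(gr$circle)
    cycEdges <- integer(0)
    for (i in seq_along(cyc)) {
      a <- cyc[i]; b <- cyc[if (i == length(cyc)) 1L else i + 1L]
      hit <- which((edges$from == a & edges$to == b) | (edges$from == b & edges$to == a))
      cycEdges <- c(cycEdges, hit[1L])
    }
    sitesOn <- strsplit(edges$sites[cycEdges], ",")
    posOn <- lapply(sitesOn, function(s) as.integer(sub("\\+.*", "", s)))
    tab <- table(unlist(posOn))
    cand <- as.integer(names(tab)[tab >= 2L])
    if (!length(cand)) cand <- as.integer(names(tab))
    counts <- as.numeric(recurrence[as.character(cand)])
    counts[is.na(counts)] <- 0
    best <- max(counts)
    winners <- cand[counts == best]
    if (length(winners) > 1L)
      warning("unresolved reticulation: recurrence tie at positions ",
        paste(sort(winners), collapse = ", "), "; breaking at the lowest position")
    posPick <- min(winners)
    onPick <- cycEdges[vapply(posOn, function(p) posPick %in% p, logical(1))]
    keyOf <- function(k) paste(sort(c(edges$from[k], edges$to[k])), collapse = "|")
    kill <- onPick[order(vapply(onPick, keyOf, character(1)), decreasing = TRUE)][1L]
    edges <- edges[-kill, , drop = FALSE]
  }
  rownames(edges) <- NULL
  methods::new("HaploNetwork", states = net@states, nodes = net@nodes,
    edges = edges, siteWeights = net@siteWeights)
}
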