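.splitSamples <- function(x) {
  if (is.na(x) || x == "") character(0) else strsplit(x, ",")[[1L]]
}

# state vector of a variant table over a given site set (network convention)
.stateVectorFor <- function(variants, sites, ref = NULL) {
  st <- rep(.REF_STATE, length(sites))
  names(st) <- sites
  v <- variants[is.na(variants$het) & variants$back %% 2L == 0L, , drop = FALSE]
  if (nrow(v)) {
    key <- ifelse(is.na(v$ins_index), as.character(v$position),
      paste0(v$position, "+", v$ins_index))
    der <- v$derived
    if (!is.null(ref)) {
      miss <- is.na(der)
      if (any(miss)) der[miss] <- chartr("ACGT", "GTAC", referenceBase(ref, v$position[miss]))
    }
    der[is.na(der)] <- "1"
    hit <- key %in% sites
    st[key[hit]] <- der[hit]
  }
  st
}

# one variant row describing the change site `site` from state a to state b
.edgeVariantRow <- function(site, a, b, ref = NULL) {
  pos <- as.integer(sub("\\+.*", "", site))
  insIdx <- if (grepl("\\+", site)) as.integer(sub(".*\\+", "", site)) else NA_integer_
  refBase <- if (!is.null(ref)) referenceBase(ref, pos) else NA_character_
  if (!is.na(insIdx)) {
    if (b == .REF_STATE)
      return(data.frame(position = pos, ins_index = insIdx, ref = NA_character_,
        derived = a, kind = "insertion", back = 1L, het = NA_character_,
        stringsAsFactors = FALSE))
    return(data.frame(position = pos, ins_index = insIdx, ref = NA_character_,
      derived = b, kind = "insertion", back = 0L, het = NA_character_,
      stringsAsFactors = FALSE))
  }
  fromBase <- if (a == .REF_STATE) refBase else a
  toBase <- if (b == .REF_STATE) refBase else b
  kind <- if (identical(toBase, "-")) "deletion"
    else if (identical(fromBase, "-")) "insertion"
    else if (!is.na(fromBase) && !is.na(toBase) && fromBase %in% c("A", "C", "G", "T") &&
             toBase %in% c("A", "C", "G", "T")) .substitutionKind(fromBase, toBase)
    else "transition"
  data.frame(position = pos, ins_index = NA_integer_, ref = fromBase,
    derived = if (b == .REF_STATE) toBase else b,
    kind = kind, back = as.integer(b == .REF_STATE), het = NA_character_,
    stringsAsFactors = FALSE)
}

#' Root a haplotype network and label its clades
#'
#' Orients an acyclic [HaploNetwork] away from a root haplotype (adding the
#' root as a new node if its state vector is not already present), turns
#' each edge into a mutation-labelled branch, and assigns to every node the
#' deepest clade whose defining variants all lie on its root path.
#'
#' @param net an acyclic [HaploNetwork] (see [resolveReticulation()]).
#' @param rootVariants variant data.frame of the root haplotype relative to
#'   the reference (zero rows roots the tree at the reference itself), or a
#'   sample id already present in the network.
#' @param cladeDefinitions named list: clade label -> character vector of
#'   defining variant tokens.
#' @param ref optional [MtReference] for allele resolution.
#' @return A [CladeTree].
#' @export
rootAndLabel <- function(net, rootVariants = emptyVariantTable(),
                         cladeDefinitions = list(), ref = NULL) {
  states <- net@states
  sites <- colnames(states)
  edges <- net@edges
  nodeSamples <- stats::setNames(net@nodes$samples, net@nodes$id)
  if (is.character(rootVariants) && length(rootVariants) == 1L) {
    hit <- vapply(nodeSamples, function(s) rootVariants %in% .splitSamples(s), logical(1))
    if (!any(hit)) stop("root sample id not found in network")
    rootId <- names(nodeSamples)[hit][1L]
  } else {
    rootState <- .stateVectorFor(rootVariants, sites, ref = ref)
    match <- which(apply(states, 1L, function(r) all(r == rootState)))
    if (length(match)) {
      rootId <- rownames(states)[match[1L]]
    } else {
      # attach the root by its variant set to the closest node
      dd <- apply(states, 1L, function(r) sum(net@siteWeights[r != rootState]))
      nearest <- rownames(states)[which.min(dd)]
      rootId <- "root"
      states <- rbind(states, rootState)
      rownames(states)[nrow(states)] <- rootId
      edges <- rbind(edges, data.frame(from = rootId, to = nearest,
        weight = min(dd),
        sites = paste(sites[states[rootId, ] != states[nearest, ]], collapse = ","),
        stringsAsFactors = FALSE))
      nodeSamples[rootId] <- ""
    }
  }
  ids <- rownames(states)
  # BFS orientation away from the root
  adj <- lapply(stats::setNames(seq_along(ids), ids), function(i) character(0))
  for (k in seq_len(nrow(edges))) {
    adj[[edges$from[k]]] <- c(adj[[edges$from[k]]], edges$to[k])
    adj[[edges$to[k]]] <- c(adj[[edges$to[k]]], edges$from[k])
  }
  parent <- stats::setNames(rep(NA_character_, length(ids)), ids)
  order <- character(0)
  queue <- rootId
  seen <- stats::setNames(logical(length(ids)), ids)
  seen[rootId] <- TRUE
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    order <- c(order, u)
    for (v in adj[[u]]) if (!seen[v]) {
      seen[v] <- TRUE
      parent[v] <- u
      queue <- c(queue, v)
    }
  }
  if (!all(seen)) stop("network is not connected")
  children <- setdiff(order, rootId)
  edgeDf <- data.frame(parent = parent[children], child = children,
    stringsAsFactors = FALSE)
  edgeVariants <- lapply(seq_len(nrow(edgeDf)), function(k) {
    p <- edgeDf$parent[k]; c0 <- edgeDf$child[k]
    diffSites <- sites[states[p, ] != states[c0, ]]
    if (!length(diffSites)) return(emptyVariantTable())
    do.call(rbind, lapply(diffSites, function(s)
      .edgeVariantRow(s, states[p, s], states[c0, s], ref = ref)))
  })
  edgeDf$n_mut <- vapply(edgeVariants, nrow, integer(1))
  # subtended sample counts, bottom-up
  own <- vapply(ids, function(id) length(.splitSamples(nodeSamples[id])), integer(1))
  nSub <- own
  for (u in rev(order)) {
    p <- parent[u]
    if (!is.na(p)) nSub[p] <- nSub[p] + nSub[u]
  }
  # clade labelling from each node's absolute (reference-relative) variant
  # state: the accumulated root-path changes applied to the root haplotype
  pathKeys <- list()
  for (u in order) {
    diffSites <- sites[states[u, ] != .REF_STATE]
    pathKeys[[u]] <- paste0(diffSites, ":", states[u, diffSites])
  }
  labels <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (length(cladeDefinitions)) {
    defs <- lapply(cladeDefinitions, function(toks)
      do.call(rbind, lapply(toks, parseVariantToken, ref = ref)))
    defKeys <- lapply(defs, function(v) {
      key <- ifelse(is.na(v$ins_index), as.character(v$position),
        paste0(v$position, "+", v$ins_index))
      der <- v$derived
      if (!is.null(ref)) {
        miss <- is.na(der)
        if (any(miss)) der[miss] <- chartr("ACGT", "GTAC", referenceBase(ref, v$position[miss]))
      }
      list(key = key, der = der)
    })
    depth <- vapply(defKeys, function(d) length(d$key), integer(1))
    matched <- stats::setNames(rep(FALSE, length(defs)), names(defs))
    for (u in ids) {
      pk <- pathKeys[[u]]
      pkSite <- sub(":.*", "", pk)
      pkState <- sub(".*:", "", pk)
      ok <- vapply(defKeys, function(d) {
        hit <- match(d$key, pkSite)
        if (any(is.na(hit))) return(FALSE)
        all(is.na(d$der) | pkState[hit] == d$der | pkState[hit] == "1")
      }, logical(1))
      if (any(ok)) {
        matched[ok] <- TRUE
        labels[u] <- names(defs)[ok][which.max(depth[ok])]
      }
    }
    if (!all(matched))
      stop("clade definition inconsistent with topology: ",
        paste(names(matched)[!matched], collapse = ", "))
  }
  nodeDf <- data.frame(id = ids, clade = labels[ids],
    samples = unname(nodeSamples[ids]), n_sub = unname(nSub[ids]),
    stringsAsFactors = FALSE)
  nodeDf$samples[is.na(nodeDf$samples)] <- ""
  methods::new("CladeTree", nodes = nodeDf, edges = edgeDf,
    edgeVariants = edgeVariants, root = rootId)
}

setMethod("show", "CladeTree", function(object) {
  cat("CladeTree rooted at", object@root, "with", nrow(object@nodes), "nodes,",
    sum(object@nodes$n_sub[object@nodes$id == object@root]), "samples,",
    sum(!is.na(object@nodes$clade)), "labelled nodes\n")
})

#' Children of a node
#' @param tree a [CladeTree]; `id` a node id.
#' @param id node id.
#' @export
childNodes <- function(tree, id) tree@edges$child[tree@edges$parent == id]

# ids of all nodes at or below `id`
.subtreeIds <- function(tree, id) {
  out <- id
  stack <- id
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    kids <- childNodes(tree, u)
    out <- c(out, kids)
    stack <- c(stack, kids)
  }
  out
}

# edges on the path root -> id (edge row indices, root side first)
.pathEdges <- function(tree, id) {
  out <- integer(0)
  u <- id
  while (u != tree@root) {
    k <- which(tree@edges$child == u)
    out <- c(k, out)
    u <- tree@edges$parent[k]
  }
  out
}

#' Shallowest node carrying a clade label
#' @param tree a [CladeTree].
#' @param clade clade label.
#' @export
cladeRootNode <- function(tree, clade) {
  hits <- tree@nodes$id[!is.na(tree@nodes$clade) & tree@nodes$clade == clade]
  subs <- tree@nodes$id[!is.na(tree@nodes$clade) &
    vapply(tree@nodes$clade, function(x) !is.na(x) && isSubclade(x, clade), logical(1))]
  hits <- unique(c(hits, subs))
  if (!length(hits)) stop("no node labelled with clade ", clade)
  depth <- vapply(hits, function(h) length(.pathEdges(tree, h)), integer(1))
  cand <- hits[depth == min(depth)]
  cand[1L]
}

#' Samples contained in a clade
#' @param tree a [CladeTree].
#' @param clade clade label.
#' @export
cladeSamples <- function(tree, clade) {
  ids <- .subtreeIds(tree, cladeRootNode(tree, clade))
  unlist(lapply(tree@nodes$samples[match(ids, tree@nodes$id)], .splitSamples))
}

#' Reconstruct a leaf's variant set from its root path
#'
#' Concatenates the branch variant lists from the root to a node, applying
#' reversals, and returns the resulting variant state relative to the root.
#' Used to verify the tree against the haplotypes it encodes.
#'
#' @param tree a [CladeTree].
#' @param id node id.
#' @return Character vector of `site:state` keys.
#' @export
rootPathState <- function(tree, id) {
  state <- list()
  for (k in .pathEdges(tree, id)) {
    ev <- tree@edgeVariants[[k]]
    for (i in seq_len(nrow(ev))) {
      site <- if (is.na(ev$ins_index[i])) as.character(ev$position[i])
        else paste0(ev$position[i], "+", ev$ins_index[i])
      if (ev$back[i] %% 2L == 1L) state[[site]] <- NULL
      else state[[site]] <- if (is.na(ev$derived[i])) "1" else ev$derived[i]
    }
  }
  if (!length(state)) return(character(0))
  sort(paste0(names(state), ":", unlist(state)))
}

#' Export a CladeTree as a newick string
#'
#' Branch lengths are mutation counts; tip labels are node ids (with sample
#' ids appended when present).
#'
#' @param tree a [CladeTree].
#' @return Character scalar in newick format.
#' @export
asNewick <- function(tree) {
  rec <- function(id) {
    kids <- childNodes(tree, id)
    lab <- id
    if (!length(kids)) return(lab)
    inner <- vapply(kids, function(k) {
      paste0(rec(k), ":", tree@edges$n_mut[tree@edges$child == k])
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")", lab)
  }
  paste0(rec(tree@root), ";")
}

#' Place a partially typed sample on a clade tree
#'
#' Finds the deepest labelled clade consistent with the sample's typed
#' states: every defining variant on the clade's root path whose position
#' is covered must be present in derived state, and the clade must be
#' positively supported by at least one covered defining variant of its own
#' stem. Deeper clades that are not excluded only because their defining
#' positions were not typed are returned as the ambiguity set. A sample
#' carrying derived states of mutually exclusive branches is unplaceable.
#'
#' @param tree a labelled [CladeTree].
#' @param variants variant data.frame of the sample.
#' @param coverage two-column matrix of typed ranges.
#' @param ref optional [MtReference].
#' @return List with elements `clade` and `ambiguity`.
#' @export
assignCladeFromMarkers <- function(tree, variants, coverage, ref = NULL) {
  labs <- tree@nodes$clade
  labelled <- tree@nodes$id[!is.na(labs)]
  if (!length(labelled)) stop("tree carries no clade labels")
  covered <- function(p) any(p >= coverage[, 1L] & p <= coverage[, 2L])
  vKeys <- .variantKeys(variants)
  vPos <- as.integer(sub("\\..*", "", sub(":.*", "", vKeys)))
  vDer <- sub(".*:", "", vKeys)
  hasDerived <- function(pos, der) {
    hit <- which(vPos == pos)
    if (!length(hit)) return(FALSE)
    any(is.na(der) | der == "t" | vDer[hit] == der | vDer[hit] == "t")
  }
  # per labelled clade: root-path defining variants and own stem variants
  cladeIds <- stats::setNames(labelled, labs[!is.na(labs)])
  cladeNames <- names(cladeIds)
  info <- lapply(cladeNames, function(cl) {
    node <- cladeRootNode(tree, cl)
    path <- .pathEdges(tree, node)
    pv <- do.call(rbind, c(list(emptyVariantTable()), tree@edgeVariants[path]))
    pv <- pv[pv$back %% 2L == 0L, , drop = FALSE]
    # stem = variants below the nearest differently labelled ancestor
    stemEdges <- integer(0)
    u <- node
    while (u != tree@root) {
      k <- which(tree@edges$child == u)
      stemEdges <- c(k, stemEdges)
      u <- tree@edges$parent[k]
      ucl <- tree@nodes$clade[tree@nodes$id == u]
      if (!is.na(ucl) && ucl != cl) break
    }
    sv <- do.call(rbind, c(list(emptyVariantTable()), tree@edgeVariants[stemEdges]))
    sv <- sv[sv$back %% 2L == 0L, , drop = FALSE]
    list(node = node, path = pv, stem = sv,
      depth = length(path))
  })
  names(info) <- cladeNames
  consistent <- vapply(cladeNames, function(cl) {
    pv <- info[[cl]]$path
    if (!nrow(pv)) return(TRUE)
    ok <- TRUE
    for (i in seq_len(nrow(pv))) {
      if (!covered(pv$position[i])) next
      if (!hasDerived(pv$position[i], pv$derived[i])) { ok <- FALSE; break }
    }
    ok
  }, logical(1))
  supported <- vapply(cladeNames, function(cl) {
    sv <- info[[cl]]$stem
    if (!nrow(sv)) return(FALSE)
    any(vapply(seq_len(nrow(sv)), function(i)
      covered(sv$position[i]) && hasDerived(sv$position[i], sv$derived[i]), logical(1)))
  }, logical(1))
  candidates <- cladeNames[consistent & supported]
  if (!length(candidates))
    stop("unplaceable: typed states conflict with every labelled root path")
  # conflict: two supported clades on incompatible paths
  onPath <- function(a, b) {
    ids <- .subtreeIds(tree, info[[a]]$node)
    info[[b]]$node %in% ids || info[[a]]$node %in% .subtreeIds(tree, info[[b]]$node)
  }
  if (length(candidates) > 1L) {
    for (i in 1:(length(candidates) - 1L)) for (j in (i + 1L):length(candidates)) {
      if (!onPath(candidates[i], candidates[j]))
        stop("unplaceable: sample is derived for markers of mutually exclusive branches (",
          candidates[i], " vs ", candidates[j], ")")
    }
  }
  depths <- vapply(candidates, function(cl) info[[cl]]$depth, integer(1))
  assigned <- candidates[which.max(depths)]
  ambiguous <- cladeNames[consistent & !supported &
    vapply(cladeNames, function(cl) {
      info[[cl]]$node %in% .subtreeIds(tree, info[[assigned]]$node) &&
        cl != assigned
    }, logical(1))]
  list(clade = assigned, ambiguity = unname(ambiguous))
}

#' Does one haplogroup label nest inside another?
#'
#' Haplogroup nomenclature alternates letters and digits (M1 -> M1a ->
#' M1a1): a label is a subclade of another when it extends it and the
#' first extra character switches character class (so M10 is not inside
#' M1).
#'
#' @param child,parent haplogroup labels.
#' @return Logical.
#' @export
isSubclade <- function(child, parent) {
  if (child == parent) return(FALSE)
  if (!startsWith(child, parent)) return(FALSE)
  lastP <- substr(parent, nchar(parent), nchar(parent))
  nextC <- substr(child, nchar(parent) + 1L, nchar(parent) + 1L)
  if (nextC == "'") return(TRUE)
  grepl("[0-9]", lastP) != grepl("[0-9]", nextC)
}

#' Build a CladeTree directly from a timed genealogy
#'
#' Converts an `ape::phylo` genealogy (e.g. from [simulateGenealogy()])
#' plus a mutation-event table (from [dropMutations()]) into a
#' mutation-labelled [CladeTree], labelling the root node so the whole
#' tree forms one dateable clade. The event table's `edge` column must
#' index rows of `gen$edge`.
#'
#' @param gen a `phylo` object (cladewise order, as returned by
#'   [dropMutations()]).
#' @param events data.frame with columns `edge`, `position`, `alt`
#'   (`NULL` for a mutation-free tree).
#' @param ref optional [MtReference] for allele bookkeeping.
#' @param label clade label given to the root.
#' @return A [CladeTree] whose tips carry the genealogy's tip labels as
#'   samples.
#' @export
cladeTreeFromGenealogy <- function(gen, events = NULL, ref = NULL, label = "ALL") {
  nTip <- length(gen$tip.label)
  nNode <- nTip + gen$Nnode
  ids <- c(gen$tip.label, paste0("n", (nTip + 1L):nNode))
  edgeDf <- data.frame(parent = ids[gen$edge[, 1L]], child = ids[gen$edge[, 2L]],
    stringsAsFactors = FALSE)
  edgeVariants <- lapply(seq_len(nrow(edgeDf)), function(e) {
    if (is.null(events)) return(emptyVariantTable())
    ev <- events[events$edge == e, , drop = FALSE]
    if (!nrow(ev)) return(emptyVariantTable())
    refB <- if (!is.null(ref)) referenceBase(ref, ev$position) else rep(NA_character_, nrow(ev))
    data.frame(position = as.integer(ev$position), ins_index = NA_integer_,
      ref = refB, derived = ev$alt,
      kind = vapply(seq_len(nrow(ev)), function(i)
        if (is.na(refB[i])) "transition" else .substitutionKind(refB[i], ev$alt[i]),
        character(1)),
      back = 0L, het = NA_character_, stringsAsFactors = FALSE)
  })
  edgeDf$n_mut <- vapply(edgeVariants, nrow, integer(1))
  nSub <- c(rep(1L, nTip), rep(0L, gen$Nnode))
  # accumulate tipward counts rootward (children listed after parents in
  # cladewise order, so a reverse pass suffices)
  for (e in rev(seq_len(nrow(gen$edge))))
    nSub[gen$edge[e, 1L]] <- nSub[gen$edge[e, 1L]] + nSub[gen$edge[e, 2L]]
  rootIdx <- setdiff(gen$edge[, 1L], gen$edge[, 2L])[1L]
  nodeDf <- data.frame(id = ids,
    clade = ifelse(seq_len(nNode) == rootIdx, label, NA_character_),
    samples = c(gen$tip.label, rep("", gen$Nnode)),
    n_sub = nSub, stringsAsFactors = FALSE)
  methods::new("CladeTree", nodes = nodeDf, edges = edgeDf,
    edgeVariants = edgeVariants, root = ids[rootIdx])
}
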