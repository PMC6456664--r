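SPLIT_STRATEGIES <- c("dcst", "first_diff", "max_divergence")

#' Choose the split column and nucleotide bipartition for a subgroup
#'
#' The core decision rule. Under the default \code{dcst} strategy every
#' column is scored with \code{\link{scoreAllColumns}} and the lowest
#' position attaining the maximal score is selected; the nucleotide whose
#' count deviates least from the subgroup midpoint (ties broken in
#' A < C < G < T order) is routed to the "up" branch and all other observed
#' nucleotides to the "down" branch. On a biallelic column this is exactly a
#' one-vs-one split; on tri-/quadallelic columns it is the midpoint-nearest
#' allele versus the rest.
#'
#' Two deliberately imbalanced alternatives are available for comparison:
#' \code{first_diff} takes the lowest position at which any two subgroup
#' rows differ (up = alphabetically first observed allele), and
#' \code{max_divergence} takes the polymorphic position whose most frequent
#' allele count is largest (up = that majority allele).
#'
#' @param rows a \linkS4class{BarcodeAlignment} or character matrix holding
#'   the subgroup (>= 2 rows).
#' @param strategy one of \code{"dcst"}, \code{"first_diff"},
#'   \code{"max_divergence"}.
#' @return A list with \code{position} (1-based column), \code{up} and
#'   \code{down} (disjoint character vectors of nucleotides), and
#'   \code{profile} (the selected column's score row).
#' @examples
#' aln <- BarcodeAlignment(c(a = "CA", b = "CC", c = "TA", d = "TC"))
#' selectSplit(aln)$position  # 1
#' @export
selectSplit <- function(rows, strategy = c("dcst", "first_diff",
                                           "max_divergence")) {
  strategy <- match.arg(strategy)
  m <- if (is.matrix(rows)) rows else alnMatrix(rows)
  if (nrow(m) < 2L) stop("subgroup must contain >= 2 sequences")
  cnt <- nucCountMatrix(m)
  nTypes <- colSums(cnt > 0L)
  poly <- which(nTypes >= 2L)
  if (length(poly) == 0L)
    stop("indistinguishable sequences: no polymorphic A/C/G/T column among { ",
         paste(rownames(m), collapse = ", "), " }")
  scores <- scoreAllColumns(m)
  if (strategy == "dcst") {
    pos <- which(scores$score == max(scores$score))[1L]
  } else if (strategy == "first_diff") {
    pos <- poly[1L]
  } else {
    topCount <- apply(cnt[, poly, drop = FALSE], 2L, max)
    pos <- poly[which.max(topCount)]  # ties: lowest position
  }
  counts <- cnt[, pos]
  observed <- NUCS[counts > 0L]
  if (strategy == "dcst") {
    mid <- midValue(nrow(m))
    dev <- abs(mid - counts[observed])
    upNuc <- observed[which.min(dev)]  # A<C<G<T order is NUCS order
  } else if (strategy == "first_diff") {
    upNuc <- observed[1L]
  } else {
    upNuc <- observed[which.max(counts[observed])]
  }
  list(position = as.integer(pos),
       up = upNuc,
       down = setdiff(observed, upNuc),
       profile = scores[pos, ])
}

#' Build the species decision tree
#'
#' Recursively partitions the full species set: at each node the split
#' chosen by \code{\link{selectSplit}} routes species carrying an "up"
#' nucleotide at the split position to the first child and the rest to the
#' second, until every subgroup holds a single species. A position may be
#' selected at several nodes. Rows carrying a non-A/C/G/T character at a
#' node's split position are routed "down" (with a warning), so the leaf
#' partition always covers every species.
#'
#' Construction is deterministic: identical input yields an identical tree,
#' and permuting input rows changes leaf enumeration order only, never the
#' selected positions.
#'
#' @param aln a \linkS4class{BarcodeAlignment} with >= 2 species, pairwise
#'   distinguishable at some A/C/G/T column.
#' @param strategy split strategy, see \code{\link{selectSplit}}.
#' @param referenceId record whose ungapped coordinates are used in node
#'   labels (default: first record).
#' @return A \linkS4class{SnpTree}.
#' @examples
#' aln <- makeBalancedCodeAlignment(k = 2, seed = 1)
#' tree <- buildTree(aln)
#' treeDepth(tree)  # 2
#' @export
buildTree <- function(aln, strategy = c("dcst", "first_diff",
                                        "max_divergence"),
                      referenceId = NULL) {
  strategy <- match.arg(strategy)
  m <- alnMatrix(aln)
  if (nrow(m) < 2L) stop("tree construction needs >= 2 species")
  if (is.null(referenceId)) referenceId <- rownames(m)[1L]
  refmap <- mapToReference(seq_len(ncol(m)), aln, referenceId)

  nodeId <- 0L
  build <- function(idx, path) {
    if (length(idx) == 1L)
      return(list(type = "leaf", species = rownames(m)[idx]))
    sp <- tryCatch(selectSplit(m[idx, , drop = FALSE], strategy),
                   error = function(e) {
                     stop("at subtree [", path, "]: ", conditionMessage(e),
                          call. = FALSE)
                   })
    chars <- m[idx, sp$position]
    upRows <- idx[chars %in% sp$up]
    downRows <- setdiff(idx, upRows)
    stray <- !(chars %in% c(sp$up, sp$down))
    if (any(stray))
      warning(sprintf(
        "species %s carry a non-ACGT character at split position %d; routed down",
        paste(rownames(m)[idx[stray]], collapse = ", "), sp$position))
    nodeId <<- nodeId + 1L
    list(type = "node", id = nodeId,
         position = sp$position,
         referencePosition = refmap$refPosition[sp$position],
         up = sp$up, down = sp$down,
         label = sprintf("%s%s(%d)", paste(sp$up, collapse = ""),
                         paste(sp$down, collapse = ""),
                         refmap$refPosition[sp$position]),
         size = length(idx),
         children = list(build(upRows, paste0(path, "U")),
                         build(downRows, paste0(path, "D"))))
  }
  root <- build(seq_len(nrow(m)), "")

  positions <- integer(); depth <- 0L
  walk <- function(node, d) {
    if (node$type == "leaf") {
      depth <<- max(depth, d)
    } else {
      positions <<- c(positions, node$position)
      walk(node$children[[1L]], d + 1L)
      walk(node$children[[2L]], d + 1L)
    }
  }
  walk(root, 0L)
  new("SnpTree", root = root, nSpecies = nrow(m), depth = depth,
      selectedPositions = sort(unique(positions)), strategy = strategy,
      referenceId = referenceId)
}

#' Summary statistics of a decision tree
#'
#' @param tree a \linkS4class{SnpTree}.
#' @return A list: \code{depth}, \code{nodeCount} (internal nodes),
#'   \code{leafCount}, \code{selectedPositionCount}, and
#'   \code{balanceIndex} — the maximum over internal nodes of the absolute
#'   difference between child subgroup sizes (0 for a perfectly balanced
#'   tree).
#' @export
treeStats <- function(tree) {
  nodes <- 0L; leaves <- 0L; balance <- 0L; sizeSum <- 0L
  walk <- function(node) {
    if (node$type == "leaf") { leaves <<- leaves + 1L; return(1L) }
    nodes <<- nodes + 1L
    l <- walk(node$children[[1L]])
    r <- walk(node$children[[2L]])
    balance <<- max(balance, abs(l - r))
    sizeSum <<- sizeSum + l + r
    l + r
  }
  walk(tree@root)
  list(depth = tree@depth, nodeCount = nodes, leafCount = leaves,
       selectedPositionCount = length(tree@selectedPositions),
       balanceIndex = balance, subgroupSizeSum = sizeSum)
}

#' Serialise a decision tree as JSON
#'
#' Nodes carry \code{position}, \code{referencePosition}, \code{up} /
#' \code{down} nucleotide strings, \code{label} and two children; leaves
#' carry the species identifier.
#'
#' @param tree a \linkS4class{SnpTree}.
#' @param path optional output path; when given the JSON is written there.
#' @return The JSON string (invisibly when \code{path} is given).
#' @export
treeToJSON <- function(tree, path = NULL) {
  strip <- function(node) {
    if (node$type == "leaf")
      return(list(type = "leaf", species = node$species))
    list(type = "node", position = node$position,
         referencePosition = node$referencePosition,
         up = paste(node$up, collapse = ""),
         down = paste(node$down, collapse = ""),
         label = node$label, size = node$size,
         children = list(strip(node$children[[1L]]),
                         strip(node$children[[2L]])))
  }
  js <- jsonlite::toJSON(list(strategy = tree@strategy,
                              nSpecies = tree@nSpecies,
                              depth = tree@depth,
                              selectedPositions = tree@selectedPositions,
                              referenceId = tree@referenceId,
                              root = strip(tree@root)),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Render a decision tree as indented text
#'
#' Each internal node prints its \code{"XY(pos)"} label (up nucleotides,
#' down nucleotides, reference-mapped position); leaves print the species.
#'
#' @param tree a \linkS4class{SnpTree}.
#' @param path optional output path.
#' @return Character vector of lines (invisibly when \code{path} is given).
#' @export
treeToText <- function(tree, path = NULL) {
  lines <- character()
  walk <- function(node, indent, branch) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      lines <<- c(lines, sprintf("%s%s- %s", pad, branch, node$species))
    } else {
      lines <<- c(lines, sprintf("%s%s%s [n=%d]", pad, branch, node$label,
                                 node$size))
      walk(node$children[[1L]], indent + 1L, "up: ")
      walk(node$children[[2L]], indent + 1L, "down: ")
    }
  }
  walk(tree@root, 0L, "")
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}
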