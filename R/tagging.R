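#' Map trimmed-alignment columns to reference-sequence coordinates
#'
#' Reported positions (node labels, tag position tables) use coordinates on
#' the ungapped, untrimmed reference record, so they can be located on the
#' original deposited sequence. For a column \code{p} of the (possibly
#' trimmed) alignment, the reference coordinate is the number of non-gap
#' reference characters in columns 1..p, plus the number of reference
#' residues that trimming removed from the 5' end (taken from
#' \code{metadata(aln)$trim}, or passed as \code{headOffset}).
#'
#' Columns where the reference itself carries a gap have no residue of
#' their own; they are reported at the nearest preceding reference residue
#' and flagged in \code{refIsGap}.
#'
#' @param positions 1-based column indices in \code{aln}.
#' @param aln a \linkS4class{BarcodeAlignment}.
#' @param referenceId record to map onto (default: first record).
#' @param headOffset reference residues removed by 5' trimming; defaults to
#'   the value recorded by \code{\link{trimAlignment}}, else 0.
#' @return A data.frame: \code{position}, \code{refPosition},
#'   \code{refIsGap}.
#' @examples
#' aln <- BarcodeAlignment(c(ref = "A-CG", other = "ATCG"))
#' mapToReference(1:4, aln)$refPosition  # 1 1 2 3
#' @export
mapToReference <- function(positions, aln, referenceId = NULL,
                           headOffset = NULL) {
  if (is.null(referenceId)) referenceId <- speciesIds(aln)[1L]
  if (!referenceId %in% speciesIds(aln))
    stop("reference record not in alignment: ", referenceId)
  if (is.null(headOffset)) {
    tr <- metadata(aln)$trim
    headOffset <- if (!is.null(tr)) unname(tr$headResidues[referenceId]) else 0L
  }
  ref <- strsplit(as.character(aln[[referenceId]]), "", fixed = TRUE)[[1L]]
  M <- length(ref)
  if (any(positions < 1L | positions > M))
    stop("position out of range 1..", M)
  resCount <- cumsum(ref != "-")
  data.frame(position = as.integer(positions),
             refPosition = as.integer(headOffset + resCount[positions]),
             refIsGap = ref[positions] == "-")
}

#' Extract per-species SNP tags
#'
#' Projects each species' aligned sequence onto the tree's selected
#' positions (ascending). Because every pair of species is separated by some
#' node whose position is among the selected positions, and the two species
#' carry different nucleotide sets there, the tags are pairwise distinct;
#' this is verified and a violation raised as an internal consistency error.
#'
#' @param tree a \linkS4class{SnpTree} built from \code{aln}.
#' @param aln the \linkS4class{BarcodeAlignment} the tree was built from.
#' @return A \linkS4class{SpeciesTagSet}.
#' @examples
#' aln <- makeBalancedCodeAlignment(k = 2, seed = 1)
#' tags <- extractTags(buildTree(aln), aln)
#' tagStrings(tags)
#' @export
extractTags <- function(tree, aln) {
  m <- alnMatrix(aln)
  if (!all(speciesIds(aln) %in% unlist(leafSpecies(tree@root))))
    stop("tree was not built from this alignment: species mismatch")
  pos <- tree@selectedPositions
  tagmat <- m[, pos, drop = FALSE]
  tags <- apply(tagmat, 1L, paste, collapse = "")
  if (anyDuplicated(tags)) {
    dup <- names(tags)[tags %in% tags[duplicated(tags)]]
    stop("internal consistency error: duplicate tags for ",
         paste(dup, collapse = ", "))
  }
  refmap <- mapToReference(pos, aln, tree@referenceId)
  new("SpeciesTagSet", species = rownames(m), tag = unname(tags),
      positions = pos, referencePositions = refmap$refPosition)
}

leafSpecies <- function(node) {
  if (node$type == "leaf") return(node$species)
  c(leafSpecies(node$children[[1L]]), leafSpecies(node$children[[2L]]))
}

#' Verify that tags and tree agree
#'
#' Routes each species' full sequence down the tree (following the "up"
#' branch when its nucleotide at the node position is in the node's up set)
#' and checks that it arrives at its own leaf; also re-checks tag
#' uniqueness. A freshly built tree always verifies; the report exists as a
#' guard for serialised/edited trees.
#'
#' @param tree a \linkS4class{SnpTree}.
#' @param tags a \linkS4class{SpeciesTagSet} from \code{\link{extractTags}}.
#' @param aln the source \linkS4class{BarcodeAlignment}.
#' @return A list: \code{ok} (logical), \code{nMismatch}, and
#'   \code{report}, a data.frame with \code{species}, \code{reachedLeaf},
#'   \code{match}.
#' @export
verifyTagRoundtrip <- function(tree, tags, aln) {
  m <- alnMatrix(aln)
  route <- function(row) {
    node <- tree@root
    while (node$type != "leaf") {
      ch <- m[row, node$position]
      node <- if (ch %in% node$up) node$children[[1L]] else node$children[[2L]]
    }
    node$species
  }
  reached <- vapply(seq_len(nrow(m)), route, character(1L))
  report <- data.frame(species = rownames(m), reachedLeaf = reached,
                       match = rownames(m) == reached)
  dupTags <- anyDuplicated(tags@tag) > 0L
  list(ok = all(report$match) && !dupTags,
       nMismatch = sum(!report$match) + as.integer(dupTags),
       report = report)
}

#' Write tag tables as TSV
#'
#' Writes the per-species tag table (\code{species_id}, \code{tag},
#' \code{tag_length}) and, optionally, a companion table of selected
#' positions with trimmed and reference coordinates.
#'
#' @param tags a \linkS4class{SpeciesTagSet}.
#' @param path output path for the tag table.
#' @param positionsPath optional output path for the positions table.
#' @return \code{path}, invisibly.
#' @export
writeTags <- function(tags, path, positionsPath = NULL) {
  utils::write.table(as.data.frame(tags), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(positionsPath)) {
    pos <- data.frame(position = tags@positions,
                      reference_position = tags@referencePositions)
    utils::write.table(pos, positionsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
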