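#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom Biostrings DNAStringSet readBStringSet writeXStringSet width
NULL

#' Species-per-row multiple sequence alignment
#'
#' A \code{BarcodeAlignment} is a \linkS4class{DNAStringSet} holding one
#' aligned barcode sequence per species. All records must have identical
#' width and unique names (the species identifiers). Gap (\code{-}) and
#' IUPAC ambiguity characters are permitted; they are carried through all
#' operations but never counted as alleles.
#'
#' Trimming information (see \code{\link{trimAlignment}}) is kept in
#' \code{metadata()} under \code{$trim}, so that selected positions can later
#' be mapped back to coordinates on an untrimmed, ungapped reference record.
#'
#' @seealso \code{\link{readAlignment}}, \code{\link{trimAlignment}},
#'   \code{\link{snpColumns}}, \code{\link{buildTree}}
#' @exportClass BarcodeAlignment
setClass("BarcodeAlignment", contains = "DNAStringSet")

setValidity("BarcodeAlignment", function(object) {
  msg <- character()
  if (length(object) < 1L)
    msg <- c(msg, "alignment must contain at least one record")
  w <- Biostrings::width(object)
  if (length(unique(w)) > 1L) {
    bad <- names(object)[which(w != w[1L])[1L]]
    msg <- c(msg, sprintf(
      "aligned records must all have the same length; record '%s' has width %d, expected %d",
      bad, w[which(w != w[1L])[1L]], w[1L]))
  }
  if (is.null(names(object)) || anyNA(names(object)) || any(names(object) == ""))
    msg <- c(msg, "every record must carry a species identifier (FASTA header)")
  else if (anyDuplicated(names(object)))
    msg <- c(msg, sprintf("duplicate species identifiers: %s",
                          paste(unique(names(object)[duplicated(names(object))]),
                                collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a BarcodeAlignment from named sequences
#'
#' @param x a named character vector of equal-length aligned sequences, or a
#'   \code{DNAStringSet}.
#' @return A \linkS4class{BarcodeAlignment}.
#' @examples
#' BarcodeAlignment(c(sp1 = "ACGT", sp2 = "ACGA"))
#' @export
BarcodeAlignment <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  new("BarcodeAlignment", x)
}

#' @describeIn BarcodeAlignment number of species (rows)
#' @param aln a \code{BarcodeAlignment}
#' @export
nSpecies <- function(aln) length(aln)

#' @describeIn BarcodeAlignment alignment width (columns)
#' @export
alignmentWidth <- function(aln) {
  if (length(aln) == 0L) 0L else Biostrings::width(aln)[1L]
}

#' @describeIn BarcodeAlignment species identifiers
#' @export
speciesIds <- function(aln) names(aln)

#' @exportMethod show
setMethod("show", "BarcodeAlignment", function(object) {
  cat(sprintf("BarcodeAlignment: %d species x %d aligned columns\n",
              nSpecies(object), alignmentWidth(object)))
  tr <- metadata(object)$trim
  if (!is.null(tr))
    cat(sprintf("  trimmed: %d head + %d tail columns removed\n",
                tr$dropHead, tr$dropTail))
  callNextMethod()
})

## internal: alignment as a character matrix (species x columns)
alnMatrix <- function(aln) {
  m <- as.matrix(aln)
  rownames(m) <- names(aln)
  m
}

#' Decision tree over SNP positions
#'
#' Binary tree produced by \code{\link{buildTree}}. Each internal node stores
#' a 1-based column of the alignment and a bipartition of the nucleotides
#' observed there; each leaf holds exactly one species. Node labels follow
#' the \code{"XY(r)"} convention: \code{X} the nucleotide(s) routed up,
#' \code{Y} those routed down, and \code{r} the position mapped onto the
#' reference record's ungapped coordinates.
#'
#' @slot root nested-list representation of the tree (see
#'   \code{\link{treeToJSON}} for the serialised shape)
#' @slot nSpecies number of leaves
#' @slot depth number of internal nodes on the longest root-to-leaf path
#' @slot selectedPositions ascending, deduplicated positions used by any node
#' @slot strategy split strategy used (\code{"dcst"}, \code{"first_diff"} or
#'   \code{"max_divergence"})
#' @slot referenceId record used for reference-coordinate node labels
#' @exportClass SnpTree
setClass("SnpTree", representation(
  root = "list",
  nSpecies = "integer",
  depth = "integer",
  selectedPositions = "integer",
  strategy = "character",
  referenceId = "character"
))

setValidity("SnpTree", function(object) {
  msg <- character()
  if (length(object@root) == 0L) msg <- c(msg, "empty tree")
  if (object@depth < ceiling(log2(max(object@nSpecies, 1L))))
    msg <- c(msg, "tree depth below ceil(log2(N)): leaves cannot be distinct")
  if (is.unsorted(object@selectedPositions, strictly = TRUE))
    msg <- c(msg, "selectedPositions must be strictly ascending")
  if (length(msg)) msg else TRUE
})

#' @describeIn SnpTree positions used by at least one node (ascending)
#' @param tree a \code{SnpTree}
#' @export
selectedPositions <- function(tree) tree@selectedPositions

#' @describeIn SnpTree longest root-to-leaf internal-node count
#' @export
treeDepth <- function(tree) tree@depth

#' @exportMethod show
setMethod("show", "SnpTree", function(object) {
  cat(sprintf("SnpTree (%s strategy): %d species, depth %d, %d selected positions\n",
              object@strategy, object@nSpecies, object@depth,
              length(object@selectedPositions)))
  cat("positions:", paste(object@selectedPositions, collapse = " "), "\n")
})

#' Per-species SNP tags
#'
#' The projection of each species' aligned sequence onto the tree's selected
#' positions, in ascending position order. Tags are guaranteed pairwise
#' distinct whenever tree construction succeeded.
#'
#' @slot species species identifiers, in alignment order
#' @slot tag nucleotide tag strings, parallel to \code{species}
#' @slot positions the shared ascending selected positions (trimmed-alignment
#'   coordinates)
#' @slot referencePositions the same positions mapped onto the reference
#'   record's ungapped, untrimmed coordinates (NA when no mapping requested)
#' @exportClass SpeciesTagSet
setClass("SpeciesTagSet", representation(
  species = "character",
  tag = "character",
  positions = "integer",
  referencePositions = "integer"
))

setValidity("SpeciesTagSet", function(object) {
  msg <- character()
  if (length(object@species) != length(object@tag))
    msg <- c(msg, "species and tag lengths differ")
  if (anyDuplicated(object@tag))
    msg <- c(msg, "tags are not pairwise distinct")
  if (length(object@tag) && any(nchar(object@tag) != length(object@positions)))
    msg <- c(msg, "every tag must have one character per selected position")
  if (length(object@referencePositions) &&
      length(object@referencePositions) != length(object@positions))
    msg <- c(msg, "referencePositions must parallel positions")
  if (length(msg)) msg else TRUE
})

#' @describeIn SpeciesTagSet tags as a named character vector
#' @param tags a \code{SpeciesTagSet}
#' @export
tagStrings <- function(tags) stats::setNames(tags@tag, tags@species)

#' @describeIn SpeciesTagSet positions shared by all tags
#' @export
tagPositions <- function(tags) tags@positions

#' @exportMethod show
setMethod("show", "SpeciesTagSet", function(object) {
  cat(sprintf("SpeciesTagSet: %d species, tag length %d\n",
              length(object@species), length(object@positions)))
  n <- min(5L, length(object@species))
  for (i in seq_len(n))
    cat(sprintf("  %-30s %s\n", object@species[i], object@tag[i]))
  if (length(object@species) > n) cat(sprintf("  ... %d more\n",
                                              length(object@species) - n))
})

#' @describeIn SpeciesTagSet coerce to a data.frame (species_id, tag,
#'   tag_length)
#' @param x a \code{SpeciesTagSet}
#' @param ... unused
#' @export
setMethod("as.data.frame", "SpeciesTagSet", function(x, ...) {
  data.frame(species_id = x@species, tag = x@tag,
             tag_length = nchar(x@tag), stringsAsFactors = FALSE)
})

#' Encoded Code 128 symbol
#'
#' @slot text the ASCII payload
#' @slot values symbol values 0..106, including the Start-B code (104), the
#'   checksum and the stop code (106)
#' @slot checksum weighted mod-103 check value (0..102)
#' @slot modules alternating bar/space module widths (1..4), bar first,
#'   including the 13-module stop pattern
#' @exportClass Code128Symbol
setClass("Code128Symbol", representation(
  text = "character",
  values = "integer",
  checksum = "integer",
  modules = "integer"
))

setValidity("Code128Symbol", function(object) {
  msg <- character()
  v <- object@values
  if (v[1L] != 104L) msg <- c(msg, "first value must be Start B (104)")
  if (v[length(v)] != 106L) msg <- c(msg, "last value must be stop (106)")
  if (object@checksum < 0L || object@checksum > 102L)
    msg <- c(msg, "checksum out of 0..102")
  if (any(object@modules < 1L | object@modules > 4L))
    msg <- c(msg, "module widths must be 1..4")
  if (sum(object@modules) != 11L * (length(v) - 1L) + 13L)
    msg <- c(msg, "total module count must be 11 per symbol plus 13 for stop")
  if (length(msg)) msg else TRUE
})

#' @exportMethod show
setMethod("show", "Code128Symbol", function(object) {
  cat(sprintf("Code128Symbol: \"%s\" (%d symbols, checksum %d, %d modules)\n",
              object@text, length(object@values), object@checksum,
              sum(object@modules)))
})
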