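#' Read an aligned FASTA file of species barcode sequences
#'
#' Reads a multiple-sequence alignment in FASTA format, one record per
#' species, and validates that all records have equal length and unique
#' identifiers. Sequences are uppercased; record order is preserved.
#'
#' @param path path to an aligned FASTA file with at least two records.
#' @param idPolicy how to derive the species identifier from the FASTA
#'   header: \code{"full_header"} keeps the whole description line,
#'   \code{"first_token"} keeps only the part before the first whitespace.
#' @return A \linkS4class{BarcodeAlignment}.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp1", "ACGT", ">sp2", "ACGA"), fa)
#' aln <- readAlignment(fa)
#' nSpecies(aln)       # 2
#' alignmentWidth(aln) # 4
#' @export
readAlignment <- function(path, idPolicy = c("full_header", "first_token")) {
  idPolicy <- match.arg(idPolicy)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                error = function(e) stop("not a readable FASTA file: ", path,
                                         " (", conditionMessage(e), ")"))
  if (length(x) == 0L) stop("FASTA file contains no records: ", path)
  if (length(x) < 2L) stop("an alignment needs at least 2 records, found ",
                           length(x))
  if (idPolicy == "first_token")
    names(x) <- sub("\\s.*$", "", names(x))
  w <- Biostrings::width(x)
  if (length(unique(w)) > 1L) {
    bad <- which(w != w[1L])[1L]
    stop(sprintf(
      "records are not aligned: '%s' has length %d but '%s' has length %d",
      names(x)[bad], w[bad], names(x)[1L], w[1L]))
  }
  if (anyDuplicated(names(x)))
    stop("duplicate species identifiers in FASTA: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  BarcodeAlignment(toupper(as.character(x)))
}

#' Write an alignment to FASTA
#'
#' @param aln a \linkS4class{BarcodeAlignment}.
#' @param path output path; sequences are wrapped at 80 columns.
#' @return \code{path}, invisibly.
#' @export
writeAlignment <- function(aln, path) {
  Biostrings::writeXStringSet(as(aln, "DNAStringSet"), path, width = 80L)
  invisible(path)
}

#' Trim alignment ends
#'
#' Removes protruding 5' and 3' alignment columns so that downstream SNP
#' selection operates on the common core of the barcode. In \code{explicit}
#' mode exactly \code{dropHead} leading and \code{dropTail} trailing columns
#' are removed. In \code{auto} mode the maximal leading and trailing runs of
#' columns containing at least one gap character (\code{-}) are removed;
#' interior columns are never touched, and a gap-free alignment is returned
#' unchanged.
#'
#' The trim bookkeeping (columns removed, and for every record the number of
#' non-gap residues discarded from its 5' end) is stored in
#' \code{metadata(aln)$trim} so that \code{\link{mapToReference}} can report
#' positions in original ungapped reference coordinates.
#'
#' @param aln a \linkS4class{BarcodeAlignment}.
#' @param mode \code{"explicit"} or \code{"auto"}.
#' @param dropHead,dropTail numbers of leading/trailing columns to remove
#'   (explicit mode).
#' @return The trimmed \linkS4class{BarcodeAlignment}.
#' @examples
#' aln <- BarcodeAlignment(c(a = "-ACG-", b = "TACGT"))
#' alignmentWidth(trimAlignment(aln, "auto"))  # 3
#' @export
trimAlignment <- function(aln, mode = c("explicit", "auto"),
                          dropHead = 0L, dropTail = 0L) {
  mode <- match.arg(mode)
  M <- alignmentWidth(aln)
  m <- alnMatrix(aln)
  if (mode == "auto") {
    hasGap <- apply(m == "-", 2L, any)
    if (!any(hasGap)) {
      dropHead <- 0L; dropTail <- 0L
    } else {
      run <- rle(hasGap)
      dropHead <- if (run$values[1L]) run$lengths[1L] else 0L
      k <- length(run$values)
      dropTail <- if (run$values[k] && k > 1L) run$lengths[k] else
        if (run$values[k] && k == 1L) 0L else 0L
      if (dropHead + dropTail >= M)
        stop("auto trim requires at least one column free of gaps")
    }
  }
  dropHead <- as.integer(dropHead); dropTail <- as.integer(dropTail)
  if (dropHead < 0L || dropTail < 0L)
    stop("trim counts must be non-negative")
  if (dropHead + dropTail >= M)
    stop(sprintf("trim range (%d + %d) leaves no columns of the %d available",
                 dropHead, dropTail, M))
  keep <- (dropHead + 1L):(M - dropTail)
  out <- BarcodeAlignment(apply(m[, keep, drop = FALSE], 1L, paste, collapse = ""))
  ## residues (non-gap characters) removed from each record's 5' end:
  ## needed to map trimmed positions back onto ungapped source coordinates
  headRes <- if (dropHead > 0L)
    rowSums(m[, seq_len(dropHead), drop = FALSE] != "-") else
    stats::setNames(integer(nrow(m)), rownames(m))
  prev <- metadata(aln)$trim
  if (!is.null(prev)) {
    ## compose with an earlier trim so reference mapping stays correct
    headRes <- headRes + prev$headResidues[names(headRes)]
    dropHeadTotal <- prev$dropHead + dropHead
    dropTailTotal <- prev$dropTail + dropTail
  } else {
    dropHeadTotal <- dropHead; dropTailTotal <- dropTail
  }
  metadata(out)$trim <- list(dropHead = dropHeadTotal, dropTail = dropTailTotal,
                             headResidues = headRes)
  out
}

#' Identify SNP columns
#'
#' A SNP column here is an alignment column containing at least two distinct
#' characters from \{A, C, G, T\} across the species set — an interspecific
#' variable site. Gap and ambiguity characters never count as alleles.
#'
#' @param aln a \linkS4class{BarcodeAlignment}.
#' @return Ascending 1-based column indices of the SNP columns.
#' @examples
#' snpColumns(BarcodeAlignment(c(a = "AAC", b = "AAT", c = "AAC")))  # 3
#' @export
snpColumns <- function(aln) {
  m <- alnMatrix(aln)
  nt <- countNucleotideTypes(m)
  which(nt >= 2L)
}

#' Read a species metadata table
#'
#' Reads a UTF-8 TSV with header columns \code{family}, \code{genus},
#' \code{species}, \code{bp} and \code{accession} (versioned GenBank
#' accessions, e.g. \code{KT883659.1}).
#'
#' @param path path to the TSV file.
#' @return A data.frame with one row per species, order preserved.
#' @export
readSpeciesMetadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("family", "genus", "species", "bp", "accession")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("metadata table is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) return(df[, required])
  df$bp <- as.integer(df$bp)
  bad <- !grepl("^[A-Za-z]+[0-9]+\\.[0-9]+$", df$accession)
  if (any(bad))
    stop("malformed accession(s): ",
         paste(utils::head(df$accession[bad], 5L), collapse = ", "))
  df[, required]
}
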