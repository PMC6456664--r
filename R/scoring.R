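NUCS <- c("A", "C", "G", "T")
## weight by number of distinct nucleotide types (1..4); the decimal
## constants are part of the scoring rule's definition, not rounded thirds
TYPE_WEIGHTS <- c(0, 1, 0.66, 0.33)

## internal: 4 x M count matrix from a character matrix of rows
nucCountMatrix <- function(m) {
  cnt <- vapply(NUCS, function(b) .colSums(m == b, nrow(m), ncol(m)),
                numeric(ncol(m)))
  if (ncol(m) == 1L) cnt <- matrix(cnt, nrow = 1L, dimnames = list(NULL, NUCS))
  t(cnt)  # 4 x M, rows A C G T
}

countNucleotideTypes <- function(m) {
  as.integer(colSums(nucCountMatrix(m) > 0L))
}

#' Per-column nucleotide frequency distribution
#'
#' Counts A, C, G and T occurrences in every column of an alignment (or of a
#' subgroup of its rows). Characters outside \{A,C,G,T\} — gaps, N, IUPAC
#' ambiguity codes — are excluded from the counts; \code{nValid} records how
#' many rows contributed an unambiguous nucleotide in each column.
#'
#' @param rows a \linkS4class{BarcodeAlignment} or a character matrix of
#'   aligned rows (species x columns).
#' @return A list with \code{counts} (4 x M integer matrix, rows A, C, G, T)
#'   and \code{nValid} (integer vector of length M).
#' @examples
#' aln <- BarcodeAlignment(c(a = "AC", b = "AT"))
#' countFrequencies(aln)$counts
#' @export
countFrequencies <- function(rows) {
  m <- if (is.matrix(rows)) rows else alnMatrix(rows)
  if (nrow(m) == 0L) stop("no rows to count")
  cnt <- nucCountMatrix(m)
  storage.mode(cnt) <- "integer"
  list(counts = cnt, nValid = as.integer(colSums(cnt)))
}

#' Subgroup midpoint
#'
#' The target size of a balanced split of a subgroup of \code{n} sequences:
#' \code{floor(n / 2)}.
#'
#' @param n subgroup size (>= 1).
#' @return \code{floor(n/2)} as an integer.
#' @examples
#' midValue(8)  # 4
#' @export
midValue <- function(n) {
  if (any(n < 1L)) stop("subgroup size must be >= 1")
  as.integer(n %/% 2L)
}

#' Column balance deviation
#'
#' For a column's allele counts, the smallest absolute deviation of any
#' observed allele count from the subgroup midpoint: a value of 0 means some
#' allele splits the subgroup exactly in half.
#'
#' Only observed nucleotides (count > 0) enter the minimum; absent
#' nucleotides would contribute a spurious \code{|mid - 0|}.
#'
#' @param counts named numeric vector of allele counts (names among A,C,G,T),
#'   or a length-4 vector in A,C,G,T order.
#' @param mid the subgroup midpoint from \code{\link{midValue}}.
#' @return The minimum \code{|mid - f|} over observed alleles, as an integer.
#' @examples
#' diffValue(c(C = 4, T = 4), mid = 4)         # 0
#' diffValue(c(A = 6, C = 1, G = 1), mid = 4)  # 2
#' @export
diffValue <- function(counts, mid) {
  f <- counts[counts > 0]
  if (length(f) == 0L)
    stop("degenerate column: no A/C/G/T characters observed")
  as.integer(min(abs(mid - f)))
}

#' Allele-multiplicity weight
#'
#' The bonus term of the column score, favouring biallelic columns:
#' 0, 1, 0.66 and 0.33 for 1, 2, 3 and 4 distinct nucleotide types.
#'
#' @param nTypes number of distinct nucleotides observed (1..4).
#' @return The weight as a numeric scalar.
#' @examples
#' weightValue(2)  # 1
#' weightValue(3)  # 0.66
#' @export
weightValue <- function(nTypes) {
  if (any(nTypes < 1L | nTypes > 4L))
    stop("nTypes must be in 1..4")
  TYPE_WEIGHTS[nTypes]
}

#' Score a single column for a subgroup
#'
#' The balanced-split score \code{(mid - diff) / mid + weight}: highest
#' (2.0 for even subgroup sizes) for a biallelic column with equal allele
#' counts, positive for every polymorphic column, and <= 0 for monomorphic
#' columns.
#'
#' @param counts allele counts as in \code{\link{diffValue}}.
#' @param n subgroup size (>= 2 — a single sequence needs no split).
#' @param position optional 1-based column index recorded in the result.
#' @return A one-row data.frame with columns \code{position}, \code{n_types},
#'   \code{mid}, \code{diff}, \code{weight}, \code{score}.
#' @examples
#' scoreColumn(c(C = 4, T = 4), n = 8)$score         # 2
#' scoreColumn(c(A = 6, C = 1, G = 1), n = 8)$score  # 1.16
#' @export
scoreColumn <- function(counts, n, position = NA_integer_) {
  if (n < 2L) stop("subgroup size must be >= 2 to score a split")
  mid <- midValue(n)
  nTypes <- sum(counts > 0)
  d <- diffValue(counts, mid)
  w <- weightValue(nTypes)
  data.frame(position = as.integer(position), n_types = as.integer(nTypes),
             mid = mid, diff = d, weight = w, score = (mid - d) / mid + w)
}

#' Score every column of a subgroup
#'
#' Vectorised evaluation of \code{\link{scoreColumn}} across all columns.
#' Columns in which the subgroup shows no A/C/G/T character at all (gaps or
#' ambiguity codes only) are unsplittable and receive score \code{-Inf}
#' (with \code{diff} NA) rather than an error.
#'
#' @param rows a \linkS4class{BarcodeAlignment} or character matrix
#'   (subgroup of rows).
#' @return A data.frame with one row per column: \code{position},
#'   \code{n_types}, \code{mid}, \code{diff}, \code{weight}, \code{score},
#'   positions ascending.
#' @examples
#' aln <- BarcodeAlignment(c(a = "AC", b = "AT"))
#' scoreAllColumns(aln)
#' @export
scoreAllColumns <- function(rows) {
  m <- if (is.matrix(rows)) rows else alnMatrix(rows)
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 rows to score columns")
  cnt <- nucCountMatrix(m)
  mid <- midValue(n)
  nTypes <- as.integer(colSums(cnt > 0L))
  dev <- abs(mid - cnt)
  dev[cnt == 0L] <- NA_real_
  d <- suppressWarnings(apply(dev, 2L, min, na.rm = TRUE))  # Inf when no obs
  w <- ifelse(nTypes >= 1L, TYPE_WEIGHTS[pmax(nTypes, 1L)], 0)
  score <- ifelse(is.finite(d), (mid - d) / mid + w, -Inf)
  data.frame(position = seq_len(ncol(m)), n_types = nTypes, mid = mid,
             diff = as.integer(ifelse(is.finite(d), d, NA)),
             weight = ifelse(nTypes >= 1L, w, 0), score = score)
}

#' Write a column score table as TSV
#'
#' @param scores a data.frame from \code{\link{scoreAllColumns}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeScores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
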