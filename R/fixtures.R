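## run expr under a local RNG state so generators never disturb the caller's
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Balanced binary-code alignment
#'
#' Generates \code{2^k} species whose identities are encoded by \code{k}
#' biallelic columns with exactly balanced allele counts: column \code{j}
#' carries bit \code{j} of the species index, so every code column splits
#' the full set (and every subset reached by splitting on other code
#' columns) exactly in half. All remaining columns are monomorphic filler.
#' Column order is shuffled by \code{seed}. This is the ideal input for the
#' balanced-split strategy: the decision tree must have depth \code{k},
#' select exactly the \code{k} code columns, and produce tags equal to the
#' planted codes.
#'
#' @param k number of code bits (1..10).
#' @param seed RNG seed; identical seeds give identical alignments.
#' @param nColumns total alignment width (default \code{max(13, 2k)}).
#' @return A \linkS4class{BarcodeAlignment}; \code{metadata()$planted} holds
#'   the code column positions (ascending) and the expected per-species
#'   codes.
#' @examples
#' aln <- makeBalancedCodeAlignment(k = 3, seed = 7)
#' length(snpColumns(aln))  # 3
#' @export
makeBalancedCodeAlignment <- function(k, seed = 1L,
                                      nColumns = max(13L, 2L * k)) {
  if (k < 1L || k > 10L) stop("k must be in 1..10")
  if (nColumns < k) stop("nColumns must be >= k")
  n <- 2L^k
  withSeed(seed, {
    cols <- matrix("", nrow = n, ncol = nColumns)
    codeCols <- sort(sample.int(nColumns, k))
    alleles <- lapply(seq_len(k), function(j) sample(NUCS, 2L))
    idx <- 0:(n - 1L)
    for (j in seq_len(k)) {
      bit <- bitwAnd(idx %/% 2L^(j - 1L), 1L)
      cols[, codeCols[j]] <- alleles[[j]][bit + 1L]
    }
    filler <- sample(NUCS, nColumns, replace = TRUE)
    for (p in setdiff(seq_len(nColumns), codeCols))
      cols[, p] <- filler[p]
    ids <- sprintf("sp%0*d", nchar(n), seq_len(n))
    aln <- BarcodeAlignment(stats::setNames(apply(cols, 1L, paste,
                                                  collapse = ""), ids))
    codes <- apply(cols[, codeCols, drop = FALSE], 1L, paste, collapse = "")
    metadata(aln)$planted <- list(columns = codeCols,
                                  codes = stats::setNames(codes, ids))
    aln
  })
}

#' Eight-species worked example
#'
#' A fixed 8 species x 13 column alignment constructed to exhibit the
#' canonical behaviour of the balanced-split scoring rule: position 1 is a
#' perfectly balanced biallelic column (counts C:4, T:4; score 2.0),
#' position 8 is triallelic (counts A:6, C:1, G:1; score 1.16), and the
#' decision tree selects positions \{1, 2, 3, 4, 7\}, with positions 3 and 4
#' each used at two nodes. Frozen — not generated — so tests can assert its
#' exact quantities.
#'
#' @return A \linkS4class{BarcodeAlignment} (8 x 13).
#' @examples
#' aln <- makeWorkedExampleAlignment()
#' scoreAllColumns(aln)$score[1]  # 2
#' @export
makeWorkedExampleAlignment <- function() {
  BarcodeAlignment(c(
    S1 = "CAAAGTCCACGTA",
    S2 = "CCAAGTCAACGTA",
    S3 = "CCGAGTCAACGTA",
    S4 = "CCGCGTCAACGTA",
    S5 = "TCAGGTAAACGTA",
    S6 = "TCCGGTAAACGTA",
    S7 = "TCATGTAAACGTA",
    S8 = "TCATGTGGACGTA"
  ))
}

#' Random alignment with planted allele-count columns
#'
#' Builds a reproducible alignment in which specified columns carry exact
#' allele counts (e.g. \code{c(C = 3, T = 3, A = 2)} for 8 species) with a
#' seed-shuffled row assignment, and all other columns are monomorphic
#' filler. Used to exercise scoring and splitting on controlled
#' mono-/bi-/tri-/quadallelic structure.
#'
#' @param nSpecies number of rows.
#' @param nColumns number of columns.
#' @param planted named list mapping column position (as character or via
#'   \code{position} entries) to a named allele-count vector summing to
#'   \code{nSpecies}; e.g. \code{list(`3` = c(C = 3, T = 3, A = 2))}.
#' @param seed RNG seed.
#' @return A \linkS4class{BarcodeAlignment}; \code{metadata()$planted}
#'   records the planted columns.
#' @examples
#' aln <- makeRandomAlignment(8, 10, list(`4` = c(C = 3, T = 3, A = 2)),
#'                            seed = 2)
#' countFrequencies(aln)$counts[, 4]
#' @export
makeRandomAlignment <- function(nSpecies, nColumns, planted = list(),
                                seed = 1L) {
  pos <- as.integer(names(planted))
  if (anyNA(pos) || anyDuplicated(pos) || any(pos < 1L | pos > nColumns))
    stop("planted positions must be distinct integers in 1..nColumns")
  for (p in names(planted)) {
    cts <- planted[[p]]
    if (is.null(names(cts)) || !all(names(cts) %in% NUCS))
      stop("planted counts must be named with nucleotides A/C/G/T")
    if (sum(cts) != nSpecies)
      stop(sprintf("planted counts at column %s sum to %d, need %d",
                   p, sum(cts), nSpecies))
  }
  withSeed(seed, {
    m <- matrix("", nrow = nSpecies, ncol = nColumns)
    filler <- sample(NUCS, nColumns, replace = TRUE)
    for (j in seq_len(nColumns)) m[, j] <- filler[j]
    for (p in names(planted)) {
      cts <- planted[[p]]
      m[, as.integer(p)] <- sample(rep(names(cts), times = cts))
    }
    ids <- sprintf("sp%0*d", nchar(nSpecies), seq_len(nSpecies))
    aln <- BarcodeAlignment(stats::setNames(apply(m, 1L, paste,
                                                  collapse = ""), ids))
    metadata(aln)$planted <- planted
    aln
  })
}
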