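# Independent brute-force oracle for split selection: direct, loop-based
# evaluation of the scoring definitions, no shared code with the package.
bruteForceSplit <- function(m) {
  n <- nrow(m)
  mid <- floor(n / 2)
  nucs <- c("A", "C", "G", "T")
  best <- list(score = -Inf, position = NA_integer_, up = NA_character_)
  for (p in seq_len(ncol(m))) {
    f <- sapply(nucs, function(b) sum(m[, p] == b))
    obs <- nucs[f > 0]
    if (length(obs) == 0) next
    devs <- sapply(obs, function(b) abs(mid - f[[b]]))
    d <- min(devs)
    nt <- length(obs)
    w <- if (nt == 1) 0 else if (nt == 2) 1 else if (nt == 3) 0.66 else 0.33
    s <- (mid - d) / mid + w
    if (s > best$score) {  # strict: lowest position wins ties
      best <- list(score = s, position = p,
                   up = obs[which(devs == d)[1]])  # obs already A<C<G<T
    }
  }
  best
}

# fully random ACGT matrix guaranteed to have >= 1 polymorphic column and
# pairwise-distinct rows are NOT required (callers handle degenerate errors)
randomAcgtMatrix <- function(n, m) {
  x <- matrix(sample(c("A", "C", "G", "T"), n * m, replace = TRUE),
              nrow = n,
              dimnames = list(sprintf("r%02d", seq_len(n)), NULL))
  x
}

asAln <- function(m) {
  BarcodeAlignment(stats::setNames(apply(m, 1, paste, collapse = ""),
                                   rownames(m)))
}

# multiset of positions used by internal nodes (one entry per node)
nodePositions <- function(tree) {
  out <- integer()
  walk <- function(node) {
    if (node$type == "node") {
      out <<- c(out, node$position)
      walk(node$children[[1]]); walk(node$children[[2]])
    }
  }
  walk(tree@root)
  out
}
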