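# Shared fixture builders and independent oracles. Oracles here are kept
# deliberately naive (brute-force scans, direct formulas) so they stay
# independent of the package's implementation paths.

# a raw library from parallel vectors of tag strings and copy numbers
makeRawLibrary <- function(tags, counts, id = "test") {
  new("RawTagLibrary", libraryId = id,
      records = data.frame(tag = tags, count = as.integer(counts),
                           stringsAsFactors = FALSE))
}

# a clean table directly from a named count vector (validity enforced)
makeCleanTable <- function(counts, id = "test") {
  new("CleanTagTable", libraryId = id, counts = as.integer(counts) |>
        stats::setNames(names(counts)))
}

# random CATG-anchored 21-nt tags
randomTags <- function(n, seed) {
  set.seed(seed)
  body <- matrix(sample(c("A", "C", "G", "T"), 17L * n, replace = TRUE),
                 nrow = n)
  paste0("CATG", do.call(paste0, as.data.frame(body)))
}

# brute-force scan of every CATG+17-nt window of a sequence, 3' to 5'
bruteVirtualTags <- function(s) {
  L <- nchar(s)
  starts <- which(vapply(seq_len(max(0L, L - 3L)),
                         function(i) substr(s, i, i + 3L) == "CATG", TRUE))
  starts <- starts[starts + 20L <= L]
  if (!length(starts)) return(character())
  tags <- substring(s, starts, starts + 20L)
  rev(tags[!grepl("N", tags)])  # never reached for ACGT input; keeps parity
}

# brute-force mapping oracle: anchored Hamming distance (CATG must match
# exactly, mismatches counted over the 17-nt variable region), exact hits
# preferred, ambiguity judged within the best distance stratum, genome as
# fallback within distance 1
bruteMapOracle <- function(queries, index) {
  tags <- indexTags(index)
  geneIds <- index@geneIds
  toMat <- function(v) vapply(v, function(t) as.integer(utf8ToInt(substr(t, 5L, 21L))),
                              integer(17L))
  M <- if (length(tags)) toMat(tags) else matrix(integer(), 17L, 0L)
  G <- if (length(index@genomeKmers)) {
    gk <- index@genomeKmers
    gk <- gk[substr(gk, 1L, 4L) == "CATG"]
    list(kmers = gk, mat = toMat(gk))
  } else NULL
  vapply(queries, function(q) {
    qv <- as.integer(utf8ToInt(substr(q, 5L, 21L)))
    if (length(tags)) {
      d <- colSums(M != qv)
      dmin <- min(d)
      if (dmin <= 1) {
        owners <- unique(unlist(geneIds[d == dmin], use.names = FALSE))
        return(if (length(owners) == 1L) "gene_unambiguous" else "gene_ambiguous")
      }
    }
    if (!is.null(G) && length(G$kmers)) {
      dg <- colSums(G$mat != qv)
      if (min(dg) <= 1) return("genome")
    }
    "unknown"
  }, "")
}

# direct Benjamini-Hochberg step-up, written from the definition
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# exhaustive hypergeometric upper tail by enumerating all n-subsets of 1..N,
# with the term taken as the first M elements
enumHyperUpper <- function(N, n, M, m) {
  if (n == 0L) return(if (m == 0L) 1 else NA_real_)
  subsets <- utils::combn(N, n)
  overlap <- colSums(subsets <= M)
  mean(overlap >= m)
}

# qPCR cycle-threshold fixture table
ctTable <- function(target, ref) data.frame(ctTarget = target, ctReference = ref)

# a tiny deterministic two-library simulated experiment used across tests
smallSim <- function(seed = 11, nGenes = 200L, depth = 50000L,
                     nLibraries = 2L, errorRate = 0, adaptorOnlyRate = 0,
                     nTagRate = 0, deFraction = 0.1, deFoldChange = 4) {
  simulateDGEExperiment(simConfig(
    nGenes = nGenes, depth = depth, nLibraries = nLibraries,
    errorRate = errorRate, adaptorOnlyRate = adaptorOnlyRate,
    nTagRate = nTagRate, deFraction = deFraction,
    deFoldChange = deFoldChange, seed = seed))
}
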