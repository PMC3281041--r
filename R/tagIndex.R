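# Virtual tag reference: enumeration of every CATG+17-nt tag a transcript
# can produce, and the merged index with one-mismatch lookup.

#' Extract all virtual CATG+17-nt tags of one transcript
#'
#' One tag per CATG occurrence with at least 17 nt downstream. The reference
#' enumerates every site (not only the 3'-most) so that tags from internal
#' sites or incomplete digestion still find their gene. Tags are returned
#' 3' to 5' with \code{site_rank} 1 for the 3'-most site; 21-nt windows
#' containing an N are skipped.
#'
#' @param geneId gene identifier.
#' @param sequence nucleotide string over \code{A,C,G,T,N}.
#' @return data.frame with columns \code{tag}, \code{gene_id},
#'   \code{site_rank}; zero rows (not an error) when the sequence has no
#'   usable site or is empty.
#' @export
#' @examples
#' extractVirtualTags("g1", paste0("AA", "CATG", "ACGTACGTACGTACGTA", "CC"))
extractVirtualTags <- function(geneId, sequence) {
  stopifnot(length(sequence) == 1L, length(geneId) == 1L)
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L)
    return(data.frame(tag = character(), gene_id = character(),
                      site_rank = integer(), stringsAsFactors = FALSE))
  if (grepl("[^ACGTN]", sequence))
    stop("sequence must be over {A,C,G,T,N}")
  pos <- gregexpr("CATG", sequence, fixed = TRUE)[[1L]]
  pos <- pos[pos > 0L & pos + 20L <= nchar(sequence)]
  if (!length(pos))
    return(data.frame(tag = character(), gene_id = character(),
                      site_rank = integer(), stringsAsFactors = FALSE))
  pos <- sort(pos, decreasing = TRUE)  # 3'-most first
  tags <- substring(sequence, pos, pos + 20L)
  keep <- !grepl("N", tags, fixed = TRUE)
  tags <- tags[keep]
  data.frame(tag = tags, gene_id = rep.int(geneId, length(tags)),
             site_rank = seq_along(tags), stringsAsFactors = FALSE)
}

#' Build the virtual tag index
#'
#' Enumerates every virtual tag of every reference gene and merges tags
#' identical in sequence across genes into single entries flagged
#' \code{ambiguous}. The stored \code{siteRank} is the smallest rank over
#' the owning genes. An optional genome 21-mer set is attached as a secondary
#' reference for the mapping precedence gene > genome > unknown.
#'
#' @param genes named [Biostrings::DNAStringSet] or named character vector of
#'   transcript sequences.
#' @param genomeKmers optional character vector of genome-derived 21-mers
#'   (see [genomeTagKmers()]).
#' @return a [VirtualTagIndex-class].
#' @export
buildTagIndex <- function(genes, genomeKmers = character()) {
  seqs <- .asNamedSeqs(genes)
  ids <- names(seqs)
  if (is.null(ids) || length(seqs) < 1L)
    stop("'genes' must be a nonempty named sequence set")
  perGene <- lapply(seq_along(seqs), function(i) extractVirtualTags(ids[i], seqs[i]))
  all <- do.call(rbind, perGene)
  if (is.null(all) || nrow(all) == 0L) {
    return(new("VirtualTagIndex", tags = character(), geneIds = list(),
               siteRank = integer(), ambiguous = logical(),
               genomeKmers = as.character(genomeKmers)))
  }
  grp <- factor(all$tag, levels = unique(all$tag))
  geneIds <- lapply(split(all$gene_id, grp), unique)
  siteRank <- vapply(split(all$site_rank, grp), min, 0L)
  tags <- levels(grp)
  new("VirtualTagIndex",
      tags = tags,
      geneIds = unname(geneIds),
      siteRank = as.integer(unname(siteRank)),
      ambiguous = unname(lengths(geneIds) > 1L),
      genomeKmers = unique(as.character(genomeKmers)))
}

#' Enumerate all 21-mers of a genome reference
#'
#' Sliding-window 21-mers of every sequence (windows containing N are
#' dropped). Intended for desk-scale secondary references; full genome
#' alignment is out of scope for tag mapping.
#'
#' @param genome DNAStringSet or character vector of genomic sequences.
#' @return character vector of unique 21-mers.
#' @export
genomeTagKmers <- function(genome) {
  seqs <- as.character(genome)
  out <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < 21L) return(character())
    substring(s, seq_len(L - 20L), seq_len(L - 20L) + 20L)
  }), use.names = FALSE)
  out <- unique(out)
  out[!grepl("N", out, fixed = TRUE)]
}

# All Hamming-distance-1 neighbours of each tag over the 17-nt variable
# region (51 variants per tag; the CATG anchor is enzymatically defined and
# never varied). Returns data.frame(query = index into 'tags', variant).
.tagNeighborhood <- function(tags) {
  n <- length(tags)
  if (!n) return(data.frame(query = integer(), variant = character()))
  qs <- vector("list", 17L * 4L)
  k <- 0L
  for (p in 5:21) {
    cur <- substr(tags, p, p)
    left <- substr(tags, 1L, p - 1L)
    right <- substr(tags, p + 1L, 21L)
    for (b in .DNA_BASES) {
      k <- k + 1L
      keep <- which(cur != b)
      qs[[k]] <- if (length(keep))
        data.frame(query = keep,
                   variant = paste0(left[keep], b, right[keep]),
                   stringsAsFactors = FALSE)
      else data.frame(query = integer(), variant = character())
    }
  }
  do.call(rbind, qs)
}
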