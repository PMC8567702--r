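#' Candidate PAV segments from one-to-one alignment blocks
#'
#' Candidates are the maximal intervals of each genome not covered by any
#' alignment block on that genome (interval complement), with intervals
#' shorter than `minLength` dropped.  Intervals are 0-based half-open.
#'
#' @param blocks data.frame of one-to-one alignment blocks with columns
#'   `chr_a`, `start_a`, `end_a`, `chr_b`, `start_b`, `end_b` (0-based
#'   half-open), as produced by a whole-genome aligner or
#'   [simulatePavPair()].
#' @param genomeLengths List with named length vectors `a` and `b`.
#' @param minLength Minimum candidate length in bp (default 100).
#' @return data.frame of candidate segments: `genome` ("a"/"b"), `chrom`,
#'   `start`, `end`, `status` ("candidate"), `residual_coverage` (NA).
#' @importFrom IRanges IRanges reduce setdiff start end width
#' @export
pavCandidates <- function(blocks, genomeLengths, minLength = 100L) {
  out <- NULL
  for (side in c("a", "b")) {
    lens <- genomeLengths[[side]]
    st <- blocks[[paste0("start_", side)]]
    en <- blocks[[paste0("end_", side)]]
    ch <- blocks[[paste0("chr_", side)]]
    if (any(st < 0 | en > lens[ch])) {
      stop("alignment block interval out of genome bounds")
    }
    for (chrom in names(lens)) {
      sel <- ch == chrom
      covered <- IRanges::reduce(IRanges::IRanges(st[sel] + 1L, en[sel]))
      gaps <- IRanges::gaps(covered, start = 1L, end = lens[[chrom]])
      gaps <- gaps[IRanges::width(gaps) >= minLength]
      if (length(gaps)) {
        out <- rbind(out, data.frame(
          genome = side, chrom = chrom,
          start = IRanges::start(gaps) - 1L, end = IRanges::end(gaps),
          status = "candidate", residual_coverage = NA_real_,
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(genome = character(), chrom = character(),
                      start = integer(), end = integer(),
                      status = character(), residual_coverage = numeric(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Validate candidate PAV segments against the other genome
#'
#' Re-searches each candidate's sequence against the other genome with an
#' exact-match k-mer seed (k = 31) scan: the fraction of candidate bases
#' covered by a k-mer also present in the other genome is the residual
#' coverage.  Candidates with residual coverage strictly greater than
#' `coverageThreshold` are rejected (they are present in both genomes
#' after all); the remainder are retained.  A candidate at exactly the
#' threshold is retained (strict `>` rule).
#'
#' @param candidates data.frame from [pavCandidates()].
#' @param genomeA,genomeB [AnnotatedGenome-class] objects carrying full
#'   chromosome sequences.
#' @param coverageThreshold Rejection threshold (default 0.8).
#' @param k Seed length (default 31).
#' @return The candidates with `residual_coverage` filled and `status`
#'   set to "retained" or "rejected".
#' @importFrom Biostrings DNAString DNAStringSet PDict countPDict
#' @export
validatePavs <- function(candidates, genomeA, genomeB,
                         coverageThreshold = 0.8, k = 31L) {
  if (!nrow(candidates)) return(candidates)
  seqs <- list(a = genomeA@sequence, b = genomeB@sequence)
  subjects <- list(
    a = Biostrings::DNAString(paste(seqs$a, collapse = "")),
    b = Biostrings::DNAString(paste(seqs$b, collapse = "")))
  for (i in seq_len(nrow(candidates))) {
    side <- candidates$genome[i]
    other <- if (side == "a") "b" else "a"
    cand <- substr(seqs[[side]][[candidates$chrom[i]]],
                   candidates$start[i] + 1L, candidates$end[i])
    n <- nchar(cand)
    if (n < k) {
      candidates$residual_coverage[i] <- 0
      candidates$status[i] <- "retained"
      next
    }
    starts <- seq_len(n - k + 1L)
    kmerStr <- vapply(starts, function(s) substr(cand, s, s + k - 1L),
                      character(1))
    uniq <- unique(kmerStr)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(uniq))
    counts <- Biostrings::countPDict(pd, subjects[[other]])
    present <- uniq[counts > 0L]
    hitStarts <- starts[kmerStr %in% present]
    cov <- logical(n)
    for (s in hitStarts) cov[s:(s + k - 1L)] <- TRUE
    rc <- mean(cov)
    candidates$residual_coverage[i] <- rc
    candidates$status[i] <- if (rc > coverageThreshold) "rejected"
                            else "retained"
  }
  candidates
}

#' PAV-related genes
#'
#' A gene qualifies as PAV-related when the fraction of its length
#' overlapped by the union of retained PAV segments is strictly greater
#' than `overlapThreshold`.
#'
#' @param retained data.frame of PAV segments (rows with
#'   `status == "retained"` are used).
#' @param genome The [AnnotatedGenome-class] the segments refer to.
#' @param overlapThreshold Overlap fraction threshold (default 0.8,
#'   strict `>`).
#' @return data.frame with `gene_id` and `overlap_fraction` for
#'   qualifying genes.
#' @importFrom IRanges IRanges reduce findOverlaps pintersect
#' @export
pavGenes <- function(retained, genome, overlapThreshold = 0.8) {
  segs <- retained[retained$status == "retained", , drop = FALSE]
  g <- genome@genes
  out <- data.frame(gene_id = character(), overlap_fraction = numeric(),
                    stringsAsFactors = FALSE)
  for (chrom in unique(g$chromosome_id)) {
    gg <- g[g$chromosome_id == chrom, ]
    ss <- segs[segs$chrom == chrom, ]
    if (!nrow(ss) || !nrow(gg)) next
    segR <- IRanges::reduce(IRanges::IRanges(ss$start + 1L, ss$end))
    geneR <- IRanges::IRanges(gg$start + 1L, gg$end)
    ov <- IRanges::findOverlaps(geneR, segR)
    if (!length(ov)) next
    inter <- IRanges::width(IRanges::pintersect(
      geneR[S4Vectors::queryHits(ov)], segR[S4Vectors::subjectHits(ov)]))
    byGene <- tapply(inter, S4Vectors::queryHits(ov), sum)
    frac <- as.numeric(byGene) /
      IRanges::width(geneR)[as.integer(names(byGene))]
    sel <- frac > overlapThreshold
    if (any(sel)) {
      out <- rbind(out, data.frame(
        gene_id = gg$gene_id[as.integer(names(byGene))[sel]],
        overlap_fraction = frac[sel], stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Summarise a PAV comparison
#'
#' @param retained PAV segment table (all statuses).
#' @param genes PAV gene table from [pavGenes()] (may combine genomes).
#' @return List of counts and total lengths per genome plus overall
#'   totals.
#' @export
pavSummary <- function(retained, genes = NULL) {
  ret <- retained[retained$status == "retained", , drop = FALSE]
  perGenome <- lapply(split(ret, ret$genome), function(d) {
    list(n_segments = nrow(d), total_bp = sum(d$end - d$start))
  })
  list(per_genome = perGenome,
       n_segments = nrow(ret),
       total_bp = sum(ret$end - ret$start),
       n_candidates = nrow(retained),
       n_rejected = sum(retained$status == "rejected"),
       n_pav_genes = if (is.null(genes)) NA_integer_ else nrow(genes))
}
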