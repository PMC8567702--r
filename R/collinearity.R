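#' Resolve homology records into anchor pairs
#'
#' Annotates each retained homology record with the chromosomes and
#' ordinals of its two genes.  Records whose gene ids cannot be resolved
#' in the respective genome are skipped with a warning.  For a
#' self-comparison (`genomeA` and `genomeB` the same genome) the trivial
#' pair (g, g) is excluded and each pair is kept once, oriented so that
#' (chr_a, ord_a) precedes (chr_b, ord_b).  Tandem arrays (consecutive
#' same-family genes within a window of `tandemWindow` ordinals) are
#' collapsed to their first member before anchoring, preventing spurious
#' self-diagonal blocks.
#'
#' @param genomeA,genomeB [AnnotatedGenome-class] objects (may be
#'   identical for a self-comparison).
#' @param homology data.frame as from [readHomologyTable()].
#' @param tandemWindow Tandem collapse window in ordinals (default 5).
#' @return data.frame of anchors: `gene_a`, `gene_b`, `chr_a`, `chr_b`,
#'   `ord_a`, `ord_b`, `score`.
#' @export
findAnchorPairs <- function(genomeA, genomeB, homology,
                            tandemWindow = 5L) {
  idxA <- .anchorIndex(genomeA, tandemWindow)
  selfCmp <- identical(genomeA, genomeB)
  idxB <- if (selfCmp) idxA else .anchorIndex(genomeB, tandemWindow)

  h <- homology
  if (!selfCmp) {
    # accept records written in either orientation
    inAB <- h$gene_a %in% rownames(idxA) & h$gene_b %in% rownames(idxB)
    inBA <- h$gene_a %in% rownames(idxB) & h$gene_b %in% rownames(idxA) &
      !inAB
    flipped <- h[inBA, ]
    names(flipped)[1:2] <- c("gene_b", "gene_a")
    h <- rbind(h[inAB, ], flipped[, names(h)])
    nUnresolved <- sum(!(homology$gene_a %in% geneTable(genomeA)$gene_id &
                           homology$gene_b %in% geneTable(genomeB)$gene_id) &
                         !(homology$gene_a %in% geneTable(genomeB)$gene_id &
                             homology$gene_b %in% geneTable(genomeA)$gene_id))
  } else {
    keep <- h$gene_a %in% rownames(idxA) & h$gene_b %in% rownames(idxA) &
      h$gene_a != h$gene_b
    nUnresolved <- sum(!(homology$gene_a %in% geneTable(genomeA)$gene_id &
                           homology$gene_b %in% geneTable(genomeA)$gene_id))
    h <- h[keep, ]
  }
  if (nUnresolved > 0L) {
    warning(nUnresolved,
            " homology record(s) skipped (unresolvable gene id)")
  }
  if (!nrow(h)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      chr_a = character(), chr_b = character(),
                      ord_a = integer(), ord_b = integer(),
                      score = numeric()))
  }
  out <- data.frame(
    gene_a = h$gene_a, gene_b = h$gene_b,
    chr_a = idxA[h$gene_a, "chromosome_id"],
    chr_b = idxB[h$gene_b, "chromosome_id"],
    ord_a = idxA[h$gene_a, "ordinal"],
    ord_b = idxB[h$gene_b, "ordinal"],
    score = ifelse(is.na(h$score), 1, h$score),
    stringsAsFactors = FALSE)
  if (selfCmp) {
    swap <- out$chr_b < out$chr_a |
      (out$chr_b == out$chr_a & out$ord_b < out$ord_a)
    out[swap, c("gene_a", "gene_b", "chr_a", "chr_b", "ord_a", "ord_b")] <-
      out[swap, c("gene_b", "gene_a", "chr_b", "chr_a", "ord_b", "ord_a")]
    out <- out[!duplicated(paste(out$gene_a, out$gene_b)), ]
  }
  rownames(out) <- NULL
  out
}

# gene -> (chromosome, ordinal) with tandem representatives only
.anchorIndex <- function(genome, tandemWindow) {
  g <- genome@genes[order(genome@genes$chromosome_id,
                          genome@genes$ordinal), ]
  drop <- logical(nrow(g))
  lastSeen <- list()
  prevChr <- ""
  for (i in seq_len(nrow(g))) {
    if (g$chromosome_id[i] != prevChr) {
      lastSeen <- list()
      prevChr <- g$chromosome_id[i]
    }
    fam <- g$family_id[i]
    prev <- lastSeen[[fam]]
    if (!is.null(prev) && g$ordinal[i] - prev <= tandemWindow) {
      drop[i] <- TRUE       # tandem duplicate of a recent same-family gene
    } else {
      lastSeen[[fam]] <- g$ordinal[i]
    }
  }
  idx <- g[!drop, c("gene_id", "chromosome_id", "ordinal")]
  rownames(idx) <- idx$gene_id
  idx
}

#' Chain anchor pairs into collinear blocks
#'
#' Weighted longest-increasing-subsequence chaining per chromosome pair
#' and orientation: the best-scoring monotone chain (ordinals strictly
#' increasing in genome A, strictly increasing or decreasing in genome B,
#' consecutive-anchor ordinal gaps of at most `maxGap` intervening genes
#' on both genomes) is extracted, its anchors removed, and the process
#' repeated until no chain of at least `minAnchors` anchors remains.
#' Equal-score ties prefer the chain with the smaller genome-A start
#' ordinal, then the smaller genome-B start.  Output blocks are sorted by
#' (chr_a, chr_b, start ordinal).
#'
#' @param anchors data.frame from [findAnchorPairs()].
#' @param maxGap Maximum intervening/non-collinear genes between
#'   consecutive anchors (default 50).
#' @param minAnchors Minimum anchors per block (default 5).
#' @param genomeAName,genomeBName Genome names recorded in the block
#'   table.
#' @return A [CollinearBlockSet-class].
#' @export
chainAnchors <- function(anchors, maxGap = 50L, minAnchors = 5L,
                         genomeAName = "A", genomeBName = "B") {
  emptyBlocks <- data.frame(
    block_id = character(), genome_a = character(),
    genome_b = character(), chr_a = character(), chr_b = character(),
    orientation = character(), n_anchors = integer(),
    median_ks = numeric(), event_layer = character(),
    stringsAsFactors = FALSE)
  emptyAnchors <- data.frame(
    block_id = character(), gene_a = character(), gene_b = character(),
    chr_a = character(), chr_b = character(), ord_a = integer(),
    ord_b = integer(), score = numeric(), ks = numeric(),
    stringsAsFactors = FALSE)
  if (is.null(anchors) || !nrow(anchors)) {
    return(CollinearBlockSet(emptyBlocks, emptyAnchors))
  }
  outBlocks <- list()
  outAnchors <- list()
  for (key in sort(unique(paste(anchors$chr_a, anchors$chr_b,
                                sep = "\r")))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- anchors[anchors$chr_a == parts[1] & anchors$chr_b == parts[2], ]
    repeat {
      best <- NULL
      for (orient in c("parallel", "antiparallel")) {
        ch <- .bestChain(sub, orient, maxGap)
        if (is.null(ch)) next
        if (is.null(best) || ch$score > best$score ||
            (ch$score == best$score &&
             (ch$startA < best$startA ||
              (ch$startA == best$startA && ch$startB < best$startB)))) {
          best <- ch
          best$orientation <- orient
        }
      }
      if (is.null(best) || length(best$rows) < minAnchors) break
      blk <- sub[best$rows, ]
      outBlocks[[length(outBlocks) + 1L]] <- data.frame(
        chr_a = parts[1], chr_b = parts[2],
        orientation = best$orientation, n_anchors = nrow(blk),
        start_a = min(blk$ord_a), start_b = min(blk$ord_b),
        stringsAsFactors = FALSE)
      outAnchors[[length(outBlocks)]] <- blk
      sub <- sub[-best$rows, , drop = FALSE]
      if (!nrow(sub)) break
    }
  }
  if (!length(outBlocks)) {
    return(CollinearBlockSet(emptyBlocks, emptyAnchors))
  }
  blocks <- do.call(rbind, outBlocks)
  ord <- order(blocks$chr_a, blocks$chr_b, blocks$start_a, blocks$start_b)
  blocks <- blocks[ord, ]
  outAnchors <- outAnchors[ord]
  blocks$block_id <- sprintf("blk%04d", seq_len(nrow(blocks)))
  blocks$genome_a <- genomeAName
  blocks$genome_b <- genomeBName
  blocks$median_ks <- NA_real_
  blocks$event_layer <- NA_character_
  anchorsOut <- do.call(rbind, lapply(seq_along(outAnchors), function(i) {
    a <- outAnchors[[i]]
    a <- a[order(a$ord_a), ]
    data.frame(block_id = blocks$block_id[i], gene_a = a$gene_a,
               gene_b = a$gene_b, chr_a = a$chr_a, chr_b = a$chr_b,
               ord_a = a$ord_a, ord_b = a$ord_b, score = a$score,
               ks = NA_real_, stringsAsFactors = FALSE)
  }))
  CollinearBlockSet(
    blocks[, c("block_id", "genome_a", "genome_b", "chr_a", "chr_b",
               "orientation", "n_anchors", "median_ks", "event_layer")],
    anchorsOut)
}

# Best weighted monotone chain within one chromosome pair and orientation.
# Returns row indices (relative to `sub`), total score, and the start
# ordinals used for tie-breaking.
.bestChain <- function(sub, orient, maxGap) {
  n <- nrow(sub)
  if (!n) return(NULL)
  oa <- sub$ord_a
  ob <- if (orient == "parallel") sub$ord_b else -sub$ord_b
  sc <- sub$score
  o <- order(oa, ob)
  oa <- oa[o]; ob <- ob[o]; sc <- sc[o]
  f <- sc
  pred <- rep(0L, n)
  startA <- oa
  startB <- ob
  lim <- maxGap + 1L
  for (i in seq_len(n)) {
    if (i == 1L) next
    for (j in seq_len(i - 1L)) {
      if (oa[j] >= oa[i] || ob[j] >= ob[i]) next
      if (oa[i] - oa[j] > lim || ob[i] - ob[j] > lim) next
      cand <- f[j] + sc[i]
      better <- cand > f[i] ||
        (cand == f[i] && (startA[j] < startA[i] ||
                          (startA[j] == startA[i] &&
                           startB[j] < startB[i])))
      if (better) {
        f[i] <- cand
        pred[i] <- j
        startA[i] <- startA[j]
        startB[i] <- startB[j]
      }
    }
  }
  bi <- which(f == max(f))
  if (length(bi) > 1L) {
    bi <- bi[order(startA[bi], startB[bi])][1L]
  }
  rows <- integer()
  i <- bi
  while (i != 0L) {
    rows <- c(i, rows)
    i <- pred[i]
  }
  list(rows = o[rows], score = f[bi], startA = startA[bi],
       startB = if (orient == "parallel") startB[bi] else -startB[bi])
}

#' Attach per-anchor Ks values and compute block medians
#'
#' Fills the `ks` column of the anchor table from a per-pair Ks table and
#' sets each block's `median_ks` to the median of its defined,
#' unsaturated anchor Ks values.  Blocks with fewer than `minDefined`
#' defined values keep an undefined median.
#'
#' @param blocks A [CollinearBlockSet-class].
#' @param ksTable data.frame with columns `gene_a`, `gene_b`, `ks` (and
#'   optionally `saturated`); pair orientation is ignored.
#' @param minDefined Minimum defined anchor Ks values for a block median
#'   (default 3).
#' @return The updated [CollinearBlockSet-class].
#' @export
attachBlockKs <- function(blocks, ksTable, minDefined = 3L) {
  a <- blocks@anchors
  b <- blocks@blocks
  ks <- ksTable$ks
  if (!is.null(ksTable$saturated)) {
    ks[ksTable$saturated %in% TRUE] <- NA_real_
  }
  keys <- c(paste(ksTable$gene_a, ksTable$gene_b, sep = "\r"),
            paste(ksTable$gene_b, ksTable$gene_a, sep = "\r"))
  vals <- c(ks, ks)
  m <- match(paste(a$gene_a, a$gene_b, sep = "\r"), keys)
  a$ks <- vals[m]
  med <- vapply(b$block_id, function(id) {
    v <- a$ks[a$block_id == id]
    v <- v[!is.na(v)]
    if (length(v) < minDefined) NA_real_ else stats::median(v)
  }, numeric(1))
  b$median_ks <- unname(med)
  blocks@anchors <- a
  blocks@blocks <- b
  blocks
}

#' Compute Nei-Gojobori Ks for every anchor of a block set
#'
#' Convenience wrapper: runs the NG86 estimator on the coding sequences of
#' each anchor pair.  Pairs where either gene lacks a CDS are skipped and
#' counted in the `skipped_missing_cds` attribute.
#'
#' @param blocks A [CollinearBlockSet-class].
#' @param genomeA,genomeB The genomes the anchors refer to.
#' @return data.frame (`gene_a`, `gene_b`, `ks`, `ka`, `saturated`)
#'   suitable for [attachBlockKs()].
#' @export
computeAnchorKs <- function(blocks, genomeA, genomeB = genomeA) {
  a <- blocks@anchors
  pairs <- unique(a[, c("gene_a", "gene_b")])
  cdsA <- genomeA@cds[pairs$gene_a]
  cdsB <- genomeB@cds[pairs$gene_b]
  have <- !is.na(cdsA) & !is.na(cdsB)
  est <- neiGojoboriTable(unname(cdsA[have]), unname(cdsB[have]))
  out <- data.frame(gene_a = pairs$gene_a[have],
                    gene_b = pairs$gene_b[have],
                    ks = est$Ks, ka = est$Ka, saturated = est$saturated,
                    stringsAsFactors = FALSE)
  attr(out, "skipped_missing_cds") <- sum(!have)
  out
}

#' Per-gene block coverage depth
#'
#' Counts, for every gene of the target genome, the number of blocks
#' whose ordinal span on that genome covers the gene.  For a
#' self-comparison both sides of each block contribute.
#'
#' @param blocks A [CollinearBlockSet-class].
#' @param genome The target [AnnotatedGenome-class].
#' @param ksBelow Optional: only count blocks with `median_ks` strictly
#'   below this value.
#' @return data.frame with `gene_id`, `chromosome_id`, `ordinal`, `depth`.
#' @export
depthProfile <- function(blocks, genome, ksBelow = NULL) {
  g <- genome@genes
  depth <- integer(nrow(g))
  b <- blocks@blocks
  a <- blocks@anchors
  if (!is.null(ksBelow)) {
    keep <- !is.na(b$median_ks) & b$median_ks < ksBelow
    b <- b[keep, , drop = FALSE]
    a <- a[a$block_id %in% b$block_id, , drop = FALSE]
  }
  nm <- genomeName(genome)
  for (id in b$block_id) {
    aa <- a[a$block_id == id, ]
    side <- character()
    if (b$genome_a[b$block_id == id] == nm) side <- c(side, "a")
    if (b$genome_b[b$block_id == id] == nm) side <- c(side, "b")
    for (s in side) {
      chr <- aa[[paste0("chr_", s)]][1]
      lo <- min(aa[[paste0("ord_", s)]])
      hi <- max(aa[[paste0("ord_", s)]])
      depth <- depth + (g$chromosome_id == chr & g$ordinal >= lo &
                          g$ordinal <= hi)
    }
  }
  data.frame(gene_id = g$gene_id, chromosome_id = g$chromosome_id,
             ordinal = g$ordinal, depth = depth, stringsAsFactors = FALSE)
}

#' Best-matched homologous region ratio between two genomes
#'
#' Estimates how many homologous subgenome copies each genome carries
#' relative to the other since their divergence, reported as a
#' `d_a : d_b` ratio of small integers.  The ortholog divergence level is located as the
#' density peak of the between-genome block medians; each genome's copy
#' number is then 1 plus the modal number of *within*-genome paralog
#' blocks younger than that level covering a gene (over genes covered by
#' at least one between-genome block).  The modal pair is reported
#' unreduced.
#'
#' @param between Between-genome [CollinearBlockSet-class].
#' @param withinA,withinB Self-comparison block sets of the two genomes
#'   (with block medians attached).
#' @param genomeA,genomeB The two genomes.
#' @return Named integer vector `c(a = d_a, b = d_b)` with attribute
#'   `ortholog_ks` (the divergence level used).
#' @export
bestMatchRatio <- function(between, withinA, withinB, genomeA, genomeB) {
  med <- between@blocks$median_ks
  med <- med[!is.na(med)]
  if (!length(med)) stop("insufficient homology: no between-genome blocks")
  level <- if (length(med) >= 10L) {
    dc <- kdeDensity(med, ksMax = max(med) + 0.2)
    dc$grid[which.max(dc$density)]
  } else {
    stats::median(med)
  }
  d <- integer(2)
  for (i in 1:2) {
    genome <- if (i == 1L) genomeA else genomeB
    within <- if (i == 1L) withinA else withinB
    covered <- depthProfile(between, genome)
    sel <- covered$depth >= 1L
    if (!any(sel)) stop("insufficient homology: no covered genes")
    para <- depthProfile(within, genome, ksBelow = level)
    dd <- para$depth[sel]
    tab <- table(dd)
    modal <- as.integer(names(tab)[which.max(tab)])
    d[i] <- 1L + modal
  }
  structure(c(a = d[1], b = d[2]), ortholog_ks = level)
}

#' Export anchor coordinates for dotplotting
#'
#' Writes a tab-separated table of anchor coordinates (one row per
#' anchor: chromosomes, ordinals, block id, orientation) for plotting.
#'
#' @param blocks A [CollinearBlockSet-class].
#' @param path Output path.
#' @export
writeDotplot <- function(blocks, path) {
  a <- blocks@anchors
  b <- blocks@blocks
  a$orientation <- b$orientation[match(a$block_id, b$block_id)]
  utils::write.table(a[, c("chr_a", "ord_a", "chr_b", "ord_b",
                           "block_id", "orientation")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
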