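#' Assign self-collinearity blocks to polyploidy event layers
#'
#' Labels every block carrying a median Ks with the fitted mixture
#' component of maximal posterior density at that median ("P1", "P2", ...
#' in order of increasing component mean).  Blocks farther than three
#' component standard deviations from every mean are labelled
#' `"unassigned"`; blocks without a median keep `NA`.
#'
#' @param blocks A [CollinearBlockSet-class] with medians attached.
#' @param peaks A [KsPeakSet-class] fitted on the same distribution.
#' @return The block set with `event_layer` filled in.
#' @export
assignEventLayers <- function(blocks, peaks) {
  comp <- peaks@components
  if (!nrow(comp)) stop("empty peak set")
  b <- blocks@blocks
  lab <- rep(NA_character_, nrow(b))
  has <- !is.na(b$median_ks)
  if (any(has)) {
    m <- b$median_ks[has]
    post <- vapply(seq_len(nrow(comp)), function(i) {
      comp$weight[i] * stats::dnorm(m, comp$mean[i], comp$sd[i])
    }, numeric(length(m)))
    post <- matrix(post, nrow = length(m))
    best <- max.col(post, ties.method = "first")
    within3 <- vapply(seq_along(m), function(j) {
      any(abs(m[j] - comp$mean) <= 3 * comp$sd)
    }, logical(1))
    lab[has] <- ifelse(within3, paste0("P", best), "unassigned")
  }
  b$event_layer <- lab
  blocks@blocks <- b
  blocks
}

#' Paint a genome with reference-chromosome segments
#'
#' Partitions the chromosomes of a target genome into segments according
#' to which reference chromosome their collinear blocks hit.  Adjacent
#' blocks hitting the same reference chromosome and separated by at most
#' `mergeGap` genes are merged; segments shorter than `minSegment` genes
#' are discarded; overlaps between consecutive segments are trimmed.
#' The provisional `proto_label` of a segment is the reference chromosome
#' id.
#'
#' @param target Target [AnnotatedGenome-class].
#' @param reference Reference [AnnotatedGenome-class].
#' @param blocks Target-versus-reference [CollinearBlockSet-class].
#' @param mergeGap Merge gap in genes (default 30).
#' @param minSegment Minimum segment length in genes (default 10).
#' @return data.frame of painted segments: `genome`, `chromosome`,
#'   `start_ord`, `end_ord` (inclusive gene-ordinal interval),
#'   `proto_label`, `orientation`, `n_genes`, `reference`.
#' @export
paintGenome <- function(target, reference, blocks, mergeGap = 30L,
                        minSegment = 10L) {
  b <- blocks@blocks
  a <- blocks@anchors
  tn <- genomeName(target)
  if (!nrow(b)) {
    warning("no blocks: empty painting")
    return(data.frame(genome = character(), chromosome = character(),
                      start_ord = integer(), end_ord = integer(),
                      proto_label = character(), orientation = character(),
                      n_genes = integer(), reference = character()))
  }
  # block footprints on the target side
  side <- if (all(b$genome_a == tn)) "a" else "b"
  refSide <- if (side == "a") "b" else "a"
  spans <- do.call(rbind, lapply(seq_len(nrow(b)), function(i) {
    aa <- a[a$block_id == b$block_id[i], ]
    data.frame(chr = aa[[paste0("chr_", side)]][1],
               lo = min(aa[[paste0("ord_", side)]]),
               hi = max(aa[[paste0("ord_", side)]]),
               ref = aa[[paste0("chr_", refSide)]][1],
               orientation = b$orientation[i],
               stringsAsFactors = FALSE)
  }))
  out <- NULL
  for (chr in sort(unique(spans$chr))) {
    s <- spans[spans$chr == chr, ]
    s <- s[order(s$lo, s$hi), ]
    merged <- s[1, , drop = FALSE]
    if (nrow(s) > 1L) {
      for (i in 2:nrow(s)) {
        last <- nrow(merged)
        if (s$ref[i] == merged$ref[last] &&
            s$lo[i] - merged$hi[last] - 1L <= mergeGap) {
          merged$hi[last] <- max(merged$hi[last], s$hi[i])
        } else {
          merged <- rbind(merged, s[i, ])
        }
      }
    }
    # trim overlaps between consecutive segments of different labels
    if (nrow(merged) > 1L) {
      for (i in 2:nrow(merged)) {
        if (merged$lo[i] <= merged$hi[i - 1L]) {
          mid <- (merged$lo[i] + merged$hi[i - 1L]) %/% 2L
          merged$hi[i - 1L] <- mid
          merged$lo[i] <- mid + 1L
        }
      }
    }
    merged$n <- merged$hi - merged$lo + 1L
    merged <- merged[merged$n >= minSegment, , drop = FALSE]
    if (nrow(merged)) {
      out <- rbind(out, data.frame(
        genome = tn, chromosome = chr, start_ord = merged$lo,
        end_ord = merged$hi, proto_label = merged$ref,
        orientation = merged$orientation, n_genes = merged$n,
        reference = genomeName(reference), stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    warning("no segments retained")
    out <- data.frame(genome = character(), chromosome = character(),
                      start_ord = integer(), end_ord = integer(),
                      proto_label = character(), orientation = character(),
                      n_genes = integer(), reference = character())
  }
  rownames(out) <- NULL
  out
}

#' Map genes to painted proto labels
#'
#' Gene-level labels from a painting: genes that are themselves anchors
#' of a target-versus-reference block are labelled by that block's
#' reference chromosome (exact), and only genes without an anchor
#' inherit the label of the painted segment spanning them (a chained
#' block may legitimately bridge a short foreign insertion, so the
#' segment span alone would over-label such interlopers).
#'
#' @param genome The painted [AnnotatedGenome-class].
#' @param painting Segments from [paintGenome()] (labels already in
#'   final form if `refLabels` is given).
#' @param blocks Optional target-versus-reference
#'   [CollinearBlockSet-class] used to label anchor genes exactly.
#' @param refLabels Optional named map from reference chromosome to
#'   final proto label (as from [inferProtoKaryotype()]).
#' @return Named character vector: gene id to proto label (NA outside
#'   retained segments).
#' @export
paintingLabels <- function(genome, painting, blocks = NULL,
                           refLabels = NULL) {
  g <- genome@genes
  lab <- rep(NA_character_, nrow(g))
  for (i in seq_len(nrow(painting))) {
    hit <- g$chromosome_id == painting$chromosome[i] &
      g$ordinal >= painting$start_ord[i] &
      g$ordinal <= painting$end_ord[i]
    lab[hit] <- painting$proto_label[i]
  }
  if (!is.null(blocks) && length(blocks)) {
    a <- blocks@anchors
    tn <- genomeName(genome)
    aSide <- if (all(blocks@blocks$genome_a == tn)) "a" else "b"
    rSide <- if (aSide == "a") "b" else "a"
    gid <- a[[paste0("gene_", aSide)]]
    ref <- a[[paste0("chr_", rSide)]]
    if (!is.null(refLabels)) {
      ref <- unname(refLabels[ref])
    }
    m <- match(gid, g$gene_id)
    ok <- !is.na(m) & !is.na(ref)
    lab[m[ok]] <- ref[ok]
  }
  stats::setNames(lab, g$gene_id)
}

#' Infer the ancestral proto-karyotype
#'
#' Builds a graph whose nodes are painted segments of the target genomes
#' plus the chromosomes of the designated lowest-multiplicity outgroup,
#' with edges linking each segment to the outgroup chromosome its blocks
#' hit (weighted by supporting genes).  Connected components whose
#' per-genome segment counts do not exceed the tree-expected
#' multiplicities become proto-chromosomes, labelled `A1..An` in order of
#' decreasing total gene content.  A component exceeding a multiplicity
#' is split by removing its weakest link (fewest supporting genes) until
#' consistent; if that fails it is flagged conflicted.
#'
#' @param paintings List of painted-segment tables (each from
#'   [paintGenome()] against the outgroup).
#' @param outgroup The outgroup [AnnotatedGenome-class].
#' @param multiplicities Named integer vector: expected maximal copy
#'   number per painted genome (e.g. `c(Cn = 4, Ac = 6)`).
#' @param minGenes Components with fewer supporting genes are dropped
#'   (mini-chromosome relics; default 10).
#' @return List with `karyotype` (a [NodeKaryotype-class] with one
#'   single-label chromosome per proto-chromosome), `labels` (map from
#'   outgroup chromosome to proto label), `segments` (all segments with
#'   final `proto_label`), and `conflicts`.
#' @importFrom igraph graph_from_data_frame components E delete_edges
#' @export
inferProtoKaryotype <- function(paintings, outgroup, multiplicities,
                                minGenes = 10L) {
  segs <- do.call(rbind, paintings)
  segs$seg_id <- sprintf("seg%04d", seq_len(nrow(segs)))
  ogChr <- chromosomeNames(outgroup)
  edges <- data.frame(from = segs$seg_id,
                      to = paste0("og:", segs$proto_label),
                      weight = segs$n_genes, stringsAsFactors = FALSE)
  verts <- data.frame(name = c(segs$seg_id, paste0("og:", ogChr)),
                      stringsAsFactors = FALSE)
  verts <- verts[!duplicated(verts$name), , drop = FALSE]
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                      vertices = verts)
  conflicts <- character()
  repeat {
    comp <- igraph::components(gr)
    bad <- NULL
    for (ci in seq_len(comp$no)) {
      members <- names(comp$membership)[comp$membership == ci]
      segMem <- segs[segs$seg_id %in% members, ]
      cnt <- table(segMem$genome)
      over <- names(cnt)[cnt > multiplicities[names(cnt)]]
      nOg <- sum(startsWith(members, "og:"))
      if (length(over) || nOg > 1L) {
        bad <- ci
        break
      }
    }
    if (is.null(bad)) break
    members <- names(comp$membership)[comp$membership == bad]
    ee <- igraph::E(gr)[.inc_edges(gr, members)]
    if (!length(ee)) {
      conflicts <- c(conflicts, paste(members, collapse = "+"))
      break
    }
    w <- igraph::edge_attr(gr, "weight", ee)
    gr <- igraph::delete_edges(gr, ee[which.min(w)])
  }
  comp <- igraph::components(gr)
  protos <- list()
  for (ci in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == ci]
    segMem <- segs[segs$seg_id %in% members, ]
    total <- sum(segMem$n_genes)
    og <- sub("^og:", "", members[startsWith(members, "og:")])
    if (total < minGenes || !length(og)) next
    protos[[length(protos) + 1L]] <- list(og = og[1], genes = total,
                                          segs = segMem$seg_id)
  }
  protos <- protos[order(-vapply(protos, `[[`, numeric(1), "genes"))]
  labels <- stats::setNames(
    sprintf("A%d", seq_along(protos)),
    vapply(protos, `[[`, character(1), "og"))
  segLab <- unlist(lapply(seq_along(protos), function(i) {
    stats::setNames(rep(sprintf("A%d", i), length(protos[[i]]$segs)),
                    protos[[i]]$segs)
  }))
  segs$proto_final <- segLab[segs$seg_id]
  chrom <- as.list(sprintf("A%d", seq_along(protos)))
  names(chrom) <- sprintf("A%d", seq_along(protos))
  list(karyotype = NodeKaryotype("proto", chrom), labels = labels,
       segments = segs, conflicts = conflicts)
}

.inc_edges <- function(gr, members) {
  unlist(igraph::incident_edges(gr,
                                which(igraph::V(gr)$name %in% members)))
}

# ---- ancestral gene-order reconstruction ---------------------------------

# One "undo the most recent WGD" step.  Given an extant gene order and a
# symmetric duplicate-partner map (gene -> homoeologous gene produced by
# that WGD), cuts chromosomes where the partner copies contradict the
# adjacency, groups fragments into homoeolog classes, and reassembles the
# pre-WGD chromosomes from partner-supported continuation evidence.
.ancestorStep <- function(genesDf, partner, gap = 30L,
                          minChromGenes = 10L, posDf = genesDf,
                          auxPartner = NULL, auxLabels = NULL,
                          cohBonus = 50L) {
  pnames <- names(partner)
  has <- genesDf$gene_id %in% pnames &
    partner[genesDf$gene_id] %in% posDf$gene_id
  pg <- genesDf[has, , drop = FALSE]
  pg <- pg[order(pg$chr, pg$ord), , drop = FALSE]
  if (!nrow(pg)) {
    return(list(chromosomes = list(), geneMap = NULL))
  }
  ordOf <- stats::setNames(posDf$ord, posDf$gene_id)
  chrOf <- stats::setNames(posDf$chr, posDf$gene_id)

  # discard partner assignments that contradict their neighbourhood: a
  # trustworthy partner is co-localised with the partner of at least one
  # neighbouring partnered gene (lone misassigned anchors would
  # otherwise cut chromosomes and seed spurious fragments)
  # partner co-location: partners must sit on one chromosome within a
  # distance that scales with the extant-side spacing (duplicate loss
  # thins the partner side, so allow about twice the spacing)
  coloc <- function(gdist, pdist) pdist <= pmax(2L * gdist, 12L)
  keepP <- logical(nrow(pg))
  for (i in seq_len(nrow(pg))) {
    p0 <- partner[[pg$gene_id[i]]]
    for (j in c(i - 2L, i - 1L, i + 1L, i + 2L)) {
      if (j < 1L || j > nrow(pg)) next
      if (pg$chr[j] != pg$chr[i]) next
      if (abs(pg$ord[j] - pg$ord[i]) > gap) next
      pj <- partner[[pg$gene_id[j]]]
      if (chrOf[[pj]] == chrOf[[p0]] &&
          coloc(abs(pg$ord[j] - pg$ord[i]),
                abs(ordOf[[pj]] - ordOf[[p0]]))) {
        keepP[i] <- TRUE
        break
      }
    }
  }
  pg <- pg[keepP, , drop = FALSE]
  if (!nrow(pg)) {
    return(list(chromosomes = list(), geneMap = NULL))
  }

  # fragments: runs of partner-supported adjacencies
  frag <- integer(nrow(pg))
  fcur <- 1L
  frag[1] <- 1L
  if (nrow(pg) > 1L) {
    for (i in 2:nrow(pg)) {
      newFrag <- TRUE
      if (pg$chr[i] == pg$chr[i - 1L] &&
          pg$ord[i] - pg$ord[i - 1L] <= gap) {
        p1 <- partner[[pg$gene_id[i - 1L]]]
        p2 <- partner[[pg$gene_id[i]]]
        if (chrOf[[p1]] == chrOf[[p2]] &&
            coloc(pg$ord[i] - pg$ord[i - 1L],
                  abs(ordOf[[p1]] - ordOf[[p2]]))) {
          newFrag <- FALSE
        }
      }
      if (newFrag) fcur <- fcur + 1L
      frag[i] <- fcur
    }
  }
  pg$frag <- frag
  fragOf <- stats::setNames(pg$frag, pg$gene_id)
  nFrag <- max(frag)

  # homoeolog classes: union fragments voted together by partner links
  votes <- table(pg$frag, fragOf[partner[pg$gene_id]])
  parentUF <- seq_len(nFrag)
  findUF <- function(x) {
    while (parentUF[x] != x) x <- parentUF[x]
    x
  }
  vi <- which(votes >= 2L, arr.ind = TRUE)
  for (r in seq_len(nrow(vi))) {
    f1 <- as.integer(rownames(votes)[vi[r, 1]])
    f2 <- as.integer(colnames(votes)[vi[r, 2]])
    r1 <- findUF(f1); r2 <- findUF(f2)
    if (r1 != r2) parentUF[max(r1, r2)] <- min(r1, r2)
  }
  classOfFrag <- vapply(seq_len(nFrag), findUF, integer(1))
  classOfFrag <- match(classOfFrag, sort(unique(classOfFrag)))
  pg$class <- classOfFrag[pg$frag]
  nClass <- max(pg$class)

  fragGenes <- split(pg$gene_id, pg$frag)
  fragClass <- vapply(split(pg$class, pg$frag), `[`, integer(1), 1)
  classSize <- tapply(rep(1L, nrow(pg)), pg$class, sum)
  # representative fragment per class: the largest
  rep_ <- integer(nClass)
  for (cl in seq_len(nClass)) {
    ff <- as.integer(names(fragClass))[fragClass == cl]
    rep_[cl] <- ff[which.max(lengths(fragGenes[as.character(ff)]))]
  }

  # continuation proposals.  Two evidence sources: (i) the extant
  # adjacency across a cut (the junction may be ancestral, with the cut
  # induced by a rearrangement in the partner copy), and (ii) the
  # partner-side continuation past a fragment end.  A rearrangement
  # produces both kinds around its breakpoints; accepting joins by
  # support under the degree/acyclicity constraints resolves them into a
  # consistent pre-WGD chromosome set.
  proposals <- NULL
  if (nrow(pg) > 1L) {
    for (i in 2:nrow(pg)) {
      if (pg$chr[i] != pg$chr[i - 1L]) next
      if (pg$ord[i] - pg$ord[i - 1L] > gap) next
      cl1 <- pg$class[i - 1L]
      cl2 <- pg$class[i]
      if (cl1 == cl2) next
      proposals <- rbind(proposals, data.frame(
        a = cl1, b = cl2,
        ga = pg$gene_id[i - 1L], gb = pg$gene_id[i],
        stringsAsFactors = FALSE))
    }
  }
  for (f in seq_len(nFrag)) {
    gg <- fragGenes[[as.character(f)]]
    if (length(gg) < 2L) next
    for (endSide in c("left", "right")) {
      gEnd <- if (endSide == "right") gg[length(gg)] else gg[1]
      gPrev <- if (endSide == "right") gg[length(gg) - 1L] else gg[2]
      q <- partner[[gEnd]]
      qPrev <- partner[[gPrev]]
      dirn <- sign(ordOf[[q]] - ordOf[[qPrev]])
      if (dirn == 0) next
      # nearest partnered gene beyond q in that direction, within gap
      qc <- chrOf[[q]]
      cand <- pg[pg$chr == qc &
                   (pg$ord - ordOf[[q]]) * dirn > 0 &
                   abs(pg$ord - ordOf[[q]]) <= gap, , drop = FALSE]
      if (!nrow(cand)) next
      q2 <- cand$gene_id[which.min(abs(cand$ord - ordOf[[q]]))]
      clF <- fragClass[[as.character(f)]]
      clT <- pg$class[pg$gene_id == q2]
      if (clF == clT) next
      proposals <- rbind(proposals, data.frame(
        a = clF, b = clT, ga = gEnd, gb = q2,
        stringsAsFactors = FALSE))
    }
  }

  # each class has two ends (lo/hi in the coordinate of its
  # representative fragment); a join consumes one end on each side
  posInRep <- function(g, cl) {
    gg <- fragGenes[[as.character(rep_[cl])]]
    i <- match(g, gg)
    if (is.na(i)) i <- match(partner[[g]], gg)
    i
  }
  classLen <- vapply(seq_len(nClass), function(cl) {
    length(fragGenes[[as.character(rep_[cl])]])
  }, integer(1))
  endOf <- function(g, cl) {
    p <- posInRep(g, cl)
    if (is.na(p)) return(NA_character_)
    if (p <= classLen[cl] / 2) "lo" else "hi"
  }

  # telomere evidence: a class end whose fragment extreme lies at an
  # extant chromosome end (in either copy) was a chromosome end at the
  # ancestral node too (fusions remove the joined telomeres, so a
  # surviving terminal position marks a real end); candidate joins on
  # such ends are spurious and dropped
  chrLo <- tapply(genesDf$ord, genesDf$chr, min)
  chrHi <- tapply(genesDf$ord, genesDf$chr, max)
  telWindow <- max(5L, gap %/% 3L)
  telomeric <- matrix(FALSE, nClass, 2L,
                      dimnames = list(NULL, c("lo", "hi")))
  for (f in seq_len(nFrag)) {
    gg <- fragGenes[[as.character(f)]]
    cl <- fragClass[[as.character(f)]]
    for (g in c(gg[1], gg[length(gg)])) {
      rowi <- match(g, pg$gene_id)
      isTel <- pg$ord[rowi] <= chrLo[[pg$chr[rowi]]] + telWindow ||
        pg$ord[rowi] >= chrHi[[pg$chr[rowi]]] - telWindow
      if (!isTel) next
      e <- endOf(g, cl)
      if (!is.na(e)) telomeric[cl, e] <- TRUE
    }
  }

  # older-layer coherence: a true rejoin reconnects two pieces of one
  # pre-WGD segment, so the older-layer duplicates of its junction genes
  # are co-localised; a breakpoint-created junction joins unrelated
  # segments whose older-layer duplicates lie far apart
  # for the older-layer test, fall back to the nearest gene with an
  # older-layer duplicate when the junction gene itself has none
  gOrd <- stats::setNames(genesDf$ord, genesDf$gene_id)
  gChr <- stats::setNames(genesDf$chr, genesDf$gene_id)
  nearestAux <- function(g) {
    if (is.null(auxPartner)) return(NA_character_)
    if (!is.na(auxPartner[g])) return(g)
    sel <- genesDf$chr == gChr[[g]] &
      abs(genesDf$ord - gOrd[[g]]) <= gap &
      genesDf$gene_id %in% names(auxPartner)
    if (!any(sel)) return(NA_character_)
    cand <- genesDf$gene_id[sel]
    cand[which.min(abs(gOrd[cand] - gOrd[[g]]))]
  }
  coherent <- function(ga, gb) {
    if (!is.null(auxPartner)) {
      na_ <- nearestAux(ga)
      nb_ <- nearestAux(gb)
      if (!is.na(na_) && !is.na(nb_)) {
        pa <- auxPartner[[na_]]
        pb <- auxPartner[[nb_]]
        if (pa %in% names(chrOf) && pb %in% names(chrOf) &&
            chrOf[[pa]] == chrOf[[pb]] &&
            abs(ordOf[[pa]] - ordOf[[pb]]) <= 3 * gap) {
          return(TRUE)
        }
      }
    }
    if (!is.null(auxLabels)) {
      la <- auxLabels[ga]
      lb <- auxLabels[gb]
      if (!is.na(la) && !is.na(lb) && la == lb) return(TRUE)
    }
    FALSE
  }

  edges <- NULL
  if (!is.null(proposals)) {
    proposals$endA <- mapply(endOf, proposals$ga, proposals$a)
    proposals$endB <- mapply(endOf, proposals$gb, proposals$b)
    proposals$w0 <- 1L
    if (!is.null(auxPartner) || !is.null(auxLabels)) {
      proposals$w0 <- proposals$w0 + cohBonus *
        mapply(coherent, proposals$ga, proposals$gb)
    }
    pr <- proposals[!is.na(proposals$endA) & !is.na(proposals$endB), ,
                    drop = FALSE]
    pr <- pr[!telomeric[cbind(pr$a, match(pr$endA, c("lo", "hi")))] &
               !telomeric[cbind(pr$b, match(pr$endB, c("lo", "hi")))], ,
             drop = FALSE]
    # canonical side order for aggregation
    swap <- pr$b < pr$a
    pr[swap, c("a", "b", "endA", "endB")] <-
      pr[swap, c("b", "a", "endB", "endA")]
    if (nrow(pr)) {
      agg <- stats::aggregate(list(w = pr$w0),
                              by = pr[, c("a", "b", "endA", "endB")],
                              FUN = sum)
      # when coherence evidence is available, only coherent joins are
      # acceptable: every legitimate rejoin reconnects pieces of one
      # pre-WGD segment and therefore carries the coherence bonus, while
      # breakpoint-created junctions do not
      if (!is.null(auxPartner) || !is.null(auxLabels)) {
        agg <- agg[agg$w >= cohBonus, , drop = FALSE]
      }
      agg <- agg[order(-agg$w, agg$a, agg$b, agg$endA, agg$endB), ,
                 drop = FALSE]
      if (!nrow(agg)) agg <- NULL
      # Competing joins attach to the same class ends (a rearrangement
      # breakpoint offers two mutually exclusive continuations of equal
      # support).  Choose, per connected group of candidate joins, the
      # end-matching that covers the most ends (then the largest total
      # support): this keeps the resolution of each breakpoint
      # consistent across its four involved ends.
      if (is.null(agg)) {
        agg <- data.frame(a = integer(), b = integer(),
                          endA = character(), endB = character(),
                          w = integer())
      }
      nodeOf <- function(cl, e) paste0(cl, ":", e)
      agg$na <- nodeOf(agg$a, agg$endA)
      agg$nb <- nodeOf(agg$b, agg$endB)
      nodes <- unique(c(agg$na, agg$nb))
      nuf <- stats::setNames(seq_along(nodes), nodes)
      findN <- function(x) {
        while (nuf[[x]] != x) x <- names(nuf)[nuf[[x]]]
        x
      }
      # union-find over node names via indices
      idx <- stats::setNames(seq_along(nodes), nodes)
      par_ <- seq_along(nodes)
      findI <- function(x) {
        while (par_[x] != x) x <- par_[x]
        x
      }
      for (r in seq_len(nrow(agg))) {
        i1 <- findI(idx[[agg$na[r]]])
        i2 <- findI(idx[[agg$nb[r]]])
        if (i1 != i2) par_[max(i1, i2)] <- min(i1, i2)
      }
      compOf <- vapply(seq_along(nodes), findI, integer(1))
      edges <- NULL
      puf <- seq_len(nClass)
      findP <- function(x) {
        while (puf[x] != x) x <- puf[x]
        x
      }
      for (cid in unique(compOf)) {
        compNodes <- nodes[compOf == cid]
        ce <- agg[agg$na %in% compNodes | agg$nb %in% compNodes, ,
                  drop = FALSE]
        chosen <- .bestEndMatching(ce)
        for (r in chosen) {
          a <- ce$a[r]; b <- ce$b[r]
          ra <- findP(a); rb <- findP(b)
          if (ra == rb) next          # would close a cycle of classes
          puf[max(ra, rb)] <- min(ra, rb)
          edges <- rbind(edges, data.frame(a = a, b = b,
                                           endA = ce$endA[r],
                                           endB = ce$endB[r],
                                           stringsAsFactors = FALSE))
        }
      }
    }
  }

  # label-guided fallback: when duplicate loss thins the data exactly at
  # an event boundary, a segment can be split across two classes with no
  # surviving partner witness.  Two free, non-telomeric class ends that
  # terminate in the same proto label (and are the only such pair) are
  # then joined.
  if (!is.null(auxLabels) && nClass > 1L) {
    usedEnd <- matrix(FALSE, nClass, 2L,
                      dimnames = list(NULL, c("lo", "hi")))
    if (!is.null(edges)) {
      for (r in seq_len(nrow(edges))) {
        usedEnd[edges$a[r], edges$endA[r]] <- TRUE
        usedEnd[edges$b[r], edges$endB[r]] <- TRUE
      }
    }
    puf2 <- seq_len(nClass)
    findP2 <- function(x) {
      while (puf2[x] != x) x <- puf2[x]
      x
    }
    if (!is.null(edges)) {
      for (r in seq_len(nrow(edges))) {
        r1 <- findP2(edges$a[r]); r2 <- findP2(edges$b[r])
        if (r1 != r2) puf2[max(r1, r2)] <- min(r1, r2)
      }
    }
    termLabel <- function(cl, e) {
      gg <- fragGenes[[as.character(rep_[cl])]]
      if (e == "hi") gg <- rev(gg)
      lab <- auxLabels[gg[seq_len(min(5L, length(gg)))]]
      lab <- lab[!is.na(lab)]
      if (length(lab)) lab[1] else NA_character_
    }
    free <- NULL
    for (cl in seq_len(nClass)) {
      for (e in c("lo", "hi")) {
        if (usedEnd[cl, e] || telomeric[cl, e]) next
        free <- rbind(free, data.frame(cl = cl, e = e,
                                       lab = termLabel(cl, e),
                                       stringsAsFactors = FALSE))
      }
    }
    if (!is.null(free)) {
      free <- free[!is.na(free$lab), , drop = FALSE]
      for (lb in unique(free$lab)) {
        cand <- free[free$lab == lb, , drop = FALSE]
        if (nrow(cand) != 2L) next
        if (cand$cl[1] == cand$cl[2]) next
        r1 <- findP2(cand$cl[1]); r2 <- findP2(cand$cl[2])
        if (r1 == r2) next
        puf2[max(r1, r2)] <- min(r1, r2)
        edges <- rbind(edges, data.frame(
          a = cand$cl[1], b = cand$cl[2], endA = cand$e[1],
          endB = cand$e[2], stringsAsFactors = FALSE))
      }
    }
  }

  # walk paths over classes, orienting each representative fragment so
  # that the joined ends meet
  adj <- vector("list", nClass)
  if (!is.null(edges)) {
    for (r in seq_len(nrow(edges))) {
      adj[[edges$a[r]]] <- c(adj[[edges$a[r]]],
                             list(list(nb = edges$b[r],
                                       myEnd = edges$endA[r],
                                       nbEnd = edges$endB[r])))
      adj[[edges$b[r]]] <- c(adj[[edges$b[r]]],
                             list(list(nb = edges$a[r],
                                       myEnd = edges$endB[r],
                                       nbEnd = edges$endA[r])))
    }
  }
  seen <- logical(nClass)
  chromGenes <- list()
  walk <- function(start, enterEnd) {
    out <- character()
    cur <- start
    entry <- enterEnd
    repeat {
      seen[cur] <<- TRUE
      gg <- fragGenes[[as.character(rep_[cur])]]
      if (identical(entry, "hi")) gg <- rev(gg)
      out <- c(out, gg)
      exits <- Filter(function(e) !seen[e$nb] &&
                        !identical(e$myEnd, entry), adj[[cur]])
      if (!length(exits)) break
      nxt <- exits[[1]]
      cur <- nxt$nb
      entry <- nxt$nbEnd
    }
    out
  }
  degs <- lengths(adj)
  for (start in order(degs)) {
    if (seen[start]) next
    usedEnds <- vapply(adj[[start]], function(e) e$myEnd, character(1))
    enterEnd <- if ("lo" %in% setdiff(c("lo", "hi"), usedEnds)) "lo"
                else if (length(usedEnds)) setdiff(c("lo", "hi"),
                                                   usedEnds[1])[1]
                else "lo"
    chromGenes[[length(chromGenes) + 1L]] <- walk(start, enterEnd)
  }
  geneMap <- NULL
  keep <- lengths(chromGenes) >= minChromGenes
  chromGenes <- chromGenes[keep]
  names(chromGenes) <- sprintf("anc%02d", seq_along(chromGenes))
  for (ci in seq_along(chromGenes)) {
    geneMap <- rbind(geneMap, data.frame(
      gene_id = chromGenes[[ci]], anc_chr = names(chromGenes)[ci],
      anc_pos = seq_along(chromGenes[[ci]]), stringsAsFactors = FALSE))
  }
  # map the non-representative copies through their partners
  if (!is.null(geneMap)) {
    inRep <- stats::setNames(geneMap$anc_pos, geneMap$gene_id)
    inRepChr <- stats::setNames(geneMap$anc_chr, geneMap$gene_id)
    others <- setdiff(pg$gene_id, geneMap$gene_id)
    pOthers <- partner[others]
    ok <- pOthers %in% names(inRep)
    if (any(ok)) {
      geneMap <- rbind(geneMap, data.frame(
        gene_id = others[ok],
        anc_chr = unname(inRepChr[pOthers[ok]]),
        anc_pos = unname(inRep[pOthers[ok]]),
        stringsAsFactors = FALSE))
    }
  }
  list(chromosomes = chromGenes, geneMap = geneMap,
       diagnostics = list(
         nFragments = nFrag, nClasses = nClass,
         classes = pg[, c("gene_id", "chr", "ord", "frag", "class")],
         edges = edges, telomeric = telomeric))
}

# Extract a symmetric gene -> duplicate-partner map for one polyploidy
# layer.  Anchors are classified individually: an anchor belongs to the
# layer whose fitted component mean is nearest to its own Ks (a block can
# legitimately chain through regions of different homology depth, so the
# block-level label is not trusted here).
.layerPartnerMap <- function(blocks, peaks, component) {
  a <- blocks@anchors
  b <- blocks@blocks
  means <- peaks@components$mean
  aa <- a[!is.na(a$ks), , drop = FALSE]
  if (!nrow(aa)) return(stats::setNames(character(), character()))
  nearest <- apply(abs(outer(aa$ks, means, "-")), 1, which.min)
  aa <- aa[nearest == component, , drop = FALSE]
  if (!nrow(aa)) return(stats::setNames(character(), character()))
  # prefer anchors of larger blocks when a gene occurs in several
  bsize <- stats::setNames(b$n_anchors, b$block_id)
  aa <- aa[order(-bsize[aa$block_id]), ]
  map <- c(stats::setNames(aa$gene_b, aa$gene_a),
           stats::setNames(aa$gene_a, aa$gene_b))
  map[!duplicated(names(map))]
}

#' Reconstruct node karyotypes along the coconut-style lineage
#'
#' Walks from the extant genome back through the two polyploidies:
#' undoing the most recent WGD (via the youngest paralog layer) yields
#' the pre-WGD karyotype, whose doubling is the post-WGD node; a second
#' undo step (via the older layer mapped onto the reconstructed
#' chromosomes) yields the pre-tau karyotype; the proto-karyotype
#' (painting components against the outgroup) is the root.  Branch events
#' between consecutive nodes are classified by parsimony pattern
#' matching.
#'
#' @param extant The extant [AnnotatedGenome-class].
#' @param protoKaryotype Root [NodeKaryotype-class] from
#'   [inferProtoKaryotype()].
#' @param geneLabels Named proto-label per extant gene (from
#'   [paintingLabels()] with final labels).
#' @param selfBlocks Self-collinearity [CollinearBlockSet-class] of the
#'   extant genome with per-anchor Ks attached.
#' @param peaks [KsPeakSet-class] fitted on the self-block medians; its
#'   components define the paralog layers.
#' @param youngComponent,oldComponent Component indices (by increasing
#'   mean) of the most recent and the older WGD (defaults 1 and 2).
#' @param gap Partner co-localisation gap in genes (default 30).
#' @param minRun Minimum genes per label run when reducing chromosomes to
#'   label sequences (default 5).
#' @param nodeNames Names of the five reconstructed nodes plus the extant
#'   genome, root first.
#' @return A [Trajectory-class] with karyotypes at the root, pre-tau,
#'   post-tau, pre-omega, post-omega and extant nodes, per-branch event
#'   tables, and branch ploidy multiplicities.
#' @export
reconstructNodeKaryotypes <- function(extant, protoKaryotype, geneLabels,
                                      selfBlocks, peaks,
                                      youngComponent = 1L,
                                      oldComponent = 2L, gap = 30L,
                                      minRun = 5L,
                                      nodeNames = c("A", "B", "C", "D",
                                                    "E", "extant")) {
  g <- extant@genes
  genesDf <- data.frame(gene_id = g$gene_id, chr = g$chromosome_id,
                        ord = g$ordinal, stringsAsFactors = FALSE)
  labelSeq <- function(geneVecs) {
    out <- lapply(geneVecs, function(v) {
      lab <- geneLabels[v]
      lab <- lab[!is.na(lab)]
      if (!length(lab)) return(character())
      r <- rle(lab)
      rle(r$values[r$lengths >= minRun])$values
    })
    out[lengths(out) > 0L]
  }
  extantChroms <- split(genesDf$gene_id[order(genesDf$chr, genesDf$ord)],
                        genesDf$chr[order(genesDf$chr, genesDf$ord)])
  kExtant <- NodeKaryotype(nodeNames[6], labelSeq(extantChroms))

  youngMap <- .layerPartnerMap(selfBlocks, peaks, youngComponent)
  oldMapExtant <- .layerPartnerMap(selfBlocks, peaks, oldComponent)
  stepE <- .ancestorStep(genesDf, youngMap, gap = gap,
                         auxPartner = oldMapExtant,
                         auxLabels = geneLabels)
  kPreOmega <- NodeKaryotype(nodeNames[4], labelSeq(stepE$chromosomes))
  kPostOmega <- NodeKaryotype(
    nodeNames[5],
    karyotypeChromosomes(kPreOmega)[
      rep(seq_along(karyotypeChromosomes(kPreOmega)), 2L)])

  # second undo step: rebuild collinearity on the reconstructed
  # pre-omega genome (every remaining duplicate pair there descends from
  # the older WGD), then undo that layer the same way
  fam <- stats::setNames(g$family_id, g$gene_id)
  ancRows <- do.call(rbind, lapply(names(stepE$chromosomes),
                                   function(ch) {
    v <- stepE$chromosomes[[ch]]
    data.frame(gene_id = v, chromosome_id = ch,
               start = seq_along(v) * 1000L,
               end = seq_along(v) * 1000L + 500L, strand = "+",
               family_id = unname(fam[v]), stringsAsFactors = FALSE)
  }))
  ancGenome <- AnnotatedGenome("anc", ancRows)
  # with the recent layer removed, a family has at most two copies left
  # on the reconstructed genome, so the older-layer partner of a gene is
  # simply its family mate (lone stray copies are ignored)
  byFam <- split(ancRows$gene_id, ancRows$family_id)
  pairs <- byFam[lengths(byFam) == 2L]
  oldMap <- character()
  if (length(pairs)) {
    m1 <- vapply(pairs, `[`, character(1), 1L)
    m2 <- vapply(pairs, `[`, character(1), 2L)
    oldMap <- stats::setNames(c(m2, m1), c(m1, m2))
  }
  gi <- geneOrderIndex(ancGenome)
  ancOrder <- data.frame(gene_id = gi$gene_id,
                         chr = gi$chromosome_id, ord = gi$ordinal,
                         stringsAsFactors = FALSE)
  stepB <- .ancestorStep(ancOrder, oldMap, gap = gap,
                         auxLabels = geneLabels)
  kPreTau <- NodeKaryotype(nodeNames[2], labelSeq(stepB$chromosomes))
  kPostTau <- NodeKaryotype(
    nodeNames[3],
    karyotypeChromosomes(kPreTau)[
      rep(seq_along(karyotypeChromosomes(kPreTau)), 2L)])

  kRoot <- NodeKaryotype(nodeNames[1],
                         karyotypeChromosomes(protoKaryotype))

  evAB <- classifyBranchEvents(kRoot, kPreTau)
  evCD <- classifyBranchEvents(kPostTau, kPreOmega)
  evEx <- classifyBranchEvents(kPostOmega, kExtant)
  none <- data.frame(kind = character(), detail = character(),
                     stringsAsFactors = FALSE)
  karyos <- list(kRoot, kPreTau, kPostTau, kPreOmega, kPostOmega, kExtant)
  names(karyos) <- nodeNames
  events <- list(evAB, none, evCD, none, evEx)
  names(events) <- paste0(nodeNames[-6], "->", nodeNames[-1])
  mult <- c(1, 2, 1, 2, 1)
  names(mult) <- names(events)
  new("Trajectory", karyotypes = karyos, events = events,
      multiplicities = mult)
}

#' Check the chromosome-count bookkeeping of a trajectory
#'
#' Asserts, per branch, `count(child) = m * count(parent) - EEJ - NF`
#' where `m` is the branch ploidy multiplier and EEJ/NF the number of
#' end-to-end joins and nested fusions classified on that branch.
#' Violations are reported, not thrown.
#'
#' @param trajectory A [Trajectory-class].
#' @return data.frame with one row per branch: counts, expectation and an
#'   `ok` flag.
#' @export
validateBookkeeping <- function(trajectory) {
  k <- trajectory@karyotypes
  ev <- trajectory@events
  mult <- trajectory@multiplicities
  out <- NULL
  for (i in seq_along(ev)) {
    parent <- chromosomeCount(k[[i]])
    child <- chromosomeCount(k[[i + 1L]])
    kinds <- ev[[i]]$kind
    m <- mult[[i]]
    expect <- m * parent - sum(kinds == "EEJ") -
      sum(kinds == "NESTED_FUSION")
    out <- rbind(out, data.frame(
      branch = names(ev)[i], parent = parent, child = child,
      multiplier = m, eej = sum(kinds == "EEJ"),
      nested_fusion = sum(kinds == "NESTED_FUSION"),
      expected = expect, ok = child == expect,
      stringsAsFactors = FALSE))
  }
  out
}

# Enumerate matchings over candidate class-end joins, maximising the
# number of ends covered and then the total support; returns row indices
# of the chosen edges.  Candidate groups are small (a handful of ends
# around one or two breakpoints), so exhaustive search is fine.
.bestEndMatching <- function(ce, maxEdges = 14L) {
  ne <- nrow(ce)
  if (!ne) return(integer())
  if (ne > maxEdges) {
    ce2 <- ce[order(-ce$w), , drop = FALSE][seq_len(maxEdges), ,
                                            drop = FALSE]
    keepRows <- match(rownames(ce2), rownames(ce))
    sub <- .bestEndMatching(ce2, maxEdges)
    return(keepRows[sub])
  }
  best <- list(card = -1L, w = -Inf, rows = integer())
  recur <- function(i, used, rows, w) {
    if (i > ne) {
      card <- length(rows)
      if (card > best$card || (card == best$card && w > best$w)) {
        best <<- list(card = card, w = w, rows = rows)
      }
      return(invisible())
    }
    # prune: even taking all remaining edges cannot beat best cardinality
    if (length(rows) + (ne - i + 1L) < best$card) return(invisible())
    na <- ce$na[i]; nb <- ce$nb[i]
    if (!(na %in% used) && !(nb %in% used)) {
      recur(i + 1L, c(used, na, nb), c(rows, i), w + ce$w[i])
    }
    recur(i + 1L, used, rows, w)
    invisible()
  }
  recur(1L, character(), integer(), 0)
  best$rows
}

# gene -> duplicate partner map from chained self-collinearity blocks,
# preferring anchors of larger blocks
.blockPartnerMap <- function(blocks) {
  aa <- blocks@anchors
  if (!nrow(aa)) return(stats::setNames(character(), character()))
  bsize <- stats::setNames(blocks@blocks$n_anchors,
                           blocks@blocks$block_id)
  aa <- aa[order(-bsize[aa$block_id]), ]
  map <- c(stats::setNames(aa$gene_b, aa$gene_a),
           stats::setNames(aa$gene_a, aa$gene_b))
  map[!duplicated(names(map))]
}
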