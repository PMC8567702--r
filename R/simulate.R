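#' Construct a karyotype evolution event
#'
#' Events operate on chromosome ids of the pre-event state.  Supported
#' kinds and their parameters:
#' \describe{
#'   \item{WGD / WGT}{whole-genome duplication / triplication; `tag` names
#'     the event (copies get `.tagK` id suffixes).}
#'   \item{EEJ}{end-to-end joining of `chr1` and `chr2` (in this order);
#'     the two junction telomeres are removed.}
#'   \item{NESTED_FUSION}{insertion of whole chromosome `insert` at an
#'     internal breakpoint of `host` (`at` genes kept before the
#'     insertion point, or `atFrac` as a fraction); both insert telomeres
#'     are removed.  A breakpoint at either chromosome end is an error
#'     (that would be an EEJ).}
#'   \item{ARM_EXCHANGE}{reciprocal exchange of the tails of `chr1` (after
#'     `at1`/`atFrac1`) and `chr2` (after `at2`/`atFrac2`); the
#'     chromosome count is unchanged.}
#'   \item{INVERSION}{reversal of the internal gene run `from..to`
#'     (1-based gene positions, or `fromFrac`/`toFrac`).}
#'   \item{FRACTIONATION}{each gene copy of a family with >= 2 copies is
#'     deleted independently with probability `prob`; the last surviving
#'     copy of a family is never deleted.}
#' }
#'
#' @param kind Event kind (see above).
#' @param ... Kind-specific parameters.
#' @return A list of class `EvolutionEvent`.
#' @export
evolutionEvent <- function(kind, ...) {
  kind <- match.arg(kind, c("WGD", "WGT", "EEJ", "NESTED_FUSION",
                            "ARM_EXCHANGE", "INVERSION", "FRACTIONATION"))
  structure(c(list(kind = kind), list(...)), class = "EvolutionEvent")
}

# ---- internal chromosome-list representation ------------------------------

.asChromList <- function(genome) {
  g <- genome@genes
  lapply(split(g[, c("gene_id", "family_id", "strand")],
               factor(g$chromosome_id,
                      levels = names(genome@chromosomeLengths))),
         function(d) d[order(g$ordinal[match(d$gene_id, g$gene_id)]), ,
                       drop = FALSE])
}

.chromListGenome <- function(name, chroms, cds, telomeres,
                             intergenic = 200L) {
  rows <- lapply(names(chroms), function(chr) {
    d <- chroms[[chr]]
    if (!nrow(d)) return(NULL)
    len <- ifelse(d$gene_id %in% names(cds),
                  nchar(cds[d$gene_id]), 300L)
    start <- cumsum(c(0L, head(len + intergenic, -1L)))
    data.frame(gene_id = d$gene_id, chromosome_id = chr,
               start = start, end = start + len, strand = d$strand,
               ordinal = seq_len(nrow(d)) - 1L, family_id = d$family_id,
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  # canonical row order (matching the AnnotatedGenome constructor), so
  # that write/read round trips are exact
  genes <- genes[order(genes$chromosome_id, genes$ordinal), , drop = FALSE]
  rownames(genes) <- NULL
  keep <- vapply(chroms, nrow, integer(1)) > 0L
  lens <- vapply(chroms[keep], function(d) {
    len <- ifelse(d$gene_id %in% names(cds), nchar(cds[d$gene_id]), 300L)
    sum(len + intergenic)
  }, numeric(1))
  tel <- telomeres[match(names(chroms)[keep], telomeres$chromosome_id), ]
  new("AnnotatedGenome", name = name, genes = genes,
      cds = cds[names(cds) %in% genes$gene_id],
      chromosomeLengths = lens, telomeres = tel,
      sequence = character())
}

.telomereRow <- function(chr, left = TRUE, right = TRUE) {
  data.frame(chromosome_id = chr, left = left, right = right,
             stringsAsFactors = FALSE)
}

.resolveAt <- function(event, field, n) {
  at <- event[[field]]
  if (is.null(at)) {
    frac <- event[[paste0(field, "Frac")]]
    if (is.null(frac)) stop("event needs '", field, "' or '",
                            field, "Frac'")
    at <- round(frac * n)
  }
  as.integer(at)
}

# ---- event application ----------------------------------------------------

#' Apply a karyotype evolution event to a genome
#'
#' Bookkeeping: WGD multiplies the chromosome count by 2 and WGT by 3; EEJ
#' and NESTED_FUSION reduce it by 1; ARM_EXCHANGE and INVERSION leave it
#' unchanged; FRACTIONATION changes gene content only.  Apart from
#' FRACTIONATION every event preserves the multiset of genes.
#' FRACTIONATION consumes random numbers from the current RNG stream.
#'
#' @param genome An [AnnotatedGenome-class].
#' @param event An [evolutionEvent()].
#' @return The post-event [AnnotatedGenome-class].
#' @export
applyEvent <- function(genome, event) {
  stopifnot(inherits(event, "EvolutionEvent"))
  chroms <- .asChromList(genome)
  cds <- genome@cds
  tel <- genome@telomeres
  kind <- event$kind

  if (kind %in% c("WGD", "WGT")) {
    m <- if (kind == "WGD") 2L else 3L
    tag <- if (is.null(event$tag)) tolower(kind) else event$tag
    out <- list()
    newTel <- NULL
    newCds <- cds
    for (chr in names(chroms)) {
      out[[chr]] <- chroms[[chr]]
      t0 <- tel[tel$chromosome_id == chr, ]
      newTel <- rbind(newTel, t0)
      for (k in 2:m) {
        cc <- chroms[[chr]]
        ids <- paste0(cc$gene_id, ".", tag, k)
        add <- cds[cc$gene_id]
        names(add) <- ids
        newCds <- c(newCds, add)
        cc$gene_id <- ids
        nm <- paste0(chr, ".", tag, k)
        out[[nm]] <- cc
        t0$chromosome_id <- nm
        newTel <- rbind(newTel, t0)
      }
    }
    return(.chromListGenome(genome@name, out, newCds, newTel))
  }

  if (kind == "EEJ") {
    c1 <- event$chr1; c2 <- event$chr2
    if (identical(c1, c2)) stop("EEJ of a chromosome with itself")
    stopifnot(c1 %in% names(chroms), c2 %in% names(chroms))
    joined <- rbind(chroms[[c1]], chroms[[c2]])
    nm <- paste0(c1, "--", c2)
    chroms[[nm]] <- joined
    chroms[[c1]] <- chroms[[c2]] <- NULL
    t1 <- tel[tel$chromosome_id == c1, ]
    t2 <- tel[tel$chromosome_id == c2, ]
    tel <- tel[!tel$chromosome_id %in% c(c1, c2), ]
    tel <- rbind(tel, .telomereRow(nm, t1$left, t2$right))
    return(.chromListGenome(genome@name, chroms, cds, tel))
  }

  if (kind == "NESTED_FUSION") {
    host <- event$host; ins <- event$insert
    stopifnot(host %in% names(chroms), ins %in% names(chroms))
    n <- nrow(chroms[[host]])
    at <- .resolveAt(event, "at", n)
    if (at <= 0L || at >= n) {
      stop("nested fusion breakpoint must be internal (got ", at,
           " of ", n, "); a terminal breakpoint would be an EEJ")
    }
    h <- chroms[[host]]
    chroms[[host]] <- rbind(h[seq_len(at), ], chroms[[ins]],
                            h[seq(at + 1L, n), ])
    chroms[[ins]] <- NULL
    tel <- tel[tel$chromosome_id != ins, ]
    return(.chromListGenome(genome@name, chroms, cds, tel))
  }

  if (kind == "ARM_EXCHANGE") {
    c1 <- event$chr1; c2 <- event$chr2
    stopifnot(c1 %in% names(chroms), c2 %in% names(chroms))
    n1 <- nrow(chroms[[c1]]); n2 <- nrow(chroms[[c2]])
    at1 <- .resolveAt(event, "at1", n1)
    at2 <- .resolveAt(event, "at2", n2)
    stopifnot(at1 > 0L, at1 < n1, at2 > 0L, at2 < n2)
    a <- chroms[[c1]]; b <- chroms[[c2]]
    chroms[[c1]] <- rbind(a[seq_len(at1), ], b[seq(at2 + 1L, n2), ])
    chroms[[c2]] <- rbind(b[seq_len(at2), ], a[seq(at1 + 1L, n1), ])
    r1 <- tel$right[tel$chromosome_id == c1]
    r2 <- tel$right[tel$chromosome_id == c2]
    tel$right[tel$chromosome_id == c1] <- r2
    tel$right[tel$chromosome_id == c2] <- r1
    return(.chromListGenome(genome@name, chroms, cds, tel))
  }

  if (kind == "INVERSION") {
    chr <- event$chr
    stopifnot(chr %in% names(chroms))
    n <- nrow(chroms[[chr]])
    from <- .resolveAt(event, "from", n)
    to <- .resolveAt(event, "to", n)
    stopifnot(from >= 1L, to <= n, from < to)
    d <- chroms[[chr]]
    seg <- d[seq(from, to), ]
    seg <- seg[rev(seq_len(nrow(seg))), ]
    seg$strand <- ifelse(seg$strand == "+", "-", "+")
    d[seq(from, to), ] <- seg
    chroms[[chr]] <- d
    return(.chromListGenome(genome@name, chroms, cds, tel))
  }

  if (kind == "FRACTIONATION") {
    p <- event$prob
    stopifnot(is.numeric(p), p >= 0, p <= 1)
    all <- do.call(rbind, lapply(names(chroms), function(chr) {
      d <- chroms[[chr]]
      if (!nrow(d)) return(NULL)
      data.frame(chr = chr, gene_id = d$gene_id, family_id = d$family_id,
                 stringsAsFactors = FALSE)
    }))
    drop <- character()
    for (ids in split(all$gene_id, all$family_id)) {
      if (length(ids) < 2L) next
      del <- stats::runif(length(ids)) < p
      if (all(del)) {
        del[sample.int(length(ids), 1L)] <- FALSE
      }
      drop <- c(drop, ids[del])
    }
    for (chr in names(chroms)) {
      d <- chroms[[chr]]
      chroms[[chr]] <- d[!d$gene_id %in% drop, , drop = FALSE]
    }
    tel <- tel[tel$chromosome_id %in%
                 names(chroms)[vapply(chroms, nrow, integer(1)) > 0L], ]
    return(.chromListGenome(genome@name, chroms, cds, tel))
  }
  stop("unhandled event kind: ", kind)
}

# ---- root genome ----------------------------------------------------------

.randomCds <- function(nCodons) {
  tab <- .codonTables()
  sense <- which(tab$sense)
  idx <- sense[sample.int(length(sense), nCodons, replace = TRUE)]
  paste(tab$codons[idx], collapse = "")
}

#' Build an ancestral proto-karyotype and its root genome
#'
#' Creates `nChromosomes` proto-chromosomes (labelled `A1`, `A2`, ...),
#' each with `genesPerChromosome` gene models carrying random coding
#' sequences (100-300 codons, i.e. 300-900 bp, no internal stop codons).
#' Each gene founds its own family (`family_id` equal to its own id), so
#' the family labels of descendant genomes trace every gene back to a root
#' gene and hence to a proto-chromosome.
#'
#' @param nChromosomes Number of proto-chromosomes (>= 1).
#' @param genesPerChromosome Genes per proto-chromosome (>= 10).
#' @param seed RNG seed.
#' @param codonRange Range of CDS lengths in codons.
#' @return An [AnnotatedGenome-class] with telomeres at both ends of every
#'   chromosome.
#' @export
buildProtoKaryotype <- function(nChromosomes = 10L,
                                genesPerChromosome = 100L, seed = 1L,
                                codonRange = c(100L, 300L)) {
  if (nChromosomes < 1L) stop("nChromosomes must be >= 1")
  if (genesPerChromosome < 10L) stop("genesPerChromosome must be >= 10")
  set.seed(seed)
  chroms <- list()
  cds <- character()
  gi <- 0L
  for (ci in seq_len(nChromosomes)) {
    ids <- sprintf("g%05d", gi + seq_len(genesPerChromosome))
    gi <- gi + genesPerChromosome
    chroms[[paste0("A", ci)]] <-
      data.frame(gene_id = ids, family_id = ids,
                 strand = sample(c("+", "-"), genesPerChromosome,
                                 replace = TRUE),
                 stringsAsFactors = FALSE)
    nc <- sample(seq(codonRange[1], codonRange[2]), genesPerChromosome,
                 replace = TRUE)
    newCds <- vapply(nc, .randomCds, character(1))
    names(newCds) <- ids
    cds <- c(cds, newCds)
  }
  tel <- do.call(rbind, lapply(names(chroms), .telomereRow))
  .chromListGenome("root", chroms, cds, tel)
}

# ---- sequence divergence --------------------------------------------------

# Core substitution placement on codon-index vectors.  Each codon position
# is marked changed with probability f * p where f is the NG86 synonymous
# (or nonsynonymous) fraction of the position and p the Jukes-Cantor
# expected difference proportion for the requested distance, so that the
# realised expected NG86 estimate of (input, output) equals the requested
# branch length.  Marked positions are replaced by a random synonymous
# (resp. nonsynonymous, non-stop) alternative, re-evaluated codon by codon
# so multiply-hit codons stay consistent.
.evolveCodons <- function(idx, branchLength, dnds = 0) {
  if (branchLength <= 0) return(idx)
  tab <- .codonTables()
  ps <- 0.75 * (1 - exp(-4 * branchLength / 3))
  ka <- branchLength * dnds
  pn <- if (ka > 0) 0.75 * (1 - exp(-4 * ka / 3)) else 0
  n <- length(idx)
  sf <- tab$synfrac[idx, , drop = FALSE]
  synmark <- matrix(stats::runif(3L * n), n, 3L) < sf * ps
  nonmark <- if (pn > 0) {
    matrix(stats::runif(3L * n), n, 3L) < (1 - sf) * pn
  } else {
    matrix(FALSE, n, 3L)
  }
  hit <- which(rowSums(synmark | nonmark) > 0L)
  for (i in hit) {
    cur <- idx[i]
    for (p in 1:3) {
      opts <- NULL
      if (synmark[i, p]) {
        opts <- tab$synAlt[[(p - 1L) * 64L + cur]]
      } else if (nonmark[i, p]) {
        opts <- tab$nonsynAlt[[(p - 1L) * 64L + cur]]
      }
      if (length(opts)) {
        cur <- opts[sample.int(length(opts), 1L)]
      }
    }
    idx[i] <- cur
  }
  idx
}

#' Evolve a coding sequence by a given synonymous distance
#'
#' Places synonymous (and, for `dnds > 0`, nonsynonymous) substitutions so
#' that the expected Nei-Gojobori Ks between input and output equals
#' `branchLength` (and Ka/Ks approximately equals `dnds`).  Substitutions
#' never introduce stop codons.  When the requested distance is so large
#' that the synonymous difference proportion is expected at or beyond the
#' Jukes-Cantor saturation bound, the result carries the attribute
#' `saturated = TRUE`.
#'
#' @param cds Coding sequence (character scalar, length a multiple of 3,
#'   no internal stops).
#' @param branchLength Expected synonymous substitutions per synonymous
#'   site (>= 0).
#' @param dnds Target Ka/Ks ratio (default 0: synonymous changes only).
#' @param seed Optional RNG seed.
#' @return The diverged coding sequence.
#' @export
evolveCds <- function(cds, branchLength, dnds = 0, seed = NULL) {
  stopifnot(branchLength >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (branchLength == 0) return(cds)
  idx <- .codonEncode(cds)
  out <- .codonDecode(.evolveCodons(idx, branchLength, dnds))
  # ps saturates at 3/4; beyond ~95% of the bound the NG86 estimate of the
  # realised divergence is no longer informative
  if (0.75 * (1 - exp(-4 * branchLength / 3)) > 0.7125) {
    attr(out, "saturated") <- TRUE
  }
  out
}

.evolveGenomeCds <- function(genome, branchLength, dnds = 0.2) {
  if (branchLength <= 0 || !length(genome@cds)) return(genome)
  cds <- genome@cds
  enc <- lapply(cds, .codonEncode)
  lens <- lengths(enc)
  big <- .evolveCodons(unlist(enc, use.names = FALSE), branchLength, dnds)
  tab <- .codonTables()
  str <- tab$codons[big]
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  out <- vapply(seq_along(lens), function(i) {
    paste(str[starts[i]:ends[i]], collapse = "")
  }, character(1))
  names(out) <- names(cds)
  genome@cds <- out
  genome
}

# ---- trajectory simulation ------------------------------------------------

#' Simulate genome evolution along a fixture tree
#'
#' Walks the fixture's branches in order.  On each branch the karyotype
#' events are applied first (at the parent-node age), then every coding
#' sequence accumulates `rate * duration` expected synonymous
#' substitutions per site.  Extant genomes keep family ids linking
#' orthologs and paralogs back to root genes, and the full ground truth
#' (events, genealogy, rates, node ages, per-node karyotypes as
#' proto-label sequences) is returned as a [TruthLog-class].
#'
#' @param fixture A fixture as returned by [coconutFixture()]: a list with
#'   `root` (chromosome/gene counts), `ages` (named node ages, My),
#'   `branches` (ordered branch specs with `from`, `to`, `rate`, `dnds`,
#'   `events`) and `lineages` (extant node names).
#' @param seed RNG seed governing all randomness.
#' @return List with `genomes` (named [AnnotatedGenome-class] per extant
#'   lineage) and `truth` (a [TruthLog-class]).
#' @export
simulateTrajectory <- function(fixture, seed = 1L) {
  set.seed(seed)
  root <- buildProtoKaryotype(fixture$root$n_chromosomes,
                              fixture$root$genes_per_chromosome,
                              seed = seed + 7L)
  set.seed(seed + 13L)
  protoLabels <- stats::setNames(root@genes$chromosome_id,
                                 root@genes$gene_id)
  states <- list()
  states[[fixture$root_node]] <- root
  events <- NULL
  karyos <- list()
  karyos[[fixture$root_node]] <- .truthKaryotype(root, protoLabels)

  for (br in fixture$branches) {
    if (is.null(states[[br$from]])) {
      stop("branch from unknown node: ", br$from)
    }
    g <- states[[br$from]]
    for (ev in br$events) {
      evObj <- do.call(evolutionEvent, ev)
      .checkEventRefs(g, evObj)
      g <- applyEvent(g, evObj)
      events <- rbind(events, data.frame(
        branch = paste0(br$from, "->", br$to), kind = ev$kind,
        detail = .eventDetail(ev),
        age = fixture$ages[[br$from]], stringsAsFactors = FALSE))
    }
    dur <- fixture$ages[[br$from]] - fixture$ages[[br$to]]
    dnds <- if (is.null(br$dnds)) 0.2 else br$dnds
    g <- .evolveGenomeCds(g, br$rate * dur, dnds)
    g@name <- br$to
    states[[br$to]] <- g
    karyos[[br$to]] <- .truthKaryotype(g, protoLabels)
  }

  genomes <- states[fixture$lineages]
  genealogy <- do.call(rbind, lapply(names(genomes), function(nm) {
    gg <- genomes[[nm]]@genes
    data.frame(genome = nm, gene_id = gg$gene_id,
               root_gene = gg$family_id, stringsAsFactors = FALSE)
  }))
  rates <- vapply(fixture$branches, function(br) br$rate, numeric(1))
  names(rates) <- vapply(fixture$branches,
                         function(br) paste0(br$from, "->", br$to),
                         character(1))
  truth <- new("TruthLog",
               events = if (is.null(events)) {
                 data.frame(branch = character(), kind = character(),
                            detail = character(), age = numeric())
               } else events,
               genealogy = genealogy, rates = rates,
               ages = unlist(fixture$ages),
               extra = list(protoLabels = protoLabels,
                            karyotypes = karyos))
  list(genomes = genomes, truth = truth)
}

.checkEventRefs <- function(genome, event) {
  chrs <- names(genome@chromosomeLengths)
  refs <- unlist(event[names(event) %in%
                         c("chr1", "chr2", "chr", "host", "insert")])
  miss <- setdiff(refs, chrs)
  if (length(miss)) {
    stop("event refers to missing chromosome(s): ",
         paste(miss, collapse = ", "))
  }
}

.eventDetail <- function(ev) {
  flds <- setdiff(names(ev), "kind")
  paste(sprintf("%s=%s", flds,
                vapply(ev[flds], function(x) paste(x, collapse = ","),
                       character(1))),
        collapse = ";")
}

# Proto-label sequence per chromosome of a (possibly internal) state, with
# runs shorter than minRun dropped to suppress stray relics.
.truthKaryotype <- function(genome, protoLabels, minRun = 5L) {
  g <- genome@genes
  labs <- unname(protoLabels[g$family_id])
  out <- lapply(split(labs[order(g$chromosome_id, g$ordinal)],
                      g$chromosome_id[order(g$chromosome_id, g$ordinal)]),
                function(v) {
                  r <- rle(v)
                  keep <- r$lengths >= minRun
                  vv <- rle(r$values[keep])$values
                  vv
                })
  out[lengths(out) > 0L]
}

#' The packaged coconut-descent trajectory fixture
#'
#' Encodes a three-ingroup-plus-calibrator simulation of the descent of a
#' 16-chromosome coconut-like genome from 10 monocot proto-chromosomes:
#' two end-to-end joins reduce 10 proto-chromosomes to 8 (node B); the tau
#' WGD doubles them to 16 (node C); five EEJ, two arm exchanges and two
#' nested fusions reduce them to 9 (node D); the omega WGD doubles them to
#' 18 (node E); and five arm exchanges plus two nested fusions form the
#' extant 16 chromosomes.  Side lineages: an unduplicated basal outgroup
#' (splitting at node A), a WGT lineage sharing tau (splitting after node
#' C, sigma triplication), and an unduplicated eudicot-like calibrator
#' splitting at the root (the monocot-eudicot calibration point,
#' 163-184 Mya, midpoint used as the root age).  Event ages use the
#' calibration midpoints (tau 137.5 My within 129-146, omega 50 My within
#' 47-53).  The WGT lineage runs 1.5x faster than the base substitution
#' rate, so the lineage rate correction has work to do.
#'
#' @param genesPerChromosome Genes per proto-chromosome (default 100).
#' @return A fixture list understood by [simulateTrajectory()].
#' @export
coconutFixture <- function(genesPerChromosome = 100L) {
  path <- system.file("extdata", "coconut_descent_fixture.json",
                      package = "KaryoTracer", mustWork = TRUE)
  fx <- jsonlite::read_json(path, simplifyVector = FALSE)
  fx$root$genes_per_chromosome <- as.integer(genesPerChromosome)
  fx$ages <- lapply(fx$ages, as.numeric)
  fx$branches <- lapply(fx$branches, function(br) {
    br$rate <- as.numeric(br$rate)
    br$events <- lapply(br$events, function(ev) {
      lapply(ev, function(x) if (is.character(x)) x else as.numeric(x))
    })
    br
  })
  fx$lineages <- unlist(fx$lineages)
  fx
}

#' Simulate a near-identical genome pair for PAV testing
#'
#' Builds a random reference genome sequence with annotated genes, then
#' derives a second accession that differs by a known set of deletions and
#' insertions.  Inserted sequence is novel random sequence, except for a
#' controllable fraction copied from elsewhere in the reference (such
#' segments are present in both accessions and must be filtered out by the
#' PAV coverage rule).  One-to-one alignment blocks between the two
#' accessions (the aligner output the PAV caller consumes) are emitted
#' from the construction, along with the ground truth.
#'
#' @param seed RNG seed.
#' @param genomeLength Reference chromosome length in bp.
#' @param nGenes Number of annotated genes.
#' @param nDeletions,nInsertions Number of deletion/insertion events
#'   applied to the second accession.
#' @param indelRange Length range of each event (bp).
#' @param copiedFraction Fraction of insertions copied from elsewhere in
#'   the reference rather than novel.
#' @return List with `genomeA`, `genomeB` ([AnnotatedGenome-class] with
#'   sequences), `blocks` (one-to-one alignment block table), and `truth`
#'   (data.frame of simulated events with genome, interval, kind,
#'   `novel` flag, and deleted gene ids).
#' @export
simulatePavPair <- function(seed = 1L, genomeLength = 400000L,
                            nGenes = 150L, nDeletions = 6L,
                            nInsertions = 6L,
                            indelRange = c(2000L, 8000L),
                            copiedFraction = 0.3) {
  set.seed(seed)
  refSeq <- paste(sample(.NTS, genomeLength, replace = TRUE),
                  collapse = "")
  geneLen <- 1200L
  slots <- floor(genomeLength / (nGenes + 1L))
  starts <- (seq_len(nGenes)) * slots
  genes <- data.frame(gene_id = sprintf("pg%04d", seq_len(nGenes)),
                      chromosome_id = "chrA", start = starts,
                      end = starts + geneLen, strand = "+",
                      family_id = sprintf("pg%04d", seq_len(nGenes)),
                      stringsAsFactors = FALSE)
  genomeA <- AnnotatedGenome("accA", genes,
                             chromosomeLengths = c(chrA = genomeLength),
                             sequence = c(chrA = refSeq))

  # choose non-overlapping event loci on the reference
  nEv <- nDeletions + nInsertions
  lens <- sample(seq(indelRange[1], indelRange[2]), nEv, replace = TRUE)
  # one event per equal-width slot keeps events and their flanks apart
  slotW <- (genomeLength - 2L * max(lens) - 4000L) %/% nEv
  if (slotW <= max(lens) + 2000L) {
    stop("genome too short for the requested events")
  }
  jitter <- sample.int(slotW - max(lens) - 2000L, nEv, replace = TRUE)
  locs <- max(lens) + 2000L + (seq_len(nEv) - 1L) * slotW + jitter
  kinds <- sample(rep(c("deletion", "insertion"),
                      c(nDeletions, nInsertions)))
  novel <- ifelse(kinds == "insertion",
                  stats::runif(nEv) >= copiedFraction, NA)

  pieces <- character()
  truth <- NULL
  blocks <- NULL
  posA <- 1L   # next unconsumed reference position
  posB <- 1L   # current length of accession B + 1
  for (i in seq_len(nEv)) {
    segEnd <- locs[i] - 1L
    seg <- substr(refSeq, posA, segEnd)
    blocks <- rbind(blocks, data.frame(
      chr_a = "chrA", start_a = posA - 1L, end_a = segEnd,
      chr_b = "chrB", start_b = posB - 1L, end_b = posB - 1L + nchar(seg),
      identity = 1.0, one_to_one = TRUE, stringsAsFactors = FALSE))
    pieces <- c(pieces, seg)
    posB <- posB + nchar(seg)
    if (kinds[i] == "deletion") {
      truth <- rbind(truth, data.frame(
        genome = "accA", kind = "deletion", start = locs[i] - 1L,
        end = locs[i] - 1L + lens[i], novel = TRUE,
        stringsAsFactors = FALSE))
      posA <- locs[i] + lens[i]
    } else {
      insSeq <- if (novel[i]) {
        paste(sample(.NTS, lens[i], replace = TRUE), collapse = "")
      } else {
        src <- sample.int(genomeLength - lens[i], 1L)
        substr(refSeq, src, src + lens[i] - 1L)
      }
      truth <- rbind(truth, data.frame(
        genome = "accB", kind = "insertion", start = posB - 1L,
        end = posB - 1L + lens[i], novel = novel[i],
        stringsAsFactors = FALSE))
      pieces <- c(pieces, insSeq)
      posB <- posB + lens[i]
      posA <- locs[i]
    }
  }
  seg <- substr(refSeq, posA, genomeLength)
  blocks <- rbind(blocks, data.frame(
    chr_a = "chrA", start_a = posA - 1L, end_a = genomeLength,
    chr_b = "chrB", start_b = posB - 1L, end_b = posB - 1L + nchar(seg),
    identity = 1.0, one_to_one = TRUE, stringsAsFactors = FALSE))
  pieces <- c(pieces, seg)
  seqB <- paste(pieces, collapse = "")

  # lift gene annotations through the alignment blocks onto accession B;
  # genes overlapping a deletion have no complete image and are dropped.
  # `deletedGenes` reports the genes losing > 80% of their length (the
  # ones the PAV gene rule is expected to call).
  delGenes <- character()
  delMostly <- character()
  for (i in which(kinds == "deletion")) {
    ov <- pmin(genes$end, locs[i] - 1L + lens[i]) -
      pmax(genes$start, locs[i] - 1L)
    hit <- ov > 0L
    delGenes <- c(delGenes, genes$gene_id[hit])
    delMostly <- c(delMostly,
                   genes$gene_id[ov / (genes$end - genes$start) > 0.8])
  }
  lifted <- genes[!genes$gene_id %in% delGenes, , drop = FALSE]
  off <- rep(NA_integer_, nrow(lifted))
  for (j in seq_len(nrow(blocks))) {
    inb <- lifted$start >= blocks$start_a[j] & lifted$end <= blocks$end_a[j]
    off[inb] <- blocks$start_b[j] - blocks$start_a[j]
  }
  lifted <- lifted[!is.na(off), , drop = FALSE]
  off <- off[!is.na(off)]
  lifted$start <- lifted$start + off
  lifted$end <- lifted$end + off
  lifted$chromosome_id <- "chrB"
  genomeB <- AnnotatedGenome(
    "accB", lifted,
    chromosomeLengths = c(chrB = nchar(seqB)),
    sequence = c(chrB = seqB))
  list(genomeA = genomeA, genomeB = genomeB, blocks = blocks,
       truth = cbind(truth, event_id = sprintf("ev%02d",
                                               seq_len(nrow(truth)))),
       deletedGenes = delMostly, disruptedGenes = delGenes)
}
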