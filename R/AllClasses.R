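#' @import methods
NULL

#' AnnotatedGenome: ordered gene models per chromosome
#'
#' The universal substrate of the pipeline: a named genome whose
#' chromosomes carry ordered gene models, optionally with coding sequences
#' and full chromosome sequences.  Coordinates are stored 0-based
#' half-open internally; the GFF3 reader/writer converts from/to the
#' 1-based inclusive convention at the I/O boundary.  `ordinal` is the
#' 0-based rank of a gene along its chromosome in start order (ties broken
#' by gene id).
#'
#' @slot name Genome name.
#' @slot genes data.frame with columns `gene_id`, `chromosome_id`,
#'   `start`, `end`, `strand`, `ordinal`, `family_id`.
#' @slot cds Named character vector of coding sequences (may be empty).
#' @slot chromosomeLengths Named numeric vector of chromosome lengths (bp).
#' @slot telomeres data.frame with columns `chromosome_id`, `left`,
#'   `right`: whether each chromosome end still carries a telomere
#'   (simulator-provided; assumed TRUE for real data).
#' @slot sequence Named character vector of full chromosome sequences
#'   (used by the PAV module; may be empty).
#' @export
setClass("AnnotatedGenome",
         representation(name = "character", genes = "data.frame",
                        cds = "character",
                        chromosomeLengths = "numeric",
                        telomeres = "data.frame",
                        sequence = "character"))

setValidity("AnnotatedGenome", function(object) {
  g <- object@genes
  need <- c("gene_id", "chromosome_id", "start", "end", "strand",
            "ordinal", "family_id")
  if (!all(need %in% names(g))) {
    return(paste("genes must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(g$gene_id)) {
    return("duplicate gene_id")
  }
  if (nrow(g) && any(g$start >= g$end)) {
    return("gene start must be < end")
  }
  if (nrow(g) && !all(g$chromosome_id %in% names(object@chromosomeLengths))) {
    return("gene on unknown chromosome")
  }
  for (chr in unique(g$chromosome_id)) {
    o <- g$ordinal[g$chromosome_id == chr]
    if (!identical(sort(o), seq_along(o) - 1L)) {
      return(sprintf("ordinals of %s are not a permutation of 0..n-1", chr))
    }
    s <- g$start[g$chromosome_id == chr][order(o)]
    if (is.unsorted(s)) {
      return(sprintf("ordinals of %s not consistent with start order", chr))
    }
  }
  if (length(object@cds)) {
    if (is.null(names(object@cds)) ||
        !all(names(object@cds) %in% g$gene_id)) {
      return("cds names must be gene ids of this genome")
    }
    if (any(nchar(object@cds) %% 3L != 0L)) {
      return("cds length must be a multiple of 3")
    }
  }
  TRUE
})

#' Construct an AnnotatedGenome
#'
#' @param name Genome name.
#' @param genes data.frame of gene models; `ordinal` and `family_id` are
#'   filled in when absent (ordinals by start position, ties by gene id).
#' @param cds Optional named character vector of coding sequences.
#' @param chromosomeLengths Optional named lengths; defaults to the last
#'   gene end per chromosome.
#' @param telomeres Optional telomere flag table; defaults to TRUE at both
#'   ends of every chromosome.
#' @param sequence Optional named chromosome sequences.
#' @return An [AnnotatedGenome-class] object.
#' @export
AnnotatedGenome <- function(name, genes, cds = character(),
                            chromosomeLengths = NULL, telomeres = NULL,
                            sequence = character()) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (is.null(genes$strand)) genes$strand <- "+"
  if (is.null(genes$family_id)) genes$family_id <- genes$gene_id
  genes <- genes[order(genes$chromosome_id, genes$start, genes$gene_id), ,
                 drop = FALSE]
  ords <- unlist(lapply(split(seq_len(nrow(genes)), genes$chromosome_id),
                        function(i) seq_along(i) - 1L), use.names = FALSE)
  genes$ordinal <- NA_integer_
  genes$ordinal[order(genes$chromosome_id)] <- ords
  genes <- genes[order(genes$chromosome_id, genes$ordinal), , drop = FALSE]
  genes <- genes[, c("gene_id", "chromosome_id", "start", "end",
                     "strand", "ordinal", "family_id")]
  rownames(genes) <- NULL
  chrs <- unique(genes$chromosome_id)
  if (is.null(chromosomeLengths)) {
    chromosomeLengths <- vapply(split(genes$end, genes$chromosome_id), max,
                                numeric(1))[chrs]
  }
  if (is.null(telomeres)) {
    telomeres <- data.frame(chromosome_id = names(chromosomeLengths),
                            left = TRUE, right = TRUE,
                            stringsAsFactors = FALSE)
  }
  new("AnnotatedGenome", name = name, genes = genes, cds = cds,
      chromosomeLengths = chromosomeLengths, telomeres = telomeres,
      sequence = sequence)
}

#' @describeIn AnnotatedGenome-class Genome name.
#' @param x,object An `AnnotatedGenome`.
#' @export
genomeName <- function(x) x@name

#' @describeIn AnnotatedGenome-class Gene model table.
#' @export
geneTable <- function(x) x@genes

#' @describeIn AnnotatedGenome-class Number of gene models.
#' @export
geneCount <- function(x) nrow(x@genes)

#' @describeIn AnnotatedGenome-class Chromosome names, in order.
#' @export
chromosomeNames <- function(x) names(x@chromosomeLengths)

#' @describeIn AnnotatedGenome-class Named chromosome lengths (bp).
#' @export
chromosomeLengths <- function(x) x@chromosomeLengths

#' @describeIn AnnotatedGenome-class Named coding sequences.
#' @export
cdsSequences <- function(x) x@cds

setMethod("show", "AnnotatedGenome", function(object) {
  cat(sprintf("AnnotatedGenome '%s': %d chromosomes, %d genes, %d CDS\n",
              object@name, length(object@chromosomeLengths),
              nrow(object@genes), length(object@cds)))
})

#' CollinearBlockSet: chained anchor-pair blocks between two genomes
#'
#' A set of collinear blocks, each a run of homologous anchor gene pairs
#' whose ordinals increase strictly in genome A and increase (parallel) or
#' decrease (antiparallel) strictly in genome B.  Blocks may carry
#' per-anchor Ks values, a block-median Ks, and an event-layer label.
#'
#' @slot blocks data.frame with one row per block: `block_id`, `genome_a`,
#'   `genome_b`, `chr_a`, `chr_b`, `orientation`, `n_anchors`,
#'   `median_ks`, `event_layer`.
#' @slot anchors data.frame with one row per anchor pair: `block_id`,
#'   `gene_a`, `gene_b`, `chr_a`, `chr_b`, `ord_a`, `ord_b`, `score`, `ks`.
#' @export
setClass("CollinearBlockSet",
         representation(blocks = "data.frame", anchors = "data.frame"))

setValidity("CollinearBlockSet", function(object) {
  b <- object@blocks
  a <- object@anchors
  if (nrow(a) && !all(a$block_id %in% b$block_id)) {
    return("anchor with unknown block_id")
  }
  for (id in b$block_id) {
    aa <- a[a$block_id == id, ]
    if (nrow(aa) < 2L) next
    if (is.unsorted(aa$ord_a, strictly = TRUE)) {
      return(sprintf("block %s: ord_a not strictly increasing", id))
    }
    db <- diff(aa$ord_b)
    if (!(all(db > 0) || all(db < 0))) {
      return(sprintf("block %s: ord_b not strictly monotone", id))
    }
  }
  TRUE
})

CollinearBlockSet <- function(blocks, anchors) {
  blocks <- as.data.frame(blocks, stringsAsFactors = FALSE)
  anchors <- as.data.frame(anchors, stringsAsFactors = FALSE)
  if (is.null(blocks$median_ks)) blocks$median_ks <- NA_real_
  if (is.null(blocks$event_layer)) blocks$event_layer <- NA_character_
  if (nrow(anchors) && is.null(anchors$ks)) anchors$ks <- NA_real_
  rownames(blocks) <- rownames(anchors) <- NULL
  new("CollinearBlockSet", blocks = blocks, anchors = anchors)
}

#' @describeIn CollinearBlockSet-class Block summary table.
#' @param x,object A `CollinearBlockSet`.
#' @export
blockTable <- function(x) x@blocks

#' @describeIn CollinearBlockSet-class Anchor pair table.
#' @export
anchorTable <- function(x) x@anchors

setMethod("show", "CollinearBlockSet", function(object) {
  cat(sprintf("CollinearBlockSet: %d blocks, %d anchors\n",
              nrow(object@blocks), nrow(object@anchors)))
})

setMethod("length", "CollinearBlockSet", function(x) nrow(x@blocks))

#' KsPeakSet: Gaussian components fitted to a Ks density curve
#'
#' @slot components data.frame with columns `mean`, `sd`, `weight`,
#'   sorted by `mean`.
#' @slot k Selected component count.
#' @slot residual Residual sum of squares of the selected fit.
#' @slot bandwidth KDE bandwidth of the underlying curve.
#' @export
setClass("KsPeakSet",
         representation(components = "data.frame", k = "integer",
                        residual = "numeric", bandwidth = "numeric"))

setValidity("KsPeakSet", function(object) {
  cc <- object@components
  if (!all(c("mean", "sd", "weight") %in% names(cc))) {
    return("components must have mean, sd, weight")
  }
  if (any(cc$weight < 0)) return("weights must be >= 0")
  if (is.unsorted(cc$mean)) return("components must be sorted by mean")
  TRUE
})

#' @describeIn KsPeakSet-class Fitted component table.
#' @param x,object A `KsPeakSet`.
#' @export
peakComponents <- function(x) x@components

#' @describeIn KsPeakSet-class Means of the fitted components.
#' @export
peakMeans <- function(x) x@components$mean

setMethod("show", "KsPeakSet", function(object) {
  cat(sprintf("KsPeakSet: k = %d (RSS %.4g)\n", object@k, object@residual))
  print(format(object@components, digits = 4))
})

#' CorrectionModel: lineage Ks rate correction and calibration
#'
#' Per-species ortholog-vs-outgroup peak positions, the reference peak
#' (their arithmetic mean), multiplicative correction coefficients
#' `c_i = reference / K_i`, and the calibration age range in My.
#'
#' @slot peaks Named numeric vector of observed ortholog peaks per species.
#' @slot reference Arithmetic mean of the peaks.
#' @slot coefficients Named correction coefficients.
#' @slot calibration Numeric length-2 age range (My), default 163-184.
#' @export
setClass("CorrectionModel",
         representation(peaks = "numeric", reference = "numeric",
                        coefficients = "numeric", calibration = "numeric"))

setValidity("CorrectionModel", function(object) {
  if (any(object@coefficients <= 0)) return("coefficients must be > 0")
  if (length(object@calibration) != 2L ||
      object@calibration[1] > object@calibration[2]) {
    return("calibration must be an increasing length-2 range")
  }
  TRUE
})

#' @describeIn CorrectionModel-class Correction coefficients.
#' @param x,object A `CorrectionModel`.
#' @export
correctionCoefficients <- function(x) x@coefficients

setMethod("show", "CorrectionModel", function(object) {
  cat(sprintf(
    "CorrectionModel: %d species, reference peak %.4f, calibration %g-%g Mya\n",
    length(object@peaks), object@reference, object@calibration[1],
    object@calibration[2]))
})

#' NodeKaryotype: a karyotype as proto-chromosome label sequences
#'
#' Chromosomes at one evolutionary node, each an ordered vector of
#' proto-chromosome labels (segment signs are not tracked: inversions are
#' normalised away before event classification).
#'
#' @slot node Node identifier.
#' @slot chromosomes Named list of character vectors of proto labels.
#' @export
setClass("NodeKaryotype",
         representation(node = "character", chromosomes = "list"))

NodeKaryotype <- function(node, chromosomes) {
  if (is.null(names(chromosomes)) && length(chromosomes)) {
    names(chromosomes) <- sprintf("%s_chr%02d", node,
                                  seq_along(chromosomes))
  }
  new("NodeKaryotype", node = node,
      chromosomes = lapply(chromosomes, as.character))
}

#' @describeIn NodeKaryotype-class Number of chromosomes.
#' @param x,object A `NodeKaryotype`.
#' @export
chromosomeCount <- function(x) length(x@chromosomes)

#' @describeIn NodeKaryotype-class Label sequences per chromosome.
#' @export
karyotypeChromosomes <- function(x) x@chromosomes

setMethod("show", "NodeKaryotype", function(object) {
  cat(sprintf("NodeKaryotype '%s': %d chromosomes\n", object@node,
              length(object@chromosomes)))
  for (nm in names(object@chromosomes)) {
    cat(sprintf("  %s: %s\n", nm,
                paste(object@chromosomes[[nm]], collapse = "-")))
  }
})

#' Trajectory: karyotypes at successive nodes plus per-branch events
#'
#' @slot karyotypes Ordered list of [NodeKaryotype-class] objects
#'   (root first).
#' @slot events Named list (one entry per branch, `"parent->child"`) of
#'   data.frames with columns `kind` and `detail`.
#' @slot multiplicities Named numeric: ploidy multiplier applied on each
#'   branch (2 for a WGD, 3 for a WGT, 1 otherwise).
#' @export
setClass("Trajectory",
         representation(karyotypes = "list", events = "list",
                        multiplicities = "numeric"))

#' @describeIn Trajectory-class Chromosome counts per node.
#' @param x,object A `Trajectory`.
#' @export
nodeCounts <- function(x) {
  vapply(x@karyotypes, chromosomeCount, integer(1))
}

#' @describeIn Trajectory-class Per-branch event tables.
#' @export
branchEvents <- function(x) x@events

setMethod("show", "Trajectory", function(object) {
  counts <- nodeCounts(object)
  cat("Trajectory:",
      paste(sprintf("%s(%d)", names(counts), counts), collapse = " -> "),
      "\n")
  for (br in names(object@events)) {
    ev <- object@events[[br]]
    if (!nrow(ev)) next
    tally <- table(ev$kind)
    cat(sprintf("  %s: %s\n", br,
                paste(sprintf("%dx %s", as.integer(tally), names(tally)),
                      collapse = ", ")))
  }
})

#' TruthLog: simulator ground truth
#'
#' Event history, gene genealogy, true lineage rates and node ages emitted
#' by the genome-evolution simulator; the reference for recovery tests.
#'
#' @slot events data.frame of applied events (`branch`, `kind`, `detail`).
#' @slot genealogy data.frame mapping every extant gene to its root gene
#'   (`genome`, `gene_id`, `root_gene`).
#' @slot rates Named numeric: synonymous substitutions/site/My per lineage.
#' @slot ages Named numeric: node ages in My.
#' @slot extra List of additional ground-truth records.
#' @export
setClass("TruthLog",
         representation(events = "data.frame", genealogy = "data.frame",
                        rates = "numeric", ages = "numeric",
                        extra = "list"))

setMethod("show", "TruthLog", function(object) {
  cat(sprintf("TruthLog: %d events, %d genealogy records, %d lineages\n",
              nrow(object@events), nrow(object@genealogy),
              length(object@rates)))
})
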