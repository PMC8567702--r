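#' Read an annotated genome from GFF3 (+ optional CDS FASTA)
#'
#' Gene features are taken from the GFF3 `gene` records; genes are ordered
#' by start coordinate per chromosome (ties broken by gene id) and 0-based
#' ordinals assigned.  GFF3 1-based inclusive coordinates are converted to
#' the internal 0-based half-open convention.  When a CDS FASTA is given,
#' sequences are attached by ID match; IDs absent from the FASTA produce a
#' warning and the gene keeps no CDS.  Optional `chromosome` features may
#' carry `telomere_left`/`telomere_right` attributes (as written by
#' [writeAnnotatedGenome()]); otherwise telomeres are assumed present.
#'
#' @param gff3Path Path to a GFF3 file.
#' @param cdsFastaPath Optional path to a FASTA of coding sequences named
#'   by gene id.
#' @param name Genome name; defaults to the file base name.
#' @return An [AnnotatedGenome-class].
#' @importFrom rtracklayer import
#' @importFrom Biostrings readDNAStringSet
#' @export
readAnnotatedGenome <- function(gff3Path, cdsFastaPath = NULL,
                                name = NULL) {
  if (!file.exists(gff3Path)) {
    stop("file not found: ", gff3Path)
  }
  lines <- readLines(gff3Path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1]]
    stop(sprintf("malformed GFF3 line %d in %s: expected 9 fields, got %d",
                 bad, gff3Path, nf[which(nf != 9L)[1]]))
  }
  gr <- rtracklayer::import(gff3Path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  if (length(genes) == 0L) {
    stop("no gene features in ", gff3Path)
  }
  md <- S4Vectors::mcols(genes)
  fam <- if ("family_id" %in% names(md)) as.character(md$family_id)
         else as.character(md$ID)
  gdf <- data.frame(
    gene_id = as.character(md$ID),
    chromosome_id = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(genes),
    strand = ifelse(as.character(GenomicRanges::strand(genes)) == "-",
                    "-", "+"),
    family_id = fam,
    stringsAsFactors = FALSE)

  chrFeat <- gr[gr$type == "chromosome"]
  telomeres <- NULL
  chromLens <- NULL
  if (length(chrFeat)) {
    cm <- S4Vectors::mcols(chrFeat)
    chromLens <- stats::setNames(GenomicRanges::end(chrFeat),
                                 as.character(cm$ID))
    if (all(c("telomere_left", "telomere_right") %in% names(cm))) {
      telomeres <- data.frame(
        chromosome_id = as.character(cm$ID),
        left = as.logical(cm$telomere_left),
        right = as.logical(cm$telomere_right),
        stringsAsFactors = FALSE)
    }
  }

  cds <- character()
  if (!is.null(cdsFastaPath)) {
    fa <- Biostrings::readDNAStringSet(cdsFastaPath)
    names(fa) <- sub("\\s.*$", "", names(fa))
    hit <- gdf$gene_id %in% names(fa)
    if (!all(hit)) {
      warning(sum(!hit), " gene(s) without CDS in FASTA; cds left empty")
    }
    cds <- stats::setNames(as.character(fa[gdf$gene_id[hit]]),
                           gdf$gene_id[hit])
  }
  if (is.null(name)) {
    name <- sub("\\.gff3?$", "", basename(gff3Path))
  }
  AnnotatedGenome(name = name, genes = gdf, cds = cds,
                  chromosomeLengths = chromLens, telomeres = telomeres)
}

#' Write an annotated genome as GFF3 (+ CDS FASTA)
#'
#' Emits one `chromosome` feature per chromosome (carrying length and
#' telomere flags) and one `gene` feature per gene model (carrying
#' `family_id`), plus a FASTA of coding sequences when present.
#' `readAnnotatedGenome()` on the emitted files reproduces the object.
#'
#' @param genome An [AnnotatedGenome-class].
#' @param gff3Path Output GFF3 path.
#' @param cdsFastaPath Optional output FASTA path for coding sequences.
#' @importFrom rtracklayer export
#' @importFrom Biostrings DNAStringSet writeXStringSet
#' @export
writeAnnotatedGenome <- function(genome, gff3Path, cdsFastaPath = NULL) {
  g <- genome@genes
  tel <- genome@telomeres
  tel <- tel[match(names(genome@chromosomeLengths), tel$chromosome_id), ]
  chrGr <- GenomicRanges::GRanges(
    seqnames = names(genome@chromosomeLengths),
    ranges = IRanges::IRanges(1L, as.integer(genome@chromosomeLengths)),
    strand = "+",
    type = "chromosome",
    ID = names(genome@chromosomeLengths),
    telomere_left = tel$left, telomere_right = tel$right)
  geneGr <- GenomicRanges::GRanges(
    seqnames = g$chromosome_id,
    ranges = IRanges::IRanges(g$start + 1L, g$end),
    strand = g$strand,
    type = "gene", ID = g$gene_id, family_id = g$family_id)
  gr <- suppressWarnings(c(chrGr, geneGr))
  rtracklayer::export(gr, gff3Path, format = "gff3")
  if (!is.null(cdsFastaPath) && length(genome@cds)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome@cds),
                                cdsFastaPath)
  }
  invisible(gff3Path)
}

#' Read a pairwise homology table
#'
#' Reads a tab-separated table of putative homologous gene pairs (such as
#' BLASTP output reduced to `gene_a`, `gene_b`, `score`, `e_value`) and
#' retains records with `e_value` strictly below the cutoff.  Rows with a
#' non-numeric e-value are rejected with a warning.  Pairs are stored at
#' most once: (a,b) and (b,a) are collapsed to the canonical ordering,
#' keeping the record with the smallest e-value.
#'
#' @param path Path to the table.  Three columns are interpreted as
#'   `gene_a`, `gene_b`, `e_value`; four or more as `gene_a`, `gene_b`,
#'   `score`, `e_value`.
#' @param eValueCutoff Retain records with `e_value <` this value
#'   (default `1e-5`).
#' @return data.frame with columns `gene_a`, `gene_b`, `score`, `e_value`.
#' @export
readHomologyTable <- function(path, eValueCutoff = 1e-5) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           colClasses = "character")
  if (ncol(raw) < 3L) {
    stop("homology table needs at least 3 columns")
  }
  if (ncol(raw) == 3L) {
    df <- data.frame(gene_a = raw[[1]], gene_b = raw[[2]], score = NA,
                     e_value = raw[[3]], stringsAsFactors = FALSE)
  } else {
    df <- data.frame(gene_a = raw[[1]], gene_b = raw[[2]],
                     score = raw[[3]], e_value = raw[[4]],
                     stringsAsFactors = FALSE)
  }
  ev <- suppressWarnings(as.numeric(df$e_value))
  if (anyNA(ev)) {
    warning(sum(is.na(ev)), " row(s) with non-numeric e-value rejected")
  }
  df$e_value <- ev
  df$score <- suppressWarnings(as.numeric(df$score))
  df <- df[!is.na(df$e_value) & df$e_value < eValueCutoff, , drop = FALSE]
  # canonical-pair deduplication, best (lowest) e-value wins
  lo <- pmin(df$gene_a, df$gene_b)
  hi <- pmax(df$gene_a, df$gene_b)
  key <- paste(lo, hi, sep = "\r")
  df <- df[order(df$e_value), , drop = FALSE]
  df <- df[!duplicated(key[order(df$e_value)]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build a homology table in memory
#'
#' Convenience constructor matching the on-disk layout used by
#' [readHomologyTable()].
#'
#' @param gene_a,gene_b Gene id vectors.
#' @param score Optional similarity scores.
#' @param e_value Optional e-values (default 0).
#' @return data.frame with columns `gene_a`, `gene_b`, `score`, `e_value`.
#' @export
homologyTable <- function(gene_a, gene_b, score = 1, e_value = 0) {
  data.frame(gene_a = gene_a, gene_b = gene_b,
             score = rep_len(score, length(gene_a)),
             e_value = rep_len(e_value, length(gene_a)),
             stringsAsFactors = FALSE)
}

#' Write / read a collinear block table
#'
#' Tab-separated, one row per block: block id, genome and chromosome pair,
#' orientation, anchor pairs as a semicolon-separated list of
#' `gene_a|gene_b|ord_a|ord_b|score|ks` records, the block-median Ks and
#' the event-layer label.  The round trip `readBlockTable(writeBlockTable(x))`
#' is lossless (numbers kept to full double precision).
#'
#' @param blocks A [CollinearBlockSet-class].
#' @param path Output (input) path.
#' @return `writeBlockTable` returns the path invisibly; `readBlockTable`
#'   returns a [CollinearBlockSet-class].
#' @export
writeBlockTable <- function(blocks, path) {
  b <- blocks@blocks
  a <- blocks@anchors
  fmt <- function(x) {
    ifelse(is.na(x), "NA", sprintf("%.12g", x))
  }
  anchorStr <- vapply(b$block_id, function(id) {
    aa <- a[a$block_id == id, , drop = FALSE]
    paste(sprintf("%s|%s|%d|%d|%s|%s", aa$gene_a, aa$gene_b,
                  aa$ord_a, aa$ord_b, fmt(aa$score), fmt(aa$ks)),
          collapse = ";")
  }, character(1))
  out <- data.frame(block_id = b$block_id, genome_a = b$genome_a,
                    genome_b = b$genome_b, chr_a = b$chr_a,
                    chr_b = b$chr_b, orientation = b$orientation,
                    n_anchors = b$n_anchors, anchors = anchorStr,
                    median_ks = fmt(b$median_ks),
                    event_layer = ifelse(is.na(b$event_layer), "NA",
                                         b$event_layer),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeBlockTable
#' @export
readBlockTable <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L) {
    return(CollinearBlockSet(
      blocks = data.frame(block_id = character(), genome_a = character(),
                          genome_b = character(), chr_a = character(),
                          chr_b = character(), orientation = character(),
                          n_anchors = integer(), median_ks = numeric(),
                          event_layer = character()),
      anchors = data.frame(block_id = character(), gene_a = character(),
                           gene_b = character(), chr_a = character(),
                           chr_b = character(), ord_a = integer(),
                           ord_b = integer(), score = numeric(),
                           ks = numeric())))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  anchors <- do.call(rbind, lapply(seq_len(nrow(raw)), function(i) {
    parts <- strsplit(strsplit(raw$anchors[i], ";", fixed = TRUE)[[1]],
                      "|", fixed = TRUE)
    data.frame(block_id = raw$block_id[i],
               gene_a = vapply(parts, `[`, "", 1),
               gene_b = vapply(parts, `[`, "", 2),
               chr_a = raw$chr_a[i], chr_b = raw$chr_b[i],
               ord_a = as.integer(vapply(parts, `[`, "", 3)),
               ord_b = as.integer(vapply(parts, `[`, "", 4)),
               score = num(vapply(parts, `[`, "", 5)),
               ks = num(vapply(parts, `[`, "", 6)),
               stringsAsFactors = FALSE)
  }))
  blocks <- data.frame(block_id = raw$block_id, genome_a = raw$genome_a,
                       genome_b = raw$genome_b, chr_a = raw$chr_a,
                       chr_b = raw$chr_b, orientation = raw$orientation,
                       n_anchors = as.integer(raw$n_anchors),
                       median_ks = num(raw$median_ks),
                       event_layer = as.character(
                         ifelse(raw$event_layer == "NA", NA,
                                raw$event_layer)),
                       stringsAsFactors = FALSE)
  CollinearBlockSet(blocks = blocks, anchors = anchors)
}

#' Gene order index
#'
#' Maps every gene id of a genome to its chromosome and 0-based ordinal.
#'
#' @param genome An [AnnotatedGenome-class].
#' @return data.frame with columns `gene_id`, `chromosome_id`, `ordinal`,
#'   row names set to gene ids.
#' @export
geneOrderIndex <- function(genome) {
  g <- genome@genes
  out <- data.frame(gene_id = g$gene_id,
                    chromosome_id = g$chromosome_id,
                    ordinal = g$ordinal, stringsAsFactors = FALSE)
  rownames(out) <- out$gene_id
  out
}
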