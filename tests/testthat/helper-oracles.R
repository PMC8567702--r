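# Independent brute-force oracles used to cross-check the package's
# implementations, plus small fixture builders.  These deliberately share
# no code with the package internals.

.NTS4 <- c("A", "C", "G", "T")
.GC <- Biostrings::GENETIC_CODE

# ---- NG86 oracle: explicit site counting and pathway enumeration ---------

oracleSitesPerCodon <- function(codon) {
  nts <- strsplit(codon, "")[[1]]
  aa <- .GC[[codon]]
  s <- 0
  for (p in 1:3) {
    for (alt in setdiff(.NTS4, nts[p])) {
      mut <- nts
      mut[p] <- alt
      mcod <- paste(mut, collapse = "")
      if (.GC[[mcod]] != "*" && .GC[[mcod]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# average synonymous / nonsynonymous differences over minimal pathways,
# excluding pathways through stop codons (all pathways when every one is
# blocked)
oracleDiffsPerPair <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  diffpos <- which(a != b)
  if (!length(diffpos)) return(c(sd = 0, nd = 0))
  perms <- if (length(diffpos) == 1L) list(diffpos) else {
    pp <- list()
    rec <- function(rest, acc) {
      if (!length(rest)) {
        pp[[length(pp) + 1L]] <<- acc
      } else {
        for (i in seq_along(rest)) rec(rest[-i], c(acc, rest[i]))
      }
    }
    rec(diffpos, integer())
    pp
  }
  tally <- function(path) {
    cur <- a
    s <- n <- 0
    blocked <- FALSE
    for (p in path) {
      nxt <- cur
      nxt[p] <- b[p]
      c1 <- paste(cur, collapse = "")
      c2 <- paste(nxt, collapse = "")
      if (.GC[[c1]] != "*" && .GC[[c2]] != "*" &&
          .GC[[c1]] == .GC[[c2]]) s <- s + 1 else n <- n + 1
      if (.GC[[c2]] == "*" && c2 != cb) blocked <- TRUE
      cur <- nxt
    }
    list(s = s, n = n, blocked = blocked)
  }
  res <- lapply(perms, tally)
  ok <- !vapply(res, `[[`, logical(1), "blocked")
  use <- if (any(ok)) res[ok] else res
  c(sd = mean(vapply(use, `[[`, numeric(1), "s")),
    nd = mean(vapply(use, `[[`, numeric(1), "n")))
}

oracleNG <- function(seqA, seqB) {
  codA <- substring(seqA, seq(1, nchar(seqA), 3), seq(3, nchar(seqA), 3))
  codB <- substring(seqB, seq(1, nchar(seqB), 3), seq(3, nchar(seqB), 3))
  keep <- !grepl("[^ACGT]", codA) & !grepl("[^ACGT]", codB) &
    .GC[codA] != "*" & .GC[codB] != "*"
  codA <- codA[keep]
  codB <- codB[keep]
  S <- (sum(vapply(codA, oracleSitesPerCodon, numeric(1))) +
          sum(vapply(codB, oracleSitesPerCodon, numeric(1)))) / 2
  N <- 3 * length(codA) - S
  d <- vapply(seq_along(codA), function(i) {
    oracleDiffsPerPair(codA[i], codB[i])
  }, numeric(2))
  sd <- sum(d["sd", ])
  nd <- sum(d["nd", ])
  ps <- sd / S
  pn <- nd / N
  list(S = S, N = N, sd = sd, nd = nd, ps = ps, pn = pn,
       Ks = if (ps >= 0.75) NA_real_ else -0.75 * log(1 - 4 * ps / 3),
       Ka = if (pn >= 0.75) NA_real_ else -0.75 * log(1 - 4 * pn / 3))
}

randomCdsOracle <- function(nCodons) {
  sense <- names(.GC)[.GC != "*"]
  paste(sample(sense, nCodons, replace = TRUE), collapse = "")
}

# ---- exhaustive maximal-chain oracle --------------------------------------

# maximum total score over all monotone chains (strictly increasing in
# ord_a; strictly increasing or decreasing in ord_b; gaps <= maxGap)
oracleBestChainScore <- function(anchors, maxGap = 50L) {
  n <- nrow(anchors)
  if (!n) return(0)
  best <- 0
  for (dirn in c(1, -1)) {
    oa <- anchors$ord_a
    ob <- anchors$ord_b * dirn
    sc <- anchors$score
    rec <- function(last, score) {
      best <<- max(best, score)
      for (i in seq_len(n)) {
        if (last > 0L) {
          if (oa[i] <= oa[last] || ob[i] <= ob[last]) next
          if (oa[i] - oa[last] > maxGap + 1L ||
              ob[i] - ob[last] > maxGap + 1L) next
        }
        rec(i, score + sc[i])
      }
    }
    rec(0L, 0)
  }
  best
}

# ---- exhaustive event-sequence oracle -------------------------------------

oracleSquash <- function(v) rle(v)$values

oracleKey <- function(chroms) {
  ks <- vapply(chroms, function(v) {
    v <- oracleSquash(v)
    r <- rev(v)
    a <- paste(v, collapse = ",")
    b <- paste(r, collapse = ",")
    if (b < a) b else a
  }, character(1))
  paste(sort(ks), collapse = "|")
}

oracleMoves <- function(chroms) {
  out <- list()
  n <- length(chroms)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    P <- chroms[[i]]
    base <- chroms[-c(i, j)]
    for (Q in list(chroms[[j]], rev(chroms[[j]]))) {
      out[[length(out) + 1L]] <- c(base, list(oracleSquash(c(P, Q))))
      for (k in seq_len(length(P) - 1L)) {
        out[[length(out) + 1L]] <-
          c(base, list(oracleSquash(c(P[1:k], Q, P[(k + 1):length(P)]))))
      }
      for (k in seq_along(P)) {
        out[[length(out) + 1L]] <-
          c(base, list(oracleSquash(c(P[1:k], Q, P[k:length(P)]))))
      }
    }
    if (i < j) {
      Q0 <- chroms[[j]]
      splits <- function(X) {
        s <- list()
        for (k in seq_len(length(X) - 1L)) {
          s[[length(s) + 1L]] <- list(X[1:k], X[(k + 1):length(X)])
        }
        for (k in seq_along(X)) {
          s[[length(s) + 1L]] <- list(X[1:k], X[k:length(X)])
        }
        s
      }
      for (Pv in list(P, rev(P))) for (Qv in list(Q0, rev(Q0))) {
        for (sp in splits(Pv)) for (sq in splits(Qv)) {
          out[[length(out) + 1L]] <-
            c(base, list(oracleSquash(c(sp[[1]], sq[[2]])),
                         oracleSquash(c(sq[[1]], sp[[2]]))))
        }
      }
    }
  }
  out
}

# minimal number of EEJ/NESTED_FUSION/ARM_EXCHANGE events turning parents
# into children, by exhaustive breadth-first search; NA if > maxDepth
oracleMinEvents <- function(parents, children, maxDepth = 3L) {
  target <- oracleKey(children)
  if (oracleKey(parents) == target) return(0L)
  frontier <- list(parents)
  seen <- new.env(parent = emptyenv())
  assign(oracleKey(parents), TRUE, envir = seen)
  for (d in seq_len(maxDepth)) {
    nxt <- list()
    for (st in frontier) {
      for (mv in oracleMoves(st)) {
        key <- oracleKey(mv)
        if (!is.null(seen[[key]])) next
        if (key == target) return(d)
        assign(key, TRUE, envir = seen)
        nxt[[length(nxt) + 1L]] <- mv
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  NA_integer_
}

# ---- misc fixtures --------------------------------------------------------

tinyGenome <- function(name = "toy",
                       starts = c(100L, 500L, 900L),
                       chrom = "chr1", cds = NULL) {
  genes <- data.frame(
    gene_id = sprintf("%s_g%d", name, seq_along(starts)),
    chromosome_id = chrom, start = starts, end = starts + 300L,
    strand = "+", stringsAsFactors = TRUE)
  genes$gene_id <- as.character(genes$gene_id)
  genes$chromosome_id <- as.character(genes$chromosome_id)
  genes$strand <- as.character(genes$strand)
  AnnotatedGenome(name, genes, cds = if (is.null(cds)) character() else cds)
}
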