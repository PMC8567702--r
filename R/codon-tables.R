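# Codon-level lookup tables shared by the Ks estimator and the sequence
# simulator.  Built once per session on first use and cached.

.kt_cache <- new.env(parent = emptyenv())

.NTS <- c("A", "C", "G", "T")

#' @importFrom Biostrings GENETIC_CODE
.codonTables <- function() {
  if (!is.null(.kt_cache$tab)) {
    return(.kt_cache$tab)
  }
  grid <- expand.grid(n3 = .NTS, n2 = .NTS, n1 = .NTS,
                      stringsAsFactors = FALSE)
  # index = 16*d1 + 4*d2 + d3 + 1 with A,C,G,T -> 0..3
  codons <- paste0(grid$n1, grid$n2, grid$n3)
  ord <- order(match(grid$n1, .NTS) * 16 + match(grid$n2, .NTS) * 4 +
                 match(grid$n3, .NTS))
  codons <- codons[ord]
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  sense <- aa != "*"

  # alt[c, p, k]: codon index obtained from codon c by setting position p
  # to the k-th of the three non-resident nucleotides
  alt <- array(NA_integer_, dim = c(64L, 3L, 3L))
  synflag <- array(FALSE, dim = c(64L, 3L, 3L))
  for (ci in seq_len(64L)) {
    nts <- strsplit(codons[ci], "")[[1]]
    for (p in 1:3) {
      others <- setdiff(.NTS, nts[p])
      for (k in 1:3) {
        mut <- nts
        mut[p] <- others[k]
        mi <- .codonIndex(paste(mut, collapse = ""))
        alt[ci, p, k] <- mi
        # a change to a stop codon counts as nonsynonymous so that
        # S + N = 3 * (number of compared codons)
        synflag[ci, p, k] <- sense[ci] && sense[mi] && aa[ci] == aa[mi]
      }
    }
  }
  synfrac <- apply(synflag, c(1, 2), sum) / 3   # 64 x 3
  sites <- rowSums(synfrac)                     # fractional syn sites/codon
  sites[!sense] <- NA_real_

  # synonymous / nonsynonymous(non-stop) replacement options per position,
  # used by the sequence simulator
  synAlt <- vector("list", 64L * 3L)
  nonsynAlt <- vector("list", 64L * 3L)
  for (ci in which(sense)) {
    for (p in 1:3) {
      a <- alt[ci, p, ]
      synAlt[[(p - 1L) * 64L + ci]] <- a[synflag[ci, p, ]]
      nonsynAlt[[(p - 1L) * 64L + ci]] <-
        a[!synflag[ci, p, ] & sense[a]]
    }
  }

  tab <- list(codons = codons, aa = aa, sense = sense, alt = alt,
              synfrac = synfrac, sites = sites,
              synAlt = synAlt, nonsynAlt = nonsynAlt)
  tab$sdnd <- .pathwayTables(tab)
  .kt_cache$tab <- tab
  tab
}

.codonIndex <- function(codon) {
  d <- match(strsplit(codon, "")[[1]], .NTS) - 1L
  16L * d[1] + 4L * d[2] + d[3] + 1L
}

# Average synonymous/nonsynonymous differences per codon pair over all
# minimal mutational pathways, excluding pathways through stop codons
# (falling back to all pathways when every one is blocked).
.pathwayTables <- function(tab) {
  sd <- matrix(0, 64L, 64L)
  nd <- matrix(0, 64L, 64L)
  perms <- list(`1` = matrix(1L, 1, 1),
                `2` = rbind(c(1L, 2L), c(2L, 1L)),
                `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                            c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  codmat <- t(vapply(tab$codons,
                     function(x) strsplit(x, "")[[1]], character(3)))
  for (a in which(tab$sense)) {
    for (b in which(tab$sense)) {
      if (a == b) next
      diffpos <- which(codmat[a, ] != codmat[b, ])
      d <- length(diffpos)
      pm <- perms[[as.character(d)]]
      ssum <- nsum <- 0
      nvalid <- 0L
      ssum_all <- nsum_all <- 0
      for (r in seq_len(nrow(pm))) {
        cur <- codmat[a, ]
        s <- n <- 0L
        blocked <- FALSE
        for (p in diffpos[pm[r, ]]) {
          nxt <- cur
          nxt[p] <- codmat[b, p]
          ic <- .codonIndex(paste(cur, collapse = ""))
          inx <- .codonIndex(paste(nxt, collapse = ""))
          if (tab$sense[ic] && tab$sense[inx] &&
              tab$aa[ic] == tab$aa[inx]) {
            s <- s + 1L
          } else {
            n <- n + 1L
          }
          if (!tab$sense[inx] && inx != b) blocked <- TRUE
          cur <- nxt
        }
        ssum_all <- ssum_all + s
        nsum_all <- nsum_all + n
        if (!blocked) {
          ssum <- ssum + s
          nsum <- nsum + n
          nvalid <- nvalid + 1L
        }
      }
      if (nvalid > 0L) {
        sd[a, b] <- ssum / nvalid
        nd[a, b] <- nsum / nvalid
      } else {
        sd[a, b] <- ssum_all / nrow(pm)
        nd[a, b] <- nsum_all / nrow(pm)
      }
    }
  }
  list(sd = sd, nd = nd)
}

# Encode a CDS string as a vector of codon indices; codons containing any
# non-ACGT symbol get NA.
.codonEncode <- function(cds) {
  v <- match(strsplit(toupper(cds), "")[[1]], .NTS) - 1L
  n <- length(v) %/% 3L
  m <- matrix(v[seq_len(3L * n)], nrow = 3L)
  idx <- 16L * m[1, ] + 4L * m[2, ] + m[3, ] + 1L
  idx
}

.codonDecode <- function(idx) {
  tab <- .codonTables()
  paste(tab$codons[idx], collapse = "")
}
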