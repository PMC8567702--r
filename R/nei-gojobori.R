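#' Nei-Gojobori (NG86) synonymous and nonsynonymous rate estimate
#'
#' Counts fractional synonymous and nonsynonymous sites per codon (a change
#' to a stop codon is counted as nonsynonymous, so `S + N` always equals
#' three times the number of compared codons), averages the site counts over
#' both sequences, averages synonymous/nonsynonymous differences over all
#' minimal mutational pathways between differing codons (pathways through
#' stop codons are excluded), and applies the Jukes-Cantor correction
#' `d = -(3/4) * log(1 - (4/3) * p)`.
#'
#' Codons containing a non-ACGT symbol in either sequence, or coding for a
#' stop in either sequence, are skipped and tallied in `skipped`.  When the
#' synonymous difference proportion reaches 3/4 the estimate is saturated:
#' `Ks` is `NA` and the `saturated` flag is set rather than an error raised.
#'
#' @param cdsA,cdsB Coding sequences (character scalars) of equal length,
#'   a multiple of three.  The caller is responsible for aligning them.
#' @return A `KsEstimate`: a list with elements `S`, `N` (fractional site
#'   counts), `sd`, `nd` (fractional difference counts), `ps`, `pn`
#'   (proportions), `Ks`, `Ka` (Jukes-Cantor corrected rates), `codons`
#'   (compared codons), `skipped`, and `saturated`.
#' @examples
#' neiGojobori("GGGGGGGGG", "GGAGGGGGG")$Ks  # 0.4408...
#' @export
neiGojobori <- function(cdsA, cdsB) {
  if (nchar(cdsA) != nchar(cdsB)) {
    stop("sequences must have equal length")
  }
  if (nchar(cdsA) %% 3L != 0L) {
    stop("sequence length must be a multiple of 3")
  }
  est <- .ng85Core(.codonEncode(cdsA), .codonEncode(cdsB))
  structure(est, class = "KsEstimate")
}

# Core on codon-index vectors; used by the scalar interface and the
# vectorised table builder.
.ng85Core <- function(ia, ib) {
  tab <- .codonTables()
  ok <- !is.na(ia) & !is.na(ib) & tab$sense[ia] & tab$sense[ib]
  ok[is.na(ok)] <- FALSE
  skipped <- sum(!ok)
  ia <- ia[ok]
  ib <- ib[ok]
  n <- length(ia)
  if (n == 0L) {
    stop("zero comparable codons")
  }
  S <- (sum(tab$sites[ia]) + sum(tab$sites[ib])) / 2
  N <- 3 * n - S
  sd <- sum(tab$sdnd$sd[cbind(ia, ib)])
  nd <- sum(tab$sdnd$nd[cbind(ia, ib)])
  ps <- if (S > 0) sd / S else 0
  pn <- if (N > 0) nd / N else 0
  saturated <- ps >= 0.75
  Ks <- if (saturated) NA_real_ else -0.75 * log(1 - 4 * ps / 3)
  Ka <- if (pn >= 0.75) NA_real_ else -0.75 * log(1 - 4 * pn / 3)
  list(S = S, N = N, sd = sd, nd = nd, ps = ps, pn = pn,
       Ks = Ks, Ka = Ka, codons = n, skipped = skipped,
       saturated = saturated)
}

#' @export
print.KsEstimate <- function(x, ...) {
  cat(sprintf(
    "NG86 estimate over %d codons (%d skipped)\n  S = %.3f  N = %.3f  sd = %.3f  nd = %.3f\n  Ks = %s  Ka = %s%s\n",
    x$codons, x$skipped, x$S, x$N, x$sd, x$nd,
    ifelse(is.na(x$Ks), "NA", sprintf("%.4f", x$Ks)),
    ifelse(is.na(x$Ka), "NA", sprintf("%.4f", x$Ka)),
    if (x$saturated) "  [saturated]" else ""))
  invisible(x)
}

#' Nei-Gojobori estimates for a table of sequence pairs
#'
#' Vectorised convenience wrapper around the NG86 estimator: computes one
#' estimate per pair of coding sequences.  Pairs where either sequence is
#' missing, of mismatched length, or without comparable codons get `NA`
#' estimates and are counted in the `failed` attribute.
#'
#' @param seqA,seqB Character vectors of coding sequences, recycled to a
#'   common length.
#' @return A data.frame with one row per pair and columns `S`, `N`, `sd`,
#'   `nd`, `ps`, `pn`, `Ks`, `Ka`, `saturated`.
#' @export
neiGojoboriTable <- function(seqA, seqB) {
  n <- max(length(seqA), length(seqB))
  if (n == 0L) {
    out <- data.frame(S = numeric(), N = numeric(), sd = numeric(),
                      nd = numeric(), ps = numeric(), pn = numeric(),
                      Ks = numeric(), Ka = numeric(),
                      saturated = logical())
    attr(out, "failed") <- 0L
    return(out)
  }
  seqA <- rep_len(seqA, n)
  seqB <- rep_len(seqB, n)
  out <- data.frame(S = rep(NA_real_, n), N = NA_real_, sd = NA_real_,
                    nd = NA_real_, ps = NA_real_, pn = NA_real_,
                    Ks = NA_real_, Ka = NA_real_, saturated = NA)
  failed <- 0L
  for (i in seq_len(n)) {
    a <- seqA[i]
    b <- seqB[i]
    if (is.na(a) || is.na(b) || !nzchar(a) || !nzchar(b) ||
        nchar(a) != nchar(b) || nchar(a) %% 3L != 0L) {
      failed <- failed + 1L
      next
    }
    est <- tryCatch(.ng85Core(.codonEncode(a), .codonEncode(b)),
                    error = function(e) NULL)
    if (is.null(est)) {
      failed <- failed + 1L
      next
    }
    out[i, c("S", "N", "sd", "nd", "ps", "pn")] <-
      c(est$S, est$N, est$sd, est$nd, est$ps, est$pn)
    out$Ks[i] <- est$Ks
    out$Ka[i] <- est$Ka
    out$saturated[i] <- est$saturated
  }
  attr(out, "failed") <- failed
  out
}
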