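# Label-sequence utilities.  Chromosomes are compared as proto-label
# sequences with adjacent duplicate labels squashed and orientation
# ignored (inversions are normalised away before event classification).

.squash <- function(v) {
  if (!length(v)) return(character())
  rle(v)$values
}

.canon <- function(v) {
  v <- .squash(v)
  r <- rev(v)
  if (paste(r, collapse = "\r") < paste(v, collapse = "\r")) r else v
}

.canonKey <- function(v) paste(.canon(v), collapse = "\r")

.sameSeq <- function(a, b) identical(.canonKey(a), .canonKey(b))

.stateKey <- function(chroms) {
  paste(sort(vapply(chroms, .canonKey, character(1))), collapse = "\n")
}

# all EEJ / NESTED_FUSION / ARM_EXCHANGE products of a chromosome
# multiset, at label granularity with mid-label breakpoints allowed
.eventMoves <- function(chroms) {
  n <- length(chroms)
  moves <- list()
  add <- function(kind, detail, newChroms) {
    moves[[length(moves) + 1L]] <<- list(kind = kind, detail = detail,
                                         chroms = newChroms)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      P <- chroms[[i]]
      base <- chroms[-c(i, j)]
      for (Q in list(chroms[[j]], rev(chroms[[j]]))) {
        add("EEJ", sprintf("%s + %s", paste(P, collapse = "-"),
                           paste(Q, collapse = "-")),
            c(base, list(.squash(c(P, Q)))))
        if (length(P) + length(Q) >= 2L) {
          # nested fusion: Q inserted at an internal point of P
          cuts <- unique(c(seq_len(max(length(P) - 1L, 0L)),
                           seq_along(P) - 0.5))
          for (cut in cuts) {
            k <- floor(cut)
            midlabel <- cut != k
            pre <- if (midlabel) P[seq_len(k + 1L)] else P[seq_len(k)]
            post <- if (midlabel) P[seq(k + 1L, length(P))] else
              P[seq(k + 1L, length(P))]
            if (!length(pre) || !length(post)) next
            add("NESTED_FUSION",
                sprintf("%s into %s", paste(Q, collapse = "-"),
                        paste(P, collapse = "-")),
                c(base, list(.squash(c(pre, Q, post)))))
          }
        }
      }
      if (i < j && length(P) + length(chroms[[j]]) <= 12L) {
        Q0 <- chroms[[j]]
        splitsOf <- function(X) {
          s <- list()
          for (k in seq_len(length(X) - 1L)) {
            s[[length(s) + 1L]] <- list(pre = X[seq_len(k)],
                                        post = X[seq(k + 1L, length(X))])
          }
          for (k in seq_along(X)) {       # breakpoint inside label k
            s[[length(s) + 1L]] <- list(pre = X[seq_len(k)],
                                        post = X[seq(k, length(X))])
          }
          s
        }
        for (Pv in list(P, rev(P))) {
          for (Qv in list(Q0, rev(Q0))) {
            for (sp in splitsOf(Pv)) {
              for (sq in splitsOf(Qv)) {
                add("ARM_EXCHANGE",
                    sprintf("%s x %s", paste(P, collapse = "-"),
                            paste(Q0, collapse = "-")),
                    c(base,
                      list(.squash(c(sp$pre, sq$post)),
                           .squash(c(sq$pre, sp$post)))))
              }
            }
          }
        }
      }
    }
  }
  moves
}

# breadth-first search for a minimal event sequence turning `parents`
# into `children` (as canonical multisets); NULL when none within depth
# or within the (deterministic) expansion budget
.eventSearch <- function(parents, children, depth = 3L,
                         maxStates = 2000L, maxExpansions = 100000L,
                         budget = NULL) {
  if (length(parents) > 8L || length(children) > 8L) return(NULL)
  if (!is.null(budget)) {
    if (budget$left <= 0L) return(NULL)
    maxExpansions <- min(maxExpansions, budget$left)
  }
  target <- .stateKey(children)
  frontier <- list(list(chroms = parents, events = NULL))
  seen <- new.env(parent = emptyenv())
  assign(.stateKey(parents), TRUE, envir = seen)
  if (.stateKey(parents) == target) return(list())
  expansions <- 0L
  for (d in seq_len(depth)) {
    nxt <- list()
    for (st in frontier) {
      moves <- .eventMoves(st$chroms)
      expansions <- expansions + length(moves)
      for (mv in moves) {
        key <- .stateKey(mv$chroms)
        if (!is.null(seen[[key]])) next
        ev <- c(st$events, list(list(kind = mv$kind, detail = mv$detail)))
        if (key == target) return(ev)
        assign(key, TRUE, envir = seen)
        if (length(nxt) < maxStates) {
          nxt[[length(nxt) + 1L]] <- list(chroms = mv$chroms, events = ev)
        }
      }
      if (expansions > maxExpansions) {
        if (!is.null(budget)) budget$left <- budget$left - expansions
        return(NULL)
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  if (!is.null(budget)) budget$left <- budget$left - expansions
  NULL
}

#' Classify the rearrangement events between two karyotypes
#'
#' Greedy-parsimony matching at proto-label resolution (adjacent equal
#' labels squashed, orientation ignored): (1) identical chromosomes are
#' matched and removed; (2) a child equal to the concatenation of two
#' whole parents is an EEJ; (3) a child equal to a parent with a second
#' whole parent inserted internally is a NESTED_FUSION; (4) a pair of
#' children forming a reciprocal prefix/suffix recombination of two
#' parents is an ARM_EXCHANGE (breakpoints inside a label are allowed:
#' the split label then appears on both sides).  Remaining chromosomes
#' are grouped by label content with covering parents and resolved by a
#' bounded breadth-first search over event sequences of at most
#' `searchDepth` events (minimal count; ties prefer EEJ, then
#' NESTED_FUSION, then ARM_EXCHANGE by generation order).  When a child
#' stays unexplained because an earlier greedy match consumed the
#' parents it needs, that match is tentatively undone and the enlarged
#' group re-searched.  Chromosomes that still defy explanation are
#' reported as `unresolved`.
#'
#' @param parent,child [NodeKaryotype-class] objects.
#' @param searchDepth Bounded-search depth (default 3).
#' @param searchBudget Total number of candidate states examined across
#'   all bounded searches of one call (deterministic work cap).
#' @return data.frame with columns `kind` and `detail`.
#' @export
classifyBranchEvents <- function(parent, child, searchDepth = 3L,
                                 searchBudget = 150000L) {
  P <- unname(karyotypeChromosomes(parent))
  C <- unname(karyotypeChromosomes(child))
  budget <- new.env(parent = emptyenv())
  budget$left <- as.integer(searchBudget)
  seqStr <- function(v) paste(v, collapse = "-")
  # assignment records: events plus the children/parents they consumed,
  # so that a later repair step can undo a premature match
  assigned <- list()
  push <- function(events, children, parents) {
    assigned[[length(assigned) + 1L]] <<-
      list(events = events, children = children, parents = parents)
  }

  # 1: identical chromosomes
  ci <- 1L
  while (ci <= length(C)) {
    hit <- which(vapply(P, .sameSeq, logical(1), C[[ci]]))
    if (length(hit)) {
      push(list(), list(C[[ci]]), list(P[[hit[1]]]))
      P <- P[-hit[1]]
      C <- C[-ci]
    } else {
      ci <- ci + 1L
    }
  }

  # 2: EEJ of two whole parents
  repeat {
    found <- FALSE
    for (ci in seq_along(C)) {
      np <- length(P)
      done <- FALSE
      cLab <- unique(C[[ci]])
      for (i in seq_len(np)) {
        if (!all(P[[i]] %in% cLab)) next
        for (j in seq_len(np)) {
          if (i == j) next
          if (!all(P[[j]] %in% cLab)) next
          if (!setequal(c(P[[i]], P[[j]]), cLab)) next
          for (Q in list(P[[j]], rev(P[[j]]))) {
            if (.sameSeq(c(P[[i]], Q), C[[ci]])) {
              push(list(list(kind = "EEJ",
                             detail = sprintf("%s + %s", seqStr(P[[i]]),
                                              seqStr(P[[j]])))),
                   list(C[[ci]]), list(P[[i]], P[[j]]))
              P <- P[-c(i, j)]
              C <- C[-ci]
              done <- TRUE
              break
            }
          }
          if (done) break
        }
        if (done) break
      }
      if (done) { found <- TRUE; break }
    }
    if (!found) break
  }

  # 3: nested fusion (child = parent-A prefix + whole parent-B + suffix)
  repeat {
    found <- FALSE
    for (ci in seq_along(C)) {
      cc <- C[[ci]]
      cLab <- unique(cc)
      done <- FALSE
      for (j in seq_along(P)) {
        if (!all(P[[j]] %in% cLab)) next
        for (Q in list(P[[j]], rev(P[[j]]))) {
          m <- length(Q)
          if (m + 1L > length(cc)) next
          for (st in seq_len(length(cc) - m + 1L)) {
            if (st == 1L || st + m - 1L == length(cc)) next
            if (!identical(cc[st:(st + m - 1L)], Q)) next
            remainder <- .squash(c(cc[seq_len(st - 1L)],
                                   cc[seq(st + m, length(cc))]))
            for (i in seq_along(P)) {
              if (i == j) next
              if (.sameSeq(P[[i]], remainder)) {
                push(list(list(kind = "NESTED_FUSION",
                               detail = sprintf("%s into %s",
                                                seqStr(P[[j]]),
                                                seqStr(P[[i]])))),
                     list(cc), list(P[[i]], P[[j]]))
                P <- P[-c(i, j)]
                C <- C[-ci]
                done <- TRUE
                break
              }
            }
            if (done) break
          }
          if (done) break
        }
        if (done) break
      }
      if (done) { found <- TRUE; break }
    }
    if (!found) break
  }

  # 4: arm exchange (reciprocal prefix/suffix recombination)
  repeat {
    found <- FALSE
    nc <- length(C)
    pLabs <- lapply(P, unique)
    for (c1 in seq_len(nc)) {
      done <- FALSE
      for (c2 in seq_len(nc)) {
        if (c2 <= c1) next
        need <- unique(c(C[[c1]], C[[c2]]))
        if (!any(vapply(pLabs, function(x) all(x %in% need),
                        logical(1)))) next
        hit <- .armExchangeMatch(P, C[[c1]], C[[c2]])
        if (!is.null(hit)) {
          push(list(list(kind = "ARM_EXCHANGE",
                         detail = sprintf("%s x %s", seqStr(P[[hit[1]]]),
                                          seqStr(P[[hit[2]]])))),
               list(C[[c1]], C[[c2]]), P[hit])
          P <- P[-hit]
          C <- C[-c(c1, c2)]
          done <- TRUE
        }
        if (done) break
      }
      if (done) { found <- TRUE; break }
    }
    if (!found) break
  }

  # 5: bounded search on residual groups
  unresolved <- list()
  while (length(C)) {
    grp <- .residualGroup(P, C)
    if (is.null(grp)) {
      unresolved <- c(unresolved, C)
      C <- list()
      break
    }
    found <- .eventSearch(P[grp$parents], C[grp$children],
                          depth = searchDepth, budget = budget)
    if (is.null(found)) {
      unresolved <- c(unresolved, C[grp$children])
      C <- C[-grp$children]
    } else {
      push(found, C[grp$children], P[grp$parents])
      C <- C[-grp$children]
      P <- P[-grp$parents]
    }
  }

  # repair: a child may be unexplainable because a greedy match consumed
  # the parents it needs; undo such matches and re-search the union
  guard <- 0L
  while (length(unresolved) && guard < 20L) {
    guard <- guard + 1L
    u <- unresolved[[1]]
    fixed <- FALSE
    overlap <- vapply(assigned, function(r) {
      length(intersect(unique(unlist(r$parents)), unique(u)))
    }, integer(1))
    tried <- 0L
    for (ri in order(-overlap)) {
      if (overlap[ri] == 0L) next
      if (tried >= 4L) break
      tried <- tried + 1L
      r <- assigned[[ri]]
      newC <- c(list(u), r$children)
      required <- unique(unlist(lapply(newC, unique)))
      extras <- which(vapply(P, function(p) all(p %in% required),
                             logical(1)))
      solution <- NULL
      usedExtras <- integer()
      extraSets <- list(integer())
      for (k in seq_len(min(2L, length(extras)))) {
        extraSets <- c(extraSets,
                       utils::combn(extras, k, simplify = FALSE))
      }
      for (es in extraSets) {
        cand <- .eventSearch(c(r$parents, P[es]), newC,
                             depth = searchDepth, budget = budget)
        if (!is.null(cand)) {
          solution <- cand
          usedExtras <- es
          break
        }
      }
      if (!is.null(solution)) {
        assigned[[ri]] <- NULL
        push(solution, newC, c(r$parents, P[usedExtras]))
        if (length(usedExtras)) P <- P[-usedExtras]
        unresolved <- unresolved[-1]
        fixed <- TRUE
        break
      }
    }
    if (!fixed) {
      assigned[[length(assigned) + 1L]] <- list(
        events = list(list(kind = "unresolved",
                           detail = sprintf("child %s not derivable",
                                            seqStr(u)))),
        children = list(u), parents = list())
      unresolved <- unresolved[-1]
    }
  }

  rows <- list()
  for (r in assigned) {
    for (ev in r$events) {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = ev$kind, detail = ev$detail, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(kind = character(), detail = character(),
               stringsAsFactors = FALSE)
  }
}

# smallest subset of residual children whose label set is exactly covered
# by a subset of residual parents
.residualGroup <- function(P, C) {
  nC <- length(C)
  if (!nC || !length(P)) return(NULL)
  for (size in seq_len(min(nC, 3L))) {
    combs <- utils::combn(nC, size, simplify = FALSE)
    for (cs in combs) {
      need <- unique(unlist(C[cs]))
      inside <- which(vapply(P, function(p) all(p %in% need), logical(1)))
      if (!length(inside)) next
      sel <- integer()
      covered <- character()
      for (pi in inside) {
        if (all(P[[pi]] %in% covered)) next
        sel <- c(sel, pi)
        covered <- union(covered, P[[pi]])
        if (setequal(covered, need)) break
      }
      if (setequal(covered, need)) {
        return(list(children = cs, parents = sel))
      }
    }
  }
  NULL
}

# find parents i<j whose reciprocal prefix/suffix recombination yields
# the unordered child pair (c1, c2); mid-label breakpoints allowed
.armExchangeMatch <- function(P, ch1, ch2, maxLen = 12L) {
  np <- length(P)
  if (length(ch1) + length(ch2) > maxLen) return(NULL)
  need <- unique(c(ch1, ch2))
  for (i in seq_len(np)) {
    if (!all(P[[i]] %in% need)) next
    for (j in seq_len(np)) {
      if (j <= i) next
      if (!all(P[[j]] %in% need)) next
      if (!setequal(c(P[[i]], P[[j]]), need)) next
      for (Pv in list(P[[i]], rev(P[[i]]))) {
        for (Qv in list(P[[j]], rev(P[[j]]))) {
          for (ii in seq_along(Pv)) {
            for (i2 in unique(c(ii, min(ii + 1L, length(Pv))))) {
              for (jj in seq_along(Qv)) {
                for (j2 in unique(c(jj, min(jj + 1L, length(Qv))))) {
                  a1 <- .squash(c(Pv[seq_len(ii)],
                                  Qv[seq(j2, length(Qv))]))
                  a2 <- .squash(c(Qv[seq_len(jj)],
                                  Pv[seq(i2, length(Pv))]))
                  if ((.sameSeq(a1, ch1) && .sameSeq(a2, ch2)) ||
                      (.sameSeq(a1, ch2) && .sameSeq(a2, ch1))) {
                    return(c(i, j))
                  }
                }
              }
            }
          }
        }
      }
    }
  }
  NULL
}
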