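# Independent oracles used by the test suite.
#
# 1) Event-sequence oracle: exhaustively simulates sequences of per-copy
#    gain, loss and (single) WGD events on explicitly labelled copies of
#    one parental allele, reconstructs each surviving genealogy, and
#    canonicalises it to a label string. Alleles evolve independently, so
#    per-allele label sets combine into route labels. Minimal event counts
#    per label are retained.
# 2) Monte-Carlo lineage oracle: parses a canonical route label into an
#    explicit copy genealogy at concrete event times and tallies the
#    multiplicity (surviving-descendant count) of uniformly placed
#    mutations.
# Both are separate code paths from the package's tagged-tree enumeration
# and symbolic edge-length spectra.

## ---- event-sequence oracle --------------------------------------------

## genealogy state: parallel vectors indexed by copy id
.oNew <- function() {
  list(parent = 0L, event = "root", born = "pre", alive = TRUE,
       wgdDone = FALSE, nGain = 0L, nLoss = 0L)
}

.oApply <- function(st, action, target = NA_integer_) {
  phase <- if (st$wgdDone) "post" else "pre"
  if (action == "gain") {
    st$alive[target] <- FALSE
    st$parent <- c(st$parent, target, target)
    st$event <- c(st$event, "gain", "gain")
    st$born <- c(st$born, phase, phase)
    st$alive <- c(st$alive, TRUE, TRUE)
    st$nGain <- st$nGain + 1L
  } else if (action == "loss") {
    st$alive[target] <- FALSE
    st$nLoss <- st$nLoss + 1L
  } else if (action == "wgd") {
    ids <- which(st$alive)
    st$alive[ids] <- FALSE
    for (id in ids) {
      st$parent <- c(st$parent, id, id)
      st$event <- c(st$event, "wgd", "wgd")
      st$born <- c(st$born, "post", "post")
      st$alive <- c(st$alive, TRUE, TRUE)
    }
    st$wgdDone <- TRUE
  }
  st
}

## ids that are alive or have alive descendants
.oSurviving <- function(st) {
  surv <- st$alive
  repeat {
    more <- seq_along(surv) %in% st$parent[surv]
    new <- surv | more
    if (identical(new, surv)) return(surv)
    surv <- new
  }
}

## canonical label of the surviving genealogy of one allele
.oLabel <- function(st, finalCount) {
  if (finalCount == 0L) return("0")
  surv <- .oSurviving(st)
  kidsOf <- function(id) {
    k <- which(st$parent == id)
    k[surv[k]]
  }
  build <- function(id) {
    kids <- kidsOf(id)
    if (!length(kids)) return("1")
    if (length(kids) == 1L) {
      s <- build(kids)
      ## a WGD duplication with one dead twin is a crossing marker; a gain
      ## with a dead twin is invisible (gain+loss cancel)
      if (st$event[kids] == "wgd") return(paste0("x(", s, ")"))
      return(s)
    }
    labs <- sort(vapply(kids, build, ""))
    tag <- if (st$event[kids[1L]] == "wgd") "w"
           else if (!st$wgdDone) "g"
           else if (st$born[kids[1L]] == "pre") "p" else "q"
    paste0(tag, "(", labs[1L], ",", labs[2L], ")")
  }
  build(1L)
}

## serialisation of the alive-or-ancestor structure, for memoisation:
## states with the same signature generate the same future label set
.oSig <- function(st) {
  surv <- .oSurviving(st)
  kidsOf <- function(id) { k <- which(st$parent == id); k[surv[k]] }
  ser <- function(id) {
    kids <- kidsOf(id)
    me <- paste0(st$event[id], substr(st$born[id], 1, 2),
                 if (st$alive[id]) "A" else "d")
    if (!length(kids)) return(me)
    paste0(me, "[", paste(sort(vapply(kids, ser, "")), collapse = ";"), "]")
  }
  paste(ser(1L), st$wgdDone, st$nGain, st$nLoss)
}

.oracleAlleleCache <- new.env(parent = emptyenv())

## DFS over all event sequences of one allele; returns named integer
## vector: canonical label -> minimal (gains + losses)
oracleAlleleHistories <- function(finalCount, wgd) {
  cacheKey <- paste0(finalCount, wgd)
  if (!is.null(.oracleAlleleCache[[cacheKey]]))
    return(.oracleAlleleCache[[cacheKey]])
  results <- new.env(parent = emptyenv())
  visited <- new.env(parent = emptyenv())
  lossBudget <- max(finalCount, 1L)
  gainBudget <- if (finalCount > 0L) 2L * finalCount - 1L else 1L
  recurse <- function(st) {
    sig <- .oSig(st)
    if (!is.null(visited[[sig]])) return(invisible(NULL))
    visited[[sig]] <- TRUE
    alive <- sum(st$alive)
    if (alive == finalCount && st$wgdDone == wgd) {
      lab <- .oLabel(st, finalCount)
      nEv <- st$nGain + st$nLoss
      cur <- results[[lab]]
      if (is.null(cur) || nEv < cur) results[[lab]] <- nEv
    }
    ## pruning: copy-count reachability under remaining budgets
    doubler <- if (wgd && !st$wgdDone) 2L else 1L
    if ((alive + (gainBudget - st$nGain)) * doubler < finalCount)
      return(invisible(NULL))
    if (alive - (lossBudget - st$nLoss) > finalCount && st$wgdDone == wgd)
      return(invisible(NULL))
    ## act on every alive copy; states reached via interchangeable copies
    ## collapse in the visited cache (canonical serialisation)
    reps <- which(st$alive)
    if (st$nGain < gainBudget)
      for (id in reps) recurse(.oApply(st, "gain", id))
    if (st$nLoss < lossBudget)
      for (id in reps) recurse(.oApply(st, "loss", id))
    if (wgd && !st$wgdDone) recurse(.oApply(st, "wgd"))
    invisible(NULL)
  }
  recurse(.oNew())
  out <- unlist(as.list(results))
  out <- out[order(names(out))]
  .oracleAlleleCache[[cacheKey]] <- out
  out
}

## combine per-allele histories into route labels with minimal event counts
oracleRoutes <- function(majorCn, minorCn, wgd) {
  a <- oracleAlleleHistories(majorCn, wgd)
  b <- if (minorCn == majorCn) a else oracleAlleleHistories(minorCn, wgd)
  out <- new.env(parent = emptyenv())
  for (i in seq_along(a)) for (j in seq_along(b)) {
    labs <- c(names(a)[i], names(b)[j])
    if (majorCn == minorCn) labs <- sort(labs)
    key <- paste(labs, collapse = "|")
    nEv <- unname(a[i] + b[j]) + as.integer(wgd)
    cur <- out[[key]]
    if (is.null(cur) || nEv < cur) out[[key]] <- nEv
  }
  v <- unlist(as.list(out))
  v[order(names(v))]
}

## ---- Monte-Carlo lineage spectrum oracle ------------------------------

## parse one allele's canonical label into nested lists
parseAlleleLabel <- function(s) {
  pos <- 1L
  parseNode <- function() {
    ch <- substr(s, pos, pos)
    if (ch == "1") { pos <<- pos + 1L; return(list(tag = "leaf")) }
    tag <- ch
    pos <<- pos + 2L                       # tag + "("
    a <- parseNode()
    if (tag == "x") {
      pos <<- pos + 1L                     # ")"
      return(list(tag = "x", kids = list(a)))
    }
    pos <<- pos + 1L                       # ","
    b <- parseNode()
    pos <<- pos + 1L                       # ")"
    list(tag = tag, kids = list(a, b))
  }
  parseNode()
}

## Copy genealogy of a route realisation: rows (birth, death, m). Gain
## times are consumed from `theta` in pre-order, matching the package's
## parameter-id order (labels are written with children sorted, exactly as
## the enumeration sorts them). Dead WGD twins are included with m = 0.
oracleGenealogy <- function(label, theta, twgd, wgdSample) {
  parts <- strsplit(label, "|", fixed = TRUE)[[1L]]
  rows <- list()
  k <- 0L                                  # theta cursor
  walk <- function(n, birth) {             # returns surviving leaves below
    if (n$tag == "leaf") {
      rows[[length(rows) + 1L]] <<- c(birth, 1, 1)
      return(1)
    }
    if (n$tag == "x") {
      rows[[length(rows) + 1L]] <<- c(twgd, 1, 0)   # dead twin
      return(walk(n$kids[[1L]], birth))
    }
    t <- if (n$tag == "w") twgd else { k <<- k + 1L; theta[k] }
    ms <- vapply(n$kids, walk, numeric(1), birth = t)
    rows[[length(rows) + 1L]] <<- c(birth, t, sum(ms))
    sum(ms)
  }
  for (p in parts) {
    if (p == "0") {
      rows[[length(rows) + 1L]] <- c(0, if (wgdSample) twgd else 1, 0)
      next
    }
    walk(parseAlleleLabel(p), 0)
  }
  out <- do.call(rbind, rows)
  colnames(out) <- c("birth", "death", "m")
  out
}

## multiplicity proportions from nMut uniformly placed mutations
oracleSpectrumMC <- function(label, theta, twgd, wgdSample, nMut = 1e5) {
  cp <- oracleGenealogy(label, theta, twgd, wgdSample)
  span <- pmax(cp[, "death"] - cp[, "birth"], 0)
  counts <- stats::rmultinom(1L, nMut, prob = span)[, 1L]
  kept <- cp[, "m"] >= 1
  tot <- sum(counts[kept])
  maxM <- max(cp[, "m"])
  prop <- vapply(seq_len(maxM), function(mm)
    sum(counts[kept & cp[, "m"] == mm]) / tot, numeric(1))
  list(prop = prop, n = tot)
}
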