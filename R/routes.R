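# Route enumeration: every history of gains, at most one WGD, and minimal
# implied losses that produces a given allele-specific copy-number state.
#
# A per-allele history is represented by its surviving-lineage tree. Node
# grammar (children unordered everywhere):
#   leaf          a surviving final copy (time 1)
#   g(A,B)        independent gain in a non-WGD sample (free time in (0,1))
#   p(A,B)        independent gain before the WGD (time in (0, t_w))
#   q(A,B)        independent gain after the WGD (time in (t_w, 1))
#   w(A,B)        WGD duplication where both daughter lineages survive
#   x(T)          a lineage crossing the WGD whose doubled copy left no
#                 surviving descendants: one implied loss, lineage continues
#   "0"           the whole allele was lost (one implied loss, no branches)
# In a WGD sample every root-to-leaf path crosses the WGD exactly once,
# either at a w node or at an x marker; p nodes sit above the crossing and
# q nodes below it. Routes whose multiplicity-spectrum functions coincide
# for all timings collapse to the same canonical serialisation (children
# sorted lexicographically; allele trees sorted when the two final allele
# copy numbers are equal).

treeLeaf <- function() list(tag = "leaf", label = "1", nleaves = 1L)

treeNode <- function(tag, children) {
  labs <- vapply(children, function(ch) ch$label, character(1))
  o <- order(labs)
  children <- children[o]
  labs <- labs[o]
  list(tag = tag,
       children = children,
       label = paste0(tag, "(", paste(labs, collapse = ","), ")"),
       nleaves = sum(vapply(children, function(ch) ch$nleaves, integer(1))))
}

## Unordered pairs from two canonical lists (i <= j when the lists are the
## same leaf-count class).
.pairTrees <- function(listA, listB, symmetric) {
  out <- list()
  for (i in seq_along(listA)) {
    jseq <- if (symmetric) i:length(listB) else seq_along(listB)
    for (j in jseq) out[[length(out) + 1L]] <- list(listA[[i]], listB[[j]])
  }
  out
}

.routeCache <- new.env(parent = emptyenv())

## All gain-tree shapes with n surviving leaves, internal nodes tagged `tag`.
.genGainTrees <- function(n, tag) {
  key <- paste0(tag, n)
  if (!is.null(.routeCache[[key]])) return(.routeCache[[key]])
  out <- if (n == 1L) {
    list(treeLeaf())
  } else {
    res <- list()
    for (a in seq_len(n %/% 2L)) {
      pairs <- .pairTrees(.genGainTrees(a, tag), .genGainTrees(n - a, tag),
                          symmetric = a == n - a)
      for (pr in pairs) res[[length(res) + 1L]] <- treeNode(tag, pr)
    }
    res
  }
  .routeCache[[key]] <- out
  out
}

## All per-allele histories with c surviving leaves in a WGD sample.
.genWgdAllele <- function(c) {
  key <- paste0("A", c)
  if (!is.null(.routeCache[[key]])) return(.routeCache[[key]])
  out <- list()
  for (tr in .genGainTrees(c, "q"))
    out[[length(out) + 1L]] <- treeNode("x", list(tr))
  if (c >= 2L) {
    for (a in seq_len(c %/% 2L)) {
      pairs <- .pairTrees(.genGainTrees(a, "q"), .genGainTrees(c - a, "q"),
                          symmetric = a == c - a)
      for (pr in pairs) out[[length(out) + 1L]] <- treeNode("w", pr)
    }
    for (a in seq_len(c %/% 2L)) {
      pairs <- .pairTrees(.genWgdAllele(a), .genWgdAllele(c - a),
                          symmetric = a == c - a)
      for (pr in pairs) out[[length(out) + 1L]] <- treeNode("p", pr)
    }
  }
  .routeCache[[key]] <- out
  out
}

.alleleVariants <- function(c, wgd) {
  if (c == 0L) return(list(NULL))   # lost allele, serialised "0"
  if (wgd) .genWgdAllele(c) else .genGainTrees(c, "g")
}

## Counting analogue of the generators (used when enumeration would be
## wasteful, e.g. above the route cap).
.ch2 <- function(k) k * (k + 1) / 2

.countGainTrees <- function(n) {
  if (n == 1L) return(1)
  tot <- 0
  for (a in seq_len(n %/% 2L)) {
    ca <- .countGainTrees(a); cb <- .countGainTrees(n - a)
    tot <- tot + if (a == n - a) .ch2(ca) else ca * cb
  }
  tot
}

.countWgdAllele <- function(c) {
  if (c == 0L) return(1)
  tot <- .countGainTrees(c)
  if (c >= 2L) {
    for (a in seq_len(c %/% 2L)) {
      ca <- .countGainTrees(a); cb <- .countGainTrees(c - a)
      tot <- tot + if (a == c - a) .ch2(ca) else ca * cb
      da <- .countWgdAllele(a); db <- .countWgdAllele(c - a)
      tot <- tot + if (a == c - a) .ch2(da) else da * db
    }
  }
  tot
}

.alleleVariantCount <- function(c, wgd) {
  if (c == 0L) return(1)
  if (wgd) .countWgdAllele(c) else .countGainTrees(c)
}

.treeLabelOrZero <- function(tree) if (is.null(tree)) "0" else tree$label

## Walk an allele tree, assigning parameter ids to gain nodes and emitting
## symbolic edges. Symbols: 0 = time 0, -1 = WGD time, -2 = time 1,
## k >= 1 = free timing parameter k.
.traverseAllele <- function(tree, state) {
  rec <- function(node, parentSym, lastGain, lastPhase) {
    if (node$tag == "leaf") {
      state$edges[[length(state$edges) + 1L]] <<-
        c(start = parentSym, end = -2L, lambda = 1L)
      return(invisible(NULL))
    }
    if (node$tag == "x") {
      # transparent WGD crossing: same lineage continues; phase boundary
      rec(node$children[[1L]], parentSym, 0L, NA_character_)
      return(invisible(NULL))
    }
    if (node$tag == "w") {
      state$edges[[length(state$edges) + 1L]] <<-
        c(start = parentSym, end = -1L, lambda = node$nleaves)
      for (ch in node$children) rec(ch, -1L, 0L, NA_character_)
      return(invisible(NULL))
    }
    # gain node: g (free), p (pre-WGD) or q (post-WGD)
    phase <- switch(node$tag, g = "free", p = "pre", q = "post")
    id <- state$nextId
    state$nextId <<- id + 1L
    parent <- if (!is.na(lastPhase) && identical(lastPhase, phase)) lastGain else 0L
    state$params[[length(state$params) + 1L]] <<-
      list(id = id, phase = phase, parent = parent)
    state$edges[[length(state$edges) + 1L]] <<-
      c(start = parentSym, end = id, lambda = node$nleaves)
    for (ch in node$children) rec(ch, id, id, phase)
    invisible(NULL)
  }
  if (!is.null(tree)) rec(tree, 0L, 0L, NA_character_)
  invisible(NULL)
}

.countTags <- function(tree, tags) {
  if (is.null(tree) || tree$tag == "leaf") return(0L)
  own <- as.integer(tree$tag %in% tags)
  own + sum(vapply(tree$children, .countTags, integer(1), tags = tags))
}

#' Construct a GainRoute from per-allele trees
#'
#' Internal constructor used by [enumerateRoutes()]; exported for use by
#' advanced callers building routes directly.
#'
#' @param majorTree,minorTree allele trees in the internal node grammar
#'   (\code{NULL} means the allele was lost).
#' @param majorCn,minorCn the final allele copy numbers.
#' @param wgd whether the sample (and hence every route) carries one WGD.
#' @return a [GainRoute-class] object.
#' @keywords internal
makeRoute <- function(majorTree, minorTree, majorCn, minorCn, wgd) {
  labM <- .treeLabelOrZero(majorTree)
  labm <- .treeLabelOrZero(minorTree)
  if (majorCn == minorCn && labm < labM) {  # unordered allele pair
    tmp <- majorTree; majorTree <- minorTree; minorTree <- tmp
    tmpl <- labM; labM <- labm; labm <- tmpl
  }
  state <- new.env(parent = emptyenv())
  state$edges <- list(); state$params <- list(); state$nextId <- 1L
  .traverseAllele(majorTree, state)
  .traverseAllele(minorTree, state)
  edges <- if (length(state$edges)) {
    as.data.frame(do.call(rbind, state$edges))
  } else data.frame(start = integer(), end = integer(), lambda = integer())
  params <- if (length(state$params)) {
    do.call(rbind, lapply(state$params, as.data.frame))
  } else data.frame(id = integer(), phase = character(), parent = integer())
  nPre <- sum(params$phase == "pre")
  nPost <- sum(params$phase == "post")
  nFree <- sum(params$phase == "free")
  nLoss <- .countTags(majorTree, "x") + .countTags(minorTree, "x") +
    as.integer(majorCn == 0L) + as.integer(minorCn == 0L)
  nGains <- nPre + nPost + nFree
  new("GainRoute",
      label = paste(labM, labm, sep = "|"),
      majorCn = as.integer(majorCn), minorCn = as.integer(minorCn),
      wgd = wgd,
      nGainsPre = as.integer(nPre + nFree), nGainsPost = as.integer(nPost),
      nLosses = as.integer(nLoss),
      nEvents = as.integer(nGains + nLoss + as.integer(wgd)),
      nParams = nrow(params),
      params = params, edges = edges)
}

#' Signal used when a segment admits more routes than the configured cap
#'
#' @param count the canonical route count of the state.
#' @param majorCn,minorCn the state.
#' @param maxRoutes the cap that was exceeded.
#' @keywords internal
tooComplexError <- function(count, majorCn, minorCn, maxRoutes) {
  stop(structure(class = c("gainTiming_too_complex", "error", "condition"),
                 list(message = sprintf(
                   "state %d+%d admits %d routes, above the cap of %d; segment reported, not timed",
                   majorCn, minorCn, count, maxRoutes),
                   call = sys.call(-1), count = count)))
}

#' Enumerate all canonical gain routes for a copy-number state
#'
#' Generates every theoretically distinguishable history of independent
#' gains, at most one WGD, and minimally placed losses that yields the
#' allele-specific state \code{majorCn + minorCn}. Routes whose expected
#' SNV multiplicity spectra coincide as functions of the event timings are
#' merged into one canonical route. In WGD samples every route contains
#' exactly one WGD; in non-WGD samples none does.
#'
#' @param majorCn integer >= 1, copies of the more abundant parental allele.
#' @param minorCn integer in \code{0..majorCn}.
#' @param wgd logical: does the sample carry a (single) WGD?
#' @param maxRoutes route cap; states admitting more canonical routes raise
#'   a condition of class \code{"gainTiming_too_complex"} carrying the
#'   count. Complex segments above the cap are reported but never timed.
#' @return list of [GainRoute-class] objects, ordered by event count then
#'   canonical label.
#' @examples
#' length(enumerateRoutes(2, 1, wgd = FALSE))  # the single-gain route
#' r <- enumerateRoutes(3, 2, wgd = TRUE)
#' vapply(mostParsimonious(r), routeId, character(1))
#' @export
enumerateRoutes <- function(majorCn, minorCn, wgd, maxRoutes = 500L) {
  majorCn <- as.integer(majorCn); minorCn <- as.integer(minorCn)
  stopifnot(majorCn >= 1L, minorCn >= 0L, minorCn <= majorCn)
  count <- countRoutes(majorCn, minorCn, wgd)
  if (count > maxRoutes) tooComplexError(count, majorCn, minorCn, maxRoutes)
  va <- .alleleVariants(majorCn, wgd)
  vb <- .alleleVariants(minorCn, wgd)
  routes <- list()
  if (majorCn == minorCn) {
    for (i in seq_along(va)) for (j in i:length(vb))
      routes[[length(routes) + 1L]] <-
        makeRoute(va[[i]], vb[[j]], majorCn, minorCn, wgd)
  } else {
    for (i in seq_along(va)) for (j in seq_along(vb))
      routes[[length(routes) + 1L]] <-
        makeRoute(va[[i]], vb[[j]], majorCn, minorCn, wgd)
  }
  ev <- vapply(routes, function(r) r@nEvents, integer(1))
  lab <- vapply(routes, function(r) r@label, character(1))
  routes[order(ev, lab)]
}

#' Count canonical gain routes for a copy-number state
#'
#' Same combinatorial object as [enumerateRoutes()] but computed by a
#' counting recursion, so states above the route cap still return their
#' count.
#'
#' @inheritParams enumerateRoutes
#' @return integer route count.
#' @export
countRoutes <- function(majorCn, minorCn, wgd) {
  majorCn <- as.integer(majorCn); minorCn <- as.integer(minorCn)
  stopifnot(majorCn >= 1L, minorCn >= 0L, minorCn <= majorCn)
  ca <- .alleleVariantCount(majorCn, wgd)
  cb <- .alleleVariantCount(minorCn, wgd)
  if (majorCn == minorCn) .ch2(ca) else ca * cb
}

#' Most parsimonious routes of a set
#'
#' @param routes list of [GainRoute-class] for one state.
#' @return the subset attaining the minimum event count, in stable order.
#' @export
mostParsimonious <- function(routes) {
  stopifnot(length(routes) > 0L)
  ev <- vapply(routes, function(r) r@nEvents, integer(1))
  routes[ev == min(ev)]
}

#' Tabulate a route set
#'
#' @param routes list of [GainRoute-class].
#' @return data.frame with one row per route: state, canonical id, gain and
#'   loss counts, total events and a parsimonious flag. Suitable for TSV
#'   export.
#' @export
routeTable <- function(routes) {
  ev <- vapply(routes, function(r) r@nEvents, integer(1))
  data.frame(
    major_cn = vapply(routes, function(r) r@majorCn, integer(1)),
    minor_cn = vapply(routes, function(r) r@minorCn, integer(1)),
    route_id = vapply(routes, function(r) r@label, character(1)),
    n_independent_gains = vapply(routes, function(r)
      r@nGainsPre + r@nGainsPost, integer(1)),
    n_gains_pre = vapply(routes, function(r) r@nGainsPre, integer(1)),
    n_gains_post = vapply(routes, function(r) r@nGainsPost, integer(1)),
    has_wgd = vapply(routes, function(r) r@wgd, logical(1)),
    n_implied_losses = vapply(routes, function(r) r@nLosses, integer(1)),
    n_events = ev,
    parsimonious = ev == min(ev))
}
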