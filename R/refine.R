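# Conforming mesh adaptation: Rivara longest-edge bisection (with recursive
# compatibility propagation, so no hanging nodes) and recoarsening of sibling
# pairs back to their parent elements.  State is transferred by linear
# interpolation: a bisection midpoint takes the mean of its edge endpoints,
# which reproduces the P1 field exactly, so every constituent's lumped-mass
# integral is preserved exactly under refinement and under the round-trip.

# mutable working copy of mesh + state
adapt_env <- function(mesh, state) {
  e <- new.env(parent = emptyenv())
  e$ref <- mesh$ref; e$cur <- mesh$cur; e$bnd <- mesh$boundary
  e$tri <- mesh$tri; e$level <- mesh$level; e$pdef <- mesh$parent_def
  e$anc <- if (is.null(mesh$anc)) vector("list", nrow(mesh$tri)) else mesh$anc
  e$alive <- rep(TRUE, nrow(mesh$tri))
  e$half_width <- mesh$half_width
  e$N <- state$N; e$M <- state$M; e$c <- state$c; e$rho <- state$rho
  e$u <- state$u; e$v <- state$v; e$eps <- state$eps
  e$mid <- new.env(parent = emptyenv())  # edge key -> midpoint node id
  e
}

edge_key <- function(a, b) paste0(min(a, b), "_", max(a, b))

# longest edge of element t in reference coordinates; deterministic tie-break
# by (length desc, smaller node pair)
longest_edge <- function(e, t) {
  nd <- e$tri[t, ]
  pairs <- rbind(nd[c(1, 2)], nd[c(2, 3)], nd[c(3, 1)])
  len <- sqrt(rowSums((e$ref[pairs[, 1], , drop = FALSE] -
                         e$ref[pairs[, 2], , drop = FALSE])^2))
  pmin_ <- pmin(pairs[, 1], pairs[, 2]); pmax_ <- pmax(pairs[, 1], pairs[, 2])
  k <- order(-len, pmin_, pmax_)[1]
  pairs[k, ]
}

find_neighbor <- function(e, t, a, b) {
  cand <- which(e$alive)
  for (x in cand) {
    if (x == t) next
    nd <- e$tri[x, ]
    if (sum(nd == a) + sum(nd == b) == 2L) return(x)
  }
  NA_integer_
}

get_midpoint <- function(e, a, b) {
  key <- edge_key(a, b)
  if (!is.null(e$mid[[key]])) return(e$mid[[key]])
  id <- nrow(e$ref) + 1L
  e$ref <- rbind(e$ref, (e$ref[a, ] + e$ref[b, ]) / 2)
  e$cur <- rbind(e$cur, (e$cur[a, ] + e$cur[b, ]) / 2)
  hw <- e$half_width
  p <- e$ref[id, ]
  e$bnd <- c(e$bnd, abs(abs(p[1]) - hw) < 1e-9 || abs(abs(p[2]) - hw) < 1e-9)
  avg2 <- function(z) c(z, (z[a] + z[b]) / 2)
  e$N <- avg2(e$N); e$M <- avg2(e$M); e$c <- avg2(e$c); e$rho <- avg2(e$rho)
  e$u <- rbind(e$u, (e$u[a, ] + e$u[b, ]) / 2)
  e$v <- rbind(e$v, (e$v[a, ] + e$v[b, ]) / 2)
  e$eps <- rbind(e$eps, (e$eps[a, ] + e$eps[b, ]) / 2)
  e$mid[[key]] <- id
  id
}

# bisect element t on edge (a, b) with midpoint m; orientation preserved
do_bisect <- function(e, t, a, b, m) {
  nd <- e$tri[t, ]
  # rotate so the split edge occupies the first two slots
  for (r in 0:2) {
    if (nd[1] %in% c(a, b) && nd[2] %in% c(a, b)) break
    nd <- nd[c(2, 3, 1)]
  }
  k <- nd[3]
  child <- rbind(c(nd[1], m, k), c(m, nd[2], k))
  parent_anc <- list(def = e$tri[t, ], level = e$level[t],
                     pdef = e$pdef[t, ], anc = e$anc[[t]])
  e$alive[t] <- FALSE
  for (ch in 1:2) {
    e$tri <- rbind(e$tri, child[ch, ])
    e$level <- c(e$level, e$level[t] + 1L)
    e$pdef <- rbind(e$pdef, e$tri[t, ])
    e$anc[[length(e$anc) + 1L]] <- parent_anc
    e$alive <- c(e$alive, TRUE)
  }
  invisible(NULL)
}

# split element t conformingly on its longest edge, propagating to
# incompatible neighbours first (Rivara)
split_conforming <- function(e, t) {
  stack <- t
  guard <- 0L
  while (length(stack) > 0) {
    guard <- guard + 1L
    if (guard > 100000L) stop("refinement propagation did not terminate")
    x <- stack[length(stack)]
    if (!e$alive[x]) { stack <- stack[-length(stack)]; next }
    ab <- longest_edge(e, x)
    nb <- find_neighbor(e, x, ab[1], ab[2])
    if (!is.na(nb)) {
      ab_nb <- longest_edge(e, nb)
      if (!setequal(ab_nb, ab)) { stack <- c(stack, nb); next }
    }
    m <- get_midpoint(e, ab[1], ab[2])
    do_bisect(e, x, ab[1], ab[2], m)
    if (!is.na(nb)) do_bisect(e, nb, ab[1], ab[2], m)
    stack <- stack[-length(stack)]
  }
  invisible(NULL)
}

# rebuild immutable mesh/state from the working copy, dropping dead elements
# and unused nodes
adapt_collect <- function(e) {
  keep_el <- which(e$alive)
  tri <- e$tri[keep_el, , drop = FALSE]
  used <- sort(unique(as.vector(tri)))
  map <- integer(nrow(e$ref)); map[used] <- seq_along(used)
  remap3 <- function(x) {
    if (all(is.na(x))) x else map[x]
  }
  remap_anc <- function(a) {
    if (is.null(a)) return(NULL)
    a$def <- map[a$def]
    if (!all(is.na(a$pdef))) a$pdef <- map[a$pdef]
    a$anc <- remap_anc(a$anc)
    a
  }
  tri2 <- matrix(map[tri], ncol = 3)
  pdef <- e$pdef[keep_el, , drop = FALSE]
  pdef2 <- t(apply(pdef, 1, remap3))
  if (nrow(pdef) == 0) pdef2 <- matrix(NA_integer_, 0, 3)
  anc2 <- lapply(e$anc[keep_el], remap_anc)
  mesh <- list(ref = e$ref[used, , drop = FALSE],
               cur = e$cur[used, , drop = FALSE],
               tri = tri2, boundary = e$bnd[used],
               level = e$level[keep_el], parent_def = pdef2, anc = anc2,
               half_width = e$half_width)
  class(mesh) <- "graft_mesh"
  state <- list(N = e$N[used], M = e$M[used], c = e$c[used],
                rho = e$rho[used],
                u = e$u[used, , drop = FALSE], v = e$v[used, , drop = FALSE],
                eps = e$eps[used, , drop = FALSE])
  class(state) <- "state_fields"
  list(mesh = mesh, state = state)
}

# refine the flagged elements (one conforming bisection each)
refine_elements <- function(mesh, state, flags, max_level = 8L) {
  e <- adapt_env(mesh, state)
  todo <- which(flags)
  capped <- e$level[todo] >= max_level
  if (any(capped)) {
    warning("refinement level cap reached for ", sum(capped),
            " element(s); skipped")
    todo <- todo[!capped]
  }
  for (t in todo) {
    if (e$alive[t]) split_conforming(e, t)
  }
  adapt_collect(e)
}

# merge sibling pairs (both children unflagged, midpoint free) back to parents
recoarsen_elements <- function(mesh, state, unflag) {
  e <- adapt_env(mesh, state)
  has_parent <- !is.na(e$pdef[, 1])
  cand <- which(e$alive & has_parent & unflag)
  if (length(cand) == 0) return(adapt_collect(e))
  sig <- apply(e$pdef[cand, , drop = FALSE], 1, function(x)
    paste(sort(x), collapse = "_"))
  groups <- split(cand, sig)
  pairs <- Filter(function(g) length(g) == 2L, groups)
  if (length(pairs) == 0) return(adapt_collect(e))
  # midpoint of each pair: the child node absent from the parent triple
  pair_mid <- vapply(pairs, function(g) {
    setdiff(unique(as.vector(e$tri[g, ])), e$pdef[g[1], ])[1]
  }, integer(1))
  # a midpoint node may only disappear if every element using it merges now
  elems_using <- function(nd) {
    which(e$alive & (e$tri[, 1] == nd | e$tri[, 2] == nd | e$tri[, 3] == nd))
  }
  for (nd in unique(pair_mid)) {
    group <- pairs[pair_mid == nd]  # 1 pair (boundary edge) or 2 (interior)
    members <- unlist(group, use.names = FALSE)
    if (!all(e$alive[members])) next
    if (!all(elems_using(nd) %in% members)) next
    for (g in group) {
      a <- e$anc[[g[1]]]
      e$alive[g] <- FALSE
      e$tri <- rbind(e$tri, a$def)
      e$level <- c(e$level, a$level)
      e$pdef <- rbind(e$pdef,
                      if (all(is.na(a$pdef))) rep(NA_integer_, 3) else a$pdef)
      e$anc[[length(e$anc) + 1L]] <- a$anc
      e$alive <- c(e$alive, TRUE)
    }
  }
  adapt_collect(e)
}

# element-wise adaptation indicator: scaled field variation per element edge
adapt_indicator <- function(mesh, state) {
  tri <- mesh$tri
  rng <- function(z) {
    el <- cbind(z[tri[, 1]], z[tri[, 2]], z[tri[, 3]])
    span <- max(z) - min(z)
    if (span <= 0) return(rep(0, nrow(tri)))
    (apply(el, 1, max) - apply(el, 1, min)) / span
  }
  rng(state$c) + rng(state$N)
}

#' Adapt the mesh: refine where the solution varies, recoarsen where it does not
#'
#' Elements whose indicator (the element-wise variation of the signal and
#' fibroblast fields, each scaled by its global range) exceeds
#' \code{indicator_threshold} are bisected on their longest reference edge,
#' with Rivara propagation keeping the triangulation conforming; sibling
#' pairs created by earlier bisections whose indicator has dropped below a
#' quarter of the threshold are merged back to their parent.  Fields are
#' transferred by linear interpolation (exact on refinement).
#'
#' @param mesh a \code{graft_mesh}.
#' @param state a \code{state_fields}.
#' @param indicator_threshold refinement threshold (dimensionless, in (0, 2]).
#' @param max_level refinement level cap; flagged elements at the cap are
#'   skipped with a warning.
#' @param indicator optional per-element indicator overriding the default.
#' @return list with the adapted \code{mesh} and \code{state}.
#' @export
refine_recoarsen <- function(mesh, state, indicator_threshold = 0.25,
                             max_level = 2L, indicator = NULL) {
  ind <- if (is.null(indicator)) adapt_indicator(mesh, state) else indicator
  out <- list(mesh = mesh, state = state)
  if (any(ind > indicator_threshold)) {
    out <- refine_elements(mesh, state, ind > indicator_threshold,
                           max_level = max_level)
  }
  ind2 <- if (is.null(indicator)) adapt_indicator(out$mesh, out$state)
          else rep(0, nrow(out$mesh$tri))
  out <- recoarsen_elements(out$mesh, out$state,
                            ind2 < indicator_threshold / 4)
  out
}
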